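test_that("all simulator outputs are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 123, n_background_variants = 50,
                           cohort_sizes = c(MD = 30, control = 30))
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  panel <- simulate_panel(cfg)
  expect_identical(simulate_family(cfg, panel, "F1"),
                   simulate_family(cfg, panel, "F1"))
  expect_identical(simulate_cohorts(cfg, panel), simulate_cohorts(cfg, panel))
})

test_that("member-keyed random streams do not leak across members", {
  cfg <- simulation_config(seed = 3, n_background_variants = 40)
  panel <- simulate_panel(cfg)
  fam <- simulate_family(cfg, panel, "F1")
  fam_other <- simulate_family(cfg, panel, "F2")
  # same master seed, different family key -> different genotypes
  expect_false(identical(fam$calls$zygosity, fam_other$calls$zygosity))
})

test_that("an empty background leaves only the causal record", {
  cfg <- simulation_config(seed = 1, n_background_variants = 0)
  panel <- simulate_panel(cfg)
  expect_equal(nrow(panel), 1L)
  expect_true(panel$causal)
  expect_equal(panel$gene, "RAB12")
  expect_equal(panel$consequence, "missense")
})

test_that("panel frequencies follow the configured spectrum", {
  sp <- af_spectrum()
  cfg <- simulation_config(seed = 8, n_background_variants = 10000,
                           spectrum = sp)
  panel <- simulate_panel(cfg)
  af <- panel$panel_af[!panel$causal]
  expect_true(all(af >= 0 & af <= sp$scale))
  # empirical mean within a 99% CI of the exact mixture mean
  se <- sqrt(spectrum_var(sp) / length(af))
  expect_lt(abs(mean(af) - spectrum_mean(sp)), qnorm(0.995) * se)
  # point mass at zero is realized
  expect_gt(mean(af == 0), 0.15)
  expect_lt(mean(af == 0), 0.25)
})

test_that("transmission is Mendelian in every seeded family", {
  dose_of <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  for (seed in 1:200) {
    cfg <- simulation_config(seed = seed, n_background_variants = 10,
                             n_children = 2)
    panel <- simulate_panel(cfg)
    fam <- simulate_family(cfg, panel, "F")
    wide <- tidyr::pivot_wider(fam$calls, names_from = "sample_id",
                               values_from = "zygosity")
    gf <- dose_of[wide$F_F]; gm <- dose_of[wide$F_M]
    for (ch in c("F_C1", "F_C2")) {
      gc <- dose_of[wide[[ch]]]
      # a child cannot carry more alleles than its parents can donate,
      # nor fewer than homozygous parents force
      expect_true(all(gc <= (gf > 0) + (gm > 0)))
      expect_true(all(gc >= (gf == 2) + (gm == 2)))
    }
  }
})

test_that("affection sampling follows penetrance and phenocopy rules", {
  # full penetrance, no phenocopies: affected iff carrier
  cfg <- simulation_config(seed = 21, penetrance = 1, phenocopy_rate = 0,
                           n_background_variants = 0, n_children = 6)
  panel <- simulate_panel(cfg)
  fam <- simulate_family(cfg, panel, "F")
  aff <- fam$pedigree$members$affection == "affected"
  expect_equal(unname(aff), unname(fam$carrier))

  # phenocopy rate 1: every non-carrier is affected, and the segregation
  # report flags exactly the non-carriers as phenocopy candidates
  cfg2 <- simulation_config(seed = 22, penetrance = 1, phenocopy_rate = 1,
                            n_background_variants = 0, n_children = 6)
  panel2 <- simulate_panel(cfg2)
  fam2 <- simulate_family(cfg2, panel2, "F")
  expect_true(all(fam2$pedigree$members$affection == "affected"))
  rep <- segregation_report(panel2$key[panel2$causal], fam2$pedigree,
                            fam2$calls)
  expect_setequal(rep$phenocopy_candidates,
                  names(fam2$carrier)[!fam2$carrier])
})

test_that("cohort genotypes respect Hardy-Weinberg at large n", {
  sp <- af_spectrum(prob_zero = 0, shape1 = 1, shape2 = 1, scale = 0.5)
  cfg <- simulation_config(seed = 9, n_background_variants = 1,
                           spectrum = sp,
                           cohort_sizes = c(control = 10000),
                           case_carrier_freq = 0, control_carrier_freq = 0)
  panel <- simulate_panel(cfg)
  panel$panel_af[!panel$causal] <- 0.2
  coh <- simulate_cohorts(cfg, panel)
  bg_key <- panel$key[!panel$causal]
  sub <- coh$calls[coh$calls$key == bg_key, ]
  n_het <- sum(sub$zygosity == "het")
  n_hom <- sum(sub$zygosity == "hom_alt")
  n <- nrow(coh$individuals)
  n_ref <- n - n_het - n_hom
  probs <- c(0.64, 0.32, 0.04)
  counts <- c(n_ref, n_het, n_hom)
  for (i in 1:3) {
    se <- sqrt(n * probs[i] * (1 - probs[i]))
    expect_lt(abs(counts[i] - n * probs[i]), 3 * se)
  }
})

test_that("cohort carrier enrichment matches the configured frequencies", {
  cfg <- simulation_config(seed = 14, n_background_variants = 0,
                           cohort_sizes = c(MD = 4000, control = 4000),
                           case_carrier_freq = 0.05,
                           control_carrier_freq = 0.01)
  coh <- simulate_cohorts(cfg)
  carriers <- coh$calls$sample_id[coh$calls$zygosity == "het"]
  md <- startsWith(carriers, "MD")
  expect_lt(abs(sum(md) / 4000 - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
  expect_lt(abs(sum(!md) / 4000 - 0.01), 3 * sqrt(0.01 * 0.99 / 4000))
  # empty configuration yields empty outputs
  empty <- simulate_cohorts(simulation_config(cohort_sizes = c(MD = 0)))
  expect_equal(nrow(empty$individuals), 0L)
  expect_equal(nrow(empty$calls), 0L)
})

test_that("closed-form survivor expectation handles the degenerate cases", {
  cfg0 <- simulation_config(fraction_protein_changing = 0,
                            n_background_variants = 100)
  expect_equal(expected_background_survivors(cfg0), 0)
  # all variants private and hypothetically carried by everyone: the
  # rarity and sharing factors are 1, leaving count x P(protein-changing)
  sp0 <- af_spectrum(prob_zero = 1)
  cfg1 <- simulation_config(spectrum = sp0, n_background_variants = 100,
                            fraction_protein_changing = 0.4)
  expect_equal(expected_background_survivors(cfg1, carry_prob = 1),
               100 * 0.4)
})

test_that("fixture bundles round-trip through the readers", {
  cfg <- simulation_config(seed = 77, n_families = 2, n_children = 3,
                           n_background_variants = 40,
                           penetrance = 1, phenocopy_rate = 0,
                           cohort_sizes = c(MD = 20, control = 20))
  dir <- file.path(tempdir(), "bundle77")
  paths <- write_fixture_bundle(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))

  vcf <- read_vcf(paths$families_vcf)
  ann <- read_annotation_table(paths$annotation)
  peds <- read_ped(paths$families_ped)
  expect_length(peds, 2L)
  expect_equal(nrow(vcf$variants), 41L)
  expect_setequal(vcf$variants$key, ann$key)
  # the written genotypes are the simulated ones
  panel <- simulate_panel(cfg)
  fam <- simulate_family(cfg, panel, "FAM1")
  merged <- merge(as.data.frame(vcf$calls), as.data.frame(fam$calls),
                  by = c("sample_id", "key"))
  expect_equal(merged$zygosity.x, merged$zygosity.y)
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$seed, 77L)
})
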