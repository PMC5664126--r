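test_that("consequence filter keeps protein-changing classes only", {
  v <- variants_fixture(4)
  v$consequence <- c("missense", "synonymous", "intronic", "splice_site")
  out <- apply_consequence_filter(v)
  expect_equal(out$consequence, c("missense", "splice_site"))
  # idempotent, order preserving
  expect_equal(apply_consequence_filter(out), out)
})

test_that("frequency filter is strict and honours the missing-af policy", {
  v <- variants_fixture(4)
  v$panel_af <- c(0.0003, 0.05, NA, 0.01)
  keep_cfg <- filter_config()
  out <- apply_frequency_filter(v, keep_cfg)
  expect_equal(out$panel_af, c(0.0003, NA)) # 0.01 fails the strict <
  drop_cfg <- filter_config(missing_af_policy = "drop")
  expect_equal(apply_frequency_filter(v, drop_cfg)$panel_af, 0.0003)
  expect_error(filter_config(maf_threshold = 1.5), "maf_threshold")
})

test_that("sharing requires every affected member to carry the variant", {
  fam <- family_fixture(child_affection = c("affected", "affected"),
                        founder_affection = c("affected", "unaffected"))
  v <- variants_fixture(1)
  k <- v$key
  all_het <- calls_fixture(c("dad", "kid1", "kid2"), k,
                           c("het", "het", "het"))
  expect_equal(nrow(shared_among_affected(fam, all_het, v)), 1L)

  one_ref <- calls_fixture(c("dad", "kid1", "kid2"), k,
                           c("het", "het", "hom_ref"))
  expect_equal(nrow(shared_among_affected(fam, one_ref, v)), 0L)

  # zygosity class is irrelevant: a homozygous carrier still shares
  hom <- calls_fixture(c("dad", "kid1", "kid2"), k,
                       c("hom_alt", "het", "het"))
  expect_equal(nrow(shared_among_affected(fam, hom, v)), 1L)

  # unaffected / unknown members impose no constraint
  mum_ref <- calls_fixture(c("dad", "mum", "kid1", "kid2"), k,
                           c("het", "hom_ref", "het", "het"))
  expect_equal(nrow(shared_among_affected(fam, mum_ref, v)), 1L)
})

test_that("missing genotypes in affecteds follow the configured policy", {
  fam <- family_fixture(child_affection = c("affected", "affected"),
                        founder_affection = c("unaffected", "unaffected"))
  v <- variants_fixture(1)
  partial <- calls_fixture(c("kid1", "kid2"), v$key, c("het", "missing"))
  expect_equal(nrow(shared_among_affected(fam, partial, v)), 0L)
  ignore_cfg <- filter_config(missing_genotype_policy = "ignore")
  expect_equal(nrow(shared_among_affected(fam, partial, v, ignore_cfg)), 1L)
  # an affected with no call row at all counts as missing too
  absent <- calls_fixture("kid1", v$key, "het")
  expect_equal(nrow(shared_among_affected(fam, absent, v)), 0L)
  expect_equal(nrow(shared_among_affected(fam, absent, v, ignore_cfg)), 1L)
})

test_that("a family without affected members is rejected", {
  fam <- family_fixture(child_affection = c("unaffected", "unknown"),
                        founder_affection = c("unaffected", "unknown"))
  v <- variants_fixture(1)
  expect_error(shared_among_affected(fam, empty_calls_tbl(), v), "FAM1")
})

test_that("cascade stage counts match an independent set-operation oracle", {
  for (seed in c(11, 12, 13)) {
    cfg <- simulation_config(seed = seed, penetrance = 1, phenocopy_rate = 0,
                             n_background_variants = 300)
    panel <- simulate_panel(cfg)
    fam <- simulate_family(cfg, panel, "FAM1")
    fcfg <- filter_config()
    res <- run_family_cascade(fam$pedigree, panel, fam$calls, fcfg)
    oracle <- oracle_cascade_counts(fam$pedigree, panel, fam$calls, fcfg)
    expect_equal(res$stage_counts, oracle$counts)
    expect_setequal(res$final_variants, oracle$final)
    # monotone and bounded by the input set
    expect_true(all(diff(res$stage_counts) <= 0))
    expect_true(all(res$final_variants %in% panel$key))
  }
})

test_that("cascade is invariant under permutation of the variant list", {
  cfg <- simulation_config(seed = 5, penetrance = 1, phenocopy_rate = 0,
                           n_background_variants = 120)
  panel <- simulate_panel(cfg)
  fam <- simulate_family(cfg, panel, "FAM1")
  res <- run_family_cascade(fam$pedigree, panel, fam$calls)
  set.seed(99)
  shuffled <- panel[sample.int(nrow(panel)), ]
  res2 <- run_family_cascade(fam$pedigree, shuffled, fam$calls)
  expect_equal(res2$stage_counts, res$stage_counts)
  expect_setequal(res2$final_variants, res$final_variants)
})

test_that("empty variant input gives all-zero stage counts", {
  fam <- family_fixture()
  v <- variants_fixture(0)
  res <- run_family_cascade(fam, v, empty_calls_tbl())
  expect_equal(res$stage_counts, rep(0L, 5L))
  expect_length(res$final_variants, 0L)
})

test_that("cross-family intersection finds genes shared by enough families", {
  lookup <- tibble::tibble(
    key = c("k1", "k2", "k3", "k4", "k5"),
    gene = c("RAB12", "RAB12", "MUC4", "MUC4", "OTHER"))
  mk <- function(fid, keys) {
    structure(list(family_id = fid, stage_names = "input",
                   stage_counts = length(keys), final_variants = keys),
              class = "cascade_result")
  }
  res <- list(mk("A", c("k1", "k5")), mk("B", "k3"),
              mk("C", "k2"), mk("D", "k4"))
  cand <- cross_family_candidates(res, lookup)
  expect_equal(cand$shared_genes, c("MUC4", "RAB12"))
  expect_equal(cand$gene_families$RAB12, c("A", "C"))
  expect_equal(cand$gene_families$MUC4, c("B", "D"))

  disjoint <- cross_family_candidates(list(mk("A", "k1"), mk("B", "k3")),
                                      lookup)
  expect_equal(disjoint$shared_genes, character(0))

  expect_error(cross_family_candidates(list(mk("A", "unknown_key")), lookup),
               "unknown_key")
})

test_that("segregation report flags phenocopies and unaffected carriers", {
  # trio with an affected father who carries two reference alleles and a
  # mildly affected mother carrying the variant homozygously
  trio <- pedigree("FAMD", tibble::tibble(
    id = c("father", "mother", "patient"),
    father_id = c(NA, NA, "father"),
    mother_id = c(NA, NA, "mother"),
    sex = c("male", "female", "male"),
    affection = c("affected", "affected", "affected")))
  k <- "18:8609447:A:G"
  calls <- calls_fixture(c("father", "mother", "patient"), k,
                         c("hom_ref", "hom_alt", "het"))
  rep <- segregation_report(k, trio, calls)
  expect_equal(rep$phenocopy_candidates, "father")
  expect_equal(rep$homozygous_carriers, "mother")
  expect_length(rep$reduced_penetrance_carriers, 0L)
  expect_equal(unname(rep$status[c("father", "mother", "patient")]),
               c("hom_ref", "hom_alt", "het"))

  # unaffected carrier mother -> reduced-penetrance flag
  fam <- family_fixture(child_affection = "affected",
                        founder_affection = c("affected", "unaffected"))
  calls2 <- calls_fixture(c("dad", "mum", "kid1"), variants_fixture(1)$key,
                          c("het", "het", "het"))
  rep2 <- segregation_report(variants_fixture(1)$key, fam, calls2)
  expect_equal(rep2$reduced_penetrance_carriers, "mum")

  # all reference, nobody affected -> nothing flagged
  fam3 <- family_fixture(child_affection = "unaffected",
                         founder_affection = c("unaffected", "unaffected"))
  calls3 <- calls_fixture(c("dad", "mum", "kid1"), variants_fixture(1)$key,
                          rep("hom_ref", 3))
  rep3 <- segregation_report(variants_fixture(1)$key, fam3, calls3)
  expect_length(rep3$phenocopy_candidates, 0L)
  expect_length(rep3$reduced_penetrance_carriers, 0L)
  expect_length(rep3$homozygous_carriers, 0L)

  # missing call -> not_determined, never flagged
  calls4 <- calls_fixture(c("dad", "mum", "kid1"), variants_fixture(1)$key,
                          c("missing", "het", "het"))
  fam4 <- family_fixture(child_affection = "affected",
                         founder_affection = c("affected", "unknown"))
  rep4 <- segregation_report(variants_fixture(1)$key, fam4, calls4)
  expect_equal(unname(rep4$status["dad"]), "not_determined")
  expect_false("dad" %in% rep4$phenocopy_candidates)
  expect_equal(rep4$reduced_penetrance_carriers, "mum") # unknown + carrier
})

test_that("planted causal variants are recovered under full penetrance", {
  hits <- 0L
  n_rep <- 30L
  for (seed in seq_len(n_rep)) {
    cfg <- simulation_config(seed = seed, penetrance = 1, phenocopy_rate = 0,
                             causal_af = 0, n_background_variants = 60)
    panel <- simulate_panel(cfg)
    fam <- simulate_family(cfg, panel, "FAM1")
    res <- run_family_cascade(fam$pedigree, panel, fam$calls)
    hits <- hits + (panel$key[panel$causal] %in% res$final_variants)
  }
  expect_equal(hits, n_rep)
})

empty_calls_tbl <- function() {
  tibble::tibble(sample_id = character(), key = character(),
                 zygosity = character())
}
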