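# Seeded generator for pedigrees, cohorts and VCF/PED/annotation fixtures
# with the statistical structure the analysis assumes: a background
# allele-frequency spectrum, one planted causal variant, Mendelian
# transmission, configurable penetrance/phenocopy, and case/control
# carrier enrichment.

#' Allele-frequency spectrum for background variants
#'
#' Mixture of a point mass at zero (variants absent from the reference
#' panel, i.e. novel) and a scaled Beta component on `(0, scale]`. The Beta
#' shape defaults skew the mass toward low frequencies, as in an exome-like
#' rare-variant spectrum.
#'
#' @param prob_zero Weight of the point mass at frequency 0.
#' @param shape1,shape2 Beta shape parameters of the continuous component.
#' @param scale Upper bound of the continuous component (frequencies live
#'   on `(0, scale]`; default 0.5).
#' @return Object of class `af_spectrum`.
#' @export
af_spectrum <- function(prob_zero = 0.2, shape1 = 0.5, shape2 = 5,
                        scale = 0.5) {
  stopifnot(prob_zero >= 0, prob_zero <= 1, shape1 > 0, shape2 > 0,
            scale > 0, scale <= 1)
  structure(list(prob_zero = prob_zero, shape1 = shape1, shape2 = shape2,
                 scale = scale), class = "af_spectrum")
}

#' @rdname af_spectrum
#' @param sp An `af_spectrum`.
#' @param n Number of draws.
#' @return `spectrum_draw`: numeric vector of frequencies.
#' @export
spectrum_draw <- function(sp, n) {
  zero <- stats::runif(n) < sp$prob_zero
  af <- sp$scale * stats::rbeta(n, sp$shape1, sp$shape2)
  ifelse(zero, 0, af)
}

#' @rdname af_spectrum
#' @return `spectrum_mean` / `spectrum_var`: the exact mean and variance of
#'   the mixture; `spectrum_cdf`: `P(af < q)` (strict, matching the rarity
#'   filter).
#' @export
spectrum_mean <- function(sp) {
  (1 - sp$prob_zero) * sp$scale * sp$shape1 / (sp$shape1 + sp$shape2)
}

#' @rdname af_spectrum
#' @export
spectrum_var <- function(sp) {
  s1 <- sp$shape1; s2 <- sp$shape2
  e2 <- (1 - sp$prob_zero) * sp$scale^2 * s1 * (s1 + 1) /
    ((s1 + s2) * (s1 + s2 + 1))
  e2 - spectrum_mean(sp)^2
}

#' @rdname af_spectrum
#' @param q Threshold.
#' @export
spectrum_cdf <- function(sp, q) {
  if (q <= 0) return(0)
  sp$prob_zero + (1 - sp$prob_zero) *
    stats::pbeta(q / sp$scale, sp$shape1, sp$shape2)
}

# consequence class mix used by the generator; protein-changing classes
# and their conditional probabilities, likewise for the non-changing rest
protein_class_probs <- c(missense = 0.70, nonsense = 0.10, frameshift = 0.10,
                         inframe_indel = 0.05, splice_site = 0.05)
neutral_class_probs <- c(synonymous = 0.40, intronic = 0.30, utr = 0.20,
                         intergenic = 0.10)

#' Simulation configuration
#'
#' Defaults mirror the motivating study design: a handful of small
#' autosomal-dominant families for discovery, screening cohorts of 241
#' musician's dystonia (MD), 74 writer's dystonia (WD), 604 other-dystonia,
#' 512 Parkinson's disease and 461 healthy-control individuals, and a
#' planted causal missense variant that is absent from the reference panel.
#' Penetrance below one and a small phenocopy rate reproduce the imperfect
#' segregation dominant dystonia pedigrees show (unaffected carriers,
#' affected non-carriers).
#'
#' @param seed Integer master seed; every derived stream is keyed on it, so
#'   a fixed seed fully determines all outputs.
#' @param n_families Number of discovery families.
#' @param n_children Offspring per (two-founder) nuclear family.
#' @param n_background_variants Background variants in the panel.
#' @param spectrum An [af_spectrum()] for background panel frequencies.
#' @param fraction_protein_changing Probability that a background variant
#'   is protein-changing.
#' @param causal_gene Gene symbol carrying the planted causal variant.
#' @param causal_af Panel frequency of the causal variant (default 0:
#'   novel).
#' @param penetrance P(affected | causal carrier).
#' @param phenocopy_rate P(affected | non-carrier).
#' @param cohort_sizes Named integer vector of screening cohort sizes.
#' @param case_cohorts Cohort labels counted as cases.
#' @param case_carrier_freq,control_carrier_freq Probability that a case /
#'   control individual is a heterozygous causal carrier; defaults are the
#'   carrier frequencies observed in the motivating screen (10/916 and
#'   1/973).
#' @param n_genes Size of the background gene pool (default: one gene per
#'   three background variants, so cross-family gene hits are possible).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_families = 2L,
                              n_children = 4L,
                              n_background_variants = 200L,
                              spectrum = af_spectrum(),
                              fraction_protein_changing = 0.4,
                              causal_gene = "RAB12",
                              causal_af = 0,
                              penetrance = 0.8,
                              phenocopy_rate = 0.05,
                              cohort_sizes = c(MD = 241L, WD = 74L,
                                               other_dystonia = 604L,
                                               PD = 512L, control = 461L),
                              case_cohorts = c("MD", "WD", "other_dystonia"),
                              case_carrier_freq = 10 / 916,
                              control_carrier_freq = 1 / 973,
                              n_genes = NULL) {
  stopifnot(inherits(spectrum, "af_spectrum"),
            fraction_protein_changing >= 0, fraction_protein_changing <= 1,
            causal_af >= 0, causal_af <= 1,
            penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1,
            case_carrier_freq >= 0, case_carrier_freq <= 1,
            control_carrier_freq >= 0, control_carrier_freq <= 1,
            n_families >= 0, n_children >= 0, n_background_variants >= 0,
            all(cohort_sizes >= 0))
  if (is.null(n_genes)) {
    n_genes <- max(1L, ceiling(n_background_variants / 3))
  }
  structure(list(
    seed = as.integer(seed),
    n_families = as.integer(n_families),
    n_children = as.integer(n_children),
    n_background_variants = as.integer(n_background_variants),
    spectrum = spectrum,
    fraction_protein_changing = fraction_protein_changing,
    causal_gene = causal_gene,
    causal_af = causal_af,
    penetrance = penetrance,
    phenocopy_rate = phenocopy_rate,
    cohort_sizes = cohort_sizes,
    case_cohorts = case_cohorts,
    case_carrier_freq = case_carrier_freq,
    control_carrier_freq = control_carrier_freq,
    n_genes = as.integer(n_genes)
  ), class = "simulation_config")
}

# Deterministic sub-stream seed from the master seed and string tokens:
# a 31-multiplier rolling hash modulo a Mersenne prime, kept below 2^31.
# Streams are keyed per (purpose, family, member), so draws for one member
# do not shift when variants are appended for another.
derive_seed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647L)
  for (tok in as.character(c(...))) {
    for (code in utf8ToInt(tok)) h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Simulate the annotated variant panel
#'
#' Draws `n_background_variants` background records (panel frequency from
#' the spectrum, consequence class protein-changing with probability
#' `fraction_protein_changing`, gene symbols from a finite pool) plus one
#' causal missense record in `causal_gene` at `causal_af`. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return Annotated variant tibble (columns as from [annotate_variants()])
#'   with a logical `causal` column; the causal record is last.
#' @export
simulate_panel <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "panel"))
  nv <- cfg$n_background_variants
  bases <- c("A", "C", "G", "T")
  if (nv > 0) {
    chrom <- as.character(sample(1:22, nv, replace = TRUE))
    pos <- sample.int(5e7, nv, replace = FALSE)
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    gene <- sprintf("GENE%04d", sample.int(cfg$n_genes, nv, replace = TRUE))
    protein <- stats::runif(nv) < cfg$fraction_protein_changing
    consequence <- ifelse(
      protein,
      sample(names(protein_class_probs), nv, replace = TRUE,
             prob = protein_class_probs),
      sample(names(neutral_class_probs), nv, replace = TRUE,
             prob = neutral_class_probs))
    af <- spectrum_draw(cfg$spectrum, nv)
    bg <- tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                         alt = alt, rsid = NA_character_, gene = gene,
                         consequence = consequence, panel_af = af,
                         causal = FALSE)
  } else {
    bg <- NULL
  }
  causal <- tibble::tibble(chrom = "18", pos = 8609447L, ref = "A", alt = "G",
                           rsid = NA_character_, gene = cfg$causal_gene,
                           consequence = "missense", panel_af = cfg$causal_af,
                           causal = TRUE)
  panel <- dplyr::bind_rows(bg, causal)
  panel$key <- variant_key(panel$chrom, panel$pos, panel$ref, panel$alt)
  dplyr::relocate(panel, "key")
}

#' Simulate one nuclear family with a planted causal variant
#'
#' Two founders plus `cfg$n_children` offspring. The father founder is a
#' heterozygous causal carrier; the mother is a non-carrier. Transmission
#' is Mendelian (each parental allele passed with probability one half,
#' independently per child and per variant). Background genotypes are drawn
#' per founder from the panel frequency under Hardy-Weinberg and inherited
#' Mendelianly by the children. Affection is sampled independently per
#' member: carriers are affected with probability `penetrance`,
#' non-carriers with probability `phenocopy_rate`.
#'
#' @param cfg A [simulation_config()].
#' @param panel Panel tibble from [simulate_panel()] (must contain exactly
#'   one `causal` row).
#' @param family_id Family identifier (also keys the random sub-streams).
#' @return List with `pedigree` (a [pedigree()]), `calls` (genotype tibble)
#'   and `carrier` (named logical: causal carrier status per member).
#' @export
simulate_family <- function(cfg, panel, family_id = "FAM1") {
  stopifnot(sum(panel$causal) == 1L)
  causal_key <- panel$key[panel$causal]
  bg <- panel[!panel$causal, ]
  father <- paste0(family_id, "_F")
  mother <- paste0(family_id, "_M")
  children <- if (cfg$n_children > 0) {
    paste0(family_id, "_C", seq_len(cfg$n_children))
  } else character(0)

  nv <- nrow(bg)
  geno <- list() # background alt-allele dosage per member
  set.seed(derive_seed(cfg$seed, family_id, father))
  geno[[father]] <- stats::rbinom(nv, 2L, bg$panel_af)
  set.seed(derive_seed(cfg$seed, family_id, mother))
  geno[[mother]] <- stats::rbinom(nv, 2L, bg$panel_af)
  causal_dosage <- c(1L, 0L)
  names(causal_dosage) <- c(father, mother)
  for (ch in children) {
    set.seed(derive_seed(cfg$seed, family_id, ch))
    geno[[ch]] <- stats::rbinom(nv, 1L, geno[[father]] / 2) +
      stats::rbinom(nv, 1L, geno[[mother]] / 2)
    causal_dosage[ch] <- stats::rbinom(1L, 1L, causal_dosage[father] / 2) +
      stats::rbinom(1L, 1L, causal_dosage[mother] / 2)
  }

  ids <- c(father, mother, children)
  carrier <- causal_dosage[ids] > 0
  set.seed(derive_seed(cfg$seed, family_id, "affection"))
  p_aff <- ifelse(carrier, cfg$penetrance, cfg$phenocopy_rate)
  affected <- stats::runif(length(ids)) < p_aff

  members <- tibble::tibble(
    id = ids,
    father_id = c(NA, NA, rep(father, length(children))),
    mother_id = c(NA, NA, rep(mother, length(children))),
    sex = c("male", "female",
            rep_len(c("male", "female"), length(children))),
    affection = ifelse(affected, "affected", "unaffected"),
    cohort = "MD"
  )
  ped <- pedigree(family_id, members)

  zyg_of <- c("hom_ref", "het", "hom_alt")
  calls <- dplyr::bind_rows(lapply(ids, function(i) {
    tibble::tibble(
      sample_id = i,
      key = c(bg$key, causal_key),
      zygosity = zyg_of[c(geno[[i]], causal_dosage[i]) + 1L]
    )
  }))
  list(pedigree = ped, calls = calls, carrier = carrier)
}

#' Simulate screening cohorts with configurable carrier enrichment
#'
#' Each case-cohort individual carries the causal variant heterozygously
#' with probability `case_carrier_freq`, control-cohort individuals with
#' `control_carrier_freq`. Background genotypes are drawn under
#' Hardy-Weinberg from the panel frequencies. Only non-reference and
#' missing calls are emitted (the tally functions treat absent pairs as
#' genotyped reference).
#'
#' @param cfg A [simulation_config()].
#' @param panel Panel tibble from [simulate_panel()], or NULL to simulate
#'   the causal variant only.
#' @return List with `individuals` (roster tibble: `id`, `cohort`,
#'   `is_index`) and `calls` (sparse genotype tibble).
#' @export
simulate_cohorts <- function(cfg, panel = NULL) {
  sizes <- cfg$cohort_sizes[cfg$cohort_sizes > 0]
  if (length(sizes) == 0L) {
    return(list(individuals = tibble::tibble(id = character(),
                                             cohort = character(),
                                             is_index = logical()),
                calls = empty_calls()))
  }
  cohorts <- names(sizes)
  individuals <- tibble::tibble(
    id = unlist(lapply(cohorts, function(co) {
      sprintf("%s_%05d", co, seq_len(sizes[[co]]))
    }), use.names = FALSE),
    cohort = rep(cohorts, times = as.integer(sizes)),
    is_index = TRUE
  )
  causal_key <- if (is.null(panel)) {
    variant_key("18", 8609447L, "A", "G")
  } else {
    panel$key[panel$causal][1]
  }
  zyg_of <- c("hom_ref", "het", "hom_alt")
  calls <- lapply(cohorts, function(co) {
    set.seed(derive_seed(cfg$seed, "cohort", co))
    n <- sizes[[co]]
    ids <- individuals$id[individuals$cohort == co]
    freq <- if (co %in% cfg$case_cohorts) cfg$case_carrier_freq
            else cfg$control_carrier_freq
    causal_carrier <- stats::runif(n) < freq
    out <- list(tibble::tibble(
      sample_id = ids[causal_carrier],
      key = causal_key,
      zygosity = "het"
    ))
    if (!is.null(panel)) {
      bg <- panel[!panel$causal & panel$panel_af > 0, ]
      if (nrow(bg)) {
        dos <- matrix(stats::rbinom(length(ids) * nrow(bg), 2L,
                                    rep(bg$panel_af, each = length(ids))),
                      nrow = length(ids))
        nz <- which(dos > 0, arr.ind = TRUE)
        if (nrow(nz)) {
          out[[2]] <- tibble::tibble(
            sample_id = ids[nz[, 1]],
            key = bg$key[nz[, 2]],
            zygosity = zyg_of[dos[nz] + 1L]
          )
        }
      }
    }
    dplyr::bind_rows(out)
  })
  list(individuals = individuals, calls = dplyr::bind_rows(calls))
}

#' Closed-form expected number of background cascade survivors
#'
#' For one simulated nuclear family, the expected count of background
#' variants surviving the full cascade is the sum over background variants
#' of P(consequence qualifies) x P(rarity filter passes and every affected
#' member carries the variant). The sharing factor is computed exactly by
#' enumerating the founders' Hardy-Weinberg genotypes: a member blocks a
#' variant when it is affected and a non-carrier, affection being
#' independent of the background genotype given causal carrier status
#' (father: carrier; mother: non-carrier; child: carrier with probability
#' one half). The joint rarity-and-sharing term is integrated over the
#' allele-frequency spectrum by quadrature.
#'
#' Counts families with no affected member as "all affected carry"
#' (vacuously true); use `penetrance = 1` when comparing against cascade
#' runs, which require at least one affected member.
#'
#' @param cfg A [simulation_config()].
#' @param filter_cfg A [filter_config()].
#' @param carry_prob Optional fixed probability that all affected members
#'   carry a background variant, overriding the pedigree model (e.g. 1 for
#'   a hypothetical variant heterozygous in everyone).
#' @return Expected survivor count (a real number).
#' @export
expected_background_survivors <- function(cfg, filter_cfg = filter_config(),
                                          carry_prob = NULL) {
  nv <- cfg$n_background_variants
  if (nv == 0L) return(0)
  # P(consequence in the protein-changing set), from the generator's mix
  p_prot <- sum(protein_class_probs[
    names(protein_class_probs) %in% filter_cfg$protein_changing_classes])
  p_neut <- sum(neutral_class_probs[
    names(neutral_class_probs) %in% filter_cfg$protein_changing_classes])
  p_cons <- cfg$fraction_protein_changing * p_prot +
    (1 - cfg$fraction_protein_changing) * p_neut

  sp <- cfg$spectrum
  thr <- filter_cfg$maf_threshold
  if (!is.null(carry_prob)) {
    p_joint <- spectrum_cdf(sp, thr) * carry_prob
    return(nv * p_cons * p_joint)
  }

  pen <- cfg$penetrance
  phen <- cfg$phenocopy_rate
  k <- cfg$n_children
  a_child <- (pen + phen) / 2 # E P(affected) for a child, causal ~ Bern(1/2)

  share_given_af <- function(p) {
    # vectorized over p; enumerate founder genotypes gf, gm in {0,1,2}
    vapply(p, function(pp) {
      gprob <- stats::dbinom(0:2, 2L, pp)
      total <- 0
      for (gf in 0:2) for (gm in 0:2) {
        bf <- as.numeric(gf > 0)
        bm <- as.numeric(gm > 0)
        cp <- 1 - (1 - gf / 2) * (1 - gm / 2) # P(child carries bg variant)
        fac <- (1 - pen * (1 - bf)) *    # father: causal carrier
          (1 - phen * (1 - bm)) *        # mother: non-carrier
          (1 - a_child * (1 - cp))^k
        total <- total + gprob[gf + 1] * gprob[gm + 1] * fac
      }
      total
    }, numeric(1))
  }

  p_joint <- sp$prob_zero * as.numeric(thr > 0) * share_given_af(0)
  if (sp$prob_zero < 1 && thr > 0) {
    upper <- min(1, thr / sp$scale)
    cont <- stats::integrate(function(u) {
      share_given_af(sp$scale * u) * stats::dbeta(u, sp$shape1, sp$shape2)
    }, lower = 0, upper = upper, rel.tol = 1e-9)$value
    p_joint <- p_joint + (1 - sp$prob_zero) * cont
  }
  nv * p_cons * p_joint
}

#' Write a complete simulated fixture bundle to a directory
#'
#' Emits the dialects the readers consume: one VCF and one PED over all
#' family members, a cohort VCF and roster TSV, the annotation TSV, and a
#' JSON manifest recording the seed and file checksums.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(cfg)
  fams <- lapply(seq_len(cfg$n_families), function(i) {
    simulate_family(cfg, panel, sprintf("FAM%d", i))
  })
  paths <- list(
    annotation = file.path(dir, "annotation.tsv"),
    families_vcf = file.path(dir, "families.vcf"),
    families_ped = file.path(dir, "families.ped"),
    cohort_vcf = file.path(dir, "cohorts.vcf"),
    cohort_roster = file.path(dir, "cohort_roster.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  ann <- dplyr::select(panel, "chrom", "pos", "ref", "alt", "gene",
                       "consequence", "panel_af")
  utils::write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fam_calls <- dplyr::bind_rows(lapply(fams, `[[`, "calls"))
  variants <- dplyr::select(panel, "chrom", "pos", "ref", "alt", "rsid", "key")
  write_vcf(variants, fam_calls, paths$families_vcf,
            samples = unique(fam_calls$sample_id))
  write_ped(lapply(fams, `[[`, "pedigree"), paths$families_ped)
  coh <- simulate_cohorts(cfg, panel)
  write_vcf(variants, coh$calls, paths$cohort_vcf,
            samples = coh$individuals$id)
  utils::write.table(coh$individuals, paths$cohort_roster, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    tool = "famscreen",
    version = as.character(utils::packageVersion("famscreen")),
    seed = cfg$seed,
    n_families = cfg$n_families,
    files = lapply(paths[names(paths) != "manifest"], function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
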