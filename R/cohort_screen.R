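# Per-cohort carrier tallies, formatted allele frequencies, carrier
# summaries, and construction of the 2x2 burden table.

#' Qualifying-variant predicate used in cohort screening
#'
#' The default screening rule: a variant qualifies when it is a missense
#' change that is rare in the reference panel. Returns a function suitable
#' for the `qualifying` argument of [tally_carriers()] and friends.
#'
#' @param maf_threshold Strict upper bound on `panel_af` (default 0.01).
#' @param keep_missing_af Treat an absent panel frequency as rare
#'   (default TRUE; a variant never seen in the panel is novel).
#' @param classes Consequence classes that qualify (default `"missense"`).
#' @return Function mapping a variant tibble to a logical vector.
#' @export
qualifying_missense <- function(maf_threshold = 0.01, keep_missing_af = TRUE,
                                classes = "missense") {
  force(maf_threshold); force(keep_missing_af); force(classes)
  function(variants) {
    af <- variants$panel_af
    rare <- !is.na(af) & af < maf_threshold
    if (keep_missing_af) rare <- rare | is.na(af)
    variants$consequence %in% classes & rare
  }
}

#' Tally carriers and allele counts per (variant, cohort)
#'
#' For each qualifying variant and each cohort: the number of genotyped
#' individuals, the number of carriers (het or hom_alt), the alternate
#' allele count (het + 2 x hom_alt), the total allele count
#' (2 x genotyped) and the formatted allele-frequency string
#' `"alt_alleles/total_alleles"` (e.g. `"3/482"`).
#'
#' Individuals with an explicitly missing call at a variant are excluded
#' from that variant's genotyped denominator. Individuals with no call row
#' at all are treated according to `absent`: as genotyped reference
#' (default, so sparse carrier-only call sets work) or as missing.
#'
#' @param individuals Roster tibble with `id` and `cohort` for every
#'   screened individual.
#' @param variants Annotated variant tibble.
#' @param calls Genotype call tibble; every `sample_id` must appear in the
#'   roster.
#' @param qualifying Predicate from [qualifying_missense()] (the default),
#'   another such function, or NULL to tally every variant.
#' @param absent How to count roster individuals with no call row at a
#'   variant: `"hom_ref"` (default) or `"missing"`.
#' @return Tibble of class `carrier_table`, one row per (key, cohort).
#' @export
tally_carriers <- function(individuals, variants, calls,
                           qualifying = qualifying_missense(),
                           absent = c("hom_ref", "missing")) {
  absent <- match.arg(absent)
  stopifnot(all(c("id", "cohort") %in% names(individuals)))
  unknown <- setdiff(unique(calls$sample_id), individuals$id)
  if (length(unknown)) {
    stop("call(s) for individual(s) absent from the cohort roster: ",
         paste(unknown, collapse = ", "))
  }
  keep <- if (is.null(qualifying)) rep(TRUE, nrow(variants))
          else qualifying(variants)
  keys <- unique(variants$key[keep])
  cohorts <- unique(individuals$cohort)
  if (length(keys) == 0L || nrow(individuals) == 0L) {
    out <- tibble::tibble(key = character(), cohort = character(),
                          n_genotyped = integer(), carriers = integer(),
                          alt_alleles = integer(), total_alleles = integer(),
                          af_string = character())
    class(out) <- c("carrier_table", class(out))
    return(out)
  }
  cohort_of <- stats::setNames(individuals$cohort, individuals$id)
  n_by_cohort <- table(factor(individuals$cohort, levels = cohorts))
  sub <- calls[calls$key %in% keys, ]
  sub$cohort <- unname(cohort_of[sub$sample_id])

  grid <- tidyr::expand_grid(key = keys, cohort = cohorts)
  agg <- sub |>
    dplyr::group_by(.data$key, .data$cohort) |>
    dplyr::summarise(
      n_listed = dplyr::n(),
      n_missing = sum(.data$zygosity == "missing"),
      carriers = sum(.data$zygosity %in% c("het", "hom_alt")),
      alt_alleles = sum((.data$zygosity == "het") +
                          2L * (.data$zygosity == "hom_alt")),
      .groups = "drop"
    )
  out <- dplyr::left_join(grid, agg, by = c("key", "cohort")) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0L)))
  roster_n <- as.integer(n_by_cohort[out$cohort])
  out$n_genotyped <- if (absent == "hom_ref") {
    roster_n - out$n_missing
  } else {
    out$n_listed - out$n_missing
  }
  out$total_alleles <- 2L * out$n_genotyped
  out$af_string <- paste0(out$alt_alleles, "/", out$total_alleles)
  out <- dplyr::select(out, "key", "cohort", "n_genotyped", "carriers",
                       "alt_alleles", "total_alleles", "af_string")
  stopifnot(all(out$carriers <= out$n_genotyped),
            all(out$alt_alleles >= out$carriers),
            all(out$alt_alleles <= 2L * out$carriers))
  class(out) <- c("carrier_table", class(out))
  out
}

#' Half-up rounding
#'
#' Rounds halves away from zero at the given number of digits (0.25 -> 0.3
#' at one decimal), unlike base `round()`'s round-half-even. A tolerance of
#' 1e-9 absorbs binary floating-point representation error in the half.
#'
#' @param x Numeric vector (non-negative use case).
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

#' Half-up percentage
#'
#' `100 * k / n` rounded half-up, matching how screening percentages are
#' usually printed.
#'
#' @param n_carriers,n_individuals Counts, `n_individuals > 0`.
#' @param decimals Decimal places (default 1).
#' @return Numeric percentage.
#' @export
percent_half_up <- function(n_carriers, n_individuals, decimals = 1L) {
  if (any(n_individuals <= 0)) stop("n_individuals must be positive")
  round_half_up(100 * n_carriers / n_individuals, decimals)
}

#' Format a carrier percentage string
#'
#' @inheritParams percent_half_up
#' @return String such as `"1.1%"`.
#' @examples
#' carrier_percent(10, 916) # "1.1%"
#' carrier_percent(1, 973)  # "0.1%"
#' @export
carrier_percent <- function(n_carriers, n_individuals, decimals = 1L) {
  p <- percent_half_up(n_carriers, n_individuals, decimals)
  paste0(formatC(p, format = "f", digits = decimals), "%")
}

#' Individual-level carrier summary per cohort group
#'
#' Counts, per group of cohorts, the individuals carrying at least one of
#' the given qualifying variants. An individual carrying two different
#' qualifying variants is counted once (individual-level burden), in
#' contrast to the per-variant allele counts of [tally_carriers()].
#'
#' @param individuals Roster tibble with `id`, `cohort`, optionally
#'   `is_index` (logical).
#' @param calls Genotype call tibble.
#' @param variant_keys Keys of the qualifying variants.
#' @param groups Named list mapping group label to cohort labels; default:
#'   one group per cohort.
#' @param exclude Ids to drop from numerators and denominators (e.g.
#'   members of the discovery families); additionally, when the roster has
#'   an `is_index` column, only index patients enter the denominators
#'   unless `index_only = FALSE`.
#' @param index_only Restrict to index patients when an `is_index` column
#'   is present (default TRUE).
#' @param decimals Decimal places for the percent string.
#' @return Tibble with `group`, `n_individuals`, `n_carriers`,
#'   `percent_string`.
#' @export
carrier_summary <- function(individuals, calls, variant_keys, groups = NULL,
                            exclude = NULL, index_only = TRUE,
                            decimals = 1L) {
  ind <- individuals
  if (!is.null(exclude)) ind <- ind[!ind$id %in% exclude, ]
  if (index_only && "is_index" %in% names(ind)) {
    ind <- ind[is.na(ind$is_index) | ind$is_index, ]
  }
  if (is.null(groups)) {
    groups <- stats::setNames(as.list(unique(ind$cohort)), unique(ind$cohort))
  }
  carrier_ids <- unique(calls$sample_id[
    calls$key %in% variant_keys & calls$zygosity %in% c("het", "hom_alt")])
  dplyr::bind_rows(lapply(names(groups), function(g) {
    members <- ind$id[ind$cohort %in% groups[[g]]]
    n <- length(members)
    k <- sum(members %in% carrier_ids)
    tibble::tibble(
      group = g, n_individuals = n, n_carriers = k,
      percent_string = if (n > 0) carrier_percent(k, n, decimals)
                       else NA_character_
    )
  }))
}

#' Build the 2x2 carrier burden table
#'
#' Rows are case and control groups, columns carrier and non-carrier
#' counts: `[[cases_carriers, cases_n - cases_carriers],
#' [ctrl_carriers, ctrl_n - ctrl_carriers]]`.
#'
#' @param cases_carriers,cases_n Carrier count and group size for cases.
#' @param ctrl_carriers,ctrl_n Same for controls.
#' @return Integer 2x2 matrix with informative dimnames.
#' @examples
#' build_burden_table(10, 916, 1, 973)
#' @export
build_burden_table <- function(cases_carriers, cases_n,
                               ctrl_carriers, ctrl_n) {
  m <- matrix(as.integer(c(cases_carriers, cases_n - cases_carriers,
                           ctrl_carriers, ctrl_n - ctrl_carriers)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("carrier", "non_carrier")))
  if (any(m < 0)) stop("negative cell in burden table: carriers exceed n?")
  m
}

#' Write a variant-by-cohort allele-frequency table (wide TSV)
#'
#' One row per qualifying variant, one allele-fraction column per cohort,
#' with annotation columns (gene, consequence, HGVS and predictor scores if
#' present) passed through.
#'
#' @param carrier_table Result of [tally_carriers()].
#' @param path Output path.
#' @param annotation Optional annotation tibble to join by `key`.
#' @return `path`, invisibly.
#' @export
write_carrier_table_tsv <- function(carrier_table, path, annotation = NULL) {
  wide <- carrier_table |>
    dplyr::select("key", "cohort", "af_string") |>
    tidyr::pivot_wider(names_from = "cohort", values_from = "af_string",
                       names_prefix = "af_")
  if (!is.null(annotation)) {
    ann <- dplyr::select(annotation,
                         -dplyr::any_of(c("chrom", "pos", "ref", "alt")))
    wide <- dplyr::left_join(wide, dplyr::distinct(ann, .data$key,
                                                   .keep_all = TRUE),
                             by = "key")
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-carrier listing (long TSV)
#'
#' One row per (carrier, variant), with all roster columns (sex, onset age,
#' phenotype, family history, ethnicity, ...) passed through untouched.
#'
#' @param individuals Roster tibble with `id` plus any clinical columns.
#' @param calls Genotype call tibble.
#' @param variant_keys Qualifying variant keys.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_carrier_listing_tsv <- function(individuals, calls, variant_keys,
                                      path) {
  hits <- calls[calls$key %in% variant_keys &
                  calls$zygosity %in% c("het", "hom_alt"), ]
  tab <- dplyr::inner_join(
    dplyr::select(hits, id = "sample_id", "key", "zygosity"),
    individuals, by = "id")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
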