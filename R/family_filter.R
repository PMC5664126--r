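# Per-family discovery procedure: consequence filter, rarity filter,
# sharing among affected members, cross-family candidate-gene intersection,
# and per-variant segregation reporting.

default_exonic_splicing <- c("missense", "synonymous", "nonsense", "frameshift",
                             "inframe_indel", "splice_site")
default_protein_changing <- c("missense", "nonsense", "frameshift",
                              "inframe_indel", "splice_site")

#' Configuration of the family filter cascade
#'
#' @param maf_threshold Panel allele frequency below which a variant counts
#'   as rare (strict `<`); default 0.01, i.e. the "known frequency < 1%"
#'   rule.
#' @param exonic_splicing_classes Consequence classes counted as exonic or
#'   splicing.
#' @param protein_changing_classes Consequence classes that change the
#'   protein (synonymous is excluded); must be a subset of
#'   `exonic_splicing_classes` plus `splice_site`.
#' @param missing_af_policy What to do with a variant whose panel frequency
#'   is unknown: `"keep"` (default; a variant absent from the panel is novel
#'   and certainly rare) or `"drop"`.
#' @param missing_genotype_policy When an affected member has a missing call
#'   at a variant: `"fail_sharing"` (default, conservative — the variant is
#'   removed) or `"ignore"` (that member imposes no constraint).
#' @param min_families_shared Minimum number of families whose surviving
#'   variants must hit a gene for it to be a cross-family candidate.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          exonic_splicing_classes = default_exonic_splicing,
                          protein_changing_classes = default_protein_changing,
                          missing_af_policy = c("keep", "drop"),
                          missing_genotype_policy = c("fail_sharing", "ignore"),
                          min_families_shared = 2L) {
  missing_af_policy <- match.arg(missing_af_policy)
  missing_genotype_policy <- match.arg(missing_genotype_policy)
  if (!is.numeric(maf_threshold) || length(maf_threshold) != 1L ||
      is.na(maf_threshold) || maf_threshold < 0 || maf_threshold > 1) {
    stop("maf_threshold must be a single number in [0, 1]")
  }
  stopifnot(all(exonic_splicing_classes %in% consequence_classes),
            all(protein_changing_classes %in% consequence_classes))
  extra <- setdiff(protein_changing_classes,
                   union(exonic_splicing_classes, "splice_site"))
  if (length(extra)) {
    stop("protein_changing_classes must be contained in ",
         "exonic_splicing_classes plus splice_site; offending: ",
         paste(extra, collapse = ", "))
  }
  structure(list(
    maf_threshold = maf_threshold,
    exonic_splicing_classes = exonic_splicing_classes,
    protein_changing_classes = protein_changing_classes,
    missing_af_policy = missing_af_policy,
    missing_genotype_policy = missing_genotype_policy,
    min_families_shared = as.integer(min_families_shared)
  ), class = "filter_config")
}

#' Keep protein-changing (exonic/splicing) variants
#'
#' Fuses the "exonic or splicing" and "affects the amino acid sequence"
#' steps: a variant survives iff its consequence class is in
#' `cfg$protein_changing_classes`. Input order is preserved and the
#' operation is idempotent.
#'
#' @param variants Annotated variant tibble (needs a `consequence` column).
#' @param cfg A [filter_config()].
#' @return Filtered variant tibble.
#' @export
apply_consequence_filter <- function(variants, cfg = filter_config()) {
  variants[variants$consequence %in% cfg$protein_changing_classes, ,
           drop = FALSE]
}

#' Keep rare variants
#'
#' A variant survives iff `panel_af < cfg$maf_threshold` (strict). Variants
#' with no panel frequency are kept under the default `"keep"` policy —
#' a variant never seen in the reference panel cannot be common — or removed
#' under `"drop"`.
#'
#' @inheritParams apply_consequence_filter
#' @return Filtered variant tibble.
#' @export
apply_frequency_filter <- function(variants, cfg = filter_config()) {
  af <- variants$panel_af
  keep <- !is.na(af) & af < cfg$maf_threshold
  if (cfg$missing_af_policy == "keep") keep <- keep | is.na(af)
  variants[keep, , drop = FALSE]
}

#' Keep variants shared among all definitely affected family members
#'
#' A variant survives iff every member with affection status `affected`
#' carries it (zygosity `het` or `hom_alt`; zygosity class is irrelevant to
#' sharing, so a homozygous carrier counts). Members with `unknown` or
#' `unaffected` status impose no constraint. An affected member with a
#' missing genotype fails the variant under the default `fail_sharing`
#' policy and is skipped under `ignore`. Individuals with no call row at a
#' variant are treated as missing.
#'
#' @param family A [pedigree()].
#' @param calls Genotype call tibble (`sample_id`, `key`, `zygosity`).
#' @param variants Variant tibble to filter.
#' @param cfg A [filter_config()].
#' @return Filtered variant tibble.
#' @export
shared_among_affected <- function(family, calls, variants,
                                  cfg = filter_config()) {
  affected <- family$members$id[family$members$affection == "affected"]
  if (length(affected) == 0L) {
    stop("family ", family$family_id, " has no affected member; ",
         "the sharing filter is undefined")
  }
  if (nrow(variants) == 0L) return(variants)
  zyg <- zygosity_matrix(calls, affected, variants$key)
  carrier <- zyg == "het" | zyg == "hom_alt"
  if (cfg$missing_genotype_policy == "ignore") {
    carrier <- carrier | zyg == "missing"
  }
  keep <- apply(carrier, 1L, all)
  variants[keep, , drop = FALSE]
}

# dense zygosity matrix (variants x samples), absent pairs -> "missing"
zygosity_matrix <- function(calls, sample_ids, keys) {
  zyg <- matrix("missing", nrow = length(keys), ncol = length(sample_ids),
                dimnames = list(keys, sample_ids))
  sub <- calls[calls$sample_id %in% sample_ids & calls$key %in% keys, ]
  if (nrow(sub)) {
    zyg[cbind(match(sub$key, keys), match(sub$sample_id, sample_ids))] <-
      sub$zygosity
  }
  zyg
}

#' Run the full per-family filter cascade
#'
#' Stages, in order: `input` (all annotated variants), `exonic_splicing`
#' (consequence in the exonic/splicing set — reported for transparency),
#' `protein_changing` (consequence filter), `rare` (panel frequency
#' filter), `shared_affected` (sharing filter). Stage counts are
#' non-increasing and the final variant set is the set of survivors.
#'
#' @param family A [pedigree()].
#' @param variants Annotated variant tibble for this family's samples.
#' @param calls Genotype call tibble.
#' @param cfg A [filter_config()].
#' @return Object of class `cascade_result` with `family_id`,
#'   `stage_names`, `stage_counts` and `final_variants` (character keys).
#' @export
run_family_cascade <- function(family, variants, calls,
                               cfg = filter_config()) {
  v0 <- variants
  v1 <- v0[v0$consequence %in% cfg$exonic_splicing_classes, , drop = FALSE]
  v2 <- apply_consequence_filter(v1, cfg)
  v3 <- apply_frequency_filter(v2, cfg)
  v4 <- shared_among_affected(family, calls, v3, cfg)
  structure(list(
    family_id = family$family_id,
    stage_names = c("input", "exonic_splicing", "protein_changing",
                    "rare", "shared_affected"),
    stage_counts = c(nrow(v0), nrow(v1), nrow(v2), nrow(v3), nrow(v4)),
    final_variants = unique(v4$key)
  ), class = "cascade_result")
}

#' @exportS3Method base::print
print.cascade_result <- function(x, ...) {
  cat("<cascade_result> family ", x$family_id, "\n", sep = "")
  for (i in seq_along(x$stage_names)) {
    cat(sprintf("  %-16s %d\n", x$stage_names[i], x$stage_counts[i]))
  }
  invisible(x)
}

#' Intersect surviving variants across families at the gene level
#'
#' Implements the hypothesis that independently ascertained families share a
#' mutation in the same gene: maps each gene hit by any family's surviving
#' variants to the set of families hitting it, and marks as shared the genes
#' hit by at least `cfg$min_families_shared` families.
#'
#' @param results List of `cascade_result` objects (one per family).
#' @param gene_lookup Tibble mapping `key` to `gene` (e.g. the annotation
#'   table); a key may map to several genes, each counted separately.
#' @param cfg A [filter_config()].
#' @return Object of class `candidate_gene_map` with `gene_families` (named
#'   list, gene -> sorted family ids), `shared_genes` (lexicographically
#'   sorted) and `variant_keys` (named list, gene -> keys).
#' @export
cross_family_candidates <- function(results, gene_lookup,
                                    cfg = filter_config()) {
  stopifnot(length(results) >= 1L)
  rows <- dplyr::bind_rows(lapply(results, function(r) {
    if (length(r$final_variants) == 0L) return(NULL)
    tibble::tibble(family_id = r$family_id, key = r$final_variants)
  }))
  gene_families <- list()
  variant_keys <- list()
  if (!is.null(rows) && nrow(rows)) {
    lk <- dplyr::distinct(gene_lookup[, c("key", "gene")])
    absent <- setdiff(rows$key, lk$key)
    if (length(absent)) {
      stop("surviving variant key(s) absent from the gene lookup: ",
           paste(absent, collapse = ", "))
    }
    hits <- dplyr::inner_join(rows, lk, by = "key",
                              relationship = "many-to-many")
    gene_families <- lapply(split(hits$family_id, hits$gene),
                            function(f) sort(unique(f)))
    variant_keys <- lapply(split(hits$key, hits$gene),
                           function(k) sort(unique(k)))
  }
  shared <- names(gene_families)[
    vapply(gene_families, length, integer(1)) >= cfg$min_families_shared]
  structure(list(
    gene_families = gene_families[order(names(gene_families))],
    shared_genes = sort(shared),
    variant_keys = variant_keys[order(names(variant_keys))],
    min_families_shared = cfg$min_families_shared
  ), class = "candidate_gene_map")
}

#' @exportS3Method base::print
print.candidate_gene_map <- function(x, ...) {
  cat("<candidate_gene_map> ", length(x$gene_families), " gene(s), ",
      length(x$shared_genes), " shared by >= ", x$min_families_shared,
      " families\n", sep = "")
  for (g in x$shared_genes) {
    cat("  ", g, ": ", paste(x$gene_families[[g]], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

seg_symbols <- c(hom_alt = "+/+", het = "+/-", hom_ref = "-/-",
                 not_determined = "?")

#' Segregation report for one variant in one family
#'
#' Assigns every family member a carrier status (`+/+` homozygous carrier,
#' `+/-` heterozygous carrier, `-/-` non-carrier, `?` not determined) and
#' flags the configurations that break perfect dominant segregation:
#' affected non-carriers (phenocopy candidates) and unaffected or
#' unknown-status carriers (reduced-penetrance carriers). Members with
#' missing calls are `not_determined` and never flagged.
#'
#' @param variant_key Canonical key of the variant.
#' @param family A [pedigree()].
#' @param calls Genotype call tibble.
#' @return Object of class `segregation_report` with `status` (named
#'   character vector over member ids), `phenocopy_candidates`,
#'   `reduced_penetrance_carriers` and `homozygous_carriers`.
#' @export
segregation_report <- function(variant_key, family, calls) {
  ids <- family$members$id
  zyg <- zygosity_matrix(calls, ids, variant_key)[1, , drop = TRUE]
  status <- ifelse(zyg == "missing", "not_determined", zyg)
  names(status) <- ids
  aff <- stats::setNames(family$members$affection, ids)
  carrier <- status %in% c("het", "hom_alt")
  structure(list(
    variant_key = variant_key,
    family_id = family$family_id,
    status = status,
    phenocopy_candidates = ids[aff == "affected" & status == "hom_ref"],
    reduced_penetrance_carriers = ids[aff %in% c("unaffected", "unknown") & carrier],
    homozygous_carriers = ids[status == "hom_alt"]
  ), class = "segregation_report")
}

#' @exportS3Method base::print
print.segregation_report <- function(x, ...) {
  cat("<segregation_report> ", x$variant_key, " in family ", x$family_id,
      "\n", sep = "")
  cat("  ", paste(names(x$status), seg_symbols[x$status], sep = ":",
                  collapse = "  "), "\n", sep = "")
  if (length(x$phenocopy_candidates)) {
    cat("  phenocopy candidates: ",
        paste(x$phenocopy_candidates, collapse = ", "), "\n", sep = "")
  }
  if (length(x$reduced_penetrance_carriers)) {
    cat("  reduced-penetrance carriers: ",
        paste(x$reduced_penetrance_carriers, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write cascade results as a long TSV (family_id, stage, count)
#' @param results List of `cascade_result` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_tsv <- function(results, path) {
  tab <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(family_id = r$family_id, stage = r$stage_names,
                   count = r$stage_counts)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a candidate-gene map as TSV (gene, n_families, family_ids, variant_keys)
#' @param map A `candidate_gene_map`.
#' @param path Output path.
#' @param shared_only Write only the shared genes (default TRUE).
#' @return `path`, invisibly.
#' @export
write_candidate_tsv <- function(map, path, shared_only = TRUE) {
  genes <- if (shared_only) map$shared_genes else names(map$gene_families)
  tab <- tibble::tibble(
    gene = genes,
    n_families = vapply(map$gene_families[genes], length, integer(1)),
    family_ids = vapply(map$gene_families[genes], paste,
                        character(1), collapse = ","),
    variant_keys = vapply(map$variant_keys[genes], paste,
                          character(1), collapse = ",")
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write segregation reports as TSV using +/+, +/-, -/- notation
#' @param reports List of `segregation_report` objects.
#' @param path Output path.
#' @param peds Optional list of pedigrees to add affection status columns.
#' @return `path`, invisibly.
#' @export
write_segregation_tsv <- function(reports, path, peds = NULL) {
  aff_lookup <- NULL
  if (!is.null(peds)) {
    ind <- ped_individuals(peds)
    aff_lookup <- stats::setNames(ind$affection, ind$id)
  }
  tab <- dplyr::bind_rows(lapply(reports, function(r) {
    tibble::tibble(
      variant_key = r$variant_key,
      family_id = r$family_id,
      individual = names(r$status),
      affection = if (is.null(aff_lookup)) NA_character_
                  else unname(aff_lookup[names(r$status)]),
      status = unname(seg_symbols[r$status]),
      phenocopy_candidate = names(r$status) %in% r$phenocopy_candidates,
      reduced_penetrance_carrier =
        names(r$status) %in% r$reduced_penetrance_carriers
    )
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
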