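# Reading and writing of the standard formats the pipeline touches:
# VCF v4.2 (via vcfR), 6/7-column PED, annotation and cohort TSV sidecars.

#' Consequence classes recognized by the annotation model
#'
#' Variant consequences are collapsed to a fixed vocabulary; anything not in
#' this set is mapped to `"other"` when an annotation table is read.
#'
#' @format Character vector of the ten recognized class labels.
#' @export
consequence_classes <- c(
  "missense", "synonymous", "nonsense", "frameshift", "inframe_indel",
  "splice_site", "intronic", "intergenic", "utr", "other"
)

zygosity_levels <- c("hom_ref", "het", "hom_alt", "missing")

#' Build a canonical variant key
#'
#' Keys are `chrom:pos:ref:alt` with the allele pair reduced to its minimal
#' representation (shared suffix then shared prefix trimmed, position
#' adjusted), so that VCF records and annotation-table rows that spell the
#' same indel differently still match.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of keys.
#' @examples
#' variant_key("18", 8609447, "A", "G")
#' variant_key("1", 100, "CAT", "CT") # right-trim, then left-trim
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  norm <- normalize_alleles(pos, ref, alt)
  paste(chrom, norm$pos, norm$ref, norm$alt, sep = ":")
}

# Minimal representation of an allele pair: trim shared trailing bases, then
# shared leading bases (keeping >= 1 base each), bumping pos for each leading
# base removed. Full left-alignment needs the reference sequence and is out
# of scope; minimal representation is enough to match keys across sources.
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- length(ref)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Read a VCF file into the internal variant/genotype model
#'
#' Multi-allelic records are split into one biallelic record per alternate
#' allele. A genotype call is produced for every sample x split variant:
#' the zygosity counts copies of that particular alternate allele, so a
#' `1/2` genotype becomes `het` for both split records and allele dosage is
#' conserved. Missing (`./.`), half-called and non-diploid genotypes map to
#' `missing`.
#'
#' @param path Path to a VCF v4.2 file (plain or gzipped).
#' @return A list with two tibbles:
#' \describe{
#'   \item{variants}{`chrom`, `pos`, `ref`, `alt`, `rsid`, `key`.}
#'   \item{calls}{`sample_id`, `key`, `zygosity` in
#'     `hom_ref`/`het`/`hom_alt`/`missing`.}
#' }
#' @seealso [write_vcf()], [read_annotation_table()]
#' @export
read_vcf <- function(path) {
  stopifnot(file.exists(path))
  validate_vcf_columns(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) {
    return(list(variants = empty_variants(), calls = empty_calls()))
  }
  gt <- v@gt # NULL when the file has no sample columns
  samples <- if (is.null(gt)) character(0) else colnames(gt)[-1L]

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt_field <- as.character(fix[, "ALT"])
  rsid <- as.character(fix[, "ID"])
  rsid[rsid %in% c(".", "")] <- NA_character_

  alt_list <- strsplit(alt_field, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_idx <- rep(seq_along(chrom), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  alt <- unlist(alt_list, use.names = FALSE)

  variants <- tibble::tibble(
    chrom = chrom[row_idx],
    pos = pos[row_idx],
    ref = ref[row_idx],
    alt = alt,
    rsid = rsid[row_idx]
  )
  bad <- variants$ref == variants$alt
  if (any(bad)) {
    stop("REF equals ALT for record(s) at position(s): ",
         paste(variants$pos[bad], collapse = ", "))
  }
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)

  if (length(samples) == 0L) {
    return(list(variants = variants, calls = empty_calls()))
  }

  # allele-count matrix per original record x sample, then expand per ALT
  gt_strings <- sub(":.*$", "", gt[, samples, drop = FALSE])
  calls <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    g <- gt_strings[, s]
    zyg <- character(length(row_idx))
    for (k in seq_along(row_idx)) {
      zyg[k] <- gt_to_zygosity(g[row_idx[k]], alt_idx[k])
    }
    calls[[s]] <- tibble::tibble(
      sample_id = samples[s],
      key = variants$key,
      zygosity = zyg
    )
  }
  list(variants = variants, calls = dplyr::bind_rows(calls))
}

# zygosity of one GT string with respect to ALT allele number `allele`
gt_to_zygosity <- function(gt, allele) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  parts <- strsplit(gt, "[/|]")[[1]]
  if (length(parts) != 2L || any(parts == ".")) return("missing") # half/non-diploid
  suppressWarnings(alleles <- as.integer(parts))
  if (anyNA(alleles)) return("missing")
  dosage <- sum(alleles == allele)
  c("hom_ref", "het", "hom_alt")[dosage + 1L]
}

validate_vcf_columns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) == 0L) stop("not a VCF: no #CHROM header line in ", path)
  n_fields <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != n_fields) {
      stop("malformed VCF line ", i, " in ", path, ": expected ", n_fields,
           " tab-separated fields, found ", nf)
    }
  }
  invisible(TRUE)
}

empty_variants <- function() {
  tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), rsid = character(), key = character())
}

empty_calls <- function() {
  tibble::tibble(sample_id = character(), key = character(),
                 zygosity = character())
}

#' Write biallelic variants and genotype calls as VCF v4.2
#'
#' One record per (already biallelic) variant. Samples are the union of
#' `calls$sample_id` unless given; pairs absent from `calls` are written as
#' `0/0`, `missing` zygosities as `./.`.
#'
#' @param variants Tibble as returned by [read_vcf()] (needs `chrom`, `pos`,
#'   `ref`, `alt`, `key`; `rsid` optional).
#' @param calls Tibble with `sample_id`, `key`, `zygosity`.
#' @param path Output path.
#' @param samples Optional character vector fixing the sample columns and
#'   their order.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, calls, path, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  rsid <- if ("rsid" %in% names(variants)) variants$rsid else NA_character_
  rsid <- ifelse(is.na(rsid), ".", rsid)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  gt_of <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  gt_mat <- matrix("0/0", nrow = nrow(variants), ncol = length(samples),
                   dimnames = list(NULL, samples))
  if (length(samples) && nrow(calls)) {
    ri <- match(calls$key, variants$key)
    ci <- match(calls$sample_id, samples)
    ok <- !is.na(ri) & !is.na(ci)
    gt_mat[cbind(ri[ok], ci[ok])] <- gt_of[calls$zygosity[ok]]
  }
  body <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    fields <- c(variants$chrom[i], variants$pos[i], rsid[i], variants$ref[i],
                variants$alt[i], ".", "PASS", ".",
                if (length(samples)) c("GT", gt_mat[i, ]))
    body[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant annotation table (TSV sidecar)
#'
#' Annotation (gene, consequence class, panel allele frequency, optional
#' external predictor scores) lives in a tab-separated sidecar rather than in
#' the VCF INFO field, keeping the pipeline independent of any particular
#' annotator dialect.
#'
#' @param path TSV with required columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `panel_af`; any further columns are carried
#'   through untouched as predictor scores.
#' @return Tibble keyed by `key` with one row per (variant, gene).
#'   `panel_af` is numeric in `[0, 1]` or `NA`; unknown consequence strings
#'   are mapped to `"other"`. A variant key annotated with conflicting gene
#'   symbols in duplicate rows raises an error naming the key (a key may
#'   legitimately appear once per overlapping gene).
#' @export
read_annotation_table <- function(path) {
  stopifnot(file.exists(path))
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "panel_af")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols)) {
    stop("annotation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ann <- tibble::as_tibble(ann)
  ann$pos <- as.integer(ann$pos)
  ann$consequence <- tolower(trimws(ann$consequence))
  ann$consequence[!ann$consequence %in% consequence_classes] <- "other"
  af <- trimws(ann$panel_af)
  af[af == ""] <- NA_character_
  ann$panel_af <- as.numeric(af)
  out_of_range <- !is.na(ann$panel_af) & (ann$panel_af < 0 | ann$panel_af > 1)
  if (any(out_of_range)) {
    stop("panel_af outside [0, 1] in annotation row(s): ",
         paste(which(out_of_range), collapse = ", "))
  }
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann <- dplyr::distinct(ann) # idempotent duplicates collapse

  dup <- ann |>
    dplyr::count(.data$key, .data$gene) |>
    dplyr::count(.data$key, name = "n_genes")
  # multiple genes per key are allowed (each counted separately); what is
  # forbidden is the same (key, gene) pair with conflicting other fields
  conflict <- ann |>
    dplyr::count(.data$key, .data$gene) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflict)) {
    stop("conflicting duplicate annotation for variant key(s): ",
         paste(unique(conflict$key), collapse = ", "))
  }
  dplyr::relocate(ann, "key")
}

#' Attach annotation to a variant table
#'
#' Left-joins annotation columns onto variants by `key`. A variant key
#' annotated to several genes yields one row per gene (each gene is counted
#' separately downstream).
#'
#' @param variants Tibble from [read_vcf()].
#' @param annotation Tibble from [read_annotation_table()].
#' @return Annotated variant tibble with `gene`, `consequence`, `panel_af`
#'   and any predictor columns; unannotated variants get `NA` gene and
#'   consequence `"other"`.
#' @export
annotate_variants <- function(variants, annotation) {
  ann <- dplyr::select(annotation, -dplyr::any_of(c("chrom", "pos", "ref", "alt")))
  out <- dplyr::left_join(variants, ann, by = "key")
  out$consequence[is.na(out$consequence)] <- "other"
  out
}

#' Read a PED pedigree file
#'
#' Whitespace-delimited, six required columns (FID IID PAT MAT SEX PHENO)
#' plus an optional seventh cohort column. PHENO 2 is affected, 1
#' unaffected, 0 or -9 unknown; SEX 1 male, 2 female, otherwise unknown;
#' parent id "0" means founder. Individuals with FID "0" become one-member
#' pedigrees.
#'
#' @param path PED file path.
#' @return List of [pedigree()] objects.
#' @export
read_ped <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("PED line(s) with fewer than 6 columns: ",
         paste(which(nf < 6L), collapse = ", "))
  }
  m <- t(vapply(fields, function(f) f[1:7][1:7], character(7)))
  ind <- tibble::tibble(
    family_id = m[, 1],
    id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = dplyr::case_match(m[, 5], "1" ~ "male", "2" ~ "female",
                            .default = "unknown"),
    affection = dplyr::case_match(m[, 6], "2" ~ "affected", "1" ~ "unaffected",
                                  .default = "unknown"),
    cohort = ifelse(is.na(m[, 7]), NA_character_, m[, 7])
  )
  singleton <- ind$family_id == "0"
  ind$family_id[singleton] <- paste0("singleton_", ind$id[singleton])
  peds <- lapply(split(ind, ind$family_id), function(members) {
    pedigree(members$family_id[1], dplyr::select(members, -"family_id"))
  })
  unname(peds[unique(ind$family_id)])
}

#' Construct a pedigree
#'
#' @param family_id Family identifier.
#' @param members Tibble/data frame with columns `id`, `father_id`,
#'   `mother_id` (NA for founders), `sex`, `affection`
#'   (`affected`/`unaffected`/`unknown`); optional `cohort`.
#' @return Object of class `pedigree`. Parent references must resolve within
#'   the family (or be NA) and the parent graph must be acyclic.
#' @export
pedigree <- function(family_id, members) {
  members <- tibble::as_tibble(members)
  stopifnot(nrow(members) >= 1L,
            all(c("id", "father_id", "mother_id", "affection") %in% names(members)))
  if (!"sex" %in% names(members)) members$sex <- "unknown"
  if (!"cohort" %in% names(members)) members$cohort <- NA_character_
  bad_aff <- !members$affection %in% c("affected", "unaffected", "unknown")
  if (any(bad_aff)) {
    stop("invalid affection value(s): ",
         paste(unique(members$affection[bad_aff]), collapse = ", "))
  }
  parents <- c(members$father_id, members$mother_id)
  unresolved <- setdiff(stats::na.omit(parents), members$id)
  if (length(unresolved)) {
    stop("family ", family_id, ": parent id(s) not present in the family: ",
         paste(unresolved, collapse = ", "))
  }
  check_acyclic(members, family_id)
  structure(list(family_id = as.character(family_id), members = members),
            class = "pedigree")
}

# topological elimination: repeatedly remove individuals whose parents have
# all been removed; leftovers indicate a parentage cycle
check_acyclic <- function(members, family_id) {
  remaining <- members$id
  repeat {
    removable <- vapply(remaining, function(i) {
      row <- members[members$id == i, ]
      ok_f <- is.na(row$father_id) || !(row$father_id %in% remaining)
      ok_m <- is.na(row$mother_id) || !(row$mother_id %in% remaining)
      ok_f && ok_m
    }, logical(1))
    if (!any(removable)) break
    remaining <- remaining[!removable]
    if (length(remaining) == 0L) return(invisible(TRUE))
  }
  stop("family ", family_id, ": cyclic parentage involving: ",
       paste(remaining, collapse = ", "))
}

#' @exportS3Method base::print
print.pedigree <- function(x, ...) {
  n_aff <- sum(x$members$affection == "affected")
  cat("<pedigree> family ", x$family_id, ": ", nrow(x$members),
      " member(s), ", n_aff, " affected\n", sep = "")
  invisible(x)
}

#' Combine pedigrees into one individual roster
#'
#' @param peds List of [pedigree()] objects.
#' @return Tibble with one row per individual, including `family_id`.
#' @export
ped_individuals <- function(peds) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  dplyr::bind_rows(lapply(peds, function(p) {
    tibble::add_column(p$members, family_id = p$family_id, .before = 1)
  }))
}

#' Write pedigrees as a PED file
#'
#' @param peds List of [pedigree()] objects (or one pedigree).
#' @param path Output path.
#' @param cohort_column Write the optional seventh cohort column when any
#'   member has a cohort label (default auto).
#' @return `path`, invisibly.
#' @export
write_ped <- function(peds, path, cohort_column = NULL) {
  ind <- ped_individuals(peds)
  ind$family_id[startsWith(ind$family_id, "singleton_")] <- "0"
  sex_code <- c(male = "1", female = "2", unknown = "0")
  aff_code <- c(affected = "2", unaffected = "1", unknown = "0")
  if (is.null(cohort_column)) cohort_column <- any(!is.na(ind$cohort))
  lines <- paste(ind$family_id, ind$id,
                 ifelse(is.na(ind$father_id), "0", ind$father_id),
                 ifelse(is.na(ind$mother_id), "0", ind$mother_id),
                 sex_code[ind$sex], aff_code[ind$affection],
                 sep = "\t")
  if (cohort_column) {
    lines <- paste(lines, ifelse(is.na(ind$cohort), "NA", ind$cohort),
                   sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort membership table
#'
#' Two-column TSV (`id`, `cohort`), optionally with a logical/0-1 `is_index`
#' column flagging index patients. When both the PED seventh column and a
#' cohort table assign a cohort, the table wins.
#'
#' @param path TSV path.
#' @return Tibble with `id`, `cohort` and (if present) `is_index`.
#' @export
read_cohort_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "cohort") %in% names(tab))) {
    stop("cohort table needs columns 'id' and 'cohort'")
  }
  tab$id <- as.character(tab$id)
  tab$cohort <- as.character(tab$cohort)
  if ("is_index" %in% names(tab)) tab$is_index <- as.logical(tab$is_index)
  tibble::as_tibble(tab)
}

#' Apply cohort labels from a cohort table to an individual roster
#'
#' @param individuals Tibble with at least `id` (and possibly a `cohort`
#'   column from the PED file).
#' @param cohort_table Tibble from [read_cohort_table()], or NULL.
#' @return `individuals` with `cohort` (and `is_index` if provided) updated;
#'   table assignments override PED assignments.
#' @export
assign_cohorts <- function(individuals, cohort_table = NULL) {
  if (!"cohort" %in% names(individuals)) individuals$cohort <- NA_character_
  if (is.null(cohort_table)) return(individuals)
  idx <- match(individuals$id, cohort_table$id)
  hit <- !is.na(idx)
  individuals$cohort[hit] <- cohort_table$cohort[idx[hit]]
  if ("is_index" %in% names(cohort_table)) {
    if (!"is_index" %in% names(individuals)) individuals$is_index <- FALSE
    individuals$is_index[hit] <- cohort_table$is_index[idx[hit]]
  }
  individuals
}
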