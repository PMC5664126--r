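# In-code fixtures shared across test files. Everything is generated at
# test time; no binary data.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal VCF text fixture; `records` are pre-formatted body lines
vcf_fixture <- function(records = character(), samples = character()) {
  header_cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(samples)) c("FORMAT", samples))
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    paste(header_cols, collapse = "\t"),
    records
  ), ext = ".vcf")
}

vcf_record <- function(chrom, pos, ref, alt, gts = character(), id = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".",
          if (length(gts)) c("GT", gts)), collapse = "\t")
}

annotation_fixture <- function(rows) {
  write_lines_tmp(c(
    "chrom\tpos\tref\talt\tgene\tconsequence\tpanel_af",
    rows
  ), ext = ".tsv")
}

# a nuclear family: 2 founders, children with given affection codes
family_fixture <- function(family_id = "FAM1",
                           child_affection = c("affected", "affected",
                                               "affected"),
                           founder_affection = c("affected", "unaffected")) {
  k <- length(child_affection)
  members <- tibble::tibble(
    id = c("dad", "mum", paste0("kid", seq_len(k))),
    father_id = c(NA, NA, rep("dad", k)),
    mother_id = c(NA, NA, rep("mum", k)),
    sex = c("male", "female", rep("unknown", k)),
    affection = c(founder_affection, child_affection)
  )
  pedigree(family_id, members)
}

calls_fixture <- function(sample_ids, keys, zygosities) {
  tibble::tibble(sample_id = sample_ids, key = keys, zygosity = zygosities)
}

# annotated variant tibble straight from values (no files involved)
variants_fixture <- function(n = 5, consequence = "missense",
                             panel_af = 0, gene = NULL, chrom = "1") {
  pos <- seq_len(n) * 100L
  tibble::tibble(
    chrom = chrom,
    pos = pos,
    ref = "A",
    alt = "G",
    key = variant_key(chrom, pos, "A", "G"),
    gene = gene %||% paste0("G", seq_len(n)),
    consequence = rep_len(consequence, n),
    panel_af = rep_len(panel_af, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force cascade used as oracle: plain set operations,
# no shared code with run_family_cascade
oracle_cascade_counts <- function(family, variants, calls, cfg) {
  es <- variants[variants$consequence %in% cfg$exonic_splicing_classes, ]
  pc <- es[es$consequence %in% cfg$protein_changing_classes, ]
  rare_keep <- logical(nrow(pc))
  for (i in seq_len(nrow(pc))) {
    af <- pc$panel_af[i]
    rare_keep[i] <- if (is.na(af)) cfg$missing_af_policy == "keep"
                    else af < cfg$maf_threshold
  }
  rare <- pc[rare_keep, ]
  affected <- family$members$id[family$members$affection == "affected"]
  shared_keep <- logical(nrow(rare))
  for (i in seq_len(nrow(rare))) {
    ok <- TRUE
    for (a in affected) {
      row <- calls[calls$sample_id == a & calls$key == rare$key[i], ]
      z <- if (nrow(row) == 0) "missing" else row$zygosity[1]
      if (z == "missing") {
        if (cfg$missing_genotype_policy == "fail_sharing") ok <- FALSE
      } else if (!z %in% c("het", "hom_alt")) {
        ok <- FALSE
      }
    }
    shared_keep[i] <- ok
  }
  list(counts = c(nrow(variants), nrow(es), nrow(pc), nrow(rare),
                  sum(shared_keep)),
       final = sort(rare$key[shared_keep]))
}
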