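# The cohort layout of the motivating dystonia screen. These counts drive
# the simulator defaults and the cohort-accounting checks.

#' Cohort layout of the motivating dystonia screen
#'
#' Per-cohort subject counts broken down by assay arm (next-generation
#' sequencing, Sanger sequencing, gene panel). The row totals are the
#' per-cohort sizes used as simulator defaults; the grand total is the
#' number of screened subjects.
#'
#' @return Tibble with `cohort`, `ngs`, `sanger`, `gene_panel`, `total`.
#' @examples
#' sum(dystonia_study_cohorts()$total) # 1906
#' @export
dystonia_study_cohorts <- function() {
  tab <- tibble::tribble(
    ~cohort,                 ~ngs, ~sanger, ~gene_panel,
    "MD",                     4L,   237L,      0L,
    "MD_relatives",           6L,     8L,      0L,
    "WD",                     0L,    54L,     20L,
    "other_dystonia",         0L,   378L,    226L,
    "PD",                     0L,     0L,    512L,
    "control",                0L,   461L,      0L
  )
  tab$total <- tab$ngs + tab$sanger + tab$gene_panel
  tab
}
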