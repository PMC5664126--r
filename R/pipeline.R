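# Orchestration: YAML-configured discovery, screening and burden runs with
# report bundles and reproducibility manifests.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    stopifnot(file.exists(config))
    cfg <- yaml::read_yaml(config)
    attr(cfg, "dir") <- dirname(normalizePath(config))
    cfg
  } else if (is.list(config)) {
    if (is.null(attr(config, "dir"))) attr(config, "dir") <- getwd()
    config
  } else {
    stop("config must be a YAML file path or a list")
  }
}

resolve_path <- function(path, cfg) {
  if (is.null(path)) return(NULL)
  if (startsWith(path, "/")) path else file.path(attr(cfg, "dir"), path)
}

filter_config_from <- function(section) {
  args <- section[names(section) %in% names(formals(filter_config))]
  do.call(filter_config, args)
}

write_manifest <- function(path, inputs, outputs, params, seed = NULL) {
  manifest <- list(
    tool = "famscreen",
    version = as.character(utils::packageVersion("famscreen")),
    seed = seed,
    parameters = params,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    reports = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run family-based discovery from a config
#'
#' Reads the VCF, PED and annotation TSV named in the `discover` section of
#' the config, runs the filter cascade in every family that has at least
#' one affected member, intersects surviving variants across families at
#' the gene level, and writes a report bundle: cascade counts TSV,
#' candidate-gene TSV, a segregation TSV covering every variant of every
#' shared gene, and a JSON manifest with input/output checksums. An empty
#' candidate map is a warning, not an error.
#'
#' @param config YAML file path or equivalent list. Recognized keys under
#'   `discover`: `vcf`, `ped`, `annotation` (paths, relative to the config
#'   file), optional `cohort_table`, `out_dir`, and any [filter_config()]
#'   argument.
#' @param out_dir Output directory; overrides `discover$out_dir`
#'   (default `"discovery_reports"` next to the config).
#' @return List with `results` (per-family `cascade_result`s),
#'   `candidates` (a `candidate_gene_map`), `segregation` (list of
#'   `segregation_report`s) and `paths`, invisibly.
#' @export
run_discovery <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  sec <- cfg$discover
  if (is.null(sec)) stop("config has no 'discover' section")
  for (key in c("vcf", "ped", "annotation")) {
    if (is.null(sec[[key]])) stop("discover config is missing '", key, "'")
  }
  vcf_path <- resolve_path(sec$vcf, cfg)
  ped_path <- resolve_path(sec$ped, cfg)
  ann_path <- resolve_path(sec$annotation, cfg)
  for (p in c(vcf_path, ped_path, ann_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (is.null(out_dir)) {
    out_dir <- resolve_path(sec$out_dir %||% "discovery_reports", cfg)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fcfg <- filter_config_from(sec)

  vcf <- read_vcf(vcf_path)
  ann <- read_annotation_table(ann_path)
  peds <- read_ped(ped_path)
  variants <- annotate_variants(vcf$variants, ann)

  with_affected <- Filter(function(p) any(p$members$affection == "affected"),
                          peds)
  if (length(with_affected) == 0L) stop("no family has an affected member")
  results <- lapply(with_affected, function(ped) {
    fam_calls <- vcf$calls[vcf$calls$sample_id %in% ped$members$id, ]
    run_family_cascade(ped, variants, fam_calls, fcfg)
  })
  candidates <- cross_family_candidates(results, variants, fcfg)
  if (length(candidates$shared_genes) == 0L) {
    warning("no gene is shared by >= ", fcfg$min_families_shared,
            " families")
  }
  seg <- list()
  for (g in candidates$shared_genes) {
    for (key in candidates$variant_keys[[g]]) {
      for (ped in with_affected) {
        if (any(vcf$calls$sample_id %in% ped$members$id &
                  vcf$calls$key == key)) {
          seg[[length(seg) + 1L]] <- segregation_report(key, ped, vcf$calls)
        }
      }
    }
  }
  paths <- list(cascade = file.path(out_dir, "cascade.tsv"),
                candidates = file.path(out_dir, "candidate_genes.tsv"),
                segregation = file.path(out_dir, "segregation.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_cascade_tsv(results, paths$cascade)
  write_candidate_tsv(candidates, paths$candidates)
  write_segregation_tsv(seg, paths$segregation, peds = peds)
  write_manifest(paths$manifest,
                 inputs = list(vcf_path, ped_path, ann_path),
                 outputs = paths[c("cascade", "candidates", "segregation")],
                 params = unclass(fcfg))
  invisible(list(results = results, candidates = candidates,
                 segregation = seg, paths = paths))
}

#' Run the cohort carrier burden test from a config
#'
#' Two input modes under the `burden` config section: explicit counts
#' (`cases_carriers`, `cases_n`, `controls_carriers`, `controls_n`) or
#' file-based (`vcf`, `annotation`, `cohort_table`, `case_cohorts`,
#' `control_cohorts`, optional `exclude` ids and [qualifying_missense()]
#' arguments), in which case individual-level carriers of qualifying
#' variants are counted per group. Produces the 2x2 table, the two-tailed
#' Fisher exact p-value and formatted carrier percentages, written as a
#' JSON report.
#'
#' @param config YAML file path or equivalent list with a `burden` section.
#' @param out Optional JSON output path; overrides `burden$out`.
#' @return The report list, invisibly.
#' @export
run_burden <- function(config, out = NULL) {
  cfg <- read_run_config(config)
  sec <- cfg$burden
  if (is.null(sec)) stop("config has no 'burden' section")
  if (!is.null(sec$cases_carriers)) {
    counts <- list(
      cases_carriers = sec$cases_carriers, cases_n = sec$cases_n,
      controls_carriers = sec$controls_carriers, controls_n = sec$controls_n)
  } else {
    vcf <- read_vcf(resolve_path(sec$vcf, cfg))
    ann <- read_annotation_table(resolve_path(sec$annotation, cfg))
    roster <- read_cohort_table(resolve_path(sec$cohort_table, cfg))
    variants <- annotate_variants(vcf$variants, ann)
    qual <- qualifying_missense(
      maf_threshold = sec$maf_threshold %||% 0.01)
    keys <- unique(variants$key[qual(variants)])
    groups <- list(cases = sec$case_cohorts,
                   controls = sec$control_cohorts)
    summ <- carrier_summary(roster, vcf$calls, keys, groups = groups,
                            exclude = unlist(sec$exclude))
    counts <- list(
      cases_carriers = summ$n_carriers[summ$group == "cases"],
      cases_n = summ$n_individuals[summ$group == "cases"],
      controls_carriers = summ$n_carriers[summ$group == "controls"],
      controls_n = summ$n_individuals[summ$group == "controls"])
  }
  if (counts$cases_n == 0L || counts$controls_n == 0L) {
    stop("empty case or control group")
  }
  tab <- build_burden_table(counts$cases_carriers, counts$cases_n,
                            counts$controls_carriers, counts$controls_n)
  fisher <- fisher_exact_two_tailed(tab)
  report <- list(
    groups = list(
      cases = list(n = counts$cases_n, carriers = counts$cases_carriers,
                   percent = carrier_percent(counts$cases_carriers,
                                             counts$cases_n)),
      controls = list(n = counts$controls_n,
                      carriers = counts$controls_carriers,
                      percent = carrier_percent(counts$controls_carriers,
                                                counts$controls_n))),
    table = list(cases = as.vector(tab[1, ]), controls = as.vector(tab[2, ])),
    fisher = test_result_json(fisher)
  )
  out <- out %||% resolve_path(sec$out, cfg)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(report)
}

#' Run the simulator from a config
#'
#' Builds a [simulation_config()] from the `simulate` section (any of its
#' arguments may appear; `seed` defaults to 1) and writes a fixture bundle
#' via [write_fixture_bundle()].
#'
#' @param config YAML file path or equivalent list.
#' @param out_dir Output directory; overrides `simulate$out_dir`.
#' @return Named list of written paths, invisibly.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  sec <- cfg$simulate %||% list()
  args <- sec[names(sec) %in% names(formals(simulation_config))]
  if (!is.null(args$cohort_sizes)) {
    args$cohort_sizes <- unlist(args$cohort_sizes)
  }
  sim_cfg <- do.call(simulation_config, args)
  out_dir <- out_dir %||% resolve_path(sec$out_dir %||% "fixtures", cfg)
  write_fixture_bundle(sim_cfg, out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
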