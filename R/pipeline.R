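# End-to-end orchestration: one config (list or YAML) drives simulate (or
# load), densities, heterogeneity, site comparison and paired changes, with
# a content-hash manifest so identical (config, seed) runs are verifiably
# identical.

#' Validate a pipeline configuration
#'
#' Schema check with machine-readable issues. A config has exactly one of
#' `input_dir` (a cohort written by [write_cohort()]) or `simulate`
#' (arguments for [cohort_config()]); optional `regions` (list with
#' `areas_mm2`, `k`, `min_tumor_fraction`, `max_attempts`), `gating`
#' (`threshold`), `min_area_mm2`, and a mandatory integer `seed` when
#' simulating.
#'
#' @param config A named list, or the path of a YAML file.
#' @return Tibble `field`, `message` (zero rows when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  issues <- list()
  note <- function(field, message)
    issues[[length(issues) + 1L]] <<- tibble(field = field,
                                             message = message)
  has_input <- !is.null(config$input_dir)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    note("input_dir/simulate",
         "exactly one of input_dir or simulate must be given")
  if (has_sim && is.null(config$seed %||% config$simulate$seed))
    note("seed", "seed is mandatory when simulating")
  if (has_sim) {
    known <- names(formals(cohort_config))
    unknown <- setdiff(names(config$simulate), known)
    if (length(unknown))
      note("simulate", paste0("unknown fields: ",
                              paste(unknown, collapse = ", "),
                              "; allowed: ", paste(known, collapse = ", ")))
  }
  if (!is.null(config$regions)) {
    if (!is.null(config$regions$areas_mm2) &&
        any(config$regions$areas_mm2 <= 0))
      note("regions.areas_mm2", "region areas must be > 0")
    if (!is.null(config$regions$k) && config$regions$k < 1)
      note("regions.k", "k must be >= 1")
    if (!is.null(config$regions$min_tumor_fraction) &&
        (config$regions$min_tumor_fraction <= 0 ||
         config$regions$min_tumor_fraction > 1))
      note("regions.min_tumor_fraction", "must be in (0, 1]")
  }
  if (!is.null(config$gating$threshold) &&
      (config$gating$threshold <= 0 || config$gating$threshold >= 1))
    note("gating.threshold", "threshold must be in (0, 1)")
  if (!is.null(config$subsets)) {
    bad <- setdiff(config$subsets, TIL_SUBSETS)
    if (length(bad))
      note("subsets", paste0("unknown subset ",
                             paste(bad, collapse = ", "),
                             "; allowed values: ",
                             paste(TIL_SUBSETS, collapse = ", ")))
  }
  if (length(issues)) dplyr::bind_rows(issues)
  else tibble(field = character(0), message = character(0))
}

#' Run the full analysis pipeline
#'
#' Simulates or loads a cohort, then writes the density table, the
#' region-density tables and concordance summaries for every configured
#' region area, the tissue-site comparison, the paired-change summary and
#' a manifest with an md5 content hash per artifact. Identical (config,
#' seed) runs produce identical hashes.
#'
#' @param config Named list or YAML path; see [validate_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  issues <- validate_config(config)
  if (nrow(issues))
    abort(paste0("invalid config:\n", paste0("  - ", issues$field, ": ",
                                             issues$message,
                                             collapse = "\n")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  threshold <- config$gating$threshold %||% 0.5
  min_area <- config$min_area_mm2 %||% MIN_COMPARTMENT_AREA_MM2
  areas <- config$regions$areas_mm2 %||% c(0.28, 3.30)
  k <- config$regions$k %||% 4
  min_tf <- config$regions$min_tumor_fraction %||% 0.5
  max_attempts <- config$regions$max_attempts %||% 10000L
  subsets <- config$subsets %||% TIL_SUBSETS

  cohort <- if (!is.null(config$input_dir)) read_cohort(config$input_dir)
  else {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    do.call(cohort_config, sim_args) |> generate_cohort()
  }

  paths <- character(0)
  emit_csv <- function(tbl, name) {
    p <- file.path(out_dir, name)
    write.csv(tbl, p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  densities <- withCallingHandlers(
    cohort_densities(cohort, min_area_mm2 = min_area,
                     threshold = threshold),
    message = function(m) {
      # keep exclusion decisions in the run log
      cat(conditionMessage(m), file = file.path(out_dir, "run.log"),
          append = TRUE)
      invokeRestart("muffleMessage")
    })
  emit_csv(densities, "densities.csv")

  for (area in areas) {
    spec <- region_spec(area_mm2 = area, k = k,
                        min_tumor_fraction = min_tf,
                        max_attempts = max_attempts)
    tbl <- withCallingHandlers(
      cohort_region_densities(cohort, spec,
                              seed = child_seed(seed, round(area * 100)),
                              threshold = threshold),
      message = function(m) {
        cat(conditionMessage(m), file = file.path(out_dir, "run.log"),
            append = TRUE)
        invokeRestart("muffleMessage")
      })
    attr(tbl, "region_area_mm2") <- area
    tag <- gsub("\\.", "p", sprintf("%.2f", area))
    emit_csv(as.data.frame(tbl), paste0("region_densities_", tag, ".csv"))
    n_eligible <- dplyr::n_distinct(tbl$sample_id[tbl$eligible])
    if (n_eligible >= 4) {
      conc <- purrr::map(subsets, function(ss)
        suppressMessages(correct_classification_rate(tbl, ss)))
      summary_tbl <- purrr::map_dfr(conc, glance)
      emit_csv(summary_tbl, paste0("concordance_", tag, ".csv"))
      p <- file.path(out_dir, paste0("concordance_", tag, ".json"))
      jsonlite::write_json(
        purrr::map(setNames(conc, subsets), function(cc)
          list(cutpoints = unname(cc$cutpoints),
               n_samples = cc$n_samples,
               correct_rate = cc$correct_rate,
               samples = cc$samples, regions = cc$regions)),
        p, dataframe = "rows", auto_unbox = TRUE, digits = NA)
      paths <- c(paths, p)
    }
  }

  sc <- site_comparison(densities)
  emit_csv(glance(sc), "site_kruskal_wallis.csv")
  emit_csv(tidy(sc), "site_dunn_pairwise.csv")

  pc <- tryCatch(paired_changes(densities), error = function(e) NULL)
  if (!is.null(pc)) emit_csv(pc, "paired_changes.csv")
  emit_csv(density_ratios(densities), "density_ratios.csv")

  manifest <- tibble(file = basename(paths),
                     md5 = unname(tools::md5sum(paths)))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
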