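# Quartile-concordance representativeness statistic.
#
# Samples are classified into quartiles of the distribution of per-sample
# mean region densities; the correct classification rate is the percentage
# of individual regions that fall into the same quartile as their parent
# sample. A rate near 100% means a single virtual core/biopsy is
# representative; 25% is chance level for exchangeable samples.

#' Per-sample mean region densities
#'
#' Arithmetic mean of the k region densities of each eligible sample;
#' ineligible samples are skipped with a log entry.
#'
#' @param region_tbl Output of [cohort_region_densities()].
#' @param subset One of [TIL_SUBSETS].
#' @return Tibble `sample_id`, `mean_density`.
#' @export
sample_region_means <- function(region_tbl, subset) {
  skipped <- unique(region_tbl$sample_id[!region_tbl$eligible])
  if (length(skipped))
    inform(paste0("skipping ineligible samples: ",
                  paste(skipped, collapse = ", ")),
           class = "tilhet_ineligible")
  region_tbl |>
    dplyr::filter(.data$eligible, .data$subset == !!subset) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(mean_density = mean(.data$density_per_mm2),
                     .groups = "drop")
}

#' Quartile cutpoints of sample means
#'
#' 25th/50th/75th percentiles by linear interpolation between order
#' statistics at rank `(n - 1) p + 1` (R's default quantile type 7).
#'
#' @param means Numeric vector of n >= 4 per-sample means.
#' @return Named numeric vector `c(Q1, Q2, Q3)`, nondecreasing.
#' @export
quartile_cutpoints <- function(means) {
  if (length(means) < 4)
    abort("need at least 4 sample means to form quartiles")
  setNames(quantile(means, c(0.25, 0.5, 0.75), type = 7, names = FALSE),
           c("Q1", "Q2", "Q3"))
}

#' Assign a value to a quartile
#'
#' Right-closed intervals: (-Inf, Q1], (Q1, Q2], (Q2, Q3], (Q3, Inf).
#' Boundary values fall to the lower quartile; with degenerate (equal)
#' cutpoints the lowest applicable quartile is returned.
#'
#' @param value Numeric (vectorized).
#' @param cutpoints Nondecreasing numeric vector `(Q1, Q2, Q3)`.
#' @return Integer quartile(s) in 1..4.
#' @export
assign_quartile <- function(value, cutpoints) {
  if (is.unsorted(cutpoints)) abort("cutpoints must be nondecreasing")
  1L + (value > cutpoints[[1]]) + (value > cutpoints[[2]]) +
    (value > cutpoints[[3]])
}

#' Correct classification rate of regions against sample quartiles
#'
#' Classifies each sample by the quartile of its mean region density, each
#' region by the same cutpoints, and reports the percentage of regions
#' whose quartile matches their own sample's.
#'
#' @param region_tbl Output of [cohort_region_densities()].
#' @param subset One of [TIL_SUBSETS].
#' @return A `concordance_result`: list with `subset`, `region_area_mm2`,
#'   `n_samples`, `cutpoints`, `samples` (per-sample mean + quartile),
#'   `regions` (per-region density, quartile, `correct`) and
#'   `correct_rate` (percent).
#' @export
correct_classification_rate <- function(region_tbl, subset) {
  means <- sample_region_means(region_tbl, subset)
  if (nrow(means) < 4)
    abort("need at least 4 eligible samples")
  cutpoints <- quartile_cutpoints(means$mean_density)
  means$quartile <- assign_quartile(means$mean_density, cutpoints)

  regions <- region_tbl |>
    dplyr::filter(.data$eligible, .data$subset == !!subset) |>
    dplyr::select("sample_id", "region_id", "density_per_mm2") |>
    dplyr::mutate(quartile = assign_quartile(.data$density_per_mm2,
                                             cutpoints)) |>
    dplyr::left_join(dplyr::select(means, "sample_id",
                                   sample_quartile = "quartile"),
                     by = "sample_id") |>
    dplyr::mutate(correct = .data$quartile == .data$sample_quartile)

  region_area <- attr(region_tbl, "region_area_mm2") %||% NA_real_
  structure(
    list(subset = subset,
         region_area_mm2 = region_area,
         n_samples = nrow(means),
         cutpoints = cutpoints,
         samples = means,
         regions = regions,
         correct_rate = 100 * mean(regions$correct)),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> %s: %d samples, cutpoints (%.1f, %.1f, %.1f), correct rate %.1f%%\n",
    x$subset, x$n_samples, x$cutpoints[[1]], x$cutpoints[[2]],
    x$cutpoints[[3]], x$correct_rate))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-region detail of a concordance result
#' @param x A `concordance_result`.
#' @param ... Unused.
#' @return Tibble of regions with densities, quartiles and correctness.
#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) {
  dplyr::mutate(x$regions, subset = x$subset, .before = 1)
}

#' One-row summary of a concordance result
#' @param x A `concordance_result`.
#' @param ... Unused.
#' @return Tibble with subset, region area, n, cutpoints, correct rate.
#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  tibble(subset = x$subset, region_area_mm2 = x$region_area_mm2,
         n_samples = x$n_samples,
         q1 = x$cutpoints[[1]], q2 = x$cutpoints[[2]], q3 = x$cutpoints[[3]],
         correct_rate = x$correct_rate)
}

#' Concordance sweep over region areas and subsets
#'
#' Re-places regions at every area (eligibility is re-evaluated per area;
#' larger regions leave fewer eligible samples) and computes the correct
#' classification rate per (area, subset).
#'
#' @param cohort A `til_cohort` tibble.
#' @param areas_mm2 Region areas to sweep (default the TMA-core and
#'   biopsy-scale areas, 0.28 and 3.30 mm^2).
#' @param subsets Subsets to analyze (default all four).
#' @param k Regions per sample.
#' @param min_tumor_fraction,max_attempts Passed to [region_spec()].
#' @param seed Root seed for region placement.
#' @return Tibble `region_area_mm2`, `subset`, `n_eligible`,
#'   `correct_rate` (NA when fewer than 4 samples are eligible).
#' @export
concordance_sweep <- function(cohort, areas_mm2 = c(0.28, 3.30),
                              subsets = TIL_SUBSETS, k = 4,
                              min_tumor_fraction = 0.5,
                              max_attempts = 10000L, seed = 1L) {
  purrr::map_dfr(seq_along(areas_mm2), function(ai) {
    area <- areas_mm2[[ai]]
    spec <- region_spec(area_mm2 = area, k = k,
                        min_tumor_fraction = min_tumor_fraction,
                        max_attempts = max_attempts)
    tbl <- suppressMessages(
      cohort_region_densities(cohort, spec, seed = child_seed(seed, ai)))
    attr(tbl, "region_area_mm2") <- area
    n_eligible <- dplyr::n_distinct(tbl$sample_id[tbl$eligible])
    purrr::map_dfr(subsets, function(ss) {
      rate <- if (n_eligible >= 4)
        suppressMessages(correct_classification_rate(tbl, ss))$correct_rate
      else NA_real_
      tibble(region_area_mm2 = area, subset = ss,
             n_eligible = n_eligible, correct_rate = rate)
    })
  })
}
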