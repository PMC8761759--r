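# Whole-sample compartment densities with the small-compartment exclusion
# rule, and H-score based luminal/basal subtype calling.

MIN_COMPARTMENT_AREA_MM2 <- 0.10

#' Per-subset, per-compartment density profile of a sample
#'
#' Densities are count / exact polygon area (cells/mm^2). A compartment
#' smaller than `min_area_mm2` (default 0.10 mm^2) is excluded: its
#' densities are `NA` and flagged, and the exclusion is logged; the other
#' compartment is unaffected.
#'
#' @param sample A [til_sample()].
#' @param min_area_mm2 Exclusion threshold in mm^2.
#' @param threshold Gating threshold passed to [gate_subsets()] when the
#'   cells are not yet gated.
#' @return Tibble `sample_id`, `subset`, `compartment`, `area_mm2`, `n`,
#'   `density_per_mm2`, `excluded`.
#' @export
density_profile <- function(sample, min_area_mm2 = MIN_COMPARTMENT_AREA_MM2,
                            threshold = 0.5) {
  counts <- subset_counts_prepared(sample, threshold)
  areas <- c(tumor = compartment_area(sample$geometry, "tumor"),
             stroma = compartment_area(sample$geometry, "stroma"))
  out <- dplyr::mutate(
    counts,
    sample_id = sample$sample_id,
    area_mm2 = unname(areas[.data$compartment]),
    excluded = .data$area_mm2 < min_area_mm2,
    density_per_mm2 = dplyr::if_else(.data$excluded, NA_real_,
                                     .data$n / .data$area_mm2))
  excl <- unique(out$compartment[out$excluded])
  for (comp in excl)
    inform(sprintf(
      "sample %s: %s compartment area %.4f mm^2 < %.2f mm^2, excluded",
      sample$sample_id, comp, areas[[comp]], min_area_mm2),
      class = "tilhet_exclusion")
  dplyr::select(out, "sample_id", "subset", "compartment", "area_mm2",
                "n", "density_per_mm2", "excluded")
}

subset_counts_prepared <- function(sample, threshold = 0.5) {
  sample$cells <- prepare_cells(sample, threshold)
  subset_counts(sample)
}

#' Density of one subset in one compartment
#'
#' @inheritParams density_profile
#' @param subset One of [TIL_SUBSETS].
#' @param compartment `"tumor"` or `"stroma"`.
#' @return Density in cells/mm^2, or `NA` when the compartment area is
#'   below `min_area_mm2`.
#' @export
subset_density <- function(sample, subset, compartment,
                           min_area_mm2 = MIN_COMPARTMENT_AREA_MM2) {
  stopifnot(subset %in% TIL_SUBSETS)
  prof <- suppressMessages(density_profile(sample, min_area_mm2))
  prof$density_per_mm2[prof$subset == subset &
                         prof$compartment == compartment]
}

#' Density profiles for a whole cohort
#'
#' @param cohort A `til_cohort` tibble.
#' @inheritParams density_profile
#' @return Row-bound [density_profile()] tibbles joined with the cohort
#'   metadata (`patient_id`, `tissue_site`, `timepoint`).
#' @export
cohort_densities <- function(cohort, min_area_mm2 = MIN_COMPARTMENT_AREA_MM2,
                             threshold = 0.5) {
  prof <- purrr::map_dfr(cohort$sample, density_profile,
                         min_area_mm2 = min_area_mm2, threshold = threshold)
  meta <- dplyr::select(as_tibble(cohort), -dplyr::any_of("sample"))
  dplyr::left_join(prof, meta, by = "sample_id")
}

#' H-score
#'
#' Product of the percentage of positive tumor cells (0-100) and the
#' staining intensity (integer 0-3), giving a score in 0-300.
#'
#' @param percent_positive Percentage in \[0, 100\] (vectorized).
#' @param intensity Integer staining intensity in {0, 1, 2, 3}.
#' @return `percent_positive * intensity`.
#' @export
h_score <- function(percent_positive, intensity) {
  if (any(percent_positive < 0 | percent_positive > 100))
    abort("percent_positive must be in [0, 100]")
  if (any(intensity != as.integer(intensity)) ||
      any(intensity < 0 | intensity > 3))
    abort("intensity must be an integer in 0..3")
  percent_positive * intensity
}

#' Luminal/basal subtype call from GATA3 and KRT5/6 H-scores
#'
#' A marker is positive when its H-score is >= 20 (inclusive). GATA3-only
#' positivity is called luminal, KRT5/6-only basal; both markers positive
#' is double_positive and neither double_negative.
#'
#' @param h_gata3,h_krt56 H-scores in \[0, 300\] (vectorized).
#' @param positivity_cutoff H-score positivity threshold, default 20.
#' @return Tibble `h_gata3`, `h_krt56`, `gata3_positive`, `krt56_positive`,
#'   `call`.
#' @export
call_subtype <- function(h_gata3, h_krt56, positivity_cutoff = 20) {
  if (any(c(h_gata3, h_krt56) < 0) || any(c(h_gata3, h_krt56) > 300))
    abort("H-scores must be in [0, 300]")
  gp <- h_gata3 >= positivity_cutoff
  kp <- h_krt56 >= positivity_cutoff
  tibble(h_gata3 = h_gata3, h_krt56 = h_krt56,
         gata3_positive = gp, krt56_positive = kp,
         call = dplyr::case_when(
           gp & kp ~ "double_positive",
           gp ~ "luminal",
           kp ~ "basal",
           TRUE ~ "double_negative"))
}
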