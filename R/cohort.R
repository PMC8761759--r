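# Synthetic cohort generation.
#
# Emulates the statistical structure the analysis assumes so every stage is
# testable without patient data: ~111 samples from ~49 patients across five
# tissue-site density strata (lymph node richest, bone poorest), stromal
# densities above intratumoral ones, clustered within-sample point patterns,
# and paired pre/post-chemotherapy samples whose densities differ by a
# configured multiplier in expectation.

#' Default per-site, per-subset density map (cells/mm^2)
#'
#' Baseline tumor/stroma intensities for the four subsets, scaled per
#' tissue site so that lymph node > urinary tract ~ soft tissue > liver >
#' bone, with stromal intensity above intratumoral intensity for every
#' subset.
#'
#' @return Tibble `tissue_site`, `subset`, `compartment`, `intensity`.
#' @export
default_site_intensities <- function() {
  base <- tibble(
    subset = rep(TIL_SUBSETS, 2),
    compartment = rep(c("tumor", "stroma"), each = 4),
    base = c(375, 140, 70, 8,     # intratumoral
             1250, 395, 250, 125) # stromal
  )
  mult <- c(urinary_tract = 1, lymph_node = 2.2, soft_tissue = 0.9,
            liver = 0.7, bone = 0.3)
  purrr::map_dfr(names(mult), function(site) {
    tibble(tissue_site = site, subset = base$subset,
           compartment = base$compartment,
           intensity = base$base * mult[[site]])
  })
}

#' Configure a synthetic cohort
#'
#' @param n_patients Number of patients (0 gives an empty cohort).
#' @param mean_extra_samples Mean number of metastasis samples per patient
#'   beyond the primary (Poisson).
#' @param site_frequencies Named probabilities for metastasis sites.
#' @param site_intensities Density map as from [default_site_intensities()].
#' @param n_chemo_pairs Patients with paired pre/post-chemotherapy samples.
#' @param paired_treatment_multiplier Post/pre density ratio (> 0).
#' @param process Within-sample point process: `"thomas_cluster"` (default),
#'   `"homogeneous_poisson"` or `"gradient_poisson"`.
#' @param offspring_mean,dispersion_sigma Thomas parameters.
#' @param frame_width,frame_height,tumor_area_fraction,stroma_band_width
#'   Geometry defaults: a 3200 x 2800 um frame whose tumor nest is about
#'   3.3 mm^2, the biopsy-scale tumor area.
#' @param tumor_cell_intensity panCK+ epithelial cells per mm^2 added to the
#'   tumor compartment (not analyzed; keeps tables realistic).
#' @param seed Root seed; all per-sample seeds derive from it.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 49,
                          mean_extra_samples = 1.27,
                          site_frequencies = c(lymph_node = 0.45,
                                               soft_tissue = 0.2,
                                               liver = 0.15,
                                               bone = 0.1,
                                               urinary_tract = 0.1),
                          site_intensities = default_site_intensities(),
                          n_chemo_pairs = 9,
                          paired_treatment_multiplier = 0.6,
                          process = "thomas_cluster",
                          offspring_mean = 25,
                          dispersion_sigma = 60,
                          frame_width = 3200,
                          frame_height = 2800,
                          tumor_area_fraction = 0.368,
                          stroma_band_width = 200,
                          tumor_cell_intensity = 400,
                          seed = 1L) {
  if (n_patients < 0) abort("n_patients must be >= 0")
  if (paired_treatment_multiplier <= 0)
    abort("paired_treatment_multiplier must be > 0")
  if (nrow(site_intensities) == 0) abort("site intensity map is empty")
  if (any(site_intensities$intensity < 0))
    abort("intensities must be >= 0")
  structure(as.list(environment()), class = "cohort_config")
}

# Intensities for one site as a named list: intens$tumor[subset] etc.
site_intensity_rows <- function(config, site) {
  rows <- dplyr::filter(config$site_intensities, .data$tissue_site == site)
  if (nrow(rows) == 0)
    abort(paste0("site '", site, "' missing from the intensity map"))
  rows
}

# Soft marker scores: positives high, negatives low, threshold 0.5 gates
# them exactly.
soft_scores <- function(flag) {
  ifelse(flag, runif(length(flag), 0.7, 1), runif(length(flag), 0, 0.3))
}

#' Simulate the cells of one sample
#'
#' T cells are placed by the configured point process at the CD3 intensity;
#' CD8 and FoxP3 positivity is assigned among them by independent thinning
#' at rates CD8/CD3 and FoxP3/CD3 (so marginal intensities match the map and
#' double positives occur). B cells (CD3-CD20+) form their own pattern, and
#' panCK+ epithelial cells pad the tumor compartment.
#'
#' @param sample_id,patient_id,tissue_site,timepoint Metadata.
#' @param geometry A [tissue_geometry()].
#' @param config A [cohort_config()] (its intensity map row for
#'   `tissue_site` is used).
#' @param seed Integer seed.
#' @param multiplier Scales every intensity (treatment effect).
#' @return A [til_sample()] with gated, compartment-labeled cells.
#' @export
simulate_sample <- function(sample_id, geometry, config,
                            patient_id = sample_id,
                            tissue_site = "urinary_tract",
                            timepoint = "other",
                            seed = 1L, multiplier = 1) {
  rows <- site_intensity_rows(config, tissue_site)
  get_int <- function(subset, compartment) {
    r <- rows[rows$subset == subset & rows$compartment == compartment, ]
    if (nrow(r) == 0) 0 else r$intensity[[1]] * multiplier
  }
  make_spec <- function(intensity) {
    if (config$process == "thomas_cluster")
      point_process_spec("thomas_cluster", intensity = intensity,
                         offspring_mean = config$offspring_mean,
                         dispersion_sigma = config$dispersion_sigma)
    else point_process_spec(config$process, intensity = intensity)
  }

  parts <- list()
  k <- 0L
  withr::with_seed(seed, {
    for (comp in c("tumor", "stroma")) {
      if (!length(geometry[[comp]])) next
      lam_cd3 <- get_int("CD3", comp)
      lam_cd8 <- get_int("CD8", comp)
      lam_fox <- get_int("FoxP3", comp)
      lam_b <- get_int("CD20", comp)

      tcells <- simulate_point_pattern(geometry, comp, make_spec(lam_cd3),
                                       seed = sample.int(2^31 - 1, 1))
      nt <- nrow(tcells)
      cd8 <- runif(nt) < (if (lam_cd3 > 0) lam_cd8 / lam_cd3 else 0)
      fox <- runif(nt) < (if (lam_cd3 > 0) lam_fox / lam_cd3 else 0)
      ro <- runif(nt) < 0.4
      bcells <- simulate_point_pattern(geometry, comp, make_spec(lam_b),
                                       seed = sample.int(2^31 - 1, 1))
      nb <- nrow(bcells)

      part <- tibble(
        x_um = c(tcells$x, bcells$x),
        y_um = c(tcells$y, bcells$y),
        CD3 = soft_scores(c(rep(TRUE, nt), rep(FALSE, nb))),
        CD8 = soft_scores(c(cd8, rep(FALSE, nb))),
        FoxP3 = soft_scores(c(fox, rep(FALSE, nb))),
        CD20 = soft_scores(c(rep(FALSE, nt), rep(TRUE, nb))),
        CD45RO = soft_scores(c(ro, rep(FALSE, nb))),
        panCK = soft_scores(rep(FALSE, nt + nb)),
        compartment = comp)
      parts[[length(parts) + 1L]] <- part

      if (comp == "tumor" && config$tumor_cell_intensity > 0) {
        epi <- simulate_point_pattern(
          geometry, "tumor",
          point_process_spec("homogeneous_poisson",
                             intensity = config$tumor_cell_intensity),
          seed = sample.int(2^31 - 1, 1))
        ne <- nrow(epi)
        parts[[length(parts) + 1L]] <- tibble(
          x_um = epi$x, y_um = epi$y,
          CD3 = soft_scores(rep(FALSE, ne)), CD8 = soft_scores(rep(FALSE, ne)),
          FoxP3 = soft_scores(rep(FALSE, ne)),
          CD20 = soft_scores(rep(FALSE, ne)),
          CD45RO = soft_scores(rep(FALSE, ne)),
          panCK = soft_scores(rep(TRUE, ne)),
          compartment = "tumor")
      }
    }
  })

  cells <- dplyr::bind_rows(parts)
  if (nrow(cells) == 0)
    cells <- tibble(x_um = numeric(0), y_um = numeric(0),
                    CD3 = numeric(0), CD8 = numeric(0), FoxP3 = numeric(0),
                    CD20 = numeric(0), CD45RO = numeric(0),
                    panCK = numeric(0), compartment = character(0))
  cells <- dplyr::bind_cols(
    tibble(cell_id = sprintf("%s_c%05d", sample_id, seq_len(nrow(cells)))),
    cells)
  cells <- gate_subsets(cells)
  til_sample(sample_id, geometry, cells, patient_id = patient_id,
             tissue_site = tissue_site, timepoint = timepoint)
}

#' Generate a synthetic cohort
#'
#' Each patient receives one urinary-tract primary plus a Poisson number of
#' metastasis samples at sites drawn from `site_frequencies`; the first
#' `n_chemo_pairs` patients instead contribute a pre/post chemotherapy pair
#' at the same site, the post sample scaled by
#' `paired_treatment_multiplier`. Deterministic for a fixed config seed.
#'
#' @param config A [cohort_config()].
#' @return A `til_cohort` tibble: `sample_id`, `patient_id`, `tissue_site`,
#'   `timepoint` and a `sample` list-column of [til_sample()] objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  plan <- withr::with_seed(config$seed, cohort_plan(config))
  samples <- purrr::pmap(plan, function(sample_id, patient_id, tissue_site,
                                        timepoint, multiplier, seed_index) {
    geom <- make_tissue_geometry(
      config$frame_width, config$frame_height,
      config$tumor_area_fraction, config$stroma_band_width,
      seed = child_seed(config$seed, 2L * seed_index),
      sample_id = sample_id)
    simulate_sample(sample_id, geom, config,
                    patient_id = patient_id, tissue_site = tissue_site,
                    timepoint = timepoint,
                    seed = child_seed(config$seed, 2L * seed_index + 1L),
                    multiplier = multiplier)
  })
  out <- dplyr::select(plan, "sample_id", "patient_id", "tissue_site",
                       "timepoint")
  out$sample <- samples
  class(out) <- c("til_cohort", class(out))
  out
}

cohort_plan <- function(config) {
  if (config$n_patients == 0)
    return(tibble(sample_id = character(0), patient_id = character(0),
                  tissue_site = character(0), timepoint = character(0),
                  multiplier = numeric(0), seed_index = integer(0)))
  rows <- list()
  idx <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", p)
    if (p <= config$n_chemo_pairs) {
      # paired pre/post chemotherapy at the primary site
      for (tp in c("metastasis_pre_chemo", "metastasis_post_chemo")) {
        idx <- idx + 1L
        rows[[idx]] <- tibble(
          sample_id = sprintf("%s_S%02d", pid, idx),
          patient_id = pid, tissue_site = "urinary_tract", timepoint = tp,
          multiplier = if (tp == "metastasis_post_chemo")
            config$paired_treatment_multiplier else 1,
          seed_index = idx)
      }
      next
    }
    idx <- idx + 1L
    rows[[idx]] <- tibble(sample_id = sprintf("%s_S%02d", pid, idx),
                          patient_id = pid, tissue_site = "urinary_tract",
                          timepoint = "untreated_primary",
                          multiplier = 1, seed_index = idx)
    n_extra <- rpois(1, config$mean_extra_samples)
    if (n_extra > 0 && length(config$site_frequencies)) {
      sites <- sample(names(config$site_frequencies), n_extra,
                      replace = TRUE, prob = config$site_frequencies)
      for (s in sites) {
        idx <- idx + 1L
        rows[[idx]] <- tibble(sample_id = sprintf("%s_S%02d", pid, idx),
                              patient_id = pid, tissue_site = s,
                              timepoint = "metastasis_pre_chemo",
                              multiplier = 1, seed_index = idx)
      }
    }
  }
  dplyr::bind_rows(rows)
}
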