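# Point-process generators: containment, calibration, determinism, limits.

test_that("zero intensity yields zero points and unknown processes error", {
  g <- rect_geometry()
  spec <- point_process_spec("homogeneous_poisson", intensity = 0)
  expect_equal(nrow(simulate_point_pattern(g, "tumor", spec, seed = 1)), 0)
  expect_error(point_process_spec("matern", intensity = 10), "arg")
  expect_error(simulate_point_pattern(g, "lumen", spec), "compartment")
})

test_that("all generated points lie inside their compartment", {
  g <- make_tissue_geometry(3200, 2800, 0.368, seed = 2)
  for (proc in c("homogeneous_poisson", "thomas_cluster",
                 "gradient_poisson")) {
    spec <- point_process_spec(proc, intensity = 300)
    for (comp in c("tumor", "stroma")) {
      pts <- simulate_point_pattern(g, comp, spec, seed = 11)
      expect_gt(nrow(pts), 0)
      expect_true(all(tilhet:::points_in_contours(pts$x, pts$y, g[[comp]])),
                  label = paste(proc, comp, "containment"))
    }
  }
})

test_that("homogeneous Poisson counts are calibrated (mean and dispersion)", {
  g <- rect_geometry(1500, 1000, tumor = rect_contour(100, 100, 1100, 1100 - 100))
  area <- compartment_area(g, "tumor") # 1 mm^2
  spec <- point_process_spec("homogeneous_poisson", intensity = 300)
  counts <- vapply(1:200, function(i)
    nrow(simulate_point_pattern(g, "tumor", spec, seed = i)), numeric(1))
  lambda <- 300 * area
  # mean within 3 standard errors of intensity x area
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  # Poisson dispersion: variance/mean near 1
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("Thomas realized intensity matches parent_intensity x offspring_mean", {
  g <- rect_geometry(4200, 3000, tumor = rect_contour(100, 100, 4100, 2600))
  area <- compartment_area(g, "tumor") # 10 mm^2
  counts <- vapply(1:100, function(i)
    nrow(simulate_thomas_pattern(g, "tumor", parent_intensity = 2,
                                 offspring_mean = 50, dispersion_sigma = 60,
                                 seed = i)), numeric(1))
  expected <- 2 * 50 * area
  # var of a Thomas total is kappa*A*(mu + mu^2)
  se <- sqrt(2 * area * (50 + 50^2) / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("Thomas limits: zero offspring and vanishing dispersion", {
  g <- rect_geometry()
  expect_equal(nrow(simulate_thomas_pattern(g, "tumor", 2, 0, 50, seed = 1)),
               0)
  expect_error(simulate_thomas_pattern(g, "tumor", 2, 10, -1, seed = 1),
               "dispersion_sigma")
  # sigma -> 0: offspring coincide with parent locations
  pts <- simulate_thomas_pattern(g, "tumor", 1, 20, 1e-9, seed = 4)
  expect_gt(nrow(pts), 0)
  expect_lt(length(unique(round(pts$x, 3))), nrow(pts) + 1)
  d <- dist(cbind(pts$x, pts$y))
  expect_true(any(as.matrix(d)[upper.tri(as.matrix(d))] < 1e-6))
})

test_that("fixed seeds reproduce realizations exactly", {
  g <- make_tissue_geometry(3200, 2800, 0.368, seed = 2)
  spec <- point_process_spec("thomas_cluster", intensity = 200)
  a <- simulate_point_pattern(g, "tumor", spec, seed = 99)
  b <- simulate_point_pattern(g, "tumor", spec, seed = 99)
  expect_identical(a, b)
})

test_that("gradient process tilts intensity along x", {
  g <- rect_geometry(4000, 2000, tumor = rect_contour(0, 0, 4000, 2000))
  spec <- point_process_spec("gradient_poisson", intensity = 400,
                             gradient_ratio = 6)
  pts <- purrr::map_dfr(1:20, function(i)
    simulate_point_pattern(g, "tumor", spec, seed = i))
  left <- sum(pts$x < 2000)
  right <- sum(pts$x >= 2000)
  expect_gt(right, 1.5 * left)
})

test_that("cohort generator recovers the paired treatment multiplier", {
  cfg <- cohort_config(n_patients = 50, n_chemo_pairs = 50,
                       paired_treatment_multiplier = 0.5,
                       process = "homogeneous_poisson",
                       tumor_cell_intensity = 0, seed = 7)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 100)
  d <- suppressMessages(cohort_densities(co)) |>
    dplyr::filter(subset == "CD3", compartment == "tumor") |>
    dplyr::select(patient_id, timepoint, density_per_mm2) |>
    tidyr::pivot_wider(names_from = timepoint,
                       values_from = density_per_mm2)
  ratio <- d$metastasis_post_chemo / d$metastasis_pre_chemo
  expect_gte(median(ratio), 0.4)
  expect_lte(median(ratio), 0.6)
})

test_that("cohort generator orders site densities as configured", {
  cfg <- cohort_config(n_patients = 18, n_chemo_pairs = 0,
                       mean_extra_samples = 2,
                       process = "homogeneous_poisson",
                       tumor_cell_intensity = 0, seed = 5)
  co <- generate_cohort(cfg)
  d <- suppressMessages(cohort_densities(co)) |>
    dplyr::filter(subset == "CD3", compartment == "tumor") |>
    dplyr::group_by(tissue_site) |>
    dplyr::summarise(m = mean(density_per_mm2), n = dplyr::n())
  m <- setNames(d$m, d$tissue_site)
  expect_true(all(c("lymph_node", "urinary_tract", "bone") %in% names(m)))
  expect_gt(m[["lymph_node"]], m[["urinary_tract"]])
  expect_gt(m[["urinary_tract"]], m[["bone"]])
})

test_that("degenerate cohort configs behave as documented", {
  co <- generate_cohort(cohort_config(n_patients = 0, seed = 1))
  expect_equal(nrow(co), 0)
  expect_error(cohort_config(site_intensities = default_site_intensities()[0, ]),
               "empty")
  expect_error(cohort_config(paired_treatment_multiplier = 0), "> 0")
})

test_that("generated cohorts are byte-identical under a fixed seed", {
  cfg <- cohort_config(n_patients = 2, n_chemo_pairs = 1,
                       tumor_cell_intensity = 0, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$sample[[1]]$cells, b$sample[[1]]$cells)
  expect_identical(a$sample[[2]]$geometry, b$sample[[2]]$geometry)
})
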