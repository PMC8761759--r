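# Spatial point-process simulation inside polygonal compartments.
#
# Three generators cover the structures the analysis has to cope with:
# homogeneous Poisson (complete spatial randomness), Thomas cluster
# (Poisson parents with Gaussian-scattered offspring - clustered
# infiltrates such as lymphoid aggregates) and gradient Poisson (a linear
# intensity trend across the frame).

#' Specify a spatial point process
#'
#' @param process One of `"homogeneous_poisson"`, `"thomas_cluster"`,
#'   `"gradient_poisson"`.
#' @param intensity Expected overall intensity in cells/mm^2.
#' @param parent_intensity Thomas only: parent (cluster-center) intensity in
#'   parents/mm^2. Defaults to `intensity / offspring_mean`.
#' @param offspring_mean Thomas only: mean offspring per parent.
#' @param dispersion_sigma Thomas only: isotropic Gaussian offspring
#'   dispersion (micrometers), must be > 0.
#' @param gradient_ratio Gradient only: max/min intensity ratio across the
#'   frame (>= 1).
#'
#' @return A `point_process_spec` list.
#' @export
point_process_spec <- function(process = c("homogeneous_poisson",
                                           "thomas_cluster",
                                           "gradient_poisson"),
                               intensity,
                               parent_intensity = NULL,
                               offspring_mean = 25,
                               dispersion_sigma = 60,
                               gradient_ratio = 4) {
  process <- match.arg(process)
  if (intensity < 0) abort("intensity must be >= 0")
  if (process == "thomas_cluster") {
    if (dispersion_sigma <= 0) abort("dispersion_sigma must be > 0")
    if (offspring_mean < 0) abort("offspring_mean must be >= 0")
    parent_intensity <- parent_intensity %||%
      (if (offspring_mean > 0) intensity / offspring_mean else 0)
    if (abs(parent_intensity * offspring_mean - intensity) >
        1e-6 * max(1, intensity))
      abort("parent_intensity * offspring_mean must equal intensity")
  }
  if (process == "gradient_poisson" && gradient_ratio < 1)
    abort("gradient_ratio must be >= 1")
  structure(list(process = process, intensity = intensity,
                 parent_intensity = parent_intensity,
                 offspring_mean = offspring_mean,
                 dispersion_sigma = dispersion_sigma,
                 gradient_ratio = gradient_ratio),
            class = "point_process_spec")
}

# Uniform points inside a contour set, by rejection from the bounding box.
runif_in_contours <- function(n, contours) {
  out_x <- numeric(0)
  out_y <- numeric(0)
  if (n == 0) return(tibble(x = out_x, y = out_y))
  bbox <- contours_bbox(contours)
  area_frac <- max(contour_area_um2(contours), 1e-12) /
    max((bbox[["xmax"]] - bbox[["xmin"]]) * (bbox[["ymax"]] - bbox[["ymin"]]),
        1e-12)
  while (length(out_x) < n) {
    m <- ceiling((n - length(out_x)) / max(area_frac, 0.01) * 1.2) + 16
    px <- runif(m, bbox[["xmin"]], bbox[["xmax"]])
    py <- runif(m, bbox[["ymin"]], bbox[["ymax"]])
    keep <- points_in_contours(px, py, contours)
    out_x <- c(out_x, px[keep])
    out_y <- c(out_y, py[keep])
  }
  tibble(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Simulate a point pattern inside one compartment
#'
#' Draws cell positions inside the named compartment of a tissue geometry
#' according to a [point_process_spec()]. All returned points lie inside the
#' compartment; the realization is reproducible for a fixed `seed`.
#'
#' @param geometry A [tissue_geometry()].
#' @param compartment `"tumor"` or `"stroma"`.
#' @param spec A [point_process_spec()].
#' @param seed Integer seed.
#'
#' @return A tibble with columns `x`, `y` (micrometers).
#' @export
simulate_point_pattern <- function(geometry, compartment, spec, seed = 1L) {
  if (!inherits(spec, "point_process_spec"))
    abort("spec must be a point_process_spec")
  if (!compartment %in% c("tumor", "stroma"))
    abort(sprintf("unknown compartment '%s'", compartment))
  contours <- geometry[[compartment]]
  if (!length(contours))
    abort(sprintf("compartment '%s' has no polygons", compartment))
  area_mm2 <- contour_area_um2(contours) / UM2_PER_MM2

  withr::with_seed(seed, {
    switch(spec$process,
      homogeneous_poisson = {
        n <- rpois(1, spec$intensity * area_mm2)
        runif_in_contours(n, contours)
      },
      thomas_cluster = sim_thomas(contours, area_mm2,
                                  spec$parent_intensity,
                                  spec$offspring_mean,
                                  spec$dispersion_sigma),
      gradient_poisson = sim_gradient(geometry, contours, area_mm2,
                                      spec$intensity, spec$gradient_ratio)
    )
  })
}

#' Simulate a Thomas cluster pattern
#'
#' Poisson(`parent_intensity` x area) parents uniform in the compartment;
#' each parent receives Poisson(`offspring_mean`) offspring displaced by an
#' isotropic Gaussian with sd `dispersion_sigma`. Offspring falling outside
#' the compartment are resampled around their parent up to 100 times, then
#' dropped, so containment is exact. The realized overall intensity is
#' approximately `parent_intensity * offspring_mean`.
#'
#' @inheritParams simulate_point_pattern
#' @param parent_intensity Parents per mm^2.
#' @param offspring_mean Mean offspring per parent.
#' @param dispersion_sigma Gaussian dispersion in micrometers (> 0).
#'
#' @return A tibble with columns `x`, `y`.
#' @export
simulate_thomas_pattern <- function(geometry, compartment, parent_intensity,
                                    offspring_mean, dispersion_sigma,
                                    seed = 1L) {
  spec <- point_process_spec("thomas_cluster",
                             intensity = parent_intensity * offspring_mean,
                             parent_intensity = parent_intensity,
                             offspring_mean = offspring_mean,
                             dispersion_sigma = dispersion_sigma)
  simulate_point_pattern(geometry, compartment, spec, seed = seed)
}

sim_thomas <- function(contours, area_mm2, parent_intensity, offspring_mean,
                       dispersion_sigma, max_tries = 100L) {
  n_parents <- rpois(1, parent_intensity * area_mm2)
  if (n_parents == 0 || offspring_mean == 0)
    return(tibble(x = numeric(0), y = numeric(0)))
  parents <- runif_in_contours(n_parents, contours)
  n_off <- rpois(n_parents, offspring_mean)
  if (sum(n_off) == 0) return(tibble(x = numeric(0), y = numeric(0)))
  ppx <- rep(parents$x, n_off)
  ppy <- rep(parents$y, n_off)
  m <- length(ppx)
  ox <- ppx + rnorm(m, 0, dispersion_sigma)
  oy <- ppy + rnorm(m, 0, dispersion_sigma)
  bad <- !points_in_contours(ox, oy, contours)
  tries <- 0L
  while (any(bad) && tries < max_tries) {
    k <- sum(bad)
    ox[bad] <- ppx[bad] + rnorm(k, 0, dispersion_sigma)
    oy[bad] <- ppy[bad] + rnorm(k, 0, dispersion_sigma)
    bad <- !points_in_contours(ox, oy, contours)
    tries <- tries + 1L
  }
  tibble(x = ox[!bad], y = oy[!bad])
}

# Linear intensity trend along x across the compartment bounding box,
# realized by thinning a homogeneous envelope at the maximum intensity.
sim_gradient <- function(geometry, contours, area_mm2, intensity,
                         gradient_ratio) {
  bbox <- contours_bbox(contours)
  # mean of the linear profile is intensity; endpoints lo and hi = r*lo
  lo <- 2 * intensity / (1 + gradient_ratio)
  hi <- gradient_ratio * lo
  n_env <- rpois(1, hi * area_mm2)
  env <- runif_in_contours(n_env, contours)
  t <- (env$x - bbox[["xmin"]]) /
    max(bbox[["xmax"]] - bbox[["xmin"]], 1e-12)
  keep <- runif(n_env) < (lo + (hi - lo) * t) / hi
  tibble(x = env$x[keep], y = env$y[keep])
}
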