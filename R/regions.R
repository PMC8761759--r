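# Virtual tumor regions: random placement of k non-overlapping regions of
# fixed area inside the tumor compartment, honoring tumor-predominance
# (min_tumor_fraction) and eligibility rules, plus per-region densities.
#
# 0.28 mm^2 regions default to circles (the cross-section of a 0.6 mm
# diameter TMA core); larger, biopsy-scale regions default to squares.
# Failure to place k regions is the INELIGIBLE data state, not an error -
# small samples drop out of the heterogeneity analysis exactly as real
# ones do.

CIRCLE_VERTICES <- 64L

#' Specify virtual tumor regions
#'
#' @param area_mm2 Region area (defaults: 0.28 mm^2, a 0.6 mm TMA core;
#'   3.30 mm^2 is the biopsy-scale alternative).
#' @param k Number of non-overlapping regions per sample (default 4).
#' @param shape `"circle"` or `"square"`; default circle for areas up to
#'   1 mm^2, square above.
#' @param min_tumor_fraction Minimum fraction of the region footprint
#'   covered by tumor (default 0.5; small stromal bands are allowed inside
#'   a region and its nominal area stays the density denominator).
#' @param max_attempts Candidate placements before a sample is declared
#'   INELIGIBLE (default 10000).
#' @return A `region_spec` list.
#' @export
region_spec <- function(area_mm2 = 0.28, k = 4, shape = NULL,
                        min_tumor_fraction = 0.5, max_attempts = 10000L) {
  if (area_mm2 <= 0) abort("area_mm2 must be > 0")
  if (k < 1) abort("k must be >= 1")
  if (min_tumor_fraction <= 0 || min_tumor_fraction > 1)
    abort("min_tumor_fraction must be in (0, 1]")
  shape <- shape %||% (if (area_mm2 <= 1) "circle" else "square")
  if (!shape %in% c("circle", "square")) abort("shape must be circle/square")
  structure(list(area_mm2 = area_mm2, k = as.integer(k), shape = shape,
                 min_tumor_fraction = min_tumor_fraction,
                 max_attempts = as.integer(max_attempts)),
            class = "region_spec")
}

# Characteristic half-extent in micrometers: circle radius or half-side.
region_half_extent <- function(area_mm2, shape) {
  area_um2 <- area_mm2 * UM2_PER_MM2
  if (shape == "circle") sqrt(area_um2 / pi) else sqrt(area_um2) / 2
}

# Maximum reach of the footprint polygon from the center: the matched-area
# 64-gon's circumradius slightly exceeds the nominal circle radius.
region_reach <- function(area_mm2, shape) {
  h <- region_half_extent(area_mm2, shape)
  if (shape == "circle")
    h / sqrt(CIRCLE_VERTICES / (2 * pi) * sin(2 * pi / CIRCLE_VERTICES))
  else h * sqrt(2)
}

# Footprint polygon of one region (circle approximated as a 64-gon whose
# area is matched to the nominal region area).
region_footprint <- function(cx, cy, area_mm2, shape) {
  h <- region_half_extent(area_mm2, shape)
  if (shape == "square")
    return(orient_contour(list(x = cx + c(-h, h, h, -h),
                               y = cy + c(-h, -h, h, h))))
  m <- CIRCLE_VERTICES
  # radius correction so the m-gon area equals the nominal circle area
  r <- h / sqrt(m / (2 * pi) * sin(2 * pi / m))
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  orient_contour(list(x = cx + r * cos(th), y = cy + r * sin(th)))
}

#' Tumor fraction of a region
#'
#' Fraction of the region footprint covered by the tumor compartment,
#' by exact polygon intersection.
#'
#' @param region One-row tibble (or list) with `center_x_um`,
#'   `center_y_um`, `area_mm2`, `shape`.
#' @param geometry A [tissue_geometry()].
#' @return Fraction in \[0, 1\].
#' @export
tumor_fraction <- function(region, geometry) {
  fp <- region_footprint(region$center_x_um, region$center_y_um,
                         region$area_mm2, region$shape)
  if (min(fp$x) < 0 || min(fp$y) < 0 || max(fp$x) > geometry$frame_width ||
      max(fp$y) > geometry$frame_height)
    abort("region footprint extends outside the frame")
  if (!length(geometry$tumor)) return(0)
  inter <- polyclip::polyclip(list(fp), geometry$tumor, op = "intersection",
                              fillA = "evenodd", fillB = "evenodd")
  sum(abs(vapply(inter, shoelace, numeric(1)))) / abs(shoelace(fp))
}

# Overlap test between a candidate and accepted regions of the same spec.
regions_overlap <- function(cx, cy, acc_x, acc_y, half, shape) {
  if (!length(acc_x)) return(FALSE)
  if (shape == "circle")
    any((acc_x - cx)^2 + (acc_y - cy)^2 < (2 * half)^2)
  else
    any(abs(acc_x - cx) < 2 * half & abs(acc_y - cy) < 2 * half)
}

#' Randomly place k non-overlapping tumor regions
#'
#' Rejection sampling: centers are drawn uniformly over the tumor
#' compartment's bounding box; a candidate is accepted when its footprint
#' lies in the frame, does not overlap an accepted region, and has tumor
#' fraction >= `min_tumor_fraction`. If `k` regions cannot be placed within
#' `max_attempts` candidates (or `k * area` already exceeds the tumor
#' area), the sample is INELIGIBLE: a zero-row region table flagged
#' accordingly.
#'
#' @param sample A [til_sample()] or [tissue_geometry()].
#' @param spec A [region_spec()].
#' @param seed Integer seed; fixed seed reproduces the centers exactly.
#' @return Tibble `region_id`, `shape`, `center_x_um`, `center_y_um`,
#'   `area_mm2`, `tumor_fraction` with attributes `eligible` (logical) and
#'   `sample_id`.
#' @export
sample_nonoverlapping_regions <- function(sample, spec = region_spec(),
                                          seed = 1L) {
  geometry <- if (inherits(sample, "til_sample")) sample$geometry else sample
  stopifnot(inherits(geometry, "tissue_geometry"),
            inherits(spec, "region_spec"))
  empty <- tibble(region_id = integer(0), shape = character(0),
                  center_x_um = numeric(0), center_y_um = numeric(0),
                  area_mm2 = numeric(0), tumor_fraction = numeric(0))

  tumor_area <- compartment_area(geometry, "tumor")
  if (spec$k * spec$area_mm2 > tumor_area) {
    inform(sprintf(
      "sample %s: tumor area %.2f mm^2 cannot host %d regions of %.2f mm^2; INELIGIBLE",
      geometry$sample_id, tumor_area, spec$k, spec$area_mm2),
      class = "tilhet_ineligible")
    return(region_set(empty, FALSE, geometry$sample_id))
  }

  half <- region_half_extent(spec$area_mm2, spec$shape)
  # frame containment and circle disjointness use the polygon's true reach
  edge <- if (spec$shape == "circle") region_reach(spec$area_mm2, "circle")
          else half
  bbox <- contours_bbox(geometry$tumor)
  acc_x <- numeric(0); acc_y <- numeric(0); acc_frac <- numeric(0)

  withr::with_seed(seed, {
    attempts <- 0L
    while (length(acc_x) < spec$k && attempts < spec$max_attempts) {
      attempts <- attempts + 1L
      cx <- runif(1, bbox[["xmin"]], bbox[["xmax"]])
      cy <- runif(1, bbox[["ymin"]], bbox[["ymax"]])
      if (cx - edge < 0 || cy - edge < 0 ||
          cx + edge > geometry$frame_width ||
          cy + edge > geometry$frame_height) next
      if (regions_overlap(cx, cy, acc_x, acc_y, edge, spec$shape)) next
      frac <- tumor_fraction(
        list(center_x_um = cx, center_y_um = cy,
             area_mm2 = spec$area_mm2, shape = spec$shape), geometry)
      if (frac < spec$min_tumor_fraction) next
      acc_x <- c(acc_x, cx); acc_y <- c(acc_y, cy)
      acc_frac <- c(acc_frac, frac)
    }
  })

  if (length(acc_x) < spec$k) {
    inform(sprintf(
      "sample %s: placed %d/%d regions of %.2f mm^2 in %d attempts; INELIGIBLE",
      geometry$sample_id, length(acc_x), spec$k, spec$area_mm2,
      spec$max_attempts),
      class = "tilhet_ineligible")
    return(region_set(empty, FALSE, geometry$sample_id))
  }
  region_set(tibble(region_id = seq_len(spec$k), shape = spec$shape,
                    center_x_um = acc_x, center_y_um = acc_y,
                    area_mm2 = spec$area_mm2, tumor_fraction = acc_frac),
             TRUE, geometry$sample_id)
}

region_set <- function(tbl, eligible, sample_id) {
  attr(tbl, "eligible") <- eligible
  attr(tbl, "sample_id") <- sample_id
  class(tbl) <- c("region_set", class(tbl))
  tbl
}

#' Is a region set eligible?
#' @param regions Result of [sample_nonoverlapping_regions()].
#' @return `TRUE` when k regions were placed.
#' @export
is_eligible <- function(regions) isTRUE(attr(regions, "eligible"))

# Cells inside one region footprint (exact circle / square test).
cells_in_region <- function(region, cells) {
  h <- region_half_extent(region$area_mm2, region$shape)
  dx <- cells$x_um - region$center_x_um
  dy <- cells$y_um - region$center_y_um
  if (region$shape == "circle") dx * dx + dy * dy <= h * h
  else abs(dx) <= h & abs(dy) <= h
}

#' Density of a subset within one region
#'
#' Count of subset cells whose position lies in the region footprint,
#' divided by the nominal region area (stromal bands inside the region are
#' counted as part of it).
#'
#' @param region One-row region tibble (or list).
#' @param cells Gated cell tibble.
#' @param subset One of [TIL_SUBSETS].
#' @return Density in cells/mm^2.
#' @export
region_density <- function(region, cells, subset) {
  stopifnot(subset %in% TIL_SUBSETS)
  inside <- cells_in_region(region, cells)
  sum(cells[[paste0(subset, "_pos")]] & inside) / region$area_mm2
}

#' Per-region densities for all subsets
#'
#' @param regions Region table from [sample_nonoverlapping_regions()].
#' @param cells Gated cell tibble.
#' @return Tidy tibble `region_id`, `subset`, `density_per_mm2`,
#'   `tumor_fraction`.
#' @export
region_densities <- function(regions, cells) {
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    tibble(region_id = reg$region_id, subset = TIL_SUBSETS,
           density_per_mm2 = vapply(TIL_SUBSETS, region_density,
                                    numeric(1), region = reg, cells = cells),
           tumor_fraction = reg$tumor_fraction)
  })
}

#' Within-sample density range
#'
#' Difference between the densest and sparsest of a sample's regions
#' (cells/mm^2), the within-sample heterogeneity summary.
#'
#' @param densities Numeric vector of >= 2 region densities.
#' @return `max(densities) - min(densities)`.
#' @export
within_sample_range <- function(densities) {
  if (length(densities) < 2)
    abort("within_sample_range needs at least 2 region densities")
  max(densities) - min(densities)
}

#' Region densities across a cohort
#'
#' Places `spec$k` regions in every sample (per-sample seeds derived from
#' `seed`) and computes per-region subset densities. Ineligible samples are
#' kept as flag rows with no regions.
#'
#' @param cohort A `til_cohort` tibble.
#' @param spec A [region_spec()].
#' @param seed Root seed.
#' @param threshold Gating threshold for ungated cells.
#' @return Tibble `sample_id`, `eligible`, `region_id`, `subset`,
#'   `density_per_mm2`, `tumor_fraction` (NA region rows for ineligible
#'   samples).
#' @export
cohort_region_densities <- function(cohort, spec = region_spec(), seed = 1L,
                                    threshold = 0.5) {
  out <- purrr::imap_dfr(cohort$sample, function(s, i) {
    regs <- sample_nonoverlapping_regions(s, spec,
                                          seed = child_seed(seed, i))
    if (!is_eligible(regs))
      return(tibble(sample_id = s$sample_id, eligible = FALSE,
                    region_id = NA_integer_, subset = NA_character_,
                    density_per_mm2 = NA_real_, tumor_fraction = NA_real_))
    cells <- prepare_cells(s, threshold)
    dens <- region_densities(regs, cells)
    dplyr::bind_cols(tibble(sample_id = s$sample_id, eligible = TRUE), dens)
  })
  attr(out, "region_area_mm2") <- spec$area_mm2
  out
}
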