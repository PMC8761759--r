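# Polygonal tissue geometry: the spatial frame all counting happens in.
#
# A compartment (tumor or stroma) is a list of closed contours, each a
# list(x, y) in micrometers. Contours follow an orientation convention:
# counter-clockwise (positive shoelace) contours are solid, clockwise ones
# are holes, and membership is decided by even-odd ray casting, so an
# annular stroma band is simply [outer CCW, inner CW].

UM2_PER_MM2 <- 1e6

shoelace <- function(contour) {
  x <- contour$x
  y <- contour$y
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  0.5 * sum(x[j] * y - x * y[j])
}

contour_area_um2 <- function(contours) {
  sum(vapply(contours, shoelace, numeric(1)))
}

orient_contour <- function(contour, hole = FALSE) {
  a <- shoelace(contour)
  if ((a < 0) != hole) contour <- list(x = rev(contour$x), y = rev(contour$y))
  contour
}

# Even-odd point-in-polygon over a set of contours, vectorized over points.
points_in_contours <- function(px, py, contours) {
  inside <- rep(FALSE, length(px))
  for (ct in contours) {
    x <- ct$x
    y <- ct$y
    n <- length(x)
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

contours_bbox <- function(contours) {
  xs <- unlist(lapply(contours, `[[`, "x"))
  ys <- unlist(lapply(contours, `[[`, "y"))
  if (length(xs) == 0) return(c(xmin = 0, xmax = 0, ymin = 0, ymax = 0))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# Fraction of a regular grid over `bbox` that falls inside `contours`;
# the rasterized counterpart of exact polygon areas. Processed in row
# blocks so fine resolutions stay within memory.
grid_fraction <- function(contours, bbox, resolution) {
  gx <- seq(bbox[["xmin"]] + resolution / 2, bbox[["xmax"]], by = resolution)
  gy <- seq(bbox[["ymin"]] + resolution / 2, bbox[["ymax"]], by = resolution)
  block <- max(1L, floor(2e6 / length(gx)))
  n_in <- 0
  for (start in seq(1L, length(gy), by = block)) {
    rows <- gy[start:min(start + block - 1L, length(gy))]
    px <- rep(gx, times = length(rows))
    py <- rep(rows, each = length(gx))
    n_in <- n_in + sum(points_in_contours(px, py, contours))
  }
  n_in / (length(gx) * length(gy))
}

#' Construct a tissue geometry from explicit polygons
#'
#' A `tissue_geometry` holds the tumor and stroma regions of one sample as
#' sets of polygon contours in micrometer coordinates (origin top-left,
#' x rightward, y downward), plus the slide frame they live in. Everything
#' downstream - compartment assignment, areas, virtual-region sampling -
#' is computed against this object.
#'
#' @param sample_id Sample identifier.
#' @param frame_width,frame_height Frame dimensions in micrometers.
#' @param tumor,stroma Lists of contours, each a `list(x, y)` in micrometers.
#'   Counter-clockwise contours are solid, clockwise contours are holes
#'   (even-odd rule). Plain solid polygons may be passed in any orientation
#'   when `normalize = TRUE` (the default).
#' @param raster_resolution Grid spacing (micrometers per pixel) used by
#'   rasterized fraction computations. Default 0.5.
#' @param normalize Reorient every contour to solid (counter-clockwise)?
#'   Set to `FALSE` when contours already encode holes by orientation.
#' @param validate Check frame containment and tumor/stroma disjointness.
#'
#' @return An object of class `tissue_geometry`.
#' @export
tissue_geometry <- function(sample_id, frame_width, frame_height,
                            tumor = list(), stroma = list(),
                            raster_resolution = 0.5,
                            normalize = TRUE, validate = TRUE) {
  stopifnot(frame_width > 0, frame_height > 0, raster_resolution > 0)
  fix <- function(contours) {
    if (length(contours) && !is.null(contours$x)) contours <- list(contours)
    if (normalize) contours <- lapply(contours, orient_contour)
    contours
  }
  tumor <- fix(tumor)
  stroma <- fix(stroma)
  geom <- structure(
    list(sample_id = as.character(sample_id),
         frame_width = frame_width, frame_height = frame_height,
         tumor = tumor, stroma = stroma,
         raster_resolution = raster_resolution),
    class = "tissue_geometry")
  if (validate) validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  for (comp in c("tumor", "stroma")) {
    for (ct in geom[[comp]]) {
      if (length(ct$x) < 3 || length(ct$x) != length(ct$y))
        abort(sprintf("%s contour must have >= 3 paired vertices", comp))
      if (any(ct$x < -1e-9) || any(ct$y < -1e-9) ||
          any(ct$x > geom$frame_width + 1e-9) ||
          any(ct$y > geom$frame_height + 1e-9))
        abort(sprintf("%s region extends outside the frame", comp))
    }
    a <- contour_area_um2(geom[[comp]])
    if (length(geom[[comp]]) && a <= 0)
      abort(sprintf("%s region has nonpositive area", comp))
  }
  if (length(geom$tumor) && length(geom$stroma)) {
    ov <- polyclip::polyclip(geom$tumor, geom$stroma, op = "intersection",
                             fillA = "evenodd", fillB = "evenodd")
    ov_um2 <- sum(abs(vapply(ov, shoelace, numeric(1))))
    if (ov_um2 > 1) # 1 um^2 tolerance for shared edges
      abort("tumor and stroma interiors overlap")
  }
  frame_um2 <- geom$frame_width * geom$frame_height
  if (contour_area_um2(geom$tumor) + contour_area_um2(geom$stroma) >
      frame_um2 * (1 + 1e-9))
    abort("tumor + stroma area exceeds the frame area")
  invisible(geom)
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf(
    "<tissue_geometry> %s: %.0f x %.0f um frame, tumor %.3f mm^2, stroma %.3f mm^2\n",
    x$sample_id, x$frame_width, x$frame_height,
    compartment_area(x, "tumor"), compartment_area(x, "stroma")))
  invisible(x)
}

#' Generate a random biopsy-like tissue geometry
#'
#' Builds an irregular star-shaped tumor nest centered in the frame,
#' surrounded by a stroma band of the requested width. Vertex radii are
#' jittered and then rescaled analytically so the realized tumor area equals
#' `tumor_area_fraction * frame area` exactly.
#'
#' @param frame_width,frame_height Frame size in micrometers.
#' @param tumor_area_fraction Target tumor area as a fraction of the frame
#'   area, in (0, 1).
#' @param stroma_band_width Width of the stroma band around the tumor, in
#'   micrometers.
#' @param seed Integer seed; the same seed reproduces the polygon exactly.
#' @param n_vertices Number of polygon vertices (default 24).
#' @param jitter Relative radial jitter; radii are drawn uniformly in
#'   `[1 - jitter, 1 + jitter]` times the base radius before rescaling.
#' @param sample_id Sample identifier stored on the geometry.
#' @inheritParams tissue_geometry
#'
#' @return A [tissue_geometry()].
#' @export
make_tissue_geometry <- function(frame_width, frame_height,
                                 tumor_area_fraction,
                                 stroma_band_width = 200,
                                 seed = 1L,
                                 n_vertices = 24,
                                 jitter = 0.1,
                                 sample_id = "synthetic",
                                 raster_resolution = 0.5) {
  stopifnot(frame_width > 0, frame_height > 0)
  if (tumor_area_fraction <= 0 || tumor_area_fraction >= 1)
    abort("tumor_area_fraction must be in (0, 1)")
  if (stroma_band_width < 0) abort("stroma_band_width must be >= 0")

  withr::with_seed(seed, {
    cx <- frame_width / 2
    cy <- frame_height / 2
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    raw <- runif(n_vertices, 1 - jitter, 1 + jitter)

    # exact-area rescale: star polygon area scales with the square of radii
    target_um2 <- tumor_area_fraction * frame_width * frame_height
    # area for radius multiplier s is s^2 * area(raw radii around center)
    base_area <- shoelace(list(x = raw * cos(theta), y = raw * sin(theta)))
    s <- sqrt(target_um2 / base_area)
    r_tumor <- s * raw
    r_outer <- r_tumor + stroma_band_width

    # distance from center to the frame boundary along each vertex direction
    ray_bound <- function(dx, dy) {
      tx <- ifelse(dx > 0, (frame_width - cx) / dx,
                   ifelse(dx < 0, -cx / dx, Inf))
      ty <- ifelse(dy > 0, (frame_height - cy) / dy,
                   ifelse(dy < 0, -cy / dy, Inf))
      pmin(tx, ty)
    }
    bound <- ray_bound(cos(theta), sin(theta))
    if (any(r_outer > 0.995 * bound))
      abort(paste0(
        "infeasible geometry request: tumor area fraction ",
        tumor_area_fraction, " with a ", stroma_band_width,
        " um stroma band does not fit in a ", frame_width, " x ",
        frame_height, " um frame"))

    tumor_ct <- orient_contour(list(x = cx + r_tumor * cos(theta),
                                    y = cy + r_tumor * sin(theta)))
    outer_ct <- orient_contour(list(x = cx + r_outer * cos(theta),
                                    y = cy + r_outer * sin(theta)))
    hole_ct <- orient_contour(tumor_ct, hole = TRUE)

    tissue_geometry(sample_id, frame_width, frame_height,
                    tumor = list(tumor_ct),
                    stroma = list(outer_ct, hole_ct),
                    raster_resolution = raster_resolution,
                    normalize = FALSE)
  })
}

#' Compartment surface area
#'
#' Exact polygon area of a compartment in mm^2 (1 mm^2 = 1e6 um^2), the
#' denominator of every whole-compartment density.
#'
#' @param geometry A [tissue_geometry()].
#' @param compartment `"tumor"` or `"stroma"`.
#' @return Area in mm^2 (0 when the compartment has no polygons).
#' @export
compartment_area <- function(geometry, compartment) {
  if (!compartment %in% c("tumor", "stroma"))
    abort(sprintf("unknown compartment '%s' (expected tumor or stroma)",
                  compartment))
  contour_area_um2(geometry[[compartment]]) / UM2_PER_MM2
}

#' Rasterized compartment area
#'
#' Grid-count counterpart of [compartment_area()], used as an internal
#' cross-check: fraction of pixels at `resolution` um spacing falling inside
#' the compartment, times the frame area.
#'
#' @inheritParams compartment_area
#' @param resolution Grid spacing in micrometers; defaults to the geometry's
#'   `raster_resolution`.
#' @return Area in mm^2.
#' @export
compartment_area_raster <- function(geometry, compartment,
                                    resolution = NULL) {
  if (!compartment %in% c("tumor", "stroma"))
    abort(sprintf("unknown compartment '%s'", compartment))
  contours <- geometry[[compartment]]
  if (!length(contours)) return(0)
  resolution <- resolution %||% geometry$raster_resolution
  bbox <- c(xmin = 0, xmax = geometry$frame_width,
            ymin = 0, ymax = geometry$frame_height)
  frac <- grid_fraction(contours, bbox, resolution)
  frac * geometry$frame_width * geometry$frame_height / UM2_PER_MM2
}
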