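# Shared fixtures: geometries, cell tables and region tables built in code.

rect_contour <- function(x0, y0, x1, y1) {
  list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# Frame fully or partly covered by a rectangular tumor; optional stroma rect.
rect_geometry <- function(frame_w = 4000, frame_h = 3000,
                          tumor = rect_contour(500, 500, 3500, 2500),
                          stroma = NULL, id = "rect") {
  tissue_geometry(id, frame_w, frame_h,
                  tumor = list(tumor),
                  stroma = if (is.null(stroma)) list() else list(stroma))
}

# Bare cell tibble with all markers defaulting to 0.
make_cells <- function(x, y, CD3 = 0, CD8 = 0, FoxP3 = 0, CD20 = 0,
                       CD45RO = 0, panCK = 0, id_prefix = "c") {
  n <- length(x)
  tibble::tibble(cell_id = sprintf("%s%04d", id_prefix, seq_len(n)),
                 x_um = x, y_um = y,
                 CD3 = rep_len(CD3, n), CD8 = rep_len(CD8, n),
                 FoxP3 = rep_len(FoxP3, n), CD20 = rep_len(CD20, n),
                 CD45RO = rep_len(CD45RO, n), panCK = rep_len(panCK, n))
}

# Sample whose tumor compartment holds a homogeneous Poisson CD3+ pattern.
poisson_cd3_sample <- function(id, geom, lambda, seed) {
  pts <- simulate_point_pattern(
    geom, "tumor",
    point_process_spec("homogeneous_poisson", intensity = lambda),
    seed = seed)
  cells <- make_cells(pts$x, pts$y, CD3 = 1, id_prefix = paste0(id, "_"))
  til_sample(id, geom, cells, patient_id = id)
}

# Independent rasterization oracle: fraction of footprint grid points that
# also fall inside the tumor contours.
raster_intersection_fraction <- function(fp, tumor, resolution) {
  bbox <- tilhet:::contours_bbox(list(fp))
  gx <- seq(bbox[["xmin"]] + resolution / 2, bbox[["xmax"]],
            by = resolution)
  gy <- seq(bbox[["ymin"]] + resolution / 2, bbox[["ymax"]],
            by = resolution)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  in_fp <- tilhet:::points_in_contours(px, py, list(fp))
  in_tumor <- tilhet:::points_in_contours(px, py, tumor)
  sum(in_fp & in_tumor) / sum(in_fp)
}

# Region-density table in the cohort_region_densities() layout, built from
# per-sample region density vectors (single subset).
manual_region_tbl <- function(densities_by_sample, subset = "CD3",
                              area_mm2 = 0.28) {
  out <- purrr::imap_dfr(densities_by_sample, function(d, id) {
    tibble::tibble(sample_id = id, eligible = TRUE,
                   region_id = seq_along(d), subset = subset,
                   density_per_mm2 = d, tumor_fraction = 1)
  })
  attr(out, "region_area_mm2") <- area_mm2
  out
}
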