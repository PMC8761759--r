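# Delimited-text and GeoJSON I/O for samples and cohorts.
#
# Cell tables are CSV (tab accepted on read), UTF-8, header required:
# cell_id, x_um, y_um, CD3, CD8, FoxP3, CD20, CD45RO, panCK[, compartment].
# Geometry is a GeoJSON FeatureCollection of Polygons with a "compartment"
# property; interior rings are holes. Coordinates are micrometers in the
# slide frame, not geographic.

#' Write a sample to disk
#'
#' Writes `<id>_cells.csv`, `<id>_geometry.geojson` and
#' `<id>_metadata.csv` into `dir`.
#'
#' @param sample A [til_sample()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sample$sample_id
  paths <- c(cells = file.path(dir, paste0(id, "_cells.csv")),
             geometry = file.path(dir, paste0(id, "_geometry.geojson")),
             metadata = file.path(dir, paste0(id, "_metadata.csv")))
  cols <- intersect(c("cell_id", "x_um", "y_um", TIL_MARKERS, "compartment"),
                    names(sample$cells))
  write.csv(sample$cells[, cols], paths[["cells"]], row.names = FALSE)
  write_geometry_geojson(sample$geometry, paths[["geometry"]])
  write.csv(tibble(sample_id = id, patient_id = sample$patient_id,
                   tissue_site = sample$tissue_site,
                   timepoint = sample$timepoint),
            paths[["metadata"]], row.names = FALSE)
  invisible(paths)
}

#' Read a sample from disk
#'
#' Counterpart of [write_sample()]; numeric fields round-trip at the
#' written precision (15 significant digits).
#'
#' @param cell_table_path CSV/TSV cell table.
#' @param geometry_path GeoJSON geometry.
#' @param metadata Named list or one-row data frame with `sample_id`,
#'   `patient_id`, `tissue_site`, `timepoint`; or the path of a metadata
#'   CSV.
#' @return A [til_sample()].
#' @export
read_sample <- function(cell_table_path, geometry_path, metadata) {
  if (is.character(metadata) && length(metadata) == 1 &&
      file.exists(metadata))
    metadata <- read.csv(metadata, stringsAsFactors = FALSE)
  metadata <- as.list(as.data.frame(metadata, stringsAsFactors = FALSE))
  sep <- if (grepl("\\.tsv$", cell_table_path)) "\t" else ","
  cells <- as_tibble(read.csv(cell_table_path, sep = sep,
                              stringsAsFactors = FALSE))
  required <- c("cell_id", "x_um", "y_um", TIL_MARKERS)
  missing <- setdiff(required, names(cells))
  if (length(missing))
    abort(paste0("missing column ", paste(missing, collapse = ", ")))
  geometry <- read_geometry_geojson(geometry_path,
                                    sample_id = metadata$sample_id)
  til_sample(metadata$sample_id, geometry, cells,
             patient_id = metadata$patient_id %||% metadata$sample_id,
             tissue_site = metadata$tissue_site %||% "other",
             timepoint = metadata$timepoint %||% "other")
}

contour_to_ring <- function(ct) {
  # closed ring, vertex repeated
  lapply(c(seq_along(ct$x), 1L), function(i) c(ct$x[i], ct$y[i]))
}

ring_to_contour <- function(ring, hole = FALSE) {
  m <- matrix(unlist(ring), ncol = 2, byrow = TRUE)
  # drop closing vertex if repeated
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
    m <- m[-nrow(m), , drop = FALSE]
  orient_contour(list(x = m[, 1], y = m[, 2]), hole = hole)
}

#' Write tissue geometry as GeoJSON
#'
#' One Polygon feature per compartment; solid contours become outer rings
#' and hole contours interior rings of the enclosing solid. Frame size and
#' raster resolution are stored as foreign members on the collection.
#'
#' @param geometry A [tissue_geometry()].
#' @param path Output path.
#' @export
write_geometry_geojson <- function(geometry, path) {
  features <- list()
  for (comp in c("tumor", "stroma")) {
    contours <- geometry[[comp]]
    if (!length(contours)) next
    solids <- Filter(function(ct) shoelace(ct) > 0, contours)
    holes <- Filter(function(ct) shoelace(ct) <= 0, contours)
    rings <- c(lapply(solids, contour_to_ring), lapply(holes, contour_to_ring))
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      properties = list(compartment = comp),
      geometry = list(type = "Polygon", coordinates = rings))
  }
  fc <- list(type = "FeatureCollection",
             frame_width_um = geometry$frame_width,
             frame_height_um = geometry$frame_height,
             raster_resolution_um = geometry$raster_resolution,
             sample_id = geometry$sample_id,
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tissue geometry from GeoJSON
#'
#' @param path GeoJSON file written by [write_geometry_geojson()] (or any
#'   FeatureCollection of Polygons with a `compartment` property plus
#'   `frame_width_um`/`frame_height_um` members).
#' @param sample_id Optional override of the stored sample id.
#' @return A [tissue_geometry()].
#' @export
read_geometry_geojson <- function(path, sample_id = NULL) {
  fc <- jsonlite::read_json(path)
  regions <- list(tumor = list(), stroma = list())
  for (feat in fc$features) {
    comp <- feat$properties$compartment
    rings <- feat$geometry$coordinates
    cts <- c(list(ring_to_contour(rings[[1]], hole = FALSE)),
             lapply(rings[-1], ring_to_contour, hole = TRUE))
    regions[[comp]] <- c(regions[[comp]], cts)
  }
  tissue_geometry(sample_id %||% fc$sample_id %||% "sample",
                  fc$frame_width_um, fc$frame_height_um,
                  tumor = regions$tumor, stroma = regions$stroma,
                  raster_resolution = fc$raster_resolution_um %||% 0.5,
                  normalize = FALSE)
}

#' Write a cohort to a directory
#'
#' Per-sample files via [write_sample()] plus one cohort-level
#' `cohort_metadata.csv`.
#'
#' @param cohort A `til_cohort` tibble (see [generate_cohort()]).
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::walk(cohort$sample, write_sample, dir = dir)
  meta <- dplyr::select(as_tibble(cohort), -dplyr::any_of("sample"))
  write.csv(meta, file.path(dir, "cohort_metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort_metadata.csv` and per-sample
#'   files.
#' @return A `til_cohort` tibble.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort_metadata.csv")
  if (!file.exists(meta_path))
    abort(paste0("no cohort_metadata.csv in ", dir, "; zero samples found"))
  meta <- as_tibble(read.csv(meta_path, stringsAsFactors = FALSE))
  if (nrow(meta) == 0) abort(paste0("empty cohort: zero samples in ", dir))
  samples <- purrr::pmap(meta, function(sample_id, ...) {
    read_sample(file.path(dir, paste0(sample_id, "_cells.csv")),
                file.path(dir, paste0(sample_id, "_geometry.geojson")),
                c(list(sample_id = sample_id), list(...)))
  })
  meta$sample <- samples
  class(meta) <- c("til_cohort", class(meta))
  meta
}
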