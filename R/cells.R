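# Phenotyped cell tables: compartment assignment, threshold gating into
# the four analyzed lymphocyte subsets, and counting.
#
# Marker scores are in [0, 1] (binary calls pass through as 0/1). Gating is
# hierarchical: CD3+ cells are total T cells; among them CD8+ marks
# cytotoxic and FoxP3+ regulatory T cells (a CD8+FoxP3+ cell is tallied in
# both, but once as a T cell); CD3-CD20+ cells are B cells. CD45RO is
# carried through but never analyzed; panCK never influences subset calls
# (tissue segmentation, not the cell's own panCK, defines the compartment).

#' A sample: geometry, cells and clinical metadata
#'
#' @param sample_id,patient_id Identifiers.
#' @param geometry A [tissue_geometry()].
#' @param cells Tibble with columns `cell_id`, `x_um`, `y_um` and the marker
#'   columns in [TIL_MARKERS] (scores in \[0, 1\]).
#' @param tissue_site One of [TIL_SITES].
#' @param timepoint Sampling context, e.g. `"untreated_primary"`,
#'   `"metastasis_pre_chemo"`, `"metastasis_post_chemo"`.
#' @param validate Check coordinates against the frame.
#'
#' @return An object of class `til_sample`.
#' @export
til_sample <- function(sample_id, geometry, cells,
                       patient_id = sample_id,
                       tissue_site = "other",
                       timepoint = "other",
                       validate = TRUE) {
  cells <- as_tibble(cells)
  required <- c("cell_id", "x_um", "y_um", TIL_MARKERS)
  missing <- setdiff(required, names(cells))
  if (length(missing))
    abort(paste0("missing column ", paste(missing, collapse = ", ")))
  if (validate && nrow(cells)) {
    bad <- cells$x_um < 0 | cells$x_um >= geometry$frame_width |
      cells$y_um < 0 | cells$y_um >= geometry$frame_height
    if (any(bad))
      abort(paste0("cells outside the frame: ",
                   paste(head(cells$cell_id[bad], 10), collapse = ", ")))
    scores <- as.matrix(cells[, TIL_MARKERS])
    if (any(scores < 0 | scores > 1))
      abort("marker scores must be in [0, 1]")
  }
  structure(list(sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 tissue_site = tissue_site,
                 timepoint = timepoint,
                 geometry = geometry,
                 cells = cells),
            class = "til_sample")
}

#' @export
print.til_sample <- function(x, ...) {
  cat(sprintf("<til_sample> %s (patient %s, %s, %s): %d cells\n",
              x$sample_id, x$patient_id, x$tissue_site, x$timepoint,
              nrow(x$cells)))
  invisible(x)
}

#' Assign cells to tissue compartments
#'
#' Point-in-polygon labeling of each cell as `tumor`, `stroma` or
#' `background`. Precedence on shared boundaries is tumor over stroma over
#' background: a point inside (or on the edge of) the tumor polygons is
#' tumor regardless of the stroma polygons.
#'
#' @param cells Tibble with `x_um`, `y_um` columns (or a single cell row).
#' @param geometry A [tissue_geometry()].
#' @return The cells tibble with a `compartment` column.
#' @export
assign_compartment <- function(cells, geometry) {
  cells <- as_tibble(cells)
  comp <- rep("background", nrow(cells))
  if (nrow(cells)) {
    in_tum <- points_in_contours(cells$x_um, cells$y_um, geometry$tumor)
    in_str <- points_in_contours(cells$x_um, cells$y_um, geometry$stroma)
    # even-odd ray casting can go either way exactly on a boundary;
    # documented precedence is tumor over stroma over background, so any
    # non-tumor point sitting on a tumor edge is reassigned to tumor.
    check <- which(!in_tum)
    if (length(check)) {
      on_edge <- points_near_contours(cells$x_um[check], cells$y_um[check],
                                      geometry$tumor)
      in_tum[check[on_edge]] <- TRUE
    }
    comp[in_str] <- "stroma"
    comp[in_tum] <- "tumor"
  }
  cells$compartment <- comp
  cells
}

# TRUE for points within eps of any polygon edge (boundary precedence).
points_near_contours <- function(px, py, contours, eps = 1e-9) {
  near <- rep(FALSE, length(px))
  for (ct in contours) {
    x <- ct$x; y <- ct$y
    n <- length(x)
    j <- n
    for (i in seq_len(n)) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      len2 <- dx * dx + dy * dy
      if (len2 == 0) { j <- i; next }
      t <- pmin(1, pmax(0, ((px - x[j]) * dx + (py - y[j]) * dy) / len2))
      d2 <- (px - (x[j] + t * dx))^2 + (py - (y[j] + t * dy))^2
      near <- near | d2 <= eps
      j <- i
    }
  }
  near
}

#' Gate cells into lymphocyte subsets
#'
#' Fixed-threshold gating of marker scores with the lymphocyte hierarchy:
#' CD3+ cells are total T cells; among CD3+ cells, CD8+ marks cytotoxic and
#' FoxP3+ regulatory T cells; CD3-CD20+ cells are B cells. Adds one logical
#' column per analyzed subset (`CD3_pos`, `CD8_pos`, `FoxP3_pos`,
#' `CD20_pos`) - a CD8+FoxP3+ cell is TRUE in both T-effector columns but
#' counted once as CD3+ - plus a single primary `phenotype` label.
#'
#' @param cells Cell tibble with marker score columns.
#' @param threshold Positivity threshold on the \[0, 1\] scores, in (0, 1).
#'   Default 0.5; binary 0/1 calls pass through unchanged.
#' @param require_cd3_for_cd8 Require CD3 co-expression for the cytotoxic
#'   (and regulatory) gates, as in a lymphocyte panel. Default `TRUE`.
#' @return The cells tibble with gating columns appended.
#' @export
gate_subsets <- function(cells, threshold = 0.5, require_cd3_for_cd8 = TRUE) {
  if (threshold <= 0 || threshold >= 1)
    abort("threshold must be in (0, 1)")
  cells <- as_tibble(cells)
  scores <- cells[, TIL_MARKERS]
  if (nrow(cells) && any(as.matrix(scores) < 0 | as.matrix(scores) > 1))
    abort("marker scores must be in [0, 1]")
  pos <- function(m) cells[[m]] >= threshold
  cd3 <- pos("CD3")
  cd8 <- pos("CD8") & (if (require_cd3_for_cd8) cd3 else TRUE)
  foxp3 <- pos("FoxP3") & (if (require_cd3_for_cd8) cd3 else TRUE)
  b <- pos("CD20") & !cd3
  cells$CD3_pos <- cd3
  cells$CD8_pos <- cd8
  cells$FoxP3_pos <- foxp3
  cells$CD20_pos <- b
  cells$phenotype <- dplyr::case_when(
    cd8 ~ "T_cytotoxic",
    foxp3 ~ "T_regulatory",
    cd3 ~ "T_other",
    b ~ "B_cell",
    TRUE ~ "other")
  cells
}

#' Count gated cells per subset and compartment
#'
#' @param sample A [til_sample()] whose cells are gated (see
#'   [gate_subsets()]) and compartment-assigned; ungated cells are gated
#'   with the default threshold first.
#' @return Tibble `subset`, `compartment`, `n` covering all four subsets x
#'   tumor/stroma (zero-filled).
#' @export
subset_counts <- function(sample) {
  cells <- prepare_cells(sample)
  grid <- tidyr::expand_grid(subset = TIL_SUBSETS,
                             compartment = c("tumor", "stroma"))
  counts <- purrr::pmap_int(grid, function(subset, compartment) {
    sum(cells[[paste0(subset, "_pos")]] & cells$compartment == compartment)
  })
  grid$n <- counts
  grid
}

# Ensure a sample's cells carry compartment and gating columns.
prepare_cells <- function(sample, threshold = 0.5) {
  cells <- sample$cells
  if (!"compartment" %in% names(cells))
    cells <- assign_compartment(cells, sample$geometry)
  if (!"CD3_pos" %in% names(cells))
    cells <- gate_subsets(cells, threshold = threshold)
  cells
}
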