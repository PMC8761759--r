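# Cohort-level nonparametric comparisons: tissue-site tests (Kruskal-Wallis
# with Dunn/Bonferroni post-hoc, gated on KW p <= 0.05), paired
# primary-vs-metastasis Wilcoxon signed-rank tests, replicate averaging,
# paired-change summaries and derived ratios. Missing densities (excluded
# compartments) are dropped with the effective n reported.

#' Kruskal-Wallis test on density groups
#'
#' Rank-based H with tie correction (delegated to [stats::kruskal.test()])
#' and a chi-square p-value on g - 1 degrees of freedom. Missing values are
#' dropped per group. When every value across all groups is identical the
#' degenerate result H = 0, p = 1 is returned.
#'
#' @param groups List of numeric vectors (one per group), or a data frame
#'   given with `value`/`group` column names.
#' @param value,group Column names when `groups` is a data frame.
#' @return Tibble `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups, value = "density_per_mm2",
                           group = "tissue_site") {
  groups <- as_group_list(groups, value, group)
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(lengths(groups) == 0)) abort("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)
    return(tibble(statistic = 0, df = length(groups) - 1L, p_value = 1,
                  n = length(x)))
  kt <- stats::kruskal.test(x, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n = length(x))
}

as_group_list <- function(groups, value, group) {
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]], drop = TRUE)
  }
  lapply(groups, function(v) v[!is.na(v)])
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics from mean ranks of the pooled sample with tie
#' correction, two-sided normal p-values, Bonferroni-adjusted over all
#' g(g-1)/2 pairs and capped at 1.
#'
#' @inheritParams kruskal_wallis
#' @return Tibble `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_bonferroni <- function(groups, value = "density_per_mm2",
                            group = "tissue_site") {
  groups <- as_group_list(groups, value, group)
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(lengths(groups) == 0)) abort("every group must be nonempty")
  labels <- names(groups) %||% as.character(seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  sizes <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term

  pairs <- utils::combn(length(groups), 2)
  m <- ncol(pairs)
  res <- purrr::map_dfr(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(s2 * (1 / sizes[[i1]] + 1 / sizes[[i2]]))
    z <- if (se > 0) (mean_ranks[[i1]] - mean_ranks[[i2]]) / se else 0
    tibble(group1 = labels[[i1]], group2 = labels[[i2]], z = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  res$p_adjusted <- pmin(1, res$p_value * m)
  res
}

#' Tissue-site comparison of densities
#'
#' For each subset x compartment: Kruskal-Wallis across tissue sites with
#' at least `min_per_site` non-missing samples; when KW p <= `alpha`,
#' Dunn's pairwise tests with Bonferroni correction.
#'
#' @param densities Tidy density table (e.g. [cohort_densities()]) with
#'   `subset`, `compartment`, `tissue_site`, `density_per_mm2`.
#' @param min_per_site Minimum samples per site for inclusion (default 5).
#' @param alpha Significance gate for the post-hoc tests (default 0.05).
#' @return A `site_comparison` object; see [tidy.site_comparison()].
#' @export
site_comparison <- function(densities, min_per_site = 5, alpha = 0.05) {
  combos <- dplyr::distinct(densities, .data$subset, .data$compartment) |>
    dplyr::filter(.data$compartment != "background")
  omnibus <- list(); pairwise <- list()
  for (i in seq_len(nrow(combos))) {
    ss <- combos$subset[[i]]; comp <- combos$compartment[[i]]
    d <- densities |>
      dplyr::filter(.data$subset == ss, .data$compartment == comp,
                    !is.na(.data$density_per_mm2)) |>
      dplyr::group_by(.data$tissue_site) |>
      dplyr::filter(dplyr::n() >= min_per_site) |>
      dplyr::ungroup()
    if (dplyr::n_distinct(d$tissue_site) < 2) next
    kw <- kruskal_wallis(d)
    omnibus[[length(omnibus) + 1L]] <-
      dplyr::bind_cols(tibble(subset = ss, compartment = comp), kw)
    if (kw$p_value <= alpha) {
      dn <- dunn_bonferroni(d)
      pairwise[[length(pairwise) + 1L]] <-
        dplyr::bind_cols(tibble(subset = ss, compartment = comp), dn)
    }
  }
  structure(list(omnibus = dplyr::bind_rows(omnibus),
                 pairwise = dplyr::bind_rows(pairwise),
                 alpha = alpha),
            class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("<site_comparison> %d omnibus tests, %d pairwise rows (gate p <= %.2f)\n",
              nrow(x$omnibus), nrow(x$pairwise), x$alpha))
  invisible(x)
}

#' Pairwise detail of a site comparison
#' @param x A `site_comparison`.
#' @param ... Unused.
#' @method tidy site_comparison
#' @export
tidy.site_comparison <- function(x, ...) x$pairwise

#' Omnibus summary of a site comparison
#' @param x A `site_comparison`.
#' @param ... Unused.
#' @method glance site_comparison
#' @export
glance.site_comparison <- function(x, ...) x$omnibus

#' Wilcoxon signed-rank test for paired densities
#'
#' Zero differences are dropped. With n <= 25 remaining pairs and no tied
#' absolute differences the exact two-sided p-value is used; otherwise the
#' normal approximation. All-zero differences give the degenerate p = 1.
#'
#' @param pre,post Equal-length numeric vectors; pairs with missing
#'   members are dropped.
#' @return Tibble `statistic` (V), `p_value`, `n_effective`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) abort("pre and post must be equal length")
  keep <- !is.na(pre) & !is.na(post)
  d <- post[keep] - pre[keep]
  d <- d[d != 0]
  if (length(d) == 0)
    return(tibble(statistic = 0, p_value = 1, n_effective = 0L))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = !exact))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_effective = length(d))
}

#' Average replicate samples per patient and context
#'
#' When a patient contributes several samples in the same context (two
#' primaries, multiple metastasis biopsies), their densities are averaged
#' into one value per patient, context, subset and compartment. Missing
#' densities are excluded from the mean; an all-missing group stays
#' missing.
#'
#' @param densities Tidy density table with `patient_id`, `timepoint`,
#'   `subset`, `compartment`, `density_per_mm2`.
#' @return Tibble with one averaged `density_per_mm2` per group and the
#'   effective number of samples `n_samples`.
#' @export
average_replicates <- function(densities) {
  densities |>
    dplyr::group_by(.data$patient_id, .data$timepoint, .data$subset,
                    .data$compartment) |>
    dplyr::summarise(
      n_samples = sum(!is.na(.data$density_per_mm2)),
      density_per_mm2 = if (all(is.na(.data$density_per_mm2))) NA_real_
        else mean(.data$density_per_mm2, na.rm = TRUE),
      .groups = "drop")
}

#' Summary of paired density changes
#'
#' Per-pair change (post - pre, cells/mm^2) summarized by median, min, max
#' and the number of pairs that decreased - the descriptive summary used
#' for small chemotherapy cohorts where formal testing is not appropriate.
#'
#' @param pre,post Equal-length numeric vectors; pairs with a missing
#'   member are dropped.
#' @return Tibble `n_pairs`, `median_change`, `min_change`, `max_change`,
#'   `n_decreased`.
#' @export
paired_change_summary <- function(pre, post) {
  if (length(pre) != length(post)) abort("pre and post must be equal length")
  keep <- !is.na(pre) & !is.na(post)
  if (!any(keep)) abort("no valid pairs")
  d <- post[keep] - pre[keep]
  tibble(n_pairs = length(d), median_change = median(d),
         min_change = min(d), max_change = max(d),
         n_decreased = sum(d < 0))
}

#' Paired changes across subsets and compartments
#'
#' Joins pre and post densities per patient (after [average_replicates()])
#' and summarizes the change per subset x compartment.
#'
#' @param densities Tidy density table with `patient_id`, `timepoint`,
#'   `subset`, `compartment`, `density_per_mm2`.
#' @param pre,post Timepoint labels to pair.
#' @return Tibble with one [paired_change_summary()] row per subset x
#'   compartment.
#' @export
paired_changes <- function(densities,
                           pre = "metastasis_pre_chemo",
                           post = "metastasis_post_chemo") {
  avg <- average_replicates(
    dplyr::filter(densities, .data$timepoint %in% c(pre, post)))
  wide <- avg |>
    dplyr::select("patient_id", "timepoint", "subset", "compartment",
                  "density_per_mm2") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = "density_per_mm2")
  if (!all(c(pre, post) %in% names(wide))) abort("no valid pairs")
  wide |>
    dplyr::group_by(.data$subset, .data$compartment) |>
    dplyr::group_modify(~ paired_change_summary(.x[[pre]], .x[[post]])) |>
    dplyr::ungroup()
}

#' Intratumoral/stromal and FoxP3/CD8 density ratios
#'
#' Per-sample ratio of intratumoral to stromal density for each subset and
#' of FoxP3+ to CD8+ density within each compartment. Ratios are missing
#' when the denominator is zero or missing.
#'
#' @param densities Tidy density table with `sample_id`, `subset`,
#'   `compartment`, `density_per_mm2`.
#' @return Tibble `sample_id`, `ratio` (label), `value`.
#' @export
density_ratios <- function(densities) {
  wide <- densities |>
    dplyr::select("sample_id", "subset", "compartment",
                  "density_per_mm2") |>
    tidyr::pivot_wider(names_from = c("subset", "compartment"),
                       values_from = "density_per_mm2")
  safe_ratio <- function(num, den) {
    ifelse(is.na(den) | den == 0, NA_real_, num / den)
  }
  out <- list()
  for (ss in TIL_SUBSETS) {
    out[[length(out) + 1L]] <- tibble(
      sample_id = wide$sample_id,
      ratio = paste0(ss, "_tumor_over_stroma"),
      value = safe_ratio(wide[[paste0(ss, "_tumor")]],
                         wide[[paste0(ss, "_stroma")]]))
  }
  for (comp in c("tumor", "stroma")) {
    out[[length(out) + 1L]] <- tibble(
      sample_id = wide$sample_id,
      ratio = paste0("FoxP3_over_CD8_", comp),
      value = safe_ratio(wide[[paste0("FoxP3_", comp)]],
                         wide[[paste0("CD8_", comp)]]))
  }
  dplyr::bind_rows(out)
}
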