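# Nonparametric cohort statistics and paired summaries.

test_that("Kruskal-Wallis matches the hand-ranked H and the reference", {
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/42 * (12 + 75) - 21 = 3.857
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 3.857, tolerance = 5e-4)
  # identical groups -> degenerate H = 0, p = 1
  kw0 <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  # random groups match stats::kruskal.test to 1e-9
  withr::with_seed(5, {
    gs <- list(rnorm(12), rnorm(9, 0.5), rnorm(15, 1))
  })
  kw2 <- kruskal_wallis(gs)
  ref <- kruskal.test(gs)
  expect_equal(kw2$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(kw2$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("data-frame interface drops missing densities", {
  df <- tibble::tibble(
    tissue_site = rep(c("a", "b"), each = 4),
    density_per_mm2 = c(1, 2, 3, NA, 10, 11, 12, NA))
  kw <- kruskal_wallis(df)
  expect_equal(kw$n, 6)
})

test_that("Dunn z^2 equals the Kruskal-Wallis H for two tie-free groups", {
  withr::with_seed(9, {
    gs <- list(a = rnorm(10), b = rnorm(14, 1))
  })
  dn <- dunn_bonferroni(gs)
  kw <- kruskal_wallis(gs)
  expect_equal(dn$z^2, kw$statistic, tolerance = 1e-9)
})

test_that("Dunn pairwise behavior on constructed groups", {
  withr::with_seed(11, {
    sep <- list(lo = rnorm(20, 0), hi = rnorm(20, 3))
  })
  dn <- dunn_bonferroni(sep)
  expect_lt(dn$p_adjusted, 0.01)
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  dn2 <- dunn_bonferroni(same)
  expect_true(all(dn2$p_adjusted == 1))
  five <- lapply(1:5, function(i) rnorm(6, i))
  expect_equal(nrow(dunn_bonferroni(five)), 10)
  expect_error(dunn_bonferroni(list(1:3, numeric(0))), "nonempty")
})

test_that("site comparison gates pairwise tests on the omnibus p-value", {
  withr::with_seed(13, {
    d <- purrr::map_dfr(c(lymph_node = 800, urinary_tract = 350,
                          bone = 100), function(m) {
      tibble::tibble(density_per_mm2 = rpois(8, m))
    }, .id = "tissue_site")
  })
  d$subset <- "CD3"; d$compartment <- "tumor"
  sc <- site_comparison(d)
  expect_equal(nrow(glance(sc)), 1)
  expect_lte(glance(sc)$p_value, 0.05)
  expect_equal(nrow(tidy(sc)), 3)
  # flat densities -> no pairwise family
  withr::with_seed(14, {
    flat <- tibble::tibble(
      tissue_site = rep(c("a", "b", "c"), each = 8),
      density_per_mm2 = rnorm(24, 100, 1),
      subset = "CD3", compartment = "tumor")
  })
  sc2 <- site_comparison(flat)
  if (glance(sc2)$p_value > 0.05) expect_equal(nrow(tidy(sc2)), 0)
})

test_that("Dunn flags the configured separation more than null pairs", {
  withr::with_seed(15, {
    hits <- matrix(0, nrow = 40, ncol = 2)
    for (r in 1:40) {
      d <- tibble::tibble(
        tissue_site = rep(c("lymph_node", "urinary_tract", "bone"),
                          each = 7),
        density_per_mm2 = c(rpois(7, 500), rpois(7, 480), rpois(7, 150)))
      dn <- dunn_bonferroni(d)
      ln_bone <- dn$p_adjusted[dn$group1 == "bone" &
                                 dn$group2 == "lymph_node" |
                                 dn$group1 == "lymph_node" &
                                 dn$group2 == "bone"]
      ln_ut <- dn$p_adjusted[dn$group1 == "lymph_node" &
                               dn$group2 == "urinary_tract" |
                               dn$group1 == "urinary_tract" &
                               dn$group2 == "lymph_node"]
      hits[r, ] <- c(ln_bone < 0.05, ln_ut < 0.05)
    }
  })
  expect_gt(sum(hits[, 1]), sum(hits[, 2]))
})

test_that("Wilcoxon signed-rank: exact enumeration, degenerates, reference", {
  # 5 pairs, all increases, distinct |d|: two-sided exact p = 2/2^5
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 6, 9, 12))
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$n_effective, 5)
  # all differences zero -> degenerate p = 1
  w0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$p_value, 1)
  expect_equal(w0$n_effective, 0)
  # random pairs match stats::wilcox.test
  withr::with_seed(21, {
    pre <- rnorm(12); post <- pre + rnorm(12, 0.3)
  })
  w2 <- wilcoxon_signed_rank(pre, post)
  ref <- wilcox.test(post, pre, paired = TRUE, exact = TRUE)
  expect_equal(w2$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("replicate averaging respects missing-density semantics", {
  d <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3", "p3"),
    timepoint = "untreated_primary",
    subset = "CD3", compartment = "tumor",
    density_per_mm2 = c(100, 200, 150, 100, NA))
  avg <- average_replicates(d)
  expect_equal(avg$density_per_mm2[avg$patient_id == "p1"], 150)
  expect_equal(avg$density_per_mm2[avg$patient_id == "p2"], 150)
  # MISSING excluded from the mean
  expect_equal(avg$density_per_mm2[avg$patient_id == "p3"], 100)
  expect_equal(avg$n_samples[avg$patient_id == "p3"], 1)
  # all-missing stays missing
  d2 <- d; d2$density_per_mm2 <- NA_real_
  expect_true(all(is.na(average_replicates(d2)$density_per_mm2)))
})

test_that("paired change summaries match brute force", {
  s <- paired_change_summary(c(100, 200, 300), c(50, 150, 350))
  expect_equal(s$median_change, -50)
  expect_equal(s$min_change, -50)
  expect_equal(s$max_change, 50)
  expect_equal(s$n_decreased, 2)
  s1 <- paired_change_summary(10, 5)
  expect_equal(c(s1$median_change, s1$min_change, s1$max_change),
               c(-5, -5, -5))
  expect_error(paired_change_summary(NA_real_, 5), "no valid pairs")
  withr::with_seed(31, {
    pre <- runif(50, 0, 500); post <- runif(50, 0, 500)
  })
  s2 <- paired_change_summary(pre, post)
  expect_equal(s2$median_change, median(post - pre))
  expect_equal(s2$n_decreased, sum(post - pre < 0))
})

test_that("paired T-cell decreases are recovered under a 0.5 multiplier", {
  # density-level paired cohorts: 20 seeded cohorts of 9 pairs
  withr::with_seed(41, {
    ok <- vapply(1:20, function(r) {
      pre <- rpois(9, 1200) / 3.3
      post <- rpois(9, 600) / 3.3
      paired_change_summary(pre, post)$median_change < 0
    }, logical(1))
  })
  expect_gte(mean(ok), 0.95)
})

test_that("density ratios go missing on zero or missing denominators", {
  d <- tidyr::expand_grid(sample_id = c("a", "b"),
                          subset = TIL_SUBSETS,
                          compartment = c("tumor", "stroma"))
  d$density_per_mm2 <- 100
  d$density_per_mm2[d$sample_id == "b" & d$subset == "CD8" &
                      d$compartment == "stroma"] <- 0
  r <- density_ratios(d)
  expect_equal(r$value[r$sample_id == "a" &
                         r$ratio == "CD8_tumor_over_stroma"], 1)
  expect_true(is.na(r$value[r$sample_id == "b" &
                              r$ratio == "CD8_tumor_over_stroma"]))
  expect_equal(r$value[r$sample_id == "a" &
                         r$ratio == "FoxP3_over_CD8_tumor"], 1)
})
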