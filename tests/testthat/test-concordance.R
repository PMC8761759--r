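# Quartile concordance: means, cutpoints, assignment, the correct
# classification rate and the area sweep.

test_that("sample means average the k region densities", {
  tbl <- manual_region_tbl(list(s1 = c(100, 200, 300, 400),
                                s2 = c(0, 0, 0, 0)))
  m <- sample_region_means(tbl, "CD3")
  expect_equal(m$mean_density[m$sample_id == "s1"], 250)
  expect_equal(m$mean_density[m$sample_id == "s2"], 0)
})

test_that("ineligible samples are skipped with a log entry", {
  tbl <- dplyr::bind_rows(
    manual_region_tbl(list(s1 = c(1, 2), s2 = c(3, 4))),
    tibble::tibble(sample_id = "s3", eligible = FALSE,
                   region_id = NA_integer_, subset = NA_character_,
                   density_per_mm2 = NA_real_, tumor_fraction = NA_real_))
  expect_message(m <- sample_region_means(tbl, "CD3"),
                 class = "tilhet_ineligible")
  expect_equal(sort(m$sample_id), c("s1", "s2"))
})

test_that("quartile cutpoints interpolate order statistics (type 7)", {
  expect_equal(unname(quartile_cutpoints(1:8)), c(2.75, 4.5, 6.25))
  expect_equal(unname(quartile_cutpoints(rep(3.2, 6))), c(3.2, 3.2, 3.2))
  expect_equal(unname(quartile_cutpoints(rep(c(0, 100), each = 4)))[2], 50)
  expect_error(quartile_cutpoints(c(1, 2, 3)), "at least 4")
})

test_that("quartile assignment uses right-closed intervals", {
  cp <- c(10, 20, 30)
  expect_equal(assign_quartile(10, cp), 1L) # boundary falls low
  expect_equal(assign_quartile(10.0001, cp), 2L)
  expect_equal(assign_quartile(31, cp), 4L)
  expect_equal(assign_quartile(c(-5, 15, 25, 1e6), cp), c(1L, 2L, 3L, 4L))
  # degenerate equal cutpoints: lowest applicable quartile
  expect_equal(assign_quartile(7, c(7, 7, 7)), 1L)
  expect_error(assign_quartile(1, c(3, 2, 1)), "nondecreasing")
})

test_that("zero within-sample variance with distinct means gives 100%", {
  means <- c(15, 25, 35, 45, 55, 65, 75, 85)
  tbl <- manual_region_tbl(setNames(lapply(means, rep, 4),
                                    paste0("s", 1:8)))
  cc <- correct_classification_rate(tbl, "CD3")
  expect_equal(cc$correct_rate, 100)
  expect_equal(cc$n_samples, 8)
})

test_that("a hand-worked mixed cohort gives 28/32 = 87.5%", {
  dens <- setNames(lapply(seq(10, 80, by = 10), rep, 4), paste0("s", 1:8))
  dens$s3 <- c(10, 10, 50, 50) # mean stays 30
  tbl <- manual_region_tbl(dens)
  cc <- correct_classification_rate(tbl, "CD3")
  expect_equal(unname(cc$cutpoints), c(27.5, 45, 62.5))
  expect_equal(cc$correct_rate, 87.5)
  bad <- cc$regions[cc$regions$sample_id == "s3", ]
  expect_true(all(!bad$correct))
})

test_that("tidy and glance expose the result tables", {
  tbl <- manual_region_tbl(setNames(lapply(c(1, 2, 3, 4) * 10, rep, 4),
                                    paste0("s", 1:4)))
  cc <- correct_classification_rate(tbl, "CD3")
  td <- tidy(cc)
  expect_true(all(c("sample_id", "region_id", "quartile", "correct") %in%
                    names(td)))
  gl <- glance(cc)
  expect_equal(gl$correct_rate, 100)
  expect_equal(gl$region_area_mm2, 0.28)
})

test_that("exchangeable-sample rate matches an independent enumeration oracle", {
  # With k regions entering their own sample's mean, a region and its mean
  # correlate at sd(mean)/sd(region) = 1/sqrt(k); the null rate therefore
  # sits near 39% for k = 4, not at the naive 25% independence floor.
  oracle_rate <- function(n, k, seed) {
    withr::with_seed(seed, {
      x <- matrix(rpois(n * k, 98), n, k)
    })
    m <- rowMeans(x)
    cp <- quantile(m, c(.25, .5, .75), type = 7)
    q <- function(v) 1 + (v > cp[1]) + (v > cp[2]) + (v > cp[3])
    100 * mean(q(x) == matrix(q(m), n, k))
  }
  pkg_rate <- function(n, k, seed) {
    withr::with_seed(seed, {
      dens <- lapply(seq_len(n), function(i) rpois(k, 98) / 0.28)
    })
    names(dens) <- sprintf("s%03d", seq_len(n))
    correct_classification_rate(manual_region_tbl(dens), "CD3")$correct_rate
  }
  pkg <- mean(vapply(1:30, function(r) pkg_rate(100, 4, 500 + r),
                     numeric(1)))
  ora <- mean(vapply(1:30, function(r) oracle_rate(100, 4, 800 + r),
                     numeric(1)))
  expect_lt(abs(pkg - ora), 4)
  expect_gt(pkg, 30)
  expect_lt(pkg, 46)
})

test_that("increasing between-sample separation never hurts the rate", {
  # separation grid at fixed within-sample noise, at the matrix level
  rate_at <- function(sep, seed) {
    withr::with_seed(seed, {
      means <- 200 + sep * rep(c(-1.5, -0.5, 0.5, 1.5), each = 5) * 50
      dens <- lapply(means, function(m) pmax(0, rnorm(4, m, 40)))
      names(dens) <- paste0("s", seq_along(dens))
    })
    correct_classification_rate(manual_region_tbl(dens), "CD3")$correct_rate
  }
  grid <- c(0, 1, 2.5)
  mean_rates <- vapply(grid, function(sep)
    mean(vapply(1:20, function(r) rate_at(sep, 7000 + r), numeric(1))),
    numeric(1))
  expect_true(all(diff(mean_rates) > -1e-9))
  expect_gt(mean_rates[3], mean_rates[1] + 10)
})

test_that("the area sweep re-evaluates eligibility per area", {
  cfg <- cohort_config(n_patients = 5, n_chemo_pairs = 0,
                       mean_extra_samples = 0,
                       process = "homogeneous_poisson",
                       tumor_cell_intensity = 0, seed = 19)
  co <- generate_cohort(cfg)
  sw <- concordance_sweep(co, areas_mm2 = c(0.28, 3.30), subsets = "CD3",
                          seed = 3)
  expect_equal(nrow(sw), 2)
  small <- sw[sw$region_area_mm2 == 0.28, ]
  large <- sw[sw$region_area_mm2 == 3.30, ]
  expect_equal(small$n_eligible, 5)
  # 4 x 3.30 mm^2 cannot fit in ~3.3 mm^2 tumors
  expect_equal(large$n_eligible, 0)
  expect_true(is.na(large$correct_rate))
  sw2 <- concordance_sweep(co, areas_mm2 = c(0.28, 3.30), subsets = "CD3",
                           seed = 3)
  expect_identical(sw, sw2)
})
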