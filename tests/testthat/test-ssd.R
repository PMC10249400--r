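test_that("PDF points count surviving richness at each threshold level", {
  pts <- build_pdf_points(c(1, 2, 2, 4))
  expect_equal(pts$conc, c(1, 2, 4))
  expect_equal(pts$sr, c(4L, 3L, 1L))
  expect_equal(pts$pdf, c(0, 0.25, 0.75))
  expect_equal(attr(pts, "sr_max"), 4L)

  # single species: one point with PDF 0
  one <- build_pdf_points(3)
  expect_equal(one$pdf, 0)
  expect_equal(one$sr, 1L)

  # all-distinct thresholds: PDF tops out at (n-1)/n
  n <- 17L
  set.seed(2); thr <- runif(n, 0.1, 5)
  pts <- build_pdf_points(thr)
  expect_equal(max(pts$pdf), (n - 1) / n)
  # invariant to input ordering; values on the 1/SR_max lattice
  expect_equal(build_pdf_points(rev(thr)), pts, ignore_attr = TRUE)
  expect_equal(pts$pdf * n, round(pts$pdf * n), tolerance = 1e-9)
  expect_true(!is.unsorted(pts$pdf))
  expect_equal(pts$pdf[1], 0)
})

test_that("fitting requires more than three PDF-concentration pairs", {
  expect_equal(check_eligibility(data.frame(conc = 1:3, pdf = 0:2 / 3)),
               "insufficient_data")
  expect_equal(check_eligibility(data.frame(conc = 1:4, pdf = 0:3 / 4)),
               "eligible")
  expect_equal(check_eligibility(data.frame()), "insufficient_data")
})

test_that("the logistic SSD has its midpoint at a and is strictly increasing", {
  for (p in list(c(2, 0.5), c(0.3, 0.05), c(17, 4))) {
    expect_equal(evaluate_ssd(p[1], p[2], p[1]), 0.5)
  }
  expect_equal(evaluate_ssd(2, 0.5, 3), 1 / (1 + exp(-2)))
  C <- seq(0, 6, by = 0.1)
  pdf <- evaluate_ssd(2, 0.5, C)
  expect_true(all(diff(pdf) > 0))
  expect_true(all(pdf > 0 & pdf < 1))
  # far below a (relative to b) the community is unaffected
  expect_lt(evaluate_ssd(10, 0.5, 0.01), 1e-6)
  expect_error(evaluate_ssd(2, 0, 1), "b must be")
})

test_that("noise-free logistic points are recovered to high precision", {
  pts <- data.frame(conc = seq(0.5, 4, length.out = 9))
  pts$pdf <- evaluate_ssd(2, 0.5, pts$conc)
  f <- fit_ssd(pts)
  expect_equal(f$status, "fitted")
  expect_equal(f$a, 2, tolerance = 1e-6)
  expect_equal(f$b, 0.5, tolerance = 1e-6)
  expect_equal(f$pseudo_r2, 1, tolerance = 1e-9)
  expect_equal(f$nrmse, 0, tolerance = 1e-6)
  expect_true(f$good_fit)
})

test_that("the fitter matches a dense grid-search oracle", {
  set.seed(31)
  for (k in 1:10) {
    a <- runif(1, 1, 4); b <- runif(1, 0.2, 1)
    pts <- data.frame(conc = sort(runif(12, 0.2, 6)))
    pts$pdf <- pmin(pmax(
      evaluate_ssd(a, b, pts$conc) + rnorm(12, 0, 0.03), 0), 1)
    f <- fit_ssd(pts)
    expect_equal(f$status, "fitted")
    oracle <- grid_search_ssd(pts)
    expect_lte(ssd_ssr(pts, f$a, f$b), oracle$ssr + 1e-8)
  }
})

test_that("parameter recovery through the full chain is within 10% at n=200", {
  w <- generate_world(world_config(
    regions = list(region_def(1L, 101L, c(0L, 0L, 10L, 10L), 2, 0.5, 200L)),
    grid = grid_spec(12L, 12L), seed = 21L))
  res <- analyse_world(w)
  fits <- fit_all_regions(res$tol)
  f <- fits[fits$level == "ecoregion", ]
  expect_equal(f$status, "fitted")
  expect_lt(abs(f$a - 2) / 2, 0.1)
  expect_lt(abs(f$b - 0.5) / 0.5, 0.1)
  expect_true(f$good_fit)
})

test_that("estimator bias shrinks as the species pool grows", {
  err_for <- function(n, block, grid_n, seeds = 1:5) {
    e <- sapply(seeds, function(s) {
      w <- generate_world(world_config(
        regions = list(region_def(1L, 101L, c(0L, 0L, block, block),
                                  2, 0.5, n)),
        grid = grid_spec(grid_n, grid_n), seed = 100L + s))
      fits <- fit_all_regions(analyse_world(w)$tol)
      f <- fits[fits$level == "ecoregion", ]
      abs(f$a - 2) / 2 + abs(f$b - 0.5) / 0.5
    })
    mean(e)
  }
  expect_lt(err_for(500L, 14L, 16L), err_for(50L, 8L, 12L))
})

test_that("Cox-Snell pseudo-R2 reduces to 1 - RSS1/RSS0", {
  expect_equal(cox_snell_r2(c(0, 0.2, 0.6, 1), c(0, 0.2, 0.6, 1)), 1)
  obs <- c(0, 0.1, 0.3, 0.55, 0.8, 0.95)
  expect_equal(cox_snell_r2(obs, rep(mean(obs), 6)), 0)
  set.seed(12)
  for (k in 1:5) {
    obs <- sort(runif(6))
    fitd <- pmin(pmax(obs + rnorm(6, 0, 0.1), 0), 1)
    rss1 <- sum((obs - fitd)^2)
    rss0 <- sum((obs - mean(obs))^2)
    expect_equal(cox_snell_r2(obs, fitd), 1 - rss1 / rss0)
  }
  expect_warning(v <- cox_snell_r2(rep(0.5, 4), c(0.4, 0.5, 0.6, 0.5)),
                 "undefined")
  expect_true(is.na(v))
})

test_that("NRMSE is the RMS residual over the mean observed PDF", {
  obs <- c(0.1, 0.3, 0.5, 0.7)
  expect_equal(nrmse(obs, obs), 0)
  # constant residual r: NRMSE = |r| / mean
  expect_equal(nrmse(obs, obs + 0.05), 0.05 / mean(obs))
  expect_warning(v <- nrmse(c(0, 0, 0), c(0, 0.1, 0)), "undefined")
  expect_true(is.na(v))
})

test_that("batch fitting records statuses without raising", {
  tol <- rbind(
    data.frame(accepted_name = paste0("s", 1:3), level = "ecoregion",
               region_id = 1L, threshold = c(1, 2, 3), n_matched = 1L),
    data.frame(accepted_name = paste0("t", 1:8), level = "ecoregion",
               region_id = 2L, threshold = seq(0.5, 4, length.out = 8),
               n_matched = 1L))
  fits <- fit_all_regions(tol)
  expect_equal(fits$status[fits$region_id == 1L], "insufficient_data")
  expect_equal(fits$status[fits$region_id == 2L], "fitted")
  expect_false(fits$good_fit[fits$region_id == 1L])
  empty <- fit_all_regions(tol[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty),
               c("region_id", "level", "a", "b", "n_pairs", "sr_max",
                 "pseudo_r2", "nrmse", "status", "good_fit"))
})

test_that("the log10 switch fits on log-concentration when enabled", {
  pts <- data.frame(conc = 10^seq(-0.5, 1, length.out = 8))
  pts$pdf <- plogis((log10(pts$conc) - 0.3) / 0.2)
  f <- fit_ssd(pts, log10 = TRUE)
  expect_equal(f$a, 0.3, tolerance = 1e-5)
  expect_equal(f$b, 0.2, tolerance = 1e-5)
  expect_equal(evaluate_ssd(f$a, f$b, 10^0.3, log10 = TRUE), 0.5,
               tolerance = 1e-5)
})
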