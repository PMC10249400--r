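fit_2_05 <- list(a = 2, b = 0.5, status = "fitted", log10 = FALSE)

test_that("marginal EF is 1000 times the SSD derivative", {
  # at the midpoint the logistic derivative is 1/(4b)
  expect_equal(marginal_ef(fit_2_05, 2), 1000 * 0.25 / 0.5)
  # saturated community: derivative vanishes far above a
  expect_lt(marginal_ef(fit_2_05, 30), 1e-15)
  # finite-difference oracle over assorted fits and concentrations
  set.seed(41)
  for (k in 1:10) {
    f <- list(a = runif(1, 0.5, 5), b = runif(1, 0.1, 2),
              status = "fitted", log10 = FALSE)
    C <- runif(1, 0.01, 8)
    h <- 1e-6 * max(C, 1)
    fd <- 1000 * (evaluate_ssd(f$a, f$b, C + h) -
                    evaluate_ssd(f$a, f$b, C - h)) / (2 * h)
    expect_equal(marginal_ef(f, C), fd, tolerance = 1e-4)
  }
  # unit self-consistency: raw derivative times 1000 is the reported value
  p <- evaluate_ssd(2, 0.5, 1.3)
  raw <- p * (1 - p) / 0.5
  expect_identical(marginal_ef(fit_2_05, 1.3), 1000 * raw)
})

test_that("average EF is the secant of the SSD times 1000", {
  expect_equal(average_ef(fit_2_05, 3, 1),
               1000 * (plogis((3 - 2) / 0.5) - plogis((1 - 2) / 0.5)) / 2)
  expect_equal(average_ef(fit_2_05, 3, 1), 380.797, tolerance = 1e-3)
  # equal states collapse to the marginal EF
  expect_equal(average_ef(fit_2_05, 2, 2), marginal_ef(fit_2_05, 2))
  # near-zero reference with a >> b approaches 1000 PDF(C)/C
  f <- list(a = 5, b = 0.2, status = "fitted", log10 = FALSE)
  expect_equal(average_ef(f, 6, 1e-9),
               1000 * evaluate_ssd(5, 0.2, 6) / 6, tolerance = 1e-6)
  # the secant of a strictly increasing SSD is positive either way round
  expect_gt(average_ef(fit_2_05, 3, 1), 0)
  expect_gt(average_ef(fit_2_05, 1, 3), 0)
  # continuity across the equality tolerance
  tol <- 1e-12
  d_wide <- abs(average_ef(fit_2_05, 2 + 10 * tol, 2, ref_tol = tol) -
                  marginal_ef(fit_2_05, 2 + 10 * tol))
  expect_lt(d_wide, 1e-6)
  expect_equal(average_ef(fit_2_05, 2 + tol / 10, 2, ref_tol = tol),
               marginal_ef(fit_2_05, 2 + tol / 10))
})

make_ef_inputs <- function() {
  cur <- matrix(2, 4, 4); ref <- matrix(0.5, 4, 4)
  eco <- matrix(NA_integer_, 4, 4); mht <- matrix(NA_integer_, 4, 4)
  eco[1:2, ] <- 1L; eco[3:4, ] <- 2L
  mht[, ] <- 9L
  fits <- data.frame(
    region_id = c(1L, 2L, 9L),
    level = c("ecoregion", "ecoregion", "realm_mht"),
    a = c(2, 2.5, 3), b = c(0.5, 0.6, 0.7),
    n_pairs = 10L, sr_max = 10L, pseudo_r2 = c(0.9, 0.3, 0.9),
    nrmse = 0.2, status = "fitted",
    good_fit = c(TRUE, FALSE, TRUE))
  list(cur = cur, ref = ref, eco = eco, mht = mht, fits = fits)
}

test_that("gridded EFs apply the zero cutoff and hierarchical fallback", {
  x <- make_ef_inputs()
  x$cur[1, 1] <- 5e-5          # below cutoff
  x$cur[1, 2] <- NA            # missing concentration
  ef <- compute_ef_grid(x$cur, x$ref, x$eco, x$mht, x$fits)
  expect_true(is.na(ef$marginal[1, 1]) && is.na(ef$average[1, 1]))
  expect_equal(ef$reason[1, 1], 1L)
  expect_equal(ef$reason[1, 2], 1L)
  # region 1 cells use the ecoregion fit
  f1 <- list(a = 2, b = 0.5, status = "fitted", log10 = FALSE)
  expect_equal(ef$marginal[2, 3], marginal_ef(f1, 2))
  expect_equal(ef$average[2, 3], average_ef(f1, 2, 0.5))
  # region 2's ecoregion fit fails the good-fit screen -> realm-MHT fit
  f9 <- list(a = 3, b = 0.7, status = "fitted", log10 = FALSE)
  expect_equal(ef$marginal[3, 1], marginal_ef(f9, 2))
  expect_equal(ef$reason[3, 1], 0L)
})

test_that("cells without any usable SSD or reference are flagged", {
  x <- make_ef_inputs()
  x$mht[3:4, ] <- NA           # region 2 has no fallback either
  ef <- compute_ef_grid(x$cur, x$ref, x$eco, x$mht, x$fits)
  expect_true(all(is.na(ef$marginal[3:4, ])))
  expect_true(all(ef$reason[3:4, ] == 2L))
  # undefined reference: marginal kept, average missing
  x2 <- make_ef_inputs()
  x2$ref[2, 2] <- NA
  ef2 <- compute_ef_grid(x2$cur, x2$ref, x2$eco, x2$mht, x2$fits)
  expect_false(is.na(ef2$marginal[2, 2]))
  expect_true(is.na(ef2$average[2, 2]))
  expect_equal(ef2$reason[2, 2], 3L)
  # shape mismatch is a hard error
  expect_error(compute_ef_grid(x$cur[1:3, ], x$ref, x$eco, x$mht, x$fits),
               "shape")
})

test_that("marginal EFs are nonnegative wherever defined", {
  w <- generate_world(two_region_world(seed = 12L))
  res <- analyse_world(w)
  fits <- fit_all_regions(res$tol)
  ef <- compute_ef_grid(w$conc[["2010"]], w$conc[["1900"]],
                        w$region_eco, w$region_mht, fits)
  def <- !is.na(ef$marginal)
  expect_true(any(def))
  expect_true(all(ef$marginal[def] >= 0))
  # every in-block cell above the cutoff got an EF (all regions fitted)
  in_block <- !is.na(w$region_eco) & w$conc[["2010"]] >= 1e-4
  expect_true(all(!is.na(ef$marginal[in_block])))
  # outside the blocks concentration is zero -> reason zero_N
  expect_true(all(ef$reason[is.na(w$region_eco)] == 1L))
})

test_that("EF class areas partition the defined cells", {
  ef <- matrix(c(10, 500, 2e5, NA), 2, 2)
  attr(ef, "grid") <- grid_spec(2L, 2L)
  tab <- ef_class_areas(ef)
  expect_equal(sum(tab$n_cells), 3L)
  expect_equal(tab$n_cells, c(1L, 1L, 1L))
  expect_equal(sum(tab$area_fraction), 1)
})
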