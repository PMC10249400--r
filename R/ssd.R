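#' Build disappeared-fraction points for one region
#'
#' Converts the tolerance thresholds of a region's species pool into
#' empirical (concentration, PDF) pairs. The concentration levels are
#' the sorted unique thresholds; at level \eqn{C_j} the surviving
#' richness \eqn{SR_j} counts species with threshold \eqn{\ge C_j}, and
#' the potentially disappeared fraction is
#' \deqn{PDF_j = 1 - SR_j / SR_{max},}
#' where \eqn{SR_{max}} is the region's total species count. By
#' construction the PDF at the smallest level is 0 and the points are
#' non-decreasing in concentration.
#'
#' @param thresholds Numeric vector of per-species tolerance thresholds
#'   (mg/L) for one region, one entry per species.
#' @return Data.frame: `conc`, `sr` (surviving richness), `pdf`; the
#'   total richness is attached as attribute `"sr_max"`.
#' @examples
#' build_pdf_points(c(1, 2, 2, 4))
#' @export
build_pdf_points <- function(thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L,
            all(thresholds > 0))
  sr_max <- length(thresholds)
  lev <- sort(unique(thresholds))
  sr <- vapply(lev, function(l) sum(thresholds >= l), integer(1))
  out <- data.frame(conc = lev, sr = sr, pdf = 1 - sr / sr_max)
  attr(out, "sr_max") <- sr_max
  out
}

#' Eligibility of a point set for SSD fitting
#'
#' A region's data are sufficient for fitting only with more than three
#' PDF--concentration pairs.
#'
#' @param points Data.frame from [build_pdf_points()] (or anything with
#'   rows as pairs).
#' @return `"eligible"` or `"insufficient_data"`.
#' @export
check_eligibility <- function(points) {
  if (NROW(points) >= 4L) "eligible" else "insufficient_data"
}

#' Evaluate a logistic SSD
#'
#' The SSD gives the potentially disappeared fraction of species at
#' total-N concentration `C`:
#' \deqn{PDF(C) = \frac{1}{1 + e^{-(C - a)/b}},}
#' where `a` (mg/L) is the concentration at which 50% of the species
#' have disappeared and `b` (mg/L, > 0) sets the slope. With
#' `log10 = TRUE` the curve is evaluated on `log10(C)` instead (then `a`
#' is in log10 mg/L units).
#'
#' @param a,b Logistic coefficients; `b > 0`.
#' @param C Concentration(s), mg/L (non-negative; positive if `log10`).
#' @param log10 Evaluate on the log10 concentration scale (default
#'   `FALSE`).
#' @return PDF value(s) in (0, 1).
#' @examples
#' evaluate_ssd(2, 0.5, 2)   # 0.5 by definition of a
#' evaluate_ssd(2, 0.5, 3)   # 1 / (1 + exp(-2))
#' @export
evaluate_ssd <- function(a, b, C, log10 = FALSE) {
  if (any(b <= 0)) stop("b must be > 0", call. = FALSE)
  x <- if (log10) base::log10(C) else C
  stats::plogis((x - a) / b)
}

#' Cox-Snell pseudo-R-squared of an SSD fit
#'
#' Likelihood-ratio statistic comparing the fitted curve to an
#' intercept-only null, \eqn{R^2_{CS} = 1 - (L_0/L_1)^{2/n}}. With
#' Gaussian likelihoods whose variance is the maximum-likelihood
#' residual variance this reduces algebraically to
#' \eqn{1 - RSS_1/RSS_0}, where \eqn{RSS_0} is the residual sum of
#' squares around the mean observed PDF.
#'
#' @param observed Observed PDF values.
#' @param fitted Fitted PDF values.
#' @return The pseudo-R-squared, or `NA` (with a warning) when all
#'   observed values are identical (\eqn{RSS_0 = 0}).
#' @export
cox_snell_r2 <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted))
  rss1 <- sum((observed - fitted)^2)
  rss0 <- sum((observed - mean(observed))^2)
  if (rss0 == 0) {
    warning("all observed PDFs identical: pseudo-R2 undefined")
    return(NA_real_)
  }
  1 - rss1 / rss0
}

#' Normalized root-mean-square error of an SSD fit
#'
#' Root-mean-square residual divided by the mean observed PDF, so the
#' error magnitude is expressed relative to the average response.
#'
#' @inheritParams cox_snell_r2
#' @return The NRMSE, or `NA` (with a warning) when the mean observed
#'   PDF is 0.
#' @export
nrmse <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted))
  m <- mean(observed)
  if (m == 0) {
    warning("mean observed PDF is 0: NRMSE undefined")
    return(NA_real_)
  }
  sqrt(mean((observed - fitted)^2)) / m
}

#' Fit a logistic SSD to PDF--concentration pairs
#'
#' Least-squares fit of [evaluate_ssd()] to the points by
#' Levenberg--Marquardt (via \pkg{minpack.lm}), with `b` bounded below
#' by `1e-9`. Start values: `a0` = the level whose observed PDF is
#' nearest 0.5 (median level when PDFs are one-sided), `b0` = level
#' range / 4 — robust for monotone step data. A failed or non-converged
#' optimisation is a recorded status, never an error, so batch fitting
#' always completes.
#'
#' @param points Data.frame with `conc` and `pdf` columns.
#' @param log10 Fit on the log10 concentration scale (default `FALSE`).
#' @return An `ssd_fit` list: `a`, `b`, `n_pairs`, `sr_max`,
#'   `pseudo_r2`, `nrmse`, `good_fit`, `status` in
#'   `{"fitted", "insufficient_data", "failed"}`, `log10`.
#' @examples
#' pts <- data.frame(conc = seq(0.5, 4, length.out = 10))
#' pts$pdf <- evaluate_ssd(2, 0.5, pts$conc)
#' fit_ssd(pts)
#' @export
fit_ssd <- function(points, log10 = FALSE) {
  stopifnot(all(c("conc", "pdf") %in% names(points)))
  out <- list(a = NA_real_, b = NA_real_, n_pairs = NROW(points),
              sr_max = attr(points, "sr_max") %||% NA_integer_,
              pseudo_r2 = NA_real_, nrmse = NA_real_,
              good_fit = FALSE, status = "insufficient_data",
              log10 = log10)
  class(out) <- "ssd_fit"
  if (check_eligibility(points) != "eligible") return(out)

  x <- if (log10) base::log10(points$conc) else points$conc
  y <- points$pdf
  a0 <- x[which.min(abs(y - 0.5))]
  if (!length(a0) || !is.finite(a0)) a0 <- stats::median(x)
  b0 <- max((max(x) - min(x)) / 4, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 / (1 + exp(-(x - a) / b)),
      start = list(a = a0, b = b0),
      lower = c(a = -Inf, b = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
  } else {
    # LM can stall on clipped or nearly degenerate step data; fall back
    # to direct SSR minimisation with b kept positive via log-transform
    ssr <- function(par)
      sum((y - stats::plogis((x - par[1]) / exp(par[2])))^2)
    op <- tryCatch(
      stats::optim(c(a0, log(b0)), ssr, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(op)) {
      out$status <- "failed"
      return(out)
    }
    cf <- c(a = op$par[1], b = exp(op$par[2]))
  }
  out$a <- unname(cf["a"]); out$b <- unname(cf["b"])
  yhat <- stats::plogis((x - out$a) / out$b)
  out$pseudo_r2 <- suppressWarnings(cox_snell_r2(y, yhat))
  out$nrmse <- suppressWarnings(nrmse(y, yhat))
  out$status <- "fitted"
  out$good_fit <- isTRUE(out$pseudo_r2 > 0.5) && isTRUE(out$nrmse < 1)
  out
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat(sprintf("<ssd_fit> status=%s a=%.4g b=%.4g n=%d pseudoR2=%.3f nrmse=%.3f good_fit=%s\n",
              x$status, x$a, x$b, x$n_pairs, x$pseudo_r2, x$nrmse,
              x$good_fit))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit SSDs for every region at both hierarchy levels
#'
#' Groups a tolerance table (as produced by
#' [derive_tolerances_hierarchy()]) by `(level, region_id)`, builds the
#' PDF points for each group and fits the logistic SSD. Statuses are
#' recorded per row; the good-fit flag is `pseudo_r2 > 0.5 & nrmse < 1`.
#' Flagged-poor fits are kept in the table (they are merely not used for
#' effect factors downstream).
#'
#' @param tolerances Data.frame with `accepted_name`, `level`,
#'   `region_id`, `threshold`.
#' @param log10 Fit on the log10 concentration scale (default `FALSE`).
#' @return Data.frame: `region_id`, `level`, `a`, `b`, `n_pairs`,
#'   `sr_max`, `pseudo_r2`, `nrmse`, `status`, `good_fit`.
#' @export
fit_all_regions <- function(tolerances, log10 = FALSE) {
  cols <- c("region_id", "level", "a", "b", "n_pairs", "sr_max",
            "pseudo_r2", "nrmse", "status", "good_fit")
  if (!NROW(tolerances)) {
    out <- data.frame(region_id = integer(), level = character(),
                      a = numeric(), b = numeric(), n_pairs = integer(),
                      sr_max = integer(), pseudo_r2 = numeric(),
                      nrmse = numeric(), status = character(),
                      good_fit = logical())
    return(out[cols])
  }
  grp <- split(tolerances,
               list(tolerances$level, tolerances$region_id), drop = TRUE)
  rows <- lapply(grp, function(g) {
    pts <- build_pdf_points(g$threshold)
    f <- fit_ssd(pts, log10 = log10)
    data.frame(region_id = g$region_id[1], level = g$level[1],
               a = f$a, b = f$b, n_pairs = f$n_pairs,
               sr_max = attr(pts, "sr_max"), pseudo_r2 = f$pseudo_r2,
               nrmse = f$nrmse, status = f$status, good_fit = f$good_fit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$level, out$region_id), cols]
  rownames(out) <- NULL
  out
}
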