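#' Effect-factor configuration
#'
#' @param current_year Year representing the current state (default
#'   2010).
#' @param ref_year Reference year for the average effect factor (default
#'   1900, a state with little anthropogenic nitrogen input).
#' @param zero_cutoff Concentration (mg/L) below which a pixel counts as
#'   zero N and carries no effect factor (default `1e-4`).
#' @param ref_tol Concentration difference (mg/L) below which current
#'   and reference states count as equal and the average effect factor
#'   takes its analytic limit, the marginal one (default `1e-12`).
#' @return An `ef_config` list.
#' @export
ef_config <- function(current_year = 2010L, ref_year = 1900L,
                      zero_cutoff = 1e-4, ref_tol = 1e-12) {
  stopifnot(zero_cutoff > 0, ref_tol >= 0)
  structure(list(current_year = as.integer(current_year),
                 ref_year = as.integer(ref_year),
                 zero_cutoff = zero_cutoff, ref_tol = ref_tol),
            class = "ef_config")
}

# raw dPDF/dC of a fitted SSD, in PDF per (mg/L)
ssd_derivative <- function(fit, C) {
  p <- evaluate_ssd(fit$a, fit$b, C, log10 = isTRUE(fit$log10))
  d <- p * (1 - p) / fit$b
  if (isTRUE(fit$log10)) d <- d / (C * log(10))
  d
}

#' Marginal effect factor
#'
#' The instantaneous biodiversity effect of adding nitrogen at the
#' current state: 1000 times the derivative of the SSD at concentration
#' `C`. For the logistic SSD the derivative is
#' \eqn{PDF(C)\,(1 - PDF(C))/b}; the factor 1000 converts the
#' reciprocal-concentration unit from L/mg to m\eqn{^3}/kg, giving
#' PDF·m\eqn{^3}·kg\eqn{^{-1}}.
#'
#' @param fit An `ssd_fit` with `status == "fitted"`.
#' @param C Current-state concentration(s), mg/L (at or above the zero
#'   cutoff; the caller is responsible for masking zero-N cells).
#' @return Marginal EF value(s), PDF·m³·kg⁻¹.
#' @examples
#' f <- list(a = 2, b = 0.5, status = "fitted", log10 = FALSE)
#' marginal_ef(f, 2)  # 1000 * 0.25 / 0.5 = 500
#' @export
marginal_ef <- function(fit, C) {
  stopifnot(fit$status == "fitted")
  1000 * ssd_derivative(fit, C)
}

#' Average effect factor
#'
#' The long-term biodiversity effect between a reference state and the
#' current state: 1000 times the secant slope of the SSD,
#' \deqn{EF_{avg} = 1000\,\frac{PDF(C_{cur}) - PDF(C_{ref})}{C_{cur} - C_{ref}}.}
#' When the two concentrations differ by less than `ref_tol` the
#' analytic limit — the marginal effect factor at `C_cur` — is returned
#' instead of an ill-conditioned quotient. Because the logistic SSD is
#' strictly increasing, the secant is positive whichever of the two
#' states is larger; it is emitted unclipped either way.
#'
#' @inheritParams marginal_ef
#' @param C_cur,C_ref Current and reference concentrations, mg/L
#'   (vectorised, recycled).
#' @param ref_tol Equality tolerance, mg/L (default `1e-12`).
#' @return Average EF value(s), PDF·m³·kg⁻¹.
#' @export
average_ef <- function(fit, C_cur, C_ref, ref_tol = 1e-12) {
  stopifnot(fit$status == "fitted")
  n <- max(length(C_cur), length(C_ref))
  C_cur <- rep_len(C_cur, n); C_ref <- rep_len(C_ref, n)
  lg <- isTRUE(fit$log10)
  out <- 1000 * (evaluate_ssd(fit$a, fit$b, C_cur, log10 = lg) -
                   evaluate_ssd(fit$a, fit$b, C_ref, log10 = lg)) /
    (C_cur - C_ref)
  deg <- abs(C_cur - C_ref) < ref_tol
  if (any(deg)) out[deg] <- marginal_ef(fit, C_cur[deg])
  out
}

#' Compute gridded marginal and average effect factors
#'
#' Per grid cell: cells whose current-state concentration is missing or
#' below the zero cutoff get no value (reason `zero_N`). Otherwise the
#' ecoregion-level SSD is used when it was fitted and passed the
#' good-fit screen; a missing, unfitted or poorly fitting ecoregion SSD
#' falls through to the realm-MHT-level SSD under the same conditions;
#' with neither available the cell gets no value (reason `no_ssd`).
#' Cells whose reference-state concentration is missing keep their
#' marginal EF but get no average EF (reason `undefined_ref`).
#'
#' @param conc_cur,conc_ref Current-state and reference-state
#'   concentration matrices (mg/L).
#' @param region_eco,region_mht Integer region rasters, co-registered
#'   with the concentration fields.
#' @param fits SSD fit table from [fit_all_regions()].
#' @param config An [ef_config()].
#' @return A list of three matrices — `marginal`, `average`
#'   (PDF·m³·kg⁻¹, `NA` where undefined) and `reason` (integer codes:
#'   0 = ok, 1 = zero_N, 2 = no_ssd, 3 = undefined_ref) — plus
#'   `reason_codes`, the code-to-label mapping.
#' @export
compute_ef_grid <- function(conc_cur, conc_ref, region_eco, region_mht,
                            fits, config = ef_config()) {
  dims <- dim(conc_cur)
  if (!identical(dims, dim(conc_ref)) ||
      !identical(dims, dim(region_eco)) ||
      !identical(dims, dim(region_mht)))
    stop("raster shape mismatch", call. = FALSE)
  marg <- matrix(NA_real_, dims[1], dims[2])
  avg <- matrix(NA_real_, dims[1], dims[2])
  reason <- matrix(0L, dims[1], dims[2])

  zero_n <- is.na(conc_cur) | conc_cur < config$zero_cutoff
  reason[zero_n] <- 1L

  usable <- fits[fits$status == "fitted" & fits$good_fit, , drop = FALSE]
  fit_row <- function(level, id) {
    r <- usable[usable$level == level & usable$region_id == id, ,
                drop = FALSE]
    if (nrow(r)) list(a = r$a[1], b = r$b[1], status = "fitted",
                      log10 = FALSE) else NULL
  }

  active <- which(!zero_n)
  if (length(active)) {
    eco_id <- region_eco[active]
    mht_id <- region_mht[active]
    # resolve each cell to one fit: ecoregion first, realm-MHT fallback
    key <- paste(eco_id, mht_id)
    for (k in unique(key)) {
      cells <- active[key == k]
      eid <- region_eco[cells[1]]; mid <- region_mht[cells[1]]
      f <- if (!is.na(eid)) fit_row("ecoregion", eid) else NULL
      if (is.null(f) && !is.na(mid)) f <- fit_row("realm_mht", mid)
      if (is.null(f)) {
        reason[cells] <- 2L
        next
      }
      cc <- conc_cur[cells]; cr <- conc_ref[cells]
      marg[cells] <- marginal_ef(f, cc)
      ok_ref <- !is.na(cr)
      if (any(ok_ref))
        avg[cells[ok_ref]] <- average_ef(f, cc[ok_ref], cr[ok_ref],
                                         ref_tol = config$ref_tol)
      reason[cells[!ok_ref]] <- 3L
    }
  }
  list(marginal = structure(marg, grid = attr(conc_cur, "grid")),
       average = structure(avg, grid = attr(conc_cur, "grid")),
       reason = structure(reason, grid = attr(conc_cur, "grid")),
       reason_codes = c(ok = 0L, zero_N = 1L, no_ssd = 2L,
                        undefined_ref = 3L))
}

#' Summarise effect-factor values into magnitude classes
#'
#' Tabulates grid cells (and their approximate surface area) into EF
#' classes, by default the three classes `<= 100`, `100--100000` and
#' `> 100000` PDF·m³·kg⁻¹ used to summarise global maps. Cell areas are
#' approximated on a spherical Earth as
#' \eqn{(res \cdot 111.195\,km)^2 \cos(lat)}.
#'
#' @param ef Matrix of EF values (`NA` ignored), with a `"grid"`
#'   attribute from the pipeline (else a global 0.5-degree grid is
#'   assumed).
#' @param breaks Internal class boundaries (default `c(100, 1e5)`).
#' @return Data.frame: `class`, `n_cells`, `area_km2`, `area_fraction`
#'   (of cells with a defined EF).
#' @export
ef_class_areas <- function(ef, breaks = c(100, 1e5)) {
  grid <- attr(ef, "grid")
  if (is.null(grid)) grid <- grid_spec(nrow(ef), ncol(ef))
  lat_mid <- grid$lat_max - grid$res * (seq_len(grid$rows) - 0.5)
  cell_area <- (grid$res * 111.195)^2 * cos(lat_mid * pi / 180)
  area <- matrix(rep(cell_area, times = grid$cols), grid$rows, grid$cols)
  def <- !is.na(ef)
  brk <- c(-Inf, breaks, Inf)
  lab <- paste0(
    c("<=", rep("", length(breaks) - 1), ">"),
    c(breaks[1],
      if (length(breaks) > 1)
        paste0(utils::head(breaks, -1), "-", breaks[-1]),
      breaks[length(breaks)]))
  cls <- cut(ef[def], breaks = brk, labels = lab)
  n <- as.integer(table(cls))
  a <- as.numeric(tapply(area[def], cls, sum, default = 0))
  data.frame(class = lab, n_cells = n, area_km2 = a,
             area_fraction = if (sum(a) > 0) a / sum(a) else rep(0, length(a)))
}
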