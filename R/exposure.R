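#' Match occurrence records to pixel-year concentrations
#'
#' Looks up, for every prepared occurrence, the total-N concentration of
#' its grid cell in the field of its year. Records whose pixel-year
#' concentration is missing, or below the zero cutoff (treated as zero
#' concentration because of measurement and modelling uncertainty), are
#' excluded from tolerance derivation and counted.
#'
#' @param records Prepared occurrences with `accepted_name`, `year`,
#'   `row`, `col`.
#' @param conc Named list of concentration matrices (mg/L), names =
#'   years as character; a field must exist for every record year.
#' @param zero_cutoff Concentration below which a pixel counts as zero N
#'   (default `1e-4` mg/L).
#' @return A list with `matched` (records plus a `concentration` column)
#'   and `report` (counts excluded per reason: `missing_conc`,
#'   `below_cutoff`).
#' @export
match_concentration <- function(records, conc, zero_cutoff = 1e-4) {
  stopifnot(is.data.frame(records), is.list(conc))
  yrs <- as.character(records$year)
  missing_fields <- setdiff(unique(yrs), names(conc))
  if (length(missing_fields))
    stop("no concentration field for year(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  C <- rep(NA_real_, nrow(records))
  for (y in unique(yrs)) {
    sel <- yrs == y
    C[sel] <- conc[[y]][cbind(records$row[sel] + 1L,
                              records$col[sel] + 1L)]
  }
  miss <- is.na(C)
  below <- !miss & C < zero_cutoff
  keep <- !miss & !below
  matched <- records[keep, , drop = FALSE]
  matched$concentration <- C[keep]
  list(matched = matched,
       report = data.frame(reason = c("missing_conc", "below_cutoff"),
                           n_removed = c(sum(miss), sum(below))))
}

#' Derive per-species tolerance thresholds per region
#'
#' A species is assumed tolerant to nitrogen up to the highest
#' concentration at which it has been observed within a region, so the
#' threshold is the maximum matched concentration over that species'
#' occurrences in the region. Regions come from a co-registered integer
#' raster (ecoregions, or the coarser realm-MHT units — pass the
#' corresponding raster and `level` label); occurrences falling in cells
#' with no region code are ignored.
#'
#' @param matched Output `$matched` of [match_concentration()].
#' @param region_raster Integer matrix of region codes (`NA` = none).
#' @param level Label stored with each record, e.g. `"ecoregion"` or
#'   `"realm_mht"`.
#' @return Data.frame: `accepted_name`, `level`, `region_id`,
#'   `threshold` (mg/L), `n_matched`.
#' @export
derive_tolerances <- function(matched, region_raster, level = "ecoregion") {
  stopifnot(is.data.frame(matched),
            all(c("accepted_name", "row", "col", "concentration") %in%
                  names(matched)))
  rid <- region_raster[cbind(matched$row + 1L, matched$col + 1L)]
  keep <- !is.na(rid)
  if (!any(keep))
    return(data.frame(accepted_name = character(), level = character(),
                      region_id = integer(), threshold = numeric(),
                      n_matched = integer()))
  d <- data.frame(accepted_name = matched$accepted_name[keep],
                  region_id = as.integer(rid[keep]),
                  concentration = matched$concentration[keep])
  agg <- stats::aggregate(concentration ~ accepted_name + region_id,
                          data = d, FUN = max)
  cnt <- stats::aggregate(cbind(n_matched = concentration) ~
                            accepted_name + region_id,
                          data = d, FUN = length)
  out <- merge(agg, cnt, by = c("accepted_name", "region_id"))
  out <- data.frame(accepted_name = out$accepted_name, level = level,
                    region_id = out$region_id, threshold = out$concentration,
                    n_matched = as.integer(out$n_matched))
  out[order(out$region_id, out$accepted_name), , drop = FALSE]
}

#' Derive tolerances at both hierarchy levels
#'
#' Computes ecoregion-level and realm-MHT-level tolerance tables by
#' re-pooling the matched occurrences under each raster (the coarser
#' level is never aggregated from ecoregion thresholds — a species seen
#' in two ecoregions of one realm-MHT gets a single pooled maximum).
#'
#' @inheritParams derive_tolerances
#' @param region_eco,region_mht Integer region rasters for the two
#'   levels.
#' @return One data.frame with both levels stacked.
#' @export
derive_tolerances_hierarchy <- function(matched, region_eco, region_mht) {
  rbind(derive_tolerances(matched, region_eco, "ecoregion"),
        derive_tolerances(matched, region_mht, "realm_mht"))
}
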