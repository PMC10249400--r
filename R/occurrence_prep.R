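#' Harmonize species names against a synonym table
#'
#' Adds an `accepted_name` column: the synonym table's accepted name when
#' the raw name is listed, otherwise the raw name itself (unmatched names
#' are kept, not dropped, so regional richness is not silently shrunk).
#'
#' @param records Data.frame with at least a `species_name` column.
#' @param synonyms Data.frame with columns `synonym` and `accepted`; the
#'   mapping must be functional (one accepted name per synonym) and
#'   accepted names map to themselves.
#' @return `records` with an `accepted_name` column; the number of raw
#'   names absent from the table is attached as attribute
#'   `"n_unmatched"`.
#' @export
harmonize_names <- function(records, synonyms) {
  stopifnot(is.data.frame(records), "species_name" %in% names(records),
            is.data.frame(synonyms),
            all(c("synonym", "accepted") %in% names(synonyms)))
  if (anyDuplicated(synonyms$synonym))
    stop("synonym table is not functional: duplicated synonym entries")
  map <- stats::setNames(synonyms$accepted, synonyms$synonym)
  hit <- records$species_name %in% names(map)
  records$accepted_name <- records$species_name
  records$accepted_name[hit] <- unname(map[records$species_name[hit]])
  attr(records, "n_unmatched") <- sum(!hit)
  records
}

#' Filter occurrence records by completeness and year window
#'
#' Removes records lacking a year or either coordinate, with coordinates
#' outside the valid longitude/latitude ranges, or with a year outside
#' the analysis window. Emulates the exclusion of occurrence records
#' without year and geographic information during inventory cleaning.
#'
#' @param records Data.frame with `year`, `longitude`, `latitude`.
#' @param window Integer vector `c(year_min, year_max)` (default
#'   `c(1970L, 2010L)`).
#' @return A list with `records` (the retained rows) and `report`, a
#'   data.frame of counts removed per reason (`no_year`, `no_coords`,
#'   `bad_coords`, `out_of_window`).
#' @export
filter_records <- function(records, window = c(1970L, 2010L)) {
  stopifnot(is.data.frame(records),
            all(c("year", "longitude", "latitude") %in% names(records)),
            length(window) == 2L)
  no_year <- is.na(records$year)
  no_coords <- !no_year & (is.na(records$longitude) | is.na(records$latitude))
  bad_coords <- !no_year & !no_coords &
    (records$longitude < -180 | records$longitude > 180 |
       records$latitude < -90 | records$latitude > 90)
  out_win <- !no_year & !no_coords & !bad_coords &
    (records$year < window[1] | records$year > window[2])
  drop <- no_year | no_coords | bad_coords | out_win
  report <- data.frame(
    reason = c("no_year", "no_coords", "bad_coords", "out_of_window"),
    n_removed = c(sum(no_year), sum(no_coords), sum(bad_coords),
                  sum(out_win)))
  list(records = records[!drop, , drop = FALSE], report = report)
}

#' Assign grid cells to occurrence records
#'
#' Adds 0-based `row`/`col` indices under the convention of
#' [grid_spec()]. Records outside the grid extent (possible for regional
#' grids) are dropped and counted.
#'
#' @param records Filtered data.frame with `longitude`, `latitude`.
#' @param grid A [grid_spec()].
#' @return `records` with `row` and `col` columns; the number of dropped
#'   out-of-extent records is attached as attribute `"n_outside"`.
#' @export
assign_cells <- function(records, grid) {
  cells <- lonlat_to_cell(records$longitude, records$latitude, grid)
  records$row <- cells$row
  records$col <- cells$col
  outside <- is.na(records$row)
  out <- records[!outside, , drop = FALSE]
  attr(out, "n_outside") <- sum(outside)
  out
}

#' Deduplicate occurrence records per species, year and cell
#'
#' Keeps at most one record per `(accepted_name, year, row, col)` key,
#' retaining the first in input order. Exposure matching operates at
#' pixel-year resolution, so finer duplicates carry no extra
#' information and would only pseudo-replicate tolerance evidence.
#'
#' @param records Data.frame with `accepted_name`, `year`, `row`, `col`.
#' @return The deduplicated data.frame.
#' @export
deduplicate <- function(records) {
  stopifnot(all(c("accepted_name", "year", "row", "col") %in%
                  names(records)))
  key <- paste(records$accepted_name, records$year, records$row,
               records$col, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Run the full occurrence-preparation stage
#'
#' Convenience wrapper: harmonize, filter, assign cells, deduplicate.
#'
#' @inheritParams harmonize_names
#' @inheritParams filter_records
#' @inheritParams assign_cells
#' @return A list with `records` (prepared table) and `report` (counts
#'   removed per reason, including `outside_grid` and `duplicate`).
#' @export
prepare_occurrences <- function(records, synonyms, grid,
                                window = c(1970L, 2010L)) {
  h <- harmonize_names(records, synonyms)
  f <- filter_records(h, window)
  a <- assign_cells(f$records, grid)
  d <- deduplicate(a)
  report <- rbind(
    f$report,
    data.frame(reason = "outside_grid", n_removed = attr(a, "n_outside")),
    data.frame(reason = "duplicate", n_removed = nrow(a) - nrow(d)))
  list(records = d, report = report)
}
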