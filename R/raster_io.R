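#' Read an ESRI ASCII grid (.asc)
#'
#' Reads the plain-text ASCII grid format used by this package for all
#' raster layers (concentration fields, region rasters, effect-factor
#' grids). The header carries `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize` and `NODATA_value`; data rows run north to south, matching
#' the row order of [grid_spec()].
#'
#' @param path File path.
#' @return A numeric matrix (`nrows` x `ncols`) with `NA` for NODATA;
#'   the matching [grid_spec()] is attached as attribute `"grid"`.
#' @seealso [write_ascii_grid()]
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid %s: expected %d values, found %d",
                 path, nr * nc, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  attr(m, "grid") <- grid_spec(nr, nc, res = hdr$cellsize)
  m
}

#' Write an ESRI ASCII grid (.asc)
#'
#' @param m Numeric matrix, rows north to south; `NA` written as NODATA.
#' @param path Output file path.
#' @param grid A [grid_spec()] describing `m` (defaults to the `"grid"`
#'   attribute of `m`, else a grid inferred from `dim(m)` at 0.5 degrees).
#' @param nodata NODATA sentinel written to file (default -9999).
#' @param digits Significant digits for data values (default 15, enough
#'   to round-trip doubles byte-stably within a session).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, grid = attr(m, "grid"),
                             nodata = -9999, digits = 15) {
  if (is.null(grid)) grid <- grid_spec(nrow(m), ncol(m))
  stopifnot(nrow(m) == grid$rows, ncol(m) == grid$cols)
  yll <- grid$lat_max - grid$rows * grid$res
  hdr <- c(
    sprintf("ncols %d", grid$cols),
    sprintf("nrows %d", grid$rows),
    sprintf("xllcorner %g", grid$lon_min),
    sprintf("yllcorner %g", yll),
    sprintf("cellsize %g", grid$res),
    sprintf("NODATA_value %g", nodata)
  )
  mm <- m
  mm[is.na(mm)] <- nodata
  body <- apply(mm, 1L, function(r)
    paste(formatC(r, format = "g", digits = digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
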