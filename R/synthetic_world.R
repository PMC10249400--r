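#' Define a synthetic region
#'
#' One rectangular block of grid cells forming an ecoregion, nested in a
#' coarser realm-major-habitat-type (realm-MHT) unit, with the true
#' logistic SSD parameters from which species tolerance thresholds are
#' drawn.
#'
#' @param region_id Integer ecoregion code (> 0).
#' @param realm_mht_id Integer realm-MHT code (> 0); several regions may
#'   share one.
#' @param block Integer vector `c(row0, col0, nrows, ncols)`: the 0-based
#'   north-west cell of the block and its size in cells.
#' @param true_a Location of the true logistic SSD: the concentration
#'   (mg/L) at which half the species pool has disappeared.
#' @param true_b Scale of the true logistic SSD (mg/L, > 0).
#' @param n_species Number of species endemic to this region.
#' @return A `region_def` list.
#' @export
region_def <- function(region_id, realm_mht_id, block, true_a, true_b,
                       n_species) {
  stopifnot(length(block) == 4L, all(block[3:4] >= 1L),
            true_a > 0, true_b > 0, n_species >= 1L,
            region_id > 0L, realm_mht_id > 0L)
  structure(list(region_id = as.integer(region_id),
                 realm_mht_id = as.integer(realm_mht_id),
                 block = as.integer(block),
                 true_a = true_a, true_b = true_b,
                 n_species = as.integer(n_species)),
            class = "region_def")
}

#' Configuration for the synthetic world generator
#'
#' Collects everything [generate_world()] needs: a grid, an analysis
#' window of years plus a historical reference year, region definitions
#' with true SSD parameters, and nuisance rates that emulate messy real
#' occurrence data (synonyms, records missing year or coordinates).
#'
#' @param regions List of [region_def()] objects with pairwise disjoint
#'   blocks that fit inside the grid.
#' @param grid A [grid_spec()]; defaults to a 60 x 60 cell sub-window.
#' @param years Analysis window `c(first, last)` (default 1970--2010,
#'   the window over which occurrences are matched to concentrations).
#' @param ref_year Reference year for the average effect factor (default
#'   1900); must precede the window.
#' @param redundancy Mean number of extra sightings per species beyond
#'   the one that pins its threshold (Poisson; default 2).
#' @param noise_sd Gaussian jitter (mg/L) added to the concentration at
#'   each species' threshold pixel-year (default 0: thresholds are
#'   recoverable exactly).
#' @param synonym_frac Fraction of species whose records are emitted
#'   under a synonym resolvable via the synonym table (default 0.1).
#' @param dirty_frac Fraction of extra records lacking year or
#'   coordinates, or dated outside the window (default 0.1).
#' @param seed Integer random seed; the world is a deterministic
#'   function of the full configuration.
#' @return A `world_config` list.
#' @export
world_config <- function(regions, grid = grid_spec(60L, 60L),
                         years = c(1970L, 2010L), ref_year = 1900L,
                         redundancy = 2, noise_sd = 0,
                         synonym_frac = 0.1, dirty_frac = 0.1,
                         seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"),
            length(years) == 2L, years[1] <= years[2],
            ref_year < years[1],
            redundancy >= 0, noise_sd >= 0,
            synonym_frac >= 0, synonym_frac <= 1,
            dirty_frac >= 0, dirty_frac <= 1)
  if (!length(regions)) stop("at least one region is required")
  if (inherits(regions, "region_def")) regions <- list(regions)
  stopifnot(all(vapply(regions, inherits, TRUE, "region_def")))
  occ <- matrix(FALSE, grid$rows, grid$cols)
  for (rg in regions) {
    b <- rg$block
    if (b[1] < 0L || b[2] < 0L ||
        b[1] + b[3] > grid$rows || b[2] + b[4] > grid$cols)
      stop(sprintf("grid too small for block of region %d", rg$region_id))
    rr <- (b[1] + 1L):(b[1] + b[3]); cc <- (b[2] + 1L):(b[2] + b[4])
    if (any(occ[rr, cc]))
      stop(sprintf("region blocks overlap at region %d", rg$region_id))
    occ[rr, cc] <- TRUE
  }
  if (anyDuplicated(vapply(regions, `[[`, 1L, "region_id")))
    stop("duplicate region_id")
  structure(list(regions = regions, grid = grid,
                 years = as.integer(years), ref_year = as.integer(ref_year),
                 redundancy = redundancy, noise_sd = noise_sd,
                 synonym_frac = synonym_frac, dirty_frac = dirty_frac,
                 seed = as.integer(seed)),
            class = "world_config")
}

# draw from logistic(a, b) truncated to (0, Inf) by redraw
rlogis_pos <- function(n, a, b) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    u <- stats::runif(length(todo))
    x <- a + b * log(u / (1 - u))
    ok <- x > 0
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic world with known SSD truth
#'
#' Builds a self-contained set of pipeline inputs: occurrence records,
#' per-year concentration fields, ecoregion and realm-MHT rasters, a
#' synonym table, and a truth table of the per-species tolerance
#' thresholds and per-region true SSD parameters.
#'
#' Species thresholds are drawn from the logistic with the region's
#' `(true_a, true_b)` by inverse-CDF sampling, redrawn when non-positive.
#' Each species is assigned one "threshold pixel-year" inside its
#' region's block whose concentration is set exactly to its threshold
#' (plus optional jitter), and an occurrence record is placed there, so
#' the max-observed-concentration tolerance rule recovers the threshold
#' by construction. Extra sightings land on pixel-years whose
#' concentration does not exceed the threshold. Remaining in-block
#' pixel-years carry concentrations drawn from the same truncated
#' logistic; cells outside all blocks carry zero concentration (below
#' the zero cutoff, so they receive no effect factor downstream). The
#' reference-year field holds low concentrations (uniform between 0.001
#' mg/L and 20% of `true_a`) inside blocks.
#'
#' @param config A [world_config()].
#' @return A list with elements `occurrences` (data.frame: species_name,
#'   year, longitude, latitude), `conc` (named list of matrices, one per
#'   year in the window plus the reference year), `region_eco` and
#'   `region_mht` (integer matrices, `NA` outside blocks), `synonyms`
#'   (data.frame: synonym, accepted), `truth` (list of data.frames
#'   `species` and `regions`), `grid`, and `config`.
#' @examples
#' w <- generate_world(world_config(
#'   regions = list(region_def(1L, 101L, c(0L, 0L, 8L, 8L), 2, 0.5, 30L)),
#'   grid = grid_spec(10L, 10L), seed = 42L))
#' nrow(w$truth$species)
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(config$seed)

  grid <- config$grid
  yrs <- config$years[1]:config$years[2]
  n_years <- length(yrs)
  zero <- matrix(0, grid$rows, grid$cols)
  conc <- stats::setNames(replicate(n_years, zero, simplify = FALSE),
                          as.character(yrs))
  ref <- zero
  region_eco <- matrix(NA_integer_, grid$rows, grid$cols)
  region_mht <- matrix(NA_integer_, grid$rows, grid$cols)

  sp_rows <- list(); occ_rows <- list(); reg_rows <- list()
  sp_counter <- 0L
  for (rg in config$regions) {
    b <- rg$block
    rr <- (b[1] + 1L):(b[1] + b[3]); cc <- (b[2] + 1L):(b[2] + b[4])
    region_eco[rr, cc] <- rg$region_id
    region_mht[rr, cc] <- rg$realm_mht_id
    n_cells <- b[3] * b[4]
    n_py <- n_cells * n_years
    if (n_py < rg$n_species)
      stop(sprintf("grid too small: region %d has %d pixel-years for %d species",
                   rg$region_id, n_py, rg$n_species))

    thr <- rlogis_pos(rg$n_species, rg$true_a, rg$true_b)
    # in-block pixel-years indexed 1..n_py: cell-major, then year
    py_cell <- rep(seq_len(n_cells), times = n_years)
    py_year <- rep(seq_len(n_years), each = n_cells)
    background <- rlogis_pos(n_py, rg$true_a, rg$true_b)
    seeded <- sample.int(n_py, rg$n_species)
    seeded_conc <- thr
    if (config$noise_sd > 0) {
      seeded_conc <- thr + stats::rnorm(rg$n_species, 0, config$noise_sd)
      seeded_conc <- pmax(seeded_conc, 1e-3)
    }
    background[seeded] <- seeded_conc
    # write concentrations into the per-year fields
    cell_r <- rr[((py_cell - 1L) %% b[3]) + 1L]
    cell_c <- cc[((py_cell - 1L) %/% b[3]) + 1L]
    for (k in seq_len(n_years)) {
      sel <- py_year == k
      idx <- cbind(cell_r[sel], cell_c[sel])
      conc[[k]][idx] <- background[sel]
    }
    ref[rr, cc] <- stats::runif(n_cells, 0.001, 0.2 * rg$true_a)

    names_sp <- sprintf("Species r%d_%03d", rg$region_id,
                        seq_len(rg$n_species))
    sp_counter <- sp_counter + rg$n_species
    sp_rows[[length(sp_rows) + 1L]] <- data.frame(
      accepted_name = names_sp, region_id = rg$region_id,
      threshold = thr, stringsAsFactors = FALSE)
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      region_id = rg$region_id, realm_mht_id = rg$realm_mht_id,
      true_a = rg$true_a, true_b = rg$true_b, n_species = rg$n_species)

    # occurrence records: the seeded sighting plus Poisson extras at
    # pixel-years not exceeding the species threshold
    for (s in seq_len(rg$n_species)) {
      pys <- seeded[s]
      n_extra <- stats::rpois(1L, config$redundancy)
      if (n_extra > 0) {
        cand <- which(background <= thr[s])
        if (length(cand))
          pys <- c(pys, cand[sample.int(length(cand), n_extra,
                                        replace = TRUE)])
      }
      bb <- cell_bounds(cell_r[pys] - 1L, cell_c[pys] - 1L, grid)
      eps <- grid$res * 1e-3
      occ_rows[[length(occ_rows) + 1L]] <- data.frame(
        species_name = names_sp[s],
        year = yrs[py_year[pys]],
        longitude = stats::runif(length(pys), bb$lon_min + eps,
                                 bb$lon_max - eps),
        latitude = stats::runif(length(pys), bb$lat_min + eps,
                                bb$lat_max - eps),
        stringsAsFactors = FALSE)
    }
  }
  species <- do.call(rbind, sp_rows)
  occurrences <- do.call(rbind, occ_rows)
  rownames(occurrences) <- NULL

  # synonym table: identity rows for all accepted names, plus synonyms
  # for a fraction of species whose records are emitted under the synonym
  n_syn <- floor(config$synonym_frac * nrow(species))
  syn_idx <- if (n_syn > 0) sample.int(nrow(species), n_syn) else integer()
  synonyms <- data.frame(synonym = species$accepted_name,
                         accepted = species$accepted_name,
                         stringsAsFactors = FALSE)
  if (n_syn > 0) {
    syn_names <- paste0(species$accepted_name[syn_idx], " (syn)")
    synonyms <- rbind(synonyms, data.frame(
      synonym = syn_names, accepted = species$accepted_name[syn_idx],
      stringsAsFactors = FALSE))
    remap <- stats::setNames(syn_names, species$accepted_name[syn_idx])
    hit <- occurrences$species_name %in% names(remap)
    occurrences$species_name[hit] <- remap[occurrences$species_name[hit]]
  }

  # dirty records: copies of clean records with year or coordinates
  # knocked out, or dated before the window, to exercise filtering
  n_dirty <- round(config$dirty_frac * nrow(occurrences))
  if (n_dirty > 0) {
    src <- occurrences[sample.int(nrow(occurrences), n_dirty,
                                  replace = TRUE), , drop = FALSE]
    kind <- rep_len(c("no_year", "no_coords", "out_of_window"), n_dirty)
    src$year[kind == "no_year"] <- NA_integer_
    src$longitude[kind == "no_coords"] <- NA_real_
    src$latitude[kind == "no_coords"] <- NA_real_
    src$year[kind == "out_of_window"] <- config$ref_year
    occurrences <- rbind(occurrences, src)
    rownames(occurrences) <- NULL
  }

  conc[[as.character(config$ref_year)]] <- ref
  for (k in seq_along(conc)) attr(conc[[k]], "grid") <- grid
  attr(region_eco, "grid") <- grid; attr(region_mht, "grid") <- grid

  list(occurrences = occurrences, conc = conc,
       region_eco = region_eco, region_mht = region_mht,
       synonyms = synonyms,
       truth = list(species = species, regions = do.call(rbind, reg_rows)),
       grid = grid, config = config)
}
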