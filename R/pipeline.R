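#' Pipeline configuration
#'
#' Declares where the pipeline reads its inputs and writes its
#' artifacts. Each input path defaults to the artifact the previous
#' stage writes into `out_dir`, so the stages `simulate`, `prepare`,
#' `fit` and `ef` chain through the filesystem and are individually
#' restartable (real occurrence tables and concentration rasters can be
#' dropped in to replace the simulated ones).
#'
#' @param out_dir Output directory for all artifacts (created if
#'   needed).
#' @param world A [world_config()] for the `simulate` stage (`NULL` when
#'   real inputs are supplied).
#' @param occurrences,synonyms Paths to delimited input tables
#'   (tab-separated; occurrences: `species_name`, `year`, `longitude`,
#'   `latitude`; synonyms: `synonym`, `accepted`).
#' @param conc_template Path template for per-year concentration
#'   rasters, with `{year}` placeholder, e.g. `"conc_{year}.asc"`.
#' @param region_eco,region_mht Paths to the two region rasters (.asc).
#' @param grid A [grid_spec()] used by `prepare`.
#' @param window Analysis year window (default `c(1970L, 2010L)`).
#' @param ef An [ef_config()].
#' @param log10 Fit SSDs on the log10 concentration scale (default
#'   `FALSE`).
#' @param seed Seed for the `simulate` stage (overrides the world
#'   config's seed so one number controls a whole run).
#' @param verbose Print stage progress (default `TRUE`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, world = NULL,
                            occurrences = file.path(out_dir, "occurrences.tsv"),
                            synonyms = file.path(out_dir, "synonyms.tsv"),
                            conc_template = file.path(out_dir, "conc_{year}.asc"),
                            region_eco = file.path(out_dir, "region_eco.asc"),
                            region_mht = file.path(out_dir, "region_mht.asc"),
                            grid = if (!is.null(world)) world$grid else grid_spec(),
                            window = c(1970L, 2010L),
                            ef = ef_config(), log10 = FALSE,
                            seed = NULL, verbose = TRUE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(ef, "ef_config"))
  if (!is.null(world)) {
    stopifnot(inherits(world, "world_config"))
    if (!is.null(seed)) world$seed <- as.integer(seed)
    window <- world$years
  }
  structure(list(out_dir = out_dir, world = world,
                 occurrences = occurrences, synonyms = synonyms,
                 conc_template = conc_template,
                 region_eco = region_eco, region_mht = region_mht,
                 grid = grid, window = as.integer(window), ef = ef,
                 log10 = log10, verbose = verbose),
            class = "pipeline_config")
}

conc_path <- function(config, year)
  gsub("{year}", year, config$conc_template, fixed = TRUE)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, what = path) {
  if (!file.exists(path))
    stop("missing upstream artifact: ", what, " (", path, ")",
         call. = FALSE)
  out <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = "NA",
                      quote = ""),
    error = function(e)
      stop("malformed input table ", path, ": ", conditionMessage(e),
           call. = FALSE))
  out
}

need_file <- function(path, what) {
  if (!file.exists(path))
    stop("missing upstream artifact: ", what, " (", path, ")",
         call. = FALSE)
  path
}

pipe_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message(sprintf(...))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, reading and writing artifacts
#' under `config$out_dir`:
#' \describe{
#'   \item{simulate}{[generate_world()]: writes `occurrences.tsv`,
#'     `synonyms.tsv`, `truth_species.tsv`, `truth_regions.tsv`,
#'     per-year `conc_<year>.asc` rasters (plus the reference year) and
#'     the two region rasters. Truth tables are labelled synthetic
#'     artifacts, never inputs to later stages.}
#'   \item{prepare}{[prepare_occurrences()]: writes
#'     `prepared_occurrences.tsv` and `filter_report.tsv`.}
#'   \item{fit}{[match_concentration()], [derive_tolerances_hierarchy()]
#'     and [fit_all_regions()]: writes `tolerances.tsv`,
#'     `match_report.tsv` and `ssd_fits.tsv`.}
#'   \item{ef}{[compute_ef_grid()] and [ef_class_areas()]: writes
#'     `ef_marginal.asc`, `ef_average.asc`, `ef_reason.asc` and
#'     `ef_class_areas.tsv`.}
#' }
#' Every stage appends an entry (inputs, outputs, row counts, seed,
#' package version) to `manifest.json`. Reruns with identical inputs
#' and seed reproduce identical tables and rasters.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("simulate", "prepare", "fit", "ef")`, or `"all"`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "prepare", "fit", "ef")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all"))
    stages <- c("simulate", "prepare", "fit", "ef")
  stages <- match.arg(stages, c("simulate", "prepare", "fit", "ef"),
                      several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  log_stage <- function(stage, outputs, counts) {
    manifest[[stage]] <<- list(
      package = "nitroSSD",
      version = as.character(utils::packageVersion("nitroSSD")),
      seed = if (!is.null(config$world)) config$world$seed else NA,
      outputs = outputs, counts = counts)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  if ("simulate" %in% stages) {
    if (is.null(config$world))
      stop("simulate stage requires a world_config", call. = FALSE)
    pipe_msg(config, "[simulate] generating synthetic world (seed %d)",
             config$world$seed)
    w <- generate_world(config$world)
    write_tsv(w$occurrences, config$occurrences)
    write_tsv(w$synonyms, config$synonyms)
    write_tsv(w$truth$species,
              file.path(config$out_dir, "truth_species.tsv"))
    write_tsv(w$truth$regions,
              file.path(config$out_dir, "truth_regions.tsv"))
    for (y in names(w$conc))
      write_ascii_grid(w$conc[[y]], conc_path(config, y))
    write_ascii_grid(w$region_eco, config$region_eco)
    write_ascii_grid(w$region_mht, config$region_mht)
    artifacts$occurrences <- config$occurrences
    log_stage("simulate",
              outputs = c(config$occurrences, config$synonyms),
              counts = list(n_occurrences = nrow(w$occurrences),
                            n_species = nrow(w$truth$species),
                            n_regions = nrow(w$truth$regions)))
  }

  if ("prepare" %in% stages) {
    occ <- read_tsv(config$occurrences, "occurrence table")
    syn <- read_tsv(config$synonyms, "synonym table")
    prep <- prepare_occurrences(occ, syn, config$grid, config$window)
    pipe_msg(config, "[prepare] %d of %d records retained",
             nrow(prep$records), nrow(occ))
    p_path <- file.path(config$out_dir, "prepared_occurrences.tsv")
    write_tsv(prep$records, p_path)
    write_tsv(prep$report, file.path(config$out_dir, "filter_report.tsv"))
    artifacts$prepared <- p_path
    log_stage("prepare", outputs = p_path,
              counts = list(n_in = nrow(occ), n_out = nrow(prep$records)))
  }

  if ("fit" %in% stages) {
    prep <- read_tsv(file.path(config$out_dir, "prepared_occurrences.tsv"),
                     "prepared occurrence table")
    yrs <- config$window[1]:config$window[2]
    conc <- lapply(stats::setNames(as.character(yrs), as.character(yrs)),
                   function(y) read_ascii_grid(
                     need_file(conc_path(config, y),
                               paste("concentration field", y))))
    eco <- read_ascii_grid(need_file(config$region_eco, "ecoregion raster"))
    mht <- read_ascii_grid(need_file(config$region_mht, "realm-MHT raster"))
    m <- match_concentration(prep, conc, config$ef$zero_cutoff)
    tol <- derive_tolerances_hierarchy(m$matched, eco, mht)
    fits <- fit_all_regions(tol, log10 = config$log10)
    pipe_msg(config, "[fit] %d region-level SSDs (%d fitted)",
             nrow(fits), sum(fits$status == "fitted"))
    f_path <- file.path(config$out_dir, "ssd_fits.tsv")
    write_tsv(tol, file.path(config$out_dir, "tolerances.tsv"))
    write_tsv(m$report, file.path(config$out_dir, "match_report.tsv"))
    write_tsv(fits, f_path)
    artifacts$fits <- f_path
    log_stage("fit", outputs = f_path,
              counts = list(n_matched = nrow(m$matched),
                            n_tolerances = nrow(tol),
                            n_fits = nrow(fits)))
  }

  if ("ef" %in% stages) {
    fits <- read_tsv(file.path(config$out_dir, "ssd_fits.tsv"),
                     "SSD fit table")
    cur <- read_ascii_grid(
      need_file(conc_path(config, config$ef$current_year),
                "current-state concentration field"))
    ref <- read_ascii_grid(
      need_file(conc_path(config, config$ef$ref_year),
                "reference-state concentration field"))
    eco <- read_ascii_grid(need_file(config$region_eco, "ecoregion raster"))
    mht <- read_ascii_grid(need_file(config$region_mht, "realm-MHT raster"))
    ef <- compute_ef_grid(cur, ref, eco, mht, fits, config$ef)
    pipe_msg(config, "[ef] %d cells with effect factors",
             sum(!is.na(ef$marginal)))
    paths <- file.path(config$out_dir,
                       c("ef_marginal.asc", "ef_average.asc",
                         "ef_reason.asc"))
    write_ascii_grid(ef$marginal, paths[1])
    write_ascii_grid(ef$average, paths[2])
    write_ascii_grid(ef$reason, paths[3])
    write_tsv(ef_class_areas(ef$average),
              file.path(config$out_dir, "ef_class_areas.tsv"))
    artifacts$ef <- paths
    log_stage("ef", outputs = paths,
              counts = list(n_ef_cells = sum(!is.na(ef$marginal)),
                            n_zero_n = sum(ef$reason == 1L),
                            n_no_ssd = sum(ef$reason == 2L)))
  }
  invisible(artifacts)
}
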