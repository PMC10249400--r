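# small synthetic-world configurations shared across tests

one_region_world <- function(n_species = 60L, seed = 1L, true_a = 2,
                             true_b = 0.5, noise_sd = 0, ...) {
  world_config(
    regions = list(region_def(1L, 101L, c(0L, 0L, 8L, 8L),
                              true_a = true_a, true_b = true_b,
                              n_species = n_species)),
    grid = grid_spec(12L, 12L), noise_sd = noise_sd, seed = seed, ...)
}

two_region_world <- function(seed = 1L, ...) {
  world_config(
    regions = list(
      region_def(1L, 101L, c(0L, 0L, 6L, 6L), true_a = 2, true_b = 0.5,
                 n_species = 50L),
      region_def(2L, 101L, c(0L, 8L, 6L, 6L), true_a = 3, true_b = 0.8,
                 n_species = 50L)),
    grid = grid_spec(16L, 16L), seed = seed, ...)
}

# run the in-memory analysis chain (prepare -> match -> tolerances) on a
# generated world; returns matched records and both tolerance tables
analyse_world <- function(w, window = w$config$years) {
  prep <- prepare_occurrences(w$occurrences, w$synonyms, w$grid, window)
  m <- match_concentration(prep$records,
                           w$conc[as.character(window[1]:window[2])])
  tol <- derive_tolerances_hierarchy(m$matched, w$region_eco, w$region_mht)
  list(prep = prep, matched = m$matched, tol = tol)
}

# independent least-squares oracle: dense lattice search over (a, b)
grid_search_ssd <- function(points, n = 200L) {
  a_grid <- seq(min(points$conc), max(points$conc), length.out = n)
  b_grid <- seq(1e-3, max(diff(range(points$conc)), 1e-2),
                length.out = n)
  best <- list(ssr = Inf)
  for (a in a_grid) {
    for (b in b_grid) {
      ssr <- sum((points$pdf - 1 / (1 + exp(-(points$conc - a) / b)))^2)
      if (ssr < best$ssr) best <- list(a = a, b = b, ssr = ssr)
    }
  }
  best$step_a <- diff(a_grid[1:2]); best$step_b <- diff(b_grid[1:2])
  best
}

ssd_ssr <- function(points, a, b)
  sum((points$pdf - 1 / (1 + exp(-(points$conc - a) / b)))^2)
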