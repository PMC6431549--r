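# Small in-code fixtures shared across test files.

five_labels <- c("1" = "AWV", "2" = "SF", "3" = "HS", "4" = "WB", "5" = "PF")

# Landscape from an integer vector filled column-wise into nr x nc.
mk_land <- function(values, nr, nc, cell_size = 30, labels = NULL) {
  landscape(matrix(as.integer(values), nr, nc), cell_size, labels)
}

# Two-class PF/SF fixture.
pf_sf_labels <- c("1" = "PF", "2" = "SF")

# Random landscape over k classes.
rand_land <- function(nr, nc, k = 3, seed = 1, cell_size = 30) {
  withr::with_seed(seed,
    landscape(matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc),
              cell_size))
}

# Random diagonally dominant stochastic matrix.
rand_dd_matrix <- function(n = 4, seed = 1, diag_min = 0.85) {
  withr::with_seed(seed, {
    P <- matrix(stats::runif(n * n), n, n)
    diag(P) <- 0
    P <- P / rowSums(P) * (1 - stats::runif(n, diag_min, 0.98))
    diag(P) <- 1 - rowSums(P)
    dimnames(P) <- list(letters[1:n], letters[1:n])
    transition_matrix(P, 1)
  })
}

# Small calibrated synthetic bundle used by CA / pipeline tests.
small_bundle <- function(nr = 60, nc = 60, n_years = 5, seed = 11) {
  cfg <- synth_config(nrow = nr, ncol = nc, n_years = n_years, seed = seed)
  land <- gen_landscape(cfg)
  drivers <- gen_drivers(cfg, land)
  series <- simulate_history(land, cfg$true_matrix, cfg$effects, drivers,
                             n_years, seed + 2L)
  list(cfg = cfg, land = land, drivers = drivers, series = series)
}
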