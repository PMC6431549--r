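#' Configuration for the synthetic study generator
#'
#' Describes a synthetic study region with known ("true") parameters: a
#' 5-class autocorrelated landscape (primary/secondary forest, settlements,
#' cleared areas, water), driver rasters of the three families used by
#' deforestation models (density, proximity, topographic), a true annual
#' transition matrix and planted driver effects. Every downstream stage of
#' the package can then be tested by recovering what was planted.
#'
#' @param nrow,ncol Grid shape in cells.
#' @param cell_size Cell size in meters (default 30).
#' @param shares Named class shares summing to 1. The default mirrors a
#'   forest-dominated landscape: mostly primary/secondary forest, a few
#'   percent cleared land, traces of settlement and water.
#' @param autocorr_length Spatial autocorrelation length of the landscape
#'   in cells (Gaussian smoothing radius); 0 gives spatially random maps.
#' @param true_matrix Annual `lulc_tmatrix` generating the history; the
#'   default has modest degradation/deforestation rates typical of an
#'   annualized multi-decade forest transition matrix.
#' @param effects List of planted WoE effects, each
#'   `list(from=, to=, driver=, range=c(lo, hi), w_plus=)`: cells whose
#'   driver value falls in the range have their transition odds multiplied
#'   by `exp(w_plus)`.
#' @param n_years History length in years.
#' @param seed Mandatory integer seed.
#' @return A `synth_config` object.
#' @export
synth_config <- function(nrow = 200, ncol = 200, cell_size = 30,
                         shares = c(AWV = 0.045, SF = 0.395, HS = 0.004,
                                    WB = 0.002, PF = 0.554),
                         autocorr_length = 6,
                         true_matrix = default_true_matrix(),
                         effects = default_effects(),
                         n_years = 10, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (abs(sum(shares) - 1) > 1e-9) stop("shares must sum to 1")
  structure(list(nrow = nrow, ncol = ncol, cell_size = cell_size,
                 shares = shares, autocorr_length = autocorr_length,
                 true_matrix = true_matrix, effects = effects,
                 n_years = n_years, seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_true_matrix <- function() {
  labs <- c("AWV", "SF", "HS", "WB", "PF")
  P <- diag(5)
  dimnames(P) <- list(labs, labs)
  P["AWV", "SF"] <- 0.016
  P["SF", "AWV"] <- 0.004
  P["SF", "PF"] <- 0.008
  P["PF", "SF"] <- 0.022
  P["PF", "AWV"] <- 0.001
  P["PF", "HS"] <- 0.0002
  diag(P) <- 1 - (rowSums(P) - diag(P))
  transition_matrix(P, 1)
}

#' @rdname synth_config
#' @export
default_effects <- function() {
  list(list(from = "PF", to = "SF", driver = "dist_roads",
            range = c(0, 600), w_plus = 1.0))
}

#' Generate an autocorrelated categorical landscape
#'
#' Thresholds a Gaussian-smoothed noise field at the share quantiles, so
#' realized shares match the requested ones up to ties and classes form
#' contiguous patches whose scale follows `autocorr_length`.
#'
#' @param cfg A `synth_config`.
#' @return A `lulc_landscape`, deterministic per seed.
#' @export
gen_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::local_seed(cfg$seed)
  field <- matrix(stats::rnorm(cfg$nrow * cfg$ncol), cfg$nrow, cfg$ncol)
  field <- smooth_gaussian(field, cfg$autocorr_length)
  qs <- stats::quantile(field, cumsum(cfg$shares), names = FALSE)
  codes <- seq_along(cfg$shares)
  v <- matrix(codes[1L], cfg$nrow, cfg$ncol)
  for (k in seq_along(qs)[-length(qs)]) {
    v[field > qs[k]] <- codes[k + 1L]
  }
  landscape(v, cfg$cell_size,
            stats::setNames(names(cfg$shares), as.character(codes)))
}

# Multi-octave smoothed noise in [0, 1]; octave scales follow the grid.
fractal_field <- function(nr, nc,
                          octaves = pmax(1, min(nr, nc) / c(8, 16, 32))) {
  f <- Reduce(`+`, lapply(seq_along(octaves), function(i) {
    smooth_gaussian(matrix(stats::rnorm(nr * nc), nr, nc), octaves[i]) /
      2^(i - 1)
  }))
  (f - min(f)) / (max(f) - min(f))
}

#' Generate synthetic driver rasters
#'
#' Builds one driver per family: `dist_roads` (proximity, m: exact distance
#' transform to a random polyline network), `dens_settlements` (density,
#' features per km2: kernel-smoothed random point counts), and the
#' topographic trio `altitude` (m, fractal noise), `slope` (degrees,
#' central differences) and `tpi` (topographic position index: elevation
#' minus its mean within a 5-cell radius). A dynamic `dist_cleared` driver
#' (distance to the current extent of AWV) is included for CA runs.
#'
#' @param cfg A `synth_config`.
#' @param land The landscape the dynamic driver is anchored to.
#' @param tpi_radius Neighbourhood radius (cells) of the TPI.
#' @return Named list of `lulc_driver`s, deterministic per seed.
#' @export
gen_drivers <- function(cfg, land, tpi_radius = 5) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::local_seed(cfg$seed + 1L)
  nr <- cfg$nrow
  nc <- cfg$ncol
  cs <- cfg$cell_size

  # proximity: random-walk polylines as a road network
  road <- matrix(FALSE, nr, nc)
  for (line in 1:2) {
    r <- sample.int(nr, 1)
    c <- 1L
    while (c <= nc) {
      road[r, c] <- TRUE
      r <- min(max(r + sample(-1:1, 1), 1L), nr)
      c <- c + 1L
    }
  }
  dist_roads <- driver_raster(distance_to(road) * cs, "dist_roads",
                              "proximity")

  # density: Poisson settlement points, kernel-smoothed counts per km2
  npts <- max(3L, stats::rpois(1, nr * nc / 2000))
  pts <- matrix(0, nr, nc)
  idx <- sample.int(nr * nc, npts)
  pts[idx] <- 1
  km2_per_cell <- (cs / 1000)^2
  dens <- pmax(smooth_gaussian(pts, 4), 0) / km2_per_cell
  dens_settlements <- driver_raster(dens, "dens_settlements", "density")

  # topographic: fractal elevation, slope, TPI
  elev <- 1000 + 2000 * fractal_field(nr, nc)
  altitude <- driver_raster(elev, "altitude", "topographic")
  slope <- driver_raster(slope_deg(elev, cs), "slope", "topographic")
  tpi <- driver_raster(tpi_index(elev, tpi_radius), "tpi", "topographic")

  dist_cleared <- driver_raster(
    distance_to(!is.na(land$values) &
                  land$values == code_of(land, "AWV")) * cs,
    "dist_cleared", "proximity", dynamic = TRUE,
    update = list(type = "distance", class = "AWV"))

  list(dist_roads = dist_roads, dens_settlements = dens_settlements,
       altitude = altitude, slope = slope, tpi = tpi,
       dist_cleared = dist_cleared)
}

#' Slope (degrees) from an elevation raster
#' @param elev Elevation matrix (m).
#' @param cell_size Cell size (m).
#' @return Slope in degrees via central differences (one-sided at edges).
#' @export
slope_deg <- function(elev, cell_size) {
  gx <- (shift_mat(elev, 0L, -1L) - shift_mat(elev, 0L, 1L)) /
    (2 * cell_size)
  gy <- (shift_mat(elev, -1L, 0L) - shift_mat(elev, 1L, 0L)) /
    (2 * cell_size)
  # one-sided differences on the border
  gx[, 1] <- (elev[, 2] - elev[, 1]) / cell_size
  gx[, ncol(elev)] <- (elev[, ncol(elev)] - elev[, ncol(elev) - 1]) /
    cell_size
  gy[1, ] <- (elev[2, ] - elev[1, ]) / cell_size
  gy[nrow(elev), ] <- (elev[nrow(elev), ] - elev[nrow(elev) - 1, ]) /
    cell_size
  atan(sqrt(gx^2 + gy^2)) * 180 / pi
}

#' Topographic position index
#' @param elev Elevation matrix.
#' @param radius Window radius in cells (default 5).
#' @return Elevation minus the mean elevation within the window (positive
#'   on peaks/ridges, negative in pits/valleys).
#' @export
tpi_index <- function(elev, radius = 5) {
  elev - box_mean(elev, radius)
}

#' Simulate a land-cover history with known parameters
#'
#' Steps the landscape forward year by year: each cell of class i moves to
#' class j with the annual Markov rate modulated by the planted WoE odds
#' factors, renormalized per (i, j) so that the aggregate expected demand
#' matches the matrix exactly. The planted effects are therefore
#' recoverable by [compute_woe()] and the matrix by [estimate_matrix()] +
#' [annualize()].
#'
#' @param initial `lulc_landscape` at year 0.
#' @param m Annual `lulc_tmatrix` (the truth).
#' @param effects Planted effects (see [synth_config()]).
#' @param drivers Named list of `lulc_driver`s the effects reference.
#' @param n_years Number of annual steps.
#' @param seed Integer seed; the whole series is deterministic per seed.
#' @return List of `n_years + 1` landscapes (year 0 first).
#' @export
simulate_history <- function(initial, m, effects, drivers, n_years, seed) {
  stopifnot(inherits(initial, "lulc_landscape"), inherits(m, "lulc_tmatrix"))
  for (ef in effects) {
    if (!ef$driver %in% names(drivers)) {
      stop("effect references missing driver '", ef$driver, "'")
    }
  }
  withr::local_seed(seed)
  series <- vector("list", n_years + 1L)
  series[[1L]] <- initial
  cur <- initial
  labs <- m$class_order
  for (year in seq_len(n_years)) {
    v <- cur$values
    lv <- matrix(label_of(cur, v), nrow(v))
    nv <- v
    for (from in labs) {
      cells <- which(!is.na(lv) & lv == from)
      if (length(cells) == 0L) next
      # per-cell odds multiplier from the planted effects
      mult <- rep(1, length(cells))
      for (ef in effects) {
        if (ef$from != from) next
        dv <- drivers[[ef$driver]]$values[cells]
        mult <- mult * ifelse(!is.na(dv) & dv >= ef$range[1] &
                                dv <= ef$range[2], exp(ef$w_plus), 1)
      }
      to_labs <- labs[labs != from & m$P[from, ] > 0]
      if (length(to_labs) == 0L) next
      # renormalize so mean per-cell rate equals the matrix rate
      probs <- matrix(0, length(cells), length(to_labs))
      for (k in seq_along(to_labs)) {
        p <- m$P[from, to_labs[k]] * mult / mean(mult)
        probs[, k] <- pmin(p, 0.95)
      }
      tot <- rowSums(probs)
      over <- tot > 0.95
      if (any(over)) probs[over, ] <- probs[over, ] * 0.95 / tot[over]
      u <- stats::runif(length(cells))
      cum <- cbind(0, t(apply(probs, 1L, cumsum)))
      for (k in seq_along(to_labs)) {
        hit <- u >= cum[, k] & u < cum[, k + 1L]
        if (any(hit)) {
          nv[cells[hit]] <- code_of(cur, to_labs[k])
        }
      }
    }
    cur <- landscape(nv, cur$cell_size, cur$class_labels)
    series[[year + 1L]] <- cur
  }
  series
}

#' Write a complete synthetic study bundle to a directory
#'
#' Generates the landscape, the drivers and the simulated history for a
#' configuration and writes everything as plain files: ESRI ASCII maps
#' (`lulc_year<k>.asc`), driver grids (`driver_<name>.asc`), the true
#' annual matrix (`true_matrix.csv`) and a `truth.yml` manifest with the
#' configuration.
#'
#' @param cfg A `synth_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_synth_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  land <- gen_landscape(cfg)
  drivers <- gen_drivers(cfg, land)
  series <- simulate_history(land, cfg$true_matrix, cfg$effects, drivers,
                             cfg$n_years, cfg$seed + 2L)
  for (i in seq_along(series)) {
    write_landscape(series[[i]],
                    file.path(dir, sprintf("lulc_year%02d.asc", i - 1L)))
  }
  for (nm in names(drivers)) {
    d <- drivers[[nm]]$values
    d[!is.finite(d)] <- -9999
    utils::write.table(round(d, 3),
                       file.path(dir, paste0("driver_", nm, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  write_transition_csv(cfg$true_matrix, file.path(dir, "true_matrix.csv"))
  yaml::write_yaml(list(
    nrow = cfg$nrow, ncol = cfg$ncol, cell_size = cfg$cell_size,
    shares = as.list(cfg$shares), autocorr_length = cfg$autocorr_length,
    n_years = cfg$n_years, seed = cfg$seed,
    effects = cfg$effects
  ), file.path(dir, "truth.yml"))
  invisible(list(landscape = land, drivers = drivers, series = series))
}
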