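test_that("landscape generation is seed-deterministic with matched shares", {
  cfg <- synth_config(nrow = 300, ncol = 300, seed = 10)
  l1 <- gen_landscape(cfg)
  l2 <- gen_landscape(cfg)
  expect_identical(l1$values, l2$values)
  l3 <- gen_landscape(synth_config(nrow = 300, ncol = 300, seed = 11))
  expect_false(identical(l1$values, l3$values))

  shares <- table(factor(unname(l1$class_labels)[l1$values],
                         levels = names(cfg$shares))) / length(l1$values)
  expect_true(all(abs(as.numeric(shares) - cfg$shares) <= 0.02))

  cfg2 <- synth_config(nrow = 300, ncol = 300, seed = 1,
                       shares = c(A = 0.5, B = 0.3, C = 0.2))
  l4 <- gen_landscape(cfg2)
  sh4 <- as.numeric(table(factor(l4$values, levels = 1:3))) / (300 * 300)
  expect_true(all(abs(sh4 - c(0.5, 0.3, 0.2)) <= 0.02))

  expect_error(synth_config(shares = c(A = 0.6, B = 0.6), seed = 1),
               "sum to 1")
  expect_error(synth_config(), "seed")
})

test_that("zero autocorrelation yields spatially random class placement", {
  cfg <- synth_config(nrow = 100, ncol = 100, autocorr_length = 0,
                      shares = c(A = 0.5, B = 0.5), seed = 4)
  l <- gen_landscape(cfg)
  v <- l$values
  # join-count statistic: proportion of horizontally/vertically adjacent
  # equal-class pairs vs the independence expectation sum(p_k^2)
  same_h <- v[, -1] == v[, -ncol(v)]
  same_v <- v[-1, ] == v[-nrow(v), ]
  obs <- mean(c(same_h, same_v))
  p <- as.numeric(table(v)) / length(v)
  expected <- sum(p^2)
  n_pairs <- length(same_h) + length(same_v)
  se <- sqrt(expected * (1 - expected) / n_pairs)
  expect_lt(abs(obs - expected), 4 * se)
})

test_that("synthetic drivers have the declared geometric properties", {
  cfg <- synth_config(nrow = 80, ncol = 80, seed = 21)
  land <- gen_landscape(cfg)
  drv <- gen_drivers(cfg, land)
  expect_setequal(names(drv),
                  c("dist_roads", "dens_settlements", "altitude", "slope",
                    "tpi", "dist_cleared"))
  # distance raster is zero exactly on the feature cells
  expect_equal(sum(drv$dist_roads$values == 0) > 0, TRUE)
  expect_true(all(drv$dist_roads$values >= 0))
  expect_true(all(drv$dens_settlements$values >= 0))
  # dynamic driver anchored to current AWV extent
  awv <- land$values == 1L
  expect_true(all(drv$dist_cleared$values[awv] == 0))
})

test_that("slope and TPI behave on constructed elevation fields", {
  flat <- matrix(1500, 20, 20)
  expect_true(all(slope_deg(flat, 30) == 0))
  expect_true(all(tpi_index(flat) == 0))

  # single peak: positive TPI at the peak, negative in the pit ring around
  # it (hand-checked against 5x5 neighborhood means)
  elev <- matrix(0, 11, 11)
  elev[6, 6] <- 100
  tpi <- tpi_index(elev, radius = 2)
  expect_equal(tpi[6, 6], 100 - 100 / 25)
  expect_equal(tpi[6, 4], 0 - 100 / 25)  # ring cell sees the peak
  expect_equal(tpi[1, 1], 0)             # far corner unaffected
})

test_that("identity-matrix histories are constant", {
  cfg <- synth_config(nrow = 40, ncol = 40, seed = 2)
  land <- gen_landscape(cfg)
  drv <- gen_drivers(cfg, land)
  P <- diag(5)
  dimnames(P) <- list(unname(five_labels), unname(five_labels))
  id <- transition_matrix(P, 1)
  ser <- simulate_history(land, id, list(), drv, 3, seed = 5)
  expect_identical(ser[[4]]$values, land$values)
})

test_that("history recovery: estimated matrix within 3 SE of the truth", {
  cfg <- synth_config(nrow = 120, ncol = 120, n_years = 10, seed = 31)
  land <- gen_landscape(cfg)
  drv <- gen_drivers(cfg, land)
  ser <- simulate_history(land, cfg$true_matrix, cfg$effects, drv,
                          cfg$n_years, seed = 32)
  est <- estimate_matrix(crosstab(ser[[1]], ser[[11]]), 10)
  truth10 <- lulcsim::tmatrix_power(cfg$true_matrix, 10)
  n_row <- table(factor(unname(land$class_labels)[land$values],
                        levels = cfg$true_matrix$class_order))
  for (from in rownames(truth10)) {
    if (n_row[from] < 50) next  # rare classes carry no power
    se <- sqrt(truth10[from, ] * (1 - truth10[from, ]) /
                 as.numeric(n_row[from]))
    expect_true(all(abs(est$P[from, ] - truth10[from, ]) <=
                      3 * se + 1e-9),
                label = paste("row", from))
  }
})

test_that("planted WoE effects are recovered in sign and magnitude", {
  errs <- sapply(1:10, function(seed) {
    cfg <- synth_config(nrow = 100, ncol = 100, n_years = 8, seed = seed)
    land <- gen_landscape(cfg)
    drv <- gen_drivers(cfg, land)
    ser <- simulate_history(land, cfg$true_matrix, cfg$effects, drv,
                            cfg$n_years, seed = seed + 500)
    first <- ser[[1]]
    last <- ser[[length(ser)]]
    ef <- cfg$effects[[1]]
    elig <- !is.na(first$values) &
      first$values == which(unname(first$class_labels) == ef$from)
    chg <- elig &
      last$values == which(unname(first$class_labels) == ef$to)
    dmax <- max(drv[[ef$driver]]$values) + 1
    wt <- compute_woe(chg, elig, drv[[ef$driver]],
                      bins = c(ef$range[1], ef$range[2], dmax))
    w_in <- wt$w_plus[1]
    w_out <- wt$w_plus[2]
    c(sign_ok = w_in > w_out, err = (w_in - w_out) - ef$w_plus)
  })
  expect_true(all(errs["sign_ok", ] == 1))
  expect_lt(mean(abs(errs["err", ])), 0.3)
})

test_that("forward simulation beats a no-change baseline on fuzzy similarity", {
  wins <- sapply(1:10, function(seed) {
    cfg <- synth_config(nrow = 60, ncol = 60, n_years = 6, seed = seed)
    land <- gen_landscape(cfg)
    drv <- gen_drivers(cfg, land)
    ser <- simulate_history(land, cfg$true_matrix, cfg$effects, drv,
                            cfg$n_years, seed = seed + 900)
    split <- 4L  # calibrate on years 0..3, hold out year 6
    est <- estimate_matrix(crosstab(ser[[1]], ser[[split]]), split - 1)
    ann <- suppressWarnings(annualize(est, force_stochastic = TRUE))
    wl <- tarahumara_whitelist()
    woe <- calibrate_woe(ser[[1]], ser[[split]], drv, wl, n_bins = 8,
                         screen = FALSE)
    fwd <- run_simulation(ser[[split]], ann, woe, patch_params(),
                          n_years = cfg$n_years - (split - 1L),
                          seed = seed, drivers = drv, whitelist = wl)
    truth <- ser[[cfg$n_years + 1L]]
    f_sim <- fuzzy_similarity(truth, fwd$landscape, max_window = 5)
    f_base <- fuzzy_similarity(truth, ser[[split]], max_window = 5)
    f_sim$similarity[3] - f_base$similarity[3]
  })
  expect_gt(mean(wins), 0)
})

test_that("synthetic bundles serialize completely", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(nrow = 30, ncol = 30, n_years = 2, seed = 77)
  write_synth_bundle(cfg, dir)
  expect_true(file.exists(file.path(dir, "lulc_year00.asc")))
  expect_true(file.exists(file.path(dir, "lulc_year02.asc")))
  expect_true(file.exists(file.path(dir, "driver_dist_roads.txt")))
  expect_true(file.exists(file.path(dir, "true_matrix.csv")))
  expect_true(file.exists(file.path(dir, "truth.yml")))
  back <- read_landscape(file.path(dir, "lulc_year00.asc"))
  expect_identical(back$values, gen_landscape(cfg)$values)
})
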