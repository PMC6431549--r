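#' Scenario specification
#'
#' A scenario perturbs the annual transition matrix and the patch dynamics
#' multiplicatively: pessimistic scenarios amplify deforestation and
#' fragmentation rates, optimistic ones damp them, the stationary scenario
#' keeps the historical trend untouched. Classes whose extent the scenario
#' holds fixed (by default human settlements and water bodies) are frozen
#' to persistence.
#'
#' @param name Scenario name.
#' @param rate_multipliers Either a single positive factor applied to every
#'   off-diagonal rate, or a data frame `from`, `to`, `factor` for
#'   per-transition factors (unlisted transitions keep factor 1).
#' @param patch_multipliers Named numeric, factors applied to
#'   `mean_patch_size` and `expander_fraction` of the patch parameters,
#'   e.g. `c(mean_patch_size = 1.5, expander_fraction = 1)`.
#' @param frozen_classes Class labels forced to persistence (identity rows,
#'   and no flow into them from other classes).
#' @param target_year Projection horizon.
#' @param seed RNG seed for the projection run.
#' @return A `lulc_scenario` object.
#' @export
scenario_spec <- function(name = "custom", rate_multipliers = 1,
                          patch_multipliers = c(mean_patch_size = 1,
                                                expander_fraction = 1),
                          frozen_classes = c("HS", "WB"),
                          target_year = 2050, seed = NULL) {
  if (is.numeric(rate_multipliers) && any(rate_multipliers <= 0)) {
    stop("rate multipliers must be > 0")
  }
  structure(list(name = name, rate_multipliers = rate_multipliers,
                 patch_multipliers = patch_multipliers,
                 frozen_classes = frozen_classes,
                 target_year = target_year, seed = seed),
            class = "lulc_scenario")
}

#' @rdname scenario_spec
#' @export
scenario_stationary <- function(target_year = 2050, seed = NULL) {
  scenario_spec("stationary", 1, target_year = target_year, seed = seed)
}

#' @rdname scenario_spec
#' @param factor Global rate multiplier (default 0.5 optimistic, 1.5
#'   pessimistic).
#' @export
scenario_optimistic <- function(factor = 0.5, target_year = 2050,
                                seed = NULL) {
  scenario_spec("optimistic", factor,
                patch_multipliers = c(mean_patch_size = factor,
                                      expander_fraction = 1),
                target_year = target_year, seed = seed)
}

#' @rdname scenario_spec
#' @export
scenario_pessimistic <- function(factor = 1.5, target_year = 2050,
                                 seed = NULL) {
  scenario_spec("pessimistic", factor,
                patch_multipliers = c(mean_patch_size = factor,
                                      expander_fraction = 1),
                target_year = target_year, seed = seed)
}

#' Read a scenario specification from YAML
#'
#' Fields: `name`, `rate_multipliers` (scalar, or list of
#' `{from, to, factor}`), `patch_multipliers` (map), `frozen_classes`,
#' `target_year`, `seed`.
#' @param path YAML file path.
#' @return A `lulc_scenario`.
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  rm <- y$rate_multipliers %||% 1
  if (is.list(rm)) {
    rm <- do.call(rbind, lapply(rm, as.data.frame))
  }
  pm <- unlist(y$patch_multipliers %||%
                 list(mean_patch_size = 1, expander_fraction = 1))
  scenario_spec(name = y$name %||% "custom", rate_multipliers = rm,
                patch_multipliers = pm,
                frozen_classes = unlist(y$frozen_classes) %||%
                  c("HS", "WB"),
                target_year = y$target_year %||% 2050, seed = y$seed)
}

#' Apply a scenario's rate perturbation to an annual matrix
#'
#' Off-diagonal entries are scaled by the scenario's multipliers and the
#' diagonal absorbs the difference; frozen classes get identity rows and no
#' inbound flow. If a row's scaled off-diagonal mass reaches 1 the scenario
#' is infeasible and an error names the row.
#'
#' @param m Annual `lulc_tmatrix`.
#' @param spec A `lulc_scenario`.
#' @return Perturbed `lulc_tmatrix`.
#' @export
apply_scenario <- function(m, spec) {
  stopifnot(inherits(m, "lulc_tmatrix"), inherits(spec, "lulc_scenario"))
  P <- m$P
  labs <- m$class_order
  fac <- matrix(1, nrow(P), ncol(P), dimnames = dimnames(P))
  rm <- spec$rate_multipliers
  if (is.data.frame(rm)) {
    for (k in seq_len(nrow(rm))) {
      if (rm$from[k] %in% labs && rm$to[k] %in% labs) {
        fac[rm$from[k], rm$to[k]] <- rm$factor[k]
      }
    }
  } else {
    fac[] <- rm
  }
  off <- row(P) != col(P)
  P[off] <- P[off] * fac[off]
  frozen <- intersect(spec$frozen_classes, labs)
  for (fz in frozen) {
    P[fz, ] <- 0
    P[fz, fz] <- 1
    P[setdiff(labs, fz), fz] <- 0  # no inbound flow either
  }
  offsum <- rowSums(P) - diag(P)
  if (any(offsum >= 1)) {
    bad <- labs[which.max(offsum)]
    stop(sprintf("scenario '%s' infeasible: off-diagonal mass %.3f >= 1 in row '%s'",
                 spec$name, max(offsum), bad))
  }
  diag(P) <- 1 - offsum
  transition_matrix(P, m$period_years)
}

# Patch parameters after scenario scaling.
scale_patch_params <- function(pp, spec) {
  f <- spec$patch_multipliers
  patch_params(
    mean_patch_size = pp$mean_patch_size * (f[["mean_patch_size"]] %||% 1),
    patch_size_variance = pp$patch_size_variance,
    isometry = pp$isometry,
    expander_fraction = min(1, pp$expander_fraction *
                              (f[["expander_fraction"]] %||% 1))
  )
}

#' Project a landscape to a target year under a scenario
#'
#' Runs the Markov-CA for `target_year - start_year` annual steps under the
#' scenario-perturbed matrix and patch parameters.
#'
#' @param initial `lulc_landscape` at `start_year`.
#' @param m Annual `lulc_tmatrix` (historical trend).
#' @param spec A `lulc_scenario`.
#' @param woe_model,params,drivers,whitelist As in [run_simulation()].
#' @param start_year Calendar year of `initial`.
#' @param seed RNG seed; defaults to the spec's seed.
#' @return List: `landscape` (at the target year), `areas` (area table for
#'   both years), `ledger`, `spec`, `matrix` (the perturbed matrix).
#' @export
project_scenario <- function(initial, m, spec, woe_model = list(),
                             params = patch_params(), drivers = list(),
                             whitelist = NULL, start_year = 2017,
                             seed = NULL) {
  stopifnot(spec$target_year > start_year)
  seed <- seed %||% spec$seed
  if (is.null(seed)) stop("a seed is required for scenario projection")
  m2 <- apply_scenario(m, spec)
  pp <- if (inherits(params, "lulc_patch_params")) {
    scale_patch_params(params, spec)
  } else lapply(params, scale_patch_params, spec = spec)
  st <- run_simulation(initial, m2, woe_model, pp,
                       n_years = spec$target_year - start_year,
                       seed = seed, drivers = drivers,
                       whitelist = whitelist)
  areas <- area_table(list(initial, st$landscape),
                      c(start_year, spec$target_year))
  list(landscape = st$landscape, areas = areas, ledger = st$ledger,
       spec = spec, matrix = m2)
}

#' Hectare change per class from start/end shares
#'
#' Converts percentage shares at the two epochs into signed hectare changes
#' on a fixed footprint:
#' `change_ha = (share_end - share_start) / 100 * total_area_ha`.
#'
#' @param at Area table holding exactly two epochs (columns `class`,
#'   `epoch`, `share_pct`), e.g. from [project_scenario()]`$areas` or
#'   [area_table_from_areas()].
#' @param total_area_ha Footprint area in hectares.
#' @param epoch_a,epoch_b Epoch labels; default: the two epochs in order.
#' @return Data frame `class`, `share_a`, `share_b`, `change_ha`.
#' @export
scenario_report <- function(at, total_area_ha, epoch_a = NULL,
                            epoch_b = NULL) {
  eps <- unique(at$epoch)
  epoch_a <- as.character(epoch_a %||% eps[1])
  epoch_b <- as.character(epoch_b %||% eps[2])
  a <- at[at$epoch == epoch_a, ]
  b <- at[at$epoch == epoch_b, ]
  i <- match(a$class, b$class)
  data.frame(class = a$class,
             share_a = a$share_pct,
             share_b = b$share_pct[i],
             change_ha = (b$share_pct[i] - a$share_pct) / 100 *
               total_area_ha)
}
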