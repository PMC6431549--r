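#' Patch-dynamics parameters for the CA allocator
#'
#' @param mean_patch_size Mean new-patch size in hectares.
#' @param patch_size_variance Variance of patch size (ha^2); 0 gives
#'   constant-size patches. Sizes are lognormal, truncated at the remaining
#'   demand.
#' @param isometry Compactness factor >= 1; larger values weight patch
#'   growth towards cells with more patch neighbours, giving rounder
#'   patches.
#' @param expander_fraction Fraction in [0, 1] of each transition's demand
#'   routed to expansion of existing patches; the remainder (plus any unmet
#'   expansion) seeds new patches.
#' @return A `lulc_patch_params` object.
#' @export
patch_params <- function(mean_patch_size = 1, patch_size_variance = 0.5,
                         isometry = 1.5, expander_fraction = 0.5) {
  stopifnot(mean_patch_size > 0, patch_size_variance >= 0, isometry >= 1,
            expander_fraction >= 0, expander_fraction <= 1)
  structure(list(mean_patch_size = mean_patch_size,
                 patch_size_variance = patch_size_variance,
                 isometry = isometry,
                 expander_fraction = expander_fraction),
            class = "lulc_patch_params")
}

#' Simulation state
#'
#' Bundles the evolving landscape, the current (possibly dynamic) driver
#' rasters, the per-step change ledger and the demand-rounding carry.
#'
#' @param landscape A `lulc_landscape`.
#' @param drivers Named list of `lulc_driver`s (may be empty).
#' @return A `ca_state` object.
#' @export
ca_state <- function(landscape, drivers = list()) {
  structure(list(landscape = landscape, drivers = drivers,
                 step_index = 0L,
                 ledger = data.frame(year = integer(0), from = character(0),
                                     to = character(0), cells = integer(0)),
                 carry = numeric(0)),
            class = "ca_state")
}

#' Per-step change demand from an annual Markov matrix
#'
#' `demand(i -> j) = count(i) * P[i, j]` cells, rounded by a
#' largest-remainder carry accumulator kept across steps so that multi-step
#' totals are unbiased even for rates far below one cell per step.
#' Negative annualization artifacts contribute zero demand.
#'
#' @param m Annual `lulc_tmatrix`.
#' @param landscape Current `lulc_landscape` (classes must match the
#'   matrix).
#' @param whitelist Optional `lulc_whitelist` limiting which transitions
#'   demand cells.
#' @param carry Named numeric carry from the previous step (names
#'   `"FROM->TO"`); empty on the first step.
#' @return List: `demand` (named integer cells per transition) and `carry`.
#' @export
demand <- function(m, landscape, whitelist = NULL, carry = numeric(0)) {
  stopifnot(inherits(m, "lulc_tmatrix"))
  labs_map <- unname(landscape$class_labels)
  if (!all(labs_map %in% m$class_order)) {
    stop("landscape classes missing from transition matrix: ",
         paste(setdiff(labs_map, m$class_order), collapse = ", "))
  }
  v <- landscape$values
  lv <- label_of(landscape, v[!is.na(v)])
  n_by <- table(factor(lv, levels = m$class_order))
  pairs <- which(m$P > 0 & row(m$P) != col(m$P), arr.ind = TRUE)
  dem <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    from <- m$class_order[pairs[k, 1]]
    to <- m$class_order[pairs[k, 2]]
    if (!is.null(whitelist) &&
        !any(whitelist$from == from & whitelist$to == to)) next
    key <- paste0(from, "->", to)
    target <- as.numeric(n_by[from]) * m$P[from, to] +
      (if (key %in% names(carry)) carry[[key]] else 0)
    d <- floor(target)
    carry[[key]] <- target - d
    dem[[key]] <- as.integer(d)
  }
  list(demand = dem, carry = carry)
}

# Frontier: from-class cells 8-adjacent to at least one to-class cell.
frontier_cells <- function(values, from_code, to_code) {
  is_to <- !is.na(values) & values == to_code
  near <- dilate_square(is_to, 1L)
  which(near & !is.na(values) & values == from_code)
}

#' Expand existing patches of the target class
#'
#' Converts up to `quantity` from-class cells that are 8-adjacent to
#' existing to-class patches, sampling without replacement with probability
#' proportional to the transition-probability surface and recomputing the
#' adjacency frontier as patches grow. Demand that cannot be met (no
#' frontier) is returned as `unmet` and typically falls through to
#' [patcher()].
#'
#' @param state A `ca_state`.
#' @param transition Character pair `c(from, to)` (class labels).
#' @param quantity Non-negative integer number of cells to convert.
#' @param prob_map Probability matrix from [probability_map()].
#' @param params A `lulc_patch_params` (unused here beyond its presence in
#'   the common allocator signature).
#' @return List: updated `state`, `changed` (cells converted) and `unmet`.
#' @export
expander <- function(state, transition, quantity, prob_map, params) {
  stopifnot(inherits(state, "ca_state"), quantity >= 0)
  if (quantity == 0) return(list(state = state, changed = 0L, unmet = 0L))
  ls <- state$landscape
  from_code <- code_of(ls, transition[1])
  to_code <- code_of(ls, transition[2])
  v <- ls$values
  remaining <- as.integer(quantity)
  changed <- 0L
  repeat {
    if (remaining == 0L) break
    fr <- frontier_cells(v, from_code, to_code)
    fr <- fr[prob_map[fr] > 0]
    if (length(fr) == 0L) break
    take <- sample_weighted(fr, remaining, prob_map[fr])
    if (length(take) == 0L) break
    v[take] <- to_code
    changed <- changed + length(take)
    remaining <- remaining - length(take)
  }
  state$landscape$values <- v
  list(state = state, changed = changed, unmet = remaining)
}

# Grow one patch from a seed up to `size` cells, preferring
# high-probability neighbours; isometry raises the weight of cells touching
# more patch members, giving compact shapes.
grow_patch <- function(v, seed, size, from_code, prob_map, isometry) {
  patch <- seed
  nr <- nrow(v)
  while (length(patch) < size) {
    cand <- integer(0)
    for (p in patch) {
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        cc <- c + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= ncol(v)) {
          cand <- c(cand, (cc - 1L) * nr + rr)
        }
      }
    }
    cand <- setdiff(unique(cand), patch)
    cand <- cand[!is.na(v[cand]) & v[cand] == from_code & prob_map[cand] > 0]
    if (length(cand) == 0L) break
    # count patch members among each candidate's 8 neighbours
    adj <- vapply(cand, function(p) {
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      n <- 0L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr
        cc <- c + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= ncol(v) &&
            ((cc - 1L) * nr + rr) %in% patch) n <- n + 1L
      }
      n
    }, integer(1))
    w <- prob_map[cand] * isometry^(adj - 1)
    pick <- sample_weighted(cand, 1L, w)
    patch <- c(patch, pick)
  }
  patch
}

#' Seed and grow new patches of the target class
#'
#' Draws patch seeds among from-class cells with probability proportional
#' to the transition-probability surface; each seed grows a patch whose
#' target size is a lognormal draw parameterized by the configured mean and
#' variance (in hectares), truncated at the remaining demand.
#'
#' @inheritParams expander
#' @return List: updated `state`, `changed`, `unmet`.
#' @export
patcher <- function(state, transition, quantity, prob_map, params) {
  stopifnot(inherits(state, "ca_state"), quantity >= 0)
  if (quantity == 0) return(list(state = state, changed = 0L, unmet = 0L))
  ls <- state$landscape
  from_code <- code_of(ls, transition[1])
  to_code <- code_of(ls, transition[2])
  v <- ls$values
  cell_ha <- cell_area_ha(ls)
  mean_cells <- max(1, params$mean_patch_size / cell_ha)
  var_cells <- params$patch_size_variance / cell_ha^2
  if (var_cells > 0) {
    sdlog2 <- log(1 + var_cells / mean_cells^2)
    meanlog <- log(mean_cells) - sdlog2 / 2
  }
  remaining <- as.integer(quantity)
  changed <- 0L
  if (all(prob_map[!is.na(v) & v == from_code] <= 0)) {
    warning("all-zero probability map: cannot seed new patches")
    return(list(state = state, changed = 0L, unmet = remaining))
  }
  repeat {
    if (remaining == 0L) break
    elig <- which(!is.na(v) & v == from_code & prob_map > 0)
    if (length(elig) == 0L) break
    seed <- sample_weighted(elig, 1L, prob_map[elig])
    size <- if (var_cells > 0) {
      stats::rlnorm(1, meanlog, sqrt(sdlog2))
    } else mean_cells
    size <- min(max(1L, as.integer(round(size))), remaining)
    patch <- grow_patch(v, seed, size, from_code, prob_map, params$isometry)
    v[patch] <- to_code
    changed <- changed + length(patch)
    remaining <- remaining - length(patch)
  }
  state$landscape$values <- v
  list(state = state, changed = changed, unmet = remaining)
}

#' Recompute dynamic driver rasters from the current landscape
#'
#' Applies each dynamic driver's update rule. Built-in rule types:
#' `list(type = "distance", class = <label>)` -- exact Euclidean distance
#' (meters) to the nearest cell of the class, `+Inf` when the class is
#' absent; `list(type = "function", fn = <function(state) matrix>)`.
#'
#' @param state A `ca_state`.
#' @return The state with dynamic drivers recomputed.
#' @export
update_dynamic_drivers <- function(state) {
  stopifnot(inherits(state, "ca_state"))
  ls <- state$landscape
  for (nm in names(state$drivers)) {
    d <- state$drivers[[nm]]
    if (!isTRUE(d$dynamic)) next
    rule <- d$update
    if (identical(rule$type, "distance")) {
      if (!rule$class %in% ls$class_labels) {
        stop("dynamic driver '", nm, "' references unknown class '",
             rule$class, "'")
      }
      target <- !is.na(ls$values) &
        ls$values == code_of(ls, rule$class)
      d$values <- distance_to(target) * ls$cell_size
    } else if (identical(rule$type, "function")) {
      d$values <- rule$fn(state)
    } else {
      stop("unknown dynamic-driver rule type for '", nm, "'")
    }
    state$drivers[[nm]] <- d
  }
  state
}

# Probability surface for one transition under the current state.
transition_prob_map <- function(state, m, from, to, woe_model) {
  ls <- state$landscape
  eligible <- !is.na(ls$values) & ls$values == code_of(ls, from)
  prior <- min(max(m$P[from, to], 1e-6), 1 - 1e-6)
  key <- paste0(from, "->", to)
  tabs <- woe_model[[key]]
  if (is.null(tabs) || length(tabs) == 0L) {
    p <- matrix(0, nrow(ls$values), ncol(ls$values))
    p[eligible] <- prior
    p
  } else {
    probability_map(tabs, state$drivers, prior, eligible)
  }
}

#' Run the Markov-CA simulation
#'
#' Per year: compute the demand of every modeled transition from the annual
#' matrix (largest-remainder carry), allocate the expander share of each
#' demand onto existing patch edges, cascade the remainder plus unmet
#' expansion to the patcher, log realized changes, then refresh dynamic
#' drivers. Identical seeds give identical outputs; leftover patcher demand
#' carries to the next year through the demand accumulator.
#'
#' @param initial `lulc_landscape` at the start year.
#' @param m Annual `lulc_tmatrix` (use [annualize()] with
#'   `force_stochastic = TRUE` on estimated matrices).
#' @param woe_model Output of [calibrate_woe()] (may be `list()` for
#'   probability surfaces flat at the prior).
#' @param params A `lulc_patch_params`, or a named list of them keyed by
#'   `"FROM->TO"`.
#' @param n_years Number of yearly steps.
#' @param seed Integer RNG seed (mandatory: the allocation is stochastic).
#' @param drivers Named list of `lulc_driver`s backing the WoE model.
#' @param whitelist Optional `lulc_whitelist`; only listed transitions are
#'   simulated.
#' @param keep_series Keep a snapshot of the landscape after every year.
#' @return A `ca_state` with fields `landscape` (final), `ledger`,
#'   `carry`, and `series` (list of landscapes, when `keep_series`).
#' @export
run_simulation <- function(initial, m, woe_model = list(),
                           params = patch_params(), n_years, seed,
                           drivers = list(), whitelist = NULL,
                           keep_series = FALSE) {
  stopifnot(inherits(initial, "lulc_landscape"), n_years >= 0)
  withr::local_seed(seed)
  state <- ca_state(initial, drivers)
  state <- update_dynamic_drivers(state)
  if (keep_series) state$series <- list(initial)
  params_for <- function(key) {
    if (inherits(params, "lulc_patch_params")) params
    else params[[key]] %||% patch_params()
  }
  for (year in seq_len(n_years)) {
    dm <- demand(m, state$landscape, whitelist, state$carry)
    state$carry <- dm$carry
    for (key in names(dm$demand)) {
      q <- dm$demand[[key]]
      # demand persists through the carry even when 0 this year
      if (q == 0L) next
      tr <- strsplit(key, "->", fixed = TRUE)[[1]]
      pp <- params_for(key)
      pmap <- transition_prob_map(state, m, tr[1], tr[2], woe_model)
      q_exp <- as.integer(round(q * pp$expander_fraction))
      res_e <- expander(state, tr, q_exp, pmap, pp)
      state <- res_e$state
      res_p <- patcher(state, tr, q - q_exp + res_e$unmet, pmap, pp)
      state <- res_p$state
      done <- res_e$changed + res_p$changed
      if (res_p$unmet > 0L) {
        state$carry[[key]] <- (state$carry[[key]] %||% 0) + res_p$unmet
      }
      if (done > 0L) {
        state$ledger <- rbind(state$ledger,
                              data.frame(year = year, from = tr[1],
                                         to = tr[2], cells = done))
      }
    }
    state <- update_dynamic_drivers(state)
    state$step_index <- year
    if (keep_series) state$series[[year + 1L]] <- state$landscape
  }
  state
}
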