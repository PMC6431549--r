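#' Weights of Evidence for one transition and one driver
#'
#' For each driver value range r, the positive weight
#' `W+(r) = ln[ (n(r & D)/n(D)) / (n(r & !D)/n(!D)) ]`, where D is the set
#' of eligible cells that underwent the transition. Positive weights mark
#' ranges that attract the transition, negative weights ranges that repel
#' it. Bins where a changed or unchanged count is zero get +0.5 additive
#' smoothing on all four counts of the bin's 2x2 table, keeping weights
#' finite on sparse transitions.
#'
#' @param change_mask Logical matrix: cells undergoing the transition
#'   (must be a subset of `eligible_mask`).
#' @param eligible_mask Logical matrix: cells of the from-class at t0.
#' @param driver A `lulc_driver`.
#' @param bins Bin edges (default: 20 equal-width bins over the driver's
#'   observed range on eligible cells).
#' @param n_bins Number of bins when `bins` is NULL.
#' @return A `woe_table`: data frame `bin_lo`, `bin_hi`, `n_change`,
#'   `n_nochange`, `w_plus`, with the driver name and bin edges as
#'   attributes.
#' @export
compute_woe <- function(change_mask, eligible_mask, driver, bins = NULL,
                        n_bins = 20) {
  stopifnot(is.logical(change_mask), is.logical(eligible_mask))
  if (any(change_mask & !eligible_mask, na.rm = TRUE)) {
    stop("change_mask must be a subset of eligible_mask")
  }
  elig <- which(eligible_mask & !is.na(driver$values))
  if (length(elig) == 0L) stop("empty eligible mask")
  changed <- change_mask[elig]
  if (!any(changed) || all(changed)) {
    stop("need at least one changed and one unchanged eligible cell")
  }
  vals <- driver$values[elig]
  if (is.null(bins)) bins <- bin_edges(vals, n_bins)
  if (is.unsorted(bins, strictly = TRUE)) {
    stop("bins must be strictly increasing edges")
  }
  idx <- bin_index(vals, bins)
  nb <- length(bins) - 1L
  a <- tabulate(idx[changed], nbins = nb)       # n(r & D)
  c_ <- tabulate(idx[!changed], nbins = nb)     # n(r & !D)
  nD <- sum(changed)
  nN <- sum(!changed)
  b <- nD - a
  d <- nN - c_
  smooth <- a == 0 | c_ == 0
  a2 <- a + 0.5 * smooth
  b2 <- b + 0.5 * smooth
  c2 <- c_ + 0.5 * smooth
  d2 <- d + 0.5 * smooth
  w <- log((a2 / (a2 + b2)) / (c2 / (c2 + d2)))
  out <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1],
                    n_change = a, n_nochange = c_, w_plus = w)
  structure(out, class = c("woe_table", "data.frame"),
            driver = driver$name, bins = bins)
}

# Per-cell W+ lookup for one WoE table.
woe_lookup <- function(wt, driver_values) {
  idx <- bin_index(driver_values, attr(wt, "bins"))
  w <- rep(NA_real_, length(idx))
  ok <- !is.na(idx)
  w[ok] <- wt$w_plus[idx[ok]]
  matrix(w, nrow(driver_values), ncol(driver_values))
}

#' Transition-probability surface from Weights of Evidence
#'
#' Combines the W+ weights of several (conditionally independent) drivers
#' into a per-cell transition probability:
#' `odds = prior/(1-prior) * exp(sum of W+)`, `P = odds/(1+odds)`. Cells
#' outside the from-class get probability 0.
#'
#' @param woe_tables List of `woe_table`s for one transition.
#' @param drivers Named list of `lulc_driver`s containing every driver the
#'   tables refer to.
#' @param prior Fraction of eligible cells expected to change per step, in
#'   (0, 1) (typically the annual Markov rate of the transition).
#' @param eligible_mask Logical matrix of from-class cells.
#' @return Numeric probability matrix in [0, 1].
#' @export
probability_map <- function(woe_tables, drivers, prior, eligible_mask) {
  if (length(prior) != 1 || !is.finite(prior) || prior <= 0 || prior >= 1) {
    stop("prior must be a single probability in (0, 1)")
  }
  s <- matrix(0, nrow(eligible_mask), ncol(eligible_mask))
  for (wt in woe_tables) {
    dn <- attr(wt, "driver")
    if (!dn %in% names(drivers)) {
      stop("missing driver raster for WoE table '", dn, "'")
    }
    w <- woe_lookup(wt, drivers[[dn]]$values)
    w[is.na(w)] <- 0
    s <- s + w
  }
  odds <- prior / (1 - prior) * exp(s)
  p <- odds / (1 + odds)
  p[!eligible_mask] <- 0
  p[is.na(p)] <- 0
  p
}

#' Calibrate a full WoE model for a set of transitions
#'
#' Convenience wrapper: for every whitelisted transition observed between
#' two maps, computes one `woe_table` per retained driver.
#'
#' @param a,b Comparable landscapes (start and end of the calibration
#'   period).
#' @param drivers Named list of `lulc_driver`s.
#' @param whitelist A `lulc_whitelist` of transitions to model.
#' @param n_bins Bins per driver.
#' @param screen Apply [screen_drivers()] per transition first?
#' @param threshold Cramer's V screening threshold.
#' @return Named list (names `"FROM->TO"`) of lists of `woe_table`s.
#' @export
calibrate_woe <- function(a, b, drivers, whitelist, n_bins = 20,
                          screen = TRUE, threshold = 0.5) {
  check_comparable(a, b)
  out <- list()
  la <- matrix(label_of(a, a$values), nrow(a$values))
  lb <- matrix(label_of(b, b$values), nrow(b$values))
  for (k in seq_len(nrow(whitelist))) {
    from <- whitelist$from[k]
    to <- whitelist$to[k]
    eligible <- !is.na(la) & la == from
    change <- eligible & !is.na(lb) & lb == to
    if (!any(change) || sum(eligible) == sum(change)) next
    use <- names(drivers)
    if (screen && length(drivers) >= 2L) {
      use <- screen_drivers(drivers, change, threshold = threshold,
                            n_bins = n_bins)$retained
    }
    tabs <- lapply(drivers[use], function(d) {
      compute_woe(change, eligible, d, n_bins = n_bins)
    })
    out[[paste0(from, "->", to)]] <- tabs
  }
  out
}

#' Write WoE tables to CSV
#'
#' Long format: `transition`, `driver`, `bin_lo`, `bin_hi`, `n_change`,
#' `n_nochange`, `w_plus`.
#' @param model Output of [calibrate_woe()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_woe_csv <- function(model, path) {
  rows <- list()
  for (tr in names(model)) {
    for (wt in model[[tr]]) {
      rows[[length(rows) + 1L]] <-
        cbind(transition = tr, driver = attr(wt, "driver"),
              as.data.frame(wt))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
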