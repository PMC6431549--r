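#' Continuous driver raster
#'
#' A spatial explanatory variable on the landscape grid. Three families are
#' distinguished, mirroring common deforestation-model inputs: `density`
#' (e.g. road density per km2), `proximity` (distance to features, m) and
#' `topographic` (altitude, slope, topographic position index). Dynamic
#' drivers (e.g. distance to cleared areas) declare an update rule and are
#' recomputed every simulation step.
#'
#' @param values Numeric matrix on the landscape grid (`NA` = nodata).
#' @param name Variable name.
#' @param kind `"density"`, `"proximity"` or `"topographic"`.
#' @param dynamic Is the driver recomputed each iteration?
#' @param update Update rule for dynamic drivers: a list such as
#'   `list(type = "distance", class = "AWV")` (Euclidean distance, in
#'   meters, to the current extent of a class).
#' @return A `lulc_driver` object.
#' @export
driver_raster <- function(values, name,
                          kind = c("density", "proximity", "topographic"),
                          dynamic = FALSE, update = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  kind <- match.arg(kind)
  if (dynamic && is.null(update)) {
    stop("dynamic drivers must declare an update rule")
  }
  structure(list(values = values, name = name, kind = kind,
                 dynamic = dynamic, update = update),
            class = "lulc_driver")
}

#' @export
print.lulc_driver <- function(x, ...) {
  cat(sprintf("<lulc_driver> '%s' (%s%s), %d x %d\n", x$name, x$kind,
              if (x$dynamic) ", dynamic" else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# chi-square statistic with expected counts from the marginals, no
# continuity correction; zero marginal rows/columns dropped with a warning.
chi2_stat <- function(counts) {
  zr <- rowSums(counts) == 0
  zc <- colSums(counts) == 0
  if (any(zr) || any(zc)) {
    warning(sprintf("dropping %d zero row(s) and %d zero column(s) before chi-square",
                    sum(zr), sum(zc)))
    counts <- counts[!zr, !zc, drop = FALSE]
  }
  total <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / total
  list(chi2 = sum((counts - expected)^2 / expected),
       total = total,
       M = min(nrow(counts), ncol(counts)) - 1L,
       counts = counts)
}

#' Contingency table between two discretized variables
#'
#' @param x,y Vectors (or matrices) of equal length; `NA`s dropped pairwise.
#'   Factors or integer bin indices.
#' @return `lulc_contingency`: `counts`, `chi2`, `total` (the grand total),
#'   `M` (min(rows, cols) - 1).
#' @export
contingency <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  counts <- unclass(table(x[ok], y[ok]))
  st <- chi2_stat(counts)
  structure(st, class = "lulc_contingency")
}

#' Cramer's V association measure
#'
#' `V = sqrt(chi2 / (total * M))` on a contingency table, in [0, 1]; values
#' above 0.5 indicate association (and hence redundancy between two
#' drivers), values below suggest independence.
#'
#' @param ct A `lulc_contingency`, or a bare counts matrix.
#' @return V in [0, 1].
#' @export
cramers_v <- function(ct) {
  if (!inherits(ct, "lulc_contingency")) {
    ct <- structure(chi2_stat(as.matrix(ct)), class = "lulc_contingency")
  }
  if (ct$total <= 0) stop("empty contingency table")
  if (ct$M < 1) stop("contingency table needs at least 2 rows and columns")
  sqrt(ct$chi2 / (ct$total * ct$M))
}

#' Equal-width bin edges over the observed range
#' @param values Numeric vector/matrix.
#' @param n_bins Number of bins (default 20).
#' @return Numeric vector of `n_bins + 1` edges.
#' @export
bin_edges <- function(values, n_bins = 20) {
  rng <- range(values[is.finite(values)], na.rm = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = n_bins + 1)
}

# Bin index per cell (1..n_bins), clamped into range; NA stays NA.
bin_index <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1L & !is.na(idx)] <- 1L
  n <- length(edges) - 1L
  idx[idx > n & !is.na(idx)] <- n
  idx[!is.finite(values)] <- n  # +Inf sentinels fall in the top bin
  idx[is.na(values)] <- NA_integer_
  idx
}

#' Screen redundant drivers with Cramer's V
#'
#' Continuous drivers are discretized into equal-width bins, all pairs are
#' cross-tabulated, and for every pair with `V > threshold` the member with
#' the weaker association to the target transition (lower V against the
#' change mask) is dropped, until all retained pairs satisfy
#' `V <= threshold`. Ties at exactly the threshold are retained.
#'
#' @param drivers Named list of `lulc_driver` objects.
#' @param change_mask Logical matrix marking cells undergoing the target
#'   transition (used to rank correlated pairs).
#' @param threshold Association threshold (default 0.5).
#' @param n_bins Bins per continuous driver (default 20).
#' @return List: `retained` (names), `dropped` (data frame `driver`,
#'   `paired_with`, `v`), `pairwise_v` (matrix).
#' @export
screen_drivers <- function(drivers, change_mask, threshold = 0.5,
                           n_bins = 20) {
  stopifnot(length(drivers) >= 2L, !is.null(names(drivers)))
  binned <- lapply(drivers, function(d) {
    bin_index(d$values, bin_edges(d$values, n_bins))
  })
  nm <- names(drivers)
  vmat <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      vmat[i, j] <- vmat[j, i] <- cramers_v(contingency(binned[[i]],
                                                        binned[[j]]))
    }
  }
  v_target <- vapply(binned, function(b) {
    cramers_v(contingency(b, as.integer(change_mask)))
  }, numeric(1))
  retained <- nm
  dropped <- data.frame(driver = character(0), paired_with = character(0),
                        v = numeric(0))
  repeat {
    sub <- vmat[retained, retained, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA
    if (all(is.na(sub)) || max(sub, na.rm = TRUE) <= threshold) break
    worst <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- retained[worst[1]]
    b <- retained[worst[2]]
    drop <- if (v_target[a] >= v_target[b]) b else a
    keep_of_pair <- setdiff(c(a, b), drop)
    dropped <- rbind(dropped, data.frame(driver = drop,
                                         paired_with = keep_of_pair,
                                         v = max(sub, na.rm = TRUE)))
    retained <- setdiff(retained, drop)
  }
  list(retained = retained, dropped = dropped, pairwise_v = vmat)
}
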