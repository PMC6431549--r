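#' Markov transition matrix for land-cover change
#'
#' A row-stochastic class-by-class probability matrix together with the
#' period length it describes: entry (i, j) is the probability that a cell
#' of class i at the start of the period is class j at its end.
#'
#' @param P Numeric square matrix with identical row/column class labels
#'   (dimnames), rows summing to 1.
#' @param period_years Positive period length in years.
#' @param tol Allowed deviation of row sums from 1. With `normalize = TRUE`
#'   rows within `tol` are rescaled to sum exactly to 1 (use for printed
#'   matrices rounded to few decimals).
#' @param normalize Rescale rows to sum to 1 after the tolerance check.
#' @return A `lulc_tmatrix` object.
#' @export
transition_matrix <- function(P, period_years, tol = 1e-9,
                              normalize = FALSE) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P), period_years > 0)
  if (is.null(rownames(P))) {
    rownames(P) <- colnames(P) <- as.character(seq_len(nrow(P)))
  }
  if (!identical(rownames(P), colnames(P))) {
    stop("row and column class labels must match")
  }
  if (any(P < -tol) || any(P > 1 + tol)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol)) {
    bad <- rownames(P)[which.max(abs(rs - 1))]
    stop(sprintf("row '%s' sums to %.6f, not 1 (tol %g)", bad,
                 rs[which.max(abs(rs - 1))], tol))
  }
  if (normalize) P <- P / rs
  structure(list(P = P, period_years = as.numeric(period_years),
                 class_order = rownames(P)),
            class = "lulc_tmatrix")
}

#' @export
print.lulc_tmatrix <- function(x, ...) {
  cat(sprintf("<lulc_tmatrix> %d classes over %g year(s)\n",
              nrow(x$P), x$period_years))
  print(round(x$P, 4))
  invisible(x)
}

#' Estimate a transition matrix from cross-tabulated counts
#'
#' Maximum-likelihood row normalization of the transition counts: the
#' historical trend of LULC change over the period separating the two maps.
#' Classes absent at the start epoch (all-zero rows) get identity rows (the
#' class persists) with a warning.
#'
#' @param tc A `lulc_crosstab` (or bare counts matrix).
#' @param period_years Years separating the two maps.
#' @return A `lulc_tmatrix` with the same period.
#' @export
estimate_matrix <- function(tc, period_years) {
  counts <- if (inherits(tc, "lulc_crosstab")) tc$counts else tc
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (sum(counts) == 0) stop("cannot estimate from all-zero counts")
  P <- counts / ifelse(rowSums(counts) > 0, rowSums(counts), 1)
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning("class(es) absent at start epoch get identity rows: ",
            paste(rownames(counts)[zero], collapse = ", "))
    P[zero, ] <- 0
    diag(P)[zero] <- 1
  }
  transition_matrix(P, period_years)
}

#' Annualize a multi-year transition matrix
#'
#' Computes the principal matrix root `A = P^(1/period)` by
#' eigendecomposition so that a matrix estimated over a multi-decade period
#' can drive yearly cellular-automata steps. The exact principal root of a
#' diagonally dominant LULC matrix can carry small negative entries; by
#' default only sub-`artifact_tol` numerical noise is zeroed (so that
#' `A^period` still reproduces `P` to machine precision) and any larger
#' negative mass is kept, reported in the `cleanup` attribute and warned
#' about. With `force_stochastic = TRUE` all negative entries are truncated
#' and rows renormalized, yielding a proper stochastic matrix at the cost of
#' round-trip exactness.
#'
#' @param m A `lulc_tmatrix`.
#' @param artifact_tol Magnitude below which negative entries are treated as
#'   numerical artifacts and zeroed.
#' @param force_stochastic Truncate all negatives and renormalize rows.
#' @return A `lulc_tmatrix` with `period_years = 1` and an attribute
#'   `cleanup` (total absolute mass removed or retained negative).
#' @export
annualize <- function(m, artifact_tol = 1e-9, force_stochastic = FALSE) {
  stopifnot(inherits(m, "lulc_tmatrix"))
  P <- m$P
  per <- m$period_years
  e <- eigen(P)
  ev <- e$values
  # the principal root is real for complex-conjugate pairs; a (numerically)
  # real eigenvalue on the non-positive axis has no principal root
  real_neg <- abs(Im(ev)) < 1e-10 & Re(ev) <= 1e-12
  if (any(real_neg)) {
    stop(sprintf("cannot annualize: non-positive real eigenvalue %.6g",
                 min(Re(ev)[real_neg])))
  }
  V <- e$vectors
  Vi <- tryCatch(solve(V), error = function(err) {
    stop("cannot annualize: matrix is not diagonalizable")
  })
  A <- Re(V %*% diag(as.complex(ev)^(1 / per), nrow(P)) %*% Vi)
  neg <- pmin(A, 0)
  artifact <- A < 0 & A >= -artifact_tol
  A[artifact] <- 0
  cleanup <- sum(abs(neg))
  if (force_stochastic) {
    A <- pmax(A, 0)
    A <- A / rowSums(A)
  } else if (any(A < 0)) {
    warning(sprintf(
      "annual matrix keeps negative entries (total mass %.3g); use force_stochastic = TRUE for a proper stochastic matrix",
      sum(abs(pmin(A, 0)))))
  }
  dimnames(A) <- dimnames(P)
  # constructed directly: the default root may keep reported sub-percent
  # negative entries, which the [0, 1] check would reject
  out <- structure(list(P = A, period_years = 1, class_order = rownames(A)),
                   class = "lulc_tmatrix")
  attr(out, "cleanup") <- cleanup
  out
}

#' Power of a transition matrix
#' @param m A `lulc_tmatrix`.
#' @param n Non-negative integer number of periods.
#' @return The matrix `P^n` (plain matrix).
#' @export
tmatrix_power <- function(m, n) {
  stopifnot(inherits(m, "lulc_tmatrix"), n >= 0)
  out <- diag(nrow(m$P))
  dimnames(out) <- dimnames(m$P)
  Pk <- m$P
  n <- as.integer(n)
  while (n > 0L) {
    if (n %% 2L == 1L) out <- out %*% Pk
    Pk <- Pk %*% Pk
    n <- n %/% 2L
  }
  out
}

#' Project class shares forward under a Markov matrix
#'
#' @param m Annual `lulc_tmatrix`.
#' @param shares Named per-class fractions summing to 1 (order of
#'   `m$class_order`).
#' @param n_years Non-negative integer horizon.
#' @return Named share vector after `n_years` steps; sums to 1.
#' @export
project_shares <- function(m, shares, n_years) {
  stopifnot(inherits(m, "lulc_tmatrix"))
  if (n_years < 0) stop("n_years must be >= 0")
  if (!is.null(names(shares))) shares <- shares[m$class_order]
  if (abs(sum(shares) - 1) > 1e-9) stop("shares must sum to 1")
  out <- as.numeric(shares %*% tmatrix_power(m, n_years))
  stats::setNames(out, m$class_order)
}

#' Transition whitelist
#'
#' The set of (from, to) class pairs a simulation is allowed to realize;
#' self-pairs are not admissible.
#' @param from,to Character vectors of equal length (class labels).
#' @return A `lulc_whitelist` data frame.
#' @export
transition_whitelist <- function(from, to) {
  stopifnot(length(from) == length(to))
  if (any(from == to)) stop("whitelist cannot contain self-transitions")
  structure(data.frame(from = from, to = to),
            class = c("lulc_whitelist", "data.frame"))
}

#' Restrict a transition matrix to whitelisted transitions
#'
#' Probability mass on off-diagonal, off-whitelist entries is moved to the
#' diagonal (the cell persists instead), keeping rows stochastic.
#'
#' @param m A `lulc_tmatrix`.
#' @param w A `lulc_whitelist`.
#' @return Restricted `lulc_tmatrix`.
#' @export
restrict <- function(m, w) {
  stopifnot(inherits(m, "lulc_tmatrix"), inherits(w, "lulc_whitelist"))
  P <- m$P
  labs <- m$class_order
  allowed <- matrix(FALSE, nrow(P), ncol(P), dimnames = dimnames(P))
  for (k in seq_len(nrow(w))) {
    if (w$from[k] %in% labs && w$to[k] %in% labs) {
      allowed[w$from[k], w$to[k]] <- TRUE
    }
  }
  diag(allowed) <- TRUE
  moved <- P * !allowed
  P[!allowed] <- 0
  diag(P) <- diag(P) + rowSums(moved)
  transition_matrix(P, m$period_years)
}

#' Read / write a transition matrix as CSV
#'
#' Layout: header = class labels, one row per from-class (first column
#' `from`), probabilities at 6 decimals; this round-trips printed matrices
#' exactly at that precision.
#'
#' @param m A `lulc_tmatrix`.
#' @param path CSV path.
#' @param period_years Period to attach on read.
#' @param ... Passed to [transition_matrix()] (e.g. `normalize`, `tol`).
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_transition_csv <- function(m, path) {
  stopifnot(inherits(m, "lulc_tmatrix"))
  df <- data.frame(from = m$class_order,
                   round(m$P, 6), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path, period_years, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  P <- as.matrix(df[, -1, drop = FALSE])
  rownames(P) <- df$from
  colnames(P) <- colnames(df)[-1]
  transition_matrix(P, period_years, ...)
}
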