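#' Cohen's kappa between two landscapes
#'
#' Cell-by-cell agreement corrected for chance:
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' taken from the confusion-matrix marginals. When both maps are constant
#' and identical (`p_e = 1`), kappa is defined as 1.
#'
#' @param a,b Comparable `lulc_landscape` objects.
#' @return List: `kappa`, `p_o`, `p_e`, `confusion` (counts matrix).
#' @export
kappa_index <- function(a, b) {
  ct <- crosstab(a, b)
  n <- ct$n_valid
  if (n == 0) stop("no jointly valid cells")
  p_o <- sum(diag(ct$counts)) / n
  p_e <- sum(rowSums(ct$counts) * colSums(ct$counts)) / n^2
  k <- if (abs(1 - p_e) < 1e-12) 1 else (p_o - p_e) / (1 - p_e)
  list(kappa = k, p_o = p_o, p_e = p_e, confusion = ct$counts)
}

# Directional fuzzy score: for every valid cell c, 1 if B's class at c
# occurs anywhere in A within the (2r+1)-window centred at c (constant
# fuzziness), else 0. Windows are clipped at map edges.
fuzzy_directional <- function(A, B, r, decay_halving = NULL) {
  valid <- !is.na(A) & !is.na(B)
  score <- matrix(0, nrow(A), ncol(A))
  if (is.null(decay_halving)) {
    for (k in unique(B[valid])) {
      present <- dilate_square(!is.na(A) & A == k, r)
      sel <- valid & B == k
      score[sel] <- as.numeric(present[sel])
    }
  } else {
    # exponential-decay membership 2^(-d / halving), maximised over the
    # window; the plain-agreement core keeps score 1 at d = 0
    for (dr in -r:r) {
      for (dc in -r:r) {
        w <- 2^(-sqrt(dr^2 + dc^2) / decay_halving)
        hit <- shift_mat(A, dr, dc) == B
        hit[is.na(hit)] <- FALSE
        score <- pmax(score, w * hit)
      }
    }
  }
  mean(score[valid])
}

#' Multi-window fuzzy similarity between observed and simulated maps
#'
#' For each odd window size w (1, 3, ..., `max_window`), a cell agrees if
#' the class one map shows there occurs within the w x w neighbourhood of
#' the other map (constant fuzziness within the window). The reported
#' similarity is the minimum of the two directional means (two-way
#' comparison); one-way and exponential-decay variants are selectable.
#' Window 1 equals the plain cell-by-cell agreement, and similarity is
#' non-decreasing in window size under the constant kernel.
#'
#' @param observed,simulated Comparable `lulc_landscape` objects.
#' @param max_window Largest (odd) window size, default 7.
#' @param method `"constant"` (crisp within-window membership) or
#'   `"exponential"` (membership decays as `2^(-d/halving)`).
#' @param direction `"two_way_min"` (default) or `"one_way"`
#'   (observed -> simulated only).
#' @param decay_halving Halving distance (cells) for the exponential
#'   kernel.
#' @return A `fuzzy_result` data frame: `window`, `similarity`, with the
#'   cell size as an attribute.
#' @export
fuzzy_similarity <- function(observed, simulated, max_window = 7,
                             method = c("constant", "exponential"),
                             direction = c("two_way_min", "one_way"),
                             decay_halving = 2) {
  check_grid(observed, simulated)
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (max_window %% 2 == 0) stop("max_window must be odd")
  windows <- seq(1, max_window, by = 2)
  halving <- if (method == "exponential") decay_halving else NULL
  sims <- vapply(windows, function(w) {
    r <- (w - 1L) / 2L
    ab <- fuzzy_directional(observed$values, simulated$values, r, halving)
    if (direction == "one_way") return(ab)
    ba <- fuzzy_directional(simulated$values, observed$values, r, halving)
    min(ab, ba)
  }, numeric(1))
  structure(data.frame(window = windows, similarity = sims),
            class = c("fuzzy_result", "data.frame"),
            cell_size = observed$cell_size)
}

#' Similarity as a function of ground distance
#'
#' Maps window sizes to ground distances. Two conventions are supported:
#' `"full"` (default) reports the full window width `w * cell_size` -- a
#' 7 x 7 window of 30 m cells is reported at 210 m -- while `"half"`
#' reports the half-width `(w - 1) / 2 * cell_size` (90 m for the same
#' window).
#'
#' @param fr A `fuzzy_result`.
#' @param convention `"full"` or `"half"`.
#' @return Data frame `window`, `distance_m`, `similarity`.
#' @export
similarity_curve <- function(fr, convention = c("full", "half")) {
  convention <- match.arg(convention)
  cs <- attr(fr, "cell_size")
  d <- if (convention == "full") fr$window * cs
       else (fr$window - 1) / 2 * cs
  data.frame(window = fr$window, distance_m = d,
             similarity = fr$similarity)
}
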