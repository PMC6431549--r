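#' Worked-example data: a Sierra Tarahumara temperate-forest landscape
#'
#' Published land-cover accounting for a ~497,000 ha temperate-forest
#' region in western Chihuahua, Mexico, classified from 30 m satellite
#' imagery into five classes (PF primary forest, SF secondary forest, HS
#' human settlements, AWV areas without vegetation, WB water bodies) at
#' three epochs (1990, 2005, 2017). Shipped as plain CSV under
#' `inst/extdata` and used throughout the package's worked examples:
#'
#' * `tarahumara_areas()`: hectares per class per epoch.
#' * `tarahumara_transition(period)`: the class transition-probability
#'   matrix printed for the period, rows renormalized to sum exactly to 1
#'   (printed rows carry 4-decimal rounding).
#' * `tarahumara_projected_shares()`: percentage shares at 2017 and the
#'   2050 projections under the stationary (`2050s`), optimistic
#'   (`2050o`) and pessimistic (`2050p`) scenarios.
#' * `tarahumara_whitelist()`: the four modeled transitions
#'   (PF->SF, PF->AWV, PF->HS, SF->AWV).
#'
#' @param period One of `"1990-2005"`, `"2005-2017"`, `"1990-2017"`.
#' @return A data frame, or a `lulc_tmatrix` for
#'   `tarahumara_transition()`.
#' @name tarahumara
NULL

extdata <- function(file) {
  system.file("extdata", file, package = "lulcsim", mustWork = TRUE)
}

#' @rdname tarahumara
#' @export
tarahumara_areas <- function() {
  utils::read.csv(extdata("tarahumara_areas.csv"))
}

#' @rdname tarahumara
#' @export
tarahumara_transition <- function(period = c("1990-2017", "1990-2005",
                                             "2005-2017")) {
  period <- match.arg(period)
  all <- utils::read.csv(extdata("tarahumara_transitions.csv"),
                         check.names = FALSE)
  d <- all[all$period == period, ]
  P <- as.matrix(d[, c("AWV", "SF", "HS", "WB", "PF")])
  rownames(P) <- d$from
  years <- diff(as.numeric(strsplit(period, "-")[[1]]))
  transition_matrix(P, years, tol = 5e-4, normalize = TRUE)
}

#' @rdname tarahumara
#' @export
tarahumara_projected_shares <- function() {
  utils::read.csv(extdata("tarahumara_projected_shares.csv"))
}

#' @rdname tarahumara
#' @export
tarahumara_whitelist <- function() {
  transition_whitelist(from = c("PF", "PF", "PF", "SF"),
                       to = c("SF", "AWV", "HS", "AWV"))
}
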