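#' Cross-tabulate two landscapes
#'
#' Counts cells per (from, to) class pair between two epochs; cells masked in
#' either map are excluded. Row marginals reproduce the per-class cell counts
#' of `a`, column marginals those of `b`.
#'
#' @param a,b Comparable `lulc_landscape` objects (epoch t0 and t1).
#' @return `lulc_crosstab`: list with `counts` (labelled from x to integer
#'   matrix) and `n_valid`.
#' @export
crosstab <- function(a, b) {
  check_grid(a, b)
  valid <- !is.na(a$values) & !is.na(b$values)
  labs <- union(unname(a$class_labels), unname(b$class_labels))
  fa <- factor(label_of(a, a$values[valid]), levels = labs)
  fb <- factor(label_of(b, b$values[valid]), levels = labs)
  counts <- unclass(table(from = fa, to = fb))
  structure(list(counts = counts, n_valid = sum(valid)),
            class = "lulc_crosstab")
}

#' @export
print.lulc_crosstab <- function(x, ...) {
  cat(sprintf("<lulc_crosstab> %d valid cells\n", x$n_valid))
  print(x$counts)
  invisible(x)
}

#' Per-class area and share accounting across epochs
#'
#' @param maps List of comparable `lulc_landscape` objects, one per epoch.
#' @param epochs Character or numeric epoch labels (same length as `maps`).
#' @return Data frame with columns `class`, `epoch`, `cells`, `area_ha`,
#'   `share_pct`; shares sum to 100 per epoch.
#' @export
area_table <- function(maps, epochs) {
  if (length(maps) == 0L) stop("need at least one map")
  stopifnot(length(maps) == length(epochs))
  for (m in maps[-1]) check_comparable(maps[[1]], m)
  ha <- cell_area_ha(maps[[1]])
  labs <- Reduce(union, lapply(maps, function(m) unname(m$class_labels)))
  out <- do.call(rbind, Map(function(m, ep) {
    v <- m$values[!is.na(m$values)]
    cnt <- table(factor(label_of(m, v), levels = labs))
    data.frame(class = labs, epoch = as.character(ep),
               cells = as.integer(cnt),
               area_ha = as.numeric(cnt) * ha,
               share_pct = 100 * as.numeric(cnt) / length(v))
  }, maps, epochs))
  rownames(out) <- NULL
  out
}

#' Build an area table from known per-class areas
#'
#' Entry point for published accounting tables: given hectares per class per
#' epoch, computes the percentage shares on each epoch's summed footprint.
#'
#' @param areas Data frame with columns `class`, `epoch`, `area_ha`.
#' @return Data frame in [area_table()] layout (without `cells`).
#' @export
area_table_from_areas <- function(areas) {
  stopifnot(all(c("class", "epoch", "area_ha") %in% names(areas)))
  out <- do.call(rbind, lapply(split(areas, areas$epoch), function(d) {
    d$share_pct <- 100 * d$area_ha / sum(d$area_ha)
    d
  }))
  rownames(out) <- NULL
  out[order(out$epoch), c("class", "epoch", "area_ha", "share_pct")]
}

#' Net area change per class between two epochs
#'
#' @param at Area table (from [area_table()] or [area_table_from_areas()]).
#' @param epoch_a,epoch_b Epoch labels; change is `epoch_b - epoch_a`.
#' @return Data frame `class`, `change_ha`. On a closed landscape the
#'   changes sum to 0.
#' @export
net_change <- function(at, epoch_a, epoch_b) {
  epoch_a <- as.character(epoch_a)
  epoch_b <- as.character(epoch_b)
  have <- unique(at$epoch)
  missing <- setdiff(c(epoch_a, epoch_b), have)
  if (length(missing)) {
    stop("unknown epoch label(s): ", paste(missing, collapse = ", "))
  }
  a <- at[at$epoch == epoch_a, ]
  b <- at[at$epoch == epoch_b, ]
  i <- match(a$class, b$class)
  data.frame(class = a$class, change_ha = b$area_ha[i] - a$area_ha)
}

#' Default change-category rules
#'
#' Deforestation: primary forest to cleared or settled land (`PF -> AWV`,
#' `PF -> HS`); degradation: canopy thinning (`PF -> SF`); recovery:
#' `SF -> PF`. Unlisted changes fall to "Other"; unchanged cells are
#' "Stable".
#' @return Data frame `from`, `to`, `category`.
#' @export
default_change_rules <- function() {
  data.frame(
    from = c("PF", "PF", "PF", "SF"),
    to = c("AWV", "HS", "SF", "PF"),
    category = c("Deforestation", "Deforestation", "Degradation", "Recovery")
  )
}

change_categories <- c("Stable", "Deforestation", "Degradation",
                       "Recovery", "Other")

#' Categorize cell-level change between two epochs
#'
#' @param a,b Comparable landscapes (earlier, later epoch).
#' @param rules Data frame `from`, `to`, `category` assigning observed
#'   transitions to categories; defaults to [default_change_rules()].
#' @return List: `map` (a `lulc_landscape` coded over Stable /
#'   Deforestation / Degradation / Recovery / Other) and `totals`
#'   (`category`, `cells`, `area_ha`).
#' @export
change_type_map <- function(a, b, rules = default_change_rules()) {
  check_grid(a, b)
  cat_code <- stats::setNames(seq_along(change_categories) - 1L,
                              change_categories)
  la <- matrix(label_of(a, a$values), nrow(a$values))
  lb <- matrix(label_of(b, b$values), nrow(b$values))
  out <- matrix(NA_integer_, nrow(la), ncol(la))
  valid <- !is.na(la) & !is.na(lb)
  out[valid] <- cat_code["Other"]
  out[valid & la == lb] <- cat_code["Stable"]
  for (k in seq_len(nrow(rules))) {
    sel <- valid & la == rules$from[k] & lb == rules$to[k]
    out[sel] <- cat_code[rules$category[k]]
  }
  map <- landscape(out, a$cell_size,
                   stats::setNames(change_categories,
                                   as.character(unname(cat_code))))
  cnt <- table(factor(change_categories[out[valid] + 1L],
                      levels = change_categories))
  totals <- data.frame(category = change_categories,
                       cells = as.integer(cnt),
                       area_ha = as.numeric(cnt) * cell_area_ha(a))
  list(map = map, totals = totals)
}

#' Annualized percent rate of area change
#'
#' Convenience helper `r = ((A2/A1)^(1/dt) - 1) * 100`. This compound-rate
#' formula is the package's own choice of change-rate summary; published
#' accounting tables in this field print rate columns without a stated
#' formula, and this helper makes no attempt to match any of them.
#'
#' @param area_a,area_b Areas (ha) at the start and end of the period.
#' @param years Period length in years.
#' @return Signed percent rate per year.
#' @export
annual_change_rate <- function(area_a, area_b, years) {
  stopifnot(years > 0)
  ((area_b / area_a)^(1 / years) - 1) * 100
}
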