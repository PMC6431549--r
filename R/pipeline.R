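#' Run configuration for the orchestrated pipeline
#'
#' A run configuration is a plain list (or a YAML file parsed into one)
#' with fields:
#' * `maps`: character vector of landscape paths, or a list of
#'   `lulc_landscape` objects;
#' * `epochs`: strictly increasing numeric epoch labels, one per map;
#' * `areas_csv`: alternatively, a CSV of published per-class areas
#'   (`class`, `epoch`, `area_ha`) bypassing the maps;
#' * `drivers`: named list of `lulc_driver` objects (or paths);
#' * `whitelist`: data frame `from`, `to`;
#' * `n_bins`, `seed`, `out_dir`, `cell_size`, `class_labels`.
#'
#' @param config Path to a YAML file or a list.
#' @return The validated configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(config$epochs)) {
    ep <- as.numeric(config$epochs)
    if (any(diff(ep) <= 0)) stop("epochs must be strictly increasing")
  }
  config
}

config_maps <- function(config) {
  maps <- config$maps
  if (is.character(maps)) {
    labels <- config$class_labels
    if (!is.null(labels)) labels <- unlist(labels)
    maps <- lapply(maps, read_landscape,
                   cell_size = config$cell_size %||% 30,
                   class_labels = labels)
  }
  harmonize_mask(maps)
}

write_manifest <- function(out_dir, config, extra = list()) {
  manifest <- utils::modifyList(list(
    package = "lulcsim",
    version = as.character(utils::packageVersion("lulcsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config_fields = names(config),
    seed = config$seed
  ), extra)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
}

#' Change analysis: areas, shares, net change, change types
#'
#' Computes the per-epoch area/share table, pairwise net changes and (for
#' map input) the categorized change map totals, writing
#' `area_table.csv`, `net_change.csv` and `change_types.csv` to the output
#' directory.
#'
#' @param config See [load_config()]; needs at least two epochs (maps or
#'   `areas_csv`).
#' @param out_dir Output directory (default `config$out_dir`).
#' @return Invisibly, a list with the computed tables.
#' @export
cmd_change_analysis <- function(config, out_dir = NULL) {
  config <- load_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  epochs <- config$epochs
  if (!is.null(config$areas_csv)) {
    areas <- utils::read.csv(config$areas_csv)
    at <- area_table_from_areas(areas)
    epochs <- sort(unique(at$epoch))
    types <- NULL
  } else {
    maps <- config_maps(config)
    if (length(maps) < 2L) stop("change analysis needs at least two epochs")
    at <- area_table(maps, epochs)
    types <- change_type_map(maps[[1L]], maps[[length(maps)]])$totals
    utils::write.csv(types, file.path(out_dir, "change_types.csv"),
                     row.names = FALSE)
  }
  if (length(epochs) < 2L) stop("change analysis needs at least two epochs")
  nc <- do.call(rbind, lapply(seq_len(length(epochs) - 1L), function(i) {
    d <- net_change(at, epochs[i], epochs[i + 1L])
    d$period <- paste0(epochs[i], "-", epochs[i + 1L])
    d
  }))
  overall <- net_change(at, epochs[1L], epochs[length(epochs)])
  overall$period <- paste0(epochs[1L], "-", epochs[length(epochs)])
  nc <- rbind(nc, overall)
  utils::write.csv(at, file.path(out_dir, "area_table.csv"),
                   row.names = FALSE)
  utils::write.csv(nc, file.path(out_dir, "net_change.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, config)
  invisible(list(area_table = at, net_change = nc, change_types = types))
}

#' Calibrate, simulate and report a scenario projection
#'
#' Estimates the transition matrix from the first and last map, annualizes
#' it (strict stochastic cleanup), calibrates the WoE model on the observed
#' changes, runs the scenario projection and writes the projected area
#' table, the hectare change report, the change ledger and a run manifest.
#'
#' @param config See [load_config()]; needs `maps`, `epochs`, `seed` and
#'   optionally `drivers`, `whitelist`, patch parameters.
#' @param scenario A `lulc_scenario`.
#' @param out_dir Output directory.
#' @return Invisibly, the [project_scenario()] result.
#' @export
cmd_simulate <- function(config, scenario, out_dir = NULL) {
  config <- load_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$seed) && is.null(scenario$seed)) {
    stop("a seed is required for simulation")
  }
  maps <- config_maps(config)
  epochs <- as.numeric(config$epochs)
  first <- maps[[1L]]
  last <- maps[[length(maps)]]
  period <- epochs[length(epochs)] - epochs[1L]
  m <- estimate_matrix(crosstab(first, last), period)
  annual <- annualize(m, force_stochastic = TRUE)
  wl <- NULL
  if (!is.null(config$whitelist)) {
    wl <- transition_whitelist(config$whitelist$from, config$whitelist$to)
  }
  drivers <- config$drivers %||% list()
  woe <- list()
  if (length(drivers) && !is.null(wl)) {
    woe <- calibrate_woe(first, last, drivers, wl,
                         n_bins = config$n_bins %||% 20)
  }
  pp <- patch_params(
    mean_patch_size = config$mean_patch_size %||% 1,
    patch_size_variance = config$patch_size_variance %||% 0.5,
    isometry = config$isometry %||% 1.5,
    expander_fraction = config$expander_fraction %||% 0.5
  )
  res <- project_scenario(last, annual, scenario, woe, pp, drivers, wl,
                          start_year = epochs[length(epochs)],
                          seed = scenario$seed %||% config$seed)
  total_ha <- sum(res$areas$area_ha[res$areas$epoch ==
                                      as.character(epochs[length(epochs)])])
  rep <- scenario_report(res$areas, total_ha)
  utils::write.csv(res$areas, file.path(out_dir, "projected_areas.csv"),
                   row.names = FALSE)
  utils::write.csv(rep, file.path(out_dir, "scenario_change.csv"),
                   row.names = FALSE)
  ha <- cell_area_ha(last)
  ledger <- res$ledger
  if (nrow(ledger)) ledger$ha <- ledger$cells * ha
  utils::write.csv(ledger, file.path(out_dir, "ledger.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, config, list(
    scenario = scenario$name,
    rate_multipliers = if (is.data.frame(scenario$rate_multipliers))
      "per-transition" else scenario$rate_multipliers,
    patch_multipliers = as.list(scenario$patch_multipliers),
    frozen_classes = scenario$frozen_classes,
    mean_patch_size = pp$mean_patch_size,
    expander_fraction = pp$expander_fraction,
    seed = scenario$seed %||% config$seed
  ))
  invisible(res)
}

#' Validate a simulated map against a reference
#'
#' Writes the kappa index and the fuzzy-similarity curve
#' (`window`, `distance_m`, `similarity`) as `validation.csv`.
#'
#' @param observed,simulated Comparable `lulc_landscape`s.
#' @param out_dir Output directory.
#' @param max_window Largest odd window (default 7).
#' @param convention Distance convention for [similarity_curve()].
#' @return Invisibly, a list with `kappa` and the curve.
#' @export
cmd_validate <- function(observed, simulated, out_dir, max_window = 7,
                         convention = "full") {
  if (max_window %% 2 == 0) stop("max_window must be odd")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k <- kappa_index(observed, simulated)
  fr <- fuzzy_similarity(observed, simulated, max_window)
  curve <- similarity_curve(fr, convention)
  curve$kappa <- k$kappa
  utils::write.csv(curve, file.path(out_dir, "validation.csv"),
                   row.names = FALSE)
  invisible(list(kappa = k, curve = curve))
}
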