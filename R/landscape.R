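#' Categorical raster landscape
#'
#' The central container of the package: an integer-coded land use / land
#' cover (LULC) map on a regular square-celled grid. Values are held as an
#' integer matrix in (row, col) convention with `NA` marking nodata cells.
#' Class codes map to short class labels (e.g. `PF` primary forest, `SF`
#' secondary forest, `HS` human settlements, `AWV` areas without vegetation,
#' `WB` water bodies).
#'
#' @param values Integer matrix of class codes; `NA` = nodata.
#' @param cell_size Cell edge length in meters (square cells, default 30 as
#'   for Landsat-derived maps).
#' @param class_labels Named character vector mapping code (name, as
#'   character) to label, e.g. `c("1" = "PF", "2" = "SF")`. Defaults to the
#'   codes themselves.
#' @return An object of class `lulc_landscape` with fields `values`,
#'   `cell_size`, `class_labels`.
#' @examples
#' m <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
#' landscape(m, cell_size = 30, class_labels = c("1" = "PF", "2" = "SF"))
#' @export
landscape <- function(values, cell_size = 30, class_labels = NULL) {
  if (is.double(values)) {
    if (any(values != round(values), na.rm = TRUE)) {
      stop("landscape values must be integer class codes")
    }
    storage.mode(values) <- "integer"
  }
  stopifnot(is.matrix(values), is.integer(values))
  if (length(cell_size) != 1L || !is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be a positive scalar (meters)")
  }
  codes <- sort(unique(values[!is.na(values)]))
  if (is.null(class_labels)) {
    class_labels <- stats::setNames(as.character(codes), as.character(codes))
  }
  if (is.null(names(class_labels))) {
    stop("class_labels must be named by integer code")
  }
  missing <- setdiff(as.character(codes), names(class_labels))
  if (length(missing)) {
    stop("codes without a class label: ", paste(missing, collapse = ", "))
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         class_labels = class_labels),
    class = "lulc_landscape"
  )
}

#' @export
print.lulc_landscape <- function(x, ...) {
  cat(sprintf("<lulc_landscape> %d x %d cells @ %g m\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  tab <- table(factor(label_of(x, x$values[!is.na(x$values)]),
                      levels = unname(x$class_labels)))
  print(tab)
  invisible(x)
}

# Label lookup for a vector of codes.
label_of <- function(x, codes) {
  unname(x$class_labels[as.character(codes)])
}

# Code lookup for a vector of labels.
code_of <- function(x, labels) {
  codes <- as.integer(names(x$class_labels))
  out <- codes[match(labels, x$class_labels)]
  if (anyNA(out)) {
    stop("unknown class label(s): ",
         paste(labels[is.na(out)], collapse = ", "))
  }
  out
}

#' Nodata mask of a landscape
#' @param x A `lulc_landscape`.
#' @return Logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(x) {
  stopifnot(inherits(x, "lulc_landscape"))
  is.na(x$values)
}

#' Are two landscapes comparable?
#'
#' Comparable means: same grid shape, same cell size, same nodata mask. All
#' change accounting and map-agreement operations require comparability.
#' @param a,b `lulc_landscape` objects.
#' @return `TRUE` or `FALSE`.
#' @export
is_comparable <- function(a, b) {
  inherits(a, "lulc_landscape") && inherits(b, "lulc_landscape") &&
    all(dim(a$values) == dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    identical(is.na(a$values), is.na(b$values))
}

# Grid compatibility only (shape + cell size); operations that exclude
# cells masked in either map use this weaker check.
check_grid <- function(a, b, what = "landscapes") {
  if (!inherits(a, "lulc_landscape") || !inherits(b, "lulc_landscape") ||
      !all(dim(a$values) == dim(b$values)) ||
      !isTRUE(all.equal(a$cell_size, b$cell_size))) {
    stop(sprintf("%s are not on the same grid (shape %s vs %s)", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  }
  invisible(TRUE)
}

check_comparable <- function(a, b, what = "landscapes") {
  if (!is_comparable(a, b)) {
    stop(sprintf("%s are not comparable (shape %s vs %s, cell %g vs %g m%s)",
                 what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x"),
                 a$cell_size, b$cell_size,
                 if (all(dim(a$values) == dim(b$values)) &&
                     !identical(is.na(a$values), is.na(b$values)))
                   ", differing nodata masks" else ""))
  }
  invisible(TRUE)
}

#' Apply the union nodata mask across several landscapes
#'
#' Change accounting is only internally consistent on a fixed footprint, so
#' multi-epoch analyses first mask every map to the union of the individual
#' nodata masks.
#' @param maps List of `lulc_landscape` objects on the same grid.
#' @return List of landscapes sharing the union mask.
#' @export
harmonize_mask <- function(maps) {
  stopifnot(length(maps) >= 1L)
  dims <- vapply(maps, function(m) dim(m$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("maps have differing grid shapes")
  }
  mask <- Reduce(`|`, lapply(maps, nodata_mask))
  lapply(maps, function(m) {
    v <- m$values
    v[mask] <- NA_integer_
    landscape(v, m$cell_size, m$class_labels)
  })
}

#' Hectares covered by one grid cell
#' @param x A `lulc_landscape`.
#' @return Scalar hectares (`cell_size^2 / 10000`).
#' @export
cell_area_ha <- function(x) {
  x$cell_size^2 / 1e4
}

# ---- raster I/O ------------------------------------------------------------

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "asc" = "ascii_grid", "txt" = "ascii_grid",
         "tif" = "geotiff", "tiff" = "geotiff",
         stop("cannot guess raster format from extension '", ext, "'"))
}

#' Read a categorical landscape from disk
#'
#' Supports single-band integer GeoTIFF (via the tiff package; georeference
#' tags are not interpreted, a warning is issued and the pixel grid is used
#' as-is) and ESRI ASCII grids. Class codes are preserved bit-exactly and
#' nodata cells are masked.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"ascii_grid"` or `"geotiff"`.
#' @param cell_size Cell size in meters; for ASCII grids the header value
#'   takes precedence.
#' @param class_labels Optional code-to-label map (see [landscape()]).
#' @param nodata_value Code treated as nodata for GeoTIFF input (ASCII grids
#'   carry their own `NODATA_value` header).
#' @return A `lulc_landscape`.
#' @export
read_landscape <- function(path, format = c("auto", "ascii_grid", "geotiff"),
                           cell_size = 30, class_labels = NULL,
                           nodata_value = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "ascii_grid") {
    read_ascii_grid(path, cell_size, class_labels)
  } else {
    warning("GeoTIFF georeference is not interpreted; ",
            "grid read as-is with cell_size = ", cell_size, " m")
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L) {
      stop("expected a single-band raster, got ", length(dim(img)), " dims")
    }
    if (is.double(img) && any(img != round(img), na.rm = TRUE)) {
      stop("non-integer band: landscape rasters must hold integer codes")
    }
    v <- matrix(as.integer(img), nrow(img), ncol(img))
    if (!is.null(nodata_value)) v[v == nodata_value] <- NA_integer_
    landscape(v, cell_size, class_labels)
  }
}

read_ascii_grid <- function(path, cell_size = 30, class_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  header <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+\\S+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- parts[2]
    i <- i + 1L
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(header))) {
    stop("not an ESRI ASCII grid: missing ncols/nrows header")
  }
  nc <- as.integer(header$ncols)
  nr <- as.integer(header$nrows)
  if (!is.null(header$cellsize)) cell_size <- as.numeric(header$cellsize)
  nodata <- header$nodata_value %||% "-9999"
  toks <- unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) != nr * nc) {
    stop(sprintf("expected %d cells, found %d", nr * nc, length(toks)))
  }
  is_nodata <- toks == nodata
  ok <- grepl("^-?[0-9]+$", toks[!is_nodata])
  if (!all(ok)) {
    stop("non-integer cell value(s) in ASCII grid, e.g. '",
         toks[!is_nodata][!ok][1], "': landscape rasters must hold integer codes")
  }
  vals <- rep(NA_integer_, length(toks))
  vals[!is_nodata] <- as.integer(toks[!is_nodata])
  v <- matrix(vals, nr, nc, byrow = TRUE)
  landscape(v, cell_size, class_labels)
}

#' Write a categorical landscape to disk
#'
#' The ESRI ASCII writer round-trips codes and mask exactly; the GeoTIFF
#' writer stores a 16-bit single band (codes must lie in 0..65534, nodata is
#' written as 65535).
#'
#' @param x A `lulc_landscape`.
#' @param path Output path.
#' @param format `"auto"`, `"ascii_grid"` or `"geotiff"`.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(x, path,
                            format = c("auto", "ascii_grid", "geotiff")) {
  stopifnot(inherits(x, "lulc_landscape"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "ascii_grid") {
    v <- x$values
    header <- c(
      sprintf("ncols %d", ncol(v)),
      sprintf("nrows %d", nrow(v)),
      "xllcorner 0", "yllcorner 0",
      sprintf("cellsize %g", x$cell_size),
      "NODATA_value -9999"
    )
    body <- apply(v, 1L, function(row) {
      row[is.na(row)] <- -9999L
      paste(row, collapse = " ")
    })
    writeLines(c(header, body), path)
  } else {
    v <- x$values
    if (any(v < 0L | v > 65534L, na.rm = TRUE)) {
      stop("GeoTIFF writer supports codes in 0..65534 only")
    }
    v[is.na(v)] <- 65535L
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}
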