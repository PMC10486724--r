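#' AFM height map
#'
#' A `heightmap` is the universal input of the pipeline: a rectangular grid of
#' surface heights in nanometres with a known, isotropic lateral pixel size.
#' Pixel indices are interpreted as pixel *centers*; the physical position of
#' pixel `(i, j)` (row, column, 1-based) is
#' `origin + (j - 1, i - 1) * pixel_size_nm`.
#'
#' @param heights Numeric matrix of heights (nm), rows x cols, all finite.
#' @param pixel_size_nm Lateral sampling step in nm/pixel, equal in x and y.
#' @param origin Physical x/y coordinates (nm) of the center of pixel (1, 1).
#' @param metadata Free-form named list carried through I/O.
#'
#' @return An object of class `heightmap`.
#' @export
#' @examples
#' hm <- heightmap(matrix(rnorm(64), 8, 8), pixel_size_nm = 10)
#' dim(hm)
heightmap <- function(heights, pixel_size_nm, origin = c(0, 0), metadata = list()) {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    afm_abort("`heights` must be a numeric matrix.", "afmtopo_invalid_parameter")
  }
  if (nrow(heights) < 2 || ncol(heights) < 2) {
    afm_abort("A heightmap needs at least 2 rows and 2 columns.",
              "afmtopo_invalid_parameter")
  }
  if (!all(is.finite(heights))) {
    afm_abort("All heights must be finite.", "afmtopo_invalid_parameter")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    afm_abort("`pixel_size_nm` must be a single positive number.",
              "afmtopo_invalid_parameter")
  }
  stopifnot(length(origin) == 2, is.list(metadata))
  structure(
    list(heights = unname(heights), pixel_size_nm = as.numeric(pixel_size_nm),
         origin = as.numeric(origin), metadata = metadata),
    class = "heightmap"
  )
}

#' @export
dim.heightmap <- function(x) dim(x$heights)

#' @export
print.heightmap <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<heightmap> %d x %d px, %.4g nm/px (%.3g x %.3g um), heights %.3g..%.3g nm\n",
    d[1], d[2], x$pixel_size_nm,
    d[2] * x$pixel_size_nm / 1000, d[1] * x$pixel_size_nm / 1000,
    min(x$heights), max(x$heights)))
  invisible(x)
}

#' Physical field size of a height map
#'
#' @param map A [heightmap()].
#' @return Named numeric vector `c(x_nm, y_nm)`: pixel count times pixel size.
#' @export
field_size <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  c(x_nm = ncol(map$heights) * map$pixel_size_nm,
    y_nm = nrow(map$heights) * map$pixel_size_nm)
}

#' Height map as a tidy tibble
#'
#' Long format with one row per pixel; convenient for ggplot2.
#'
#' @param x A [heightmap()].
#' @param ... Unused.
#' @return A tibble with columns `x_nm`, `y_nm`, `height_nm`.
#' @method as_tibble heightmap
#' @export
as_tibble.heightmap <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    x_nm = rep(x$origin[1] + (seq_len(d[2]) - 1) * x$pixel_size_nm, each = d[1]),
    y_nm = rep(x$origin[2] + (seq_len(d[1]) - 1) * x$pixel_size_nm, times = d[2]),
    height_nm = as.vector(x$heights)
  )
}

# ---- native text format: <name>.hm.txt matrix + <name>.hm.json sidecar ----

sidecar_path <- function(path) sub("\\.hm\\.txt$", ".hm.json", path)

#' Write a height map to the native text format
#'
#' The native format is a whitespace-separated numeric matrix (`<name>.hm.txt`,
#' one map row per line) plus a JSON sidecar (`<name>.hm.json`) holding the
#' pixel size, units, origin and metadata. Text is used deliberately: it
#' round-trips bit-exactly under version control and needs no vendor software.
#'
#' @param map A [heightmap()].
#' @param path Output path; `.hm.txt` is appended if absent.
#' @return The path of the matrix file, invisibly.
#' @export
write_heightmap <- function(map, path) {
  stopifnot(inherits(map, "heightmap"))
  if (!grepl("\\.hm\\.txt$", path)) path <- paste0(path, ".hm.txt")
  lines <- apply(map$heights, 1, function(r)
    paste(formatC(r, format = "g", digits = 9), collapse = " "))
  tryCatch(writeLines(lines, path),
           error = function(e) afm_abort(
             paste0("Cannot write '", path, "': ", conditionMessage(e)),
             "afmtopo_io_error"))
  side <- list(
    format = "afmtopo-heightmap", version = 1L, units = "nm",
    pixel_size_nm = map$pixel_size_nm, origin_nm = map$origin,
    rows = nrow(map$heights), cols = ncol(map$heights),
    metadata = map$metadata
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a height map
#'
#' Two dialects are supported: the package's native matrix + JSON sidecar
#' format (see [write_heightmap()]), and a generic AFM ASCII grid export with
#' `#`-comment header lines declaring `width`/`height` (pixels), the physical
#' x size and the units. Heights and pixel sizes are normalised to nm on
#' import (declared units may be nm, um or m).
#'
#' @param path Path to the `.hm.txt` (native) or ASCII grid file.
#' @param dialect `"native"` or `"asciigrid"`; default guesses from the
#'   presence of a sidecar file.
#' @return A [heightmap()].
#' @export
read_heightmap <- function(path, dialect = c("auto", "native", "asciigrid")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    afm_abort(paste0("File not found: ", path), "afmtopo_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (file.exists(sidecar_path(path))) "native" else "asciigrid"
  }
  if (dialect == "native") read_heightmap_native(path) else read_heightmap_ascii(path)
}

parse_matrix_lines <- function(lines, offset = 0L) {
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      afm_abort(sprintf("Non-numeric cell in data line %d.", i + offset),
                "afmtopo_format_error")
    }
    vals
  })
  n <- lengths(rows)
  if (length(unique(n)) != 1) {
    bad <- which(n != n[1])[1]
    afm_abort(sprintf("Ragged row at data line %d: %d values, expected %d.",
                      bad + offset, n[bad], n[1]),
              "afmtopo_format_error")
  }
  do.call(rbind, rows)
}

read_heightmap_native <- function(path) {
  side_file <- sidecar_path(path)
  if (!file.exists(side_file)) {
    afm_abort(paste0("Missing sidecar file: ", side_file), "afmtopo_format_error")
  }
  side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
  if (is.null(side$pixel_size_nm)) {
    afm_abort("Sidecar lacks `pixel_size_nm`.", "afmtopo_format_error")
  }
  h <- parse_matrix_lines(readLines(path))
  heightmap(h, side$pixel_size_nm,
            origin = side$origin_nm %||% c(0, 0),
            metadata = as.list(side$metadata %||% list()))
}

unit_to_nm <- function(u) {
  switch(tolower(u),
         "nm" = 1, "um" = 1e3, "µm" = 1e3, "micron" = 1e3,
         "mm" = 1e6, "m" = 1e9,
         afm_abort(paste0("Unknown unit: ", u), "afmtopo_format_error"))
}

read_heightmap_ascii <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^\\s*#", lines)
  hdr <- lines[is_hdr]
  kv <- list()
  for (l in hdr) {
    m <- regmatches(l, regexec("^\\s*#\\s*([A-Za-z_.-]+)\\s*[:=]\\s*(.+)$", l))[[1]]
    if (length(m) == 3) kv[[tolower(m[2])]] <- trimws(m[3])
  }
  data_lines <- lines[!is_hdr & nzchar(trimws(lines))]
  h <- parse_matrix_lines(data_lines, offset = sum(is_hdr))
  units <- kv[["units"]] %||% kv[["unit"]] %||% "nm"
  scale <- unit_to_nm(units)
  xsize <- kv[["x-size"]] %||% kv[["xsize"]] %||% kv[["width_physical"]] %||% NULL
  psize <- kv[["pixel_size"]] %||% kv[["pixel-size"]] %||% NULL
  if (!is.null(psize)) {
    pixel_nm <- as.numeric(psize) * scale
  } else if (!is.null(xsize)) {
    pixel_nm <- as.numeric(xsize) * scale / ncol(h)
  } else {
    afm_abort("ASCII grid header lacks a pixel or physical size.",
              "afmtopo_format_error")
  }
  if (!is.finite(pixel_nm) || pixel_nm <= 0) {
    afm_abort("Invalid pixel size in ASCII grid header.", "afmtopo_format_error")
  }
  heightmap(h * scale, pixel_nm, metadata = kv[setdiff(names(kv),
            c("units", "unit", "x-size", "xsize", "pixel_size", "pixel-size"))])
}

# ---- geometry ----

#' Crop a rectangular physical region out of a height map
#'
#' Pixel counts are `floor(extent_nm / pixel_size_nm)` with a minimum of 2, so
#' the crop never exceeds the requested physical size. Used e.g. to cut the
#' 6 x 5 um fragment-counting sections or 5 x 5 um membrane patches out of a
#' whole-cell scan.
#'
#' @param map A [heightmap()].
#' @param center_nm Physical x/y center of the requested rectangle (nm).
#' @param width_nm,height_nm Requested physical extents (nm) in x and y.
#' @return A [heightmap()] covering the sub-grid, with its origin updated.
#' @export
crop_region <- function(map, center_nm, width_nm, height_nm = width_nm) {
  stopifnot(inherits(map, "heightmap"), length(center_nm) == 2)
  px <- map$pixel_size_nm
  if (width_nm < 2 * px || height_nm < 2 * px) {
    afm_abort("Requested crop is smaller than 2 pixels.", "afmtopo_bounds_error")
  }
  nc <- max(2L, floor(width_nm / px))
  nr <- max(2L, floor(height_nm / px))
  j0 <- round((center_nm[1] - width_nm / 2 - map$origin[1]) / px) + 1
  i0 <- round((center_nm[2] - height_nm / 2 - map$origin[2]) / px) + 1
  if (j0 < 1 || i0 < 1 || j0 + nc - 1 > ncol(map$heights) ||
      i0 + nr - 1 > nrow(map$heights)) {
    afm_abort("Requested rectangle lies outside the map.", "afmtopo_bounds_error")
  }
  heightmap(map$heights[i0:(i0 + nr - 1), j0:(j0 + nc - 1), drop = FALSE], px,
            origin = map$origin + c(j0 - 1, i0 - 1) * px,
            metadata = map$metadata)
}

#' Extract an axis-aligned height profile
#'
#' Returns the cross-section along one grid row or column, as plotted beneath
#' each cell image in AFM figures.
#'
#' @param map A [heightmap()].
#' @param row,col 1-based index of the row (y cross-section along x) or column
#'   to extract; give exactly one.
#' @return A tibble with columns `distance_nm` and `height_nm`, carrying the
#'   source pixel size and line descriptor as attributes
#'   (`pixel_size_nm`, `line`).
#' @export
extract_profile <- function(map, row = NULL, col = NULL) {
  stopifnot(inherits(map, "heightmap"))
  if (is.null(row) == is.null(col)) {
    afm_abort("Give exactly one of `row` or `col`.", "afmtopo_bounds_error")
  }
  px <- map$pixel_size_nm
  if (!is.null(row)) {
    if (row < 1 || row > nrow(map$heights)) {
      afm_abort("Row index outside the grid.", "afmtopo_bounds_error")
    }
    h <- map$heights[row, ]
    line <- paste0("row ", row)
  } else {
    if (col < 1 || col > ncol(map$heights)) {
      afm_abort("Column index outside the grid.", "afmtopo_bounds_error")
    }
    h <- map$heights[, col]
    line <- paste0("col ", col)
  }
  out <- tibble::tibble(distance_nm = (seq_along(h) - 1) * px, height_nm = h)
  attr(out, "pixel_size_nm") <- px
  attr(out, "line") <- line
  out
}
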