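#' Cell-table schema
#'
#' Names the columns of a cell-table CSV (one row per cell) and,
#' optionally, the explicit study domain. When `domain` is `NULL` the
#' tight bounding box of the accepted rows is used and this is recorded
#' in the returned pattern's provenance message.
#'
#' @param x_column,y_column Coordinate column names (um).
#' @param categorical_column Categorical mark column name, or `NULL`.
#' @param continuous_columns Character vector of continuous mark column
#'   names (may be empty).
#' @param domain Optional [domain()].
#' @return An object of class `"cell_table_schema"`.
#' @export
cell_table_schema <- function(x_column = "x", y_column = "y",
                              categorical_column = "cell_type",
                              continuous_columns = character(0),
                              domain = NULL) {
  if (!is.null(domain)) stopifnot(inherits(domain, "domain"))
  structure(list(x_column = x_column, y_column = y_column,
                 categorical_column = categorical_column,
                 continuous_columns = continuous_columns,
                 domain = domain),
            class = "cell_table_schema")
}

#' Read a cell table CSV as a point pattern
#'
#' Expects a comma-separated file with a header row. Coordinates must be
#' finite numbers; rows whose coordinates fall outside an explicit
#' schema domain are dropped with a message reporting the count.
#'
#' @param path CSV file path.
#' @param schema A [cell_table_schema()].
#' @return A [point_pattern()].
#' @export
read_cell_table <- function(path, schema = cell_table_schema()) {
  stopifnot(inherits(schema, "cell_table_schema"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c(schema$x_column, schema$y_column, schema$categorical_column,
              schema$continuous_columns)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")))
  }
  x <- df[[schema$x_column]]
  y <- df[[schema$y_column]]
  for (v in list(x, y)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad)) {
      stop(sprintf("non-numeric coordinate at row %d of %s", bad[1L], path))
    }
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (!is.null(schema$domain)) {
    keep <- in_domain(x, y, schema$domain)
    if (any(!keep)) {
      message(sprintf("dropped %d row(s) outside the explicit domain",
                      sum(!keep)))
      df <- df[keep, , drop = FALSE]
      x <- x[keep]; y <- y[keep]
    }
  } else {
    message("domain inferred as the tight bounding box of the points")
  }
  marks <- if (is.null(schema$categorical_column)) NULL else {
    df[[schema$categorical_column]]
  }
  cont <- if (length(schema$continuous_columns)) {
    df[schema$continuous_columns]
  } else NULL
  point_pattern(x, y, marks, schema$domain, continuous = cont)
}

#' Write a point pattern as a cell-table CSV
#'
#' Columns: `x`, `y`, `cell_type`, then any continuous mark columns.
#' Read back with [read_cell_table()] the coordinates and marks
#' round-trip exactly (within 1e-9 um).
#'
#' @param pattern A [point_pattern()].
#' @param path Output CSV path.
#' @export
write_cell_table <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  df <- data.frame(x = pattern$x, y = pattern$y,
                   cell_type = pattern$marks)
  if (!is.null(pattern$continuous)) df <- cbind(df, pattern$continuous)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a single-band intensity raster
#'
#' Accepts a whitespace-delimited plain-text matrix or (when the `tiff`
#' package is available) a single-band TIFF. Returns the matrix oriented
#' so that `raster[i, j]` is row `i` from the BOTTOM of the image (y
#' increases with `i`) and column `j` from the left.
#'
#' @param path Raster file path (`.tif`/`.tiff` or text).
#' @return A numeric matrix.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF rasters requires the 'tiff' package")
    }
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    # TIFF row 1 is the image top; flip so row 1 is the lowest y
    return(img[nrow(img):1, , drop = FALSE])
  }
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Sample an intensity raster on a regular point lattice
#'
#' Segmentation-free analysis mode: instead of cell centroids, places one
#' point at each node of a regular lattice over the raster extent and
#' attaches the local pixel intensity as a continuous mark, so that
#' [wpcf()] and [wpcf_continuous()] can be applied directly to
#' unsegmented images. Nodes are centered within each `spacing` cell
#' (offset `spacing / 2` from the raster origin), so the lattice is
#' symmetric under image flips.
#'
#' @param raster Numeric matrix of intensities; `raster[i, j]` is row `i`
#'   from the bottom (see [read_raster()]).
#' @param pixel_size Side length of one pixel (um).
#' @param spacing Lattice spacing (um), `>= pixel_size`.
#' @param threshold Optional intensity cutoff: if given, each point also
#'   carries the categorical mark `"positive"` (intensity above the
#'   threshold) or `"negative"`.
#' @param column Name for the continuous intensity column.
#' @return A [point_pattern()] whose domain is the raster extent.
#' @export
lattice_sample <- function(raster, pixel_size, spacing,
                           threshold = NULL, column = "intensity") {
  raster <- as.matrix(raster)
  if (spacing < pixel_size) stop("spacing must be at least the pixel size")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  width <- ncol(raster) * pixel_size
  height <- nrow(raster) * pixel_size
  xs <- seq(spacing / 2, width, by = spacing)
  ys <- seq(spacing / 2, height, by = spacing)
  nodes <- expand.grid(x = xs, y = ys)
  # nearest pixel to each node
  col_idx <- pmin(pmax(ceiling(nodes$x / pixel_size), 1L), ncol(raster))
  row_idx <- pmin(pmax(ceiling(nodes$y / pixel_size), 1L), nrow(raster))
  intens <- raster[cbind(row_idx, col_idx)]
  marks <- if (is.null(threshold)) NULL else {
    ifelse(intens > threshold, "positive", "negative")
  }
  cont <- stats::setNames(data.frame(intens), column)
  point_pattern(nodes$x, nodes$y, marks,
                domain(0, width, 0, height), continuous = cont)
}
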