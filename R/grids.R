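#' Aligned multi-layer covariate grid
#'
#' A lightweight planar grid container: named covariate layers as numeric
#' matrices of identical shape (row 1 = northernmost row, as in ESRI ASCII
#' grids), a cell size in km (cell area = `cell_km^2`), the lower-left
#' corner of the grid in the same planar km coordinate system, and optional
#' named logical region masks (country / protected / range scenarios).
#'
#' @param layers Named list of numeric matrices, all the same shape.
#' @param cell_km Cell edge length in km.
#' @param xll,yll Coordinates of the grid's lower-left corner (km).
#' @param masks Named list of logical matrices, same shape as the layers.
#' @return Object of class `covariate_grid`.
#' @examples
#' g <- covariate_grid(list(temp = matrix(25, 4, 5)), cell_km = 10)
#' g$cell_km^2  # cell area, km^2
#' @export
covariate_grid <- function(layers, cell_km, xll = 0, yll = 0,
                           masks = list()) {
  .check(is.list(layers) && length(layers) >= 1 && !is.null(names(layers)) &&
           all(nzchar(names(layers))), "`layers` must be a named list")
  dims <- lapply(layers, dim)
  .check(all(vapply(layers, is.matrix, logical(1))) &&
           all(vapply(dims, identical, logical(1), dims[[1]])),
         "all layers must be matrices of identical shape")
  .check(is.numeric(cell_km) && length(cell_km) == 1L && cell_km > 0,
         "`cell_km` must be a positive scalar")
  if (length(masks) > 0) {
    .check(!is.null(names(masks)) && all(nzchar(names(masks))),
           "`masks` must be named")
    .check(all(vapply(masks, function(m)
      is.logical(m) && identical(dim(m), dims[[1]]), logical(1))),
      "masks must be logical matrices matching the layer shape")
  }
  structure(list(layers = layers, cell_km = cell_km,
                 xll = xll, yll = yll, masks = masks),
            class = "covariate_grid")
}

#' @export
print.covariate_grid <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("Covariate grid: %d x %d cells of %g km (%g km^2 each)\n",
              d[1], d[2], x$cell_km, x$cell_km^2))
  cat(sprintf("  layers: %s\n", paste(names(x$layers), collapse = ", ")))
  if (length(x$masks) > 0)
    cat(sprintf("  masks: %s\n", paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Cell centres of a covariate grid
#'
#' @param grid A [covariate_grid()].
#' @param cells Linear cell indices (column-major, as returned by
#'   [which()] on a layer matrix); default all cells.
#' @return Data frame with `cell`, `x`, `y` (planar km).
#' @export
cell_centers <- function(grid, cells = NULL) {
  .check(inherits(grid, "covariate_grid"), "`grid` must be a covariate_grid")
  d <- dim(grid$layers[[1]])
  if (is.null(cells)) cells <- seq_len(prod(d))
  rc <- arrayInd(cells, d)
  cs <- grid$cell_km
  data.frame(cell = cells,
             x = grid$xll + (rc[, 2] - 0.5) * cs,
             y = grid$yll + (d[1] - rc[, 1] + 0.5) * cs)
}

#' Read / write an ESRI ASCII grid
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by cell
#' values row by row from the northernmost row. `NODATA` cells become `NA`
#' on read and vice versa on write.
#'
#' @param path File path.
#' @return `read_ascii_grid`: a list with `values` (matrix, row 1 = north),
#'   `xll`, `yll`, `cell_size`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    .check(key %in% names(hdr), "ASCII grid header lacks `%s`", key)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  .check(length(vals) == hdr$ncols * hdr$nrows,
         "ASCII grid has %d values, expected %d", length(vals),
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cell_size = hdr$cellsize, nodata = nodata)
}

#' @rdname read_ascii_grid
#' @param values Numeric matrix (row 1 = northernmost row).
#' @param xll,yll Lower-left corner coordinates.
#' @param cell_size Cell edge length (same units as `xll`/`yll`).
#' @param nodata Value written for `NA` cells (default -9999).
#' @param digits Significant digits written (default 10).
#' @export
write_ascii_grid <- function(values, path, xll = 0, yll = 0, cell_size = 1,
                             nodata = -9999, digits = 10) {
  .check(is.matrix(values), "`values` must be a matrix")
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", xll),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", cell_size),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# internal: block mean of a matrix by an integer factor; NA propagates
.block_mean <- function(m, f) {
  .check(nrow(m) %% f == 0 && ncol(m) %% f == 0,
         "grid dimensions (%d x %d) not divisible by factor %d",
         nrow(m), ncol(m), f)
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  # average rows within blocks, then columns
  rows <- rep(seq_len(nr), each = f)
  m1 <- rowsum(m, rows, reorder = TRUE) / f
  cols <- rep(seq_len(nc), each = f)
  out <- t(rowsum(t(m1), cols, reorder = TRUE) / f)
  dimnames(out) <- NULL
  out
}

#' Aggregate a grid to coarser cells by block mean
#'
#' Each coarse cell is the mean of the `factor^2` contributing fine cells;
#' a missing fine cell makes the coarse cell missing. Masks are aggregated
#' by "any contributing cell eligible".
#'
#' @param grid A [covariate_grid()].
#' @param factor Integer aggregation factor (e.g. 10 to go from 1 km to
#'   10 km cells). Grid dimensions must be divisible by it.
#' @return A new, coarser [covariate_grid()].
#' @export
aggregate_grid <- function(grid, factor) {
  .check(inherits(grid, "covariate_grid"), "`grid` must be a covariate_grid")
  .check(.is_count(factor), "`factor` must be a positive integer")
  f <- as.integer(factor)
  if (f == 1L) return(grid)
  layers <- lapply(grid$layers, .block_mean, f = f)
  masks <- lapply(grid$masks, function(m) .block_mean(m * 1, f) > 0)
  covariate_grid(layers, cell_km = grid$cell_km * f,
                 xll = grid$xll, yll = grid$yll, masks = masks)
}

#' Load aligned covariate layers from ESRI ASCII grids
#'
#' Reads one ASCII grid per layer, checks that all share the same
#' geotransform (corner, cell size, shape), and optionally aggregates to a
#' coarser target resolution by block mean.
#'
#' @param paths Named character vector of file paths; names become layer
#'   names (unnamed paths use the file base name).
#' @param target_cell_km Optional coarser cell size; must be an integer
#'   multiple of the native cell size.
#' @param cell_km Native cell size in km if the files' `cellsize` header is
#'   in other units; default uses the header value as km.
#' @return A [covariate_grid()].
#' @export
load_covariate_grid <- function(paths, target_cell_km = NULL, cell_km = NULL) {
  .check(length(paths) >= 1, "no paths given")
  nms <- names(paths)
  if (is.null(nms)) nms <- rep("", length(paths))
  nms[!nzchar(nms)] <- sub("\\.[^.]*$", "", basename(paths[!nzchar(nms)]))
  grids <- lapply(paths, read_ascii_grid)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    .check(identical(dim(g$values), dim(ref$values)) &&
             g$xll == ref$xll && g$yll == ref$yll &&
             g$cell_size == ref$cell_size,
           "covariate layers are not aligned (extent or cell size differs)")
  }
  native_km <- if (is.null(cell_km)) ref$cell_size else cell_km
  grid <- covariate_grid(setNames(lapply(grids, `[[`, "values"), nms),
                         cell_km = native_km, xll = ref$xll, yll = ref$yll)
  if (!is.null(target_cell_km)) {
    f <- target_cell_km / native_km
    .check(abs(f - round(f)) < 1e-9 && f >= 1,
           "`target_cell_km` must be an integer multiple of the native cell size")
    grid <- aggregate_grid(grid, round(f))
  }
  grid
}

#' Extract covariate values at point locations
#'
#' Containing-cell (nearest-pixel) lookup with no interpolation: the cell
#' containing each point under the half-open convention
#' `[x, x + w) x [y, y + h)` (lower-left inclusive) supplies its values.
#' Points outside the grid extent are flagged and get missing values.
#'
#' @param grid A [covariate_grid()].
#' @param points Data frame with planar `x`, `y` columns in the grid's
#'   coordinate system (km).
#' @param log10_offset_cols Optional character vector of layer names to
#'   transform as `log10(value + 1)` after extraction (used for strongly
#'   skewed layers such as human population density; the +1 offset admits
#'   zeros).
#' @return Data frame: one row per point with one column per layer, plus
#'   `inside` (logical).
#' @export
extract_covariates_at_points <- function(grid, points,
                                         log10_offset_cols = NULL) {
  .check(inherits(grid, "covariate_grid"), "`grid` must be a covariate_grid")
  .check(all(c("x", "y") %in% names(points)), "`points` needs x/y columns")
  d <- dim(grid$layers[[1]])
  cs <- grid$cell_km
  col <- floor((points$x - grid$xll) / cs) + 1
  row_from_bottom <- floor((points$y - grid$yll) / cs) + 1
  row <- d[1] - row_from_bottom + 1
  inside <- col >= 1 & col <= d[2] & row >= 1 & row <= d[1]
  out <- data.frame(row.names = seq_len(nrow(points)))
  for (nm in names(grid$layers)) {
    v <- rep(NA_real_, nrow(points))
    idx <- cbind(row[inside], col[inside])
    v[inside] <- grid$layers[[nm]][idx]
    if (nm %in% log10_offset_cols) v <- log10(v + 1)
    out[[nm]] <- v
  }
  out$inside <- inside
  out
}

#' Read a flat key = value pipeline configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric; comma-separated
#' numeric lists become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  .check(file.exists(path), "config file `%s` does not exist", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    .check(length(kv) == 2, "malformed config line: `%s`", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
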