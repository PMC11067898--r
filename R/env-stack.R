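#' Environmental raster stack
#'
#' An `env_stack` holds co-registered single-band rasters on a shared
#' regular lon/lat grid with a common NA mask. Grids are cell-centre
#' addressed with row 1 at the northern edge; all coordinates are WGS84
#' decimal degrees. NA propagates by union across layers: a cell that is NA
#' in any layer is NA in every layer, so every retained cell carries a
#' complete environmental vector.
#'
#' @param layers named list of numeric matrices (same dimensions), one per
#'   environmental variable, row 1 = northernmost row.
#' @param origin numeric `c(lon, lat)` of the centre of the upper-left
#'   (north-west) cell.
#' @param cell_size cell edge length in decimal degrees (> 0).
#'
#' @return An object of class `env_stack` with elements `layers` (matrices,
#'   union mask applied), `origin`, `cell_size`, `n_rows`, `n_cols`,
#'   `na_mask` (logical matrix, `TRUE` = missing).
#' @export
env_stack <- function(layers, origin = c(0, 0), cell_size = 1) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty named list of matrices")
  nms <- names(layers)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
    stop("layer names must be present and unique")
  if (!all(vapply(layers, is.matrix, logical(1))))
    stop("each layer must be a numeric matrix")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same dimensions")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a positive scalar")
  mask <- Reduce(`|`, lapply(layers, function(m) is.na(m) | !is.finite(m)))
  layers <- lapply(layers, function(m) {
    m[mask] <- NA_real_
    storage.mode(m) <- "double"
    m
  })
  structure(
    list(layers = layers, origin = as.numeric(origin[1:2]),
         cell_size = cell_size, n_rows = nrow(layers[[1]]),
         n_cols = ncol(layers[[1]]), na_mask = mask),
    class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layer(s), %d x %d cells, cell size %g deg\n",
              length(x$layers), x$n_rows, x$n_cols, x$cell_size))
  cat("  variables:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  NA cells: %d / %d\n", sum(x$na_mask), length(x$na_mask)))
  invisible(x)
}

#' @export
dim.env_stack <- function(x) c(x$n_rows, x$n_cols, length(x$layers))

#' Subset an environmental stack by variable name
#'
#' Returns the sub-stack holding only the requested variables, in the
#' requested order. Used to restrict analyses to a retained variable set
#' (e.g. variables little affected by temperate-latitude seasonality).
#'
#' @param stack an [env_stack].
#' @param keep character vector of layer names to retain, in output order.
#' @return An [env_stack] with the requested layers.
#' @export
select_variables <- function(stack, keep) {
  stopifnot(inherits(stack, "env_stack"))
  missing <- setdiff(keep, names(stack$layers))
  if (length(missing))
    stop("unknown variable(s): ", paste(missing, collapse = ", "))
  env_stack(stack$layers[keep], origin = stack$origin,
            cell_size = stack$cell_size)
}

# ---- grid arithmetic ------------------------------------------------------

#' Cell-centre coordinates of every grid cell
#' @param stack an [env_stack].
#' @return A two-column matrix (lon, lat), cells in column-major matrix order.
#' @export
cell_centers <- function(stack) {
  lon <- stack$origin[1] + (seq_len(stack$n_cols) - 1) * stack$cell_size
  lat <- stack$origin[2] - (seq_len(stack$n_rows) - 1) * stack$cell_size
  cbind(lon = rep(lon, each = stack$n_rows),
        lat = rep(lat, times = stack$n_cols))
}

#' Map lon/lat points to grid cell indices (nearest cell centre)
#' @param stack an [env_stack].
#' @param pts two-column matrix (lon, lat).
#' @return Integer vector of linear (column-major) cell indices; NA for
#'   points falling outside the grid.
#' @export
cell_index <- function(stack, pts) {
  pts <- as.matrix(pts)
  col <- round((pts[, 1] - stack$origin[1]) / stack$cell_size) + 1
  row <- round((stack$origin[2] - pts[, 2]) / stack$cell_size) + 1
  bad <- row < 1 | row > stack$n_rows | col < 1 | col > stack$n_cols
  idx <- (col - 1L) * stack$n_rows + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Environmental values of the stack as a cell-by-variable matrix
#' @param stack an [env_stack].
#' @param cells optional integer vector of linear cell indices (default: all).
#' @return Numeric matrix, one row per requested cell, one column per layer.
#' @export
stack_values <- function(stack, cells = NULL) {
  vals <- vapply(stack$layers, as.vector, numeric(stack$n_rows * stack$n_cols))
  if (!is.matrix(vals)) vals <- matrix(vals, ncol = length(stack$layers),
                                       dimnames = list(NULL, names(stack$layers)))
  if (!is.null(cells)) vals <- vals[cells, , drop = FALSE]
  vals
}

# ---- ESRI ASCII grid I/O --------------------------------------------------

#' Read a single raster layer from an ESRI ASCII grid file
#'
#' The ASCII grid (`.asc`) format stores a regular lon/lat grid as plain
#' text: a six-line header (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, `nodata_value`) followed by rows of
#' values, north row first.
#'
#' @param path file path.
#' @return A list with `values` (matrix, row 1 north), `origin` (lon/lat of
#'   the upper-left cell centre) and `cell_size`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("not an ASCII grid: ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  nc <- hdr$ncols; nr <- hdr$nrows; cs <- hdr$cellsize
  if (is.null(nc) || is.null(nr) || is.null(cs))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path))
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) vals[vals == nodata] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  # llcorner addresses the lower-left cell corner; llcenter its centre
  xll <- hdr$xllcorner %||% hdr$xllcenter
  yll <- hdr$yllcorner %||% hdr$yllcenter
  x0 <- if (!is.null(hdr$xllcorner)) xll + cs / 2 else xll
  y0 <- if (!is.null(hdr$yllcorner)) yll + cs / 2 else yll
  list(values = m, origin = c(x0, y0 + (nr - 1) * cs), cell_size = cs)
}

#' Write a raster layer to an ESRI ASCII grid file
#' @param values numeric matrix, row 1 = northernmost row.
#' @param origin lon/lat of the upper-left cell centre.
#' @param cell_size cell size in degrees.
#' @param path output file path.
#' @param nodata value used to encode NA (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, origin, cell_size, path, nodata = -9999) {
  nr <- nrow(values); nc <- ncol(values)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", origin[1] - cell_size / 2),
    sprintf("yllcorner %.10g", origin[2] - (nr - 1) * cell_size - cell_size / 2),
    sprintf("cellsize %.10g", cell_size),
    sprintf("nodata_value %g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read co-registered raster layers into an environmental stack
#'
#' Reads one or more single-band ASCII grid rasters, verifies that every
#' raster sits on the first raster's grid (origin, cell size, shape), and
#' applies the union NA mask.
#'
#' @param paths character vector of `.asc` file paths; layer names default
#'   to file base names.
#' @param names optional character vector of layer names.
#' @return An [env_stack].
#' @export
read_env_stack <- function(paths, names = NULL) {
  if (length(paths) == 0L) stop("no raster paths given")
  if (is.null(names))
    names <- vapply(paths, function(p) sub("\\.[^.]*$", "", basename(p)), "")
  first <- read_asc(paths[[1]])
  layers <- list(first$values)
  for (p in paths[-1]) {
    r <- read_asc(p)
    if (!isTRUE(all.equal(r$cell_size, first$cell_size)) ||
        !isTRUE(all.equal(r$origin, first$origin, tolerance = 1e-9)) ||
        !identical(dim(r$values), dim(first$values))) {
      # allow overlapping grids only when identical; disjoint extents error
      stop("raster ", p, " is not on the grid of ", paths[[1]],
           " (origin/cell size/shape mismatch)")
    }
    layers <- c(layers, list(r$values))
  }
  names(layers) <- names
  env_stack(layers, origin = first$origin, cell_size = first$cell_size)
}

#' Write every layer of a stack as ASCII grids
#' @param stack an [env_stack].
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_env_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(stack$layers), ".asc"))
  for (i in seq_along(stack$layers))
    write_asc(stack$layers[[i]], stack$origin, stack$cell_size, paths[i])
  invisible(paths)
}
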