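#' Environmental raster stack
#'
#' An `env_stack` holds a set of co-registered single-band environmental
#' raster layers on a regular longitude/latitude grid, together with the grid
#' transform and a shared missing-data mask. All layers must have identical
#' dimensions and identical NA patterns; missing cells are stored as `NA` and
#' serialised with a nodata sentinel.
#'
#' Row 1 of each layer matrix is the northernmost row (the usual raster
#' convention); column 1 is the westernmost column.
#'
#' @param layers named list of numeric matrices, one per variable. All
#'   matrices must share dimensions and NA mask.
#' @param units named character vector of unit strings, one per layer
#'   (defaults to `""` for unnamed units).
#' @param xll,yll longitude/latitude of the lower-left corner of the grid,
#'   decimal degrees WGS84.
#' @param cellsize cell edge length in decimal degrees; must be > 0.
#' @param nodata sentinel written for missing cells on serialisation.
#' @param crs free-text tag of the coordinate reference system.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, units = NULL, xll = 0, yll = 0, cellsize = 1,
                      nodata = -9999, crs = "WGS84 (EPSG:4326)") {
  if (!is.list(layers) || length(layers) == 0L || is.null(names(layers)) ||
      any(!nzchar(names(layers))))
    stop("`layers` must be a non-empty named list of matrices")
  if (!all(vapply(layers, is.matrix, logical(1))))
    stop("all layers must be matrices")
  if (cellsize <= 0) stop("`cellsize` must be > 0")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stop(sprintf("layer '%s' (%dx%d) does not match layer '%s' (%dx%d)",
                 names(layers)[bad], dims[1, bad], dims[2, bad],
                 names(layers)[1], dims[1, 1], dims[2, 1]))
  }
  mask <- is.na(layers[[1]])
  for (nm in names(layers)[-1])
    if (!identical(is.na(layers[[nm]]), mask))
      stop(sprintf("nodata mask of layer '%s' differs from layer '%s'",
                   nm, names(layers)[1]))
  if (is.null(units)) units <- setNames(rep("", length(layers)), names(layers))
  units <- setNames(as.character(units)[seq_along(layers)], names(layers))
  structure(list(layers = layers, units = units, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs = crs),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("env_stack: %d layer(s), %d rows x %d cols, cellsize %g deg\n",
              length(x$layers), d[1], d[2], x$cellsize))
  cat(sprintf("  origin (lower-left): %g, %g  [%s]\n", x$xll, x$yll, x$crs))
  for (nm in names(x$layers)) {
    v <- x$layers[[nm]]
    cat(sprintf("  %-18s [%s]  range %.4g .. %.4g  (%d nodata)\n", nm,
                x$units[[nm]], min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                sum(is.na(v))))
  }
  invisible(x)
}

#' @export
dim.env_stack <- function(x) dim(x$layers[[1]])

#' @rdname env_stack
#' @param x an object.
#' @export
is.env_stack <- function(x) inherits(x, "env_stack")

# ---- ESRI ASCII grid serialisation ------------------------------------------

#' Read a single-band ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII grid dialect (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by rows
#' of values, first row northernmost). Cells equal to the nodata sentinel
#' become `NA`.
#'
#' @param path file path.
#' @return list with `values` (matrix, row 1 = north), `xll`, `yll`,
#'   `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("unreadable raster %s: missing header field(s) %s", path,
                 paste(setdiff(need, names(hdr)), collapse = ", ")))
  nodata <- hdr[["nodata_value"]] %||% -9999
  toks <- unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals))
    stop(sprintf("unreadable raster %s: non-numeric cell value '%s'",
                 path, toks[which(is.na(vals))[1]]))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("unreadable raster %s: expected %d values, found %d",
                 path, nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

#' Write a single-band ESRI ASCII grid
#'
#' @param values numeric matrix, row 1 = northernmost. `NA` cells are written
#'   as the nodata sentinel.
#' @param path output file path.
#' @param xll,yll lower-left corner, decimal degrees.
#' @param cellsize cell size, decimal degrees.
#' @param nodata nodata sentinel value.
#' @return invisibly, `path`.
#' @export
write_ascii_grid <- function(values, path, xll = 0, yll = 0, cellsize = 1,
                             nodata = -9999) {
  stopifnot(is.matrix(values))
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.17g", xll), sprintf("yllcorner %.17g", yll),
           sprintf("cellsize %.17g", cellsize),
           sprintf("NODATA_value %.17g", nodata))
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read co-registered raster layers into an environmental stack
#'
#' Reads one ESRI ASCII grid per variable and assembles an [env_stack()].
#' Grids are required to agree exactly in shape and transform; mismatches are
#' an error naming the offending pair — no silent resampling or alignment is
#' performed. The nodata mask is the union of the per-layer masks only if the
#' masks already agree; differing masks are an error.
#'
#' @param paths character vector of raster file paths.
#' @param names variable name per path.
#' @param units optional unit string per path.
#' @inheritParams env_stack
#' @return an [env_stack()].
#' @export
read_env_stack <- function(paths, names, units = NULL,
                           crs = "WGS84 (EPSG:4326)") {
  stopifnot(length(paths) == length(names), length(paths) >= 1L)
  grids <- lapply(paths, read_ascii_grid)
  ref <- grids[[1]]
  for (k in seq_along(grids)[-1]) {
    g <- grids[[k]]
    if (!identical(dim(g$values), dim(ref$values)) ||
        !isTRUE(all.equal(c(g$xll, g$yll, g$cellsize),
                          c(ref$xll, ref$yll, ref$cellsize))))
      stop(sprintf(
        "layer '%s' (%s) does not align with layer '%s' (%s): shape/transform mismatch",
        names[k], paths[k], names[1], paths[1]))
  }
  layers <- setNames(lapply(grids, `[[`, "values"), names)
  env_stack(layers, units = units, xll = ref$xll, yll = ref$yll,
            cellsize = ref$cellsize, nodata = ref$nodata, crs = crs)
}

#' Write a stack (all layers) as ASCII grids
#'
#' @param stack an [env_stack()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_env_stack <- function(stack, dir) {
  stopifnot(is.env_stack(stack))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], p, stack$xll, stack$yll,
                     stack$cellsize, stack$nodata)
    p
  }, character(1))
  paths
}

#' Write a suitability grid using a template stack's georeferencing
#'
#' @param grid numeric matrix of suitability values in `[0, 1]` (or `NA` for
#'   nodata); must match the template's shape.
#' @param template an [env_stack()] supplying transform and nodata sentinel;
#'   the template's nodata cells are forced to nodata in the output.
#' @param path output path (ESRI ASCII grid).
#' @return invisibly, `path`.
#' @export
write_suitability_raster <- function(grid, template, path) {
  stopifnot(is.env_stack(template))
  if (!identical(dim(grid), dim(template$layers[[1]])))
    stop(sprintf("suitability grid is %dx%d but template is %dx%d",
                 nrow(grid), ncol(grid),
                 nrow(template$layers[[1]]), ncol(template$layers[[1]])))
  grid[is.na(template$layers[[1]])] <- NA_real_
  bad <- !is.na(grid) & (grid < 0 | grid > 1)
  if (any(bad)) stop("suitability values must lie in [0, 1] or be NA")
  write_ascii_grid(grid, path, template$xll, template$yll,
                   template$cellsize, template$nodata)
}

# ---- point-to-cell lookup ---------------------------------------------------

# Row/col of the cell containing each point (cell-center convention,
# row 1 = northernmost). Points outside the grid get NA.
cell_index <- function(stack, lon, lat) {
  nr <- nrow(stack$layers[[1]]); nc <- ncol(stack$layers[[1]])
  col <- floor((lon - stack$xll) / stack$cellsize) + 1L
  row_from_bottom <- floor((lat - stack$yll) / stack$cellsize) + 1L
  row <- nr - row_from_bottom + 1L
  out <- col < 1L | col > nc | row < 1L | row > nr |
    !is.finite(col) | !is.finite(row)
  row[out] <- NA_integer_; col[out] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Longitude/latitude of cell centers for (row, col) index matrix.
cell_center <- function(stack, row, col) {
  nr <- nrow(stack$layers[[1]])
  lon <- stack$xll + (col - 0.5) * stack$cellsize
  lat <- stack$yll + (nr - row + 0.5) * stack$cellsize
  cbind(longitude = lon, latitude = lat)
}

#' Extract environmental values at point locations
#'
#' Samples every layer of the stack at the cell containing each point
#' (cell-center convention). Points outside the grid or on nodata cells
#' yield `NA` for all variables.
#'
#' @param stack an [env_stack()].
#' @param lon,lat numeric vectors of point coordinates, decimal degrees.
#' @return data.frame with one column per layer, one row per point.
#' @export
extract_env <- function(stack, lon, lat) {
  stopifnot(is.env_stack(stack), length(lon) == length(lat))
  idx <- cell_index(stack, lon, lat)
  flat <- (idx[, "col"] - 1L) * nrow(stack$layers[[1]]) + idx[, "row"]
  out <- lapply(stack$layers, function(m) {
    v <- rep(NA_real_, length(lon))
    ok <- !is.na(flat)
    v[ok] <- m[flat[ok]]
    v
  })
  as.data.frame(out, optional = TRUE)
}
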