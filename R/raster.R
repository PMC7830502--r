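#' Gridded raster surface
#'
#' A minimal in-memory container for a single-band georeferenced grid.
#' Values are stored as a numeric matrix with row 1 at the top (north);
#' missing cells are `NA` internally and mapped to the `nodata` sentinel
#' only on disk. The affine transform is north-up with square or
#' rectangular cells of positive size.
#'
#' Cell membership follows a half-open convention: a point (x, y) belongs
#' to the cell whose x-interval is `[x0, x0 + xres)` and whose y-interval
#' is `(y0 - yres, y0]`, so a point on a shared edge belongs to exactly
#' one cell. The same rule drives value extraction, polygon masking and
#' occupancy counting, which keeps those operations mutually consistent.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xmin x coordinate of the west edge (not the first cell center).
#' @param ymax y coordinate of the north edge.
#' @param xres,yres positive cell sizes in coordinate units.
#' @param crs free-text coordinate reference identifier (e.g. "EPSG:4326").
#' @param nodata sentinel written to disk for `NA` cells.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymax = nrow(values), xres = 1,
                        yres = xres, crs = "EPSG:4326", nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (xres <= 0 || yres <= 0) stop("cell sizes must be positive")
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 xres = xres, yres = yres, crs = crs, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d rows x %d cols, res %g x %g, crs %s\n",
              nrow(v), ncol(v), x$xres, x$yres, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$xres,
              x$ymax - nrow(v) * x$yres, x$ymax))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  values: min %g, max %g, NA cells %d\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  invisible(x)
}

#' Grid definition of a raster
#'
#' @param x a `raster_grid` or an object with the same fields.
#' @return list with `xmin`, `ymax`, `xres`, `yres`, `nrow`, `ncol`, `crs`.
#' @export
grid_def <- function(x) {
  list(xmin = x$xmin, ymax = x$ymax, xres = x$xres, yres = x$yres,
       nrow = nrow(x$values), ncol = ncol(x$values), crs = x$crs)
}

same_grid <- function(a, b, tol = 1e-9) {
  da <- grid_def(a); db <- grid_def(b)
  da$crs == db$crs && da$nrow == db$nrow && da$ncol == db$ncol &&
    abs(da$xmin - db$xmin) < tol && abs(da$ymax - db$ymax) < tol &&
    abs(da$xres - db$xres) < tol && abs(da$yres - db$yres) < tol
}

#' Cell-center coordinates
#'
#' @param x a `raster_grid` or grid definition list.
#' @return list with vectors `x` (length ncol) and `y` (length nrow,
#'   north to south).
#' @export
cell_centers <- function(x) {
  d <- if (inherits(x, "raster_grid")) grid_def(x) else x
  list(x = d$xmin + (seq_len(d$ncol) - 0.5) * d$xres,
       y = d$ymax - (seq_len(d$nrow) - 0.5) * d$yres)
}

#' Locate points on the grid (half-open cell rule)
#'
#' @param grid a `raster_grid` or grid definition.
#' @param x,y point coordinates.
#' @return data.frame with `row`, `col` (NA when outside the extent).
#' @export
cell_of <- function(grid, x, y) {
  d <- if (inherits(grid, "raster_grid")) grid_def(grid) else grid
  col <- floor((x - d$xmin) / d$xres) + 1L
  row <- floor((d$ymax - y) / d$yres) + 1L
  # top edge belongs to row 1 under the (y0 - h, y0] rule
  row[y == d$ymax] <- 1L
  bad <- col < 1L | col > d$ncol | row < 1L | row > d$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Read and write rasters as ESRI ASCII grid
#'
#' Plain-text single-band raster format (NCOLS/NROWS/XLLCORNER/... header
#' followed by row-major values, row 1 = north). The CRS, and exact
#' x/y resolutions when they differ, are kept in a small JSON sidecar
#' (`<path>.aux.json`); values round-trip bit-identically via `%.17g`
#' formatting.
#'
#' @param path file path (conventionally `.asc`).
#' @param grid a `raster_grid` to write.
#' @return `read_raster` returns a `raster_grid`; `write_raster` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character(0); val <- list()
  for (i in 1:6) hdr[i] <- readLines(con, n = 1)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- toupper(kv[, 1]); num <- as.numeric(kv[, 2])
  names(num) <- key
  ncols <- as.integer(num[["NCOLS"]]); nrows <- as.integer(num[["NROWS"]])
  cellsize <- num[["CELLSIZE"]]; nodata <- num[["NODATA_VALUE"]]
  vals <- scan(con, what = double(), n = ncols * nrows, quiet = TRUE)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  aux_path <- paste0(path, ".aux.json")
  crs <- "EPSG:4326"; xres <- cellsize; yres <- cellsize
  if (file.exists(aux_path)) {
    aux <- jsonlite::read_json(aux_path, simplifyVector = TRUE)
    if (!is.null(aux$crs)) crs <- aux$crs
    if (!is.null(aux$xres)) xres <- aux$xres
    if (!is.null(aux$yres)) yres <- aux$yres
  }
  raster_grid(m, xmin = num[["XLLCORNER"]],
              ymax = num[["YLLCORNER"]] + nrows * yres,
              xres = xres, yres = yres, crs = crs, nodata = nodata)
}

#' @rdname read_raster
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  if (abs(grid$xres - grid$yres) > 1e-12)
    stop("ASCII grid supports square cells only; got xres != yres")
  hdr <- c(sprintf("NCOLS %d", ncol(v)),
           sprintf("NROWS %d", nrow(v)),
           sprintf("XLLCORNER %.17g", grid$xmin),
           sprintf("YLLCORNER %.17g", grid$ymax - nrow(v) * grid$yres),
           sprintf("CELLSIZE %.17g", grid$xres),
           sprintf("NODATA_VALUE %.17g", grid$nodata))
  out <- v
  out[!is.finite(out)] <- grid$nodata
  rows <- apply(out, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  jsonlite::write_json(list(crs = grid$crs, xres = grid$xres,
                            yres = grid$yres),
                       paste0(path, ".aux.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Resample a raster onto a target grid
#'
#' Bilinear interpolation between cell centers for continuous layers;
#' nearest (containing cell under the half-open rule) for categorical
#' layers. Target cells outside the source extent, or with any `NA`
#' support, come back `NA`.
#'
#' @param grid source `raster_grid`.
#' @param target_def grid definition list (see [grid_def()]).
#' @param method `"bilinear"` or `"nearest"`.
#' @param categorical logical; categorical layers must use `"nearest"`.
#' @return a `raster_grid` on `target_def`.
#' @export
resample_to_grid <- function(grid, target_def, method = c("bilinear", "nearest"),
                             categorical = FALSE) {
  method <- match.arg(method)
  if (categorical && method != "nearest")
    stop("categorical layers must be resampled with method = 'nearest'")
  d <- grid_def(grid)
  tc <- cell_centers(target_def)
  xs <- rep(tc$x, times = target_def$nrow)
  ys <- rep(tc$y, each = target_def$ncol)
  if (max(xs) < d$xmin || min(xs) > d$xmin + d$ncol * d$xres ||
      max(ys) < d$ymax - d$nrow * d$yres || min(ys) > d$ymax)
    stop("target grid does not overlap the source raster")
  v <- grid$values
  if (method == "nearest") {
    idx <- cell_of(d, xs, ys)
    out <- rep(NA_real_, length(xs))
    ok <- !is.na(idx$row)
    out[ok] <- v[cbind(idx$row[ok], idx$col[ok])]
  } else {
    # fractional position in units of source cell centers
    fx <- (xs - (d$xmin + 0.5 * d$xres)) / d$xres
    fy <- ((d$ymax - 0.5 * d$yres) - ys) / d$yres
    c0 <- pmin(pmax(floor(fx), 0), d$ncol - 1L)
    r0 <- pmin(pmax(floor(fy), 0), d$nrow - 1L)
    c1 <- pmin(c0 + 1, d$ncol - 1L)
    r1 <- pmin(r0 + 1, d$nrow - 1L)
    wx <- pmin(pmax(fx - c0, 0), 1)
    wy <- pmin(pmax(fy - r0, 0), 1)
    g <- function(r, c) v[cbind(r + 1L, c + 1L)]
    out <- (1 - wy) * ((1 - wx) * g(r0, c0) + wx * g(r0, c1)) +
      wy * ((1 - wx) * g(r1, c0) + wx * g(r1, c1))
    outside <- fx < -0.5 | fx > d$ncol - 0.5 | fy < -0.5 | fy > d$nrow - 0.5
    out[outside] <- NA_real_
  }
  m <- matrix(out, nrow = target_def$nrow, ncol = target_def$ncol, byrow = TRUE)
  raster_grid(m, xmin = target_def$xmin, ymax = target_def$ymax,
              xres = target_def$xres, yres = target_def$yres,
              crs = target_def$crs, nodata = grid$nodata)
}
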