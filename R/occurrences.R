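#' Occurrence records for one species
#'
#' @param species species label.
#' @param lon,lat coordinates in decimal degrees (WGS84).
#' @return an object of class `occurrence_set`: a data.frame with columns
#'   `species`, `lon`, `lat`.
#' @export
occurrence_set <- function(species, lon, lat) {
  stopifnot(length(lon) == length(lat))
  structure(data.frame(species = rep_len(as.character(species), length(lon)),
                       lon = as.numeric(lon), lat = as.numeric(lat)),
            class = c("occurrence_set", "data.frame"))
}

#' Read and write occurrence CSV (`species,lon,lat`)
#'
#' @param path CSV path.
#' @param occ an [occurrence_set] to write.
#' @return `read_occurrences` returns an `occurrence_set`;
#'   `write_occurrences` returns `path` invisibly.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species,lon,lat")
  occurrence_set(df$species, df$lon, df$lat)
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[c("species", "lon", "lat")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Clean raw occurrence records
#'
#' Applies the standard pre-modelling filters: drop records outside the
#' analysis extent, drop records on excluded land-cover classes (e.g.
#' water, built-up), and deduplicate to at most one record per analysis
#' grid cell. Records are pre-sorted lexicographically on (lon, lat) and
#' the first record per cell is kept, so the result is independent of
#' input order and the operation is idempotent.
#'
#' @param raw an [occurrence_set].
#' @param extent optional extent polygon as a two-column matrix of (x, y)
#'   vertices (closed implicitly); `NULL` uses the grid's bounding box.
#' @param landcover optional categorical [raster_grid] aligned to `grid`.
#' @param excluded_classes integer classes to exclude (default: the
#'   synthetic dialect's water and urban codes).
#' @param grid grid definition of the analysis grid.
#' @return a cleaned `occurrence_set`; warns (not errors) when empty.
#' @export
clean_occurrences <- function(raw, grid, extent = NULL, landcover = NULL,
                              excluded_classes = c(3L, 4L)) {
  df <- as.data.frame(raw)
  df <- df[order(df$lon, df$lat), , drop = FALSE]
  idx <- cell_of(grid, df$lon, df$lat)
  keep <- !is.na(idx$row)
  if (!is.null(extent))
    keep <- keep & point_in_polygon(df$lon, df$lat, extent)
  if (!is.null(landcover)) {
    if (!isTRUE(all.equal(grid_def(landcover)[c("xmin", "ymax", "xres", "yres")],
                          grid[c("xmin", "ymax", "xres", "yres")])))
      stop("landcover raster is not aligned to the analysis grid")
    cls <- rep(NA_real_, nrow(df))
    ok <- !is.na(idx$row)
    cls[ok] <- landcover$values[cbind(idx$row[ok], idx$col[ok])]
    keep <- keep & !is.na(cls) & !(cls %in% excluded_classes)
  }
  df <- df[keep, , drop = FALSE]
  idx <- idx[keep, , drop = FALSE]
  dup <- duplicated(paste(idx$row, idx$col))
  df <- df[!dup, , drop = FALSE]
  if (nrow(df) == 0)
    warning("no occurrence records survive cleaning")
  occurrence_set(if (nrow(df)) df$species else character(0), df$lon, df$lat)
}

# Even-odd ray-casting point-in-polygon; vertices as n x 2 matrix,
# boundary points count as inside (tolerance eps).
point_in_polygon <- function(x, y, poly, eps = 1e-12) {
  nv <- nrow(poly)
  inside <- logical(length(x))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    # boundary check for this edge
    d <- point_segment_distance(x, y, xi, yi, xj, yj)
    inside <- inside | d <= eps
    j <- i
  }
  inside
}

# Vectorized distance from points to one segment.
point_segment_distance <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(x)) else
    pmin(pmax(((x - x1) * dx + (y - y1) * dy) / len2, 0), 1)
  sqrt((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2)
}

#' Extract predictor values at points
#'
#' Reads the containing cell (half-open rule) of each point for every
#' layer. Points falling on an `NA` (nodata) cell of any layer are
#' excluded with a message; points outside the raster extent are an
#' error.
#'
#' @param stack a [predictor_stack].
#' @param lon,lat point coordinates (or pass an [occurrence_set] as
#'   `lon`).
#' @return data.frame with columns `lon`, `lat` and one column per layer.
#' @export
extract_at_points <- function(stack, lon, lat = NULL) {
  if (inherits(lon, "occurrence_set")) { lat <- lon$lat; lon <- lon$lon }
  g <- stack[[names(stack)[1]]]
  idx <- cell_of(g, lon, lat)
  if (anyNA(idx$row)) stop("point(s) outside the raster extent")
  out <- data.frame(lon = lon, lat = lat)
  for (n in names(stack))
    out[[n]] <- stack[[n]]$values[cbind(idx$row, idx$col)]
  bad <- !stats::complete.cases(out)
  if (any(bad)) {
    message(sum(bad), " point(s) on nodata cells excluded")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Assemble a presence/pseudo-absence sample table
#'
#' @param stack a [predictor_stack].
#' @param presences an [occurrence_set] of presence points.
#' @param absences data.frame or matrix of pseudo-absence (lon, lat).
#' @return data.frame with `lon`, `lat`, binary `label` (1 = presence)
#'   and one column per predictor, no missing values.
#' @export
build_sample_table <- function(stack, presences, absences) {
  p <- extract_at_points(stack, presences)
  a <- extract_at_points(stack, absences[, 1], absences[, 2])
  p$label <- 1L; a$label <- 0L
  rbind(p, a)[, c("lon", "lat", "label", names(stack))]
}
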