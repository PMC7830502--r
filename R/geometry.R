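#' Delaunay triangulation (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation. Occurrence sets are small
#' (tens to hundreds of points), so the O(n^2) incremental construction
#' is ample. Cocircular degeneracies — common for points on grid-cell
#' centers — are broken by an infinitesimal deterministic coordinate
#' jitter (1e-9 of the extent), far below any distance that matters to
#' alpha-hull circumradius tests.
#'
#' @param points two-column matrix of (x, y).
#' @return integer matrix, one row per triangle, columns indexing
#'   `points`; zero rows when all points are collinear.
#' @export
delaunay_triangulation <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  ext <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-12)
  # deterministic symmetry-breaking jitter
  px <- pts[, 1] + sin(1e4 * seq_len(n) + 0.3) * ext * 1e-9
  py <- pts[, 2] + sin(2e4 * seq_len(n) + 1.1) * ext * 1e-9
  cx <- mean(range(px)); cy <- mean(range(py))
  big <- 20 * ext
  sx <- c(cx - big, cx + big, cx)
  sy <- c(cy - big, cy - big, cy + 1.5 * big)
  X <- c(px, sx); Y <- c(py, sy)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- matrix(c(s1, s2, s3), ncol = 3)
  circum <- function(t) {
    ax <- X[t[1]]; ay <- Y[t[1]]; bx <- X[t[2]]; by <- Y[t[2]]
    cx2 <- X[t[3]]; cy2 <- Y[t[3]]
    d <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    if (abs(d) < 1e-300) return(c(NA, NA, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ux - ax)^2 + (uy - ay)^2))
  }
  cc <- matrix(circum(tris[1, ]), nrow = 1)
  for (p in seq_len(n)) {
    d2 <- (cc[, 1] - X[p])^2 + (cc[, 2] - Y[p])^2
    bad <- which(d2 < cc[, 3]^2 * (1 - 1e-12))
    if (!length(bad)) next
    # boundary = edges of bad triangles appearing exactly once
    edges <- do.call(rbind, lapply(bad, function(i) {
      t <- tris[i, ]
      rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    new_t <- cbind(boundary, p)
    new_c <- t(apply(new_t, 1, circum))
    tris <- rbind(tris, new_t)
    cc <- rbind(cc, new_c)
  }
  keep <- apply(tris, 1, function(t) all(t <= n))
  tris <- tris[keep, , drop = FALSE]
  dimnames(tris) <- NULL
  tris
}

triangle_circumradius <- function(pts, tri) {
  a <- sqrt(sum((pts[tri[1], ] - pts[tri[2], ])^2))
  b <- sqrt(sum((pts[tri[2], ] - pts[tri[3], ])^2))
  cl <- sqrt(sum((pts[tri[3], ] - pts[tri[1], ])^2))
  s <- (a + b + cl) / 2
  area2 <- s * (s - a) * (s - b) * (s - cl)
  if (area2 <= 0) return(Inf)
  a * b * cl / (4 * sqrt(area2))
}

triangle_area <- function(pts, tri) {
  abs((pts[tri[2], 1] - pts[tri[1], 1]) * (pts[tri[3], 2] - pts[tri[1], 2]) -
        (pts[tri[3], 1] - pts[tri[1], 1]) *
        (pts[tri[2], 2] - pts[tri[1], 2])) / 2
}

#' Alpha-hull extent of occurrence
#'
#' Classical alpha-shape: Delaunay triangulation of the occurrence
#' points with triangles whose circumradius exceeds `alpha` discarded;
#' the union of the surviving (interior-disjoint) triangles is the hull,
#' which may be multipart for disjunct distributions. As alpha tends to
#' infinity the hull equals the convex hull. When the points are too few
#' or collinear for a triangulation, the hull degenerates to the points
#' themselves (containment then relies entirely on the buffer) and is
#' flagged `degenerate`.
#'
#' @param points two-column matrix or data.frame of (lon, lat), or an
#'   [occurrence_set].
#' @param alpha positive circumradius cutoff in coordinate units
#'   (degrees); default `2 *` the median nearest-neighbor distance.
#' @param buffer_deg outward buffer in degrees applied by containment
#'   tests and [buffer_eoo()] (default 0.1).
#' @return object of class `eoo_hull`: list with `points`, `triangles`,
#'   `alpha`, `buffer_deg`, `degenerate`.
#' @export
alpha_hull <- function(points, alpha = NULL, buffer_deg = 0.1) {
  if (inherits(points, "occurrence_set"))
    points <- cbind(points$lon, points$lat)
  pts <- unique(as.matrix(points))
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  if (buffer_deg < 0) stop("buffer must be non-negative")
  if (is.null(alpha)) alpha <- 2 * median_nn_distance(pts)
  degenerate <- FALSE
  tris <- NULL
  if (nrow(pts) >= 3) {
    tris <- tryCatch(delaunay_triangulation(pts), error = function(e) NULL)
    if (!is.null(tris) && nrow(tris)) {
      r <- apply(tris, 1, triangle_circumradius, pts = pts)
      tris <- tris[r <= alpha, , drop = FALSE]
    }
  }
  if (is.null(tris) || nrow(tris) == 0) {
    degenerate <- TRUE
    warning("degenerate point set (collinear or too few points, or alpha ",
            "too small); hull falls back to buffered points")
    tris <- matrix(integer(0), ncol = 3)
  }
  structure(list(points = pts, triangles = tris, alpha = alpha,
                 buffer_deg = buffer_deg, degenerate = degenerate),
            class = "eoo_hull")
}

median_nn_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(1)
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  stats::median(apply(dm, 1, min))
}

#' Set the buffer of an extent-of-occurrence hull
#'
#' The buffer is an outward Euclidean (Minkowski) buffer in degree
#' units, applied analytically during containment tests; 0.1 degrees is
#' roughly 12 km at the equator.
#'
#' @param hull an `eoo_hull`.
#' @param buffer_deg non-negative buffer in degrees.
#' @return the hull with the buffer set.
#' @export
buffer_eoo <- function(hull, buffer_deg = 0.1) {
  stopifnot(inherits(hull, "eoo_hull"))
  if (buffer_deg < 0) stop("buffer must be non-negative")
  hull$buffer_deg <- buffer_deg
  hull
}

#' @export
print.eoo_hull <- function(x, ...) {
  cat(sprintf("alpha-hull EOO: %d points, %d triangles, alpha %.4g, buffer %.3g deg%s\n",
              nrow(x$points), nrow(x$triangles), x$alpha, x$buffer_deg,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Point containment in a (buffered) alpha hull
#'
#' A point is contained when it lies inside any hull triangle or within
#' `buffer_deg` of the hull (Euclidean distance to the nearest triangle
#' edge or, for a degenerate hull, to the nearest input point).
#'
#' @param hull an `eoo_hull`.
#' @param x,y point coordinates.
#' @return logical vector.
#' @export
eoo_contains <- function(hull, x, y) {
  inside <- logical(length(x))
  pts <- hull$points
  for (i in seq_len(nrow(hull$triangles))) {
    t <- hull$triangles[i, ]
    inside <- inside | point_in_triangle(x, y, pts[t[1], ], pts[t[2], ],
                                         pts[t[3], ])
    if (all(inside)) return(inside)
  }
  b <- hull$buffer_deg
  if (b > 0) {
    todo <- which(!inside)
    if (length(todo)) {
      d <- eoo_distance(hull, x[todo], y[todo])
      inside[todo] <- d <= b
    }
  } else if (hull$degenerate) {
    # zero buffer on a degenerate hull contains only the points themselves
    for (k in seq_len(nrow(pts)))
      inside <- inside | (x == pts[k, 1] & y == pts[k, 2])
  }
  inside
}

# Distance from points to the hull's triangle edges (or points when
# degenerate); 0 is not returned for interior points — callers test
# interior membership first.
eoo_distance <- function(hull, x, y) {
  d <- rep(Inf, length(x))
  pts <- hull$points
  if (nrow(hull$triangles)) {
    for (i in seq_len(nrow(hull$triangles))) {
      t <- hull$triangles[i, ]
      for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
        p1 <- pts[t[e[1]], ]; p2 <- pts[t[e[2]], ]
        d <- pmin(d, point_segment_distance(x, y, p1[1], p1[2], p2[1], p2[2]))
      }
    }
  } else {
    for (k in seq_len(nrow(pts)))
      d <- pmin(d, sqrt((x - pts[k, 1])^2 + (y - pts[k, 2])^2))
  }
  d
}

point_in_triangle <- function(x, y, a, b, c, eps = 1e-12) {
  sign_of <- function(p1x, p1y, p2, p3)
    (p1x - p3[1]) * (p2[2] - p3[2]) - (p2[1] - p3[1]) * (p1y - p3[2])
  d1 <- sign_of(x, y, a, b)
  d2 <- sign_of(x, y, b, c)
  d3 <- sign_of(x, y, c, a)
  has_neg <- d1 < -eps | d2 < -eps | d3 < -eps
  has_pos <- d1 > eps | d2 > eps | d3 > eps
  !(has_neg & has_pos)
}

#' Area of a (buffered) hull
#'
#' The unbuffered hull area is the exact sum of its interior-disjoint
#' triangle areas. With a positive buffer the area is estimated by
#' counting containment on a fine grid over the buffered bounding box
#' (`resolution^2` cells), which converges to the Minkowski-sum area.
#'
#' @param hull an `eoo_hull`.
#' @param buffered include the buffer (default `TRUE` when the hull has
#'   one).
#' @param resolution grid cells per axis for the buffered estimate.
#' @return area in squared coordinate units.
#' @export
eoo_area <- function(hull, buffered = hull$buffer_deg > 0, resolution = 400) {
  if (!buffered) {
    if (!nrow(hull$triangles)) return(0)
    return(sum(apply(hull$triangles, 1, triangle_area, pts = hull$points)))
  }
  b <- hull$buffer_deg
  xr <- range(hull$points[, 1]) + c(-b, b) * 1.05
  yr <- range(hull$points[, 2]) + c(-b, b) * 1.05
  gx <- seq(xr[1], xr[2], length.out = resolution)
  gy <- seq(yr[1], yr[2], length.out = resolution)
  cellarea <- diff(gx[1:2]) * diff(gy[1:2])
  xs <- rep(gx, times = resolution)
  ys <- rep(gy, each = resolution)
  sum(eoo_contains(hull, xs, ys)) * cellarea
}

#' Write an EOO hull as GeoJSON
#'
#' The geometry is the unbuffered alpha-hull triangle multipolygon;
#' `alpha` and `buffer_deg` are recorded as feature properties (the
#' buffer is applied analytically by containment tests rather than
#' polygonized).
#'
#' @param hull an `eoo_hull`.
#' @param path output path.
#' @param species species name recorded in the properties.
#' @return `path`, invisibly.
#' @export
write_eoo_geojson <- function(hull, path, species = "") {
  polys <- lapply(seq_len(nrow(hull$triangles)), function(i) {
    t <- hull$triangles[i, ]
    ring <- hull$points[c(t, t[1]), , drop = FALSE]
    list(lapply(seq_len(nrow(ring)), function(j) as.numeric(ring[j, ])))
  })
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(species = species, alpha = hull$alpha,
                        buffer_deg = hull$buffer_deg,
                        degenerate = hull$degenerate),
      geometry = list(type = "MultiPolygon", coordinates = polys))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
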