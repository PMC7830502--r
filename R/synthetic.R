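#' Spatially autocorrelated random surface
#'
#' Generates a smooth random field by convolving white noise with a
#' separable gaussian kernel (standard deviation = `correlation_range`
#' cells, truncated at three standard deviations, renormalized at the
#' edges), then min-max rescaling to `[vmin, vmax]`. A stand-in for
#' bioclim-style climate layers: larger `correlation_range` gives
#' stronger spatial autocorrelation.
#'
#' @param n_rows,n_cols grid dimensions (at least 8).
#' @param correlation_range positive kernel width in cells.
#' @param seed integer RNG seed; output is a pure function of arguments.
#' @param vmin,vmax bounds of the rescaled output (e.g. an observed
#'   bioclim range such as 21.75-33.65 degrees C).
#' @param grid grid definition list for the result (defaults to a unit
#'   grid at the origin).
#' @return a [raster_grid] whose min and max equal `vmin` and `vmax`.
#' @export
make_random_field <- function(n_rows, n_cols, correlation_range, seed,
                              vmin = 0, vmax = 1, grid = NULL) {
  if (n_rows < 8 || n_cols < 8) stop("grid must be at least 8 x 8")
  if (correlation_range <= 0) stop("correlation_range must be positive")
  if (vmax <= vmin) stop("vmax must exceed vmin")
  noise <- with_seed(seed, matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols))
  half <- max(1L, ceiling(3 * correlation_range))
  k <- stats::dnorm(-half:half, sd = correlation_range)
  smooth1 <- function(m, kern) {
    # band-matrix convolution with edge renormalization
    n <- nrow(m)
    C <- matrix(0, n, n)
    for (d in -half:half) {
      i <- seq_len(n); j <- i + d
      ok <- j >= 1 & j <= n
      C[cbind(i[ok], j[ok])] <- kern[d + half + 1]
    }
    C <- C / rowSums(C)
    C %*% m
  }
  sm <- smooth1(t(smooth1(noise, k)), k)
  sm <- t(sm)
  rng <- range(sm)
  if (rng[1] == rng[2]) sm[] <- (vmin + vmax) / 2
  else sm <- vmin + (sm - rng[1]) / (rng[2] - rng[1]) * (vmax - vmin)
  if (is.null(grid))
    grid <- list(xmin = 0, ymax = n_rows, xres = 1, yres = 1,
                 nrow = n_rows, ncol = n_cols, crs = "EPSG:4326")
  raster_grid(sm, xmin = grid$xmin, ymax = grid$ymax, xres = grid$xres,
              yres = grid$yres, crs = grid$crs)
}

#' Synthetic predictor stack
#'
#' One autocorrelated layer per spec, all on a shared grid. Layer seeds
#' are derived deterministically from `seed` and the layer position so
#' layers are mutually independent but jointly reproducible.
#'
#' @param layer_specs list of lists with fields `name`, `min`, `max`,
#'   `correlation_range`.
#' @param grid grid definition (see [grid_def()]); default 100 x 100
#'   cells of nominal 2 km.
#' @param seed integer master seed.
#' @return a [predictor_stack].
#' @export
make_predictor_stack <- function(layer_specs, grid = default_grid(), seed = 1) {
  nm <- vapply(layer_specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate layer names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  layers <- lapply(seq_along(layer_specs), function(i) {
    s <- layer_specs[[i]]
    make_random_field(grid$nrow, grid$ncol, s$correlation_range,
                      seed = stage_seed(seed, paste0("layer:", s$name)),
                      vmin = s$min, vmax = s$max, grid = grid)
  })
  names(layers) <- nm
  predictor_stack(layers)
}

#' Default analysis grid for synthetic data
#'
#' 100 x 100 square cells of nominal 2 km on a metric-like affine, so one
#' suitable cell contributes 4 km2 of occupancy and the arithmetic stays
#' transparent. Coordinates are plain grid units (cell size 0.02 "degrees"
#' standing in for 60 arc-seconds).
#' @param nrow,ncol grid dimensions.
#' @param xres cell size in coordinate units.
#' @return a grid definition list.
#' @export
default_grid <- function(nrow = 100, ncol = 100, xres = 0.02) {
  list(xmin = 0, ymax = nrow * xres, xres = xres, yres = xres,
       nrow = nrow, ncol = ncol, crs = "EPSG:4326")
}

#' Parametric virtual niche
#'
#' Defines true habitat suitability as a product of per-driver responses:
#' gaussian (`exp(-0.5 ((x - optimum)/breadth)^2)`, maximal at the
#' optimum) or logistic (`1 / (1 + exp(-slope (x - inflection)))`,
#' monotone in the driver).
#'
#' @param drivers named list; each element a list with `kind`
#'   (`"gaussian"` or `"logistic"`) and either `optimum` + `breadth`
#'   (> 0) or `inflection` + `slope`.
#' @return an object of class `virtual_niche`.
#' @export
virtual_niche <- function(drivers) {
  if (length(drivers) < 1) stop("at least one driver is required")
  if (is.null(names(drivers)) || any(names(drivers) == ""))
    stop("drivers must be named after predictor layers")
  for (n in names(drivers)) {
    d <- drivers[[n]]
    kind <- match.arg(d$kind, c("gaussian", "logistic"))
    if (kind == "gaussian") {
      if (is.null(d$optimum) || is.null(d$breadth) || d$breadth <= 0)
        stop("gaussian driver '", n, "' needs optimum and breadth > 0")
    } else if (is.null(d$inflection) || is.null(d$slope))
      stop("logistic driver '", n, "' needs inflection and slope")
    drivers[[n]]$kind <- kind
  }
  structure(list(drivers = drivers, combine = "product"),
            class = "virtual_niche")
}

#' True suitability surface of a virtual niche
#'
#' @param stack a [predictor_stack] containing every niche driver.
#' @param niche a [virtual_niche].
#' @return a [raster_grid] with values in `[0, 1]`.
#' @export
true_suitability <- function(stack, niche) {
  stopifnot(inherits(niche, "virtual_niche"))
  missing <- setdiff(names(niche$drivers), names(stack))
  if (length(missing))
    stop("niche driver layer(s) missing from stack: ",
         paste(missing, collapse = ", "))
  g <- stack[[names(niche$drivers)[1]]]
  suit <- matrix(1, nrow(g$values), ncol(g$values))
  for (n in names(niche$drivers)) {
    d <- niche$drivers[[n]]
    x <- stack[[n]]$values
    r <- if (d$kind == "gaussian")
      exp(-0.5 * ((x - d$optimum) / d$breadth)^2)
    else 1 / (1 + exp(-d$slope * (x - d$inflection)))
    suit <- suit * r
  }
  g$values <- suit
  g
}

#' Sample presence records from a suitability surface
#'
#' Draws cells without replacement with probability proportional to
#' suitability and returns their centers as occurrence points — at most
#' one record per cell, mirroring the deduplication applied to real
#' occurrence data. Optionally contaminates a fraction of records with
#' uniform random cells (observation error); no contamination by default.
#'
#' @param suitability a [raster_grid] with values in `[0, 1]`.
#' @param n_target number of records wanted; the result has
#'   `min(n_target, number of cells with positive suitability)` rows.
#' @param seed integer RNG seed.
#' @param species species label for the records.
#' @param contamination fraction in `[0, 1)` of records replaced by
#'   uniform draws over all non-`NA` cells.
#' @return an [occurrence_set].
#' @export
sample_presences <- function(suitability, n_target, seed, species = "virtual",
                             contamination = 0) {
  v <- as.vector(t(suitability$values))  # row-major: index = (row-1)*ncol + col
  v[is.na(v)] <- 0
  if (any(v < -1e-9 | v > 1 + 1e-9)) stop("suitability must lie in [0, 1]")
  if (n_target < 1) stop("n_target must be at least 1")
  support <- which(v > 0)
  if (!length(support)) stop("suitability is zero everywhere: empty support")
  n <- min(n_target, length(support))
  d <- grid_def(suitability)
  idx <- with_seed(seed, {
    # sample(x, ...) with scalar x would draw from 1:x
    picked <- if (length(support) == 1) support
    else sample(support, n, prob = v[support])
    n_bad <- floor(contamination * n)
    if (n_bad > 0) {
      all_cells <- which(!is.na(as.vector(t(suitability$values))))
      picked[seq_len(n_bad)] <- sample(all_cells, n_bad)
    }
    picked
  })
  row <- (idx - 1L) %/% d$ncol + 1L
  col <- (idx - 1L) %% d$ncol + 1L
  cc <- cell_centers(d)
  occurrence_set(species, lon = cc$x[col], lat = cc$y[row])
}

#' Categorical land-cover surface
#'
#' Thresholds an autocorrelated field at the `1 - forest_fraction`
#' quantile to produce a spatially coherent forest class (class 1) whose
#' areal proportion equals `forest_fraction` up to grid rounding; the
#' remaining cells are split among grassland (2), water (3) and urban (4)
#' classes at fixed 70/20/10 proportions by independent seeded draws.
#'
#' @param grid grid definition list.
#' @param forest_fraction target forest proportion in `(0, 1]`.
#' @param seed integer RNG seed.
#' @return a categorical [raster_grid] with integer classes 1-4.
#' @export
make_landcover <- function(grid = default_grid(), forest_fraction, seed) {
  if (forest_fraction <= 0 || forest_fraction > 1)
    stop("forest_fraction must be in (0, 1]")
  if (forest_fraction == 1) {
    g <- raster_grid(matrix(1, grid$nrow, grid$ncol), xmin = grid$xmin,
                     ymax = grid$ymax, xres = grid$xres, yres = grid$yres,
                     crs = grid$crs)
    return(g)
  }
  f <- make_random_field(grid$nrow, grid$ncol, correlation_range = 5,
                         seed = stage_seed(seed, "landcover"), grid = grid)
  cut <- stats::quantile(f$values, 1 - forest_fraction, names = FALSE)
  cls <- matrix(2, grid$nrow, grid$ncol)
  cls[f$values >= cut] <- 1
  nonforest <- which(cls != 1)
  other <- with_seed(stage_seed(seed, "landcover-classes"),
                     sample(c(2, 3, 4), length(nonforest), replace = TRUE,
                            prob = c(0.7, 0.2, 0.1)))
  cls[nonforest] <- other
  f$values <- cls
  f
}

#' Land-cover class codes used by the synthetic generator
#' @return named integer vector (forest, grassland, water, urban).
#' @export
landcover_classes <- function() c(forest = 1L, grassland = 2L,
                                  water = 3L, urban = 4L)

#' Write a complete virtual-species scenario to disk
#'
#' Writes the predictor stack (ASCII grids), occurrence CSV
#' (`species,lon,lat`) and a JSON sidecar with the niche parameters and
#' seed — the ground truth for recovery tests.
#'
#' @param dir output directory.
#' @param stack a [predictor_stack].
#' @param occ an [occurrence_set].
#' @param niche a [virtual_niche].
#' @param seed the seed used to generate the scenario.
#' @return `dir`, invisibly.
#' @export
write_virtual_species <- function(dir, stack, occ, niche, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(stack, file.path(dir, "stack"))
  write_occurrences(occ, file.path(dir, "occurrences.csv"))
  jsonlite::write_json(list(niche = niche$drivers, combine = niche$combine,
                            seed = seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Canonical virtual-species study conditions
#'
#' Builds the package's reference simulation: a 100 x 100 grid of four
#' autocorrelated predictors (a temperature-range-like driver "bio7" on
#' a 0-100 scale plus three decoy layers), a narrow gaussian niche on
#' the cool tail of the driver (optimum 25, breadth 3 — a montane-type
#' specialist occupying roughly 5% of the landscape), and presence
#' records sampled proportional to true suitability. A warming offset
#' applied to the driver moves conditions into the densely sampled warm
#' side of the landscape, the configuration under which projected
#' contraction is identifiable.
#'
#' @param seed integer master seed.
#' @param n_presences number of occurrence records (default 40).
#' @param optimum,breadth gaussian niche parameters on the driver.
#' @return list with `stack`, `niche`, `suitability` (true surface),
#'   `occurrences`, `driver` (the driver layer name), `seed`.
#' @export
virtual_study <- function(seed = 1, n_presences = 40, optimum = 25,
                          breadth = 3) {
  specs <- list(
    list(name = "bio7", min = 0, max = 100, correlation_range = 8),
    list(name = "bio3", min = 20, max = 60, correlation_range = 8),
    list(name = "bio12", min = 300, max = 2000, correlation_range = 8),
    list(name = "elev", min = 1000, max = 5000, correlation_range = 8))
  stack <- make_predictor_stack(specs, seed = stage_seed(seed, "stack"))
  niche <- virtual_niche(list(bio7 = list(kind = "gaussian",
                                          optimum = optimum,
                                          breadth = breadth)))
  suit <- true_suitability(stack, niche)
  occ <- sample_presences(suit, n_presences,
                          seed = stage_seed(seed, "occurrences"),
                          species = "virtual")
  list(stack = stack, niche = niche, suitability = suit,
       occurrences = occ, driver = "bio7", seed = seed)
}
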