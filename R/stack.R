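#' Stack of aligned predictor layers
#'
#' An ordered, named collection of [raster_grid] layers sharing one grid
#' (transform, CRS, shape). This is the container for bioclim-style
#' climate predictors, suitability surfaces and land-cover masks.
#'
#' @param layers named list of `raster_grid` objects on a common grid.
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers) {
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique, non-empty names")
  if (!all(vapply(layers, inherits, logical(1), "raster_grid")))
    stop("all layers must be raster_grid objects")
  if (length(layers) > 1)
    for (i in 2:length(layers))
      if (!same_grid(layers[[1]], layers[[i]]))
        stop("layer '", nm[i], "' is not aligned with layer '", nm[1], "'")
  structure(list(layers = layers), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  d <- grid_def(x$layers[[1]])
  cat(sprintf("predictor_stack: %d layers on %d x %d grid (res %g, crs %s)\n",
              length(x$layers), d$nrow, d$ncol, d$xres, d$crs))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[[.predictor_stack` <- function(x, name) {
  if (is.character(name) && !name %in% names(x$layers))
    stop("no layer named '", name, "' in stack")
  x$layers[[name]]
}

#' @export
names.predictor_stack <- function(x) names(x$layers)

#' @export
length.predictor_stack <- function(x) length(x$layers)

#' Average several aligned stacks layer by layer
#'
#' Per-cell arithmetic mean of each layer across stacks, e.g. an ensemble
#' average of several general-circulation-model projections.
#'
#' @param stacks list of `predictor_stack` objects with identical layer
#'   names and grids.
#' @return a `predictor_stack`.
#' @export
average_stacks <- function(stacks) {
  if (length(stacks) < 1) stop("need at least one stack")
  nm <- names(stacks[[1]])
  for (s in stacks[-1]) {
    if (!identical(names(s), nm)) stop("stacks have different layer names")
    if (!same_grid(s$layers[[1]], stacks[[1]]$layers[[1]]))
      stop("stacks are on different grids")
  }
  out <- lapply(nm, function(n) {
    g <- stacks[[1]][[n]]
    acc <- Reduce(`+`, lapply(stacks, function(s) s[[n]]$values))
    g$values <- acc / length(stacks)
    g
  })
  names(out) <- nm
  predictor_stack(out)
}

#' Per-layer climate perturbation
#'
#' Describes a simple future climate as `layer * factor + offset` applied
#' layer by layer — an additive warming and/or multiplicative scaling
#' standing in for a downscaled climate-model projection.
#'
#' @param offset named numeric vector of additive offsets (layer units).
#' @param factor named numeric vector of multiplicative factors (> 0);
#'   layers absent from both vectors are left unchanged.
#' @return an object of class `climate_delta`.
#' @export
climate_delta <- function(offset = numeric(0), factor = numeric(0)) {
  if (length(offset) && is.null(names(offset)))
    stop("offset must be a named vector")
  if (length(factor)) {
    if (is.null(names(factor))) stop("factor must be a named vector")
    if (any(factor <= 0)) stop("multiplicative factors must be positive")
  }
  structure(list(offset = offset, factor = factor), class = "climate_delta")
}

#' Apply a climate perturbation to a stack
#'
#' @param current a `predictor_stack`.
#' @param delta a [climate_delta].
#' @return a `predictor_stack` on the same grid with
#'   `out = current * factor + offset` per layer.
#' @export
apply_climate_delta <- function(current, delta) {
  stopifnot(inherits(current, "predictor_stack"),
            inherits(delta, "climate_delta"))
  touched <- union(names(delta$offset), names(delta$factor))
  missing <- setdiff(touched, names(current))
  if (length(missing))
    stop("climate delta references missing layer(s): ",
         paste(missing, collapse = ", "))
  out <- current$layers
  for (n in names(out)) {
    f <- if (n %in% names(delta$factor)) delta$factor[[n]] else 1
    o <- if (n %in% names(delta$offset)) delta$offset[[n]] else 0
    out[[n]]$values <- out[[n]]$values * f + o
  }
  predictor_stack(out)
}

#' Read and write a predictor stack as a directory of ASCII grids
#'
#' One `<layer>.asc` per layer plus a `layers.json` manifest preserving
#' layer order.
#'
#' @param stack a `predictor_stack`.
#' @param dir directory path.
#' @return `write_stack` returns `dir` invisibly; `read_stack` a
#'   `predictor_stack`.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (n in names(stack))
    write_raster(stack[[n]], file.path(dir, paste0(n, ".asc")))
  jsonlite::write_json(list(layers = names(stack)),
                       file.path(dir, "layers.json"))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  man <- file.path(dir, "layers.json")
  if (!file.exists(man)) stop("no layers.json manifest in ", dir)
  nm <- unlist(jsonlite::read_json(man, simplifyVector = TRUE)$layers)
  layers <- lapply(nm, function(n) read_raster(file.path(dir, paste0(n, ".asc"))))
  names(layers) <- nm
  predictor_stack(layers)
}
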