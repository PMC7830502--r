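#' Mask a binary suitability raster by an EOO polygon
#'
#' Cells whose centers fall outside the buffered hull become 0
#' (unsuitable); cells inside are unchanged; nodata propagates. Cell
#' centers follow the same half-open convention as extraction and
#' occupancy counting, so no cell is double-counted at the boundary.
#'
#' @param binary a binary [raster_grid].
#' @param eoo an `eoo_hull` (see [alpha_hull()]).
#' @return a binary `raster_grid`.
#' @export
mask_by_polygon <- function(binary, eoo) {
  stopifnot(inherits(eoo, "eoo_hull"))
  d <- grid_def(binary)
  cc <- cell_centers(d)
  v <- binary$values
  suit <- which(!is.na(v) & v == 1)
  if (length(suit)) {
    row <- (suit - 1L) %% d$nrow + 1L
    col <- (suit - 1L) %/% d$nrow + 1L
    keep <- eoo_contains(eoo, cc$x[col], cc$y[row])
    v[suit[!keep]] <- 0
  }
  if (all(is.na(v) | v == 0) && any(!is.na(binary$values) & binary$values == 1))
    warning("EOO polygon removes every suitable cell")
  binary$values <- v
  binary
}

#' Mask a binary raster by land-cover class
#'
#' Suitable cells are kept only where the land-cover class is in
#' `allowed_classes` (e.g. forest); elsewhere they become 0.
#'
#' @param binary a binary [raster_grid].
#' @param landcover a categorical [raster_grid] aligned with `binary`.
#' @param allowed_classes integer vector of permitted classes.
#' @return a binary `raster_grid`.
#' @export
mask_by_landcover <- function(binary, landcover, allowed_classes) {
  if (!same_grid(binary, landcover))
    stop("land-cover raster is not aligned with the binary raster")
  v <- binary$values
  block <- !is.na(v) & v == 1 &
    (is.na(landcover$values) | !(landcover$values %in% allowed_classes))
  v[block] <- 0
  binary$values <- v
  binary
}

#' Area of occupancy from a masked binary raster
#'
#' Counts suitable cells and converts to area at a nominal fixed cell
#' area (default 4 km2 for 2-km cells); no latitude correction, matching
#' grid-cell-counting occupancy assessment.
#'
#' @param binary_masked binary [raster_grid], already EOO- and
#'   land-cover-masked.
#' @param cell_area_km2 area per cell (default 4).
#' @param threshold_rule,scenario labels carried into the estimate.
#' @return object of class `aoo_estimate`: list with `cell_count`,
#'   `cell_area_km2`, `area_km2`, `threshold_rule`, `scenario`.
#' @export
compute_aoo <- function(binary_masked, cell_area_km2 = 4,
                        threshold_rule = "fixed_05", scenario = "current") {
  n <- sum(binary_masked$values == 1, na.rm = TRUE)
  structure(list(cell_count = n, cell_area_km2 = cell_area_km2,
                 area_km2 = n * cell_area_km2,
                 threshold_rule = threshold_rule, scenario = scenario),
            class = "aoo_estimate")
}

#' @export
print.aoo_estimate <- function(x, ...) {
  cat(sprintf("AOO [%s, %s]: %d cells = %g km2\n", x$threshold_rule,
              x$scenario, x$cell_count, x$area_km2))
  invisible(x)
}

# change-map class codes
CHANGE_CLASSES <- c(never = 0, loss = 1, stable = 2, gain = 3)

#' Current-vs-future change map
#'
#' Per cell: suitable in both maps = stable (2); suitable now only =
#' loss (1); suitable in the future only = gain (3); suitable in
#' neither = never (0). Nodata propagates.
#'
#' @param current_bin,future_bin aligned binary [raster_grid]s.
#' @return object of class `change_map`: a categorical `raster_grid`
#'   with a `dispersal` attribute.
#' @export
make_change_map <- function(current_bin, future_bin) {
  if (!same_grid(current_bin, future_bin))
    stop("current and future binary rasters are not aligned")
  cur <- current_bin$values; fut <- future_bin$values
  cls <- matrix(CHANGE_CLASSES[["never"]], nrow(cur), ncol(cur))
  cls[cur == 1 & fut == 1] <- CHANGE_CLASSES[["stable"]]
  cls[cur == 1 & fut == 0] <- CHANGE_CLASSES[["loss"]]
  cls[cur == 0 & fut == 1] <- CHANGE_CLASSES[["gain"]]
  cls[is.na(cur) | is.na(fut)] <- NA_real_
  out <- current_bin
  out$values <- cls
  class(out) <- c("change_map", class(out))
  attr(out, "dispersal") <- "full"
  out
}

#' Apply a dispersal scenario to a change map
#'
#' Under no dispersal, newly suitable cells cannot be colonized: gain
#' cells are reclassified as never-suitable. Under full dispersal the
#' map is unchanged.
#'
#' @param change a `change_map`.
#' @param scenario `"full"` or `"none"`.
#' @return the adjusted `change_map` (with its `dispersal` attribute
#'   set).
#' @export
apply_dispersal <- function(change, scenario = c("full", "none")) {
  scenario <- match.arg(scenario)
  if (scenario == "none") {
    v <- change$values
    v[!is.na(v) & v == CHANGE_CLASSES[["gain"]]] <- CHANGE_CLASSES[["never"]]
    change$values <- v
  }
  attr(change, "dispersal") <- scenario
  change
}

#' Future occupancy from a change map
#'
#' The post-dispersal future suitable set is stable + gain.
#'
#' @param change a `change_map`.
#' @param cell_area_km2 area per cell.
#' @param threshold_rule label carried through.
#' @return an `aoo_estimate` with scenario `"future"`.
#' @export
aoo_from_change <- function(change, cell_area_km2 = 4,
                            threshold_rule = "fixed_05") {
  v <- change$values
  n <- sum(v %in% CHANGE_CLASSES[c("stable", "gain")], na.rm = TRUE)
  structure(list(cell_count = n, cell_area_km2 = cell_area_km2,
                 area_km2 = n * cell_area_km2,
                 threshold_rule = threshold_rule, scenario = "future"),
            class = "aoo_estimate")
}

#' Percent change in area of occupancy
#'
#' `100 * (future - current) / current`; negative values are losses,
#' positive values gains. The risk classifier consumes
#' `loss = max(0, -change)`.
#'
#' @param current,future `aoo_estimate` objects (current count > 0).
#' @return percent change (a single number).
#' @export
aoo_change_percent <- function(current, future) {
  if (current$cell_count == 0)
    stop("current AOO is zero; change undefined")
  100 * (future$cell_count - current$cell_count) / current$cell_count
}

#' Write a change map as ASCII grid
#'
#' Class table: 0 never, 1 loss, 2 stable, 3 gain.
#' @param change a `change_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_change_map <- function(change, path) {
  g <- change
  class(g) <- "raster_grid"
  write_raster(g, path)
}
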