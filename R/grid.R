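#' Kilometres per degree of latitude
#'
#' Single constant used for every degree-to-kilometre conversion in the
#' package (cell areas, centroid shifts). Spherical mean-Earth value.
#'
#' @format A length-one numeric, 111.32 km per degree.
#' @export
KM_PER_DEG <- 111.32

#' Define a regular latitude-longitude grid
#'
#' Cell-center convention: latitude ascending, longitude in \[-180, 180).
#' Cell centers sit at `edge + resolution/2`. The extents must be exact
#' multiples of the resolution.
#'
#' @param lat_min,lat_max,lon_min,lon_max Grid edges in degrees.
#' @param resolution Cell size in degrees (default 0.5).
#' @return An object of class `grid_spec` with fields `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max`, `resolution`, `n_lat`, `n_lon`.
#' @examples
#' grid_spec(45, 70, -10, 10)
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max, resolution = 0.5) {
  stopifnot(resolution > 0, lat_max > lat_min, lon_max > lon_min)
  if (lat_min < -90 || lat_max > 90) stop("latitude edges must lie in [-90, 90]")
  if (lon_min < -180 || lon_max > 180) stop("longitude edges must lie in [-180, 180]")
  n_lat <- (lat_max - lat_min) / resolution
  n_lon <- (lon_max - lon_min) / resolution
  if (abs(n_lat - round(n_lat)) > 1e-8 || abs(n_lon - round(n_lon)) > 1e-8) {
    stop("grid extents must be exact multiples of the resolution")
  }
  structure(
    list(
      lat_min = lat_min, lat_max = lat_max,
      lon_min = lon_min, lon_max = lon_max,
      resolution = resolution,
      n_lat = as.integer(round(n_lat)), n_lon = as.integer(round(n_lon))
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %g deg, %d x %d cells, lat [%g, %g], lon [%g, %g]\n",
    x$resolution, x$n_lat, x$n_lon, x$lat_min, x$lat_max, x$lon_min, x$lon_max
  ))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return Numeric vector of cell-center latitudes (ascending) or longitudes.
#' @export
lat_centers <- function(spec) {
  spec$lat_min + spec$resolution / 2 + (seq_len(spec$n_lat) - 1) * spec$resolution
}

#' @rdname lat_centers
#' @export
lon_centers <- function(spec) {
  spec$lon_min + spec$resolution / 2 + (seq_len(spec$n_lon) - 1) * spec$resolution
}

same_spec <- function(a, b, tol = 1e-9) {
  all(
    abs(a$lat_min - b$lat_min) < tol, abs(a$lat_max - b$lat_max) < tol,
    abs(a$lon_min - b$lon_min) < tol, abs(a$lon_max - b$lon_max) < tol,
    abs(a$resolution - b$resolution) < tol
  )
}

#' Locate records on the grid (half-open cell convention)
#'
#' Each cell is the half-open box `[edge, edge + resolution)` in both axes,
#' so a point exactly on a lower edge belongs to the cell whose lower edge it
#' matches. Points outside the grid get `NA` indices.
#'
#' @param lon,lat Coordinate vectors (equal length).
#' @param spec A [grid_spec()].
#' @return A list with integer vectors `row` (latitude index, ascending) and
#'   `col` (longitude index), `NA` where the point is off-grid.
#' @export
cell_index <- function(lon, lat, spec) {
  row <- floor((lat - spec$lat_min) / spec$resolution) + 1
  col <- floor((lon - spec$lon_min) / spec$resolution) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > spec$n_lat | col < 1 | col > spec$n_lon
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' A single gridded environmental layer
#'
#' @param spec A [grid_spec()].
#' @param variable Layer name, one of `sst`, `sbt`, `salinity`, `ice`, `npp`,
#'   `depth`, `dist_coast` (other names are allowed but unchecked).
#' @param values Numeric matrix `n_lat x n_lon` (rows = latitude, ascending);
#'   `NA` marks land / missing cells.
#' @param units Unit string (stored, not interpreted).
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(spec, variable, values, units = "") {
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_lat, spec$n_lon))) {
    stop("values must be an n_lat x n_lon matrix matching the grid spec")
  }
  if (variable == "depth" && any(values < 0, na.rm = TRUE)) {
    stop("depth must be non-negative where present")
  }
  if (variable == "ice" && any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("ice concentration must lie in [0, 1]")
  }
  structure(list(spec = spec, variable = variable, values = values, units = units),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf(
    "<env_grid> %s [%s], %d x %d cells, %d missing\n",
    x$variable, x$units, x$spec$n_lat, x$spec$n_lon, sum(is.na(x$values))
  ))
  invisible(x)
}

#' A stack of environmental layers for one period
#'
#' All layers must share one [grid_spec()].
#'
#' @param period_label Period name, e.g. `"1985"` or `"2050"`.
#' @param layers Named list of [env_grid()] objects (names = variables).
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(period_label, layers) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  spec <- layers[[1]]$spec
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "env_grid")) stop("layers must be env_grid objects")
    if (!same_spec(layers[[nm]]$spec, spec)) stop("all layers must share one grid spec")
    if (!identical(layers[[nm]]$variable, nm)) {
      stop(sprintf("layer name '%s' does not match its variable '%s'",
                   nm, layers[[nm]]$variable))
    }
  }
  structure(list(period_label = period_label, spec = spec, layers = layers),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> period %s: %s\n", x$period_label,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Sea mask of an environmental stack
#'
#' A cell counts as sea when its SST layer (or, failing that, the first
#' layer) is non-missing.
#'
#' @param env An [env_stack()].
#' @return Logical matrix, `TRUE` on sea cells.
#' @export
sea_mask <- function(env) {
  ref <- if ("sst" %in% names(env$layers)) env$layers$sst else env$layers[[1]]
  !is.na(ref$values)
}

#' A boolean region membership mask
#'
#' @param spec A [grid_spec()].
#' @param member Logical matrix `n_lat x n_lon`.
#' @param label Region label (basin or polygon id).
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(spec, member, label) {
  member <- as.matrix(member)
  if (!all(dim(member) == c(spec$n_lat, spec$n_lon))) {
    stop("member mask shape must match the grid spec")
  }
  structure(list(spec = spec, member = member, label = label), class = "region_mask")
}

#' A per-cell relative habitat suitability (or abundance) surface
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix `n_lat x n_lon`, non-negative where present,
#'   `NA` on land/missing cells.
#' @param species,model,period Labels carried through the pipeline.
#' @return An object of class `suitability_map`.
#' @export
suitability_map <- function(spec, values, species = "", model = "", period = "") {
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_lat, spec$n_lon))) {
    stop("values must match the grid spec")
  }
  if (any(values < 0, na.rm = TRUE)) stop("suitability must be non-negative")
  structure(
    list(spec = spec, values = values, species = species, model = model,
         period = period),
    class = "suitability_map"
  )
}

#' @export
print.suitability_map <- function(x, ...) {
  pos <- sum(x$values > 0, na.rm = TRUE)
  cat(sprintf("<suitability_map> %s / %s / %s: %d positive cells, max %.3g\n",
              x$species, x$model, x$period, pos,
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

nearest_index <- function(src_centers, tgt_centers) {
  # per-axis nearest neighbour; ties resolved toward the lower coordinate
  # (src_centers ascending, so the first minimiser is the lower one)
  vapply(tgt_centers, function(t) which.min(abs(src_centers - t)), integer(1))
}

#' Nearest-neighbour regridding
#'
#' Each target cell takes the value of the source cell whose center is
#' nearest (Euclidean in degrees); the lat/lon axes are independent so the
#' search is separable. Distance ties go to the lower latitude, then lower
#' longitude.
#'
#' @param grid An [env_grid()].
#' @param target Target [grid_spec()].
#' @return An [env_grid()] on `target`.
#' @export
regrid_nearest <- function(grid, target) {
  src <- grid$spec
  if (src$lat_max <= target$lat_min || target$lat_max <= src$lat_min ||
      src$lon_max <= target$lon_min || target$lon_max <= src$lon_min) {
    stop("source and target grids do not overlap")
  }
  ri <- nearest_index(lat_centers(src), lat_centers(target))
  ci <- nearest_index(lon_centers(src), lon_centers(target))
  env_grid(target, grid$variable, grid$values[ri, ci, drop = FALSE], grid$units)
}

#' Area of a grid cell in square kilometres
#'
#' `area = (K * res) * (K * res * cos(lat))` with `K` = [KM_PER_DEG];
#' even in latitude and strictly decreasing in `|lat|`.
#'
#' @param lat_center Cell-center latitude(s), degrees, `|lat| < 90`.
#' @param resolution Cell size in degrees.
#' @return Cell area(s) in square kilometres.
#' @examples
#' cell_area_km2(0, 0.5) # about 3098 km2
#' @export
cell_area_km2 <- function(lat_center, resolution) {
  stopifnot(all(abs(lat_center) < 90))
  (KM_PER_DEG * resolution)^2 * cos(lat_center * pi / 180)
}

#' Matrix of per-cell areas for a grid
#'
#' @param spec A [grid_spec()].
#' @return Numeric `n_lat x n_lon` matrix of areas in square kilometres.
#' @export
cell_area_matrix <- function(spec) {
  matrix(rep(cell_area_km2(lat_centers(spec), spec$resolution), spec$n_lon),
         nrow = spec$n_lat)
}
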