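point_on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > eps * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
  px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

point_in_polygon <- function(px, py, ring) {
  # ray casting, boundary-inclusive (a point on an edge or vertex is inside)
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) n <- n - 1  # drop closing vertex
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[j, 1]; y2 <- ring[j, 2]
    if (point_on_segment(px, py, x1, y1, x2, y2)) return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Rasterize a protected-area polygon onto the analysis grid
#'
#' Member cells are those whose centers fall inside the polygon; points on
#' the boundary count as inside (a deterministic convention).
#'
#' @param polygon A `list(name =, ring =)` polygon (closed lon/lat ring), as
#'   produced by [make_protected_areas()] or [read_polygons()].
#' @param spec A [grid_spec()].
#' @return An object of class `protected_area`: `name`, `ring`, and `cells`
#'   (integer matrix with columns `row`, `col`).
#' @export
rasterize_area <- function(polygon, spec) {
  ring <- polygon$ring
  latc <- lat_centers(spec)
  lonc <- lon_centers(spec)
  rows <- which(latc >= min(ring[, 2]) - spec$resolution &
                  latc <= max(ring[, 2]) + spec$resolution)
  cols <- which(lonc >= min(ring[, 1]) - spec$resolution &
                  lonc <= max(ring[, 1]) + spec$resolution)
  cells <- NULL
  for (r in rows) {
    for (cl in cols) {
      if (point_in_polygon(lonc[cl], latc[r], ring)) {
        cells <- rbind(cells, c(row = r, col = cl))
      }
    }
  }
  if (is.null(cells)) {
    stop("polygon ", polygon$name, " contains no grid-cell centers")
  }
  structure(list(name = polygon$name, ring = ring, cells = cells),
            class = "protected_area")
}

#' @export
print.protected_area <- function(x, ...) {
  cat(sprintf("<protected_area> %s: %d cells\n", x$name, nrow(x$cells)))
  invisible(x)
}

area_cell_values <- function(map, area) {
  map$values[area$cells]
}

#' Standardize suitability across protected areas
#'
#' Min-max rescales suitability over the pooled set of all protected-area
#' cells from BOTH periods (per species and model), mapping the pooled
#' minimum to 0 and maximum to 1. Pooling across periods keeps the
#' future-minus-baseline deltas comparable and bounded in \[-1, 1\].
#'
#' @param baseline,future [suitability_map()]s on one grid.
#' @param areas List of [protected_area][rasterize_area()] objects.
#' @return List with `std_baseline` and `std_future` (matrices, `NA` outside
#'   protected-area cells), `pooled_min`, `pooled_max`, and `areas`.
#' @export
standardize_rhs <- function(baseline, future, areas) {
  stopifnot(length(areas) >= 1)
  if (!same_spec(baseline$spec, future$spec)) stop("grid spec mismatch")
  all_cells <- do.call(rbind, lapply(areas, function(a) a$cells))
  pooled <- c(baseline$values[all_cells], future$values[all_cells])
  pooled <- pooled[!is.na(pooled)]
  if (length(unique(pooled)) < 2) {
    stop("pooled protected-area suitabilities are constant: cannot standardize")
  }
  mn <- min(pooled); mx <- max(pooled)
  spec <- baseline$spec
  std <- function(map) {
    out <- matrix(NA_real_, spec$n_lat, spec$n_lon)
    out[all_cells] <- (map$values[all_cells] - mn) / (mx - mn)
    out
  }
  list(std_baseline = std(baseline), std_future = std(future),
       pooled_min = mn, pooled_max = mx, areas = areas)
}

#' Per-area change in standardized habitat suitability
#'
#' For each protected area: the per-cell delta (future minus baseline on the
#' shared standardisation), its mean, and the mean baseline value. The
#' overall summary reports both averaging orders — the mean over area means
#' and the mean over all pooled cells — since they differ when areas have
#' unequal sizes.
#'
#' @param std Output of [standardize_rhs()].
#' @param species,model Labels copied into the report.
#' @return An object of class `rhs_report`: `by_area` data.frame (`area`,
#'   `n_cells`, `mean_baseline`, `mean_delta`), `per_cell` (named list of
#'   delta vectors), and `overall` (`mean_of_area_means`,
#'   `mean_over_cells`).
#' @export
rhs_change <- function(std, species = "", model = "") {
  delta <- std$std_future - std$std_baseline
  by_area <- do.call(rbind, lapply(std$areas, function(a) {
    d <- delta[a$cells]
    b <- std$std_baseline[a$cells]
    data.frame(
      species = species, model = model, area = a$name,
      n_cells = nrow(a$cells),
      mean_baseline = mean(b, na.rm = TRUE),
      mean_delta = mean(d, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  per_cell <- stats::setNames(
    lapply(std$areas, function(a) delta[a$cells]),
    vapply(std$areas, `[[`, character(1), "name")
  )
  all_d <- unlist(per_cell)
  structure(
    list(by_area = by_area, per_cell = per_cell,
         overall = data.frame(
           species = species, model = model,
           mean_of_area_means = mean(by_area$mean_delta, na.rm = TRUE),
           mean_over_cells = mean(all_d, na.rm = TRUE),
           stringsAsFactors = FALSE
         )),
    class = "rhs_report"
  )
}

#' @export
print.rhs_report <- function(x, ...) {
  cat(sprintf("<rhs_report> %s / %s: %d areas, mean delta %.4f\n",
              x$overall$species, x$overall$model, nrow(x$by_area),
              x$overall$mean_of_area_means))
  invisible(x)
}
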