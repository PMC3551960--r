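#' Latitudinal centroid of a distribution
#'
#' Abundance-weighted mean latitude over non-missing cells:
#' `L = sum(L_i * Abd_i) / sum(Abd_i)` with `L_i` the cell-center latitude
#' and `Abd_i` the cell's suitability (or simulated abundance). Suitability
#' enters unweighted by cell area (an area-weighted variant is available via
#' `area_weighted = TRUE` and documented as a deviation).
#'
#' @param map A [suitability_map()] with positive total abundance.
#' @param area_weighted Weight each cell by its area in km2 (default FALSE).
#' @return Centroid latitude in degrees north.
#' @export
latitudinal_centroid <- function(map, area_weighted = FALSE) {
  w <- map$values
  if (area_weighted) w <- w * cell_area_matrix(map$spec)
  tot <- sum(w, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) stop("all-zero map: centroid undefined")
  lat <- matrix(rep(lat_centers(map$spec), map$spec$n_lon), map$spec$n_lat)
  sum(lat * w, na.rm = TRUE) / tot
}

#' Centroid shift in kilometres
#'
#' `shift = (L_future - L_baseline) * K` with `K` = [KM_PER_DEG]. Positive
#' values are poleward in the northern hemisphere; negative equatorward.
#'
#' @param centroid_baseline,centroid_future Centroid latitudes, degrees N.
#' @return Shift in km (signed).
#' @examples
#' centroid_shift_km(55, 56) # 111.32
#' @export
centroid_shift_km <- function(centroid_baseline, centroid_future) {
  stopifnot(is.finite(centroid_baseline), is.finite(centroid_future))
  (centroid_future - centroid_baseline) * KM_PER_DEG
}

#' Range area above a threshold
#'
#' Sum of cell areas (km2) over cells whose thresholded suitability is
#' positive.
#'
#' @param map A [suitability_map()].
#' @param t Threshold in \[0, 1\] (default 0).
#' @return Area in km2.
#' @export
range_area <- function(map, t = 0) {
  vals <- apply_threshold(map, t)$values
  sum(cell_area_matrix(map$spec)[!is.na(vals) & vals > 0])
}

#' Range loss, gain and net change between periods
#'
#' Set membership is thresholded suitability > 0. Loss is the current-range
#' area absent from the (full-dispersal) future range, as a percent of the
#' current area — the area lost even under no dispersal. Gain is the newly
#' suitable area as a percent of the current area — realised only under full
#' dispersal. `net_pct = gain_pct - loss_pct`.
#'
#' @param current,future [suitability_map()]s on one grid.
#' @param t Threshold in \[0, 1\].
#' @return A one-row data.frame: `species, model, area_baseline_km2,
#'   loss_pct, gain_pct, net_pct`.
#' @export
range_change <- function(current, future, t = 0) {
  if (!same_spec(current$spec, future$spec)) stop("grid spec mismatch")
  cur <- apply_threshold(current, t)$values
  fut <- apply_threshold(future, t)$values
  in_cur <- !is.na(cur) & cur > 0
  in_fut <- !is.na(fut) & fut > 0
  areas <- cell_area_matrix(current$spec)
  a_cur <- sum(areas[in_cur])
  if (a_cur == 0) stop("current range is empty: change undefined")
  loss <- 100 * sum(areas[in_cur & !in_fut]) / a_cur
  gain <- 100 * sum(areas[in_fut & !in_cur]) / a_cur
  data.frame(
    species = current$species, model = current$model,
    area_baseline_km2 = a_cur,
    loss_pct = loss, gain_pct = gain, net_pct = gain - loss,
    stringsAsFactors = FALSE
  )
}

#' Schoener's D overlap between two distributions
#'
#' Each map is normalised to sum to 1 over the cells where both are
#' non-missing (model outputs are relative suitabilities, not probabilities,
#' so normalisation is required before the index applies); then
#' `D = 1 - 0.5 * sum(|p_x - p_y|)`, ranging from 0 (disjoint supports) to 1
#' (identical distributions). Symmetric and invariant to positive rescaling
#' of either map.
#'
#' @param map_x,map_y [suitability_map()]s on one grid, each with positive
#'   total over the shared cells.
#' @return D in \[0, 1\].
#' @export
schoener_d <- function(map_x, map_y) {
  if (!same_spec(map_x$spec, map_y$spec)) stop("grid spec mismatch")
  shared <- !is.na(map_x$values) & !is.na(map_y$values)
  x <- map_x$values[shared]
  y <- map_y$values[shared]
  sx <- sum(x); sy <- sum(y)
  if (sx <= 0 || sy <= 0) stop("zero-sum map over shared cells: D undefined")
  d <- 1 - 0.5 * sum(abs(x / sx - y / sy))
  min(max(d, 0), 1)  # guard rounding at the boundaries
}

#' Percent change in overlap with a damping offset
#'
#' `100 * (D_future - D_baseline) / (D_baseline + 0.1)`. The 0.1 added to the
#' baseline value keeps percentages from exploding when the baseline overlap
#' is near zero.
#'
#' @param D_baseline,D_future Overlap values in \[0, 1\].
#' @param offset Damping offset added to the baseline (default 0.1).
#' @return Percent change.
#' @examples
#' overlap_change_pct(0.4, 0.5) # +20
#' @export
overlap_change_pct <- function(D_baseline, D_future, offset = 0.1) {
  stopifnot(all(D_baseline >= 0 & D_baseline <= 1),
            all(D_future >= 0 & D_future <= 1))
  100 * (D_future - D_baseline) / (D_baseline + offset)
}
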