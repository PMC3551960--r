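#' Clip a suitability map by regions and depth
#'
#' Suitability is zeroed outside the union of allowed regions (an empty
#' region list means no region clip) and wherever depth exceeds
#' `max_depth * depth_inflation`. The default inflation of 1.5 widens the
#' species' reported depth limit by 50% so deepening under warming is not
#' cut off, and the same rule must be applied to baseline and future maps so
#' the clip does not manufacture between-period differences.
#'
#' @param map A [suitability_map()].
#' @param depth Bathymetry [env_grid()] on the same grid.
#' @param max_depth Species maximum depth, m (> 0).
#' @param regions List of [region_mask()]s whose union is retained; `list()`
#'   disables the region clip.
#' @param depth_inflation Multiplier (>= 1) on `max_depth` (default 1.5).
#' @return The clipped [suitability_map()].
#' @export
apply_clip <- function(map, depth, max_depth, regions = list(),
                       depth_inflation = 1.5) {
  stopifnot(max_depth > 0, depth_inflation >= 1)
  if (!same_spec(map$spec, depth$spec)) stop("depth grid spec mismatch")
  vals <- map$values
  too_deep <- !is.na(depth$values) &
    depth$values > max_depth * depth_inflation
  vals[too_deep & !is.na(vals)] <- 0
  if (length(regions) > 0) {
    allowed <- Reduce(`|`, lapply(regions, function(r) {
      if (!same_spec(r$spec, map$spec)) {
        stop("region mask spec mismatch: ", r$label)
      }
      r$member
    }))
    vals[!allowed & !is.na(vals)] <- 0
  }
  suitability_map(map$spec, vals, map$species, map$model, map$period)
}

#' Select the maximum sensitivity-plus-specificity threshold
#'
#' Candidate thresholds are the unique predicted values at the held-out test
#' presence cells. Sensitivity at `t` is the fraction of test presences with
#' suitability `>= t`; specificity is the fraction of background cells not in
#' the test presence set with suitability `< t` (presence-only data, so
#' background non-presences act as pseudo-absences). Returns the candidate
#' maximising their sum; ties go to the smallest threshold. When the map is
#' constant over test and background cells there is nothing to discriminate:
#' that value is returned with `attr(, "no_discrimination") = TRUE` and a
#' warning.
#'
#' @param map A [suitability_map()] (typically the clipped baseline map).
#' @param test_presence A [presence_grid()] of held-out presences.
#' @param background A [region_mask()] of evaluation cells.
#' @return The chosen threshold, with attributes `sensitivity`,
#'   `specificity`, and `no_discrimination`.
#' @export
select_max_ss_threshold <- function(map, test_presence, background) {
  if (!same_spec(map$spec, test_presence$spec) ||
      !same_spec(map$spec, background$spec)) {
    stop("grid spec mismatch")
  }
  pres <- which(test_presence$present)
  if (length(pres) == 0) stop("test presence set is empty")
  bg_abs <- which(background$member & !test_presence$present)
  if (length(bg_abs) == 0) stop("background minus presences is empty")
  v_pres <- map$values[pres]
  v_abs <- map$values[bg_abs]
  v_pres <- v_pres[!is.na(v_pres)]
  v_abs <- v_abs[!is.na(v_abs)]
  if (length(v_pres) == 0) stop("test presences all fall on missing cells")

  cands <- sort(unique(v_pres))
  if (length(unique(c(v_pres, v_abs))) == 1) {
    warning("map has no discrimination: all evaluated values identical")
    out <- cands[1]
    attr(out, "sensitivity") <- 1
    attr(out, "specificity") <- 0
    attr(out, "no_discrimination") <- TRUE
    return(out)
  }
  sens <- vapply(cands, function(t) mean(v_pres >= t), numeric(1))
  spc <- vapply(cands, function(t) mean(v_abs < t), numeric(1))
  best <- which.max(sens + spc)  # which.max takes the first (smallest) tie
  out <- cands[best]
  attr(out, "sensitivity") <- sens[best]
  attr(out, "specificity") <- spc[best]
  attr(out, "no_discrimination") <- FALSE
  out
}

#' Apply a suitability threshold
#'
#' Values below `t` become 0; values at or above `t` are kept unchanged, so
#' the thresholded map still carries relative suitability in the core range.
#'
#' @param map A [suitability_map()].
#' @param t Threshold in \[0, 1\].
#' @return The thresholded [suitability_map()].
#' @export
apply_threshold <- function(map, t) {
  stopifnot(t >= 0, t <= 1)
  vals <- map$values
  vals[!is.na(vals) & vals < t] <- 0
  suitability_map(map$spec, vals, map$species, map$model, map$period)
}

#' Impose a dispersal scenario on a future prediction
#'
#' Under `full_dispersal` the future map is returned unchanged (the species
#' may occupy all newly suitable habitat). Under `no_dispersal` the future
#' map is zeroed outside the thresholded current range, restricting the
#' species to cells it already occupies.
#'
#' @param current,future [suitability_map()]s on one grid from the same
#'   model.
#' @param scenario `"no_dispersal"` or `"full_dispersal"`.
#' @param t Threshold defining the current range (cells with thresholded
#'   current suitability > 0).
#' @return The scenario-adjusted future [suitability_map()].
#' @export
apply_dispersal_scenario <- function(current, future,
                                     scenario = c("full_dispersal",
                                                  "no_dispersal"),
                                     t = 0) {
  scenario <- match.arg(scenario)
  if (!same_spec(current$spec, future$spec)) stop("grid spec mismatch")
  if (scenario == "full_dispersal") return(future)
  cur_range <- apply_threshold(current, t)$values
  inside <- !is.na(cur_range) & cur_range > 0
  vals <- future$values
  vals[!is.na(vals) & !inside] <- 0
  suitability_map(future$spec, vals, future$species, future$model,
                  future$period)
}
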