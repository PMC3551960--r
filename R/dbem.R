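#' Parameters of the dynamic bioclimate envelope simulation
#'
#' @param r Intrinsic logistic growth rate, per year (>= 0; default 0.5; 0
#'   gives a pure-dispersal model useful for mass-balance checks).
#' @param d Dispersal fraction exchanged with neighbours per year, in
#'   \[0, 1\] (default 0.1).
#' @param K_scale Carrying-capacity scale, abundance units (default 1).
#' @param start_year,end_year Simulation window (annual steps).
#' @param n_bins Number of preference-profile bins per variable (default 20).
#' @return An object of class `dbem_params`.
#' @export
dbem_params <- function(r = 0.5, d = 0.1, K_scale = 1,
                        start_year = 1985, end_year = 2050, n_bins = 20) {
  stopifnot(r >= 0, d >= 0, d <= 1, K_scale > 0, end_year >= start_year,
            n_bins >= 1)
  structure(list(r = r, d = d, K_scale = K_scale,
                 start_year = start_year, end_year = end_year, n_bins = n_bins),
            class = "dbem_params")
}

#' Derive per-variable preference profiles from a seed distribution
#'
#' Bins each variable's values over sea cells into `n_bins` equal-width bins
#' and scores every bin by the suitability-weighted cell count, normalised so
#' the best bin equals 1.
#'
#' @param seed_distribution A [suitability_map()] with at least one positive
#'   cell.
#' @param env An [env_stack()].
#' @param n_bins Number of bins (>= 1; a single bin gives a flat profile).
#' @param variables Variables to profile.
#' @return Named list of profiles: `list(variable, bin_edges, values)`.
#' @export
derive_profiles <- function(seed_distribution, env, n_bins = 20,
                            variables = c("sst", "sbt", "salinity")) {
  w_all <- as.vector(seed_distribution$values)
  if (all(is.na(w_all)) || sum(w_all, na.rm = TRUE) == 0) {
    stop("seed distribution has no positive cells")
  }
  profiles <- list()
  for (v in variables) {
    layer <- env$layers[[v]]
    if (is.null(layer)) stop("env stack lacks variable: ", v)
    vals <- as.vector(layer$values)
    ok <- !is.na(vals) & !is.na(w_all)
    rng <- range(vals[ok])
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)  # constant layer: one wide bin
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(vals[ok], edges, rightmost.closed = TRUE)
    wsum <- vapply(seq_len(n_bins), function(b) sum(w_all[ok][bin == b]),
                   numeric(1))
    if (max(wsum) == 0) stop("seed distribution is zero wherever ", v,
                             " is observed")
    profiles[[v]] <- list(variable = v, bin_edges = edges,
                          values = wsum / max(wsum))
  }
  profiles
}

profile_value <- function(profile, v) {
  out <- numeric(length(v))
  ok <- !is.na(v)
  bin <- findInterval(v[ok], profile$bin_edges, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= length(profile$values)
  vals <- numeric(sum(ok))
  vals[inside] <- profile$values[bin[inside]]
  out[ok] <- vals
  out[!ok] <- NA
  out
}

#' Carrying capacity from preference profiles
#'
#' `K_i = K_scale * geometric mean over variables of the profile value` at
#' cell i; variable values outside every bin score 0, and K is 0 on land.
#'
#' @param profiles Profiles from [derive_profiles()].
#' @param env An [env_stack()].
#' @param K_scale Carrying-capacity scale.
#' @return Numeric `n_lat x n_lon` matrix of carrying capacities (0 on land).
#' @export
carrying_capacity <- function(profiles, env, K_scale = 1) {
  spec <- env$spec
  k <- length(profiles)
  prod_s <- matrix(1, spec$n_lat, spec$n_lon)
  for (v in names(profiles)) {
    pv <- profile_value(profiles[[v]], as.vector(env$layers[[v]]$values))
    prod_s <- prod_s * matrix(pv, spec$n_lat, spec$n_lon)
  }
  K <- K_scale * prod_s^(1 / k)
  K[!sea_mask(env) | is.na(K)] <- 0
  K
}

#' One annual step of the dynamic bioclimate envelope model
#'
#' Growth is logistic toward the local carrying capacity
#' (`A' = A + r A (1 - A/K)`; where `K = 0`, `A' = max(A (1 - r), 0)`),
#' followed by dispersal as a symmetric exchange: each pair of 4-neighbour
#' sea cells swaps a fraction `d/4` of each member's post-growth abundance.
#' The exchange formulation conserves total abundance exactly and gives
#' no-flux boundaries at land and domain edges.
#'
#' @param state List with `year`, abundance matrix `A` and carrying-capacity
#'   matrix `K` (class `dbem_state`).
#' @param K_next Carrying-capacity matrix for the incremented year.
#' @param params A [dbem_params()].
#' @param sea Logical sea mask (abundance moves only between sea cells).
#' @return Updated `dbem_state`.
#' @export
step_dbem <- function(state, K_next, params, sea) {
  A <- state$A; K <- state$K
  r <- params$r; d <- params$d
  grown <- A
  pos <- K > 0
  grown[pos] <- A[pos] + r * A[pos] * (1 - A[pos] / K[pos])
  grown[!pos] <- pmax(A[!pos] * (1 - r), 0)
  grown[grown < 0] <- 0
  grown[!sea] <- 0
  if (any(!is.finite(grown[sea]))) {
    stop("non-finite abundance: simulation unstable; reduce r or d")
  }

  A2 <- grown
  n_lat <- nrow(A); n_lon <- ncol(A)
  if (d > 0) {
    exchange <- function(ra, ca, rb, cb) {
      # symmetric d/4 exchange between cell sets a and b (both sea)
      both <- sea[ra, ca, drop = FALSE] & sea[rb, cb, drop = FALSE]
      fa <- (d / 4) * grown[ra, ca, drop = FALSE] * both
      fb <- (d / 4) * grown[rb, cb, drop = FALSE] * both
      A2[ra, ca] <<- A2[ra, ca, drop = FALSE] - fa + fb
      A2[rb, cb] <<- A2[rb, cb, drop = FALSE] - fb + fa
    }
    if (n_lat > 1) exchange(1:(n_lat - 1), 1:n_lon, 2:n_lat, 1:n_lon)
    if (n_lon > 1) exchange(1:n_lat, 1:(n_lon - 1), 1:n_lat, 2:n_lon)
  }

  structure(list(year = state$year + 1L, A = A2, K = K_next),
            class = "dbem_state")
}

interp_stack <- function(baseline, future, frac) {
  layers <- lapply(names(baseline$layers), function(v) {
    b <- baseline$layers[[v]]
    f <- future$layers[[v]]
    env_grid(b$spec, v, b$values + frac * (f$values - b$values), b$units)
  })
  env_stack(sprintf("interp_%0.3f", frac), stats::setNames(layers, names(baseline$layers)))
}

#' Run the dynamic bioclimate envelope simulation
#'
#' Derives preference profiles from the seed distribution on the baseline
#' environment, initialises abundance at the baseline carrying capacity, and
#' steps annually from `start_year` to `end_year` while each environmental
#' layer is interpolated linearly between the baseline and future stacks
#' (period-average endpoint states standing in for yearly climate output).
#'
#' @param seed_distribution A [suitability_map()] for the baseline period.
#' @param baseline,future [env_stack()]s sharing one grid and land mask.
#' @param params A [dbem_params()].
#' @param variables Variables used for the preference profiles.
#' @return List with `map` (end-year abundance rescaled to \[0, 1\] as a
#'   [suitability_map()]), `trajectory` (data.frame `year`,
#'   `total_abundance`, `centroid`), and `profiles`.
#' @export
run_dbem <- function(seed_distribution, baseline, future, params,
                     variables = c("sst", "sbt", "salinity")) {
  if (!same_spec(baseline$spec, future$spec)) {
    stop("baseline and future stacks must share one grid spec")
  }
  sea <- sea_mask(baseline)
  profiles <- derive_profiles(seed_distribution, baseline, params$n_bins,
                              variables)
  K0 <- carrying_capacity(profiles, baseline, params$K_scale)
  state <- structure(list(year = params$start_year, A = K0, K = K0),
                     class = "dbem_state")
  years <- params$start_year:params$end_year
  span <- params$end_year - params$start_year
  traj <- data.frame(year = years, total_abundance = NA_real_,
                     centroid = NA_real_)
  record <- function(i, A) {
    traj$total_abundance[i] <<- sum(A)
    m <- A; m[!sea] <- NA
    traj$centroid[i] <<- latitudinal_centroid(
      suitability_map(baseline$spec, m)
    )
  }
  record(1, state$A)
  if (span > 0) {
    for (i in seq_len(span)) {
      env_next <- interp_stack(baseline, future, i / span)
      K_next <- carrying_capacity(profiles, env_next, params$K_scale)
      state <- step_dbem(state, K_next, params, sea)
      record(i + 1, state$A)
    }
  }
  A <- state$A
  mx <- max(A)
  vals <- if (mx > 0) A / mx else A
  vals[!sea] <- NA
  list(
    map = suitability_map(baseline$spec, vals,
                          species = seed_distribution$species,
                          model = "dbem", period = future$period_label),
    trajectory = traj,
    profiles = profiles
  )
}
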