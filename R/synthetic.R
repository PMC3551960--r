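with_seed <- function(seed, code) {
  # run code under a local RNG stream without disturbing global state
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameters of a synthetic shelf-sea climate scenario
#'
#' The default scenario emulates a temperate shelf sea: a 0.5-degree grid over
#' 45-70N, 10W-10E; baseline SST falling linearly from 14 C at the
#' equatorward edge to 4 C at the poleward edge; sea bottom temperature
#' tracking SST with a small offset (shallow, well-mixed water column); mean
#' depth near 90 m (50 m shelf deepening offshore at 2 m per cell); and a
#' future period warmer than the baseline by a uniform `warming_delta`
#' (default 1.27 C, a plausible mid-century shelf-sea warming; 0.77 C is a
#' comparable second scenario).
#'
#' @param spec Grid ([grid_spec()]).
#' @param sst_equator,sst_pole Baseline SST (C) at the equatorward/poleward
#'   row centers.
#' @param warming_delta Future minus baseline mean SST, C.
#' @param sbt_offset SST minus SBT, C.
#' @param depth_shelf Depth at the coast-adjacent cell, m.
#' @param depth_slope Deepening per cell away from the coast, m.
#' @param noise_sd SD of cell-level Gaussian SST noise, C (shared by both
#'   periods, so the warming delta is exact).
#' @param land_fraction Fraction of eastern columns that are land, in \[0, 1).
#' @param seed Integer RNG seed.
#' @return An object of class `scenario_params`.
#' @export
scenario_params <- function(spec = grid_spec(45, 70, -10, 10, 0.5),
                            sst_equator = 14, sst_pole = 4,
                            warming_delta = 1.27, sbt_offset = 0.5,
                            depth_shelf = 50, depth_slope = 2,
                            noise_sd = 0.5, land_fraction = 0.1, seed = 1) {
  stopifnot(is.finite(warming_delta), noise_sd >= 0,
            land_fraction >= 0, land_fraction < 1,
            depth_shelf >= 0, depth_slope >= 0)
  structure(
    list(spec = spec, sst_equator = sst_equator, sst_pole = sst_pole,
         warming_delta = warming_delta, sbt_offset = sbt_offset,
         depth_shelf = depth_shelf, depth_slope = depth_slope,
         noise_sd = noise_sd, land_fraction = land_fraction, seed = seed),
    class = "scenario_params"
  )
}

#' Generate a baseline/future pair of environmental stacks
#'
#' Baseline SST is a linear latitudinal gradient plus Gaussian cell noise;
#' future SST adds a uniform warming delta to the same field (so the sea-cell
#' mean difference equals the delta exactly). SBT = SST - offset. Depth,
#' salinity, primary productivity and distance-to-coast depend only on the
#' (seed-deterministic) coastline; sea-ice concentration is a deterministic
#' function of the period's SST. Both periods share one land mask.
#'
#' @param params A [scenario_params()].
#' @param period_labels Labels of the two periods.
#' @return List with elements `baseline` and `future`, both [env_stack()].
#' @export
make_env_scenario <- function(params,
                              period_labels = c("1985", "2050")) {
  spec <- params$spec
  if (spec$n_lat < 2) stop("degenerate grid: need at least 2 latitude rows")
  n_lat <- spec$n_lat; n_lon <- spec$n_lon
  latc <- lat_centers(spec)

  n_land <- round(params$land_fraction * n_lon)
  land_cols <- if (n_land > 0) (n_lon - n_land + 1):n_lon else integer(0)
  sea <- matrix(TRUE, n_lat, n_lon)
  if (n_land > 0) sea[, land_cols] <- FALSE

  # cells to the nearest coast: eastern land band if present, else east edge
  coast_col <- if (n_land > 0) n_lon - n_land + 1 else n_lon + 1
  cells_to_coast <- matrix(rep(coast_col - seq_len(n_lon), each = n_lat),
                           n_lat, n_lon)

  frac <- (latc - latc[1]) / (latc[n_lat] - latc[1])
  sst_grad <- matrix(rep(params$sst_equator +
                           (params$sst_pole - params$sst_equator) * frac, n_lon),
                     n_lat, n_lon)
  noise <- with_seed(params$seed, {
    matrix(stats::rnorm(n_lat * n_lon, 0, params$noise_sd), n_lat, n_lon)
  })
  sst_base <- sst_grad + noise
  sst_fut <- sst_base + params$warming_delta

  depth <- params$depth_shelf + params$depth_slope * cells_to_coast
  salinity <- 34 + 0.03 * cells_to_coast
  npp <- 300 + 500 * exp(-cells_to_coast / 15)
  dist_coast <- cells_to_coast * spec$resolution * KM_PER_DEG
  ice_of <- function(sst) pmin(pmax((0 - sst) / 2, 0), 1)

  mask <- function(v) { v[!sea] <- NA; v }
  build <- function(label, sst) {
    env_stack(label, list(
      sst = env_grid(spec, "sst", mask(sst), "degC"),
      sbt = env_grid(spec, "sbt", mask(sst - params$sbt_offset), "degC"),
      salinity = env_grid(spec, "salinity", mask(salinity), "psu"),
      ice = env_grid(spec, "ice", mask(ice_of(sst)), "fraction"),
      npp = env_grid(spec, "npp", mask(npp), "mgC m-2 d-1"),
      depth = env_grid(spec, "depth", mask(depth), "m"),
      dist_coast = env_grid(spec, "dist_coast", mask(dist_coast), "km")
    ))
  }
  list(baseline = build(period_labels[1], sst_base),
       future = build(period_labels[2], sst_fut))
}

#' Define a virtual species by its true environmental envelope
#'
#' Each variable gets a trapezoid `(min_abs, pref_min, pref_max, max_abs)`:
#' suitability 0 outside the absolute limits, 1 on the preferred plateau,
#' linear ramps between.
#'
#' @param name Species label.
#' @param envelope Named list; each element a length-4 ascending numeric
#'   vector per variable.
#' @param depth_limit Maximum depth (m) the species tolerates.
#' @param detectability Sampling detectability in \[0, 1\].
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(name, envelope, depth_limit = Inf,
                            detectability = 1) {
  stopifnot(length(envelope) >= 1, !is.null(names(envelope)),
            detectability >= 0, detectability <= 1)
  for (v in names(envelope)) {
    tz <- envelope[[v]]
    if (length(tz) != 4 || is.unsorted(tz)) {
      stop("envelope for ", v, " must be 4 ascending numbers ",
           "(min_abs, pref_min, pref_max, max_abs)")
    }
  }
  structure(list(name = name, envelope = envelope, depth_limit = depth_limit,
                 detectability = detectability),
            class = "virtual_species")
}

trapezoid_suit <- function(v, tz) {
  a <- tz[1]; b <- tz[2]; cc <- tz[3]; d <- tz[4]
  s <- numeric(length(v))
  s[!is.na(v) & v >= b & v <= cc] <- 1
  if (b > a) {
    i <- !is.na(v) & v >= a & v < b
    s[i] <- (v[i] - a) / (b - a)
  }
  if (d > cc) {
    i <- !is.na(v) & v > cc & v <= d
    s[i] <- (d - v[i]) / (d - cc)
  }
  s[is.na(v)] <- NA
  s
}

#' True suitability of a virtual species over an environmental stack
#'
#' Product over envelope variables of the per-variable trapezoid, zeroed
#' beyond the species' depth limit (when a depth layer is present).
#'
#' @param species A [virtual_species()].
#' @param env An [env_stack()].
#' @return A [suitability_map()] (values in \[0, 1\]).
#' @export
true_suitability <- function(species, env) {
  spec <- env$spec
  s <- matrix(1, spec$n_lat, spec$n_lon)
  for (v in names(species$envelope)) {
    if (is.null(env$layers[[v]])) stop("env stack lacks variable: ", v)
    sv <- trapezoid_suit(as.vector(env$layers[[v]]$values), species$envelope[[v]])
    s <- s * matrix(sv, spec$n_lat, spec$n_lon)
  }
  if (is.finite(species$depth_limit) && !is.null(env$layers$depth)) {
    s[!is.na(env$layers$depth$values) &
        env$layers$depth$values > species$depth_limit] <- 0
  }
  s[!sea_mask(env)] <- NA
  suitability_map(spec, s, species = species$name, model = "truth",
                  period = env$period_label)
}

#' Sample presence-only occurrence records from a virtual species
#'
#' Cells are drawn (with replacement) with probability proportional to the
#' species' true suitability times its detectability; each record is jittered
#' uniformly within its cell. Years are uniform on `year_range` (default
#' 1971-2000, a typical training window for period-averaged climatologies)
#' and sources mimic public occurrence databases.
#'
#' @param species A [virtual_species()].
#' @param env An [env_stack()].
#' @param n Number of records (>= 1).
#' @param seed Integer RNG seed.
#' @param year_range Length-2 integer vector of sampling years.
#' @return Data.frame with columns `species, lon, lat, year, source`.
#' @export
sample_occurrences <- function(species, env, n, seed,
                               year_range = c(1971, 2000)) {
  stopifnot(n >= 1)
  if (species$detectability == 0) {
    stop("species has zero detectability: no records can be sampled")
  }
  suit <- true_suitability(species, env)
  w <- as.vector(suit$values) * species$detectability
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("species has no suitable cells in this environment")
  spec <- env$spec
  with_seed(seed, {
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    row <- (idx - 1) %% spec$n_lat + 1
    col <- (idx - 1) %/% spec$n_lat + 1
    res <- spec$resolution
    data.frame(
      species = species$name,
      lon = spec$lon_min + (col - 1) * res + stats::runif(n) * res,
      lat = spec$lat_min + (row - 1) * res + stats::runif(n) * res,
      year = sample(seq(year_range[1], year_range[2]), n, replace = TRUE),
      source = sample(c("obis", "gbif", "ices"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate synthetic protected-area polygons
#'
#' Places `n_areas` non-overlapping axis-aligned rectangles of 2-5 x 2-5
#' grid cells (>= 4 cells each), labelled `cSAC_1..n`. Polygon edges follow
#' cell edges, so member cell centers are strictly interior.
#'
#' @param spec A [grid_spec()].
#' @param n_areas Number of areas (>= 1).
#' @param seed Integer RNG seed.
#' @param max_tries Placement attempts per area before giving up.
#' @return List of `list(name =, ring =)` polygons (closed lon/lat rings).
#' @export
make_protected_areas <- function(spec, n_areas, seed, max_tries = 2000) {
  stopifnot(n_areas >= 1)
  res <- spec$resolution
  occupied <- matrix(FALSE, spec$n_lat, spec$n_lon)
  with_seed(seed, {
    polys <- vector("list", n_areas)
    for (k in seq_len(n_areas)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        w <- sample(2:5, 1); h <- sample(2:5, 1)
        if (w > spec$n_lon || h > spec$n_lat) next
        c0 <- sample.int(spec$n_lon - w + 1, 1)
        r0 <- sample.int(spec$n_lat - h + 1, 1)
        rows <- r0:(r0 + h - 1); cols <- c0:(c0 + w - 1)
        if (any(occupied[rows, cols])) next
        occupied[rows, cols] <- TRUE
        lon0 <- spec$lon_min + (c0 - 1) * res
        lat0 <- spec$lat_min + (r0 - 1) * res
        ring <- cbind(
          lon = c(lon0, lon0 + w * res, lon0 + w * res, lon0, lon0),
          lat = c(lat0, lat0, lat0 + h * res, lat0 + h * res, lat0)
        )
        polys[[k]] <- list(name = sprintf("cSAC_%d", k), ring = ring)
        placed <- TRUE
        break
      }
      if (!placed) stop("grid too small to place ", n_areas,
                        " non-overlapping protected areas")
    }
    polys
  })
}
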