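# shared fixture builders (all fixtures are generated in code)

test_spec <- function(n_lat = 8, n_lon = 8, res = 0.5,
                      lat_min = 50, lon_min = 0) {
  grid_spec(lat_min, lat_min + n_lat * res, lon_min, lon_min + n_lon * res, res)
}

# a suitability map with seeded positive values (optionally with NA cells)
rand_map <- function(spec, seed, na_cells = integer(0), species = "sp",
                     model = "m", period = "p") {
  vals <- with_seed_test(seed, matrix(stats::runif(spec$n_lat * spec$n_lon),
                                      spec$n_lat, spec$n_lon))
  vals[na_cells] <- NA
  suitability_map(spec, vals, species, model, period)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# small noise-free scenario used across model tests
quiet_scenario <- function(spec = grid_spec(45, 70, -10, 10, 0.5),
                           warming_delta = 1.27, land_fraction = 0.1,
                           seed = 1) {
  make_env_scenario(scenario_params(
    spec = spec, warming_delta = warming_delta, noise_sd = 0,
    land_fraction = land_fraction, seed = seed
  ))
}

# scenario whose uniform warming equals an exact k-row poleward translation
# of the thermal field (linear gradient, no noise)
shifted_scenario <- function(k_rows = 3, spec = grid_spec(45, 70, -10, 10, 0.5),
                             sst_equator = 14, sst_pole = 4, seed = 1) {
  step <- (sst_equator - sst_pole) / (spec$n_lat - 1)
  make_env_scenario(scenario_params(
    spec = spec, sst_equator = sst_equator, sst_pole = sst_pole,
    warming_delta = k_rows * step, noise_sd = 0, land_fraction = 0.1,
    seed = seed
  ))
}

# presence grid from explicit cell indices
presence_from_cells <- function(spec, cells, species = "sp") {
  m <- matrix(FALSE, spec$n_lat, spec$n_lon)
  m[cells] <- TRUE
  presence_grid(spec, m, species)
}
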