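uniform_env <- function(spec, sst = 10, land_cols = integer(0)) {
  v <- matrix(sst, spec$n_lat, spec$n_lon)
  if (length(land_cols)) v[, land_cols] <- NA
  env_stack("1985", list(sst = env_grid(spec, "sst", v)))
}

test_that("preference profiles recover an indicator seed distribution", {
  sc <- quiet_scenario(land_fraction = 0)
  env <- sc$baseline
  sst <- env$layers$sst$values
  seed_vals <- ifelse(!is.na(sst) & sst >= 9 & sst <= 11, 1, 0)
  seed_map <- suitability_map(env$spec, seed_vals)
  prof <- derive_profiles(seed_map, env, n_bins = 20, variables = "sst")$sst
  mids <- (prof$bin_edges[-1] + prof$bin_edges[-21]) / 2
  inside <- mids >= 9 & mids <= 11
  expect_true(all(prof$values[inside] > 0))
  # bins wholly outside [9, 11] carry no weight (edge bins may straddle)
  strict_out <- prof$bin_edges[-1] < 9 | prof$bin_edges[-21] > 11
  expect_true(all(prof$values[strict_out] == 0))
  expect_equal(max(prof$values), 1)
})

test_that("single positive cell and single-bin profiles behave as declared", {
  spec <- test_spec(4, 4)
  env <- uniform_env(spec, sst = 10)
  env$layers$sst$values[] <- matrix(seq(8, 11.75, by = 0.25), 4, 4)
  one <- matrix(0, 4, 4); one[2, 2] <- 0.7
  prof <- derive_profiles(suitability_map(spec, one), env, n_bins = 8,
                          variables = "sst")$sst
  expect_equal(sum(prof$values > 0), 1)
  expect_equal(max(prof$values), 1)

  flat <- derive_profiles(suitability_map(spec, matrix(1, 4, 4)), env,
                          n_bins = 1, variables = "sst")$sst
  expect_equal(flat$values, 1)
  expect_error(derive_profiles(suitability_map(spec, matrix(0, 4, 4)), env),
               "no positive cells")
})

test_that("carrying capacity combines profiles by geometric mean", {
  spec <- test_spec(1, 2)
  env <- env_stack("p", list(
    sst = env_grid(spec, "sst", matrix(c(10, 10), 1, 2)),
    sbt = env_grid(spec, "sbt", matrix(c(8, 20), 1, 2))
  ))
  profiles <- list(
    sst = list(variable = "sst", bin_edges = c(9, 11), values = 1),
    sbt = list(variable = "sbt", bin_edges = c(7, 9), values = 0.25)
  )
  K <- carrying_capacity(profiles, env, K_scale = 2)
  expect_equal(K[1, 1], 2 * sqrt(1 * 0.25))  # K_scale * sqrt(1 * 0.25)
  expect_equal(K[1, 2], 0)                   # sbt outside all bins
  profiles$sbt$values <- 1
  K2 <- carrying_capacity(profiles, env, K_scale = 1)
  expect_equal(K2[1, 1], 1)                  # max bin for all variables
})

test_that("a homogeneous population at carrying capacity is a fixed point", {
  spec <- test_spec(6, 6)
  sea <- matrix(TRUE, 6, 6)
  K <- matrix(0.8, 6, 6)
  state <- structure(list(year = 2000L, A = K, K = K), class = "dbem_state")
  out <- step_dbem(state, K, dbem_params(r = 0.5, d = 0.3), sea)
  expect_equal(out$A, K)
  expect_equal(out$year, 2001L)
})

test_that("without dispersal each cell follows the scalar logistic map", {
  spec <- test_spec(3, 3)
  sea <- matrix(TRUE, 3, 3)
  K <- matrix(1, 3, 3)
  A <- matrix(0.05, 3, 3)
  state <- structure(list(year = 0L, A = A, K = K), class = "dbem_state")
  scalar <- 0.05
  r <- 0.5
  for (i in 1:30) {
    state <- step_dbem(state, K, dbem_params(r = r, d = 0), sea)
    scalar <- scalar + r * scalar * (1 - scalar)
    expect_equal(state$A[2, 2], scalar)
  }
  expect_lt(abs(state$A[1, 1] - 1), 1e-3)  # monotone logistic approach to K
})

test_that("pure dispersal conserves total abundance to 1e-9 relative", {
  spec <- test_spec(10, 10)
  sea <- matrix(TRUE, 10, 10)
  sea[3:5, 6:8] <- FALSE  # irregular land: no-flux boundaries
  A <- with_seed_test(71, matrix(stats::runif(100), 10, 10))
  A[!sea] <- 0
  K <- matrix(1, 10, 10)
  state <- structure(list(year = 0L, A = A, K = K), class = "dbem_state")
  total0 <- sum(A)
  for (i in 1:50) {
    state <- step_dbem(state, K, dbem_params(r = 0, d = 0.4), sea)
  }
  expect_lt(abs(sum(state$A) - total0) / total0, 1e-9)
  expect_true(all(state$A >= 0))
  expect_true(all(state$A[!sea] == 0))
})

test_that("in a constant environment the simulation stays at equilibrium", {
  sc <- quiet_scenario()
  sp <- virtual_species("vs", list(sst = c(7, 8.5, 11, 12.5)))
  seed_map <- true_suitability(sp, sc$baseline)

  # without dispersal the capacity field is an exact fixed point
  params0 <- dbem_params(d = 0, start_year = 1985, end_year = 2015)
  run0 <- run_dbem(seed_map, sc$baseline, sc$baseline, params0)
  K0 <- carrying_capacity(run0$profiles, sc$baseline)
  expect_equal(run0$map$values[!is.na(run0$map$values)],
               (K0 / max(K0))[sea_mask(sc$baseline)], tolerance = 1e-12)
  expect_lt(diff(range(run0$trajectory$centroid)), 1e-9)

  # with dispersal the stationary state is a growth/diffusion balance that
  # stays close to the capacity field and does not drift
  params <- dbem_params(start_year = 1985, end_year = 2015)
  run <- run_dbem(seed_map, sc$baseline, sc$baseline, params)
  sea <- sea_mask(sc$baseline)
  expect_gt(stats::cor(run$map$values[sea], K0[sea]), 0.99)
  traj <- run$trajectory
  late <- traj$centroid[traj$year >= 2005]
  expect_lt(diff(range(late)), 1e-4)
})

test_that("end year equal to start year returns the normalised seed capacity", {
  sc <- quiet_scenario()
  sp <- virtual_species("vs", list(sst = c(7, 8.5, 11, 12.5)))
  seed_map <- true_suitability(sp, sc$baseline)
  params <- dbem_params(start_year = 1985, end_year = 1985)
  run <- run_dbem(seed_map, sc$baseline, sc$future, params)
  K0 <- carrying_capacity(run$profiles, sc$baseline)
  expect_equal(max(run$map$values, na.rm = TRUE), 1)
  expect_equal(nrow(run$trajectory), 1)
  expect_equal(run$map$values[5, 5], (K0 / max(K0))[5, 5])
})

test_that("poleward forcing moves the centroid poleward but not past it", {
  k <- 2
  sc <- shifted_scenario(k_rows = k)
  sp <- virtual_species("vs", list(sst = c(7, 8, 10, 11)))
  seed_map <- true_suitability(sp, sc$baseline)
  params <- dbem_params(r = 0.5, d = 0.3, start_year = 1985, end_year = 2050)
  run <- run_dbem(seed_map, sc$baseline, sc$future, params,
                  variables = c("sst", "sbt"))
  start_c <- run$trajectory$centroid[1]
  end_c <- run$trajectory$centroid[nrow(run$trajectory)]
  shift_deg <- end_c - start_c
  expect_gt(shift_deg, 0)
  # bounded by the forcing: the capacity field translates k cells; dispersal
  # smoothing at the band edges may add at most a small fraction of a cell
  expect_lte(shift_deg, k * 0.5 + 0.1 * 0.5)
})

test_that("unstable dynamics are reported, not silently propagated", {
  spec <- test_spec(3, 3)
  sea <- matrix(TRUE, 3, 3)
  A <- matrix(Inf, 3, 3)
  state <- structure(list(year = 0L, A = A, K = matrix(1, 3, 3)),
                     class = "dbem_state")
  expect_error(step_dbem(state, matrix(1, 3, 3), dbem_params(), sea),
               "unstable")
})
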