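env_from_values <- function(spec, sst_vals, extra = list()) {
  layers <- c(list(sst = env_grid(spec, "sst", matrix(sst_vals, spec$n_lat,
                                                      spec$n_lon))),
              extra)
  env_stack("train", layers)
}

test_that("fitted trapezoid knots match the linear-interpolation percentiles", {
  spec <- test_spec(5, 1)
  env <- env_from_values(spec, c(8, 9, 10, 11, 12))
  pg <- presence_from_cells(spec, 1:5)
  fit <- fit_envelope(pg, env, variables = "sst")
  expect_equal(unname(fit$trapezoids$sst),
               c(8, 8.4, 11.6, 12))
  # independent percentile oracle: manual linear interpolation at p=0.1/0.9
  x <- sort(c(8, 9, 10, 11, 12))
  h <- (length(x) - 1) * c(0.1, 0.9) + 1
  oracle <- x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  expect_equal(unname(fit$trapezoids$sst[2:3]), oracle)
})

test_that("the buffer widens absolute limits by a fraction of the pref range", {
  spec <- test_spec(5, 1)
  env <- env_from_values(spec, c(8, 9, 10, 11, 12))
  pg <- presence_from_cells(spec, 1:5)
  fit <- fit_envelope(pg, env, variables = "sst", buffer = 0.1)
  width <- 11.6 - 8.4
  expect_equal(unname(fit$trapezoids$sst[1]), 8 - 0.1 * width)
  expect_equal(unname(fit$trapezoids$sst[4]), 12 + 0.1 * width)
})

test_that("a constant variable gives a degenerate point envelope", {
  spec <- test_spec(5, 1)
  env <- env_from_values(spec, rep(10, 5))
  pg <- presence_from_cells(spec, 1:5)
  fit <- fit_envelope(pg, env, variables = "sst")
  expect_equal(unname(fit$trapezoids$sst), rep(10, 4))
  pred <- predict_envelope(fit, env)
  expect_true(all(pred$values == 1))
  env2 <- env_from_values(spec, c(10, 10, 10.5, 10, 10))
  pred2 <- predict_envelope(fit, env2)
  expect_equal(as.vector(pred2$values), c(1, 1, 0, 1, 1))
})

test_that("prediction follows the trapezoid ramps and combination rules", {
  spec <- test_spec(1, 1)
  model <- structure(list(
    species = "sp",
    trapezoids = list(sst = c(min_abs = 8, pref_min = 10, pref_max = 12,
                              max_abs = 14),
                      sbt = c(min_abs = 6, pref_min = 8, pref_max = 10,
                              max_abs = 12)),
    variables_used = c("sst", "sbt"), combination_rule = "product"
  ), class = "envelope_model")
  at <- function(sst, sbt) {
    env <- env_stack("p", list(
      sst = env_grid(spec, "sst", matrix(sst, 1, 1)),
      sbt = env_grid(spec, "sbt", matrix(sbt, 1, 1))
    ))
    predict_envelope(model, env)$values[1, 1]
  }
  expect_equal(at(11, 9), 1)       # both at preference
  expect_equal(at(9, 9), 0.5)      # halfway up the left ramp
  expect_equal(at(15, 9), 0)       # beyond max_abs: product annihilates
  expect_equal(at(9, 7), 0.25)     # two half-ramps multiply
  model$combination_rule <- "geometric_mean"
  geo <- structure(model, class = "envelope_model")
  expect_equal(at2 <- predict_envelope(geo, env_stack("p", list(
    sst = env_grid(spec, "sst", matrix(9, 1, 1)),
    sbt = env_grid(spec, "sbt", matrix(7, 1, 1))
  )))$values[1, 1], 0.5)           # sqrt(0.5 * 0.5)
})

test_that("fit-then-predict scores >= 95% of training presences as suitable", {
  # noisy scenario: continuous cell values, so only the handful of cells at
  # a variable's observed extreme sit exactly on a zero ramp endpoint
  sc <- make_env_scenario(scenario_params(seed = 8))
  sp <- virtual_species("vs", list(sst = c(7, 8.5, 11, 12.5)))
  occ <- sample_occurrences(sp, sc$baseline, 400, seed = 41)
  pg <- aggregate_to_grid(qc_filter(occ, sc$baseline)$records,
                          sc$baseline$spec)
  fit <- fit_envelope(pg, sc$baseline)
  pred <- predict_envelope(fit, sc$baseline)
  frac_pos <- mean(pred$values[pg$present] > 0, na.rm = TRUE)
  expect_gte(frac_pos, 0.95)
})

test_that("envelope fit recovers the preference bounds of a virtual species", {
  # gridded design: SST takes discrete 0.5 C row values, so the sampling
  # distribution's 10th/90th percentiles concentrate exactly on the true
  # preference bounds (ramp mass < 10% per side by construction)
  spec <- grid_spec(45, 75, -180, 20, 0.5)
  sc <- make_env_scenario(scenario_params(
    spec = spec, sst_equator = 20.5, sst_pole = -9, noise_sd = 0,
    land_fraction = 0, seed = 1
  ))
  truth <- c(8, 10, 18, 20)
  sp <- virtual_species("vs", list(sst = truth))
  occ <- sample_occurrences(sp, sc$baseline, 2000, seed = 11)
  pg <- aggregate_to_grid(occ, spec)
  fit <- fit_envelope(pg, sc$baseline, variables = "sst")
  n <- 2000
  sd_v <- stats::sd(sc$baseline$layers$sst$values[pg$present])
  tol <- 0.5 * sd_v / sqrt(n)
  expect_lt(abs(fit$trapezoids$sst[["pref_min"]] - truth[2]), tol + 1e-12)
  expect_lt(abs(fit$trapezoids$sst[["pref_max"]] - truth[3]), tol + 1e-12)
})

test_that("predictions are shift-equivariant under a poleward translation", {
  k <- 3
  sc <- shifted_scenario(k_rows = k)
  sp <- virtual_species("vs", list(sst = c(7, 8, 10, 11)))
  occ <- sample_occurrences(sp, sc$baseline, 400, seed = 51)
  pg <- aggregate_to_grid(qc_filter(occ, sc$baseline)$records, sc$baseline$spec)
  fit <- fit_envelope(pg, sc$baseline, variables = c("sst", "sbt"))
  cur <- predict_envelope(fit, sc$baseline)
  fut <- predict_envelope(fit, sc$future)
  n_lat <- sc$baseline$spec$n_lat
  # future map rows k+1..n equal baseline rows 1..n-k (exact translation)
  expect_equal(fut$values[(k + 1):n_lat, ], cur$values[1:(n_lat - k), ])
})

test_that("fit errors are informative", {
  spec <- test_spec(5, 1)
  env <- env_from_values(spec, c(8, 9, 10, 11, 12))
  expect_error(fit_envelope(presence_from_cells(spec, 1:4), env,
                            variables = "sst"), "at least 5")
  expect_error(fit_envelope(presence_from_cells(spec, 1:5), env,
                            variables = "oxygen"), "lacks variable")
  env_na <- env_from_values(spec, rep(NA_real_, 5))
  expect_error(fit_envelope(presence_from_cells(spec, 1:5), env_na,
                            variables = "sst"), "missing at every")
})

test_that("envelope models survive a JSON round trip", {
  spec <- test_spec(5, 1)
  env <- env_from_values(spec, c(8, 9, 10, 11, 12))
  fit <- fit_envelope(presence_from_cells(spec, 1:5), env, variables = "sst")
  path <- withr::local_tempfile(fileext = ".json")
  write_envelope_model(fit, path)
  back <- read_envelope_model(path)
  expect_equal(back$trapezoids$sst, fit$trapezoids$sst)
  expect_equal(predict_envelope(back, env)$values,
               predict_envelope(fit, env)$values)
})
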