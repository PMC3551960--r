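test_that("latitudinal centroid handles point masses and symmetric pairs", {
  spec <- grid_spec(50, 61, 0, 2, 0.5)
  latc <- lat_centers(spec)
  at_lat <- function(lat) which(abs(latc - lat) < 1e-9)

  m <- matrix(0, spec$n_lat, spec$n_lon)
  m[at_lat(55.25), 2] <- 0.7
  expect_equal(latitudinal_centroid(suitability_map(spec, m)), 55.25)

  m2 <- matrix(0, spec$n_lat, spec$n_lon)
  m2[at_lat(50.25), 1] <- 0.4
  m2[at_lat(60.25), 2] <- 0.4
  expect_equal(latitudinal_centroid(suitability_map(spec, m2)), 55.25)

  expect_error(latitudinal_centroid(suitability_map(spec, m * 0)), "all-zero")
})

test_that("centroid matches a brute-force weighted mean on random maps", {
  spec <- test_spec(8, 8)
  latc <- lat_centers(spec)
  for (seed in c(111, 112, 113)) {
    map <- rand_map(spec, seed, na_cells = c(5, 22))
    num <- 0; den <- 0
    for (i in 1:8) {
      for (j in 1:8) {
        v <- map$values[i, j]
        if (!is.na(v)) {
          num <- num + latc[i] * v
          den <- den + v
        }
      }
    }
    expect_equal(latitudinal_centroid(map), num / den)
  }
})

test_that("a map mirrored about a latitude has its centroid on that latitude", {
  spec <- test_spec(8, 4)
  vals <- with_seed_test(121, matrix(stats::runif(32), 8, 4))
  mirrored <- (vals + vals[8:1, ]) / 2
  mid <- mean(lat_centers(spec))
  expect_equal(latitudinal_centroid(suitability_map(spec, mirrored)), mid)
})

test_that("centroid shift converts degrees to km with one constant", {
  expect_equal(centroid_shift_km(55, 56), 111.32)
  expect_equal(centroid_shift_km(56, 55), -111.32)
  expect_equal(centroid_shift_km(55, 55), 0)
  expect_equal(centroid_shift_km(50, 51.5), 1.5 * KM_PER_DEG)
})

test_that("range area sums cell areas over the thresholded support", {
  spec <- grid_spec(-0.5, 0.5, 0, 1, 0.5)  # cells straddling the equator
  m <- matrix(0, 2, 2)
  expect_equal(range_area(suitability_map(spec, m)), 0)
  m[1, 1] <- 0.9
  a <- range_area(suitability_map(spec, m), t = 0)
  expect_equal(a, cell_area_km2(-0.25, 0.5))
  expect_equal(round(cell_area_km2(0, 0.5)), 3098)
})

test_that("range change decomposes into loss and gain percentages", {
  spec <- test_spec(4, 4)
  cur <- matrix(0, 4, 4); cur[, 1:2] <- 1
  fut_same <- suitability_map(spec, cur, "sp", "m")
  cur_map <- suitability_map(spec, cur, "sp", "m")
  same <- range_change(cur_map, fut_same, t = 0.5)
  expect_equal(same$loss_pct, 0)
  expect_equal(same$gain_pct, 0)
  expect_equal(same$net_pct, 0)

  # shift by one column: half of a 2-column range leaves, an equal band enters
  fut <- matrix(0, 4, 4); fut[, 2:3] <- 1
  shifted <- range_change(cur_map, suitability_map(spec, fut, "sp", "m"),
                          t = 0.5)
  expect_equal(shifted$loss_pct, 50)
  expect_equal(shifted$gain_pct, 50)
  expect_equal(shifted$net_pct, 0)

  grown <- matrix(0, 4, 4); grown[, 1:3] <- 1
  net <- range_change(cur_map, suitability_map(spec, grown, "sp", "m"), 0.5)
  expect_equal(net$loss_pct, 0)
  expect_equal(net$gain_pct, 50)
  expect_error(range_change(suitability_map(spec, matrix(0, 4, 4)), fut_same),
               "empty")
})

test_that("Schoener's D is 1 for identical maps and 0 for disjoint supports", {
  spec <- test_spec(8, 8)
  m <- rand_map(spec, 131)
  expect_equal(schoener_d(m, m), 1)

  left <- matrix(0, 8, 8); left[, 1:4] <- with_seed_test(132, runif(32)) + 0.1
  right <- matrix(0, 8, 8); right[, 5:8] <- with_seed_test(133, runif(32)) + 0.1
  expect_equal(schoener_d(suitability_map(spec, left),
                          suitability_map(spec, right)), 0)
})

test_that("Schoener's D equals 1 - L1/2 against an independent loop oracle", {
  spec <- test_spec(8, 8)
  for (seed in c(141, 142, 143)) {
    x <- rand_map(spec, seed, na_cells = 7)
    y <- rand_map(spec, seed + 10, na_cells = 7)
    d <- schoener_d(x, y)
    # plain-loop oracle over shared cells
    xs <- 0; ys <- 0
    for (i in 1:8) for (j in 1:8) {
      if (!is.na(x$values[i, j]) && !is.na(y$values[i, j])) {
        xs <- xs + x$values[i, j]; ys <- ys + y$values[i, j]
      }
    }
    acc <- 0
    for (i in 1:8) for (j in 1:8) {
      if (!is.na(x$values[i, j]) && !is.na(y$values[i, j])) {
        acc <- acc + abs(x$values[i, j] / xs - y$values[i, j] / ys)
      }
    }
    expect_equal(d, 1 - acc / 2)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("Schoener's D is symmetric and scale-invariant", {
  spec <- test_spec(8, 8)
  x <- rand_map(spec, 151)
  y <- rand_map(spec, 152)
  expect_equal(schoener_d(x, y), schoener_d(y, x))
  x5 <- suitability_map(spec, x$values * 5)
  expect_equal(schoener_d(x5, y), schoener_d(x, y))
  z <- suitability_map(spec, matrix(0, 8, 8))
  expect_error(schoener_d(x, z), "zero-sum")
})

test_that("overlap percent change applies the 0.1 damping offset", {
  expect_equal(overlap_change_pct(0.4, 0.4), 0)
  expect_equal(overlap_change_pct(0.4, 0.5), 20)
  expect_equal(overlap_change_pct(0, 0.05), 50)  # offset damps the zero baseline
  expect_error(overlap_change_pct(-0.1, 0.5))
})

test_that("a 3-cell poleward translation yields the analytic centroid shift", {
  k <- 3
  sc <- shifted_scenario(k_rows = k)
  sp <- virtual_species("vs", list(sst = c(7, 8, 10, 11)))
  occ <- sample_occurrences(sp, sc$baseline, 400, seed = 161)
  pg <- aggregate_to_grid(qc_filter(occ, sc$baseline)$records,
                          sc$baseline$spec)
  fit <- fit_envelope(pg, sc$baseline, variables = c("sst", "sbt"))
  cur <- predict_envelope(fit, sc$baseline)
  fut <- predict_envelope(fit, sc$future)
  shift <- centroid_shift_km(latitudinal_centroid(cur),
                             latitudinal_centroid(fut))
  # within one cell width (0.5 deg) of the analytic 166.98 km
  expect_lt(abs(shift - k * 0.5 * KM_PER_DEG), 0.5 * KM_PER_DEG)
})
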