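test_that("degenerate spec gives the closed-form constant series", {
  sp <- climate_spec(annual_mean = 18.3, annual_amplitude = 0,
                     diurnal_range = 4, noise_sd = 0, seed = 1,
                     year = 2020)
  w <- generate_series(sp)
  expect_equal(nrow(w), 366)  # leap year
  expect_true(all(w$i_max == 20.3))
  expect_true(all(w$i_min == 16.3))
  expect_true(all(w$i_mean == 18.3))
})

test_that("noise-free seasonal peak sits at phase_day with value mean + amplitude", {
  sp <- climate_spec(annual_mean = 10, annual_amplitude = 12,
                     phase_day = 205, noise_sd = 0, seed = 1,
                     year = 2021)
  w <- generate_series(sp)
  doy <- as.integer(format(w$date, "%j"))
  expect_equal(max(w$i_mean), 22, tolerance = 1e-9)
  expect_equal(doy[which.max(w$i_mean)], 205)
})

test_that("generation is seed-deterministic and leaves the caller's RNG alone", {
  a <- generate_series(climate_spec(seed = 9))
  b <- generate_series(climate_spec(seed = 9))
  expect_identical(a, b)
  expect_false(identical(a$i_mean,
                         generate_series(climate_spec(seed = 10))$i_mean))
  expect_equal(attr(a, "seed"), 9L)
  set.seed(123); x1 <- stats::rnorm(1)
  set.seed(123); invisible(generate_series(climate_spec(seed = 9)))
  x2 <- stats::rnorm(1)
  expect_identical(x1, x2)
})

test_that("generated series always satisfy the weather invariants", {
  for (seed in 1:8) {
    w <- generate_series(climate_spec(seed = seed, noise_sd = 3))
    expect_silent(validate_weather(w))
    expect_true(all(w$i_min <= w$i_mean & w$i_mean <= w$i_max))
  }
})

test_that("a 1x1 grid reproduces the point generator", {
  sp <- climate_spec(seed = 4, year = 2020)
  cube <- generate_grid(sp, nx = 1, ny = 1)
  w <- generate_series(sp)
  expect_equal(cube$tmean[, 1, 1], w$i_mean)
  expect_equal(cube$tmax[, 1, 1], w$i_max)
  expect_equal(cell_series(cube, 1, 1)$i_min, w$i_min)
})

test_that("the lapse gradient cools the grid northward", {
  cube <- generate_grid(climate_spec(seed = 2, noise_sd = 0),
                        nx = 2, ny = 4, lapse = -0.5)
  means <- apply(cube$tmean, 2, mean)  # by row, row 1 = north
  expect_true(all(diff(means) > 0))    # warms toward the south
  expect_equal(means[4] - means[1], 1.5, tolerance = 1e-9)
})

test_that("mask fraction bounds behave and latitudes follow the geotransform", {
  cube0 <- generate_grid(climate_spec(seed = 3), 3, 3, mask_fraction = 0)
  expect_true(all(cube0$host_mask))
  cube1 <- generate_grid(climate_spec(seed = 3), 3, 3, mask_fraction = 1)
  expect_false(any(cube1$host_mask))
  lats <- cell_latitudes(cube0)
  expect_length(lats, 3)
  expect_true(all(diff(lats) < 0))  # row 1 northernmost
  expect_equal(lats[3], cube0$origin_y + 0.5 * cube0$cellsize)
  cube0$crs <- "EPSG:32633"
  expect_error(cell_latitudes(cube0), "projected")
  expect_equal(cell_latitudes(cube0, 46.1), rep(46.1, 3))
})

test_that("spec validation rejects negative dispersion parameters", {
  expect_error(climate_spec(annual_amplitude = -1), ">= 0")
  expect_error(climate_spec(noise_sd = -0.1), ">= 0")
})
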