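test_that("MAE over paired onset dates handles offsets and exclusions", {
  d <- as.Date("2020-04-01") + 0:2
  expect_equal(as.numeric(mae_days(d, d)), 0)
  expect_equal(as.numeric(mae_days(d[1:2] + c(2, -4), d[1:2])), 3.0)
  m <- mae_days(c(d[1] + 1, as.Date(NA), d[3]), d)
  expect_equal(as.numeric(m), 0.5)
  expect_equal(attr(m, "n"), 2L)
  expect_equal(attr(m, "n_excluded"), 1L)
  expect_error(mae_days(as.Date(c(NA, NA)), d[1:2]), "no valid")
})

make_obs_fixture <- function(sites = 2, years = 2020, seed0 = 100) {
  p <- rity_params()
  weather <- list()
  rows <- list()
  for (s in seq_len(sites)) for (y in years) {
    w <- generate_series(climate_spec(seed = seed0 + 13 * s + y,
                                      year = y))
    key <- paste0("site", s, "_", y)
    weather[[key]] <- w
    rows[[key]] <- data.frame(
      site = paste0("site", s), year = y, latitude = 46.0,
      observed_swarming = detect_onset(w, p$swarm_dd, p),
      observed_infestation = detect_onset(w, p$infest_dd, p))
  }
  list(obs = do.call(rbind, rows), weather = weather)
}

test_that("calibration recovers the start date that generated the observations", {
  fx <- make_obs_fixture()
  cal <- calibrate_start_date(fx$obs, fx$weather,
                              candidates = candidate_grid("03-01", "03-20"))
  tab <- cal$mae_by_candidate
  chosen <- tab[tab$candidate == cal$chosen_start, ]
  expect_equal(chosen$mae_combined, 0)
  # the generating date is in the argmin set
  expect_equal(tab$mae_combined[tab$candidate == "03-07"], 0)
  # tie-break: chosen is the latest zero-MAE candidate
  zeros <- tab$candidate[tab$qualified & tab$mae_combined == 0]
  expect_equal(cal$chosen_start, max(zeros))
})

test_that("a single candidate is returned with its MAE", {
  fx <- make_obs_fixture(sites = 1)
  cal <- calibrate_start_date(fx$obs, fx$weather, candidates = "03-07")
  expect_equal(cal$chosen_start, "03-07")
  expect_equal(nrow(cal$mae_by_candidate), 1)
  expect_equal(cal$mae_by_candidate$mae_combined, 0)
  expect_output(print(cal), "chosen start date")
  expect_equal(unname(coef(cal)), 66L)  # day-of-year of 7 March
})

test_that("predicted onsets are non-decreasing in the start date", {
  w <- generate_series(climate_spec(seed = 5, year = 2020))
  p <- rity_params()
  onsets <- as.Date(vapply(candidate_grid("02-15", "04-15"),
                           function(cand) {
                             pc <- p; pc$start_date <- cand
                             format(detect_onset(w, pc$swarm_dd, pc))
                           }, character(1)))
  expect_true(!is.unsorted(onsets, na.rm = TRUE))
})

test_that("candidates that rarely predict are disqualified, not argmin", {
  fx <- make_obs_fixture()
  # late-summer candidates cannot accumulate the thresholds in time
  cal <- calibrate_start_date(
    fx$obs, fx$weather,
    candidates = c("03-07", "10-15"), min_coverage = 0.9)
  tab <- cal$mae_by_candidate
  expect_false(tab$qualified[tab$candidate == "10-15"])
  expect_equal(cal$chosen_start, "03-07")
})

test_that("observation rows without weather or dates are rejected", {
  fx <- make_obs_fixture(sites = 1)
  expect_error(calibrate_start_date(fx$obs, list(), "03-07"),
               "no weather")
  bad <- fx$obs
  bad$observed_swarming <- as.Date(NA)
  bad$observed_infestation <- as.Date(NA)
  expect_error(calibrate_start_date(bad, fx$weather, "03-07"),
               "at least one")
})
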