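P <- rity_params()

test_that("degree-day accumulator truncates negative increments at zero", {
  expect_equal(degree_day_accumulator(rep(18.3, 6)), 10 * (1:6))
  expect_equal(degree_day_accumulator(rep(8.3, 10)), rep(0, 10))
  expect_equal(degree_day_accumulator(c(5.0, 20.0)), c(0, 11.7))
  expect_error(degree_day_accumulator(c(1, NA)), "non-missing")
})

test_that("onset detection reproduces the hand-derived chronology", {
  w <- const_weather(2020, 8, 13, 18.3)
  # 10 dd/day from 7 March: 53 dd reached on day 6, 155.6 dd on day 16
  expect_equal(detect_onset(w, 53.0, P), as.Date("2020-03-12"))
  expect_equal(detect_onset(w, 155.6, P), as.Date("2020-03-22"))
})

test_that("the flight gate delays onset past the degree-day crossing", {
  d <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  imax <- rep(13.3, length(d))                # 5 dd/day, gate closed
  imax[d == as.Date("2020-03-17")] <- 20.0    # first warm day
  w <- weather_series(d, imax - 8, imax - 4, imax)
  # cum = 50 after 10 cold days; 17 March brings cum 61.7 and flight
  expect_equal(detect_onset(w, 53.0, P), as.Date("2020-03-17"))
})

test_that("onset is absent when the flight gate never opens", {
  w <- const_weather(2020, 6, 10, 14.5)   # strict > 14.5 never holds
  expect_true(is.na(detect_onset(w, 53.0, P)))
})

test_that("brood accumulation is inclusive of the onset day and scaled by K", {
  dates <- seq(as.Date("2020-03-07"), as.Date("2020-10-31"), by = "day")
  n <- length(dates)
  ts <- accumulate_brood(dates[1], rep(5.57, n), dates, 557)
  expect_equal(ts[100], 1.0)
  expect_equal(accumulate_brood(dates[5], rep(0, n), dates, 557),
               rep(0, n))
  ts2 <- accumulate_brood(dates[20], rep(55.7, n), dates, 557)
  expect_equal(ts2[19], 0)        # zero before onset
  expect_equal(ts2[20], 0.1)      # onset day included
  expect_error(accumulate_brood(as.Date("2020-01-01"), rep(1, n),
                                dates, 557), "outside")
})

test_that("brood scheduling uses strict thermal thresholds with both gates", {
  dates <- seq(as.Date("2020-03-07"), as.Date("2020-10-31"), by = "day")
  n <- length(dates)
  tsum_f1 <- cumsum(rep(55.7, n)) / 557   # 0.1 per day from day 1
  warm <- rep(20, n); long <- rep(15, n)
  fil <- schedule_filial(tsum_f1, warm, long, dates, P)
  # day 10 gives exactly 1.0 which fails the strict >, so F2 on day 11
  expect_equal(unname(fil["F2"]), dates[11])
  expect_equal(unname(fil["F3"]), dates[21])
  sis <- schedule_sisters(tsum_f1, warm, long, dates, P)
  expect_equal(unname(sis["S1"]), dates[6])   # 0.5 exactly fails on day 5
  expect_equal(unname(sis["S2"]), dates[16])
  # diapause: short days block every initiation
  short <- rep(14.0, n)
  expect_true(all(is.na(schedule_filial(tsum_f1, warm, short, dates, P))))
  expect_true(all(is.na(schedule_sisters(tsum_f1, warm, short, dates, P))))
  # never enough development for a sister brood
  expect_true(all(is.na(schedule_sisters(rep(0.4, n), warm, long,
                                         dates, P))))
})

test_that("stage classification uses half-open intervals owned upward", {
  expect_equal(as.character(classify_stage(0.05)), "egg")
  expect_equal(as.character(classify_stage(0.1)), "larva")
  expect_equal(as.character(classify_stage(0.55)), "pupa")
  expect_equal(as.character(classify_stage(c(0, 0.5, 0.6, 1.0, 2.3))),
               c("egg", "pupa", "teneral_adult", "emerged_adult",
                 "emerged_adult"))
  expect_error(classify_stage(-0.1), "non-negative")
})

test_that("generation counting applies the 0.6 hibernation threshold", {
  mk <- function(id, v) list(brood_id = id, final_tsum = v)
  b <- list(mk("F1", 1.2), mk("F2", 0.7), mk("F3", 0.3), mk("S1", 0.61))
  expect_equal(count_generations(b, P),
               c(n_filial = 2L, n_sister = 1L))
  expect_equal(count_generations(list(), P),
               c(n_filial = 0L, n_sister = 0L))
  expect_equal(count_generations(list(mk("F1", 0.6)), P)[["n_filial"]], 1L)
})

test_that("point simulation composes the chain and handles cold years", {
  r <- simulate_point(const_weather(2020, 8, 13, 18.3), 46.37, P, "avg")
  expect_equal(r$swarming_onset, as.Date("2020-03-12"))
  expect_equal(r$infestation_onset, as.Date("2020-03-22"))
  expect_equal(r$broods$F1$onset, as.Date("2020-03-22"))
  cold <- simulate_point(const_weather(2020, 2, 5, 8.0), 46.37, P, "avg")
  expect_true(is.na(cold$swarming_onset))
  expect_length(cold$broods, 0)
  expect_equal(c(cold$n_filial, cold$n_sister), c(0L, 0L))
})

test_that("simulation is deterministic and invariant under scenario ordering", {
  w <- generate_series(climate_spec(seed = 11, year = 2020))
  a <- simulate_point(w, 46.37, P, "avg")
  b <- simulate_point(w, 46.37, P, "avg")
  expect_identical(a, b)
})

test_that("engine agrees with the naive brute-force recomputation", {
  for (seed in c(3, 14)) {
    w <- generate_series(climate_spec(seed = seed, year = 2020))
    for (sc in c("avg", "max")) {
      eng <- simulate_point(w, 46.37, P, sc)
      ora <- oracle_point(w, 46.37, sc)
      expect_equal(eng$swarming_onset, ora$swarming)
      expect_equal(eng$infestation_onset, ora$infestation)
      eng_fin <- vapply(eng$broods, `[[`, numeric(1), "final_tsum")
      expect_equal(sort(names(eng_fin)), sort(names(ora$final)))
      expect_equal(eng_fin[names(ora$final)], ora$final)
    }
  }
})

test_that("tsum series are non-decreasing and onsets are ordered", {
  for (seed in 1:10) {
    w <- generate_series(climate_spec(seed = seed, year = 2020))
    r <- simulate_point(w, 46.37, P, "max")
    for (b in r$broods) {
      expect_true(all(diff(b$tsum) >= 0))
      expect_true(all(b$tsum[r$dates < b$onset] == 0))
    }
    if (!is.na(r$swarming_onset) && !is.na(r$infestation_onset))
      expect_lte(r$swarming_onset, r$infestation_onset)
    ord <- c("F1", "S1", "F2", "S2", "F3")
    on <- lapply(r$broods[ord], `[[`, "onset")
    present <- !vapply(on, is.null, logical(1))
    od <- do.call(c, on[present])
    expect_true(!is.unsorted(od))
  }
})

test_that("warmer scenarios dominate below the optimum temperature", {
  w <- generate_series(climate_spec(seed = 21, year = 2020,
                                    annual_mean = 8))
  rs <- lapply(c("min", "avg", "max"),
               function(s) simulate_point(w, 46.37, P, s))
  # all bark temps below the optimum -> linear branch -> monotone
  bts <- bark_temps(forest_air_temps(window_weather(
    w, "2020-03-07", "2020-10-31")))
  expect_true(all(as.matrix(bts) <= 30.4))
  f1 <- lapply(rs, function(r) r$broods$F1$tsum)
  expect_true(all(f1[[1]] <= f1[[2]] + 1e-12))
  expect_true(all(f1[[2]] <= f1[[3]] + 1e-12))
})

test_that("rity front end exposes summary, daily table and plot", {
  w <- generate_series(climate_spec(seed = 7, year = 2020))
  fit <- rity(w, 46.37)
  expect_s3_class(fit, "rity")
  expect_named(fit, c("min", "avg", "max"))
  s <- summary(fit)
  expect_true(all(c("scenario", "brood", "onset", "final_tsum",
                    "survives") %in% names(s)))
  daily <- as.data.frame(fit)
  expect_true(all(daily$tsum >= 0))
  expect_setequal(unique(daily$scenario), c("min", "avg", "max"))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit, scenario = "avg"))
  expect_output(print(fit), "potential generations")
})

test_that("incomplete weather windows fail with the missing dates named", {
  w <- const_weather(2020)
  w2 <- w[w$date <= as.Date("2020-09-30"), ]
  class(w2) <- class(w)
  expect_error(simulate_point(w2, 46.37, P, "avg"), "missing")
})
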