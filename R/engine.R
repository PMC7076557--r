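#' Cumulative degree-day accumulator
#'
#' Running sum of daily `max(0, i_max - base)` from the first element
#' of the series onward. Negative daily increments (days colder than
#' the base) are truncated at zero, the standard degree-day convention,
#' so a cold snap never erases accrued thermal cue.
#'
#' @param i_max numeric vector of daily maximum air temperatures, degC,
#'   starting at the simulation start date.
#' @param base base temperature, degC (default the lower development
#'   threshold 8.3).
#' @return Cumulative degree-day vector, same length as `i_max`.
#' @export
degree_day_accumulator <- function(i_max, base = 8.3) {
  if (!is.numeric(i_max) || anyNA(i_max))
    stop("`i_max` must be numeric and non-missing", call. = FALSE)
  cumsum(pmax(0, i_max - base))
}

#' Detect the onset of a spring phenological event
#'
#' Earliest day on which the cumulative degree-day sum over raw daily
#' maximum air temperatures (`sum(max(0, i_max - dt_l))` from the start
#' date) reaches `dd_threshold` AND that same day's `i_max` strictly
#' exceeds the flight-activity temperature. Days on which the sum has
#' crossed the threshold but flight is not possible do not trigger the
#' event; it is declared on the first day both conditions hold
#' simultaneously. With the default thresholds 53.0 dd and 155.6 dd
#' this yields the onset of spring swarming and of infestation.
#'
#' Gates are evaluated on the uncorrected gridded-product `i_max`, not
#' the forest air temperature; only development (effective bark
#' temperature) uses the corrected chain.
#'
#' @param w a daily weather series covering the simulation window.
#' @param dd_threshold cumulative degree-days required, dd.
#' @param p model parameters, see [rity_params()].
#' @return Onset `Date`, or `NA` (class `Date`) if the event never
#'   occurs within the window.
#' @export
detect_onset <- function(w, dd_threshold, p = rity_params()) {
  w <- validate_weather(w)
  win <- resolve_window(p, format(w$date[1], "%Y"))
  ww <- window_weather(w, win$start, win$end)
  cum <- degree_day_accumulator(ww$i_max, p$dev$dt_l)
  hit <- which(cum >= dd_threshold & ww$i_max > p$flight_t)
  if (length(hit) == 0) return(as.Date(NA))
  ww$date[hit[1]]
}

#' Relative thermal sum of one brood
#'
#' Accumulates daily effective bark temperature from the brood's onset
#' day (inclusive) through each subsequent day and divides by the
#' thermal sum K required for total development. Zero before onset;
#' not capped at 1 (values above 1 mean the brood has emerged and are
#' what triggers the next filial generation).
#'
#' @param onset onset `Date` of the brood.
#' @param bteff numeric vector of daily effective bark temperatures
#'   (degree-days per day) over the simulation window.
#' @param dates `Date` vector parallel to `bteff`.
#' @param k thermal sum for total development, dd (default 557).
#' @return Numeric vector of daily relative thermal sums, parallel to
#'   `dates`; non-decreasing, zero before `onset`.
#' @export
accumulate_brood <- function(onset, bteff, dates, k = 557) {
  onset <- as.Date(onset)
  i <- match(onset, dates)
  if (is.na(i))
    stop("brood onset ", onset, " outside the simulation window ",
         dates[1], "..", dates[length(dates)], call. = FALSE)
  ts <- numeric(length(bteff))
  ts[i:length(bteff)] <- cumsum(bteff[i:length(bteff)]) / k
  ts
}

# First index satisfying tsum > threshold plus both onset-day gates,
# or NA. Shared by filial and sister scheduling: the thresholds are
# strict (as printed), the flight gate strict, the day-length gate
# non-strict.
first_brood_day <- function(tsum_f1, threshold, i_max, daylength, p) {
  hit <- which(tsum_f1 > threshold & i_max > p$flight_t &
                 daylength >= p$daylength_gate)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Schedule later filial generations
#'
#' Onset of the second and third (and further, up to `max_filial`)
#' filial generations: generation F(k) is initiated on the earliest day
#' with `Tsum_F1 > k - 1` (strict, on the first generation's relative
#' thermal sum, exactly as printed), daily `i_max` above the flight
#' temperature, and day length at or above the diapause gate. Short
#' days block initiation only; a brood already initiated keeps
#' accumulating until the end of the window.
#'
#' @param tsum_f1 daily relative thermal sum of the first filial
#'   generation.
#' @param i_max raw daily maximum air temperatures over the window.
#' @param daylength daily day lengths, hours.
#' @param dates `Date` vector parallel to the series.
#' @param p model parameters.
#' @return Named `Date` vector (`F2`, `F3`, ...) with `NA` where a
#'   generation is never initiated.
#' @export
schedule_filial <- function(tsum_f1, i_max, daylength, dates,
                            p = rity_params()) {
  ks <- seq_len(p$max_filial)[-1]
  if (length(ks) == 0) return(stats::setNames(as.Date(character()), character()))
  idx <- vapply(ks, function(k)
    first_brood_day(tsum_f1, k - 1, i_max, daylength, p), integer(1))
  stats::setNames(dates[idx], paste0("F", ks))
}

#' Schedule sister broods
#'
#' Onset of the j-th sister brood, laid by re-emerged parental beetles:
#' earliest day with `Tsum_F1 > j - 0.5` (strict), daily `i_max` above
#' the flight temperature, and day length at or above the diapause
#' gate. The first sister brood's onset is the predicted re-emergence
#' date of the parental beetles.
#'
#' @inheritParams schedule_filial
#' @return Named `Date` vector (`S1`, `S2`, ...) with `NA` where a
#'   brood is never initiated.
#' @export
schedule_sisters <- function(tsum_f1, i_max, daylength, dates,
                             p = rity_params()) {
  js <- seq_len(p$max_sister)
  if (length(js) == 0) return(stats::setNames(as.Date(character()), character()))
  idx <- vapply(js, function(j)
    first_brood_day(tsum_f1, j - 0.5, i_max, daylength, p), integer(1))
  stats::setNames(dates[idx], paste0("S", js))
}

#' Developmental stage from a relative thermal sum
#'
#' Maps a relative thermal sum to the developmental stage of the brood.
#' Intervals are half-open with the lower bound owned by the later
#' stage (a deterministic tie-break of the nominal closed ranges):
#' egg \[0, 0.1), larva \[0.1, 0.5), pupa \[0.5, 0.6),
#' teneral adult \[0.6, 1.0), emerged adult at 1.0 and above.
#'
#' @param rel_tsum numeric vector of relative thermal sums, `>= 0`.
#' @param bounds the four interior breakpoints (default
#'   `c(0.1, 0.5, 0.6, 1.0)`).
#' @return Factor with levels `egg`, `larva`, `pupa`, `teneral_adult`,
#'   `emerged_adult`.
#' @export
classify_stage <- function(rel_tsum, bounds = c(0.1, 0.5, 0.6, 1.0)) {
  if (!is.numeric(rel_tsum) || anyNA(rel_tsum) || any(rel_tsum < 0))
    stop("`rel_tsum` must be non-negative numeric", call. = FALSE)
  labs <- c("egg", "larva", "pupa", "teneral_adult", "emerged_adult")
  cut(rel_tsum, breaks = c(-Inf, bounds, Inf), labels = labs,
      right = FALSE)
}

#' Count potential generations
#'
#' Number of filial generations and sister broods whose relative
#' thermal sum at the end of the season reaches the hibernation
#' threshold (default 0.6, preimaginal development complete): only
#' those can overwinter as young adults and count toward the annual
#' number of potential generations. Initiated broods below the
#' threshold are ignored. Counts are reported separately for filial
#' and sister broods.
#'
#' @param broods a list of brood tracks as found in a simulation
#'   result: each element has `brood_id` (starting `"F"` or `"S"`) and
#'   `final_tsum`.
#' @param p model parameters.
#' @return Integer vector `c(n_filial = , n_sister = )`.
#' @export
count_generations <- function(broods, p = rity_params()) {
  surv <- vapply(broods, function(b)
    isTRUE(b$final_tsum >= p$hibernation_min), logical(1))
  ids <- vapply(broods, function(b) b$brood_id, character(1))
  c(n_filial = sum(surv & startsWith(ids, "F")),
    n_sister = sum(surv & startsWith(ids, "S")))
}

# Build one brood track (list) from an onset date, or NULL if absent.
brood_track <- function(id, onset, bteff, dates, p) {
  if (is.na(onset)) return(NULL)
  ts <- accumulate_brood(onset, bteff, dates, p$k_total)
  final <- ts[length(ts)]
  list(brood_id = id, onset = onset, tsum = ts, final_tsum = final,
       survives = final >= p$hibernation_min)
}

#' Simulate beetle phenology at one site
#'
#' Runs the full daily stepping chain at a point for one scenario:
#' gridded-product temperatures are corrected to forest air
#' temperatures and then bark temperatures; the scenario selects which
#' bark temperature (minimum, mean or maximum) drives development via
#' the effective-temperature function; onset of swarming and
#' infestation are detected on the raw daily maxima; the first filial
#' generation starts at infestation and later filial generations and
#' sister broods are initiated from its relative thermal sum under the
#' flight and photoperiod gates; each initiated brood accumulates its
#' own relative thermal sum until the end of the window, where
#' surviving broods are counted. Fully deterministic.
#'
#' @param w a daily weather series covering the simulation window
#'   (31 October) from at or before the start date (7 March).
#' @param latitude site latitude, degrees north (drives day length).
#' @param p model parameters, see [rity_params()].
#' @param scenario `"min"`, `"avg"` or `"max"`: which daily bark
#'   temperature drives development.
#' @return An object of class `"rity_point"`: a list with elements
#'   `scenario`, `dates`, `swarming_onset`, `infestation_onset`,
#'   `broods` (named list of brood tracks with `onset`, `tsum`,
#'   `final_tsum`, `survives`), `n_filial`, `n_sister`, `latitude`,
#'   `params`, and the daily driver series (`i_max`, `bteff`,
#'   `daylength`).
#' @seealso [rity()] for the multi-scenario front end with methods.
#' @export
simulate_point <- function(w, latitude, p = rity_params(),
                           scenario = c("avg", "min", "max")) {
  scenario <- match.arg(scenario)
  w <- validate_weather(w)
  win <- resolve_window(p, format(w$date[1], "%Y"))
  ww <- window_weather(w, win$start, win$end)
  dates <- ww$date

  at <- forest_air_temps(ww)
  bt <- bark_temps(at)
  bt_dev <- switch(scenario, min = bt$bt_min, avg = bt$bt_mean,
                   max = bt$bt_max)
  bteff <- effective_series(bt_dev, p$dev)
  doy <- as.integer(format(dates, "%j"))
  daylen <- day_length(latitude, doy, p$horizon)

  swarming <- detect_onset(ww, p$swarm_dd, p)
  infestation <- detect_onset(ww, p$infest_dd, p)

  broods <- list()
  if (!is.na(infestation)) {
    f1 <- brood_track("F1", infestation, bteff, dates, p)
    broods$F1 <- f1
    fil <- schedule_filial(f1$tsum, ww$i_max, daylen, dates, p)
    sis <- schedule_sisters(f1$tsum, ww$i_max, daylen, dates, p)
    for (id in names(sis))
      broods[[id]] <- brood_track(id, sis[[id]], bteff, dates, p)
    for (id in names(fil))
      broods[[id]] <- brood_track(id, fil[[id]], bteff, dates, p)
    broods <- Filter(Negate(is.null), broods)
  }
  counts <- count_generations(broods, p)

  structure(list(scenario = scenario, dates = dates,
                 swarming_onset = swarming,
                 infestation_onset = infestation, broods = broods,
                 n_filial = unname(counts["n_filial"]),
                 n_sister = unname(counts["n_sister"]),
                 latitude = latitude, params = p,
                 i_max = ww$i_max, bteff = bteff, daylength = daylen),
            class = "rity_point")
}
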