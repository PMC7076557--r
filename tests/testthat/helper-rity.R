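# Shared fixtures: constant-weather builder and an independent
# brute-force oracle that re-derives every cumulative quantity from
# scratch each day with naive loops (no cumsum, no shared code path
# with the stepping engine beyond parameter values).

const_weather <- function(year = 2020, i_min = 8, i_mean = 13,
                          i_max = 18.3) {
  d <- seq(as.Date(paste0(year, "-01-01")),
           as.Date(paste0(year, "-12-31")), by = "day")
  weather_series(d, rep(i_min, length(d)), rep(i_mean, length(d)),
                 rep(i_max, length(d)))
}

# scalar effective temperature, written out independently
oracle_bteff <- function(bt) {
  if (bt <= 8.3 || bt >= 38.9) return(0)
  if (bt <= 30.4) return(bt - 8.3)
  v <- (30.4 - 8.3) * (exp(0.02876507 * bt) -
    exp(0.02876507 * 40.9958913 - (40.9958913 - bt) / 3.5922336) -
    1.24657367)
  max(0, v)
}

oracle_daylength <- function(lat, doy) {
  dec <- 23.44 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  x <- -tan(lat * pi / 180) * tan(dec)
  x <- min(1, max(-1, x))
  2 * acos(x) * 180 / pi / 15
}

# Full naive re-simulation of one site-year for one scenario.
# Returns onsets (Dates), per-brood final tsums and the daily F1 tsum.
oracle_point <- function(w, latitude, scenario) {
  start <- as.Date(paste0(format(w$date[1], "%Y"), "-03-07"))
  end <- as.Date(paste0(format(w$date[1], "%Y"), "-10-31"))
  keep <- w$date >= start & w$date <= end
  dates <- w$date[keep]
  imax <- w$i_max[keep]
  n <- length(dates)
  raw <- switch(scenario, min = w$i_min[keep], avg = w$i_mean[keep],
                max = w$i_max[keep])
  at <- switch(scenario,
               min = 1.44 + 0.82 * raw,
               avg = 0.50 + 0.81 * raw,
               max = 1.03 + 0.86 * raw)
  bt <- switch(scenario,
               min = 0.56 + 0.99 * at,
               avg = -0.48 + 1.03 * at,
               max = 0.03 + 0.99 * at)
  bteff <- vapply(bt, oracle_bteff, numeric(1))
  doy <- as.integer(format(dates, "%j"))
  dl <- vapply(doy, function(d) oracle_daylength(latitude, d),
               numeric(1))

  onset_of <- function(thr) {
    for (d in seq_len(n)) {
      s <- 0
      for (j in seq_len(d)) s <- s + max(0, imax[j] - 8.3)
      if (s >= thr && imax[d] > 14.5) return(d)
    }
    NA_integer_
  }
  sw <- onset_of(53.0)
  inf <- onset_of(155.6)

  tsum_from <- function(from, upto) {
    s <- 0
    for (j in from:upto) s <- s + bteff[j]
    s / 557
  }
  out <- list(swarming = if (is.na(sw)) as.Date(NA) else dates[sw],
              infestation = if (is.na(inf)) as.Date(NA) else dates[inf],
              final = c(), onsets = c())
  if (is.na(inf)) return(out)
  # daily F1 tsum, re-summed from scratch each day
  ts1 <- numeric(n)
  for (d in inf:n) ts1[d] <- tsum_from(inf, d)
  finals <- c(F1 = ts1[n])
  onsets <- c(F1 = dates[inf])
  thresholds <- c(S1 = 0.5, S2 = 1.5, S3 = 2.5, F2 = 1, F3 = 2)
  for (b in names(thresholds)) {
    o <- NA_integer_
    for (d in seq_len(n)) {
      if (ts1[d] > thresholds[[b]] && imax[d] > 14.5 && dl[d] >= 14.5) {
        o <- d; break
      }
    }
    if (!is.na(o)) {
      finals[b] <- tsum_from(o, n)
      onsets[b] <- dates[o]
    }
  }
  out$final <- finals
  out$onsets <- as.Date(onsets, origin = "1970-01-01")
  out
}
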