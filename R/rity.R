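#' Simulate spruce bark beetle phenology
#'
#' Front end of the phenology model: simulates one site-year under one
#' or more temperature scenarios and returns a classed result with
#' print, summary, plot and as.data.frame methods. The `"min"`,
#' `"avg"` and `"max"` scenarios drive development with the daily
#' minimum, mean and maximum bark temperature respectively and bracket
#' the plausible development envelope at the site.
#'
#' @param w a daily weather series (see [weather_series()]) covering
#'   the simulation window.
#' @param latitude site latitude, degrees north.
#' @param p model parameters, see [rity_params()].
#' @param scenarios character vector of scenarios to run, a subset of
#'   `c("min", "avg", "max")` (default all three).
#' @return An object of class `"rity"`: a named list of
#'   [simulate_point()] results, one per scenario, with attributes
#'   `latitude` and `params`.
#' @examples
#' w <- generate_series(climate_spec(seed = 1, year = 2020))
#' fit <- rity(w, latitude = 46.37)
#' fit
#' summary(fit)
#' @export
rity <- function(w, latitude, p = rity_params(),
                 scenarios = c("min", "avg", "max")) {
  scenarios <- match.arg(scenarios, c("min", "avg", "max"),
                         several.ok = TRUE)
  res <- lapply(scenarios, function(s) simulate_point(w, latitude, p, s))
  names(res) <- scenarios
  structure(res, latitude = latitude, params = p, class = "rity")
}

fmt_date <- function(d) if (is.na(d)) "not reached" else format(d)

#' @export
print.rity_point <- function(x, ...) {
  cat(sprintf("Phenology simulation (%s scenario), %s .. %s, lat %.2f N\n",
              toupper(x$scenario), x$dates[1], x$dates[length(x$dates)],
              x$latitude))
  cat("  swarming onset   :", fmt_date(x$swarming_onset), "\n")
  cat("  infestation onset:", fmt_date(x$infestation_onset), "\n")
  if (length(x$broods)) {
    for (b in x$broods)
      cat(sprintf("  %-3s onset %s, final Tsum %.3f%s\n", b$brood_id,
                  format(b$onset), b$final_tsum,
                  if (b$survives) " (hibernates)" else ""))
  } else cat("  no broods initiated\n")
  cat(sprintf("  potential generations: %d filial + %d sister\n",
              x$n_filial, x$n_sister))
  invisible(x)
}

#' @export
print.rity <- function(x, ...) {
  for (s in names(x)) { print(x[[s]]); cat("\n") }
  invisible(x)
}

#' Per-brood summary table of a phenology simulation
#'
#' One row per scenario and brood with onset date, end-of-season
#' relative thermal sum, stage reached and hibernation survival, plus
#' the onset and generation-count columns of the site.
#'
#' @param object a `"rity"` object.
#' @param ... unused.
#' @return A data frame of class `"summary.rity"`.
#' @export
summary.rity <- function(object, ...) {
  rows <- lapply(names(object), function(s) {
    r <- object[[s]]
    if (length(r$broods) == 0)
      return(data.frame(scenario = s, brood = NA_character_,
                        onset = as.Date(NA), final_tsum = NA_real_,
                        stage = NA_character_, survives = NA,
                        swarming = r$swarming_onset,
                        infestation = r$infestation_onset,
                        n_filial = r$n_filial, n_sister = r$n_sister))
    do.call(rbind, lapply(r$broods, function(b)
      data.frame(scenario = s, brood = b$brood_id, onset = b$onset,
                 final_tsum = b$final_tsum,
                 stage = as.character(classify_stage(
                   b$final_tsum, r$params$stage_bounds)),
                 survives = b$survives, swarming = r$swarming_onset,
                 infestation = r$infestation_onset,
                 n_filial = r$n_filial, n_sister = r$n_sister)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.rity", "data.frame")
  out
}

#' @export
print.summary.rity <- function(x, ...) {
  cat("Brood summary (per scenario)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Long-form daily development table
#'
#' One row per date, scenario and brood with the relative thermal sum
#' and developmental stage — the tidy daily output of the simulation.
#'
#' @param x a `"rity"` object.
#' @param ... unused.
#' @return Data frame with columns `date`, `scenario`, `brood_id`,
#'   `tsum`, `stage`.
#' @export
as.data.frame.rity <- function(x, ...) {
  rows <- lapply(names(x), function(s) {
    r <- x[[s]]
    do.call(rbind, lapply(r$broods, function(b)
      data.frame(date = r$dates, scenario = s, brood_id = b$brood_id,
                 tsum = b$tsum,
                 stage = as.character(classify_stage(
                   b$tsum, r$params$stage_bounds)))))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(date = as.Date(character()),
                      scenario = character(), brood_id = character(),
                      tsum = numeric(), stage = character())
  rownames(out) <- NULL
  out
}

#' Plot relative thermal sums
#'
#' Draws the daily relative thermal sum of every brood under each
#' simulated scenario, with the hibernation threshold as a horizontal
#' dotted line and the day the photoperiod drops below the diapause
#' gate as a vertical dotted line.
#'
#' @param x a `"rity"` object.
#' @param scenario which scenario to draw (default the first one).
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rity <- function(x, scenario = names(x)[1], ...) {
  r <- x[[scenario]]
  p <- r$params
  ymax <- max(1.05, vapply(r$broods, function(b) max(b$tsum), 0))
  graphics::plot(r$dates, rep(0, length(r$dates)), type = "n",
                 ylim = c(0, ymax), xlab = "", ylab = "relative thermal sum",
                 main = sprintf("Brood development, %s scenario",
                                toupper(scenario)), ...)
  graphics::abline(h = p$hibernation_min, lty = 3)
  gate_off <- which(r$daylength >= p$daylength_gate)
  if (length(gate_off) && max(gate_off) < length(r$dates))
    graphics::abline(v = r$dates[max(gate_off)], lty = 3)
  cols <- grDevices::hcl.colors(max(1L, length(r$broods)), "Dark 3")
  i <- 0
  for (b in r$broods) {
    i <- i + 1
    on <- b$tsum > 0 | r$dates >= b$onset
    graphics::lines(r$dates[on], b$tsum[on], col = cols[i], lwd = 2)
  }
  if (length(r$broods))
    graphics::legend("topleft", legend = vapply(r$broods, `[[`, "",
                                                "brood_id"),
                     col = cols[seq_along(r$broods)], lwd = 2, bty = "n")
  invisible(x)
}
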