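#' Phenology model parameters
#'
#' All tunable constants of the daily stepping engine, with the
#' published defaults. The simulation runs stepwise from `start_date`
#' to `end_date` of one calendar year.
#'
#' @param swarm_dd cumulative degree-days of daily `max(0, i_max - dt_l)`
#'   required for onset of spring swarming (default 53.0 dd).
#' @param infest_dd cumulative degree-days required for onset of
#'   infestation (default 155.6 dd).
#' @param flight_t daily maximum air temperature (gridded-product
#'   `i_max`) that must be strictly exceeded for flight activity on the
#'   onset day of any phenological event (default 14.5 degC).
#' @param daylength_gate minimum day length for initiation of new
#'   filial generations and sister broods; shorter days induce diapause
#'   (default 14.5 h).
#' @param k_total thermal sum required for total development,
#'   K (default 557 dd); relative thermal sums are accumulated
#'   effective temperature divided by K.
#' @param hibernation_min minimum end-of-season relative thermal sum
#'   for an initiated brood to hibernate successfully and be counted in
#'   the annual number of potential generations (default 0.6, i.e.
#'   pupal development complete).
#' @param start_date,end_date simulation window, `"MM-DD"` strings or
#'   `Date`s (defaults 7 March and 31 October; the year is taken from
#'   the weather series).
#' @param dev development-function constants, see [dev_params()].
#' @param max_filial,max_sister maximum number of filial generations /
#'   sister broods tracked (defaults 3 and 3).
#' @param stage_bounds relative-thermal-sum breakpoints separating
#'   egg / larva / pupa / teneral adult / emerged adult
#'   (default `c(0.1, 0.5, 0.6, 1.0)`).
#' @param horizon day-length horizon convention passed to
#'   [day_length()] (default 0, geometric).
#' @return A list of class `"rity_params"`.
#' @export
rity_params <- function(swarm_dd = 53.0, infest_dd = 155.6,
                        flight_t = 14.5, daylength_gate = 14.5,
                        k_total = 557, hibernation_min = 0.6,
                        start_date = "03-07", end_date = "10-31",
                        dev = dev_params(), max_filial = 3L,
                        max_sister = 3L,
                        stage_bounds = c(0.1, 0.5, 0.6, 1.0),
                        horizon = 0) {
  p <- list(swarm_dd = swarm_dd, infest_dd = infest_dd,
            flight_t = flight_t, daylength_gate = daylength_gate,
            k_total = k_total, hibernation_min = hibernation_min,
            start_date = start_date, end_date = end_date, dev = dev,
            max_filial = as.integer(max_filial),
            max_sister = as.integer(max_sister),
            stage_bounds = stage_bounds, horizon = horizon)
  if (!(swarm_dd > 0 && swarm_dd < infest_dd))
    stop("require 0 < swarm_dd < infest_dd", call. = FALSE)
  if (flight_t <= dev$dt_l)
    stop("flight_t must exceed the lower development threshold",
         call. = FALSE)
  if (!(hibernation_min > 0 && hibernation_min < 1))
    stop("hibernation_min must lie in (0, 1)", call. = FALSE)
  if (k_total <= 0) stop("k_total must be positive", call. = FALSE)
  if (length(stage_bounds) != 4 || is.unsorted(stage_bounds, strictly = TRUE) ||
      stage_bounds[1] <= 0 || stage_bounds[4] > 1)
    stop("stage_bounds must be 4 strictly increasing values in (0, 1]",
         call. = FALSE)
  if (p$max_filial < 1L || p$max_sister < 0L)
    stop("max_filial >= 1 and max_sister >= 0 required", call. = FALSE)
  class(p) <- "rity_params"
  p
}

# Resolve an "MM-DD" or Date field to a Date in `year`; start must
# precede end within the same calendar year.
resolve_window <- function(p, year) {
  as_md <- function(x) {
    if (inherits(x, "Date")) return(x)
    as.Date(paste0(year, "-", x))
  }
  start <- as_md(p$start_date); end <- as_md(p$end_date)
  if (is.na(start) || is.na(end))
    stop("invalid start_date/end_date", call. = FALSE)
  if (!(start < end))
    stop("start_date must precede end_date", call. = FALSE)
  list(start = start, end = end)
}

#' @export
print.rity_params <- function(x, ...) {
  cat("Phenology model parameters\n")
  cat(sprintf("  onset thresholds : swarming %.1f dd, infestation %.1f dd (on i_max - %.1f)\n",
              x$swarm_dd, x$infest_dd, x$dev$dt_l))
  cat(sprintf("  flight gate      : i_max > %.1f degC\n", x$flight_t))
  cat(sprintf("  diapause gate    : day length >= %.1f h\n", x$daylength_gate))
  cat(sprintf("  total development: K = %g dd; hibernation at Tsum >= %.2f\n",
              x$k_total, x$hibernation_min))
  cat(sprintf("  window           : %s .. %s; broods <= F%d, S%d\n",
              x$start_date, x$end_date, x$max_filial, x$max_sister))
  invisible(x)
}
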