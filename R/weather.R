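#' Construct a daily weather series
#'
#' A daily weather series is a data frame with one row per calendar day
#' and columns `date` (class `Date`), `i_min`, `i_mean`, `i_max`
#' (daily minimum, mean and maximum air temperature, degC) as supplied
#' by a gridded nowcasting product or a station. The constructor
#' validates the series invariants: dates strictly increasing by one
#' day with no gaps, no missing values, and `i_min <= i_mean <= i_max`
#' on every day.
#'
#' @param date `Date` vector (or ISO-8601 character).
#' @param i_min,i_mean,i_max daily temperatures, degC.
#' @return A validated data frame of class `c("rity_weather", "data.frame")`.
#' @export
weather_series <- function(date, i_min, i_mean, i_max) {
  w <- data.frame(date = as.Date(date), i_min = as.numeric(i_min),
                  i_mean = as.numeric(i_mean), i_max = as.numeric(i_max))
  class(w) <- c("rity_weather", "data.frame")
  validate_weather(w)
}

#' Validate a daily weather series
#'
#' Checks the invariants of a daily weather series and fails with a
#' precise message naming the first offending date or row. Returns the
#' (possibly re-classed) series invisibly usable in a pipeline.
#'
#' @param w a data frame with columns `date`, `i_min`, `i_mean`, `i_max`.
#' @return `w`, with class `rity_weather` prepended if absent.
#' @export
validate_weather <- function(w) {
  need <- c("date", "i_min", "i_mean", "i_max")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("weather series lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(w) == 0) stop("weather series is empty", call. = FALSE)
  if (anyNA(w[need]))
    stop("weather series contains missing values (first at row ",
         which(rowSums(is.na(w[need])) > 0)[1], ")", call. = FALSE)
  d <- diff(as.integer(w$date))
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    stop("dates not strictly increasing at ", w$date[i + 1], call. = FALSE)
  }
  if (any(d > 1)) {
    i <- which(d > 1)[1]
    stop("gap in daily series: missing date(s) after ", w$date[i],
         " (next present date ", w$date[i + 1], ")", call. = FALSE)
  }
  bad <- which(!(w$i_min <= w$i_mean & w$i_mean <= w$i_max))
  if (length(bad))
    stop("temperature ordering i_min <= i_mean <= i_max violated on ",
         w$date[bad[1]], " (row ", bad[1], ")", call. = FALSE)
  if (!inherits(w, "rity_weather")) class(w) <- c("rity_weather", class(w))
  w
}

# Subset a weather series to [from, to], failing loudly if days are missing.
window_weather <- function(w, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  keep <- w$date >= from & w$date <= to
  ww <- w[keep, , drop = FALSE]
  want <- seq(from, to, by = "day")
  if (nrow(ww) != length(want) || !all(ww$date == want)) {
    missing <- setdiff(format(want), format(ww$date))
    stop("weather does not cover ", from, "..", to, "; missing: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5),
         call. = FALSE)
  }
  rownames(ww) <- NULL
  ww
}
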