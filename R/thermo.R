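#' Development-rate function parameters
#'
#' Constants of the piecewise daily effective bark temperature function:
#' lower development threshold `dt_l` (8.3 degC), optimum `t_o`
#' (30.4 degC), upper threshold `dt_u` (38.9 degC) and the four
#' constants of the nonlinear branch used between the optimum and the
#' upper threshold.
#'
#' @param dt_l lower development threshold, degC.
#' @param t_o optimum temperature, degC.
#' @param dt_u upper development threshold, degC.
#' @param alpha,beta,gamma nonlinear-branch coefficients (all > 0).
#' @param t_max_nl nonlinear-curve temperature constant, degC.
#' @return A list of class `"dev_params"`.
#' @export
dev_params <- function(dt_l = 8.3, t_o = 30.4, dt_u = 38.9,
                       alpha = 0.02876507, beta = 3.5922336,
                       gamma = 1.24657367, t_max_nl = 40.9958913) {
  p <- list(dt_l = dt_l, t_o = t_o, dt_u = dt_u, alpha = alpha,
            beta = beta, gamma = gamma, t_max_nl = t_max_nl)
  if (!(dt_l < t_o && t_o < dt_u && dt_u < t_max_nl))
    stop("require dt_l < t_o < dt_u < t_max_nl", call. = FALSE)
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("alpha, beta, gamma must be positive", call. = FALSE)
  class(p) <- "dev_params"
  p
}

#' Forest-stand air temperatures from gridded-product temperatures
#'
#' Linear correction of daily minimum, mean and maximum air temperatures
#' from a gridded nowcasting product to air temperatures inside the
#' forest stand:
#' \deqn{AT_{min} = 1.44 + 0.82 I_{min}}
#' \deqn{AT_{mean} = 0.50 + 0.81 I_{mean}}
#' \deqn{AT_{max} = 1.03 + 0.86 I_{max}}
#'
#' @param w a daily weather series as returned by [weather_series()],
#'   or any data frame with columns `i_min`, `i_mean`, `i_max`.
#' @return A data frame with columns `at_min`, `at_mean`, `at_max`
#'   (degC), one row per input day.
#' @export
forest_air_temps <- function(w) {
  stopifnot(all(c("i_min", "i_mean", "i_max") %in% names(w)))
  data.frame(at_min  = 1.44 + 0.82 * w$i_min,
             at_mean = 0.50 + 0.81 * w$i_mean,
             at_max  = 1.03 + 0.86 * w$i_max)
}

#' Bark temperatures from forest air temperatures
#'
#' Linear models giving daily minimum, mean and maximum temperatures
#' under the bark from the corresponding forest air temperatures:
#' \deqn{BT_{min} = 0.56 + 0.99 AT_{min}}
#' \deqn{BT_{mean} = -0.48 + 1.03 AT_{mean}}
#' \deqn{BT_{max} = 0.03 + 0.99 AT_{max}}
#'
#' @param at a data frame with columns `at_min`, `at_mean`, `at_max`,
#'   as returned by [forest_air_temps()].
#' @return A data frame with columns `bt_min`, `bt_mean`, `bt_max` (degC).
#' @export
bark_temps <- function(at) {
  stopifnot(all(c("at_min", "at_mean", "at_max") %in% names(at)))
  data.frame(bt_min  = 0.56 + 0.99 * at$at_min,
             bt_mean = -0.48 + 1.03 * at$at_mean,
             bt_max  = 0.03 + 0.99 * at$at_max)
}

#' Daily effective bark temperature
#'
#' The portion of a daily bark temperature contributing to beetle
#' development, in degree-days per day. Piecewise in bark temperature
#' `bt`:
#' * `bt <= dt_l` or `bt >= dt_u`: 0;
#' * `dt_l < bt <= t_o` (linear branch): `bt - dt_l`;
#' * `t_o < bt < dt_u` (nonlinear branch):
#'   \deqn{(T_O - DT_L)(e^{\alpha BT} - e^{\alpha T_{max} -
#'   (T_{max} - BT)/\beta} - \gamma)}
#'
#' The linear branch owns `bt = t_o` exactly as printed, so the function
#' drops discontinuously from 22.1 to ~21.67 dd just above the optimum;
#' no smoothing is applied. The nonlinear branch is clamped at a floor
#' of 0 (its value at `dt_u` is ~+0.014 dd, but parameter edits or
#' roundoff could dip microscopically negative and development rates
#' cannot be negative).
#'
#' @param bt bark temperature, degC (vectorised).
#' @param p development-function constants, see [dev_params()].
#' @return Effective temperature in degree-days per day, `>= 0`.
#' @examples
#' effective_bark_temp(c(8.3, 20, 30.4, 35, 38.9))
#' @export
effective_bark_temp <- function(bt, p = dev_params()) {
  if (!is.numeric(bt) || any(!is.finite(bt)))
    stop("`bt` must be finite numeric", call. = FALSE)
  out <- numeric(length(bt))
  lin <- bt > p$dt_l & bt <= p$t_o
  out[lin] <- bt[lin] - p$dt_l
  nl <- bt > p$t_o & bt < p$dt_u
  if (any(nl)) {
    b <- bt[nl]
    v <- (p$t_o - p$dt_l) *
      (exp(p$alpha * b) -
         exp(p$alpha * p$t_max_nl - (p$t_max_nl - b) / p$beta) -
         p$gamma)
    out[nl] <- pmax(0, v)
  }
  out
}

#' Effective bark temperature series
#'
#' Elementwise [effective_bark_temp()] over a daily bark-temperature
#' series.
#'
#' @param bt_series numeric vector of daily bark temperatures, degC.
#' @param p development-function constants, see [dev_params()].
#' @return Numeric vector of daily degree-days, same length as input.
#' @export
effective_series <- function(bt_series, p = dev_params()) {
  effective_bark_temp(bt_series, p)
}
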