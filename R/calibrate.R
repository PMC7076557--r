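#' Mean absolute error between predicted and observed dates, in days
#'
#' Pairs with an absent (`NA`) prediction are excluded from the mean
#' and counted; the exclusion count is attached so the caller can
#' report prediction coverage. Pairs with an absent observation are
#' also skipped.
#'
#' @param predicted,observed paired `Date` vectors of equal length.
#' @return The MAE in days (numeric), with attributes `n` (valid pairs
#'   used) and `n_excluded` (pairs dropped for an absent prediction
#'   against a present observation). Errors if no valid pair remains.
#' @export
mae_days <- function(predicted, observed) {
  predicted <- as.Date(predicted); observed <- as.Date(observed)
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must be paired", call. = FALSE)
  has_obs <- !is.na(observed)
  valid <- has_obs & !is.na(predicted)
  excluded <- sum(has_obs & is.na(predicted))
  if (!any(valid))
    stop("no valid prediction/observation pairs", call. = FALSE)
  mae <- mean(abs(as.numeric(predicted[valid] - observed[valid])))
  structure(mae, n = sum(valid), n_excluded = excluded)
}

#' Calibrate the spring start date of the phenology model
#'
#' The latest calendar date from which the degree-day sums for onset
#' of swarming and infestation should be accumulated is found by an
#' iteration over candidate start dates: for each candidate the onset
#' detection is re-run for every observed site-year and the candidate
#' minimising the combined mean absolute error (the unweighted mean of
#' the swarming MAE and the infestation MAE) is chosen; among tied
#' minima the latest candidate wins. Candidates whose prediction
#' coverage falls below `min_coverage` of the observation pairs are
#' disqualified, so a start date too late to ever accumulate the
#' thresholds cannot win by attrition.
#'
#' @param obs data frame of onset observations with columns `site`,
#'   `year`, `latitude`, `observed_swarming`, `observed_infestation`
#'   (`Date` or ISO character; `NA` = not observed; each row needs at
#'   least one).
#' @param weather named list of daily weather series, one per
#'   site-year, keyed `"<site>_<year>"`, each covering the earliest
#'   candidate through the end of the season.
#' @param candidates candidate start dates as `"MM-DD"` strings
#'   (default every day from 1 February to 30 April).
#' @param p model parameters (its `start_date` is overridden by each
#'   candidate in turn).
#' @param min_coverage minimum fraction of pairs a candidate must
#'   predict to qualify (default 0.9).
#' @return An object of class `"rity_calibration"`: list with
#'   `chosen_start` (`"MM-DD"`), `mae_by_candidate` (data frame with
#'   one row per candidate: the two MAEs, the combined MAE, pair and
#'   exclusion counts, qualification flag) and `n_pairs`.
#' @export
calibrate_start_date <- function(obs, weather,
                                 candidates = candidate_grid(),
                                 p = rity_params(),
                                 min_coverage = 0.9) {
  need <- c("site", "year", "observed_swarming", "observed_infestation")
  if (!all(need %in% names(obs)))
    stop("`obs` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  obs$observed_swarming <- as.Date(obs$observed_swarming)
  obs$observed_infestation <- as.Date(obs$observed_infestation)
  if (any(is.na(obs$observed_swarming) & is.na(obs$observed_infestation)))
    stop("every observation row needs at least one observed date",
         call. = FALSE)
  keys <- paste(obs$site, obs$year, sep = "_")
  missing_w <- setdiff(keys, names(weather))
  if (length(missing_w))
    stop("no weather for site-year(s): ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  n_pairs <- sum(!is.na(obs$observed_swarming)) +
    sum(!is.na(obs$observed_infestation))

  one_candidate <- function(cand) {
    pc <- p
    pc$start_date <- cand
    pred_sw <- pred_in <- as.Date(rep(NA, nrow(obs)))
    for (i in seq_len(nrow(obs))) {
      ww <- weather[[keys[i]]]
      pred_sw[i] <- detect_onset(ww, pc$swarm_dd, pc)
      pred_in[i] <- detect_onset(ww, pc$infest_dd, pc)
    }
    term <- function(pred, o) {
      if (all(is.na(o))) return(list(mae = NA_real_, n = 0L, excl = 0L))
      if (all(is.na(pred[!is.na(o)])))
        return(list(mae = NA_real_, n = 0L, excl = sum(!is.na(o))))
      m <- mae_days(pred, o)
      list(mae = as.numeric(m), n = attr(m, "n"),
           excl = attr(m, "n_excluded"))
    }
    sw <- term(pred_sw, obs$observed_swarming)
    inf <- term(pred_in, obs$observed_infestation)
    covered <- sw$n + inf$n
    combined <- mean(c(sw$mae, inf$mae), na.rm = TRUE)
    data.frame(candidate = cand, mae_swarming = sw$mae,
               mae_infestation = inf$mae,
               mae_combined = if (is.nan(combined)) NA_real_ else combined,
               n_used = covered,
               n_excluded = sw$excl + inf$excl,
               qualified = covered >= min_coverage * n_pairs &
                 !is.nan(combined))
  }

  tab <- do.call(rbind, lapply(candidates, one_candidate))
  rownames(tab) <- NULL
  q <- tab[tab$qualified & !is.na(tab$mae_combined), , drop = FALSE]
  if (nrow(q) == 0)
    stop("no candidate start date qualifies (coverage < ",
         min_coverage, ")", call. = FALSE)
  best <- q[q$mae_combined <= min(q$mae_combined) + 1e-12, , drop = FALSE]
  # latest candidate among the minima, per the calibration rule
  chosen <- best$candidate[order(best$candidate)][nrow(best)]
  structure(list(chosen_start = chosen, mae_by_candidate = tab,
                 n_pairs = n_pairs, min_coverage = min_coverage),
            class = "rity_calibration")
}

#' Candidate start-date grid
#'
#' Every calendar day between two month-day bounds, as `"MM-DD"`
#' strings (a non-leap reference year is used to enumerate days).
#'
#' @param from,to bounds as `"MM-DD"` (defaults 1 February, 30 April).
#' @return Character vector of `"MM-DD"` candidates.
#' @export
candidate_grid <- function(from = "02-01", to = "04-30") {
  d <- seq(as.Date(paste0("2001-", from)), as.Date(paste0("2001-", to)),
           by = "day")
  format(d, "%m-%d")
}

#' @export
print.rity_calibration <- function(x, ...) {
  cat("Start-date calibration over", nrow(x$mae_by_candidate),
      "candidates,", x$n_pairs, "observation pairs\n")
  i <- match(x$chosen_start, x$mae_by_candidate$candidate)
  cat(sprintf("  chosen start date: %s (combined MAE %.3f days)\n",
              x$chosen_start, x$mae_by_candidate$mae_combined[i]))
  invisible(x)
}

#' @export
coef.rity_calibration <- function(object, ...) {
  c(start_doy = as.integer(format(
    as.Date(paste0("2001-", object$chosen_start)), "%j")))
}
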