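#' Build a log-ratio series for one storage temperature
#'
#' Turns the plate counts of one temperature series into the quantity the
#' first-order model is fitted on, ln(Nt/N0).
#'
#' Under `mean_log` aggregation, ln(count) is averaged across replicates at
#' each checkpoint (the log of the geometric mean) and the time-0 average is
#' subtracted, so the series starts at exactly 0. Under `pooled` aggregation
#' every replicate contributes its own ln(count / count at its time 0), one
#' point per observation.
#'
#' @param study a `stability_study`.
#' @param temperature series temperature in degC (matched within 0.01 degC).
#' @param config a [run_config()]; `replicate_aggregation` selects the mode.
#' @return An object of class `log_ratio_series` with fields `temperature`,
#'   `times` (months), `log_ratios` (ln Nt/N0), `n_replicates` (per point)
#'   and `aggregation`.
#' @examples
#' cfg <- synthetic_study_config(k_by_temperature = c("25" = 0.5),
#'                               biological_cv = 0, counting = "none")
#' s <- simulate_study(cfg)
#' build_log_ratio_series(s, 25)
#' @export
build_log_ratio_series <- function(study, temperature, config = run_config()) {
  stopifnot(inherits(study, "stability_study"))
  obs <- study$observations
  sel <- obs[abs(obs$temperature_C - temperature) <= TEMPERATURE_TOL, ,
             drop = FALSE]
  if (!nrow(sel)) {
    stop("no observations at ", temperature, " degC in study '",
         study$label, "'", call. = FALSE)
  }
  if (any(sel$cfu_per_g <= 0)) {
    stop("non-positive counts in the ", temperature,
         " degC series; apply an LOD policy before fitting", call. = FALSE)
  }
  if (length(unique(sel$time_months)) < 2) {
    stop("insufficient data: series at ", temperature,
         " degC has fewer than 2 distinct time points", call. = FALSE)
  }

  if (config$replicate_aggregation == "mean_log") {
    times <- sort(unique(sel$time_months))
    if (!0 %in% times) {
      stop("incomplete series: no time-0 observation at ", temperature,
           " degC", call. = FALSE)
    }
    mean_ln <- vapply(times, function(t) {
      mean(log(sel$cfu_per_g[sel$time_months == t]))
    }, numeric(1))
    n_rep <- vapply(times, function(t) sum(sel$time_months == t), integer(1))
    log_ratios <- mean_ln - mean_ln[times == 0]
  } else {
    reps <- unique(sel$replicate_id)
    times <- numeric(0); log_ratios <- numeric(0)
    for (r in reps) {
      rr <- sel[sel$replicate_id == r, , drop = FALSE]
      base <- rr$cfu_per_g[rr$time_months == 0]
      if (!length(base)) {
        stop("incomplete series: replicate ", r, " at ", temperature,
             " degC lacks a time-0 observation", call. = FALSE)
      }
      ln0 <- mean(log(base))
      times <- c(times, rr$time_months)
      log_ratios <- c(log_ratios, log(rr$cfu_per_g) - ln0)
    }
    ord <- order(times)
    times <- times[ord]; log_ratios <- log_ratios[ord]
    n_rep <- rep(1L, length(times))
  }

  structure(
    list(temperature = temperature, times = times, log_ratios = log_ratios,
         n_replicates = n_rep, aggregation = config$replicate_aggregation),
    class = "log_ratio_series"
  )
}

#' @export
print.log_ratio_series <- function(x, ...) {
  cat("ln(Nt/N0) series at ", x$temperature, " degC (",
      x$aggregation, " aggregation), ", length(x$times), " points\n", sep = "")
  print(data.frame(time_months = x$times, log_ratio = x$log_ratios,
                   n = x$n_replicates), row.names = FALSE)
  invisible(x)
}

#' Fit first-order viability-loss kinetics to one temperature series
#'
#' Ordinary least squares of ln(Nt/N0) on time. The destruction rate is
#' k = -slope (months^-1); decimal-reduction times D1, D2, D3 are attached
#' whenever k > 0. With `fit_mode = "through_origin"` the intercept is fixed
#' at 0 and the coefficient of determination is the uncentered
#' 1 - SSE / sum(y^2), since the centered version is ill-defined without an
#' intercept; with `free_intercept` it is the usual 1 - SSE/SST.
#'
#' @param series a `log_ratio_series` (or a list/data frame with `times` and
#'   `log_ratios`).
#' @param config a [run_config()]; `fit_mode` selects the intercept handling.
#' @return An object of class `decay_fit` with fields `temperature`, `k`,
#'   `k_se`, `intercept`, `r_squared`, `n_points`, `fit_mode` and `D1`, `D2`,
#'   `D3` (`NA` when k <= 0).
#' @examples
#' s <- list(temperature = 25, times = c(0, 3, 6, 9, 12),
#'           log_ratios = -0.5 * c(0, 3, 6, 9, 12))
#' fit_decay(s)$k
#' @export
fit_decay <- function(series, config = run_config()) {
  t <- series$times
  y <- series$log_ratios
  if (length(t) != length(y)) {
    stop("times and log_ratios differ in length", call. = FALSE)
  }
  n_min <- if (config$fit_mode == "through_origin") 2L else 3L
  if (length(t) < n_min) {
    stop("insufficient data: ", length(t), " point(s); ", config$fit_mode,
         " fitting needs at least ", n_min, call. = FALSE)
  }
  if (length(unique(t)) < 2) {
    stop("singular design: all time values identical", call. = FALSE)
  }

  if (config$fit_mode == "free_intercept") {
    fit <- stats::lm(y ~ t)
    slope <- unname(stats::coef(fit)["t"])
    intercept <- unname(stats::coef(fit)["(Intercept)"])
    sse <- sum(stats::residuals(fit)^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sse / sst else 1
    # slope SE from the residual variance; avoids summary.lm's chatter on
    # exact fits
    k_se <- if (length(t) > 2) {
      sqrt(sse / (length(t) - 2) / sum((t - mean(t))^2))
    } else {
      NA_real_
    }
  } else {
    fit <- stats::lm(y ~ t - 1)
    slope <- unname(stats::coef(fit)["t"])
    intercept <- 0
    sse <- sum(stats::residuals(fit)^2)
    ssy <- sum(y^2)
    r2 <- if (ssy > 0) 1 - sse / ssy else 1
    k_se <- if (length(t) > 1) {
      sqrt(sse / (length(t) - 1) / sum(t^2))
    } else {
      NA_real_
    }
  }

  k <- -slope
  ds <- if (k > 0) d_values(k) else c(D1 = NA_real_, D2 = NA_real_,
                                      D3 = NA_real_)
  structure(
    list(
      temperature = if (!is.null(series$temperature)) series$temperature
                    else NA_real_,
      k = k, k_se = unname(k_se), intercept = intercept,
      r_squared = r2, n_points = length(t), fit_mode = config$fit_mode,
      D1 = unname(ds["D1"]), D2 = unname(ds["D2"]), D3 = unname(ds["D3"])
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, sig_figs = 2L, ...) {
  cat("First-order decay fit",
      if (!is.na(x$temperature)) paste0(" at ", x$temperature, " degC"),
      " (", x$fit_mode, ", n = ", x$n_points, ")\n", sep = "")
  cat("  k  = ", signif(x$k, sig_figs), " months^-1   (full: ",
      format(x$k, digits = 10), ")\n", sep = "")
  cat("  R2 = ", format(x$r_squared, digits = 4), "\n", sep = "")
  if (!is.na(x$D1)) {
    cat("  D1/D2/D3 = ", paste(signif(c(x$D1, x$D2, x$D3), sig_figs),
                               collapse = " / "), " months\n", sep = "")
  } else {
    cat("  non-decaying series (k <= 0): D-values undefined\n")
  }
  invisible(x)
}

#' Decimal-reduction times from a destruction rate
#'
#' D1 is the time for the viable population to fall by 90% (one log10);
#' under first-order kinetics D1 = ln(10)/k. D2 and D3 extend this to 99%
#' and 99.9% reductions: D2 = 2 D1, D3 = 3 D1.
#'
#' @param k destruction rate, months^-1; must be > 0.
#' @return Named numeric vector `c(D1, D2, D3)` in months.
#' @examples
#' d_values(0.51)  # D1 about 4.5 months
#' @export
d_values <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("d_values() requires a single destruction rate k > 0", call. = FALSE)
  }
  d1 <- log(10) / k
  c(D1 = d1, D2 = 2 * d1, D3 = 3 * d1)
}

#' Fit decay kinetics for every temperature series of a study
#'
#' Convenience wrapper running [build_log_ratio_series()] and [fit_decay()]
#' over all storage temperatures.
#'
#' @param study a `stability_study`.
#' @param config a [run_config()].
#' @return A list of `decay_fit` objects, one per temperature, in increasing
#'   temperature order; collapse with [as.data.frame.decay_fit_list()].
#' @export
fit_study_kinetics <- function(study, config = run_config()) {
  temps <- study_temperatures(study)
  fits <- lapply(temps, function(tmp) {
    fit_decay(build_log_ratio_series(study, tmp, config), config)
  })
  structure(fits, class = "decay_fit_list")
}

#' @export
print.decay_fit_list <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Tabulate a list of decay fits
#'
#' @param x a `decay_fit_list` from [fit_study_kinetics()].
#' @param ... unused.
#' @return Data frame with one row per temperature: k, its standard error,
#'   R-squared and the D-values.
#' @export
as.data.frame.decay_fit_list <- function(x, ...) {
  do.call(rbind, lapply(x, function(f) {
    data.frame(temperature_C = f$temperature, k = f$k, k_se = f$k_se,
               intercept = f$intercept, r_squared = f$r_squared,
               n_points = f$n_points, D1 = f$D1, D2 = f$D2, D3 = f$D3)
  }))
}
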