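#' Relative tolerance band check
#'
#' A measurement agrees with its prediction when it falls inside a symmetric
#' relative band around the predicted value:
#' |observed - predicted| <= band * predicted. The default 30% reflects the
#' commonly accepted overall variability of plate counts (biology, sampling,
#' serial dilution).
#'
#' @param observed observed value(s), e.g. CFU/g.
#' @param predicted predicted value(s), > 0 (recycled against `observed`).
#' @param band relative band, a fraction strictly between 0 and 1.
#' @return Logical vector, `TRUE` where the observation lies within the band.
#' @examples
#' band_check(1.29e9, 1e9)          # inside +/-30%
#' band_check(1.35e9, 1e9)          # outside
#' @export
band_check <- function(observed, predicted, band = 0.30) {
  if (!is.numeric(band) || length(band) != 1L || band <= 0 || band >= 1) {
    stop("band must be a fraction strictly between 0 and 1", call. = FALSE)
  }
  if (any(predicted <= 0)) {
    stop("predicted values must be positive", call. = FALSE)
  }
  abs(observed - predicted) <= band * predicted
}

#' Compare observed destruction rates against a reference kinetic
#'
#' Implements the batch-evaluation procedure: destruction rates measured on a
#' new batch are set against the rates the reference Arrhenius model predicts
#' at the same temperatures. Agreement is summarised by the guiding
#' coefficient — the slope of a through-origin regression of observed on
#' predicted k, which is 1 under perfect proportional agreement — together
#' with its uncentered R-squared, and per-pair band verdicts. Free-intercept
#' regression diagnostics are attached for reference.
#'
#' @param observed data frame with columns `temperature_C` and `k`
#'   (months^-1), or a `decay_fit_list`.
#' @param fit the reference `arrhenius_fit`.
#' @param band relative tolerance band for per-pair verdicts (default 0.30).
#' @param counts optional data frame of count-level checks with columns
#'   `temperature_C`, `time_months`, `observed_cfu`, `predicted_cfu`;
#'   a `within_band` verdict is appended to each row.
#' @return An object of class `comparison_report`: `pairs` (temperature,
#'   k_observed, k_predicted, within_band), `guiding_coefficient`,
#'   `r_squared`, free-intercept `slope_free`/`intercept_free`,
#'   `count_checks` (or NULL) and `band`.
#' @examples
#' ref <- fit_arrhenius(data.frame(temperature_C = c(20, 25, 30),
#'                                 k = c(0.03, 0.08, 0.19)))
#' compare_k(data.frame(temperature_C = 40, k = 1.17), ref)
#' @export
compare_k <- function(observed, fit, band = 0.30, counts = NULL) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  if (inherits(observed, "decay_fit_list")) {
    observed <- as.data.frame(observed)
  }
  observed <- as.data.frame(observed)
  if (!nrow(observed)) {
    stop("no observed (temperature, k) pairs to compare", call. = FALSE)
  }
  if (!all(c("temperature_C", "k") %in% names(observed))) {
    stop("`observed` needs columns temperature_C and k", call. = FALSE)
  }

  pred <- as.numeric(predict_k(fit, observed$temperature_C))
  obs <- observed$k
  # through-origin least squares: slope = sum(obs*pred)/sum(pred^2)
  gc <- sum(obs * pred) / sum(pred^2)
  ss_res <- sum((obs - gc * pred)^2)
  r2 <- if (sum(obs^2) > 0) 1 - ss_res / sum(obs^2) else 1

  if (nrow(observed) >= 3) {
    free <- stats::lm(obs ~ pred)
    slope_free <- unname(stats::coef(free)["pred"])
    intercept_free <- unname(stats::coef(free)["(Intercept)"])
  } else {
    slope_free <- NA_real_
    intercept_free <- NA_real_
  }

  pairs <- data.frame(
    temperature_C = observed$temperature_C,
    k_observed = obs, k_predicted = pred,
    within_band = band_check(obs, pred, band)
  )

  count_checks <- NULL
  if (!is.null(counts)) {
    counts <- as.data.frame(counts)
    needed <- c("temperature_C", "time_months", "observed_cfu",
                "predicted_cfu")
    if (!all(needed %in% names(counts))) {
      stop("`counts` needs columns ", paste(needed, collapse = ", "),
           call. = FALSE)
    }
    counts$within_band <- band_check(counts$observed_cfu,
                                     counts$predicted_cfu, band)
    count_checks <- counts
  }

  structure(
    list(pairs = pairs, guiding_coefficient = gc, r_squared = r2,
         slope_free = slope_free, intercept_free = intercept_free,
         count_checks = count_checks, band = band),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Observed-vs-predicted destruction rates (",
      nrow(x$pairs), " temperature(s), band +/-", x$band * 100, "%)\n",
      sep = "")
  print(x$pairs, row.names = FALSE)
  cat("  guiding coefficient (through-origin slope): ",
      format(x$guiding_coefficient, digits = 5),
      "  (R2 = ", format(x$r_squared, digits = 4), ")\n", sep = "")
  if (!is.null(x$count_checks)) {
    cat("  count-level checks:\n")
    print(x$count_checks, row.names = FALSE)
  }
  verdict <- all(x$pairs$within_band) &&
    (is.null(x$count_checks) || all(x$count_checks$within_band))
  cat("  overall: ", if (verdict) "PASS" else "FAIL",
      " (all checks within band: ", verdict, ")\n", sep = "")
  invisible(x)
}

#' Truncate a study at a time horizon
#'
#' Keeps observations with time <= `horizon` months.
#'
#' @param study a `stability_study`.
#' @param horizon months.
#' @return A `stability_study` restricted to the horizon.
#' @export
truncate_study <- function(study, horizon) {
  stopifnot(inherits(study, "stability_study"))
  obs <- study$observations
  kept <- obs[obs$time_months <= horizon, , drop = FALSE]
  stability_study(kept, label = paste0(study$label, " (<=", horizon, " mo)"),
                  metadata = study$metadata, validate = FALSE)
}

#' Study-length robustness of the kinetic parameters
#'
#' Runs the full pipeline (per-temperature decay fits, then the Arrhenius
#' fit) on the same study truncated at two time horizons and reports the
#' relative differences in each destruction rate and in the activation
#' energy. A short accelerated-design question in practice: does a 6-month
#' follow-up give the same kinetic as the 12-month one the ICH Q1A guideline
#' requires? On data that follow the model exactly the differences are zero
#' at any pair of horizons.
#'
#' @param study a `stability_study` covering both horizons.
#' @param horizon_a shorter horizon, months.
#' @param horizon_b longer horizon, months.
#' @param config a [run_config()].
#' @param tolerance relative difference below which the two fits are called
#'   concordant (default 0.15).
#' @return An object of class `robustness_report`: per-temperature table of
#'   `k_a`, `k_b`, `delta_k_rel` (= (k_a - k_b)/k_b), the two Arrhenius
#'   fits, `delta_ea_rel`, the horizons, tolerance and a `concordant` flag.
#' @export
truncation_robustness <- function(study, horizon_a, horizon_b,
                                  config = run_config(), tolerance = 0.15) {
  stopifnot(inherits(study, "stability_study"))
  if (horizon_a >= horizon_b) {
    stop("horizon_a must be shorter than horizon_b", call. = FALSE)
  }
  if (max(study$observations$time_months) < horizon_b) {
    stop("study does not cover the longer horizon (", horizon_b, " months)",
         call. = FALSE)
  }
  run <- function(horizon) {
    s <- truncate_study(study, horizon)
    n_min <- if (config$fit_mode == "through_origin") 2L else 3L
    for (tmp in study_temperatures(s)) {
      sel <- s$observations[abs(s$observations$temperature_C - tmp) <=
                              TEMPERATURE_TOL, , drop = FALSE]
      if (length(unique(sel$time_months)) < n_min) {
        stop("insufficient data at horizon ", horizon, " months: series at ",
             tmp, " degC has fewer than ", n_min, " checkpoints",
             call. = FALSE)
      }
    }
    fits <- fit_study_kinetics(s, config)
    list(fits = fits, arrhenius = fit_arrhenius(fits))
  }
  a <- run(horizon_a)
  b <- run(horizon_b)

  ta <- as.data.frame(a$fits); tb <- as.data.frame(b$fits)
  merged <- merge(ta[c("temperature_C", "k")], tb[c("temperature_C", "k")],
                  by = "temperature_C", suffixes = c("_a", "_b"))
  merged$delta_k_rel <- (merged$k_a - merged$k_b) / merged$k_b
  delta_ea_rel <- (a$arrhenius$Ea - b$arrhenius$Ea) / b$arrhenius$Ea

  structure(
    list(per_temperature = merged,
         arrhenius_a = a$arrhenius, arrhenius_b = b$arrhenius,
         delta_ea_rel = delta_ea_rel,
         horizons = c(horizon_a, horizon_b), tolerance = tolerance,
         concordant = all(abs(merged$delta_k_rel) <= tolerance) &&
           abs(delta_ea_rel) <= tolerance),
    class = "robustness_report"
  )
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Study-length robustness: ", x$horizons[1], " vs ", x$horizons[2],
      " months\n", sep = "")
  print(x$per_temperature, row.names = FALSE)
  cat("  Ea: ", format(x$arrhenius_a$Ea / 1000, digits = 4), " vs ",
      format(x$arrhenius_b$Ea / 1000, digits = 4), " kJ/mol (relative diff ",
      format(x$delta_ea_rel, digits = 3), ")\n", sep = "")
  cat("  concordant at +/-", x$tolerance * 100, "%: ", x$concordant, "\n",
      sep = "")
  invisible(x)
}
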