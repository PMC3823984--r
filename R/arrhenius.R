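#' Gas constant, J mol^-1 K^-1
#' @keywords internal
GAS_CONSTANT <- 8.314

# Celsius -> Kelvin, with a physicality check
to_kelvin <- function(temperature_C) {
  if (any(temperature_C <= -273.15)) {
    stop("temperature at or below absolute zero", call. = FALSE)
  }
  temperature_C + 273.15
}

#' Fit the Arrhenius temperature model to destruction rates
#'
#' The Arrhenius equation k = A exp(-Ea/(R T)) is linear in ln k versus 1/T
#' (T in Kelvin): the slope is -Ea/R and the intercept ln A. This fits that
#' line by ordinary least squares, so the activation energy Ea = -slope * R
#' (R = 8.314 J mol^-1 K^-1) and the frequency factor A = exp(intercept).
#'
#' @param points destruction rates by temperature: a data frame with columns
#'   `temperature_C` and `k`, a `decay_fit_list` from [fit_study_kinetics()],
#'   or a named numeric vector of k keyed by temperature (degC). All k must
#'   be positive and temperatures distinct; at least two points are required
#'   (a two-point fit carries a warning since its R-squared is trivially 1).
#' @return An object of class `arrhenius_fit` with fields `slope` (Kelvin),
#'   `intercept` (ln months^-1), `Ea` (J/mol), `A` (months^-1), `r_squared`,
#'   `n_points` and `fitted_temperature_range` (degC).
#' @examples
#' fit <- fit_arrhenius(data.frame(temperature_C = c(20, 25, 30),
#'                                 k = c(0.51, 0.80, 1.34)))
#' signif(fit$Ea / 1000, 2)  # activation energy, kJ/mol
#' @export
fit_arrhenius <- function(points) {
  if (inherits(points, "decay_fit_list")) {
    points <- as.data.frame(points)
  } else if (is.numeric(points) && !is.null(names(points))) {
    points <- data.frame(temperature_C = as.numeric(names(points)),
                         k = unname(points))
  }
  points <- as.data.frame(points)
  if (!all(c("temperature_C", "k") %in% names(points))) {
    stop("`points` needs columns temperature_C and k", call. = FALSE)
  }
  tc <- points$temperature_C; k <- points$k
  if (length(k) < 2) {
    stop("at least two (temperature, k) points are required", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("all destruction rates must be positive and finite to take ln k",
         call. = FALSE)
  }
  if (anyDuplicated(round(tc / TEMPERATURE_TOL))) {
    stop("singular design: duplicate temperatures", call. = FALSE)
  }

  x <- 1 / to_kelvin(tc)
  y <- log(k)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)["x"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  if (length(k) == 2) {
    warning("Arrhenius fit from only two points: R-squared is trivially 1",
            call. = FALSE)
  }

  structure(
    list(slope = slope, intercept = intercept,
         Ea = -slope * GAS_CONSTANT, A = exp(intercept),
         r_squared = r2, n_points = length(k),
         fitted_temperature_range = range(tc)),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, sig_figs = 2L, ...) {
  cat("Arrhenius fit of ln k vs 1/T (", x$n_points, " temperatures, ",
      paste(x$fitted_temperature_range, collapse = "-"), " degC)\n", sep = "")
  cat("  Ea = ", signif(x$Ea / 1000, sig_figs), " kJ/mol   (full: ",
      format(x$Ea / 1000, digits = 8), ")\n", sep = "")
  cat("  A  = ", format(x$A, digits = 4), " months^-1\n", sep = "")
  cat("  R2 = ", format(x$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict the destruction rate at any temperature
#'
#' Evaluates the fitted Arrhenius line, k = exp(intercept + slope / T_K).
#' Temperatures outside the fitted range are extrapolations — the central use
#' of accelerated stability testing — and are flagged, never refused.
#'
#' @param fit an `arrhenius_fit`.
#' @param temperature degC (vectorised).
#' @return Numeric destruction rate(s), months^-1, with attribute
#'   `extrapolated` (logical, per element).
#' @examples
#' fit <- fit_arrhenius(data.frame(temperature_C = c(20, 25, 30),
#'                                 k = c(0.03, 0.08, 0.19)))
#' predict_k(fit, 40)  # accelerated condition, outside the fitted range
#' @export
predict_k <- function(fit, temperature) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  tk <- to_kelvin(temperature)
  k <- exp(fit$intercept + fit$slope / tk)
  rng <- fit$fitted_temperature_range
  attr(k, "extrapolated") <-
    temperature < rng[1] - TEMPERATURE_TOL |
    temperature > rng[2] + TEMPERATURE_TOL
  k
}

#' Predict viable count at a storage condition and time
#'
#' First-order decay forward in time: Nt = N0 exp(-k t), with k either given
#' directly or obtained from an Arrhenius fit at the requested temperature.
#' The result carries a symmetric relative tolerance band around the
#' prediction, the practical acceptance window for plate-count agreement.
#'
#' @param fit_or_k an `arrhenius_fit`, or a single destruction rate
#'   (months^-1).
#' @param N0 initial viable count, CFU/g (> 0).
#' @param time months since time 0 (>= 0).
#' @param temperature degC; required when `fit_or_k` is an Arrhenius fit.
#' @param band relative band as a fraction of the predicted count
#'   (default 0.30).
#' @return An object of class `viability_prediction`: `temperature`, `time`,
#'   `k_used`, `log_ratio` (= -k t), `predicted_count`, `band_low`,
#'   `band_high` (CFU/g) and `extrapolated`.
#' @examples
#' predict_viability(0.08, N0 = 1e10, time = 12)
#' @export
predict_viability <- function(fit_or_k, N0, time, temperature = NULL,
                              band = 0.30) {
  if (!is.numeric(N0) || length(N0) != 1L || N0 <= 0) {
    stop("N0 must be a single positive count", call. = FALSE)
  }
  if (!is.numeric(time) || length(time) != 1L || time < 0) {
    stop("time must be a single non-negative number of months", call. = FALSE)
  }
  extrapolated <- FALSE
  if (inherits(fit_or_k, "arrhenius_fit")) {
    if (is.null(temperature)) {
      stop("temperature is required when predicting from an Arrhenius fit",
           call. = FALSE)
    }
    k <- predict_k(fit_or_k, temperature)
    extrapolated <- attr(k, "extrapolated")
    k <- as.numeric(k)
  } else {
    k <- as.numeric(fit_or_k)
    if (length(k) != 1L || !is.finite(k)) {
      stop("fit_or_k must be an arrhenius_fit or a single rate", call. = FALSE)
    }
  }
  log_ratio <- -k * time
  nt <- N0 * exp(log_ratio)
  structure(
    list(temperature = if (is.null(temperature)) NA_real_ else temperature,
         time = time, k_used = k, log_ratio = log_ratio,
         predicted_count = nt,
         band_low = nt * (1 - band), band_high = nt * (1 + band),
         band = band, extrapolated = isTRUE(extrapolated)),
    class = "viability_prediction"
  )
}

#' @export
print.viability_prediction <- function(x, ...) {
  cat("Predicted viability at t = ", x$time, " months",
      if (!is.na(x$temperature)) paste0(", T = ", x$temperature, " degC"),
      if (x$extrapolated) " (extrapolated T)", "\n", sep = "")
  cat("  k used = ", format(x$k_used, digits = 4), " months^-1;  ln(Nt/N0) = ",
      format(x$log_ratio, digits = 4), "\n", sep = "")
  cat("  Nt = ", format(x$predicted_count, digits = 3), " CFU/g  [band +/-",
      x$band * 100, "%: ", format(x$band_low, digits = 3), " - ",
      format(x$band_high, digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Shelf-life against a specification limit
#'
#' Time for the viable count to decay from `N0` to the limit `N_min` under
#' first-order kinetics: t* = ln(N0/N_min)/k. With `N_min = N0/10` this is
#' exactly the decimal-reduction time D1.
#'
#' @param fit_or_k an `arrhenius_fit` (with `temperature`) or a destruction
#'   rate, months^-1.
#' @param N0 initial count, CFU/g.
#' @param N_min specification limit, CFU/g; 0 < N_min <= N0.
#' @param temperature degC, when predicting k from an Arrhenius fit.
#' @return Shelf-life in months. `Inf` with a warning when k <= 0 (no finite
#'   shelf-life under a non-decaying kinetic).
#' @examples
#' shelf_life(0.51, N0 = 1e10, N_min = 1e9)  # one decade = D1
#' @export
shelf_life <- function(fit_or_k, N0, N_min, temperature = NULL) {
  if (!is.numeric(N0) || N0 <= 0) stop("N0 must be positive", call. = FALSE)
  if (!is.numeric(N_min) || N_min <= 0) {
    stop("N_min must be positive", call. = FALSE)
  }
  if (N_min > N0) {
    stop("N_min exceeds N0: the specification is never met by decay",
         call. = FALSE)
  }
  k <- if (inherits(fit_or_k, "arrhenius_fit")) {
    if (is.null(temperature)) {
      stop("temperature is required when predicting from an Arrhenius fit",
           call. = FALSE)
    }
    as.numeric(predict_k(fit_or_k, temperature))
  } else {
    as.numeric(fit_or_k)
  }
  if (k <= 0) {
    warning("k <= 0: no finite shelf-life under a non-decaying kinetic",
            call. = FALSE)
    return(Inf)
  }
  log(N0 / N_min) / k
}

#' Serialise an Arrhenius fit to JSON
#'
#' Field-for-field JSON mirror of the `arrhenius_fit` object, usable as the
#' reference kinetic in batch evaluation.
#'
#' @param fit an `arrhenius_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_arrhenius <- function(fit, path) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an Arrhenius fit from JSON
#'
#' @param path path written by [write_arrhenius()].
#' @return An `arrhenius_fit`.
#' @export
read_arrhenius <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("slope", "intercept", "Ea", "A", "r_squared", "n_points",
              "fitted_temperature_range")
  if (!all(needed %in% names(raw))) {
    stop("not an Arrhenius-fit file (missing field(s): ",
         paste(setdiff(needed, names(raw)), collapse = ", "), "): ", path,
         call. = FALSE)
  }
  structure(raw[needed], class = "arrhenius_fit")
}
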