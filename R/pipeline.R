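#' Characterize a product from a stability study
#'
#' The product-characterisation workflow: read (or accept) a study, fit
#' first-order decay per storage temperature, fit the Arrhenius model across
#' temperatures, and write the kinetic-parameter table (k and D-values per
#' temperature), the Arrhenius parameters and, optionally, diagnostic plots
#' to an output directory.
#'
#' @param study a `stability_study`, or a path to a study CSV.
#' @param config a [run_config()], or a path to a YAML/JSON config.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param plots also write ln(Nt/N0) and Arrhenius plots (requires ggplot2).
#' @return An object of class `pipeline_result` with `decay_fits`,
#'   `arrhenius`, `d_table` (data frame analogue of a kinetic-parameter
#'   table) and `provenance`.
#' @examples
#' s <- simulate_study(synthetic_study_config(
#'   Ea = 140e3, A = arrhenius_frequency_factor(140e3, 0.08, 25), seed = 3))
#' run_characterize(s)
#' @export
run_characterize <- function(study, config = run_config(), out_dir = NULL,
                             plots = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.character(study)) study <- read_study(study, config)
  stopifnot(inherits(study, "stability_study"),
            inherits(config, "run_config"))

  fits <- fit_study_kinetics(study, config)
  arr <- fit_arrhenius(fits)
  d_table <- as.data.frame(fits)

  result <- structure(
    list(decay_fits = fits, arrhenius = arr, d_table = d_table,
         comparison = NULL,
         provenance = list(study_label = study$label,
                           config = unclass(config),
                           n_observations = nrow(study$observations),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fits_json(fits, file.path(out_dir, "fits.json"),
                    sig_figs = config$report_sig_figs)
    write_arrhenius(arr, file.path(out_dir, "arrhenius.json"))
    utils::write.table(d_table, file.path(out_dir, "kinetics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (plots) {
      save_characterize_plots(study, fits, arr, config, out_dir)
    }
  }
  result
}

#' Evaluate a new batch against a reference kinetic
#'
#' The batch-release workflow: fit destruction rates for the new batch,
#' compare them with the rates predicted by a reference Arrhenius model at
#' the same temperatures, and report band verdicts and the guiding
#' coefficient.
#'
#' @param new_study a `stability_study` for the new batch, or a CSV path.
#' @param reference an `arrhenius_fit`, or a path to a JSON file written by
#'   [write_arrhenius()].
#' @param config a [run_config()] or a config-file path; supplies the
#'   acceptance band.
#' @param out_dir optional output directory for `report.json`.
#' @return A `pipeline_result` whose `comparison` field holds the
#'   [compare_k()] report; `passed` is `TRUE` when every check is within the
#'   band.
#' @export
run_evaluate_batch <- function(new_study, reference, config = run_config(),
                               out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.character(new_study)) new_study <- read_study(new_study, config)
  if (is.character(reference)) reference <- read_arrhenius(reference)
  stopifnot(inherits(new_study, "stability_study"),
            inherits(reference, "arrhenius_fit"))
  if (!nrow(new_study$observations)) {
    stop("insufficient data: the new study holds no observations",
         call. = FALSE)
  }

  fits <- fit_study_kinetics(new_study, config)
  comparison <- compare_k(fits, reference, band = config$acceptance_band)

  result <- structure(
    list(decay_fits = fits, arrhenius = reference, d_table = as.data.frame(fits),
         comparison = comparison,
         passed = all(comparison$pairs$within_band),
         provenance = list(study_label = new_study$label,
                           config = unclass(config),
                           n_observations = nrow(new_study$observations),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      pairs = comparison$pairs,
      guiding_coefficient = comparison$guiding_coefficient,
      r_squared = comparison$r_squared,
      band = comparison$band,
      passed = result$passed
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Stability pipeline result for '", x$provenance$study_label, "'\n",
      sep = "")
  cat("-- kinetic parameters per temperature --\n")
  print(x$d_table, row.names = FALSE)
  cat("-- Arrhenius model --\n")
  print(x$arrhenius)
  if (!is.null(x$comparison)) {
    cat("-- batch evaluation --\n")
    print(x$comparison)
  }
  invisible(x)
}

# JSON list of decay-fit records, full precision plus rounded headline fields
write_fits_json <- function(fits, path, sig_figs = 2L) {
  recs <- lapply(fits, function(f) {
    rec <- unclass(f)
    rec$k_rounded <- signif(f$k, sig_figs)
    rec$D1_rounded <- if (is.na(f$D1)) NA else signif(f$D1, sig_figs)
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Plot a study's log-ratio series by temperature
#'
#' ln(Nt/N0) against time with the fitted first-order lines, one colour per
#' storage temperature.
#'
#' @param study a `stability_study`.
#' @param config a [run_config()].
#' @return A ggplot object.
#' @export
plot_log_ratios <- function(study, config = run_config()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  temps <- study_temperatures(study)
  pts <- do.call(rbind, lapply(temps, function(tmp) {
    s <- build_log_ratio_series(study, tmp, config)
    data.frame(temperature = factor(tmp), time = s$times,
               log_ratio = s$log_ratios)
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time, y = .data$log_ratio,
                                    colour = .data$temperature)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "time (months)", y = "ln(Nt/N0)",
                  colour = "temperature (degC)") +
    ggplot2::theme_minimal()
}

#' Arrhenius plot of fitted destruction rates
#'
#' ln k against 1/T (Kelvin) with the fitted straight line.
#'
#' @param fits a `decay_fit_list` or data frame with `temperature_C`, `k`.
#' @param fit optional `arrhenius_fit` to draw; refitted from `fits` when
#'   absent.
#' @return A ggplot object.
#' @export
plot_arrhenius <- function(fits, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- if (inherits(fits, "decay_fit_list")) as.data.frame(fits) else
    as.data.frame(fits)
  if (is.null(fit)) fit <- fit_arrhenius(df)
  df$inv_T <- 1 / (df$temperature_C + 273.15)
  df$ln_k <- log(df$k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inv_T, y = .data$ln_k)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "1/T (K^-1)", y = "ln k") +
    ggplot2::theme_minimal()
}

save_characterize_plots <- function(study, fits, arr, config, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping plots", call. = FALSE)
    return(invisible(NULL))
  }
  ggplot2::ggsave(file.path(out_dir, "log_ratios.png"),
                  plot_log_ratios(study, config),
                  width = 6, height = 4, dpi = 150)
  ggplot2::ggsave(file.path(out_dir, "arrhenius.png"),
                  plot_arrhenius(fits, arr),
                  width = 6, height = 4, dpi = 150)
  invisible(NULL)
}
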