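#' Run configuration for a stability analysis
#'
#' Bundles the analysis choices that every stage of the pipeline consults:
#' how the per-temperature decay line is fitted, how replicates are collapsed
#' to one log-ratio per checkpoint, how counts at or below the limit of
#' detection are treated, and the relative tolerance band used when a new
#' batch is judged against a reference kinetic.
#'
#' @param fit_mode `"free_intercept"` (default) regresses ln(Nt/N0) on time
#'   with an estimated intercept, so measurement error in the time-0 aggregate
#'   does not bias the slope; `"through_origin"` forces the line through 0,
#'   which the ratio form ln(N0/N0) = 0 suggests.
#' @param replicate_aggregation `"mean_log"` (default) averages ln(count)
#'   across replicates at each checkpoint (the log of the geometric mean);
#'   `"pooled"` keeps every replicate's own ratio series.
#' @param lod_policy what to do with counts flagged below the limit of
#'   detection: `"drop"` (default, with a warning) or `"substitute_half_lod"`
#'   which replaces the recorded limit by half its value.
#' @param report_sig_figs significant figures used only at presentation;
#'   all computation runs at full precision. Default 2, matching how headline
#'   kinetic parameters are conventionally reported.
#' @param acceptance_band relative tolerance (fraction of the predicted value)
#'   for batch-evaluation verdicts. Default 0.30, the accepted overall
#'   variability of plate counts from biology, sampling and dilution.
#' @param seed optional integer seed recorded for reproducibility of any
#'   stochastic stage.
#'
#' @return An object of class `run_config`.
#' @examples
#' cfg <- run_config(fit_mode = "through_origin")
#' cfg$acceptance_band
#' @export
run_config <- function(fit_mode = c("free_intercept", "through_origin"),
                       replicate_aggregation = c("mean_log", "pooled"),
                       lod_policy = c("drop", "substitute_half_lod"),
                       report_sig_figs = 2L,
                       acceptance_band = 0.30,
                       seed = NULL) {
  fit_mode <- match.arg(fit_mode)
  replicate_aggregation <- match.arg(replicate_aggregation)
  lod_policy <- match.arg(lod_policy)
  if (!is.numeric(report_sig_figs) || length(report_sig_figs) != 1L ||
      report_sig_figs < 1) {
    stop("`report_sig_figs` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(acceptance_band) || length(acceptance_band) != 1L ||
      acceptance_band <= 0 || acceptance_band >= 1) {
    stop("`acceptance_band` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single integer or NULL", call. = FALSE)
    }
    seed <- as.integer(seed)
  }
  structure(
    list(
      fit_mode = fit_mode,
      replicate_aggregation = replicate_aggregation,
      lod_policy = lod_policy,
      report_sig_figs = as.integer(report_sig_figs),
      acceptance_band = acceptance_band,
      seed = seed
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds the fields of [run_config()] under the same names; absent
#' fields take their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Stability-analysis run configuration\n")
  cat("  fit mode:              ", x$fit_mode, "\n")
  cat("  replicate aggregation: ", x$replicate_aggregation, "\n")
  cat("  LOD policy:            ", x$lod_policy, "\n")
  cat("  acceptance band:       ±", x$acceptance_band * 100, "%\n", sep = "")
  cat("  report sig. figs:      ", x$report_sig_figs, "\n")
  if (!is.null(x$seed)) cat("  seed:                  ", x$seed, "\n")
  invisible(x)
}

# Canonical CSV column order. One plate-count observation per row.
STUDY_COLUMNS <- c("batch_id", "temperature_C", "time_months",
                   "replicate_id", "cfu_per_g", "below_lod")

# Temperatures within this tolerance (degrees C) are treated as the same
# storage condition when grouping series; guards against float-key drift.
TEMPERATURE_TOL <- 0.01

#' Construct a stability study
#'
#' A stability study is a labelled collection of plate-count observations,
#' one row per (batch, temperature, time, replicate) measurement, expressed
#' in CFU per gram.
#'
#' @param observations data frame with columns `batch_id`, `temperature_C`,
#'   `time_months`, `replicate_id`, `cfu_per_g` and optionally `below_lod`
#'   (logical; `TRUE` means `cfu_per_g` records the limit of detection, not a
#'   measurement).
#' @param label free-text study label.
#' @param metadata named list of free-form study metadata (product name,
#'   growth medium, ...).
#' @param validate run structural validation (default `TRUE`).
#'
#' @return An object of class `stability_study` with elements `label`,
#'   `observations` (canonicalised data frame) and `metadata`.
#' @examples
#' obs <- data.frame(
#'   batch_id = "B1", temperature_C = 25,
#'   time_months = c(0, 3, 6), replicate_id = "r1",
#'   cfu_per_g = 1e10 * exp(-0.08 * c(0, 3, 6))
#' )
#' stability_study(obs, label = "demo")
#' @export
stability_study <- function(observations, label = "study",
                            metadata = list(), validate = TRUE) {
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  if (!"below_lod" %in% names(obs)) obs$below_lod <- rep(FALSE, nrow(obs))
  missing_cols <- setdiff(STUDY_COLUMNS, names(obs))
  if (length(missing_cols)) {
    stop("observations are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- obs[STUDY_COLUMNS]
  obs$batch_id <- as.character(obs$batch_id)
  obs$replicate_id <- as.character(obs$replicate_id)
  obs$temperature_C <- as.numeric(obs$temperature_C)
  obs$time_months <- as.numeric(obs$time_months)
  obs$cfu_per_g <- as.numeric(obs$cfu_per_g)
  obs$below_lod <- as.logical(obs$below_lod)
  obs$below_lod[is.na(obs$below_lod)] <- FALSE
  # deterministic row order: temperature, replicate, time
  obs <- obs[order(obs$temperature_C, obs$replicate_id, obs$time_months), ,
             drop = FALSE]
  rownames(obs) <- NULL
  study <- structure(
    list(label = as.character(label), observations = obs,
         metadata = metadata),
    class = "stability_study"
  )
  if (validate) validate_study(study)
  study
}

#' Validate a stability study
#'
#' Checks physical plausibility of every observation and the structural
#' requirements of downstream fitting: every (temperature, replicate) series
#' must contain a time-0 observation (needed to define N0) and every
#' temperature series must span at least two distinct time points.
#'
#' @param study a `stability_study`.
#' @param require_complete error (rather than warn) on series without a
#'   time-0 observation. Default `TRUE`.
#' @return The study, invisibly, if valid; otherwise an error describing
#'   every offending row or series.
#' @export
validate_study <- function(study, require_complete = TRUE) {
  stopifnot(inherits(study, "stability_study"))
  obs <- study$observations
  problems <- character(0)
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) sprintf("row %d: %s", idx, msg) else character(0)
  }
  problems <- c(
    problems,
    bad(is.na(obs$cfu_per_g), "count is missing or non-numeric"),
    bad(!is.na(obs$cfu_per_g) & obs$cfu_per_g < 0, "negative count"),
    bad(is.na(obs$time_months), "time is missing or non-numeric"),
    bad(!is.na(obs$time_months) & obs$time_months < 0, "negative time"),
    bad(is.na(obs$temperature_C) | obs$temperature_C < -80 |
          obs$temperature_C > 100,
        "temperature outside plausible range (-80..100 degC)")
  )
  if (length(problems)) {
    stop("invalid observations in study '", study$label, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  incomplete <- character(0)
  for (tmp in study_temperatures(study)) {
    sel <- obs[abs(obs$temperature_C - tmp) <= TEMPERATURE_TOL, , drop = FALSE]
    if (length(unique(sel$time_months)) < 2) {
      incomplete <- c(incomplete, sprintf(
        "series at %g degC has fewer than 2 distinct time points", tmp))
    }
    for (rep in unique(sel$replicate_id)) {
      if (!any(sel$time_months[sel$replicate_id == rep] == 0)) {
        incomplete <- c(incomplete, sprintf(
          "series (%g degC, replicate %s) lacks a time-0 observation",
          tmp, rep))
      }
    }
  }
  if (length(incomplete)) {
    msg <- paste0("incomplete series in study '", study$label, "':\n  ",
                  paste(incomplete, collapse = "\n  "))
    if (require_complete) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(study)
}

#' Distinct storage temperatures of a study
#'
#' Temperatures closer than 0.01 degC are merged into one series.
#'
#' @param study a `stability_study`.
#' @return Sorted numeric vector of series temperatures (degC).
#' @export
study_temperatures <- function(study) {
  temps <- sort(unique(study$observations$temperature_C))
  if (!length(temps)) return(numeric(0))
  out <- temps[1]
  for (t in temps[-1]) {
    if (t - out[length(out)] > TEMPERATURE_TOL) out <- c(out, t)
  }
  out
}

#' @export
print.stability_study <- function(x, ...) {
  obs <- x$observations
  cat("Stability study '", x$label, "'\n", sep = "")
  cat("  ", nrow(obs), " observations, ",
      length(study_temperatures(x)), " temperature series (",
      paste(study_temperatures(x), collapse = ", "), " degC)\n", sep = "")
  cat("  time span: ", min(obs$time_months), "-", max(obs$time_months),
      " months; ", length(unique(obs$replicate_id)), " replicate id(s)\n",
      sep = "")
  if (length(x$metadata)) {
    cat("  metadata: ",
        paste(names(x$metadata), unlist(x$metadata), sep = "=",
              collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a stability study from CSV
#'
#' Expects the documented schema
#' `batch_id,temperature_C,time_months,replicate_id,cfu_per_g[,below_lod]`,
#' one observation per row. Malformed rows are reported with their line
#' numbers; zero counts cannot enter log space and are handled according to
#' `config$lod_policy`.
#'
#' @param path CSV file path.
#' @param config a [run_config()]; controls the LOD policy.
#' @param label study label; defaults to the file name.
#' @param metadata named list attached to the study.
#' @return A validated `stability_study`.
#' @export
read_study <- function(path, config = run_config(),
                       label = NULL, metadata = list()) {
  if (!file.exists(path)) {
    stop("study file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  required <- setdiff(STUDY_COLUMNS, "below_lod")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("CSV schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"below_lod" %in% names(raw)) raw$below_lod <- "FALSE"
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  cfu <- num("cfu_per_g"); tim <- num("time_months"); tmp <- num("temperature_C")
  lod <- toupper(trimws(raw$below_lod)) %in% c("TRUE", "T", "1", "YES")

  problems <- character(0)
  flag <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) sprintf("line %d: %s", line_no[idx], msg) else character(0)
  }
  problems <- c(
    problems,
    flag(is.na(cfu), "cfu_per_g is not a number"),
    flag(!is.na(cfu) & cfu < 0, "negative cfu_per_g"),
    flag(is.na(tim), "time_months is not a number"),
    flag(!is.na(tim) & tim < 0, "negative time_months"),
    flag(is.na(tmp) | tmp < -80 | tmp > 100,
         "temperature_C missing or outside -80..100")
  )
  if (length(problems)) {
    stop("validation error(s) in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  obs <- data.frame(
    batch_id = raw$batch_id, temperature_C = tmp, time_months = tim,
    replicate_id = raw$replicate_id, cfu_per_g = cfu, below_lod = lod,
    stringsAsFactors = FALSE
  )

  # LOD handling: flagged rows hold the limit of detection, not a count.
  # Unflagged zero counts are unusable in log space under either policy.
  zero_unflagged <- obs$cfu_per_g == 0 & !obs$below_lod
  if (any(zero_unflagged)) {
    warning(sum(zero_unflagged),
            " zero count(s) without a below_lod flag dropped (cannot enter",
            " log space)", call. = FALSE)
    obs <- obs[!zero_unflagged, , drop = FALSE]
  }
  if (any(obs$below_lod)) {
    if (config$lod_policy == "drop") {
      warning(sum(obs$below_lod), " below-LOD observation(s) dropped per",
              " lod_policy = 'drop'", call. = FALSE)
      obs <- obs[!obs$below_lod, , drop = FALSE]
    } else {
      usable <- obs$below_lod & obs$cfu_per_g > 0
      if (any(obs$below_lod & !usable)) {
        warning(sum(obs$below_lod & !usable),
                " below-LOD row(s) with no positive detection limit dropped",
                call. = FALSE)
        obs <- obs[!(obs$below_lod & obs$cfu_per_g == 0), , drop = FALSE]
      }
      obs$cfu_per_g[obs$below_lod] <- obs$cfu_per_g[obs$below_lod] / 2
    }
  }

  stability_study(obs,
                  label = if (is.null(label)) basename(path) else label,
                  metadata = metadata)
}

#' Write a stability study to CSV
#'
#' Emits the documented schema with deterministic row order
#' (temperature, replicate, time), UTF-8 encoded. An empty study yields a
#' header-only file.
#'
#' @param study a `stability_study`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "stability_study"))
  out <- study$observations[STUDY_COLUMNS]
  # %.17g preserves doubles exactly across the text round trip
  for (col in c("temperature_C", "time_months", "cfu_per_g")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}
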