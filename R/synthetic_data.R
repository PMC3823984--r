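#' ICH-style checkpoint schedules
#'
#' Canonical storage-condition grids used in stability testing of dried
#' probiotic products: long-term conditions at 20/25/30 degC with
#' checkpoints every three months, and an accelerated arm at 40 degC with
#' monthly checkpoints.
#'
#' @param design one of `"laboratory"` (20/25/30 degC at 0,3,6,9,12 months),
#'   `"long_term"` (20/25/30 degC at 0,3,6,9,12,18,24 months) or
#'   `"recent_batch"` (20/25/30 degC at 0,1,3,6 plus 40 degC monthly to 6).
#' @return Named list mapping temperature (degC, as names) to checkpoint
#'   months.
#' @examples
#' ich_schedule("long_term")
#' @export
ich_schedule <- function(design = c("laboratory", "long_term",
                                    "recent_batch")) {
  design <- match.arg(design)
  switch(design,
    laboratory = list(`20` = c(0, 3, 6, 9, 12),
                      `25` = c(0, 3, 6, 9, 12),
                      `30` = c(0, 3, 6, 9, 12)),
    long_term = list(`20` = c(0, 3, 6, 9, 12, 18, 24),
                     `25` = c(0, 3, 6, 9, 12, 18, 24),
                     `30` = c(0, 3, 6, 9, 12, 18, 24)),
    recent_batch = list(`20` = c(0, 1, 3, 6),
                        `25` = c(0, 1, 3, 6),
                        `30` = c(0, 1, 3, 6),
                        `40` = 0:6)
  )
}

#' Frequency factor matching a target rate at a reference temperature
#'
#' Solves k = A exp(-Ea/(R T)) for A so that the Arrhenius line passes
#' through a chosen (temperature, k) anchor. Convenient for parameterising
#' simulations by an activation energy plus one realistic rate.
#'
#' @param Ea activation energy, J/mol.
#' @param k_ref destruction rate at the reference temperature, months^-1.
#' @param temperature_ref reference temperature, degC.
#' @return Frequency factor A, months^-1.
#' @examples
#' arrhenius_frequency_factor(140e3, k_ref = 0.08, temperature_ref = 25)
#' @export
arrhenius_frequency_factor <- function(Ea, k_ref, temperature_ref) {
  stopifnot(Ea >= 0, k_ref > 0)
  k_ref * exp(Ea / (GAS_CONSTANT * to_kelvin(temperature_ref)))
}

#' Configuration of a synthetic stability study
#'
#' Defines the true kinetics, sampling design and noise model of a simulated
#' plate-count stability study. Two parameterisations of the truth are
#' supported: a map of destruction rates by temperature, or an Arrhenius
#' pair (Ea, A) from which rates at the scheduled temperatures follow.
#'
#' The noise model has two layers. Between-replicate (and between-batch)
#' biological variability is lognormal and multiplicative on the starting
#' count: each replicate's N0 has geometric mean `N0_mean` and coefficient
#' of variation `biological_cv`. Counting noise emulates plate counting
#' after serial dilution as a single effective Poisson layer: at the
#' starting count, a plate carries `plated_volume_equivalent` expected
#' colonies, and the observed CFU/g is the Poisson draw rescaled back —
#' unbiased, with relative error shrinking as counts grow.
#'
#' @param k_by_temperature named numeric vector of true rates, months^-1,
#'   keyed by temperature in degC (e.g. `c("25" = 0.08)`); all > 0.
#' @param Ea,A alternative truth: Arrhenius activation energy (J/mol,
#'   >= 0) and frequency factor (months^-1).
#' @param N0_mean geometric-mean starting count, CFU/g. Default 1e10, a
#'   typical probiotic-powder load.
#' @param biological_cv between-replicate coefficient of variation of N0
#'   (default 0.30, the accepted overall plate-count variability).
#' @param schedule named list temperature -> checkpoint months; defaults to
#'   the schedule of `ich_schedule("laboratory")`. Every arm must include
#'   time 0.
#' @param n_replicates replicates per temperature (default 3).
#' @param counting `"poisson"` (default) or `"none"` for noiseless counts.
#' @param plated_volume_equivalent expected colonies per plate at N0
#'   (default 200, mid countable range); sets the Poisson intensity scale.
#' @param k_cv optional lognormal CV on each replicate's rate (default 0,
#'   i.e. all replicates share the true kinetic).
#' @param seed integer seed; the study is bit-reproducible given the config.
#' @return An object of class `synthetic_study_config`.
#' @examples
#' synthetic_study_config(Ea = 140e3,
#'   A = arrhenius_frequency_factor(140e3, 0.08, 25),
#'   schedule = ich_schedule("long_term"), seed = 1)
#' @export
synthetic_study_config <- function(k_by_temperature = NULL,
                                   Ea = NULL, A = NULL,
                                   N0_mean = 1e10,
                                   biological_cv = 0.30,
                                   schedule = ich_schedule("laboratory"),
                                   n_replicates = 3L,
                                   counting = c("poisson", "none"),
                                   plated_volume_equivalent = 200,
                                   k_cv = 0,
                                   seed = 1L) {
  counting <- match.arg(counting)
  has_map <- !is.null(k_by_temperature)
  if (missing(schedule) && has_map) {
    # default grid restricted to the configured temperatures
    schedule <- stats::setNames(
      rep(list(c(0, 3, 6, 9, 12)), length(k_by_temperature)),
      names(k_by_temperature))
  }
  has_arr <- !is.null(Ea) && !is.null(A)
  if (has_map == has_arr) {
    stop("specify exactly one truth: k_by_temperature, or Ea with A",
         call. = FALSE)
  }
  mode <- if (has_map) "per_temperature_k" else "arrhenius"
  if (has_map) {
    if (is.null(names(k_by_temperature)) || any(k_by_temperature <= 0)) {
      stop("k_by_temperature must be a named vector of positive rates",
           call. = FALSE)
    }
  } else {
    if (Ea < 0) stop("Ea must be non-negative", call. = FALSE)
    if (A <= 0) stop("A must be positive", call. = FALSE)
  }
  if (N0_mean <= 0) stop("N0_mean must be positive", call. = FALSE)
  if (biological_cv < 0) stop("biological_cv must be >= 0", call. = FALSE)
  if (k_cv < 0) stop("k_cv must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("need at least one replicate", call. = FALSE)
  if (plated_volume_equivalent <= 0) {
    stop("plated_volume_equivalent must be positive", call. = FALSE)
  }
  if (is.null(names(schedule)) ||
      !all(vapply(schedule, function(ts) 0 %in% ts, logical(1)))) {
    stop("schedule must be a named (temperature) list and every arm must",
         " include time 0", call. = FALSE)
  }
  structure(
    list(mode = mode, k_by_temperature = k_by_temperature, Ea = Ea, A = A,
         N0_mean = N0_mean, biological_cv = biological_cv,
         schedule = schedule, n_replicates = as.integer(n_replicates),
         counting = counting,
         plated_volume_equivalent = plated_volume_equivalent,
         k_cv = k_cv, seed = as.integer(seed)),
    class = "synthetic_study_config"
  )
}

# lognormal sdlog giving a target coefficient of variation
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

# true destruction rate at a temperature under the configured truth
true_k <- function(config, temperature) {
  if (config$mode == "per_temperature_k") {
    temps <- as.numeric(names(config$k_by_temperature))
    hit <- which(abs(temps - temperature) <= TEMPERATURE_TOL)
    if (!length(hit)) {
      stop("no true k configured at ", temperature, " degC", call. = FALSE)
    }
    unname(config$k_by_temperature[hit[1]])
  } else {
    config$A * exp(-config$Ea / (GAS_CONSTANT * to_kelvin(temperature)))
  }
}

#' Simulate one plate-count measurement
#'
#' Draws the observed CFU/g for a known true count under the configured
#' counting model: a Poisson draw at the effective colony-count scale,
#' rescaled back to CFU/g, so the expectation equals the true count.
#' Consumes the current RNG state; seed externally for reproducibility.
#'
#' @param true_cfu_per_g true count(s), CFU/g, >= 0 (vectorised).
#' @param config a [synthetic_study_config()] (uses `counting`,
#'   `plated_volume_equivalent`, `N0_mean`).
#' @return Observed count(s), CFU/g.
#' @export
simulate_plate_count <- function(true_cfu_per_g, config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  if (any(true_cfu_per_g < 0)) {
    stop("true counts must be non-negative", call. = FALSE)
  }
  if (config$counting == "none") return(true_cfu_per_g)
  scale <- config$plated_volume_equivalent / config$N0_mean
  stats::rpois(length(true_cfu_per_g), true_cfu_per_g * scale) / scale
}

#' Simulate a full stability study
#'
#' Forward model: for every scheduled temperature and replicate, the true
#' viable count decays exponentially, N(t) = N0_rep exp(-k_T t), from a
#' replicate-specific starting count drawn lognormally around `N0_mean`;
#' each checkpoint is then observed through the plate-count layer. Zero
#' colony draws are recorded at the counting limit of detection with the
#' `below_lod` flag set. Bit-reproducible from `config$seed`.
#'
#' @param config a [synthetic_study_config()].
#' @param label study label.
#' @return A `stability_study` in the standard schema.
#' @examples
#' cfg <- synthetic_study_config(k_by_temperature = c("25" = 0.08), seed = 7)
#' simulate_study(cfg)
#' @export
simulate_study <- function(config, label = "synthetic study") {
  stopifnot(inherits(config, "synthetic_study_config"))
  set.seed(config$seed)
  sdlog_n0 <- lognormal_sdlog(config$biological_cv)
  sdlog_k <- lognormal_sdlog(config$k_cv)
  scale <- config$plated_volume_equivalent / config$N0_mean

  rows <- list()
  for (temp_name in names(config$schedule)) {
    temperature <- as.numeric(temp_name)
    times <- sort(unique(config$schedule[[temp_name]]))
    k_t <- true_k(config, temperature)
    for (r in seq_len(config$n_replicates)) {
      n0_rep <- config$N0_mean *
        exp(stats::rnorm(1, mean = 0, sd = sdlog_n0))
      k_rep <- if (config$k_cv > 0) {
        k_t * exp(stats::rnorm(1, mean = 0, sd = sdlog_k))
      } else {
        k_t
      }
      true_counts <- n0_rep * exp(-k_rep * times)
      observed <- simulate_plate_count(true_counts, config)
      below_lod <- observed == 0 & config$counting == "poisson"
      if (any(below_lod)) observed[below_lod] <- 1 / scale  # 1-colony LOD
      rows[[length(rows) + 1L]] <- data.frame(
        batch_id = "synthetic",
        temperature_C = temperature,
        time_months = times,
        replicate_id = sprintf("r%d", r),
        cfu_per_g = observed,
        below_lod = below_lod,
        stringsAsFactors = FALSE
      )
    }
  }
  obs <- do.call(rbind, rows)
  stability_study(obs, label = label,
                  metadata = list(generator = "probistab::simulate_study",
                                  seed = config$seed,
                                  mode = config$mode),
                  validate = FALSE)
}
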