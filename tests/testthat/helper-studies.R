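# Fixture builders shared across the suite. Everything is generated in code.

# Noiseless study following exact first-order decay at the given rates.
exact_study <- function(k_by_temp = c("20" = 0.51, "25" = 0.80, "30" = 1.34),
                        times = c(0, 3, 6, 9, 12),
                        n0 = 1e10, n_replicates = 3) {
  rows <- do.call(rbind, lapply(names(k_by_temp), function(tn) {
    k <- k_by_temp[[tn]]
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(batch_id = "fix", temperature_C = as.numeric(tn),
                 time_months = times, replicate_id = paste0("r", r),
                 cfu_per_g = n0 * exp(-k * times),
                 stringsAsFactors = FALSE)
    }))
  }))
  stability_study(rows, label = "exact fixture")
}

# Random valid study for round-trip properties.
random_study <- function(seed) {
  set.seed(seed)
  temps <- sort(sample(c(5, 20, 25, 30, 37, 40), sample(2:4, 1)))
  times <- sort(unique(c(0, sample(1:24, sample(2:5, 1)))))
  n_rep <- sample(1:4, 1)
  rows <- do.call(rbind, lapply(temps, function(tmp) {
    do.call(rbind, lapply(seq_len(n_rep), function(r) {
      data.frame(batch_id = sprintf("batch-%d", seed),
                 temperature_C = tmp, time_months = times,
                 replicate_id = paste0("rep", r),
                 cfu_per_g = 10^stats::runif(length(times), 6, 11),
                 below_lod = FALSE, stringsAsFactors = FALSE)
    }))
  }))
  stability_study(rows, label = sprintf("random-%d", seed),
                  metadata = list(origin = "helper"))
}

# Independent OLS oracle via the normal equations (no lm()).
ols_slope_intercept <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Forward Arrhenius evaluation, independent of fit_arrhenius/predict_k.
forward_k <- function(Ea, A, temp_C) A * exp(-Ea / (8.314 * (temp_C + 273.15)))

table3_k <- data.frame(temperature_C = c(20, 25, 30), k = c(0.51, 0.80, 1.34))
table4_k <- data.frame(temperature_C = c(20, 25, 30), k = c(0.03, 0.08, 0.19))
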