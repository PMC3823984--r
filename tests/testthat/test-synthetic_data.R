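test_that("noiseless simulation reproduces the forward model exactly", {
  k <- 0.25
  cfg <- synthetic_study_config(k_by_temperature = c("25" = k),
                                biological_cv = 0, counting = "none",
                                N0_mean = 1e10, seed = 1)
  s <- simulate_study(cfg)
  obs <- s$observations
  expect_equal(obs$cfu_per_g, 1e10 * exp(-k * obs$time_months),
               tolerance = 1e-12)
  fit <- fit_study_kinetics(s)[[1]]
  expect_equal(fit$k, k, tolerance = 1e-10)
})

test_that("simulation is bit-identical for identical config and seed", {
  cfg <- synthetic_study_config(Ea = 140e3,
                                A = arrhenius_frequency_factor(140e3, 0.08, 25),
                                seed = 77)
  expect_identical(simulate_study(cfg)$observations,
                   simulate_study(cfg)$observations)
  cfg2 <- synthetic_study_config(Ea = 140e3,
                                 A = arrhenius_frequency_factor(140e3, 0.08, 25),
                                 seed = 78)
  expect_false(identical(simulate_study(cfg)$observations,
                         simulate_study(cfg2)$observations))
})

test_that("replicate starting counts realise the configured lognormal CV", {
  cfg <- synthetic_study_config(k_by_temperature = c("25" = 0.1),
                                biological_cv = 0.30, counting = "none",
                                schedule = list(`25` = c(0, 1)),
                                n_replicates = 10000, seed = 12)
  s <- simulate_study(cfg)
  n0 <- s$observations$cfu_per_g[s$observations$time_months == 0]
  expect_equal(sd(n0) / mean(n0), 0.30, tolerance = 0.01)
  # geometric mean anchored at N0_mean
  expect_equal(mean(log(n0)), log(1e10), tolerance = 0.01)
})

test_that("plate-count noise is unbiased with Poisson variance at the colony scale", {
  cfg <- synthetic_study_config(k_by_temperature = c("25" = 0.1),
                                N0_mean = 1e10,
                                plated_volume_equivalent = 200, seed = 1)
  expect_equal(simulate_plate_count(0, cfg), 0)  # Poisson(0) is always 0
  set.seed(31)
  true <- 2.5e9  # 50 expected colonies at this scale
  draws <- simulate_plate_count(rep(true, 1e5), cfg)
  lambda <- 50
  se_mean <- sqrt(lambda / 1e5) / (200 / 1e10)
  expect_lt(abs(mean(draws) - true), 3 * se_mean)
  colonies <- draws * 200 / 1e10
  expect_equal(var(colonies), lambda, tolerance = 0.05 * lambda)
})

test_that("counting = none passes counts through untouched", {
  cfg <- synthetic_study_config(k_by_temperature = c("25" = 0.1),
                                counting = "none", seed = 1)
  expect_identical(simulate_plate_count(c(0, 1e9, 3e10), cfg),
                   c(0, 1e9, 3e10))
})

test_that("Arrhenius-mode studies have k strictly increasing in temperature", {
  cfg <- synthetic_study_config(Ea = 140e3,
                                A = arrhenius_frequency_factor(140e3, 0.08, 25),
                                biological_cv = 0, counting = "none",
                                schedule = ich_schedule("long_term"), seed = 1)
  ks <- as.data.frame(fit_study_kinetics(simulate_study(cfg)))$k
  expect_true(all(diff(ks) > 0))
})

test_that("zero colony draws are recorded at the detection limit and flagged", {
  cfg <- synthetic_study_config(k_by_temperature = c("40" = 2.5),
                                schedule = list(`40` = 0:6),
                                plated_volume_equivalent = 50,
                                biological_cv = 0, seed = 6)
  s <- simulate_study(cfg)
  obs <- s$observations
  lod_rows <- obs[obs$below_lod, ]
  expect_gt(nrow(lod_rows), 0)  # k*6 = 15 ln-decades: zeros are certain
  expect_true(all(lod_rows$cfu_per_g == 1e10 / 50))
})

test_that("config validation rejects inconsistent truths and schedules", {
  expect_error(synthetic_study_config(), "exactly one truth")
  expect_error(synthetic_study_config(k_by_temperature = c("25" = 0.1),
                                      Ea = 1e5, A = 1), "exactly one truth")
  expect_error(synthetic_study_config(k_by_temperature = c(0.1)),
               "named vector")
  expect_error(synthetic_study_config(Ea = -1, A = 1), "non-negative")
  expect_error(
    synthetic_study_config(k_by_temperature = c("25" = 0.1),
                           schedule = list(`25` = c(3, 6))),
    "include time 0")
  expect_error(synthetic_study_config(k_by_temperature = c("25" = 0.1),
                                      biological_cv = -0.1), ">= 0")
})

test_that("ich_schedule returns the standard checkpoint grids", {
  lab <- ich_schedule("laboratory")
  expect_equal(names(lab), c("20", "25", "30"))
  expect_equal(lab$`20`, c(0, 3, 6, 9, 12))
  long <- ich_schedule("long_term")
  expect_equal(long$`25`, c(0, 3, 6, 9, 12, 18, 24))
  recent <- ich_schedule("recent_batch")
  expect_equal(recent$`40`, 0:6)
  expect_equal(recent$`20`, c(0, 1, 3, 6))
})
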