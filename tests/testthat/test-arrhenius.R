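test_that("Ea and A are recovered to machine precision from forward-generated rates", {
  cases <- list(c(Ea = 100e3, A = 1e9), c(Ea = 71e3, A = 2.6e12),
                c(Ea = 0, A = 0.5))
  for (cs in cases) {
    temps <- c(20, 25, 30)
    pts <- data.frame(temperature_C = temps,
                      k = forward_k(cs["Ea"], cs["A"], temps))
    fit <- fit_arrhenius(pts)
    expect_equal(fit$Ea, unname(cs["Ea"]), tolerance = 1e-9)
    expect_equal(fit$A, unname(cs["A"]), tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("structural identities Ea = -slope*R and A = exp(intercept) hold", {
  fit <- fit_arrhenius(table3_k)
  expect_equal(fit$Ea, -fit$slope * 8.314, tolerance = 1e-14)
  expect_equal(fit$A, exp(fit$intercept), tolerance = 1e-14)
})

test_that("two equal rates give a flat line with Ea = 0 and A = k", {
  expect_warning(fit <- fit_arrhenius(data.frame(
    temperature_C = c(20, 30), k = c(0.4, 0.4))), "two points")
  expect_equal(fit$Ea, 0, tolerance = 1e-8)
  expect_equal(fit$A, 0.4, tolerance = 1e-8)
})

test_that("non-positive rates and duplicate temperatures are rejected", {
  expect_error(fit_arrhenius(data.frame(temperature_C = c(20, 25),
                                        k = c(0.5, -0.1))), "positive")
  expect_error(fit_arrhenius(data.frame(temperature_C = c(25, 25),
                                        k = c(0.5, 0.6))), "duplicate")
  expect_error(fit_arrhenius(data.frame(temperature_C = 25, k = 0.5)),
               "at least two")
})

test_that("predict_k reproduces fitted knots and flags extrapolation", {
  pts <- data.frame(temperature_C = c(20, 30), k = c(0.1, 0.4))
  suppressWarnings(fit <- fit_arrhenius(pts))
  k20 <- predict_k(fit, 20)
  expect_equal(as.numeric(k20), 0.1, tolerance = 1e-12)
  expect_false(attr(k20, "extrapolated"))
  k40 <- predict_k(fit, 40)
  expect_true(attr(k40, "extrapolated"))
  expect_error(predict_k(fit, -300), "absolute zero")
})

test_that("predict_k equals forward evaluation at unseen temperatures", {
  Ea <- 100e3; A <- 1e9
  temps <- c(20, 25, 30)
  fit <- fit_arrhenius(data.frame(temperature_C = temps,
                                  k = forward_k(Ea, A, temps)))
  expect_equal(as.numeric(predict_k(fit, 35)), forward_k(Ea, A, 35),
               tolerance = 1e-9)
})

test_that("predict_k is monotone in temperature iff Ea > 0", {
  fit <- fit_arrhenius(table4_k)
  ks <- as.numeric(predict_k(fit, seq(5, 45, by = 5)))
  expect_true(all(diff(ks) > 0))
})

test_that("predict_viability matches the closed form N0 exp(-k t)", {
  p <- predict_viability(0.08, N0 = 1e10, time = 12)
  expect_equal(p$predicted_count, 1e10 * exp(-0.96), tolerance = 1e-12)
  expect_equal(p$log_ratio, -0.96)
  expect_equal(p$band_low, p$predicted_count * 0.7)
  expect_equal(p$band_high, p$predicted_count * 1.3)
  # t = 0 conserves N0 whatever the rate
  expect_equal(predict_viability(2.7, N0 = 3e9, time = 0)$predicted_count,
               3e9)
  # one D1 is exactly a tenfold drop
  p10 <- predict_viability(0.51, N0 = 1e10, time = log(10) / 0.51)
  expect_equal(p10$predicted_count, 1e9, tolerance = 1e-12)
  expect_error(predict_viability(0.5, N0 = 1e10, time = -1),
               "non-negative")
  expect_error(predict_viability(0.5, N0 = 0, time = 1), "positive")
})

test_that("predict_viability decreases strictly in time for k > 0", {
  counts <- vapply(0:12, function(t) {
    predict_viability(0.3, N0 = 1e10, time = t)$predicted_count
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("shelf_life solves ln(N0/Nmin)/k and equals D1 for a tenfold drop", {
  for (k in c(0.08, 0.51, 1.34)) {
    expect_equal(shelf_life(k, N0 = 1e10, N_min = 1e9),
                 unname(d_values(k)["D1"]), tolerance = 1e-12)
  }
  expect_equal(shelf_life(log(10), N0 = 1e10, N_min = 1e7), 3,
               tolerance = 1e-12)
  expect_equal(shelf_life(0.51, N0 = 1e10, N_min = 1e10), 0)
  expect_warning(t_inf <- shelf_life(0, N0 = 1e10, N_min = 1e9),
                 "no finite shelf-life")
  expect_equal(t_inf, Inf)
  expect_error(shelf_life(0.5, N0 = 1e9, N_min = 1e10), "exceeds N0")
})

test_that("an Arrhenius fit survives a JSON round trip", {
  fit <- fit_arrhenius(table4_k)
  path <- withr::local_tempfile(fileext = ".json")
  write_arrhenius(fit, path)
  back <- read_arrhenius(path)
  expect_equal(back$Ea, fit$Ea)
  expect_equal(back$slope, fit$slope)
  expect_equal(as.numeric(predict_k(back, 40)),
               as.numeric(predict_k(fit, 40)))
  expect_error(read_arrhenius(withr::local_tempfile()), "not found")
})
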