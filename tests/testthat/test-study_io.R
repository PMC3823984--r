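test_that("write/read round-trips arbitrary valid studies", {
  for (seed in c(11, 42, 303)) {
    s <- random_study(seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_study(s, path)
    s2 <- read_study(path, label = s$label)
    expect_identical(s2$observations, s$observations)
  }
})

test_that("a 3-replicate, 5-checkpoint, 3-temperature CSV yields 45 rows in 9 series", {
  s <- exact_study()
  expect_equal(nrow(s$observations), 45)
  series <- unique(s$observations[c("temperature_C", "replicate_id")])
  expect_equal(nrow(series), 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(s, path)
  expect_equal(length(readLines(path)), 46)  # header + 45 rows
})

test_that("malformed rows are diagnosed with their line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "batch_id,temperature_C,time_months,replicate_id,cfu_per_g",
    "b1,25,0,r1,1e10",
    "b1,25,3,r1,-5",
    "b1,25,6,r1,abc"
  ), path)
  expect_error(read_study(path), "line 3.*negative cfu_per_g")
  expect_error(read_study(path), "line 4.*not a number")
})

test_that("missing required columns are a schema error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("batch_id,temperature_C,time_months,cfu_per_g",
               "b1,25,0,1e10"), path)
  expect_error(read_study(path), "missing column.*replicate_id")
})

test_that("series without a time-0 observation are flagged as incomplete", {
  obs <- data.frame(batch_id = "b", temperature_C = 25,
                    time_months = c(3, 6, 9), replicate_id = "r1",
                    cfu_per_g = 1e9)
  expect_error(stability_study(obs), "lacks a time-0 observation")
})

test_that("non-ASCII batch labels survive the round trip", {
  obs <- data.frame(batch_id = "lyophilisé-n°5",
                    temperature_C = 25, time_months = c(0, 6),
                    replicate_id = "r1", cfu_per_g = c(1e10, 5e9))
  s <- stability_study(obs, label = "utf8")
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(s, path)
  expect_identical(read_study(path)$observations$batch_id,
                   rep("lyophilisé-n°5", 2))
})

test_that("an empty study writes a header-only CSV", {
  s <- stability_study(
    data.frame(batch_id = character(), temperature_C = numeric(),
               time_months = numeric(), replicate_id = character(),
               cfu_per_g = numeric()),
    label = "empty", validate = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(s, path)
  expect_equal(length(readLines(path)), 1)
})

test_that("LOD policies drop or halve flagged counts, with warnings for zeros", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "batch_id,temperature_C,time_months,replicate_id,cfu_per_g,below_lod",
    "b1,25,0,r1,1e10,FALSE",
    "b1,25,3,r1,1e4,TRUE",
    "b1,25,6,r1,0,FALSE",
    "b1,25,9,r1,5e9,FALSE"
  ), path)
  warns <- capture_warnings(
    s_drop <- read_study(path, run_config(lod_policy = "drop")))
  expect_match(warns, "zero count", all = FALSE)
  expect_match(warns, "below-LOD", all = FALSE)
  expect_equal(nrow(s_drop$observations), 2)  # LOD row and zero row removed
  suppressWarnings(
    s_half <- read_study(path, run_config(lod_policy = "substitute_half_lod"))
  )
  halved <- s_half$observations[s_half$observations$time_months == 3, ]
  expect_equal(halved$cfu_per_g, 5e3)
})

test_that("run_config validates its fields and reads from YAML", {
  expect_error(run_config(acceptance_band = 1.2), "between 0 and 1")
  expect_error(run_config(report_sig_figs = 0), ">= 1")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fit_mode: through_origin", "acceptance_band: 0.2"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$fit_mode, "through_origin")
  expect_equal(cfg$acceptance_band, 0.2)
  writeLines("unknown_field: 1", path)
  expect_error(read_run_config(path), "unknown config field")
})

test_that("temperatures within 0.01 degC collapse into one series", {
  obs <- data.frame(batch_id = "b",
                    temperature_C = c(25, 25.004, 25, 25.004),
                    time_months = c(0, 0, 6, 6),
                    replicate_id = c("r1", "r2", "r1", "r2"),
                    cfu_per_g = 1e9)
  s <- stability_study(obs, validate = FALSE)
  expect_equal(length(study_temperatures(s)), 1)
})
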