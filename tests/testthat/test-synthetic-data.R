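test_that("default scenario matches the study design", {
  cfg <- default_scenario()
  expect_s3_class(cfg, "scenario_config")
  expect_length(cfg$callers, 8)                      # 4 translocated + 4 baseline
  expect_equal(unname(table(cfg$colony_of)), c(4L, 4L), ignore_attr = TRUE)
  expect_equal(cfg$n_params_per_type[["trill"]], 17L)
  expect_equal(cfg$n_params_per_type[["phee"]], 15L)
  expect_equal(sort(unique(cfg$schedule$week)), c(0, 0.5, 1:16))
  # 2 females / 2 males per colony
  for (col in cfg$colonies) {
    expect_equal(sum(cfg$sexes[cfg$colony_of == col] == "F"), 2)
  }
  # convergence for trill/phee, divergence for food
  expect_true(all(cfg$convergence_rate$trill > 0))
  expect_true(all(cfg$convergence_rate$phee > 0))
  expect_true(all(cfg$convergence_rate$food < 0))
})

test_that("scenario validation rejects malformed configurations", {
  expect_error(default_scenario(individual_sd = -1), "SD")
  expect_error(default_scenario(dialect_offset = list(
    trill = numeric(16), phee = numeric(15), food = numeric(15))),
    "length 17")
  bad_sched <- data.frame(condition = "Before", week = 0.25,
                          trill = 5, phee = 5, food = 5)
  expect_error(default_scenario(schedule = bad_sched), "coding")
  zero_sched <- data.frame(condition = "Before", week = 0,
                           trill = 0, phee = 5, food = 5)
  expect_error(simulate_features(default_scenario(schedule = zero_sched)),
               "positive")
})

test_that("feature simulation is deterministic and schedule-faithful", {
  cfg <- small_scenario()
  sim1 <- simulate_features(cfg, seed = 42)
  sim2 <- simulate_features(cfg, seed = 42)
  expect_identical(sim1, sim2)
  sim3 <- simulate_features(cfg, seed = 43)
  expect_false(identical(sim1$features, sim3$features))

  f <- sim1$features
  # call counts per (caller, call type, schedule block) match targets
  counts <- table(f$caller, f$call_type, f$week)
  expect_true(all(counts[, "trill", "1"] == 6))
  expect_true(all(counts[, "phee", "0"] == 6))
  # trill rows have 17 usable parameters, phee/food 15 (NA padding)
  expect_false(anyNA(f[f$call_type == "trill", paste0("para_", 16:17)]))
  expect_true(all(is.na(f[f$call_type != "trill", "para_17"])))
})

test_that("week 0 group offset equals the dialect offset; rate 0 is static", {
  sched <- data.frame(condition = c("Before", rep("NewSoc", 2)),
                      week = c(0, 1, 16), trill = 150)
  cfg <- scenario_config(
    call_types = "trill",
    dialect_offset = list(trill = factor_aligned_offset(17, 2)),
    schedule = sched,
    convergence_rate = list(trill = c(F = 0, M = 0)),
    individual_sd = 0, call_sd = 1, seed = 3
  )
  f <- simulate_features(cfg, seed = 9)$features
  pc <- paste0("para_", sprintf("%02d", 1:17))
  grp_mean <- function(colony, wk) {
    colMeans(f[f$colony == colony & f$week == wk, pc])
  }
  # at week 0 the translocated group sits at the dialect offset; shared
  # noise factors correlate the group-mean errors across parameters, so
  # judge by the average absolute deviation rather than per parameter
  diff0 <- grp_mean("MA", 0) - grp_mean("ZH", 0)
  expect_lt(mean(abs(diff0 - cfg$dialect_offset$trill)), 0.1)
  # with zero rates the offset does not move between weeks 1 and 16
  d1 <- grp_mean("MA", 1) - grp_mean("ZH", 1)
  d16 <- grp_mean("MA", 16) - grp_mean("ZH", 16)
  expect_lt(mean(abs(d16 - d1)), 0.15)
})

test_that("convergence factor decays only with social exposure", {
  expect_equal(vocalaccom:::convergence_factor(0, 0.1), 1)
  expect_equal(vocalaccom:::convergence_factor(0.5, 0.1), 1)   # quarantine
  expect_equal(vocalaccom:::convergence_factor(10, 0.1), exp(-1))
  expect_gt(vocalaccom:::convergence_factor(4, -0.05), 1)      # divergence
})

test_that("waveform synthesis guards its preconditions", {
  expect_error(synth_call_spec("phee", duration = 0, f0_start = 7000),
               "duration")
  expect_error(synth_call_spec("trill", duration = 0.3, f0_start = 500,
                               fm_extent = 2000), "positive")
  spec <- synth_call_spec("phee", duration = 0.2, f0_start = 10000)
  expect_error(synthesize_waveform(spec, sample_rate = 20000), "too low")
  w <- synthesize_waveform(spec, sample_rate = 96000, seed = 1)
  expect_s3_class(w, "call_waveform")
  expect_lte(max(abs(w$samples)), 1)
})

test_that("scenario YAML round-trips", {
  cfg <- small_scenario()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(cfg, path)
  back <- read_scenario_yaml(path)
  expect_equal(back$dialect_offset, cfg$dialect_offset)
  expect_equal(back$schedule, cfg$schedule)
  expect_equal(back$sexes, cfg$sexes)
  # and the round-tripped scenario simulates identically
  expect_identical(simulate_features(cfg, seed = 5),
                   simulate_features(back, seed = 5))
})

test_that("feature tables round-trip through CSV", {
  sim <- simulate_features(small_scenario(), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(sim$features, path)
  back <- read_feature_csv(path)
  expect_equal(back, sim$features, tolerance = 1e-12)
})
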