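tone_wave <- function(f0 = 7000, duration = 0.4, snr = Inf, seed = 2,
                      type = "phee") {
  synthesize_waveform(
    synth_call_spec(type, duration = duration, f0_start = f0,
                    noise_snr = snr),
    sample_rate = 96000, seed = seed)
}

test_that("a pure tone is tracked and measured correctly", {
  w <- tone_wave()
  ctr <- track_f0(w)
  expect_true(ctr$measurable)
  expect_equal(mean(ctr$f0, na.rm = TRUE), 7000, tolerance = 0.01)
  f <- extract_features(w, ctr)
  expect_s3_class(f, "acoustic_features")
  expect_length(f, 15)
  expect_equal(f[["f0_mean"]], 7000, tolerance = 0.01)
  expect_equal(f[["pct_dur_f0max"]], 100)
  expect_lt(f[["jitter"]], 0.1)
  # slope and variation are tracker noise only: tiny relative to F0
  expect_lt(f[["f0_abs_slope"]], 0.01 * 7000)
  expect_lt(f[["f0_var_per_s"]], 0.01 * 7000)
  expect_equal(f[["duration"]], 0.4, tolerance = 0.05)
  expect_true(f[["f0_min"]] <= f[["f0_mean"]] &&
                f[["f0_mean"]] <= f[["f0_max"]])
})

test_that("a linear chirp's contour endpoints match the sweep", {
  w <- synthesize_waveform(
    synth_call_spec("food", duration = 0.15, f0_start = 6000,
                    f0_end = 8000),
    sample_rate = 96000, seed = 4)
  v <- track_f0(w)$f0
  v <- v[!is.na(v)]
  expect_equal(v[1], 6000, tolerance = 0.02)
  expect_equal(v[length(v)], 8000, tolerance = 0.02)
})

test_that("trill FM rate and extent survive a synthesis round-trip", {
  w <- synthesize_waveform(
    synth_call_spec("trill", duration = 0.5, f0_start = 7000,
                    fm_rate = 30, fm_extent = 1000, noise_snr = 20),
    sample_rate = 96000, seed = 3)
  f <- extract_features(w)
  expect_length(f, 17)
  expect_equal(f[["fm_rate"]], 30, tolerance = 0.05)
  expect_equal(f[["fm_extent"]], 1000, tolerance = 0.05)
  expect_equal(f[["f0_mean"]], 7000, tolerance = 0.01)
  # the extrema-based extent estimator agrees to within its noise
  f2 <- extract_features(w, extent_method = "extrema")
  expect_equal(f2[["fm_extent"]], 1000, tolerance = 0.1)
})

test_that("silence and noise-only calls are flagged unmeasurable", {
  silence <- call_waveform(rep(0, 19200), 96000, call_type = "phee")
  ctr <- track_f0(silence)
  expect_false(ctr$measurable)
  f <- extract_features(silence, ctr)
  expect_true(all(is.na(f)))
  expect_false(attr(f, "measurable"))

  set.seed(8)
  noise <- call_waveform(rnorm(19200, sd = 0.1), 96000, call_type = "phee")
  expect_false(track_f0(noise)$measurable)
})

test_that("features are invariant to global amplitude scaling", {
  w <- tone_wave(snr = 25)
  w_scaled <- w
  w_scaled$samples <- w$samples * 0.123
  f1 <- extract_features(w)
  f2 <- extract_features(w_scaled)
  expect_equal(unclass(f1), unclass(f2), tolerance = 1e-10)
})

test_that("flat-spectrum noise has energy quartiles at W/4, W/2, 3W/4", {
  set.seed(11)
  sr <- 96000
  noise <- call_waveform(rnorm(sr / 2), sr, call_type = "phee")
  sp <- vocalaccom:::avg_power_spectrum(noise$samples, sr)
  w_nyq <- sr / 2
  expect_equal(vocalaccom:::energy_quantile_freq(sp$freq, sp$power, 0.25),
               w_nyq * 0.25, tolerance = 0.03)
  expect_equal(vocalaccom:::energy_quantile_freq(sp$freq, sp$power, 0.50),
               w_nyq * 0.50, tolerance = 0.03)
  expect_equal(vocalaccom:::energy_quantile_freq(sp$freq, sp$power, 0.75),
               w_nyq * 0.75, tolerance = 0.03)
})

test_that("local jitter matches hand computation and flags degeneracy", {
  expect_equal(local_jitter(rep(0.001, 50)), 0)
  # periods 1, 1.1, 1 ms: mean |diff| = 0.1, mean = 1.0333... -> 9.677%
  expect_equal(local_jitter(c(1, 1.1, 1) / 1000), 100 * 0.1 / (3.1 / 3),
               tolerance = 1e-12)
  expect_warning(j <- local_jitter(0.001), "fewer than 2")
  expect_true(is.na(j))
  # brute-force oracle on random period sequences
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1), 1e-4, 2e-4)
    oracle <- 100 * mean(abs(p[-1] - p[-length(p)])) / mean(p)
    expect_equal(local_jitter(p), oracle, tolerance = 1e-12)
  }
})

test_that("call selection applies exclusion flags then first-k quotas", {
  calls <- data.frame(
    session = "s1",
    call_type = c(rep("phee", 12), rep("trill", 6)),
    onset = c(1:12, 1:6),
    flagged = c(rep(FALSE, 12), FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  )
  out <- select_calls(calls)
  expect_equal(sum(out$call_type == "phee"), 10)      # first ten of twelve
  expect_equal(out$onset[out$call_type == "phee"], 1:10)
  expect_equal(sum(out$call_type == "trill"), 4)      # 6 - 2 flagged, < quota
  # under-quota sessions keep everything
  few <- data.frame(session = "s2", call_type = "trill", onset = 1:3)
  expect_equal(nrow(select_calls(few)), 3)
})

test_that("weekly inclusion filter drops sparse cells and is idempotent", {
  f <- data.frame(
    caller = rep(c("a", "b"), c(4, 5)),
    call_type = "trill",
    week = 3
  )
  out <- weekly_inclusion_filter(f)
  expect_equal(unique(out$caller), "b")               # 4 < 5 dropped, 5 kept
  expect_equal(weekly_inclusion_filter(out), out)
})

test_that("WAV files round-trip and match an independent reader", {
  w <- tone_wave(duration = 0.05)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 96000)
  expect_equal(back$samples, w$samples, tolerance = 2 / 32767)

  py <- Sys.which("python")
  if (nzchar(py)) {
    out <- system2(py, c("-c", shQuote(paste0(
      "import wave; f = wave.open('", path, "');",
      "print(f.getnchannels(), f.getsampwidth(), f.getframerate(),",
      "f.getnframes())"))), stdout = TRUE)
    expect_equal(out, sprintf("1 2 96000 %d", length(w$samples)))
  }
})
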