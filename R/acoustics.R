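#' Track the fundamental frequency contour of a call
#'
#' Short-time autocorrelation pitch tracking in the spirit of Boersma's
#' method: the call is cut into overlapping frames, each frame's normalized
#' autocorrelation is evaluated over the lag range corresponding to
#' `[floor, ceiling]` Hz, and the highest peak (refined by parabolic
#' interpolation) gives the frame's F0. Frames whose peak correlation falls
#' below `voicing_threshold`, or whose energy is negligible, are marked
#' unvoiced. Defaults target the tonal range of marmoset calls.
#'
#' @param wave a `call_waveform`.
#' @param floor,ceiling F0 search range in Hz; `floor < ceiling < Nyquist`.
#' @param step frame step in seconds (default 5 ms).
#' @param window analysis window length in seconds; default `3 / floor`
#'   (three periods of the lowest admissible F0).
#' @param voicing_threshold minimum normalized autocorrelation for a frame
#'   to count as voiced.
#' @param octave_cost per-octave penalty on longer lags when picking the
#'   autocorrelation peak; resolves the octave ambiguity of periodic
#'   signals (every multiple of the true period correlates equally well)
#'   in favour of the higher F0 candidate.
#' @return An `f0_contour`: `time` (frame centers, s, origin at call
#'   start), `f0` (Hz, `NA` where unvoiced), `step`, and a `measurable`
#'   flag that is `FALSE` when no frame is voiced (such calls are dropped
#'   from analysis, mirroring the study's exclusion of calls that could not
#'   be measured in full).
#' @export
track_f0 <- function(wave, floor = 3000, ceiling = 14000, step = 0.005,
                     window = 3 / floor, voicing_threshold = 0.5,
                     octave_cost = 0.1) {
  stopifnot(inherits(wave, "call_waveform"))
  sr <- wave$sample_rate
  if (!(floor < ceiling && ceiling < sr / 2)) {
    stop("need floor < ceiling < Nyquist", call. = FALSE)
  }
  x <- wave$samples
  win_n <- max(16L, round(window * sr))
  step_n <- max(1L, round(step * sr))
  lag_min <- max(2L, base::floor(sr / ceiling))   # args shadow base fns here
  lag_max <- base::ceiling(sr / floor)
  if (length(x) < win_n + lag_max + 1L) {
    stop("waveform shorter than one analysis frame", call. = FALSE)
  }
  starts <- seq(1L, length(x) - win_n - lag_max, by = step_n)
  peak_amp <- max(abs(x), 1e-12)
  lags <- lag_min:lag_max

  f0 <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    seg <- x[s:(s + win_n + lag_max - 1L)]
    seg <- seg - mean(seg)
    a <- seg[seq_len(win_n)]
    e_a <- sum(a * a)
    if (sqrt(e_a / win_n) < 1e-4 * peak_amp) next   # silent frame
    r <- vapply(lags, function(l) {
      b <- seg[(l + 1L):(l + win_n)]
      sum(a * b) / sqrt(e_a * sum(b * b))
    }, numeric(1))
    j <- which.max(r - octave_cost * log2(lags / lag_min))
    if (!is.finite(r[j]) || r[j] < voicing_threshold) next
    lag <- lags[j]
    if (j > 1L && j < length(r)) {   # parabolic peak refinement
      denom <- r[j - 1L] - 2 * r[j] + r[j + 1L]
      if (denom < 0) lag <- lag + 0.5 * (r[j - 1L] - r[j + 1L]) / denom
    }
    cand <- sr / lag
    if (cand >= floor && cand <= ceiling) f0[i] <- cand
  }
  structure(list(
    time = (starts - 1L + win_n / 2) / sr,
    f0 = f0,
    step = step_n / sr,
    measurable = any(!is.na(f0))
  ), class = "f0_contour")
}

#' @export
print.f0_contour <- function(x, ...) {
  cat(sprintf("f0_contour: %d frames (step %.1f ms), %d voiced%s\n",
              length(x$f0), 1000 * x$step, sum(!is.na(x$f0)),
              if (x$measurable) "" else " [unmeasurable]"))
  invisible(x)
}

#' Local jitter of a period sequence
#'
#' Mean absolute difference between consecutive periods divided by the
#' mean period, as a percentage: cycle-to-cycle irregularity of the
#' fundamental.
#'
#' @param periods numeric vector of consecutive period estimates (s).
#' @return Jitter in percent; `NA` with a warning when fewer than two
#'   periods are available (undefined).
#' @export
local_jitter <- function(periods) {
  periods <- periods[is.finite(periods)]
  if (length(periods) < 2L) {
    warning("jitter undefined for fewer than 2 periods")
    return(NA_real_)
  }
  100 * mean(abs(diff(periods))) / mean(periods)
}

# Average power spectrum (Welch, Hann window, 50% overlap) of the call.
avg_power_spectrum <- function(x, sr, n_fft = 1024L) {
  n_fft <- min(n_fft, 2^floor(log2(length(x))))
  hop <- n_fft %/% 2L
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_fft) - 1) / (n_fft - 1))
  starts <- seq(1L, length(x) - n_fft + 1L, by = hop)
  n_bins <- n_fft %/% 2L + 1L
  acc <- numeric(n_bins)
  per_frame <- matrix(0, length(starts), n_bins)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + n_fft - 1L)] * w
    p <- Mod(stats::fft(seg)[seq_len(n_bins)])^2
    per_frame[i, ] <- p
    acc <- acc + p
  }
  list(freq = (seq_len(n_bins) - 1) * sr / n_fft,
       power = acc / length(starts),
       per_frame = per_frame)
}

# Frequency at a given cumulative-energy fraction, with linear
# interpolation between spectral bins.
energy_quantile_freq <- function(freq, power, q) {
  cum <- cumsum(power) / sum(power)
  i <- which(cum >= q)[1]
  if (i == 1L) return(freq[1])
  f0 <- freq[i - 1L]; f1 <- freq[i]
  c0 <- cum[i - 1L];  c1 <- cum[i]
  f0 + (q - c0) / (c1 - c0) * (f1 - f0)
}

# Dominant modulation frequency of the (detrended) F0 contour via a
# zero-padded periodogram with parabolic peak refinement.
contour_fm_rate <- function(f0, step) {
  n <- length(f0)
  t <- seq_len(n)
  f0 <- stats::residuals(stats::lm(f0 ~ t))   # remove mean and drift
  n_fft <- 2^ceiling(log2(n * 8L))
  spec <- Mod(stats::fft(c(f0, numeric(n_fft - n))))[seq_len(n_fft %/% 2L)]^2
  fr <- (seq_len(n_fft %/% 2L) - 1) / (n_fft * step)
  keep <- fr > 1 / (n * step)      # exclude the DC/trend lobe
  j <- which(keep)[which.max(spec[keep])]
  rate <- fr[j]
  if (j > 1L && j < length(spec)) {
    y0 <- spec[j - 1L]; y1 <- spec[j]; y2 <- spec[j + 1L]
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) rate <- rate + (0.5 * (y0 - y2) / denom) / (n_fft * step)
  }
  rate
}

# Peak-to-trough modulation depth. "sine" fits a least-squares sinusoid at
# the detected rate (robust to frame-level tracking noise); "extrema"
# averages local maxima minus local minima of the raw contour.
contour_fm_extent <- function(f0, step, rate,
                              method = c("sine", "extrema")) {
  method <- match.arg(method)
  n <- length(f0)
  t <- (seq_len(n) - 1) * step
  resid <- stats::residuals(stats::lm(f0 ~ t))
  if (method == "sine") {
    s <- sin(2 * pi * rate * t); c_ <- cos(2 * pi * rate * t)
    fit <- stats::lm(resid ~ s + c_ - 1)
    return(2 * sqrt(sum(stats::coef(fit)^2)))
  }
  d <- diff(resid)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  troughs <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  if (!length(peaks) || !length(troughs)) return(0)
  mean(resid[peaks]) - mean(resid[troughs])
}

#' Extract the per-call acoustic parameter vector
#'
#' Computes the study's per-call parameters from a waveform and its F0
#' contour: F0 at call start and end, mean/min/max F0, the percentage of
#' the call for which F0 is at its maximum (within 1%), the absolute F0
#' slope (|end - start| / duration), the mean frame-to-frame F0 variation
#' per second, the frequency at the first/second/third quartiles of
#' spectral energy, the peak frequency of the whole-call average spectrum,
#' the percentage of frames whose spectral peak lies within 1% of it,
#' local jitter, and the call duration (measured between the first and
#' last frames within 25 dB of the energy-envelope peak). Trills
#' additionally get the frequency-modulation rate and extent of the F0
#' contour, for 17 parameters against 15 for phee and food calls.
#'
#' All parameters are invariant to global amplitude scaling. Unvoiced
#' frames are excluded from every F0 statistic.
#'
#' @param wave a `call_waveform` (its `call_type` decides 15 vs 17
#'   parameters).
#' @param contour optional `f0_contour`; tracked with defaults if missing.
#' @param extent_method method for the trill FM extent, `"sine"` (default)
#'   or `"extrema"`; see Details in the package vignette.
#' @param ... passed on to [track_f0()] when `contour` is missing.
#' @return Named numeric vector of class `acoustic_features` (length 17
#'   for trills, 15 otherwise), or `NA`s with attribute
#'   `measurable = FALSE` when the contour is unmeasurable.
#' @export
extract_features <- function(wave, contour = NULL,
                             extent_method = c("sine", "extrema"), ...) {
  stopifnot(inherits(wave, "call_waveform"))
  extent_method <- match.arg(extent_method)
  if (is.null(contour)) contour <- track_f0(wave, ...)
  is_trill <- identical(wave$call_type, "trill")
  feat_names <- c("f0_start", "f0_end", "f0_mean", "f0_min", "f0_max",
                  "pct_dur_f0max", "f0_abs_slope", "f0_var_per_s",
                  "q1_freq", "q2_freq", "q3_freq", "peak_freq",
                  "pct_time_peak_freq", "jitter", "duration")
  if (is_trill) feat_names <- c(feat_names, "fm_rate", "fm_extent")

  voiced <- which(!is.na(contour$f0))
  if (!contour$measurable || length(voiced) < 3L) {
    out <- stats::setNames(rep(NA_real_, length(feat_names)), feat_names)
    attr(out, "measurable") <- FALSE
    class(out) <- "acoustic_features"
    return(out)
  }
  f0 <- contour$f0[voiced]
  step <- contour$step
  x <- wave$samples
  sr <- wave$sample_rate

  # duration on a -25 dB energy-envelope threshold relative to the peak
  win_n <- max(16L, round(step * sr))
  starts <- seq(1L, length(x) - win_n + 1L, by = win_n)
  env <- vapply(starts,
                function(s) sqrt(mean(x[s:(s + win_n - 1L)]^2)), numeric(1))
  above <- which(env >= max(env) * 10^(-25 / 20))
  duration <- (max(above) - min(above) + 1L) * win_n / sr

  spec <- avg_power_spectrum(x, sr)
  peak_freq <- spec$freq[which.max(spec$power)]
  frame_peaks <- spec$freq[apply(spec$per_frame, 1, which.max)]
  pct_time_peak <- 100 * mean(abs(frame_peaks - peak_freq) <=
                                0.01 * peak_freq)

  f0_max <- max(f0)
  out <- c(
    f0_start = f0[1],
    f0_end = f0[length(f0)],
    f0_mean = mean(f0),
    f0_min = min(f0),
    f0_max = f0_max,
    pct_dur_f0max = 100 * mean(f0 >= 0.99 * f0_max),
    f0_abs_slope = abs(f0[length(f0)] - f0[1]) / duration,
    f0_var_per_s = mean(abs(diff(f0))) / step,
    q1_freq = energy_quantile_freq(spec$freq, spec$power, 0.25),
    q2_freq = energy_quantile_freq(spec$freq, spec$power, 0.50),
    q3_freq = energy_quantile_freq(spec$freq, spec$power, 0.75),
    peak_freq = peak_freq,
    pct_time_peak_freq = pct_time_peak,
    jitter = suppressWarnings(local_jitter(1 / f0)),
    duration = duration
  )
  if (is_trill) {
    rate <- contour_fm_rate(f0, step)
    out <- c(out, fm_rate = rate,
             fm_extent = contour_fm_extent(f0, step, rate, extent_method))
  }
  attr(out, "measurable") <- TRUE
  class(out) <- "acoustic_features"
  out
}

#' Select calls from a session under the study quotas
#'
#' Calls flagged as overlapping, noisy or unmeasurable are excluded first;
#' then the chronologically first `k` calls of each call type are kept per
#' session (defaults: 10 phee, 5 trill, 20 food). Sessions with fewer clean
#' calls than the quota keep everything they have.
#'
#' @param calls data frame with columns `session`, `call_type`, `onset`
#'   (chronological order within session) and optionally `flagged`
#'   (logical; excluded before quota selection).
#' @param quotas named integer vector of per-session quotas by call type.
#' @return The filtered data frame.
#' @export
select_calls <- function(calls,
                         quotas = c(phee = 10, trill = 5, food = 20)) {
  stopifnot_cols(calls, c("session", "call_type", "onset"), "calls")
  if (!is.null(calls$flagged)) calls <- calls[!calls$flagged, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(calls)),
                              list(calls$session, calls$call_type),
                              drop = TRUE), function(idx) {
    idx <- idx[order(calls$onset[idx])]
    ct <- calls$call_type[idx[1]]
    k <- quotas[[ct]] %||% length(idx)
    if (is.na(k)) k <- length(idx)
    idx[seq_len(min(k, length(idx)))]
  }))
  out <- calls[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum weekly call-count inclusion filter
#'
#' Drops every (caller, call type, week) cell that contributes fewer than
#' `min_calls` calls (default 5), the study's inclusion rule for the
#' longitudinal analysis. The filter is idempotent.
#'
#' @param features feature table with `caller`, `call_type`, `week`.
#' @param min_calls minimum calls per cell.
#' @return Filtered feature table; a message reports dropped rows.
#' @export
weekly_inclusion_filter <- function(features, min_calls = 5) {
  stopifnot_cols(features, c("caller", "call_type", "week"), "feature table")
  key <- interaction(features$caller, features$call_type, features$week,
                     drop = TRUE)
  counts <- table(key)
  keep <- counts[as.character(key)] >= min_calls
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("weekly_inclusion_filter: dropped %d of %d calls (< %d per caller x call type x week)",
                    n_drop, nrow(features), min_calls))
  }
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
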