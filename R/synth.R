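#' Specification of a synthetic call
#'
#' Describes a tonal test call for the waveform synthesizer. The contour
#' depends on the call type: a phee is a long tone whose fundamental drifts
#' linearly from `f0_start` to `f0_end`; a trill carries sinusoidal
#' frequency modulation at `fm_rate` with peak-to-trough depth `fm_extent`
#' around the same linear carrier; a food call is a short rising chirp.
#'
#' @param call_type one of `"trill"`, `"phee"`, `"food"`.
#' @param duration call duration in seconds (> 0).
#' @param f0_start,f0_end fundamental frequency at call start/end, Hz.
#' @param fm_rate modulation rate in Hz (trill only, >= 0).
#' @param fm_extent peak-to-trough modulation depth in Hz (trill only).
#' @param envelope `"hann"` (raised-cosine fade over the whole call) or
#'   `"flat"` (short 5 ms cosine ramps only).
#' @param noise_snr signal-to-noise ratio of added white noise in dB;
#'   `Inf` for a clean signal.
#' @return An object of class `synth_call_spec`.
#' @export
synth_call_spec <- function(call_type = c("phee", "trill", "food"),
                            duration,
                            f0_start,
                            f0_end = f0_start,
                            fm_rate = 0,
                            fm_extent = 0,
                            envelope = c("flat", "hann"),
                            noise_snr = Inf) {
  call_type <- match.arg(call_type)
  envelope <- match.arg(envelope)
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be > 0", call. = FALSE)
  }
  if (fm_rate < 0) stop("fm_rate must be >= 0", call. = FALSE)
  if (min(f0_start, f0_end) - fm_extent / 2 <= 0) {
    stop("F0 contour must stay positive", call. = FALSE)
  }
  structure(list(call_type = call_type, duration = duration,
                 f0_start = f0_start, f0_end = f0_end,
                 fm_rate = fm_rate, fm_extent = fm_extent,
                 envelope = envelope, noise_snr = noise_snr),
            class = "synth_call_spec")
}

#' Synthesize a mono call waveform from a spec
#'
#' Generates `sin(phi(t))` with instantaneous frequency following the
#' spec's contour (phase as the cumulative integral of F0), applies the
#' amplitude envelope, and adds white Gaussian noise at the requested SNR.
#'
#' @param spec a [synth_call_spec()].
#' @param sample_rate sampling rate in Hz; must be at least four times the
#'   highest instantaneous frequency so the fundamental is comfortably
#'   below Nyquist.
#' @param seed seed for the noise generator.
#' @param caller,colony,sex,condition,week optional metadata carried on the
#'   returned waveform.
#' @return A `call_waveform`: list with `samples` (numeric, in -1..1),
#'   `sample_rate` and the metadata fields.
#' @export
synthesize_waveform <- function(spec, sample_rate = 96000, seed = 1L,
                                caller = NA_character_, colony = NA_character_,
                                sex = NA_character_,
                                condition = NA_character_, week = NA_real_) {
  stopifnot(inherits(spec, "synth_call_spec"))
  f_max <- max(spec$f0_start, spec$f0_end) + spec$fm_extent / 2
  if (sample_rate < 4 * f_max) {
    stop(sprintf(paste("sample_rate %g too low for a %g Hz contour;",
                       "need at least %g"), sample_rate, f_max, 4 * f_max),
         call. = FALSE)
  }
  n <- max(2L, round(spec$duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- spec$f0_start + (spec$f0_end - spec$f0_start) * t / spec$duration
  if (spec$call_type == "trill" && spec$fm_rate > 0) {
    f0 <- f0 + (spec$fm_extent / 2) * sin(2 * pi * spec$fm_rate * t)
  }
  phase <- 2 * pi * cumsum(f0) / sample_rate
  x <- sin(phase)
  if (spec$envelope == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  } else {
    ramp_n <- min(n %/% 4, round(0.005 * sample_rate))
    if (ramp_n > 1) {
      ramp <- 0.5 - 0.5 * cos(pi * (seq_len(ramp_n) - 1) / (ramp_n - 1))
      x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * ramp
      x[n + 1 - seq_len(ramp_n)] <- x[n + 1 - seq_len(ramp_n)] * ramp
    }
  }
  if (is.finite(spec$noise_snr)) {
    sig_rms <- sqrt(mean(x^2))
    noise_sd <- sig_rms / 10^(spec$noise_snr / 20)
    x <- x + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  x <- x / max(abs(x), 1e-12) * 0.95
  call_waveform(x, sample_rate, caller = caller, colony = colony, sex = sex,
                call_type = spec$call_type, condition = condition, week = week)
}

#' Construct a call waveform object
#'
#' @param samples numeric vector of amplitudes in -1..1 (mono).
#' @param sample_rate sampling rate in Hz.
#' @param caller,colony,sex,call_type,condition,week per-call metadata.
#' @return An object of class `call_waveform`.
#' @export
call_waveform <- function(samples, sample_rate,
                          caller = NA_character_, colony = NA_character_,
                          sex = NA_character_, call_type = NA_character_,
                          condition = NA_character_, week = NA_real_) {
  stopifnot(is.numeric(samples), length(samples) >= 2, sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 caller = caller, colony = colony, sex = sex,
                 call_type = call_type, condition = condition, week = week),
            class = "call_waveform")
}

#' @export
print.call_waveform <- function(x, ...) {
  cat(sprintf("call_waveform: %.3f s @ %g Hz (%s)\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              x$call_type %||% NA))
  invisible(x)
}

#' Read and write mono 16-bit PCM RIFF WAV files
#'
#' Minimal RIFF reader/writer for the package's one audio format: mono,
#' 16-bit PCM, any sampling rate. Samples are stored as amplitudes in
#' -1..1.
#'
#' @param wave a `call_waveform`.
#' @param path file path.
#' @return `read_wav()` returns a `call_waveform` (without metadata).
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "call_waveform"))
  pcm <- as.integer(pmax(-32767, pmin(32767, round(wave$samples * 32767))))
  n_bytes <- length(pcm) * 2L
  sr <- as.integer(round(wave$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")      # PCM, mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")        # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")     # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave_id <- readChar(con, 4)
  if (riff != "RIFF" || wave_id != "WAVE") {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  sample_rate <- NULL
  repeat {
    chunk <- readChar(con, 4)
    if (length(chunk) == 0 || nchar(chunk) < 4) {
      stop("no data chunk found in ", path, call. = FALSE)
    }
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (chunk == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("only mono PCM WAV is supported", call. = FALSE)
      }
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      bits <- readBin(con, "integer", 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit PCM is supported", call. = FALSE)
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (chunk == "data") {
      pcm <- readBin(con, "integer", size %/% 2L, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(sample_rate)) stop("fmt chunk missing in ", path, call. = FALSE)
  call_waveform(pcm / 32767, sample_rate)
}
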