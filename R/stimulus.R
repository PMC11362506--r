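# Digital stimulus synthesis: tones, noise, gaps, amplitude modulation.
#
# Levels are in dB FS (decibels relative to digital full scale), which is
# purely relative: absolute presentation level depends on the listener's
# hardware. For tones 0 dB FS means peak amplitude 1.0; noise is scaled so
# its RMS matches the RMS of a full-scale sine (1/sqrt(2)) at 0 dB FS.

#' Sampled audio waveform
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate Samples per second. 48000 is the default (the most
#'   common browser/audio-interface rate); 44100 is equally supported.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate = 48000) {
  if (!is.numeric(samples)) stop("'samples' must be numeric")
  if (length(samples) && max(abs(samples)) > 1 + 1e-12)
    stop("waveform samples must lie in [-1, 1]")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz (%.1f ms), peak %.4g\n",
              length(x$samples), x$sample_rate, duration_ms(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @rdname waveform
#' @param wave A `waveform`.
#' @return `duration_ms()`: the duration in milliseconds.
#' @export
duration_ms <- function(wave) 1000 * length(wave$samples) / wave$sample_rate

ms_to_samples <- function(ms, sample_rate) as.integer(round(ms * sample_rate / 1000))

#' Pure-tone specification
#'
#' @param frequency Tone frequency in Hz (> 0, below Nyquist at synthesis).
#' @param duration_ms Total duration in ms, ramps included.
#' @param level_dbfs Peak level in dB FS (<= 0; 0 dB FS = peak 1.0).
#' @param ramp_ms Duration of each raised-cosine onset/offset ramp, in ms.
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(frequency = 1000, duration_ms = 250, level_dbfs = -20,
                      ramp_ms = 10) {
  if (frequency <= 0) stop("'frequency' must be positive")
  if (duration_ms <= 0) stop("'duration_ms' must be positive")
  if (level_dbfs > 0) stop("'level_dbfs' must be <= 0 (0 dB FS is full scale)")
  if (ramp_ms < 0 || 2 * ramp_ms > duration_ms)
    stop("ramps must satisfy 0 <= 2 * ramp_ms <= duration_ms")
  structure(list(frequency = frequency, duration_ms = duration_ms,
                 level_dbfs = level_dbfs, ramp_ms = ramp_ms),
            class = "tone_spec")
}

#' Noise-burst specification
#'
#' Gaussian white noise; there is no frequency parameter. The same seed
#' regenerates the identical sample sequence.
#'
#' @param duration_ms Total duration in ms, ramps included.
#' @param level_dbfs Level in dB FS; the noise RMS is matched to the RMS
#'   of a full-scale sine at the same nominal level.
#' @param ramp_ms Raised-cosine ramp duration in ms.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(duration_ms = 500, level_dbfs = -20, ramp_ms = 10,
                       seed = 1L) {
  if (duration_ms <= 0) stop("'duration_ms' must be positive")
  if (level_dbfs > 0) stop("'level_dbfs' must be <= 0 (0 dB FS is full scale)")
  if (ramp_ms < 0 || 2 * ramp_ms > duration_ms)
    stop("ramps must satisfy 0 <= 2 * ramp_ms <= duration_ms")
  structure(list(duration_ms = duration_ms, level_dbfs = level_dbfs,
                 ramp_ms = ramp_ms, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Synthesise a pure tone
#'
#' A sine wave at the specified frequency with peak amplitude
#' `10^(level_dbfs / 20)`, gated on and off with raised-cosine ramps.
#' Deterministic.
#'
#' @param spec A [tone_spec()].
#' @param sample_rate Samples per second.
#' @return A [waveform()].
#' @examples
#' w <- pure_tone(tone_spec(1000, 250, 0, 10))
#' length(w$samples)  # 12000 at 48 kHz
#' @export
pure_tone <- function(spec, sample_rate = 48000) {
  stopifnot(inherits(spec, "tone_spec"))
  if (spec$frequency >= sample_rate / 2)
    stop("tone frequency ", spec$frequency, " Hz is at or above the Nyquist ",
         "frequency (", sample_rate / 2, " Hz): the tone would alias")
  n <- ms_to_samples(spec$duration_ms, sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  amp <- 10^(spec$level_dbfs / 20)
  apply_ramps(waveform(amp * sin(2 * pi * spec$frequency * t), sample_rate),
              spec$ramp_ms)
}

#' Apply raised-cosine onset/offset ramps
#'
#' Multiplies the first and last `ramp_ms` of the waveform by the
#' half-cosine gate `g(t) = 0.5 * (1 - cos(pi * t / T))`, rising from 0 to
#' 1 at onset and mirrored at offset. Plateau samples are untouched.
#'
#' @param wave A `waveform`.
#' @param ramp_ms Ramp duration in ms; must not exceed half the waveform.
#' @return The ramped `waveform`.
#' @export
apply_ramps <- function(wave, ramp_ms) {
  stopifnot(inherits(wave, "waveform"))
  if (ramp_ms < 0) stop("'ramp_ms' must be non-negative")
  nr <- ms_to_samples(ramp_ms, wave$sample_rate)
  if (nr == 0L) return(wave)
  n <- length(wave$samples)
  if (2L * nr > n)
    stop("ramps (2 x ", ramp_ms, " ms) exceed the waveform duration")
  g <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1L) / nr))
  wave$samples[seq_len(nr)] <- wave$samples[seq_len(nr)] * g
  wave$samples[n - seq_len(nr) + 1L] <- wave$samples[n - seq_len(nr) + 1L] * g
  wave
}

#' Synthesise Gaussian white noise
#'
#' Seeded Gaussian noise scaled so its RMS equals the RMS of a full-scale
#' sine at the nominal level, `10^(level_dbfs / 20) / sqrt(2)`, then
#' ramped and hard-limited to `[-1, 1]`. The same seed always reproduces
#' the identical sample sequence; the caller's RNG state is untouched.
#'
#' @param spec A [noise_spec()].
#' @param sample_rate Samples per second.
#' @return A [waveform()].
#' @export
white_noise <- function(spec, sample_rate = 48000) {
  stopifnot(inherits(spec, "noise_spec"))
  n <- ms_to_samples(spec$duration_ms, sample_rate)
  x <- with_local_seed(spec$seed, stats::rnorm(n))
  target_rms <- 10^(spec$level_dbfs / 20) / sqrt(2)
  x <- x * target_rms / sqrt(mean(x^2))
  x <- pmin(pmax(x, -1), 1)
  apply_ramps(waveform(x, sample_rate), spec$ramp_ms)
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Insert a silent gap
#'
#' Sets a window of `gap_ms` to zero. By default the gap is abrupt (no
#' edge ramps) and centred at the waveform midpoint; the output length
#' equals the input length.
#'
#' @param wave A `waveform`.
#' @param gap_ms Gap duration in ms; must be shorter than the waveform. A
#'   zero-length gap is the identity.
#' @param position `"center"`, or a numeric onset time in ms.
#' @return The gapped `waveform`.
#' @export
insert_gap <- function(wave, gap_ms, position = "center") {
  stopifnot(inherits(wave, "waveform"))
  if (gap_ms < 0) stop("'gap_ms' must be non-negative")
  if (gap_ms >= duration_ms(wave))
    stop("gap (", gap_ms, " ms) must be shorter than the waveform (",
         duration_ms(wave), " ms)")
  ng <- ms_to_samples(gap_ms, wave$sample_rate)
  if (ng == 0L) return(wave)
  n <- length(wave$samples)
  start <- if (identical(position, "center")) (n - ng) %/% 2L
           else ms_to_samples(as.numeric(position), wave$sample_rate)
  if (start < 0L || start + ng > n) stop("gap window falls outside the waveform")
  wave$samples[start + seq_len(ng)] <- 0
  wave
}

#' Sinusoidally amplitude-modulate a waveform
#'
#' Multiplies the carrier by the envelope `1 + m * sin(2*pi*f*t + phase)`
#' with modulation index `m = depth_percent / 100`. With
#' `compensate = TRUE` (default) the result is divided by `1 + m`, which
#' guarantees the output stays within `[-1, 1]` at the cost of lowering
#' the overall level; with `compensate = FALSE` the raw modulated signal
#' is returned and may clip downstream. Depth 0 is an exact identity.
#'
#' @param wave A `waveform` carrier.
#' @param depth_percent Modulation depth, 0 to 100.
#' @param mod_rate_hz Modulation rate in Hz (default 20).
#' @param mod_phase Modulator starting phase in radians.
#' @param compensate Divide by `1 + m` to prevent clipping.
#' @return The modulated `waveform`.
#' @export
amplitude_modulate <- function(wave, depth_percent, mod_rate_hz = 20,
                               mod_phase = 0, compensate = TRUE) {
  stopifnot(inherits(wave, "waveform"))
  if (depth_percent < 0 || depth_percent > 100)
    stop("'depth_percent' must lie in [0, 100]")
  m <- depth_percent / 100
  if (m == 0) return(wave)
  t <- (seq_along(wave$samples) - 1L) / wave$sample_rate
  env <- 1 + m * sin(2 * pi * mod_rate_hz * t + mod_phase)
  y <- wave$samples * env
  if (compensate) y <- y / (1 + m)
  wave$samples <- y
  wave
}

#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' Samples outside `[-1, 1]` are an error, never silently clipped. A
#' round-trip through [read_wav()] reproduces the samples to within one
#' quantisation step (2^-15).
#'
#' @param wave A `waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "waveform"))
  if (length(wave$samples) && max(abs(wave$samples)) > 1)
    stop("samples exceed [-1, 1]; refusing to clip while writing WAV")
  pcm <- as.integer(round(wave$samples * 32767))
  sr <- as.integer(round(wave$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(c(1L, 1L), con, size = 2, endian = "little")    # PCM, mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")   # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal reader for the files produced by [write_wav()].
#'
#' @param path WAV file path.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file: ", path)
  readBin(con, integer(), 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAV file: ", path)
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono WAV is supported")
      sr <- readBin(con, integer(), 1, size = 4, endian = "little")
      readBin(con, integer(), 1, size = 4, endian = "little")
      bits <- readBin(con, integer(), 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit WAV is supported")
    } else if (id == "data") {
      if (is.null(sr)) stop("data chunk precedes fmt chunk in ", path)
      pcm <- readBin(con, integer(), size / 2, size = 2, endian = "little",
                     signed = TRUE)
      return(waveform(pcm / 32767, sr))
    } else {
      readBin(con, raw(), size)
    }
  }
}
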