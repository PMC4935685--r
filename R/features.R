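#' Acoustic feature extraction from spectrogram frames
#'
#' These functions compute, per spectrogram frame, the four acoustic features
#' used throughout the package: mean frequency, fundamental frequency (FF),
#' frequency change, and harmonicity. They exist to build synthetic audio
#' fixtures and to validate externally supplied contours; contour tables
#' remain the canonical input (see [songio]).
#'
#' A spectrogram frame is a vector of strictly increasing frequency-band
#' centers `freqs_hz` with nonnegative intensities `intens`.
#'
#' @name features
NULL

#' Spectrogram configuration
#'
#' Defaults follow the standard measurement setup for zebra finch song:
#' 256-point Hamming window, 0.5 ms time step, 420 Hz high-pass cutoff,
#' 22.05 kHz sample rate.
#'
#' @param window_pts FFT window length in samples.
#' @param step_ms time step between frames (ms).
#' @param highpass_hz high-pass cutoff; bands below are discarded.
#' @param sample_rate_hz audio sample rate; other rates should be resampled.
#' @return list of class `spectro_config`.
#' @export
spectro_config <- function(window_pts = 256, step_ms = 0.5,
                           highpass_hz = 420, sample_rate_hz = 22050) {
  stopf(step_ms > 0, "step_ms must be > 0")
  stopf(highpass_hz >= 0, "highpass_hz must be >= 0")
  structure(list(window_pts = window_pts, step_ms = step_ms,
                 window = "hamming", highpass_hz = highpass_hz,
                 sample_rate_hz = sample_rate_hz),
            class = "spectro_config")
}

#' Spectrogram of a mono waveform
#'
#' Thin wrapper over a short-time Fourier transform (Hamming window) that
#' returns magnitude frames in the shape the feature functions expect. Bands
#' below the high-pass cutoff are dropped.
#'
#' @param wave numeric waveform (mono).
#' @param config a [spectro_config()].
#' @return list with `freqs_hz`, `times_ms`, and `intens` (bands x frames
#'   magnitude matrix).
#' @export
spectrogram_frames <- function(wave, config = spectro_config()) {
  step <- max(1L, round(config$sample_rate_hz * config$step_ms / 1000))
  sg <- signal::specgram(wave, n = config$window_pts,
                         Fs = config$sample_rate_hz,
                         window = signal::hamming(config$window_pts),
                         overlap = config$window_pts - step)
  keep <- sg$f >= config$highpass_hz
  list(freqs_hz = as.numeric(sg$f[keep]),
       times_ms = as.numeric(sg$t) * 1000,
       intens = abs(sg$S)[keep, , drop = FALSE])
}

#' Mean frequency of a spectrogram frame
#'
#' Intensity-weighted mean of the band frequencies: each band's frequency is
#' multiplied by its intensity, summed, and divided by the total intensity.
#'
#' @param freqs_hz strictly increasing band center frequencies.
#' @param intens nonnegative band intensities.
#' @return mean frequency in Hz, bounded by the band range; `NA` if the frame
#'   carries no energy.
#' @export
mean_frequency <- function(freqs_hz, intens) {
  stopf(length(freqs_hz) == length(intens), "freqs and intens differ in length")
  tot <- sum(intens)
  if (tot <= 0) return(NA_real_)
  sum(freqs_hz * intens) / tot
}

#' Harmonicity of a spectrogram frame
#'
#' Proportion of the spectrum's intensity found within +/- FF/4 of each
#' harmonic (integer multiple) of the fundamental frequency. Harmonic windows
#' are truncated at the Nyquist frequency; bands straddling a window edge
#' contribute in proportion to their overlap (each band is treated as an
#' interval of width equal to the local band spacing).
#'
#' @param freqs_hz,intens spectrogram frame.
#' @param ff_hz fundamental frequency (> 0).
#' @param nyquist_hz upper frequency limit (default: top band edge).
#' @return harmonicity in \[0,1\]; `NA` if the frame carries no energy.
#' @export
harmonicity <- function(freqs_hz, intens, ff_hz, nyquist_hz = NULL) {
  stopf(ff_hz > 0, "ff_hz must be > 0")
  tot <- sum(intens)
  if (tot <= 0) return(NA_real_)
  n <- length(freqs_hz)
  half <- if (n > 1) diff(freqs_hz) / 2 else ff_hz / 8
  lo <- freqs_hz - c(half[1], half)[seq_len(n)]
  hi <- freqs_hz + c(half, half[n - 1])[seq_len(n)]
  if (is.null(nyquist_hz)) nyquist_hz <- max(hi)
  kmax <- max(1L, floor(nyquist_hz / ff_hz))
  inside <- numeric(n)
  for (k in seq_len(kmax)) {
    wlo <- k * ff_hz - ff_hz / 4
    whi <- min(k * ff_hz + ff_hz / 4, nyquist_hz)
    ov <- pmax(0, pmin(hi, whi) - pmax(lo, wlo))
    inside <- inside + ov
  }
  frac <- pmin(1, inside / (hi - lo))
  min(1, sum(intens * frac) / tot)
}

#' Frequency change from a fundamental-frequency track
#'
#' Linear regression of FF against time over a short window, with the slope
#' mapped through an arctangent onto \[0,1\]: 0 means falling infinitely
#' quickly, 0.5 means flat, 1 means rising infinitely quickly,
#' `fc = atan(c * slope) / pi + 0.5`. The scaling constant `c` (ms/Hz)
#' defaults to 0.02 so that a slope of +/-50 Hz/ms maps to 0.75/0.25.
#'
#' @param t_ms frame times (ms).
#' @param ff_hz FF values (Hz); at least 2 finite points required.
#' @param slope_scale arctangent scaling constant `c`.
#' @return frequency change in \[0,1\], or `NA` with fewer than 2 valid points.
#' @export
frequency_change <- function(t_ms, ff_hz, slope_scale = 0.02) {
  ok <- is.finite(t_ms) & is.finite(ff_hz)
  if (sum(ok) < 2) return(NA_real_)
  t <- t_ms[ok]; f <- ff_hz[ok]
  tc <- t - mean(t)
  if (all(tc == 0)) return(NA_real_)
  slope <- sum(tc * (f - mean(f))) / sum(tc * tc)   # least-squares slope
  atan(slope_scale * slope) / pi + 0.5
}

#' Frequency-change contour over an FF track
#'
#' Applies [frequency_change()] in a centered rolling window.
#'
#' @param t_ms,ff_hz FF track.
#' @param window_frames window length in frames (default 5, i.e. 2.5 ms at a
#'   0.5 ms step).
#' @param slope_scale see [frequency_change()].
#' @return numeric vector of fc values, one per frame.
#' @export
frequency_change_contour <- function(t_ms, ff_hz, window_frames = 5,
                                     slope_scale = 0.02) {
  n <- length(t_ms)
  half <- window_frames %/% 2
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    frequency_change(t_ms[idx], ff_hz[idx], slope_scale)
  }, numeric(1))
}

#' Fundamental frequency estimation by harmonic-comb scoring
#'
#' For each frame, candidate fundamentals on a geometric grid are scored by
#' the fraction of spectral intensity falling within their harmonic windows
#' (+/- FF/4 around each integer multiple), with a small bonus increasing in
#' candidate frequency to resolve the subharmonic ambiguity (any subharmonic
#' of the true FF captures the same energy). Frame-to-frame continuity is
#' enforced by a Viterbi pass penalizing octave-scale jumps. This replaces
#' interactive, per-element tuning of FF tracking with an automatic
#' continuity penalty, so estimates from other trackers will differ in
#' detail.
#'
#' @param frames output of [spectrogram_frames()] (or a compatible list).
#' @param fmin_hz,fmax_hz candidate FF range (defaults 400-8000 Hz).
#' @param n_candidates grid resolution.
#' @param jump_penalty Viterbi cost per octave of inter-frame FF jump.
#' @param voicing_threshold minimum comb score for a frame to count as voiced.
#' @return data.frame with `t_ms`, `ff_hz` (NA where unvoiced), and
#'   `confidence` (the comb score).
#' @export
estimate_ff <- function(frames, fmin_hz = 400, fmax_hz = 8000,
                        n_candidates = 240, jump_penalty = 1,
                        voicing_threshold = 0.25) {
  freqs <- frames$freqs_hz
  S <- frames$intens
  nt <- ncol(S)
  cand <- exp(seq(log(fmin_hz), log(fmax_hz), length.out = n_candidates))
  nyq <- max(freqs)
  score <- matrix(0, n_candidates, nt)
  voiced <- colSums(S) > 0
  for (j in which(voiced)) {
    score[, j] <- vapply(cand, function(f0)
      harmonicity(freqs, S[, j], f0, nyquist_hz = nyq), numeric(1))
  }
  # small monotone-in-frequency bonus breaks exact subharmonic ties
  bonus <- 0.02 * log2(cand / fmin_hz) / log2(fmax_hz / fmin_hz)
  emit <- score + bonus
  # Viterbi over the candidate grid
  best <- rep(NA_integer_, nt)
  use <- which(voiced & apply(score, 2, max) >= voicing_threshold)
  if (length(use) > 0) {
    lcand <- log2(cand)
    prev <- emit[, use[1]]
    back <- matrix(NA_integer_, n_candidates, length(use))
    if (length(use) > 1) {
      for (jj in 2:length(use)) {
        tot <- outer(prev, rep(1, n_candidates)) -
          jump_penalty * abs(outer(lcand, lcand, "-"))
        arg <- max.col(t(tot))
        back[, jj] <- arg
        prev <- tot[cbind(arg, seq_len(n_candidates))] + emit[, use[jj]]
      }
    }
    k <- which.max(prev)
    for (jj in rev(seq_along(use))) {
      best[use[jj]] <- k
      if (jj > 1) k <- back[k, jj]
    }
  }
  conf <- rep(0, nt)
  conf[!is.na(best)] <- score[cbind(best[!is.na(best)], which(!is.na(best)))]
  data.frame(t_ms = frames$times_ms,
             ff_hz = ifelse(is.na(best), NA_real_, cand[best]),
             confidence = conf)
}

#' Full feature contours for a spectrogram
#'
#' Convenience wrapper: estimates FF, then computes mean frequency,
#' frequency change, and harmonicity per frame, returning a contour
#' data.frame in the [songio] frame format.
#'
#' @param frames output of [spectrogram_frames()].
#' @param ... passed to [estimate_ff()].
#' @return data.frame with `t_ms`, `ff_hz`, `mf_hz`, `fc`, `harm` (NA where
#'   unvoiced).
#' @export
feature_contours <- function(frames, ...) {
  ff <- estimate_ff(frames, ...)
  nt <- ncol(frames$intens)
  mf <- vapply(seq_len(nt), function(j)
    mean_frequency(frames$freqs_hz, frames$intens[, j]), numeric(1))
  harm <- vapply(seq_len(nt), function(j) {
    if (is.na(ff$ff_hz[j])) return(NA_real_)
    harmonicity(frames$freqs_hz, frames$intens[, j], ff$ff_hz[j])
  }, numeric(1))
  fc <- frequency_change_contour(ff$t_ms, ff$ff_hz)
  data.frame(t_ms = ff$t_ms, ff_hz = ff$ff_hz, mf_hz = mf, fc = fc,
             harm = harm)
}
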