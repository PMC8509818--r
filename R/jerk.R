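#' Jerk of the stylus trajectory
#'
#' Jerk is the third time derivative of position, the standard smoothness
#' quantity in movement analysis. It is computed as the per-axis third finite
#' difference of (x, y) divided by dt^3 (dt = 1/sampling_rate), combined as
#' the per-frame Euclidean norm, so the result is a non-negative magnitude in
#' cm/s^3 of length n - 3.
#'
#' @param rec a \code{drawing_recording} with at least 4 samples.
#' @return object of class \code{jerk_series}: list with \code{values},
#'   \code{units}, \code{sampling_rate}.
#' @export
jerk_trajectory <- function(rec) {
  s <- rec$samples
  if (nrow(s) < 4L) stop("recording too short for jerk (need >= 4 samples)")
  dt3 <- (1 / rec$sampling_rate)^3
  jx <- diff(s$x, differences = 3L) / dt3
  jy <- diff(s$y, differences = 3L) / dt3
  structure(list(values = sqrt(jx^2 + jy^2), units = "cm/s^3",
                 sampling_rate = rec$sampling_rate),
            class = "jerk_series")
}

#' Jerk of the pen pressure
#'
#' Third finite difference of the pressure channel divided by dt^3; signed
#' values are retained (pressure is scalar, so no norm is taken).
#'
#' @inheritParams jerk_trajectory
#' @return a \code{jerk_series} in pressure-units/s^3, length n - 3.
#' @export
jerk_pressure <- function(rec) {
  s <- rec$samples
  if (nrow(s) < 4L) stop("recording too short for jerk (need >= 4 samples)")
  dt3 <- (1 / rec$sampling_rate)^3
  structure(list(values = diff(s$pressure, differences = 3L) / dt3,
                 units = "pressure-units/s^3",
                 sampling_rate = rec$sampling_rate),
            class = "jerk_series")
}

#' @export
print.jerk_series <- function(x, ...) {
  cat(sprintf("<jerk_series> %d frames @ %g Hz (%s)\n",
              length(x$values), x$sampling_rate, x$units))
  invisible(x)
}

#' Extract the fixed analysis window from a jerk series
#'
#' The first \code{window_frames} values (512 by default, i.e. 512/120 ~
#' 4.27 s) are used for featurization regardless of total drawing time, so
#' classification is independent of drawing duration. No padding is done:
#' shorter series are an error, since compliant drawings last over 5 s
#' (>= 600 frames).
#'
#' @param series a \code{jerk_series}.
#' @param config a \code{feature_config}.
#' @return a \code{jerk_series} of length \code{config$window_frames}.
#' @export
extract_window <- function(series, config = feature_config()) {
  n <- length(series$values)
  if (n < config$window_frames)
    stop(sprintf("recording shorter than analysis window (%d < %d frames)",
                 n, config$window_frames))
  series$values <- series$values[seq_len(config$window_frames)]
  series
}

# periodic (DFT-even) Hanning window of length n
hanning_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Chunked Hanning/FFT spectral features of a jerk window
#'
#' The analysis window is split into \code{n_chunks} consecutive
#' non-overlapping chunks of \code{chunk_frames} frames. Each chunk is
#' multiplied by a periodic Hanning window and discrete-Fourier-transformed;
#' the magnitude spectrum is taken and the components from the first harmonic
#' up to \code{max_retained_freq} are retained (DC is dropped). Under the
#' defaults (32-frame chunks at 120 Hz) the retained bins sit at 3.75, 7.5,
#' ..., 60 Hz -- 16 bins -- giving a 16 x 16 = 256-dimensional feature when
#' flattened chunk-major.
#'
#' @param window a \code{jerk_series} of exactly \code{window_frames} values
#'   (see \code{\link{extract_window}}).
#' @param config a \code{feature_config}.
#' @return object of class \code{spectral_features}: list with
#'   \code{matrix} (n_chunks x n_retained_bins), \code{bin_freqs} (Hz) and
#'   \code{flattened} (chunk-major vector).
#' @export
chunk_spectrum <- function(window, config = feature_config()) {
  v <- window$values
  if (length(v) != config$window_frames)
    stop(sprintf("window length %d != window_frames %d",
                 length(v), config$window_frames))
  m <- config$chunk_frames
  freqs <- (seq_len(m) - 1L) * config$sampling_rate / m
  keep <- which(freqs > 0 & freqs <= config$max_retained_freq)
  w <- hanning_window(m)
  chunks <- matrix(v, nrow = m, ncol = config$n_chunks)   # column = chunk
  mags <- apply(chunks, 2L, function(ch) Mod(stats::fft(ch * w))[keep])
  feat <- t(mags)                                          # row = chunk
  structure(list(matrix = feat, bin_freqs = freqs[keep],
                 flattened = as.vector(t(feat))),
            class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf("<spectral_features> %d chunks x %d bins (%.4g-%.4g Hz), %d-dim flattened\n",
              nrow(x$matrix), ncol(x$matrix), min(x$bin_freqs),
              max(x$bin_freqs), length(x$flattened)))
  invisible(x)
}

#' Extract the full per-subject feature bundle
#'
#' Assembles the four training-data sets from one recording: the pressure-jerk
#' spectrogram (set 1), the trajectory-jerk spectrogram (set 2), the spiral
#' tracing RMSE (set 3) and the maximum pen pressure (set 4).
#'
#' @param rec a \code{drawing_recording}.
#' @param guide a \code{guide_spiral} (the template the subject traced).
#' @param config a \code{feature_config}.
#' @return a \code{feature_bundle}.
#' @export
extract_bundle <- function(rec, guide = guide_spiral(),
                           config = feature_config()) {
  if (!inherits(rec, "drawing_recording"))
    stop("rec must be a drawing_recording")
  with_set <- function(i, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("feature set %d failed for subject %s: %s",
                   i, rec$subject_id, conditionMessage(e)), call. = FALSE))
  }
  sp <- with_set(1L, chunk_spectrum(extract_window(jerk_pressure(rec), config),
                                    config)$flattened)
  st <- with_set(2L, chunk_spectrum(extract_window(jerk_trajectory(rec), config),
                                    config)$flattened)
  rmse <- with_set(3L, spiral_rmse(to_polar(rec$samples, guide$center), guide))
  mp <- with_set(4L, max_pressure(rec))
  feature_bundle(rec$subject_id, sp, st, rmse, mp, rec$label)
}
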