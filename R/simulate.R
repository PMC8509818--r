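#' Group-level simulation parameters
#'
#' Describes how one diagnostic group draws the spiral. A simulated subject
#' advances along the guide with smoothly varying angular speed over a drawn
#' duration, with three radial disturbance sources: a slow random-walk shape
#' bias (inaccurate tracing), band-limited physiological tremor (default
#' 4-12 Hz, inside the 3.75-60 Hz feature band), and an initial start-position
#' offset that decays within ~0.25 s, i.e. entirely inside the excluded first
#' turn. Pen pressure follows a smooth rise-plateau-fall envelope whose peak
#' is drawn per subject, plus band-limited jitter, clipped to the device range.
#'
#' @param tremor_amplitude SD of the band-limited radial tremor (cm).
#' @param tremor_band tremor pass-band in Hz (length 2).
#' @param radial_bias_sd SD of the slow radial shape error (cm).
#' @param pressure_peak_mean,pressure_peak_sd per-subject peak pressure draw
#'   (device units), clipped to \code{[0, PRESSURE_MAX]}.
#' @param pressure_jitter_sd SD of band-limited pressure jitter (device units).
#' @param speed_modulation relative SD of the smooth angular-speed variation.
#' @param start_offset_sd per-axis SD of the initial position offset (cm).
#' @param duration_mean,duration_sd drawing duration draw (s), truncated so
#'   every drawing lasts longer than 5 s.
#' @return an object of class \code{group_params}.
#' @export
group_params <- function(tremor_amplitude = 0.02, tremor_band = c(4, 12),
                         radial_bias_sd = 0.05,
                         pressure_peak_mean = 3.2, pressure_peak_sd = 0.3,
                         pressure_jitter_sd = 0.01,
                         speed_modulation = 0.1, start_offset_sd = 0.1,
                         duration_mean = 8, duration_sd = 1.5) {
  p <- list(tremor_amplitude = tremor_amplitude, tremor_band = tremor_band,
            radial_bias_sd = radial_bias_sd,
            pressure_peak_mean = pressure_peak_mean,
            pressure_peak_sd = pressure_peak_sd,
            pressure_jitter_sd = pressure_jitter_sd,
            speed_modulation = speed_modulation,
            start_offset_sd = start_offset_sd,
            duration_mean = duration_mean, duration_sd = duration_sd)
  sds <- c(p$tremor_amplitude, p$radial_bias_sd, p$pressure_peak_sd,
           p$pressure_jitter_sd, p$speed_modulation, p$start_offset_sd,
           p$duration_sd)
  if (any(sds < 0)) stop("all SD parameters must be >= 0")
  if (length(tremor_band) != 2L || tremor_band[1] <= 0 ||
      tremor_band[2] <= tremor_band[1])
    stop("tremor_band must be an increasing positive Hz interval")
  structure(p, class = "group_params")
}

#' Default non-CTS (healthy control) simulation parameters
#' @return a \code{group_params}.
#' @export
non_cts_params <- function() group_params()

#' Default CTS-like simulation parameters
#'
#' Relative to controls: stronger 4-12 Hz tremor, larger slow shape error
#' (higher spiral RMSE), lower and more variable peak pen pressure, larger
#' start offset and slower, more variable drawing.
#' @return a \code{group_params}.
#' @export
cts_params <- function() {
  group_params(tremor_amplitude = 0.06, radial_bias_sd = 0.12,
               pressure_peak_mean = 2.4, pressure_peak_sd = 0.4,
               pressure_jitter_sd = 0.03, start_offset_sd = 0.2,
               duration_mean = 9, duration_sd = 2)
}

#' Cohort specification
#'
#' @param n_non_cts,n_cts group sizes (defaults 31 and 33).
#' @param non_cts_params,cts_params per-group \code{group_params}.
#' @param seed integer master seed; per-subject seeds are derived from it and
#'   the subject index, so identical specs give byte-identical cohorts.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_non_cts = 31L, n_cts = 33L,
                        non_cts_params = spiralscreen::non_cts_params(),
                        cts_params = spiralscreen::cts_params(),
                        seed = 1L) {
  stopifnot(n_non_cts >= 0L, n_cts >= 0L)
  structure(list(n_non_cts = as.integer(n_non_cts), n_cts = as.integer(n_cts),
                 non_cts_params = non_cts_params, cts_params = cts_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# run code under a local RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic per-subject seed from (master seed, subject index);
# Lehmer-style mixing, kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
              as.numeric(index) * 16807) %% 2147483647)
}

# band-limited gaussian noise with exactly the requested SD
bandlimited_noise <- function(n, band, fs, sd_target) {
  if (sd_target == 0) return(numeric(n))
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  raw <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
  s <- stats::sd(raw)
  if (s == 0) return(numeric(n))
  raw / s * sd_target
}

# C1 rise-plateau-fall envelope on [0, 1] (smoothstep shoulders)
plateau_envelope <- function(u, shoulder = 0.15) {
  ss <- function(z) 3 * z^2 - 2 * z^3
  out <- rep(1, length(u))
  lo <- u < shoulder; hi <- u > 1 - shoulder
  out[lo] <- ss(u[lo] / shoulder)
  out[hi] <- ss((1 - u[hi]) / shoulder)
  out
}

#' Simulate one spiral-drawing recording
#'
#' Generates a single continuous stroke tracing the guide spiral at 120 Hz
#' under the disturbance model of \code{\link{group_params}}. Radial
#' disturbances are ramped in over the first half turn so the trace cannot
#' cross the spiral centre; the ramped region lies entirely inside the
#' first-turn exclusion zone of \code{\link{spiral_rmse}}. With all noise
#' parameters at zero the result reproduces the guide exactly (RMSE 0) with
#' maximum pressure equal to \code{pressure_peak_mean}.
#'
#' @param params a \code{group_params}.
#' @param guide a \code{guide_spiral}.
#' @param seed integer seed; identical seeds give identical recordings.
#' @param subject_id,label recording metadata.
#' @return a validated \code{drawing_recording} of duration > 5 s.
#' @export
simulate_recording <- function(params, guide = guide_spiral(), seed = 1L,
                               subject_id = "sim", label = "unknown") {
  fs <- 120
  with_seed(seed, {
    repeat {
      dur <- stats::rnorm(1, params$duration_mean, params$duration_sd)
      if (dur > 5.05) break
    }
    n <- as.integer(ceiling(dur * fs))
    t <- (0:(n - 1)) / fs

    # smooth angular-speed modulation: a few low-frequency sinusoids
    f <- stats::runif(3, 0.05, 0.4)
    ph <- stats::runif(3, 0, 2 * pi)
    a <- abs(stats::rnorm(3))
    mod <- drop(sin(outer(t, 2 * pi * f) + rep(ph, each = n)) %*% a)
    if (stats::sd(mod) > 0) mod <- mod / stats::sd(mod)
    omega <- pmax(1 + params$speed_modulation * mod, 0.1)
    theta <- guide$theta_end * (cumsum(omega) - omega[1]) /
      (sum(omega) - omega[1])

    bias <- stats::rnorm(n)
    bias <- cumsum(bias)
    if (params$radial_bias_sd > 0 && stats::sd(bias) > 0) {
      bias <- (bias - mean(bias)) / stats::sd(bias) * params$radial_bias_sd
    } else bias <- numeric(n)
    tremor <- bandlimited_noise(n, params$tremor_band, fs,
                                params$tremor_amplitude)
    ramp <- pmin(theta / pi, 1)
    r <- pmax(guide$scale * theta + ramp * (bias + tremor), 0)

    off <- stats::rnorm(2) * params$start_offset_sd
    decay <- exp(-t / 0.08)
    x <- guide$center[1] - r * cos(theta) + off[1] * decay
    y <- guide$center[2] - r * sin(theta) + off[2] * decay

    peak <- min(max(stats::rnorm(1, params$pressure_peak_mean,
                                 params$pressure_peak_sd), 0), PRESSURE_MAX)
    env <- plateau_envelope(t / (n / fs))
    jitter <- bandlimited_noise(n, params$tremor_band, fs,
                                params$pressure_jitter_sd)
    pressure <- pmin(pmax(peak * env + env * jitter, 0), PRESSURE_MAX)

    drawing_recording(
      data.frame(frame = 0:(n - 1), x = x, y = y, pressure = pressure),
      subject_id = subject_id, label = label, sampling_rate = fs)
  })
}

#' Simulate a labelled two-group cohort
#'
#' Generates \code{n_non_cts + n_cts} recordings with per-subject seeds
#' derived deterministically from the master seed and the subject index
#' (stable under reordering). Under the default group parameters the CTS
#' group has higher median spiral RMSE, lower median maximum pen pressure,
#' and more band-limited tremor energy in its jerk spectra.
#'
#' @param spec a \code{cohort_spec}.
#' @param guide a \code{guide_spiral}.
#' @return list of \code{drawing_recording} (non-CTS subjects first).
#' @export
simulate_cohort <- function(spec = cohort_spec(), guide = guide_spiral()) {
  recs <- vector("list", spec$n_non_cts + spec$n_cts)
  idx <- 0L
  for (i in seq_len(spec$n_non_cts)) {
    idx <- idx + 1L
    recs[[idx]] <- simulate_recording(
      spec$non_cts_params, guide, derive_seed(spec$seed, idx),
      subject_id = sprintf("nonCTS_%03d", i), label = "non-CTS")
  }
  for (i in seq_len(spec$n_cts)) {
    idx <- idx + 1L
    recs[[idx]] <- simulate_recording(
      spec$cts_params, guide, derive_seed(spec$seed, idx),
      subject_id = sprintf("CTS_%03d", i), label = "CTS")
  }
  recs
}
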