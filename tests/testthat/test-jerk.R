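test_that("third differencing annihilates low-order polynomials", {
  still <- make_recording(100, fx = function(t) 0 * t + 2,
                          fy = function(t) 0 * t - 1)
  expect_equal(jerk_trajectory(still)$values, rep(0, 97))

  quad <- make_recording(100, fx = function(t) t^2)
  expect_equal(jerk_trajectory(quad)$values, rep(0, 97), tolerance = 1e-8)

  expect_equal(jerk_pressure(make_recording(100))$values, rep(0, 97))
})

test_that("jerk of t^3 recovers the analytic third derivative 6", {
  cub <- make_recording(200, fx = function(t) t^3)
  j <- jerk_trajectory(cub)
  expect_equal(length(j$values), 197)
  expect_true(all(abs(j$values - 6) < 1e-6))

  cubp <- make_recording(200, fp = function(t) pmin(t^3, 4.166667))
  jp <- jerk_pressure(cubp)
  # restrict to frames before the pressure clip engages
  expect_true(all(abs(jp$values[1:100] - 6) < 1e-6))
})

test_that("pressure jerk of an alternating signal matches the difference-table oracle", {
  n <- 40
  alt <- (-1)^(0:(n - 1)) * 0.5 + 1  # alternating 1.5 / 0.5
  rec <- make_recording(n, fp = function(t) alt)
  j <- jerk_pressure(rec)
  # hand derivation: for a_i = c*(-1)^i, delta^3 a_i = -8c*(-1)^i
  dt3 <- (1 / 120)^3
  oracle <- -8 * 0.5 * (-1)^(0:(n - 4)) / dt3
  expect_equal(j$values, oracle)
  expect_error(jerk_pressure(make_recording(3)), "too short")
})

test_that("window extraction takes exactly the first 512 frames", {
  rec <- make_recording(703, fx = function(t) sin(t))
  j <- jerk_trajectory(rec)        # length 700
  w <- extract_window(j)
  expect_equal(length(w$values), 512)
  expect_identical(w$values, j$values[1:512])

  exact <- j; exact$values <- j$values[1:512]
  expect_identical(extract_window(exact)$values, exact$values)
  short <- j; short$values <- j$values[1:511]
  expect_error(extract_window(short), "shorter than analysis window")
})

test_that("chunked spectra have the documented shape and frequency support", {
  set.seed(2)
  w <- structure(list(values = rnorm(512), units = "u", sampling_rate = 120),
                 class = "jerk_series")
  sf <- chunk_spectrum(w)
  expect_equal(length(sf$flattened), 256)
  expect_equal(dim(sf$matrix), c(16, 16))
  expect_true(all(sf$bin_freqs <= 60))
  expect_true(all(sf$bin_freqs > 0))
  expect_equal(sf$bin_freqs, seq(3.75, 60, by = 3.75))
  expect_true(all(sf$flattened >= 0))
  # flattening is chunk-major: first 16 values are chunk 1's bins
  expect_equal(sf$flattened[1:16], unname(sf$matrix[1, ]))

  # zero in, zero out
  w0 <- w; w0$values <- rep(0, 512)
  expect_equal(chunk_spectrum(w0)$flattened, rep(0, 256))

  # non-default geometry: 8 chunks x 16 frames -> 8 retained bins (7.5..60 Hz)
  cfg <- feature_config(window_frames = 128L, n_chunks = 8L,
                        chunk_frames = 16L)
  w8 <- w; w8$values <- w$values[1:128]
  sf8 <- chunk_spectrum(w8, cfg)
  expect_equal(dim(sf8$matrix), c(8, 8))
  expect_equal(length(sf8$flattened), 64)
  expect_error(chunk_spectrum(w8), "window length")
})

test_that("a 7.5 Hz sinusoid lands in bin 2 and magnitudes match a naive DFT", {
  t <- (0:511) / 120
  w <- structure(list(values = sin(2 * pi * 7.5 * t), units = "u",
                      sampling_rate = 120), class = "jerk_series")
  sf <- chunk_spectrum(w)
  for (ch in 1:16) expect_equal(which.max(sf$matrix[ch, ]), 2)

  hann <- 0.5 * (1 - cos(2 * pi * (0:31) / 32))
  for (ch in c(1, 7, 16)) {
    seg <- w$values[((ch - 1) * 32 + 1):(ch * 32)] * hann
    expect_equal(unname(sf$matrix[ch, ]), naive_dft_mag(seg)[2:17],
                 tolerance = 1e-9)
  }
})

test_that("spectral magnitudes are homogeneous in the input scale", {
  set.seed(4)
  v <- rnorm(512)
  mk <- function(values) structure(list(values = values, units = "u",
                                        sampling_rate = 120),
                                   class = "jerk_series")
  base <- chunk_spectrum(mk(v))$flattened
  expect_equal(chunk_spectrum(mk(-2.5 * v))$flattened, 2.5 * base,
               tolerance = 1e-12)
})

test_that("extract_bundle composes the four component operations", {
  g <- guide_spiral()
  rec <- simulate_recording(non_cts_params(), g, seed = 33,
                            subject_id = "S1", label = "non-CTS")
  b <- extract_bundle(rec, g)
  expect_s3_class(b, "feature_bundle")
  expect_equal(length(b$spectral_pressure), 256)
  expect_equal(length(b$spectral_trajectory), 256)

  cfg <- feature_config()
  expect_equal(b$spectral_pressure,
               chunk_spectrum(extract_window(jerk_pressure(rec), cfg),
                              cfg)$flattened)
  expect_equal(b$spectral_trajectory,
               chunk_spectrum(extract_window(jerk_trajectory(rec), cfg),
                              cfg)$flattened)
  expect_equal(b$rmse, spiral_rmse(to_polar(rec$samples, g$center), g))
  expect_equal(b$max_pressure, max_pressure(rec))

  # determinism and error labelling
  expect_identical(extract_bundle(rec, g), b)
  short <- rec; short$samples <- rec$samples[1:400, ]
  expect_error(extract_bundle(short, g), "feature set 1")
})
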