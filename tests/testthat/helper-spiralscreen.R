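# shared fixtures and independent oracles

# recording built from analytic channel functions of time (s)
make_recording <- function(n, fx = function(t) t, fy = function(t) 0 * t,
                           fp = function(t) 0 * t + 1, fs = 120,
                           subject_id = "test", label = "unknown") {
  t <- (0:(n - 1)) / fs
  drawing_recording(
    data.frame(frame = 0:(n - 1), x = fx(t), y = fy(t),
               pressure = fp(t)),
    subject_id = subject_id, label = label, sampling_rate = fs)
}

# naive O(N^2) DFT magnitude — independent of stats::fft
naive_dft_mag <- function(v) {
  n <- length(v)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    Mod(sum(v * exp(-2i * pi * kk * (0:(n - 1)) / n))), numeric(1))
}

# pairwise-concordance AUC (ties counted 1/2) — independent of the
# trapezoid integration in roc_analysis
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == "CTS"]
  neg <- scores[labels == "non-CTS"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# polar trace constructed directly (bypasses to_polar)
polar_trace <- function(theta, r) {
  structure(list(theta = theta, r = r), class = "polar_trace")
}

# small feature bundle with arbitrary spectral dimension
make_bundle <- function(id, label, k = 4, seed = 1) {
  set.seed(seed)
  feature_bundle(id, abs(rnorm(k)), abs(rnorm(k)),
                 rmse = abs(rnorm(1, 0.1, 0.02)),
                 max_pressure = runif(1, 1, 4), label = label)
}

# well-separated 1-D two-class data for classifier tests
separable_data <- function(n_per = 10, gap = 1, jitter = 0.01, seed = 42) {
  set.seed(seed)
  x <- matrix(c(-gap + rnorm(n_per, sd = jitter),
                gap + rnorm(n_per, sd = jitter)), ncol = 1)
  labels <- rep(c("non-CTS", "CTS"), each = n_per)
  list(x = x, labels = labels)
}
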