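# Independent brute-force oracles used to validate the feature integrators
# and correlators. These deliberately avoid the package's production code
# paths (pracma::trapz, stats::convolve).

# trapezoid rule on the unit index grid
trapz_oracle <- function(y) {
  n <- length(y)
  sum((y[-n] + y[-1]) / 2)
}

# Feature 1 oracle: area between the rising edge and the trough-to-peak chord
f1_oracle <- function(w) {
  kp <- which.max(w)
  chord <- w[1] + (w[kp] - w[1]) * (seq_len(kp) - 1) / (kp - 1)
  trapz_oracle(abs(w[seq_len(kp)] - chord))
}

# Feature 2 oracle: signed area about the one-third-peak baseline
f2_oracle <- function(w) {
  base <- max(w) / 3
  trapz_oracle(pmax(w - base, 0)) - trapz_oracle(pmax(base - w, 0))
}

# full linear cross-correlation r[l] = sum_k t[k] * s[k - l], brute force
# over every lag (0-based indices, lags -(N-1)..(N-1))
xcorr_oracle <- function(t, s) {
  N <- length(t)
  vapply(-(N - 1):(N - 1), function(l) {
    acc <- 0
    for (k in 0:(N - 1)) {
      j <- k - l
      if (j >= 0 && j <= N - 1) acc <- acc + t[k + 1] * s[j + 1]
    }
    acc
  }, numeric(1))
}

# same brute-force sum per lag, with the inner k-sum done as one vector
# product (still independent of stats::convolve); used where the fully
# scalar double loop would be needlessly slow
xcorr_oracle_vec <- function(t, s) {
  N <- length(t)
  vapply(-(N - 1):(N - 1), function(l) {
    k <- max(0, l):min(N - 1, N - 1 + l)
    sum(t[k + 1] * s[k - l + 1])
  }, numeric(1))
}

f3_oracle <- function(sample, template) {
  sum(abs(xcorr_oracle(template, sample) - xcorr_oracle(template, template)))
}

# random plausible normalized 200-point waveform (smooth, in [0, 1])
random_waveform <- function() {
  x <- stats::filter(rnorm(220), rep(1 / 21, 21), sides = 2)
  x <- x[!is.na(x)][1:200]
  (x - min(x)) / (max(x) - min(x))
}

# short noiseless bleed session reused across tests
quiet_session <- function(duration = 120, sbp0 = 120, dbp0 = 90,
                          sbp_end = 80, dbp_end = 50, noise_sd = 0,
                          drift_amp = 0, seed = 1L) {
  generate_bleed_session(
    bleed_scenario(duration = duration, sbp0 = sbp0, dbp0 = dbp0,
                   sbp_end = sbp_end, dbp_end = dbp_end, noise_sd = noise_sd,
                   drift_amp = drift_amp, seed = seed),
    pulse_shape()
  )
}

# two-Gaussian feature set with separability d-prime on f1 (f2/f3 are noise)
gaussian_features <- function(n_per_class, d_prime = 2, seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    f1 = c(rnorm(n_per_class, 0), rnorm(n_per_class, d_prime)),
    f2 = rnorm(2 * n_per_class),
    f3 = rnorm(2 * n_per_class),
    label = rep(0:1, each = n_per_class)
  )
}
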