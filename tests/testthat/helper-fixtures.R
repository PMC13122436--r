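# shared fixture builders -----------------------------------------------------

# a seeded uniform sample (null replicates for calibration checks)
with_seed_runif <- function(seed, n) {
  set.seed(seed)
  runif(n)
}

# noiseless configs used by round-trip tests
iso_clean <- function() isoscape_config(measurement_sd = 0)

# a small deterministic profile descending through both thresholds
toy_profile <- function() {
  chem_profile("toy",
               radius_um = c(100, 200, 300, 320, 400, 500, 600, 625, 700),
               sr8786 = c(0.7090, 0.7090, 0.7090, 0.7080, 0.7070,
                          0.7070, 0.7070, 0.70800, 0.70918),
               srv = c(1, 1, 1, 1, 1, 1.2, 2, 2.6, 3))
}

# brute-force first-crossing scan over all segments (independent of the
# package implementation): checks every consecutive pair plus exact hits
brute_crossing <- function(radius, values, threshold, direction,
                           start_radius = -Inf) {
  v <- if (direction == "downward") values - threshold else threshold - values
  best <- NA_real_
  for (i in seq_along(v)) {
    if (v[i] == 0 && radius[i] >= start_radius &&
        (i == 1 || v[i - 1] > 0)) {
      best <- radius[i]; break
    }
    if (i > 1 && v[i - 1] > 0 && v[i] < 0) {
      r <- radius[i - 1] + (radius[i] - radius[i - 1]) *
        v[i - 1] / (v[i - 1] - v[i])
      if (r >= start_radius) { best <- r; break }
    }
    if (i > 1 && v[i - 1] > 0 && v[i] == 0 && radius[i] >= start_radius) {
      best <- radius[i]; break
    }
  }
  best
}

# dip values for fixed small samples, frozen from an exact linear-programming
# formulation of "sup-norm distance to the nearest unimodal CDF" (solved per
# candidate modal gap with the convex/concave shape constraints and the
# modal-interval coupling), computed with an independent LP solver
dip_oracle_cases <- function() {
  list(
    list(x = c(0, 0.01, 10, 10.01),                d = 0.2497500000),
    list(x = c(1, 2, 3, 4),                        d = 0.1250000000),
    list(x = c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2),      d = 0.0833333333),
    list(x = c(1, 1.1, 1.3, 1.4, 9, 9.2, 9.3, 9.5), d = 0.2345679012),
    list(x = c(2, 2.2, 2.3, 2.5, 2.6, 7, 7.1, 7.4, 7.6, 7.9),
         d = 0.2075471698),
    list(x = c(0.05, 0.18, 0.21, 0.35, 0.47, 0.58, 0.66, 0.79, 0.93),
         d = 0.0728395062),
    list(x = c(5, 5.05, 5.1, 5.12, 5.2, 5.22, 5.3, 5.33, 5.4, 5.41, 5.5,
               5.52),                              d = 0.0681818182)
  )
}
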