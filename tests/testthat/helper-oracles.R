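# Independent brute-force oracles: the same statistics re-coded from the
# definitions, kept free of any package internals, used to cross-check the
# implementation on random inputs.

oracle_z <- function(p) stats::qnorm(1 - (1 - p) / 2)

oracle_prri <- function(mean, cv_pct, n, quantile) {
  half <- quantile * mean * (cv_pct / 100) * sqrt(1 + 1 / n)
  c(mean - half, mean + half)
}

oracle_rcv <- function(cv_pct, quantile) quantile * sqrt(2) * cv_pct

# Brute-force flag counter: loops point by point / pair by pair.
oracle_count_interval_flags <- function(values, lower, upper) {
  k <- 0L
  for (v in values) if (v < lower || v > upper) k <- k + 1L
  k
}

oracle_count_rcv_flags <- function(values, threshold) {
  k <- 0L
  for (i in 2:length(values)) {
    if (values[i - 1] <= 0) next
    if (100 * abs(values[i] - values[i - 1]) / values[i - 1] > threshold)
      k <- k + 1L
  }
  k
}

# Small two-measurand panel fixture used by flagging and IO tests.
make_mini_panel <- function() {
  list(
    series = list(
      a = result_series(c(0, 7, 14), c(4.0, 5.0, 6.5), "a"),
      b = result_series(c(0, 7, 14), c(1.2, 1.3, 1.1), "b")),
    profiles = list(
      a = bv_profile("a", "U", cv_i = 11.1, cv_g = 17.1, cv_a = 1.26,
                     pop_ri_lower = 3.5, pop_ri_upper = 9.5,
                     display_decimals = 1),
      b = bv_profile("b", "U", cv_i = 10.8, cv_g = 22.5, cv_a = 3.55,
                     pop_ri_lower = 1.1, pop_ri_upper = 3.2,
                     display_decimals = 1)),
    hsps = list(
      a = hsp_estimate(4.8, 0.5, 3, cv_t = 9.45),
      b = hsp_estimate(1.4, 0.1, 3, cv_t = 6.62)))
}
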