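# Independent Haar oracle: coefficients computed as explicit inner
# products with the Haar basis (closed form), not via the filter cascade
# the package uses. Detail level j, position k averages the first half of
# the 2^j-sample block against the second half; the deepest approximation
# is a scaled block sum.
oracle_haar <- function(x, levels) {
  n <- length(x)
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    blk <- 2^j
    nk <- n / blk
    details[[j]] <- vapply(seq_len(nk), function(k) {
      i0 <- (k - 1) * blk
      (sum(x[(i0 + 1):(i0 + blk / 2)]) - sum(x[(i0 + blk / 2 + 1):(i0 + blk)])) /
        sqrt(blk)
    }, numeric(1))
  }
  blk <- 2^levels
  approx <- vapply(seq_len(n / blk), function(k) {
    i0 <- (k - 1) * blk
    sum(x[(i0 + 1):(i0 + blk)]) / sqrt(blk)
  }, numeric(1))
  list(details = details, approx = approx)
}

oracle_dc1_pct <- function(x, levels = 5L) {
  o <- oracle_haar(x, levels)
  e_d <- vapply(o$details, function(d) sum(d^2), numeric(1))
  100 * e_d[1] / (sum(e_d) + sum(o$approx^2))
}

# convenience: noise-free magnitude series for a pure regime
synth_series <- function(duration_s = 32, episodes = list(), noise = 0,
                         seed = 1, ...) {
  cfg <- gait_sim_config(
    duration_s = duration_s, fog_episodes = episodes,
    noise_sd_ms2 = noise, seed = seed, ...
  )
  magnitude(simulate_gait(cfg)$record)
}
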