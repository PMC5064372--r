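# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# Pure-bisection solve for free E on [0, e_total] of the conservation
# function f(E) = E*(1 + I1/(KD1+E) + I2/(KD2+E)) - e_total, to a
# relative interval width of 1e-12 on E_free.
bisection_bound_fraction <- function(e_total, i1, i2, kd1, kd2) {
  f <- function(ef) ef * (1 + i1 / (kd1 + ef) + i2 / (kd2 + ef)) - e_total
  lo <- 0
  hi <- e_total
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  ef <- (lo + hi) / 2
  1 - ef / e_total
}

# Random valid competitive systems, log-uniform over 1 pM - 10 uM.
random_systems <- function(n, seed = 421L) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      v <- 10^stats::runif(5, log10(1e-12), log10(1e-5))
      binding_system(e_total = v[1], i1_total = v[2], i2_total = v[3],
                     kd1 = v[4], kd2 = v[5])
    })
  })
}

# Brute-force exhaustive permutation two-sided p-value for the
# Mann-Whitney U, by enumerating every assignment of the pooled values
# into a group of size n1 (midranks for ties).
permutation_p_oracle <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Noise-free binding curve drawn directly from the quadratic model,
# bypassing the generator.
model_curve <- function(a, t, kd, e_total, grid, sd = NA_real_,
                        curve_id = "model") {
  y <- t + a * fraction_bound_single(e_total, grid, kd)
  mstcompete:::new_binding_curve(
    data.frame(conc_M = grid, depletion_permille = y,
               sd_permille = rep(sd, length(grid)),
               n = rep(if (is.na(sd)) 1L else 3L, length(grid))),
    e_total = e_total, curve_id = curve_id)
}

serial_grid <- function(top = 1e-6, steps = 16L) sort(top / 2^(seq_len(steps) - 1L))
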