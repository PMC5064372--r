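test_that("expected depletion composes solver and linear signal map", {
  sig <- signal_model(d_free = 20, d_bound = 50)
  # no ligand: free-enzyme depletion
  s0 <- binding_system("0.5nM", 0, 0, kd1 = "500nM", kd2 = "0.2nM")
  expect_equal(expected_depletion(s0, sig), 20)
  # saturating competitor: bound-enzyme depletion
  s1 <- binding_system("0.5nM", 0, 1e6 * 0.2e-9, kd1 = "500nM", kd2 = "0.2nM")
  expect_equal(expected_depletion(s1, sig), 50, tolerance = 1e-5 * 30 / 50)
  # mid case against the bisection oracle composed with the linear map
  sm <- binding_system("0.5nM", "75nM", "1nM", kd1 = "500nM", kd2 = "0.2nM")
  x_or <- bisection_bound_fraction(0.5e-9, 75e-9, 1e-9, 500e-9, 0.2e-9)
  expect_equal(expected_depletion(sm, sig), 20 + 30 * x_or, tolerance = 1e-8)
})

test_that("signal model and design validation", {
  expect_error(signal_model(d_free = 50, d_bound = 20), "exceed")
  expect_error(signal_model(f0 = 0))
  expect_error(signal_model(noise_sd = -1))
  expect_error(assay_design("5nM", "50uM", dilution_steps = 1))
  d <- kd_assay_design(seed = 3)
  expect_equal(d$e_total, 5e-9)
  g <- dilution_grid(d)
  expect_equal(length(g), 17L)
  expect_equal(max(g) / min(g), 2^16)  # five orders of magnitude
  expect_equal(amplitude_assay_design()$e_total, 5e-10)
})

test_that("noise-free dataset reproduces expected depletion exactly", {
  des <- kd_assay_design(seed = 5)
  truth <- binding_system("5nM", kd1 = "500nM", kd2 = "0.2nM")
  sig0 <- signal_model(noise_sd = 0, offset_sd = 0)
  ds <- generate_binding_dataset(des, truth, sig0, vary = "i1")
  expected <- ds$truth$expected
  merged <- merge(ds$points, expected, by = "conc_M",
                  suffixes = c("", "_true"))
  expect_equal(merged$depletion_permille, merged$depletion_permille_true,
               tolerance = 1e-12)
})

test_that("seeding contract: equal seeds bit-identical, unequal differ", {
  des1 <- amplitude_assay_design(seed = 42)
  truth <- binding_system("500pM", i1_total = "75nM", kd1 = "500nM",
                          kd2 = "0.2nM")
  a <- generate_binding_dataset(des1, truth)
  b <- generate_binding_dataset(des1, truth)
  expect_identical(a$points, b$points)
  # regeneration from the embedded truth record is bit-identical
  c <- generate_binding_dataset(a$truth$design, a$truth$system,
                                a$truth$signal, vary = a$truth$vary)
  expect_identical(a$points, c$points)
  d <- generate_binding_dataset(amplitude_assay_design(seed = 43), truth)
  expect_false(identical(a$points, d$points))
})

test_that("per-experiment offsets are constant within an experiment", {
  des <- amplitude_assay_design(seed = 8)
  truth <- binding_system("500pM", i1_total = "75nM", kd1 = "500nM",
                          kd2 = "0.2nM")
  sig <- signal_model(noise_sd = 0, offset_sd = 3)
  ds <- generate_binding_dataset(des, truth, sig)
  merged <- merge(ds$points, ds$truth$expected, by = "conc_M",
                  suffixes = c("", "_true"))
  resid <- merged$depletion_permille - merged$depletion_permille_true
  by_exp <- tapply(resid, merged$experiment_id, function(v) diff(range(v)))
  expect_true(all(by_exp < 1e-9))
  expect_equal(sort(unique(round(resid, 9))),
               sort(round(ds$truth$offsets, 9)))
})

test_that("noiseless end-to-end amplitude pipeline recovers the truth", {
  des <- amplitude_assay_design(seed = 21)
  sig0 <- signal_model(noise_sd = 0, offset_sd = 0)
  run_pipe <- function(i1) {
    truth <- binding_system("500pM", i1_total = i1, kd1 = "500nM",
                            kd2 = "0.2nM")
    ds <- generate_binding_dataset(des, truth, sig0)
    curves <- align_baselines(dataset_curves(ds))
    x0 <- solve_competitive_equilibrium(
      binding_system(des$e_total, i1, 0, kd1 = truth$kd1, kd2 = truth$kd2))$x
    list(fits = lapply(curves, fit_amplitude),
         a_true = (sig0$d_bound - sig0$d_free) * (1 - x0),
         t_true = sig0$d_free + (sig0$d_bound - sig0$d_free) * x0)
  }

  # without competing inhibitor the titration is exactly the quadratic
  # law: the round trip is exact
  r0 <- run_pipe(0)
  for (f in r0$fits) {
    expect_equal(f$a, r0$a_true, tolerance = 1e-6)
    expect_equal(f$t, r0$t_true, tolerance = 1e-6)
    expect_equal(f$kd, 0.2e-9, tolerance = 1e-6)
  }

  # with the plasma inhibitor present, the single-site model is an
  # apparent-parameter description (exact only in the free-competitor
  # limit); recovery is still well within 0.1%
  r1 <- run_pipe(75e-9)
  for (f in r1$fits) {
    expect_equal(f$a, r1$a_true, tolerance = 1e-3)
    expect_equal(f$t, r1$t_true, tolerance = 1e-3)
  }
})

test_that("cohort generator: medians, dispersion-zero limit, seeding", {
  g0 <- generate_cohort(8, 18, median_high = 15, median_low = 30,
                        dispersion = 0, seed = 1)
  expect_equal(g0$high, rep(15, 8))
  expect_equal(g0$low, rep(30, 18))
  g1 <- generate_cohort(seed = 2)
  g2 <- generate_cohort(seed = 2)
  expect_identical(g1, g2)
  expect_error(generate_cohort(0, 5))
  expect_error(generate_cohort(median_high = -1))

  # large-sample medians approach the prescribed ones
  big <- generate_cohort(2000, 2000, median_high = 15, median_low = 30,
                         dispersion = 0.4, seed = 3)
  expect_equal(median(big$high), 15, tolerance = 0.05)
  expect_equal(median(big$low), 30, tolerance = 0.05)
})

test_that("null p-values are uniform; two-fold medians give real power", {
  # equal medians, large n (normal-approximation path): the p-value is
  # approximately U(0,1); Kolmogorov-Smirnov at alpha = 0.01 over 1000
  # simulations
  ps <- vapply(1:1000, function(s) {
    g <- generate_cohort(60, 60, median_high = 20, median_low = 20,
                         dispersion = 0.4, seed = s)
    compare_groups(g$high, g$low)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  # two-fold separated medians at the cohort sizes 8 vs 18: report the
  # empirical power at alpha = 0.001 (simulation summary, no fixed
  # expectation; it must at least beat the null rate)
  hits <- vapply(1:1000, function(s) {
    g <- generate_cohort(8, 18, median_high = 15, median_low = 30,
                         dispersion = 0.4, seed = 5000 + s)
    compare_groups(g$high, g$low)$p_value < 0.001
  }, logical(1))
  power <- mean(hits)
  message(sprintf("empirical power at alpha=0.001 (8 vs 18, 2-fold): %.3f",
                  power))
  expect_gt(power, 0.01)
})
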