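test_that("trivial and limiting cases of the competitive solver", {
  # no ligands: all enzyme free
  s <- binding_system("0.5nM", 0, 0, kd1 = "500nM", kd2 = "0.2nM")
  st <- solve_competitive_equilibrium(s)
  expect_equal(st$x, 0)
  expect_equal(st$e_free, s$e_total)

  # vast excess of tight competitor saturates the enzyme
  s <- binding_system("0.5nM", 0, 1e6 * 0.2e-9, kd1 = "500nM", kd2 = "0.2nM")
  expect_equal(solve_competitive_equilibrium(s)$x, 1, tolerance = 1e-5)

  # validation
  expect_error(binding_system("1nM", -1e-9, 0, kd1 = 1e-9, kd2 = 1e-9))
  expect_error(binding_system("1nM", 0, 0, kd1 = 0, kd2 = 1e-9))
  expect_error(binding_system(NaN, 0, 0, kd1 = 1e-9, kd2 = 1e-9))
  expect_error(solve_competitive_equilibrium(
    binding_system(0, 0, 0, kd1 = 1e-9, kd2 = 1e-9)))
})

test_that("solver matches the bisection oracle on the spec example", {
  s <- binding_system("1nM", "500nM", "5nM", kd1 = "500nM", kd2 = "0.1nM")
  x_oracle <- bisection_bound_fraction(1e-9, 500e-9, 5e-9, 500e-9, 0.1e-9)
  expect_equal(solve_competitive_equilibrium(s)$x, x_oracle,
               tolerance = 1e-8)
})

test_that("conservation, bracket and oracle equivalence on random systems", {
  systems <- random_systems(1000)
  for (s in systems) {
    st <- solve_competitive_equilibrium(s)
    # species conservation at 1e-9 relative
    expect_equal(st$e_free + st$ei1 + st$ei2, s$e_total,
                 tolerance = 1e-9)
    expect_equal(st$i1_free + st$ei1, s$i1_total, tolerance = 1e-9)
    expect_equal(st$i2_free + st$ei2, s$i2_total, tolerance = 1e-9)
    expect_true(st$e_free >= 0 && st$e_free <= s$e_total)
    expect_true(st$x >= 0 && st$x <= 1)
    expect_equal(st$x, (st$ei1 + st$ei2) / s$e_total, tolerance = 1e-12)
    # agreement with the independent bisection oracle
    x_oracle <- bisection_bound_fraction(s$e_total, s$i1_total, s$i2_total,
                                         s$kd1, s$kd2)
    expect_lt(abs(st$x - x_oracle), 1e-8)
  }
})

test_that("cubic smallest-root route agrees with the bracketed solver", {
  systems <- random_systems(200, seed = 77L)
  for (s in systems) {
    x_a <- solve_competitive_equilibrium(s)$x
    x_b <- solve_equilibrium_cubic(s)$x
    expect_lt(abs(x_a - x_b), 1e-8)
  }
})

test_that("quadratic single-site law: closed form, limits, clamping", {
  expect_equal(fraction_bound_single(1, 0, 1), 0)
  expect_equal(fraction_bound_single(2.5e-9, 0, 1e-9), 0)
  expect_equal(fraction_bound_single(1, 1, 1), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  # stoichiometric limit KD -> 0 with excess ligand
  expect_equal(fraction_bound_single(1e-9, 100e-9, 1e-9 * 1e-9), 1,
               tolerance = 1e-6)
  # never NaN, stays within [0, min(1, L/E)]
  l <- c(0, 1e-12, 1e-9, 1e-6, 1e-3)
  x <- fraction_bound_single(1e-9, l, 1e-9)
  expect_true(all(is.finite(x)))
  expect_true(all(x >= 0 & x <= pmin(1, l / 1e-9)))
})

test_that("I1 = 0 reduces the competitive solution to the quadratic form", {
  grid <- serial_grid(1e-6, 17L)
  tpl <- binding_system("0.5nM", 0, 0, kd1 = "500nM", kd2 = "0.2nM")
  curve <- simulate_binding_curve(tpl, grid)
  expect_equal(curve$bound_fractions,
               fraction_bound_single(0.5e-9, grid, 0.2e-9),
               tolerance = 1e-10)
})

test_that("simulated curves are monotone with valid bound fractions", {
  tpl <- binding_system("0.5nM", "75nM", 0, kd1 = "500nM", kd2 = "0.2nM")
  grid <- serial_grid(1e-6, 17L)
  curve <- simulate_binding_curve(tpl, grid)
  expect_true(all(diff(curve$bound_fractions) >= -1e-12))
  expect_true(all(curve$bound_fractions >= 0 & curve$bound_fractions <= 1))
  expect_error(simulate_binding_curve(tpl, numeric(0)))
  expect_error(simulate_binding_curve(tpl, c(2e-9, 1e-9)))
})

test_that("theoretical amplitude: windows, limits and monotonicity", {
  tpl <- binding_system("0.5nM", "75nM", 0, kd1 = "500nM", kd2 = "0.2nM")
  grid <- serial_grid(1e-6, 17L)
  curve <- simulate_binding_curve(tpl, grid)
  expect_error(theoretical_amplitude(curve, 1:10, 5:17))
  expect_error(theoretical_amplitude(curve, integer(0), 15:17))

  # flat curve: titrant far below KD2 and E everywhere
  flat <- simulate_binding_curve(tpl, serial_grid(1e-15, 8L))
  expect_lt(abs(theoretical_amplitude(flat)), 1e-3)

  # no competitor, grid spanning zero to saturation: amplitude -> 1
  tpl0 <- binding_system("0.5nM", 0, 0, kd1 = "500nM", kd2 = "0.2nM")
  wide <- simulate_binding_curve(tpl0, c(1e-15, serial_grid(1e-4, 25L)))
  expect_equal(theoretical_amplitude(wide, 1L, length(wide$concentrations)),
               1, tolerance = 1e-3)

  # weaker low-affinity inhibitor (larger KD1) -> larger amplitude;
  # the two pool affinities are a natural example
  amp_at <- function(kd1, i1 = 75e-9) {
    theoretical_amplitude(simulate_binding_curve(
      binding_system("0.5nM", i1, 0, kd1 = kd1, kd2 = "0.2nM"), grid))
  }
  expect_gt(amp_at(1300e-9), amp_at(500e-9))
  # doubling KD1 / doubling I1
  expect_gte(amp_at(1000e-9), amp_at(500e-9))
  expect_lte(amp_at(500e-9, i1 = 150e-9), amp_at(500e-9, i1 = 75e-9))

  # 10-point log sweeps
  kd_sweep <- 10^seq(log10(50e-9), log10(5e-6), length.out = 10)
  amps_kd <- vapply(kd_sweep, amp_at, numeric(1))
  expect_true(all(diff(amps_kd) >= -1e-12))
  i1_sweep <- 10^seq(log10(5e-9), log10(5e-6), length.out = 10)
  amps_i1 <- vapply(i1_sweep, function(i1) amp_at(500e-9, i1), numeric(1))
  expect_true(all(diff(amps_i1) <= 1e-12))
})

test_that("concentration parsing handles unit suffixes", {
  expect_equal(parse_conc("500pM"), 5e-10)
  expect_equal(parse_conc(c("5nM", "1.3uM", "2 mM")), c(5e-9, 1.3e-6, 2e-3))
  expect_equal(parse_conc(7.5e-9), 7.5e-9)
  expect_error(parse_conc("five nM"))
})
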