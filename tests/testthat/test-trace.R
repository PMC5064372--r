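make_trace <- function(values, dt = 0.1, ir_on = 5, ir_off = 30, ...) {
  times <- seq(0, by = dt, length.out = length(values))
  fluorescence_trace(times, values, ir_on = ir_on, ir_off = ir_off, ...)
}

test_that("trace constructor validates timing and sampling", {
  expect_error(make_trace(rep(1, 400), ir_on = 30, ir_off = 5))
  expect_error(make_trace(rep(1, 400), ir_on = 5, ir_off = 100))
  expect_error(make_trace(rep(1, 4), dt = 10))
  expect_error(fluorescence_trace(c(0, 1, 1, 2, 3, 4, 5, 6, 7, 8),
                                  rep(1, 10), 0.5, 8))
  expect_s3_class(make_trace(rep(1000, 351)), "fluorescence_trace")
})

test_that("background subtraction: identity, constants, round trip", {
  n <- 351
  sample <- make_trace(rep(800, n))
  expect_equal(subtract_background(sample, sample)$fluorescence, rep(0, n))

  bg <- make_trace(rep(50, n))
  out <- subtract_background(sample, bg)
  expect_equal(out$fluorescence, rep(750, n))
  expect_equal(out$capillary_id, sample$capillary_id)

  # adding then subtracting a plasma-like background is an exact round trip
  sig <- generate_trace(30, signal_model(), conc_M = 1e-9)
  plasma <- generate_background_trace(signal_model())
  observed <- sig
  observed$fluorescence <- sig$fluorescence + plasma$fluorescence
  rec <- subtract_background(observed, plasma)
  expect_equal(rec$fluorescence, sig$fluorescence, tolerance = 1e-12)

  # incompatible grids need explicit interpolation
  bg2 <- fluorescence_trace(seq(0, 35, by = 0.07),
                            rep(50, length(seq(0, 35, by = 0.07))), 5, 30)
  expect_error(subtract_background(sample, bg2))
  expect_equal(subtract_background(sample, bg2, interpolate = TRUE)$fluorescence,
               rep(750, n))
})

test_that("depletion definition, windows and gain invariance", {
  n <- 351
  f <- rep(1000, n)
  hot <- seq(0, 35, by = 0.1) > 5 & seq(0, 35, by = 0.1) <= 30
  f[hot] <- 990
  tr <- make_trace(f)
  expect_equal(compute_depletion(tr)$depletion_permille, 10)
  expect_equal(compute_depletion(make_trace(rep(1000, n)))$depletion_permille, 0)

  # gain invariance: multiplying the trace leaves depletion unchanged
  tr2 <- tr; tr2$fluorescence <- 3.7 * tr$fluorescence
  expect_equal(compute_depletion(tr2)$depletion_permille,
               compute_depletion(tr)$depletion_permille, tolerance = 1e-12)

  # windows must respect the laser phases
  expect_error(compute_depletion(tr, cold_window = c(4, 6)))
  expect_error(compute_depletion(tr, hot_window = c(29, 31)))
  neg <- make_trace(rep(-5, n))
  expect_error(compute_depletion(neg))
})

test_that("generator round trip recovers the prescribed depletion", {
  sig <- signal_model(trace_noise_sd = 0)
  for (d in c(0, 12.5, 30)) {
    tr <- generate_trace(d, sig)
    got <- compute_depletion(tr)$depletion_permille
    expect_lt(abs(got - d), 1e-3)
  }
  # noise-free zero-depletion trace is constant F0
  tr0 <- generate_trace(0, sig)
  expect_equal(tr0$fluorescence, rep(sig$f0, length(tr0$times)))
})

test_that("replicate aggregation computes mean, sample SD and n", {
  pts <- data.frame(conc_M = rep(c(1e-9, 2e-9), each = 3),
                    depletion_permille = c(10, 12, 14, 20, 20, 20),
                    replicate_id = rep(1:3, 2), capillary_id = "c")
  cv <- aggregate_replicates(pts, e_total = "500pM", curve_id = "t")
  expect_equal(cv$depletion_permille, c(12, 20))
  expect_equal(cv$sd_permille, c(2, 0))
  expect_equal(cv$n, c(3L, 3L))
  expect_equal(attr(cv, "e_total"), 5e-10)

  one <- aggregate_replicates(pts[1, ], e_total = 5e-10)
  expect_equal(one$depletion_permille, 10)
  expect_true(is.na(one$sd_permille))
  expect_equal(one$n, 1L)
})

test_that("baseline alignment shifts to a common plateau, shape preserved", {
  grid <- serial_grid(1e-6, 17L)
  base <- model_curve(30, 5, 0.2e-9, 0.5e-9, grid, sd = 1)
  shifted <- base
  shifted$depletion_permille <- base$depletion_permille + 5
  attr(shifted, "curve_id") <- "shifted"

  out <- align_baselines(list(base, shifted))
  expect_equal(out[[1]]$depletion_permille, out[[2]]$depletion_permille,
               tolerance = 1e-9)
  # pure translation: pairwise differences unchanged
  expect_equal(diff(out[[2]]$depletion_permille),
               diff(shifted$depletion_permille), tolerance = 1e-12)
  # recovered shifts are the negated offsets (up to the common reference)
  expect_equal(attr(out[[1]], "baseline_shift") -
                 attr(out[[2]], "baseline_shift"), 5, tolerance = 1e-9)

  # aligning a single curve to its own plateau is a zero shift
  self <- align_baselines(base, reference = mean(
    base$depletion_permille[base$conc_M >= max(base$conc_M) / 4]))
  expect_equal(attr(self[[1]], "baseline_shift"), 0, tolerance = 1e-12)

  # a still-rising curve has no plateau: warned and passed unshifted
  rising <- model_curve(30, 5, 5e-5, 0.5e-9, grid)
  expect_warning(out2 <- align_baselines(list(base, rising)))
  expect_false(attr(out2[[2]], "aligned"))
  expect_equal(out2[[2]]$depletion_permille, rising$depletion_permille)
})

test_that("alignment leaves the fitted amplitude unchanged", {
  grid <- serial_grid(1e-6, 16L)
  cv <- model_curve(28, 3, 0.2e-9, 0.5e-9, grid, sd = 1)
  f0 <- fit_amplitude(cv)
  f1 <- fit_amplitude(align_baselines(cv, reference = 100)[[1]])
  expect_equal(f1$a, f0$a, tolerance = 1e-9)
  expect_equal(f1$kd, f0$kd, tolerance = 1e-9)
})

test_that("trace and curve files round-trip bit exactly", {
  tr <- generate_trace(17.3, signal_model(), conc_M = 2.5e-9,
                       capillary_id = "e1_c01_r2", replicate_id = 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, p)
  back <- read_trace(p)
  expect_identical(back$times, tr$times)
  expect_identical(back$fluorescence, tr$fluorescence)
  expect_identical(back$conc_M, tr$conc_M)
  expect_identical(back$capillary_id, tr$capillary_id)

  cv <- model_curve(30, 5, 1e-9, 5e-10, serial_grid(1e-6, 8L), sd = 1.25)
  pc <- withr::local_tempfile(fileext = ".tsv")
  write_binding_curve(cv, pc)
  back <- read_binding_curve(pc)
  expect_identical(back$conc_M, cv$conc_M)
  expect_identical(back$depletion_permille, cv$depletion_permille)
  expect_identical(back$sd_permille, cv$sd_permille)
  expect_equal(attr(back, "e_total"), attr(cv, "e_total"))
})
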