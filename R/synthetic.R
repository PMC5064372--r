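#' Signal model linking bound fraction to thermophoretic depletion
#'
#' The measured depletion of a capillary is modelled as a linear mix of
#' the depletion of free and bound enzyme,
#' `D = D_free + (D_bound - D_free) * x`, with a single `d_bound` for
#' both complexes (depletion reads the proportion of bound enzyme, not
#' which inhibitor holds it). Bound enzyme must deplete more than free
#' enzyme (`d_bound > d_free`), which fixes the sign convention: the
#' amplitude of a competition curve is positive.
#'
#' Defaults place the assay in a realistic MST regime: 20 vs 50 permille
#' depletion, 1000 a.u. cold fluorescence, 1.5 s thermophoresis and
#' back-diffusion time constants, depletion noise of 5% of the dynamic
#' range and per-experiment baseline offsets of 10% of it (the offsets
#' the baseline alignment step removes).
#'
#' @param d_free,d_bound depletion (permille) of free and fully bound
#'   enzyme; `d_bound > d_free`.
#' @param f0 cold-phase fluorescence (a.u., > 0).
#' @param tau_on,tau_off thermophoresis equilibration and back-diffusion
#'   time constants (s, > 0).
#' @param noise_sd technical noise SD on depletion (permille).
#' @param offset_sd SD of the per-experiment baseline offset (permille).
#' @param trace_noise_sd additive noise SD on trace fluorescence (a.u.).
#' @param background_level fluorescence of the plasma background
#'   capillary (a.u.).
#' @return object of class `signal_model`.
#' @export
signal_model <- function(d_free = 20, d_bound = 50, f0 = 1000,
                         tau_on = 1.5, tau_off = 1.5,
                         noise_sd = 0.05 * (d_bound - d_free),
                         offset_sd = 0.10 * (d_bound - d_free),
                         trace_noise_sd = 0, background_level = 50) {
  if (!(d_bound > d_free)) stop("d_bound must exceed d_free")
  if (f0 <= 0) stop("f0 must be > 0")
  if (tau_on <= 0 || tau_off <= 0) stop("time constants must be > 0")
  if (noise_sd < 0 || offset_sd < 0 || trace_noise_sd < 0) {
    stop("noise SDs must be >= 0")
  }
  structure(list(d_free = d_free, d_bound = d_bound, f0 = f0,
                 tau_on = tau_on, tau_off = tau_off,
                 noise_sd = noise_sd, offset_sd = offset_sd,
                 trace_noise_sd = trace_noise_sd,
                 background_level = background_level),
            class = "signal_model")
}

#' Assay designs for the two competition-MST measurements
#'
#' `amplitude_assay_design()` reproduces the amplitude measurement:
#' 500 pM labeled enzyme in 7.5% plasma, titrant serially diluted 1:1
#' over five orders of magnitude (17 steps, a 2^16 range), three
#' technical replicates per point, three independent experiments,
#' 25/5 s IR on/off. `kd_assay_design()` reproduces the dissociation
#' constant measurement: 5 nM enzyme, the low-affinity inhibitor
#' titrated instead of the competitor, four independent measurements,
#' 20/5 s IR on/off.
#'
#' @param e_total total labeled enzyme (molar or unit string).
#' @param dilution_top top concentration of the 1:1 series.
#' @param dilution_steps number of points in the series (17 spans five
#'   orders of magnitude).
#' @param n_technical technical replicates per concentration.
#' @param n_experiments independent experiment-level replicates.
#' @param plasma_fraction final plasma fraction (0.075).
#' @param ir_on_s,ir_off_s IR laser on and off durations (s).
#' @param seed integer seed recorded in every generated artifact.
#' @return object of class `assay_design`.
#' @export
assay_design <- function(e_total, dilution_top, dilution_steps = 17L,
                         n_technical = 3L, n_experiments = 3L,
                         plasma_fraction = 0.075,
                         ir_on_s = 25, ir_off_s = 5, seed = 1L) {
  e <- parse_conc(e_total); top <- parse_conc(dilution_top)
  if (e <= 0 || top <= 0) stop("concentrations must be positive")
  if (dilution_steps < 2L) stop("need >= 2 dilution steps")
  if (n_technical < 1L || n_experiments < 1L) stop("replicate counts must be >= 1")
  structure(list(e_total = e, dilution_top = top,
                 dilution_steps = as.integer(dilution_steps),
                 n_technical = as.integer(n_technical),
                 n_experiments = as.integer(n_experiments),
                 plasma_fraction = plasma_fraction,
                 ir_on_s = ir_on_s, ir_off_s = ir_off_s,
                 seed = as.integer(seed)),
            class = "assay_design")
}

#' @rdname assay_design
#' @export
amplitude_assay_design <- function(seed = 1L, e_total = "500pM",
                                   dilution_top = "1uM") {
  assay_design(e_total, dilution_top, dilution_steps = 17L,
               n_technical = 3L, n_experiments = 3L,
               ir_on_s = 25, ir_off_s = 5, seed = seed)
}

#' @rdname assay_design
#' @export
kd_assay_design <- function(seed = 1L, e_total = "5nM",
                            dilution_top = "50uM") {
  assay_design(e_total, dilution_top, dilution_steps = 17L,
               n_technical = 3L, n_experiments = 4L,
               ir_on_s = 20, ir_off_s = 5, seed = seed)
}

#' Concentration grid of a 1:1 serial dilution, ascending
#' @param design an [assay_design()].
#' @return molar concentrations, lowest first.
#' @export
dilution_grid <- function(design) {
  sort(design$dilution_top / 2^(seq_len(design$dilution_steps) - 1L))
}

#' Expected depletion of a capillary at equilibrium
#'
#' Composes the competitive equilibrium solver with the linear signal
#' model: `D = d_free + (d_bound - d_free) * x`.
#'
#' @param system a [binding_system()].
#' @param signal a [signal_model()].
#' @return expected depletion in permille.
#' @export
expected_depletion <- function(system, signal) {
  stopifnot(inherits(signal, "signal_model"))
  x <- solve_competitive_equilibrium(system)$x
  signal$d_free + (signal$d_bound - signal$d_free) * x
}

#' Generate a replicate set of synthetic binding curves with ground truth
#'
#' Emulates either competition-MST workflow on a known system. For the
#' amplitude assay (`vary = "i2"`) the titrant I2 runs over the dilution
#' grid with the plasma inhibitor I1 fixed; for the K_D assay
#' (`vary = "i1"`) the inhibitor I1 is titrated with no competitor
#' present. Per experiment a baseline offset is drawn once
#' (N(0, offset_sd); this is what baseline alignment removes), and each
#' technical replicate adds independent N(0, noise_sd) depletion noise.
#' The returned object embeds the complete ground truth (noise-free
#' expected depletions, true system, design, signal model and seed), so
#' any downstream estimate can be checked against truth and the dataset
#' can be regenerated bit-identically.
#'
#' @param design an [assay_design()]; its `seed` drives all randomness.
#' @param truth a [binding_system()] template holding the true totals and
#'   dissociation constants; the titrated species is overridden by the
#'   dilution grid.
#' @param signal a [signal_model()].
#' @param vary which species the dilution series titrates.
#' @return object of class `mst_dataset`: `points` (data.frame with
#'   `conc_M`, `depletion_permille`, `replicate_id`, `experiment_id`,
#'   `capillary_id`) and `truth` (list with `expected` per-concentration
#'   noise-free depletions and bound fractions, `offsets`, `system`,
#'   `design`, `signal`, `vary`, `seed`).
#' @export
generate_binding_dataset <- function(design, truth, signal = signal_model(),
                                     vary = c("i2", "i1")) {
  vary <- match.arg(vary)
  stopifnot(inherits(design, "assay_design"),
            inherits(truth, "binding_system"),
            inherits(signal, "signal_model"))
  grid <- dilution_grid(design)
  expected <- vapply(grid, function(cM) {
    sys <- truth
    sys$e_total <- design$e_total
    if (vary == "i2") sys$i2_total <- cM
    else { sys$i1_total <- cM; sys$i2_total <- 0 }
    expected_depletion(sys, signal)
  }, numeric(1))
  x_true <- (expected - signal$d_free) / (signal$d_bound - signal$d_free)

  gen <- function() {
    offsets <- stats::rnorm(design$n_experiments, 0, signal$offset_sd)
    pts <- do.call(rbind, lapply(seq_len(design$n_experiments), function(e) {
      do.call(rbind, lapply(seq_along(grid), function(i) {
        d <- expected[i] + offsets[e] +
          stats::rnorm(design$n_technical, 0, signal$noise_sd)
        data.frame(conc_M = grid[i], depletion_permille = d,
                   replicate_id = seq_len(design$n_technical),
                   experiment_id = e,
                   capillary_id = sprintf("e%d_c%02d_r%d", e, i,
                                          seq_len(design$n_technical)))
      }))
    }))
    list(points = pts, offsets = offsets)
  }
  out <- withr::with_seed(design$seed, gen())

  structure(list(
    points = out$points,
    truth = list(expected = data.frame(conc_M = grid,
                                       depletion_permille = expected,
                                       bound_fraction = x_true),
                 offsets = out$offsets,
                 system = truth, design = design, signal = signal,
                 vary = vary, seed = design$seed)
  ), class = "mst_dataset")
}

#' Per-experiment binding curves of a synthetic dataset
#'
#' Aggregates each experiment's technical replicates into a
#' `binding_curve` via [aggregate_replicates()].
#'
#' @param dataset an `mst_dataset`.
#' @return list of `binding_curve`s, one per experiment.
#' @export
dataset_curves <- function(dataset) {
  stopifnot(inherits(dataset, "mst_dataset"))
  e_total <- dataset$truth$design$e_total
  lapply(split(dataset$points, dataset$points$experiment_id), function(df) {
    aggregate_replicates(df, e_total = e_total,
                         curve_id = sprintf("experiment_%s",
                                            df$experiment_id[1]))
  })
}

#' Generate a capillary fluorescence time trace
#'
#' Piecewise phenomenological trace behind a prescribed steady-state
#' depletion `d` (permille): constant `f0` during the cold phase, then
#' `f0 * (1 - d/1000 * (1 - exp(-(t - ir_on)/tau_on)))` while the IR
#' laser heats, then exponential back-diffusion toward `f0` with
#' `tau_off` after laser-off, plus optional additive Gaussian noise.
#' With a hot window placed many `tau_on` after laser-on,
#' [compute_depletion()] recovers `d` to well below 1e-3 permille.
#'
#' @param depletion prescribed equilibrated depletion (permille).
#' @param signal a [signal_model()] (`f0`, time constants, trace noise).
#' @param conc_M,capillary_id,replicate_id metadata for the trace.
#' @param pre_s cold-phase duration before laser-on (s).
#' @param on_s,off_s IR on and recovery durations (s).
#' @param dt sampling interval (s).
#' @param f0 override of the cold fluorescence (used for background
#'   traces at `background_level`).
#' @param seed optional seed for the trace noise.
#' @return a `fluorescence_trace` with `ir_on = pre_s`,
#'   `ir_off = pre_s + on_s`.
#' @export
generate_trace <- function(depletion, signal = signal_model(),
                           conc_M = NA_real_, capillary_id = NA,
                           replicate_id = NA,
                           pre_s = 5, on_s = 25, off_s = 5, dt = 0.1,
                           f0 = signal$f0, seed = NULL) {
  stopifnot(inherits(signal, "signal_model"))
  times <- seq(0, pre_s + on_s + off_s, by = dt)
  ir_on <- pre_s; ir_off <- pre_s + on_s
  fl <- rep(f0, length(times))
  on <- times > ir_on & times <= ir_off
  fl[on] <- f0 * (1 - depletion / 1000 *
                    (1 - exp(-(times[on] - ir_on) / signal$tau_on)))
  f_end <- f0 * (1 - depletion / 1000 * (1 - exp(-on_s / signal$tau_on)))
  off <- times > ir_off
  fl[off] <- f0 - (f0 - f_end) * exp(-(times[off] - ir_off) / signal$tau_off)
  if (signal$trace_noise_sd > 0) {
    noise <- function() stats::rnorm(length(fl), 0, signal$trace_noise_sd)
    fl <- fl + if (is.null(seed)) noise() else withr::with_seed(seed, noise())
  }
  fluorescence_trace(times, fl, ir_on = ir_on, ir_off = ir_off,
                     conc_M = conc_M, capillary_id = capillary_id,
                     replicate_id = replicate_id)
}

#' @rdname generate_trace
#' @export
generate_background_trace <- function(signal = signal_model(), pre_s = 5,
                                      on_s = 25, off_s = 5, dt = 0.1,
                                      seed = NULL) {
  generate_trace(0, signal, capillary_id = "background",
                 pre_s = pre_s, on_s = on_s, off_s = off_s, dt = dt,
                 f0 = signal$background_level, seed = seed)
}

#' Generate a full trace-level synthetic dataset
#'
#' For every capillary of the design, the steady-state depletion is
#' drawn as in [generate_binding_dataset()] and rendered into an
#' observed fluorescence trace as signal plus the shared plasma
#' background (so the background-subtraction step has real work to do).
#' One background trace per experiment is generated.
#'
#' @inheritParams generate_binding_dataset
#' @return list of class `mst_trace_dataset`: `experiments` (each with
#'   `samples`, a list of observed traces, and `background`), and the
#'   same `truth` record as the curve-level generator.
#' @export
generate_trace_dataset <- function(design, truth, signal = signal_model(),
                                   vary = c("i2", "i1")) {
  vary <- match.arg(vary)
  base <- generate_binding_dataset(design, truth, signal, vary)
  bg <- generate_background_trace(signal, on_s = design$ir_on_s,
                                  off_s = design$ir_off_s)
  experiments <- lapply(split(base$points, base$points$experiment_id),
                        function(df) {
    samples <- lapply(seq_len(nrow(df)), function(i) {
      tr <- generate_trace(df$depletion_permille[i], signal,
                           conc_M = df$conc_M[i],
                           capillary_id = df$capillary_id[i],
                           replicate_id = df$replicate_id[i],
                           on_s = design$ir_on_s, off_s = design$ir_off_s)
      tr$fluorescence <- tr$fluorescence + bg$fluorescence
      tr
    })
    list(samples = samples, background = bg)
  })
  structure(list(experiments = experiments, truth = base$truth),
            class = "mst_trace_dataset")
}

#' Generate synthetic cohort amplitude samples
#'
#' Two log-normal amplitude samples with prescribed medians, emulating a
#' cohort split into high and low lung-function groups (default sizes 8
#' and 18). A log-normal with log-mean `log(median)` has exactly the
#' requested median for any dispersion.
#'
#' @param n_high,n_low group sizes (>= 1).
#' @param median_high,median_low group median amplitudes (permille, > 0).
#' @param dispersion SD of log amplitude (0 collapses each group onto
#'   its median).
#' @param seed integer seed.
#' @return list with `high`, `low` (numeric amplitude vectors) and a
#'   `truth` record.
#' @export
generate_cohort <- function(n_high = 8L, n_low = 18L,
                            median_high = 15, median_low = 30,
                            dispersion = 0.4, seed = 1L) {
  if (n_high < 1L || n_low < 1L) stop("group sizes must be >= 1")
  if (median_high <= 0 || median_low <= 0) stop("medians must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  sam <- withr::with_seed(seed, list(
    high = stats::rlnorm(n_high, meanlog = log(median_high), sdlog = dispersion),
    low = stats::rlnorm(n_low, meanlog = log(median_low), sdlog = dispersion)
  ))
  list(high = sam$high, low = sam$low,
       truth = list(n_high = n_high, n_low = n_low,
                    median_high = median_high, median_low = median_low,
                    dispersion = dispersion, seed = seed))
}

#' Generate a synthetic titration series
#'
#' Ideal tight-binding titration `activity = max(0, 1 - amount/E)` with
#' optional Gaussian noise on the activity readout.
#'
#' @param enzyme_concentration assay enzyme concentration (molar or unit
#'   string); also the equivalence point of the ideal series.
#' @param n_points number of titration points from 0 to
#'   `1.5 * enzyme_concentration`.
#' @param noise_sd SD of activity noise.
#' @param seed integer seed.
#' @return a [titration_series()] with the truth in attribute `truth`.
#' @export
generate_titration_series <- function(enzyme_concentration, n_points = 12L,
                                      noise_sd = 0, seed = 1L) {
  e <- parse_conc(enzyme_concentration)
  if (e <= 0) stop("enzyme_concentration must be > 0")
  amounts <- seq(0, 1.5 * e, length.out = n_points)
  act <- pmax(0, 1 - amounts / e)
  if (noise_sd > 0) {
    act <- withr::with_seed(seed,
                            act + stats::rnorm(n_points, 0, noise_sd))
  }
  out <- titration_series(amounts, act, enzyme_concentration = e,
                          amount_scale = "molar")
  attr(out, "truth") <- list(equivalence = e, noise_sd = noise_sd, seed = seed)
  out
}
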