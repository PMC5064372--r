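#' Define a two-inhibitor competitive binding system
#'
#' A labeled enzyme E is shared between two reversible 1:1 complexes,
#' E + I1 <-> EI1 and E + I2 <-> EI2, with dissociation constants `kd1`
#' and `kd2`. In the assay this package models, E is catalytically
#' inactive labeled neutrophil elastase, I1 the low-affinity inhibitor
#' alpha-1-antitrypsin present in diluted plasma, and I2 the high-affinity
#' titrant elafin. All concentrations are totals; free and complexed
#' species at equilibrium are obtained with
#' [solve_competitive_equilibrium()].
#'
#' @param e_total total labeled enzyme concentration (molar, or string with
#'   unit suffix, see [parse_conc()]). Must be >= 0.
#' @param i1_total,i2_total total inhibitor concentrations (>= 0).
#' @param kd1,kd2 dissociation constants of EI1 and EI2 (> 0). `kd2 = Inf`
#'   is allowed and removes the second complex (continuous limit).
#' @return an object of class `binding_system`.
#' @examples
#' binding_system("500pM", i1_total = "75nM", i2_total = "1nM",
#'                kd1 = "500nM", kd2 = "0.2nM")
#' @export
binding_system <- function(e_total, i1_total = 0, i2_total = 0, kd1, kd2) {
  sys <- list(
    e_total  = parse_conc(e_total),
    i1_total = parse_conc(i1_total),
    i2_total = parse_conc(i2_total),
    kd1      = parse_conc(kd1),
    kd2      = parse_conc(kd2)
  )
  .check_scalar(sys$e_total, "e_total", lower = 0)
  .check_scalar(sys$i1_total, "i1_total", lower = 0)
  .check_scalar(sys$i2_total, "i2_total", lower = 0)
  .check_scalar(sys$kd1, "kd1", allow_inf = TRUE)
  .check_scalar(sys$kd2, "kd2", allow_inf = TRUE)
  if (sys$kd1 <= 0) stop("kd1 must be > 0")
  if (sys$kd2 <= 0) stop("kd2 must be > 0")
  structure(sys, class = "binding_system")
}

#' @export
print.binding_system <- function(x, ...) {
  cat("Competitive binding system (concentrations in nM):\n")
  cat(sprintf("  E_total  = %g\n  I1_total = %g\n  I2_total = %g\n",
              x$e_total * 1e9, x$i1_total * 1e9, x$i2_total * 1e9))
  cat(sprintf("  KD(EI1)  = %g\n  KD(EI2)  = %g\n",
              x$kd1 * 1e9, x$kd2 * 1e9))
  invisible(x)
}

# conservation excess for free E: strictly increasing on [0, e_total],
# f(0) = -e_total < 0 and f(e_total) >= 0, so the physical root is unique.
.free_e_excess <- function(ef, sys) {
  t1 <- if (sys$i1_total > 0 && is.finite(sys$kd1))
    sys$i1_total / (sys$kd1 + ef) else 0
  t2 <- if (sys$i2_total > 0 && is.finite(sys$kd2))
    sys$i2_total / (sys$kd2 + ef) else 0
  ef * (1 + t1 + t2) - sys$e_total
}

.free_e_excess_deriv <- function(ef, sys) {
  d <- 1
  if (sys$i1_total > 0 && is.finite(sys$kd1))
    d <- d + sys$i1_total * sys$kd1 / (sys$kd1 + ef)^2
  if (sys$i2_total > 0 && is.finite(sys$kd2))
    d <- d + sys$i2_total * sys$kd2 / (sys$kd2 + ef)^2
  d
}

.equilibrium_state_from_free_e <- function(ef, sys) {
  ef <- min(max(ef, 0), sys$e_total)
  ei1 <- if (is.finite(sys$kd1)) ef * sys$i1_total / (sys$kd1 + ef) else 0
  ei2 <- if (is.finite(sys$kd2)) ef * sys$i2_total / (sys$kd2 + ef) else 0
  x <- if (sys$e_total > 0) min(max((ei1 + ei2) / sys$e_total, 0), 1) else 0
  structure(list(
    e_free  = ef,
    i1_free = sys$i1_total - ei1,
    i2_free = sys$i2_total - ei2,
    ei1 = ei1, ei2 = ei2, x = x,
    system = sys
  ), class = "equilibrium_state")
}

#' Solve the two-inhibitor competitive mass-action equilibrium
#'
#' Solves the coupled mass-action system for free enzyme `E_free` on the
#' bracket `[0, E_total]` using a safeguarded monotone root find (the
#' conservation function is strictly increasing there, so the physical
#' root is unique), then a few Newton polish steps to machine precision.
#' This is numerically equivalent to selecting the smallest non-negative
#' real root of the cubic in the bound fraction x (see
#' [solve_equilibrium_cubic()], which is retained as an independent
#' algebraic cross-check).
#'
#' @param system a [binding_system()] with `e_total > 0`.
#' @return an object of class `equilibrium_state` with fields `e_free`,
#'   `i1_free`, `i2_free`, `ei1`, `ei2` (molar) and `x`, the fraction of
#'   occupied enzyme `(EI1 + EI2)/E_total`.
#' @examples
#' s <- binding_system("1nM", "500nM", "5nM", kd1 = "500nM", kd2 = "0.1nM")
#' solve_competitive_equilibrium(s)$x
#' @export
solve_competitive_equilibrium <- function(system) {
  if (!inherits(system, "binding_system")) {
    system <- do.call(binding_system, as.list(system))
  }
  if (system$e_total <= 0) stop("e_total must be > 0 to solve the equilibrium")
  if (system$i1_total == 0 && system$i2_total == 0) {
    return(.equilibrium_state_from_free_e(system$e_total, system))
  }
  f <- function(ef) .free_e_excess(ef, system)
  root <- stats::uniroot(f, lower = 0, upper = system$e_total,
                         f.lower = -system$e_total,
                         f.upper = f(system$e_total),
                         tol = system$e_total * 1e-14,
                         maxiter = 2000L)$root
  # Newton polish; the derivative is available analytically and >= 1
  for (i in 1:4) {
    step <- .free_e_excess(root, system) / .free_e_excess_deriv(root, system)
    root <- min(max(root - step, 0), system$e_total)
  }
  .equilibrium_state_from_free_e(root, system)
}

#' Cubic-polynomial route to the competitive equilibrium
#'
#' Eliminating the complexes from the conservation laws yields a cubic in
#' free E (equivalently in the bound fraction x); the physically
#' admissible solution is the smallest non-negative real root in x that
#' leaves all free concentrations non-negative. This route exists as an
#' algebraic cross-check of [solve_competitive_equilibrium()]; the
#' bracketed solver is the production path because it is unconditionally
#' stable.
#'
#' Coefficients are assembled in units of `e_total` to keep the companion
#' eigenproblem well conditioned at sub-nanomolar concentrations.
#'
#' @param system a [binding_system()] with `e_total > 0` and finite `kd2`.
#' @return an `equilibrium_state`, as for [solve_competitive_equilibrium()].
#' @export
solve_equilibrium_cubic <- function(system) {
  if (!inherits(system, "binding_system")) {
    system <- do.call(binding_system, as.list(system))
  }
  if (system$e_total <= 0) stop("e_total must be > 0")
  if (!is.finite(system$kd1) || !is.finite(system$kd2)) {
    stop("cubic route requires finite dissociation constants")
  }
  e <- system$e_total
  k1 <- system$kd1 / e; k2 <- system$kd2 / e
  a1 <- system$i1_total / e; a2 <- system$i2_total / e
  # u = E_free / e_total; u*(k1+u)*(k2+u) + a1*u*(k2+u) + a2*u*(k1+u)
  #   - (k1+u)*(k2+u) = 0
  c3 <- 1
  c2 <- k1 + k2 + a1 + a2 - 1
  c1 <- k1 * k2 + a1 * k2 + a2 * k1 - (k1 + k2)
  c0 <- -k1 * k2
  roots <- polyroot(c(c0, c1, c2, c3))
  re <- Re(roots)
  ok <- abs(Im(roots)) < 1e-8 * pmax(1, abs(re)) &
    re >= -1e-12 & re <= 1 + 1e-9
  if (!any(ok)) stop("no admissible real root found (internal error)")
  # smallest non-negative root in x = 1 - u  <=>  largest admissible u
  u <- max(re[ok])
  .equilibrium_state_from_free_e(u * e, system)
}

#' Bound fraction for a single-site interaction (quadratic law)
#'
#' Exact solution of the 1:1 mass-action law accounting for ligand
#' depletion: for totals `E`, `L` and dissociation constant `KD`, the
#' fraction of bound enzyme is
#' \deqn{x = \frac{(K_D + E + L) - \sqrt{(K_D + E + L)^2 - 4EL}}{2E}.}
#' Evaluated in the cancellation-free form `2L / (b + sqrt(b^2 - 4EL))`
#' with `b = KD + E + L`; a discriminant driven negative by rounding is
#' clamped to zero so the function never returns NaN.
#'
#' @param e_total total enzyme (> 0), molar or unit string.
#' @param l_total total ligand (>= 0), may be a vector (the titration axis).
#' @param kd dissociation constant (> 0).
#' @return bound fraction(s) in `[0, min(1, L/E)]`.
#' @examples
#' fraction_bound_single(1, 1, 1)  # (3 - sqrt(5))/2
#' @export
fraction_bound_single <- function(e_total, l_total, kd) {
  e <- parse_conc(e_total); l <- parse_conc(l_total); k <- parse_conc(kd)
  .check_scalar(e, "e_total")
  .check_scalar(k, "kd")
  if (e <= 0) stop("e_total must be > 0")
  if (k <= 0) stop("kd must be > 0")
  if (any(!is.finite(l)) || any(l < 0)) stop("l_total must be finite and >= 0")
  b <- k + e + l
  disc <- pmax(b * b - 4 * e * l, 0)
  x <- 2 * l / (b + sqrt(disc))
  pmin(pmax(x, 0), pmin(1, ifelse(l > 0, l / e, 1)))
}

#' Simulate a theoretical competition binding curve
#'
#' Evaluates the fraction of occupied enzyme x along a grid of titrant
#' (I2) totals, holding the rest of the system fixed. This reproduces the
#' mass-action simulations used to characterise how the thermophoretic
#' amplitude responds to the competitor's concentration and affinity.
#'
#' @param template a [binding_system()]; its `i2_total` is overridden by
#'   the grid.
#' @param i2_grid strictly increasing, non-negative titrant totals (molar
#'   or unit strings).
#' @return object of class `theoretical_curve` with `concentrations`,
#'   `bound_fractions` and the shared `system_template`.
#' @export
simulate_binding_curve <- function(template, i2_grid) {
  if (!inherits(template, "binding_system")) stop("template must be a binding_system")
  grid <- parse_conc(i2_grid)
  if (length(grid) == 0L) stop("i2_grid must be non-empty")
  if (any(!is.finite(grid)) || any(grid < 0)) stop("i2_grid must be finite and >= 0")
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("i2_grid must be strictly increasing")
  }
  x <- vapply(grid, function(i2) {
    sys <- template
    sys$i2_total <- i2
    solve_competitive_equilibrium(sys)$x
  }, numeric(1))
  structure(list(concentrations = grid, bound_fractions = x,
                 system_template = template),
            class = "theoretical_curve")
}

#' Theoretical thermophoretic amplitude of a simulated curve
#'
#' The amplitude is the difference between the mean bound fraction over a
#' high-concentration window (saturating titrant) and a low-concentration
#' window (vanishing titrant). On experimental depletion curves the same
#' difference, in per-mille units, is the assay's primary readout.
#'
#' @param curve a `theoretical_curve`.
#' @param low_window,high_window integer index vectors into the grid; the
#'   low window must precede (not overlap) the high window. Defaults: the
#'   first and last three points.
#' @return dimensionless amplitude in `[-1, 1]` (>= 0 for monotone curves).
#' @export
theoretical_amplitude <- function(curve,
                                  low_window = seq_len(min(3L, length(curve$concentrations))),
                                  high_window = NULL) {
  n <- length(curve$concentrations)
  if (is.null(high_window)) high_window <- seq.int(max(1L, n - 2L), n)
  low_window <- as.integer(low_window); high_window <- as.integer(high_window)
  if (length(low_window) == 0L || length(high_window) == 0L) {
    stop("windows must be non-empty")
  }
  if (any(low_window < 1L) || any(high_window > n)) stop("window out of range")
  if (max(low_window) >= min(high_window)) {
    stop("low window must precede the high window without overlap")
  }
  mean(curve$bound_fractions[high_window]) - mean(curve$bound_fractions[low_window])
}

#' Export a theoretical curve as delimited text
#'
#' Writes columns `conc_M`, `bound_fraction` preceded by a single JSON
#' header line mirroring the system template, so the curve is
#' self-describing.
#'
#' @param curve a `theoretical_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_theoretical_curve <- function(curve, path) {
  tpl <- curve$system_template
  hdr <- jsonlite::toJSON(
    list(e_total_M = tpl$e_total, i1_total_M = tpl$i1_total,
         kd1_M = tpl$kd1, kd2_M = tpl$kd2),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  writeLines("conc_M\tbound_fraction", con)
  writeLines(sprintf("%.17g\t%.17g", curve$concentrations,
                     curve$bound_fractions), con)
  invisible(path)
}
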