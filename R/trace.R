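#' One capillary's fluorescence time trace
#'
#' Container for a raw MST capillary measurement: fluorescence against
#' time, with the IR-laser on/off times recorded in the metadata (the
#' assay uses on/off schedules such as 25/5 s or 20/5 s). At least five
#' samples are required before laser-on and five during the heating
#' phase, so that window means are defined.
#'
#' @param times seconds, strictly increasing.
#' @param fluorescence arbitrary units, same length as `times`. Negative
#'   values are tolerated (they arise after background subtraction) and
#'   flagged in the `has_negative` attribute.
#' @param ir_on,ir_off laser-on and laser-off times (s), with
#'   `ir_on < ir_off <= max(times)`.
#' @param conc_M ligand (titrant) concentration in this capillary, molar.
#' @param capillary_id,replicate_id identifiers carried through processing.
#' @return object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, fluorescence, ir_on, ir_off,
                               conc_M = NA_real_, capillary_id = NA,
                               replicate_id = NA) {
  times <- as.numeric(times); fluorescence <- as.numeric(fluorescence)
  if (length(times) != length(fluorescence)) {
    stop("times and fluorescence must have equal length")
  }
  if (any(!is.finite(times)) || any(!is.finite(fluorescence))) {
    stop("times and fluorescence must be finite")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  .check_scalar(ir_on, "ir_on"); .check_scalar(ir_off, "ir_off")
  if (!(ir_on < ir_off && ir_off <= times[length(times)])) {
    stop("need ir_on < ir_off <= last time")
  }
  if (sum(times < ir_on) < 5L) stop("need >= 5 samples before ir_on")
  if (sum(times >= ir_on & times <= ir_off) < 5L) {
    stop("need >= 5 samples within [ir_on, ir_off]")
  }
  structure(list(times = times, fluorescence = fluorescence,
                 ir_on = ir_on, ir_off = ir_off,
                 conc_M = as.numeric(parse_conc(conc_M)),
                 capillary_id = capillary_id, replicate_id = replicate_id,
                 has_negative = any(fluorescence < 0)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: %d samples, t = [%g, %g] s, IR %g-%g s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$ir_on, x$ir_off))
  if (!is.na(x$conc_M)) cat(sprintf("  ligand conc: %g nM\n", x$conc_M * 1e9))
  invisible(x)
}

#' Subtract a background trace from a sample trace
#'
#' Plasma autofluorescence is measured in a separate capillary without
#' labeled enzyme; its time trace is subtracted pointwise from each
#' sample trace before depletion is computed. Time grids must agree to
#' 1e-6 s unless `interpolate = TRUE`, in which case the background is
#' linearly interpolated onto the sample grid (constant extrapolation at
#' the ends).
#'
#' @param sample,background `fluorescence_trace` objects.
#' @param interpolate allow interpolation of a background measured on a
#'   different grid.
#' @return a `fluorescence_trace` with the sample's metadata; the
#'   fraction of negative points after subtraction is recorded in the
#'   `negative_fraction` attribute.
#' @export
subtract_background <- function(sample, background, interpolate = FALSE) {
  stopifnot(inherits(sample, "fluorescence_trace"),
            inherits(background, "fluorescence_trace"))
  same_grid <- length(sample$times) == length(background$times) &&
    all(abs(sample$times - background$times) <= 1e-6)
  if (same_grid) {
    bg <- background$fluorescence
  } else if (interpolate) {
    bg <- stats::approx(background$times, background$fluorescence,
                        xout = sample$times, rule = 2)$y
  } else {
    stop("sample and background time grids differ; set interpolate = TRUE")
  }
  out <- sample
  out$fluorescence <- sample$fluorescence - bg
  out$has_negative <- any(out$fluorescence < 0)
  attr(out, "negative_fraction") <- mean(out$fluorescence < 0)
  out
}

.default_cold_window <- function(trace, width = 1.0) {
  c(max(trace$times[1], trace$ir_on - width), trace$ir_on)
}
.default_hot_window <- function(trace, width = 1.0) {
  c(max(trace$ir_on, trace$ir_off - width), trace$ir_off)
}

#' Thermophoretic depletion of a trace, in per mille
#'
#' The fluorescence after the temperature jump, once thermophoresis has
#' equilibrated (hot window), is normalised to the fluorescence before IR
#' heating (cold window):
#' \deqn{D = (1 - \bar F_{hot} / \bar F_{cold}) \times 1000\ \text{permille}.}
#' Positive depletion means fluorescence dropped in the heated spot;
#' bound enzyme depletes more strongly than free enzyme, so depletion
#' grows with the bound fraction. By default the cold window is the last
#' 1 s before laser-on and the hot window the last 1 s before laser-off
#' (the window widths are not dictated by the assay; both are
#' configurable). The readout is invariant under rescaling of the whole
#' trace, so detector gain does not matter.
#'
#' @param trace a `fluorescence_trace` (background-subtracted if a
#'   background applies).
#' @param cold_window,hot_window numeric `c(start, end)` in seconds;
#'   the cold window must lie before `ir_on`, the hot window within
#'   `(ir_on, ir_off]`.
#' @return one-row data.frame of class `depletion_point` with columns
#'   `conc_M`, `depletion_permille`, `replicate_id`, `capillary_id`.
#' @export
compute_depletion <- function(trace, cold_window = NULL, hot_window = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (is.null(cold_window)) cold_window <- .default_cold_window(trace)
  if (is.null(hot_window)) hot_window <- .default_hot_window(trace)
  if (!(cold_window[1] < cold_window[2] && cold_window[2] <= trace$ir_on)) {
    stop("cold window must lie before ir_on")
  }
  if (!(hot_window[1] >= trace$ir_on && hot_window[1] < hot_window[2] &&
        hot_window[2] <= trace$ir_off)) {
    stop("hot window must lie within (ir_on, ir_off]")
  }
  ci <- trace$times >= cold_window[1] & trace$times <= cold_window[2] &
    trace$times < trace$ir_on
  hi <- trace$times >= hot_window[1] & trace$times <= hot_window[2] &
    trace$times > trace$ir_on
  if (!any(ci) || !any(hi)) stop("empty depletion window")
  f_cold <- mean(trace$fluorescence[ci])
  f_hot <- mean(trace$fluorescence[hi])
  if (f_cold <= 0) stop("mean cold fluorescence must be > 0")
  out <- data.frame(conc_M = trace$conc_M,
                    depletion_permille = (1 - f_hot / f_cold) * 1000,
                    replicate_id = trace$replicate_id,
                    capillary_id = trace$capillary_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("depletion_point", class(out))
  out
}

#' Aggregate technical replicates into a binding curve
#'
#' Groups depletion points by ligand concentration and records per
#' concentration the mean depletion, the sample standard deviation
#' (n - 1 denominator; `NA` for a single replicate) and the replicate
#' count, matching the triplicate design of the assay.
#'
#' @param points data.frame with columns `conc_M` and
#'   `depletion_permille` (rows from [compute_depletion()] rbind
#'   together, or generator output).
#' @param e_total total labeled enzyme concentration (molar or unit
#'   string); stored on the curve for downstream fitting.
#' @param curve_id identifier for this curve (e.g. sample or experiment).
#' @return a `binding_curve`: data.frame with columns `conc_M`,
#'   `depletion_permille`, `sd_permille`, `n`, sorted by concentration,
#'   with attributes `e_total` and `curve_id`.
#' @export
aggregate_replicates <- function(points, e_total, curve_id = "curve") {
  stopifnot(is.data.frame(points),
            all(c("conc_M", "depletion_permille") %in% names(points)))
  if (nrow(points) == 0L) stop("no depletion points supplied")
  if (any(!is.finite(points$depletion_permille))) stop("non-finite depletion")
  key <- points$conc_M
  sp <- split(points$depletion_permille, format(key, digits = 17))
  conc <- vapply(split(key, format(key, digits = 17)), `[[`, numeric(1), 1L)
  ord <- order(conc)
  curve <- data.frame(
    conc_M = conc[ord],
    depletion_permille = vapply(sp, mean, numeric(1))[ord],
    sd_permille = vapply(sp, function(v)
      if (length(v) >= 2L) stats::sd(v) else NA_real_, numeric(1))[ord],
    n = vapply(sp, length, integer(1))[ord],
    row.names = NULL
  )
  new_binding_curve(curve, e_total = e_total, curve_id = curve_id)
}

new_binding_curve <- function(df, e_total, curve_id = "curve",
                              normalized = FALSE) {
  stopifnot(all(c("conc_M", "depletion_permille", "sd_permille", "n") %in%
                  names(df)))
  if (anyDuplicated(df$conc_M)) stop("concentrations must be unique")
  df <- df[order(df$conc_M), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            e_total = parse_conc(e_total),
            curve_id = curve_id,
            normalized = normalized,
            class = c("binding_curve", "data.frame"))
}

#' @export
print.binding_curve <- function(x, ...) {
  cat(sprintf("Binding curve '%s' (E_total = %g nM%s), %d concentrations\n",
              attr(x, "curve_id"), attr(x, "e_total") * 1e9,
              if (isTRUE(attr(x, "normalized"))) ", normalized 0-1" else "",
              nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

# plateau of the saturating high end: mean over points with
# conc >= max(conc)/4, i.e. the top steps of a 1:1 dilution series.
# slope_tol is a fraction of the curve's dynamic range per decade; a
# curve still rising at the top exceeds it, technical noise does not.
.plateau <- function(curve, slope_tol = 0.25) {
  sel <- curve$conc_M >= max(curve$conc_M) / 4
  if (sum(sel) < 2L) return(list(value = NA_real_, ok = FALSE))
  d <- curve$depletion_permille[sel]
  lc <- log10(curve$conc_M[sel])
  slope <- stats::coef(stats::lm(d ~ lc))[[2]]
  rng <- diff(range(curve$depletion_permille))
  ok <- rng == 0 || abs(slope) <= slope_tol * max(rng, .Machine$double.eps)
  list(value = mean(d), ok = ok, slope = slope)
}

#' Align binding-curve baselines at saturating titrant
#'
#' At saturating competitor concentration every curve reports the same
#' fully-bound state, so residual offsets there are instrumental; each
#' curve is shifted by a constant so that its saturation plateau equals
#' `reference`. The plateau is estimated as the mean depletion over
#' points with concentration >= max/4 (the top two steps of a 1:1
#' series); a curve whose plateau still has appreciable slope (> 25% of
#' the curve's dynamic range per decade) is judged non-saturating,
#' passed through unshifted with a warning, and flagged.
#'
#' Shifting is a pure translation: all within-curve differences, and
#' hence any fitted amplitude, are preserved exactly.
#'
#' @param curves a `binding_curve` or list of them.
#' @param reference target plateau depletion (permille). Default: the mean
#'   of the curves' own plateau estimates.
#' @return list of shifted `binding_curve`s; each carries attributes
#'   `baseline_shift` (applied constant) and `aligned` (logical).
#' @export
align_baselines <- function(curves, reference = NULL) {
  if (inherits(curves, "binding_curve")) curves <- list(curves)
  plats <- lapply(curves, .plateau)
  if (is.null(reference)) {
    vals <- vapply(plats[vapply(plats, `[[`, logical(1), "ok")],
                   `[[`, numeric(1), "value")
    if (length(vals) == 0L) stop("no curve has a usable saturation plateau")
    reference <- mean(vals)
  }
  mapply(function(curve, pl) {
    if (!pl$ok) {
      warning(sprintf("curve '%s': no saturating plateau; left unshifted",
                      attr(curve, "curve_id")))
      attr(curve, "baseline_shift") <- 0
      attr(curve, "aligned") <- FALSE
      return(curve)
    }
    shift <- reference - pl$value
    curve$depletion_permille <- curve$depletion_permille + shift
    attr(curve, "baseline_shift") <- shift
    attr(curve, "aligned") <- TRUE
    curve
  }, curves, plats, SIMPLIFY = FALSE)
}
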