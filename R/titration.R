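#' Residual-activity titration series
#'
#' Functional inhibitor concentration is measured by incubating a
#' constant amount of active-site-titrated enzyme with a dilution series
#' of the inhibitor-containing sample (e.g. plasma) and reading the
#' residual enzymatic activity: activity falls linearly to zero at the
#' stoichiometric equivalence point for a tight-binding inhibitor.
#'
#' @param inhibitor_amounts non-negative, strictly increasing; either
#'   molar amounts (`amount_scale = "molar"`) or dilution fractions of
#'   the sample (`amount_scale = "dilution"`).
#' @param residual_activities fraction of uninhibited activity,
#'   typically in `[0, ~1.1]`.
#' @param enzyme_concentration active-site-titrated enzyme concentration
#'   in the assay (molar or unit string).
#' @param amount_scale interpretation of `inhibitor_amounts`.
#' @return object of class `titration_series`.
#' @export
titration_series <- function(inhibitor_amounts, residual_activities,
                             enzyme_concentration,
                             amount_scale = c("molar", "dilution")) {
  amount_scale <- match.arg(amount_scale)
  a <- as.numeric(inhibitor_amounts)
  act <- as.numeric(residual_activities)
  if (length(a) != length(act)) stop("amounts and activities must match")
  if (length(a) < 4L) stop("need >= 4 titration points")
  if (any(!is.finite(a)) || any(a < 0)) stop("amounts must be finite and >= 0")
  if (length(a) > 1L && any(diff(a) <= 0)) {
    stop("amounts must be strictly increasing")
  }
  if (any(!is.finite(act))) stop("activities must be finite")
  structure(list(amounts = a, activities = act,
                 enzyme_concentration = parse_conc(enzyme_concentration),
                 amount_scale = amount_scale),
            class = "titration_series")
}

#' Linear equivalence-point fit of a titration series
#'
#' Activities are first normalised to the zero-inhibitor point (the
#' amount-0 point if present, otherwise the smallest-amount point, with
#' a warning), which makes the endpoint invariant to a uniform gain
#' error in the activity readout. An ordinary least-squares line is then
#' fitted through the points in the linear window (normalised activity
#' in `[0.1, 0.9]` by default, where neither baseline curvature nor the
#' tight-binding break distorts the slope), and the equivalence point is
#' its x-intercept.
#'
#' For a dilution-scale series the functional inhibitor concentration of
#' the undiluted sample is `enzyme_concentration / equivalence`; for a
#' molar-scale series the equivalence amount itself is the functional
#' concentration at 1:1 stoichiometry and `enzyme_concentration /
#' equivalence` is reported as the functional fraction of the nominal
#' inhibitor.
#'
#' @param series a [titration_series()].
#' @param window numeric length-2: linear window on normalised activity.
#' @return object of class `equivalence_fit`: `equivalence` (same scale
#'   as the amounts), `functional_concentration` (molar),
#'   `functional_fraction` (molar scale only), `slope`, `intercept`,
#'   `r_squared`, `n_linear`.
#' @export
fit_equivalence_point <- function(series, window = c(0.1, 0.9)) {
  stopifnot(inherits(series, "titration_series"))
  act <- series$activities
  if (series$amounts[1] == 0) {
    a0 <- act[1]
  } else {
    warning("no zero-inhibitor point; normalizing to the smallest amount")
    a0 <- act[1]
  }
  if (!is.finite(a0) || a0 <= 0) stop("zero-inhibitor activity must be > 0")
  norm_act <- act / a0
  sel <- norm_act >= window[1] & norm_act <= window[2]
  if (sum(sel) < 3L) stop("need >= 3 points in the linear window")
  fit <- stats::lm(norm_act[sel] ~ series$amounts[sel])
  b <- stats::coef(fit)
  if (b[[2]] >= 0) stop("activity must decrease with inhibitor amount")
  equivalence <- -b[[1]] / b[[2]]
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((norm_act[sel] - mean(norm_act[sel]))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  e <- series$enzyme_concentration
  out <- list(equivalence = equivalence,
              slope = b[[2]], intercept = b[[1]],
              r_squared = r2, n_linear = sum(sel),
              amount_scale = series$amount_scale)
  if (series$amount_scale == "dilution") {
    out$functional_concentration <- e / equivalence
    out$functional_fraction <- NA_real_
  } else {
    out$functional_concentration <- equivalence
    out$functional_fraction <- e / equivalence
  }
  structure(out, class = "equivalence_fit")
}

#' @export
print.equivalence_fit <- function(x, ...) {
  cat(sprintf("Equivalence point: %.4g (%s scale), R^2 = %.4f (%d points)\n",
              x$equivalence, x$amount_scale, x$r_squared, x$n_linear))
  cat(sprintf("  functional inhibitor concentration: %.4g nM\n",
              x$functional_concentration * 1e9))
  invisible(x)
}

#' Read a titration series from delimited text
#'
#' Columns `amount` and `activity`; metadata lines `# enzyme_M=` and
#' `# scale=` as written by [write_titration_series()].
#' @param path file path.
#' @return a [titration_series()].
#' @export
read_titration_series <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  df <- utils::read.table(text = lines[!grepl("^#", lines)],
                          header = TRUE, sep = "\t")
  titration_series(df$amount, df$activity,
                   enzyme_concentration = .meta_num(meta$enzyme_M),
                   amount_scale = meta$scale %||% "molar")
}

#' @rdname read_titration_series
#' @param series a [titration_series()].
#' @export
write_titration_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta(con, list(enzyme_M = series$enzyme_concentration,
                        scale = series$amount_scale))
  writeLines("amount\tactivity", con)
  writeLines(sprintf("%.17g\t%.17g", series$amounts, series$activities), con)
  invisible(path)
}
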