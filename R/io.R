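#' Read and write trace and curve files
#'
#' Plain-text formats used throughout the package. A trace file holds
#' `# key=value` metadata lines (ir_on, ir_off, conc_M, capillary,
#' replicate) followed by tab-separated `time` and `fluorescence`
#' columns; a curve file holds metadata (e_total_M, curve_id, normalized)
#' and the columns `conc_M`, `depletion_permille`, `sd_permille`, `n`.
#' Numbers are written with 17 significant digits so a write/read round
#' trip is bit exact.
#'
#' @param trace a `fluorescence_trace`.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return the
#'   reconstructed object.
#' @name trace_io
NULL

.write_meta <- function(con, meta) {
  for (k in names(meta)) {
    v <- meta[[k]]
    v <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    writeLines(sprintf("# %s=%s", k, v), con)
  }
}

# metadata numbers may legitimately be missing (e.g. a background
# capillary has no ligand concentration)
.meta_num <- function(x) {
  if (is.null(x) || x %in% c("NA", "NaN", "")) return(NA_real_)
  as.numeric(x)
}

.read_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^=]+)=(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta(con, list(ir_on = trace$ir_on, ir_off = trace$ir_off,
                        conc_M = trace$conc_M,
                        capillary = trace$capillary_id,
                        replicate = trace$replicate_id))
  writeLines("time\tfluorescence", con)
  writeLines(sprintf("%.17g\t%.17g", trace$times, trace$fluorescence), con)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  fluorescence_trace(
    times = df$time, fluorescence = df$fluorescence,
    ir_on = .meta_num(meta$ir_on), ir_off = .meta_num(meta$ir_off),
    conc_M = .meta_num(meta$conc_M),
    capillary_id = meta$capillary %||% NA,
    replicate_id = meta$replicate %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname trace_io
#' @param curve a `binding_curve`.
#' @export
write_binding_curve <- function(curve, path) {
  stopifnot(inherits(curve, "binding_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta(con, list(e_total_M = attr(curve, "e_total"),
                        curve_id = attr(curve, "curve_id"),
                        normalized = isTRUE(attr(curve, "normalized"))))
  writeLines("conc_M\tdepletion_permille\tsd_permille\tn", con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g\t%d",
                     curve$conc_M, curve$depletion_permille,
                     curve$sd_permille, curve$n), con)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_binding_curve <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          na.strings = c("NA", "nan"))
  new_binding_curve(df,
                    e_total = .meta_num(meta$e_total_M),
                    curve_id = meta$curve_id %||% "curve",
                    normalized = identical(meta$normalized, "TRUE"))
}
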