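#' Parse concentrations with unit suffixes to molar
#'
#' Concentration inputs throughout the package are either plain numerics
#' (interpreted as molar) or strings with an explicit unit suffix, e.g.
#' `"500pM"`, `"5 nM"`, `"1.3uM"`. Mixing pM and nM silently is the main
#' practical source of error in binding assays, so user-facing interfaces
#' accept the string form.
#'
#' @param x numeric vector (molar) or character vector with unit suffix.
#'   Recognised suffixes: `fM`, `pM`, `nM`, `uM` (or `µM`), `mM`, `M`.
#' @return numeric vector in molar.
#' @examples
#' parse_conc("500pM")   # 5e-10
#' parse_conc(c("5nM", "1uM"))
#' parse_conc(2e-9)      # passthrough
#' @export
parse_conc <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  if (!is.character(x)) {
    stop("concentration must be numeric (molar) or character with unit suffix")
  }
  mult <- c(fM = 1e-15, pM = 1e-12, nM = 1e-9, uM = 1e-6,
            "µM" = 1e-6, mM = 1e-3, M = 1)
  out <- vapply(x, function(s) {
    s <- gsub("[[:space:]]", "", s)
    m <- regmatches(s, regexec("^([-+0-9.eE]+)(fM|pM|nM|uM|µM|mM|M)$", s))[[1]]
    if (length(m) != 3L) {
      # allow a bare number in a string
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("cannot parse concentration: '", s, "'", call. = FALSE)
      return(v)
    }
    as.numeric(m[2]) * mult[[m[3]]]
  }, numeric(1), USE.NAMES = FALSE)
  out
}

.check_scalar <- function(x, name, lower = -Inf, allow_inf = FALSE) {
  if (length(x) != 1L || is.na(x) || (!allow_inf && !is.finite(x))) {
    stop(name, " must be a single finite value", call. = FALSE)
  }
  if (x < lower) stop(name, " must be >= ", lower, call. = FALSE)
  invisible(x)
}
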