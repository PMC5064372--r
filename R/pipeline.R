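#' Workflow runners
#'
#' High-level entry points chaining the package's modules into the four
#' assay workflows (theory simulation, amplitude determination, global
#' K_D determination, cohort comparison) plus the synthetic-data
#' generator. Each runner takes a configuration (a named list, or a path
#' to a JSON file with the same structure), writes its outputs and a
#' manifest (`manifest.json`: package version, seed, md5 of the
#' canonicalised config) into `config$out` if given, and returns its
#' report invisibly. A thin command-line wrapper over these functions
#' ships in `inst/cli/mst_pipeline.R`.
#'
#' Concentrations in configs may be unit strings (`"500pM"`, `"5nM"`).
#'
#' @param config named list or path to a JSON config file.
#' @return the workflow report, invisibly.
#' @name pipeline
NULL

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

.write_manifest <- function(out_dir, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  manifest <- list(
    package = "mstcompete",
    version = as.character(utils::packageVersion("mstcompete")),
    seed = config$seed %||% NA,
    config_md5 = unname(tools::md5sum(cfg_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.config_system <- function(block) {
  binding_system(e_total = block$e_total,
                 i1_total = block$i1_total %||% 0,
                 i2_total = block$i2_total %||% 0,
                 kd1 = block$kd1, kd2 = block$kd2 %||% "0.2nM")
}

.config_signal <- function(block) {
  if (is.null(block)) return(signal_model())
  do.call(signal_model, block)
}

#' @rdname pipeline
#' @details `run_simulate_theory` sweeps either `kd1` or `i1_total`
#'   (config `sweep = "kd1"` or `"i1"`, `sweep_values` a vector of
#'   concentrations) over a titrant grid (`i2_top`, `i2_steps`) around a
#'   template system, writes one theoretical curve file per sweep value
#'   plus an amplitude-versus-parameter table, and returns that table.
#' @export
run_simulate_theory <- function(config) {
  config <- .load_config(config)
  sweep <- config$sweep %||% "kd1"
  if (!sweep %in% c("kd1", "i1")) stop("sweep must be 'kd1' or 'i1'")
  values <- parse_conc(config$sweep_values)
  if (length(values) == 0L) stop("sweep_values must be non-empty")
  template <- .config_system(config$system)
  top <- parse_conc(config$i2_top %||% "1uM")
  steps <- config$i2_steps %||% 17L
  grid <- sort(top / 2^(seq_len(steps) - 1L))

  rows <- lapply(seq_along(values), function(i) {
    sys <- template
    if (sweep == "kd1") sys$kd1 <- values[i] else sys$i1_total <- values[i]
    curve <- simulate_binding_curve(sys, grid)
    if (!is.null(config$out)) {
      dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
      write_theoretical_curve(curve, file.path(
        config$out, sprintf("theory_%s_%02d.tsv", sweep, i)))
    }
    data.frame(sweep = sweep, value_M = values[i],
               amplitude = theoretical_amplitude(curve))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(config$out)) {
    utils::write.table(tab, file.path(config$out, "amplitude_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    .write_manifest(config$out, config)
  }
  invisible(tab)
}

.curve_from_traces <- function(trace_paths, background_path, e_total,
                               curve_id) {
  if (is.null(background_path)) {
    stop("trace input requires a background trace file")
  }
  if (!file.exists(background_path)) {
    stop("background trace file not found: ", background_path)
  }
  bg <- read_trace(background_path)
  pts <- do.call(rbind, lapply(trace_paths, function(p) {
    compute_depletion(subtract_background(read_trace(p), bg))
  }))
  aggregate_replicates(pts, e_total = e_total, curve_id = curve_id)
}

#' @rdname pipeline
#' @details `run_amplitude` runs the amplitude workflow end to end. Each
#'   entry of `config$samples` is a list with an `id` and either
#'   `curve_file` (curve-level input; trace stages skipped) or
#'   `trace_files` plus `background_file` (trace-level input:
#'   background-subtract, depletion, aggregate). All sample curves are
#'   baseline-aligned together, then each is fitted with
#'   [fit_amplitude()]. Requires `config$e_total` unless curve files
#'   carry it.
#' @export
run_amplitude <- function(config) {
  config <- .load_config(config)
  samples <- config$samples
  if (is.null(samples) || length(samples) == 0L) stop("no samples in config")
  curves <- lapply(samples, function(s) {
    if (!is.null(s$curve_file)) {
      cv <- read_binding_curve(s$curve_file)
      attr(cv, "curve_id") <- s$id %||% attr(cv, "curve_id")
      cv
    } else if (!is.null(s$trace_files)) {
      .curve_from_traces(s$trace_files, s$background_file,
                         e_total = config$e_total,
                         curve_id = s$id %||% "sample")
    } else {
      stop("sample '", s$id %||% "?", "': need curve_file or trace_files")
    }
  })
  aligned <- align_baselines(curves, reference = config$reference %||% NULL)
  fits <- lapply(aligned, function(cv) {
    fit_amplitude(cv, e_total = config$e_total %||% attr(cv, "e_total"))
  })
  report <- lapply(fits, function(f) {
    list(id = f$curve_id, A = f$a, t = f$t, KD_M = f$kd,
         A_se = f$a_se, t_se = f$t_se, KD_se_M = f$kd_se,
         converged = f$converged, kd_identifiable = f$kd_identifiable,
         weighted = f$weighted)
  })
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out, "amplitude_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_manifest(config$out, config)
  }
  invisible(list(fits = fits, curves = aligned, report = report))
}

#' @rdname pipeline
#' @details `run_kd` runs the dissociation-constant workflow:
#'   `config$curve_files` (or in-memory `curves`) are baseline-aligned,
#'   normalized to the 0-1 bound-fraction scale (with a notice if they
#'   were not already normalized), and globally fitted with
#'   [global_fit_kd()]. A single curve is allowed with a warning, since
#'   a global fit wants at least three replicates.
#' @export
run_kd <- function(config) {
  config <- .load_config(config)
  curves <- config$curves
  if (is.null(curves)) {
    if (is.null(config$curve_files)) stop("need curve_files or curves")
    curves <- lapply(config$curve_files, read_binding_curve)
  }
  if (length(curves) < 3L) {
    warning("global fit of fewer than three replicate curves")
  }
  if (!all(vapply(curves, function(cv) isTRUE(attr(cv, "normalized")),
                  logical(1)))) {
    message("normalizing input curves to the 0-1 bound-fraction scale")
    curves <- align_baselines(curves)
    curves <- lapply(curves, normalize_curve)
  }
  fit <- global_fit_kd(curves, e_total = config$e_total %||% NULL)
  report <- list(KD_M = fit$kd, KD_sd_M = fit$kd_sd,
                 n_curves = fit$n_curves, converged = fit$converged)
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out, "kd_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_manifest(config$out, config)
  }
  invisible(fit)
}

#' @rdname pipeline
#' @details `run_cohort` compares two amplitude samples
#'   (`config$values_a`, `config$values_b`, or a `generate` block passed
#'   to [generate_cohort()]) with [compare_groups()] and reports the
#'   medians, U and two-sided p-value.
#' @export
run_cohort <- function(config) {
  config <- .load_config(config)
  if (!is.null(config$generate)) {
    gen <- do.call(generate_cohort, config$generate)
    a <- gen$high; b <- gen$low
  } else {
    a <- config$values_a; b <- config$values_b
  }
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  cmp <- compare_groups(a, b)
  report <- list(U = cmp$u, p_value = cmp$p_value, method = cmp$method,
                 median_a = cmp$median_a, median_b = cmp$median_b,
                 n_a = cmp$n_a, n_b = cmp$n_b)
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out, "cohort.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_manifest(config$out, config)
  }
  invisible(cmp)
}

#' @rdname pipeline
#' @details `run_generate` writes a synthetic dataset to disk: per
#'   experiment one curve file, plus `ground_truth.json`. Config blocks:
#'   `design` (see [assay_design()]; or `assay = "amplitude"`/`"kd"`
#'   with a `seed`), `system` (the truth), `signal`, `vary`.
#' @export
run_generate <- function(config) {
  config <- .load_config(config)
  if (is.null(config$out)) stop("generate workflow requires config$out")
  design <- if (!is.null(config$design)) {
    do.call(assay_design, config$design)
  } else if (identical(config$assay, "kd")) {
    kd_assay_design(seed = config$seed %||% 1L)
  } else {
    amplitude_assay_design(seed = config$seed %||% 1L)
  }
  truth <- .config_system(config$system)
  signal <- .config_signal(config$signal)
  ds <- generate_binding_dataset(design, truth, signal,
                                 vary = config$vary %||% "i2")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  curves <- dataset_curves(ds)
  paths <- vapply(seq_along(curves), function(i) {
    p <- file.path(config$out, sprintf("curve_exp%d.tsv", i))
    write_binding_curve(curves[[i]], p)
    p
  }, character(1))
  gt <- ds$truth
  gt$system <- unclass(gt$system); gt$design <- unclass(gt$design)
  gt$signal <- unclass(gt$signal)
  jsonlite::write_json(gt, file.path(config$out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  .write_manifest(config$out, config)
  invisible(list(dataset = ds, curve_files = paths))
}
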