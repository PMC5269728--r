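# End-to-end orchestration: configuration, per-record processing, report
# assembly, and the command-line entry point.

.config_defaults <- function() {
  list(baseline_window = c(730, 750),
       peak_method = "template",
       point_window = c(0.20, 0.80),
       point_window_fallback = c(0.05, 0.95),
       n_primary = 20L,
       n_secondary = 50L,
       qc_thresholds = list(density = 0.01, limb_sd = 12, method_diff = 6),
       bleach_peak_drop = 0.5,
       bleach_shortwave_max = 420,
       class_boundaries = c(uvs = 420, sws = 475, mws = 530),
       tangent_n = 5L,
       df_method = "satterthwaite",
       alpha = 0.05,
       beta = TRUE,
       normalize_mode = "peak",
       cone_ratios = c(UVS = 1, SWS = 1, MWS = 1, LWS = 1),
       droplet_b_mid = 0.04,
       droplet_mid_offset = 15,
       mask_populations = FALSE,
       seed = NULL)
}

#' Pipeline configuration
#'
#' Collects every tunable surfaced by the analysis modules, with the
#' package defaults: baseline window 730-750 nm, primary point-selection
#' window 0.20-0.80 fractional absorbance, 20 primary / 50 secondary
#' points, the strict QC thresholds (density > 0.01 OD, limb SD < 12 nm,
#' method difference < 6 nm), Satterthwaite denominator df, peak-1 curve
#' normalisation and unit cone ratios. Unknown keys are rejected so typos
#' cannot silently fall back to defaults. The resolved configuration is
#' written beside every pipeline run.
#'
#' @param ... Overrides of the defaults, by name.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad) || is.null(names(ov)) || any(!nzchar(names(ov))))
      stop(sprintf("unknown configuration keys: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    cfg[names(ov)] <- ov
  }
  stopifnot(length(cfg$baseline_window) == 2L,
            cfg$point_window[1] >= 0, cfg$point_window[2] <= 1,
            cfg$point_window[1] < cfg$point_window[2],
            cfg$n_primary >= 2L, cfg$n_secondary >= 2L,
            cfg$qc_thresholds$density > 0,
            cfg$df_method %in% c("satterthwaite", "containment"),
            cfg$normalize_mode %in% c("peak", "ratio", "none"))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Process a set of MSP records into a per-cell results table
#'
#' Runs [estimate_lambda_max()] on every record, assigns a pigment class
#' from the estimate and the putative morphology label, and collects the
#' QC verdicts. With `config$mask_populations = TRUE`, estimation runs on
#' records whose population and bird identity have been replaced by opaque
#' codes (blind processing); the metadata are re-attached to the finished
#' estimates, which cannot depend on them.
#'
#' @param records List of `msp_record` objects.
#' @param config A [pipeline_config()].
#' @return A data.frame with one row per record: identifiers, all estimate
#'   fields, `pigment_class`, `qc_passed`, `qc_regime`, `qc_failed`
#'   (comma-separated failed criteria).
#' @export
process_records <- function(records, config = pipeline_config()) {
  est_input <- records
  if (isTRUE(config$mask_populations)) {
    est_input <- lapply(seq_along(records), function(i) {
      r <- records[[i]]
      r$population <- "masked"
      r$bird_id <- sprintf("masked_%04d", i)
      r
    })
  }
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    est <- estimate_lambda_max(est_input[[i]], config = config)
    morph <- if (r$putative_class == "rod") "rod"
    else if (r$putative_class %in% c("LWS", "MWS", "SWS", "UVS"))
      "single cone"
    else NULL
    cls <- if (is.finite(est$lambda_max_primary) &&
               est$lambda_max_primary >= 330 &&
               est$lambda_max_primary <= 620)
      classify_pigment(est$lambda_max_primary, morphology = morph,
                       boundaries = config$class_boundaries)
    else "unknown"
    failed <- est$qc$criteria$criterion[!est$qc$criteria$pass]
    data.frame(cell_id = r$cell_id, bird_id = r$bird_id,
               population = r$population,
               putative_class = r$putative_class,
               pigment_class = cls,
               lambda_max_primary = est$lambda_max_primary,
               sd_right_limb = est$sd_right_limb,
               lambda_max_secondary = est$lambda_max_secondary,
               method_difference = est$method_difference,
               transverse_density = est$transverse_density,
               n_points_primary = est$n_points_primary,
               n_points_secondary = est$n_points_secondary,
               bleached = est$bleached,
               qc_passed = est$qc$passed,
               qc_regime = est$qc$regime,
               qc_failed = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole chain on a study (in memory or read from a
#' directory): per-cell lambda_max estimation with QC, droplet lambda_cut
#' measurement, the population comparison report, and per-population eye
#' models. The run is deterministic given its inputs and configuration;
#' a QC log records every excluded record and why.
#'
#' @param study An `msp_study` (from [generate_study()] or [read_study()])
#'   or a path to a study directory.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; outputs and the resolved config are
#'   written there via [write_pipeline_outputs()].
#' @return A list: `cells`, `droplets`, `report`, `eye_models`, `qc_log`,
#'   `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(study)) study <- read_study(study)
  cells <- process_records(study$records, config = config)
  droplets <- NULL
  if (length(study$droplet_records))
    droplets <- measure_droplets(study$droplet_records,
                                 tangent_n = config$tangent_n)
  report <- NULL
  if (length(unique(cells$population)) >= 2L)
    report <- comparison_report(cells, droplet_results = droplets,
                                df_method = config$df_method,
                                alpha = config$alpha)
  eye <- NULL
  if (!is.null(report) && !is.null(report$droplets))
    eye <- tryCatch(
      suppressWarnings(population_eye_models(
        report, cone_ratios = config$cone_ratios,
        normalize = config$normalize_mode,
        b_mid = config$droplet_b_mid,
        mid_offset = config$droplet_mid_offset)),
      error = function(e) NULL)
  qc_log <- cells[!cells$qc_passed,
                  c("cell_id", "bird_id", "population", "putative_class",
                    "qc_regime", "qc_failed")]
  result <- list(cells = cells, droplets = droplets, report = report,
                 eye_models = eye, qc_log = qc_log,
                 config = unclass(config))
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# --- command line interface ------------------------------------------------

.cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument: %s", a), call. = FALSE)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      flags[[key]] <- TRUE
      i <- i + 1L
    }
  }
  flags
}

.cli_need <- function(flags, key) {
  if (is.null(flags[[key]]))
    stop(sprintf("missing required flag --%s", key), call. = FALSE)
  flags[[key]]
}

#' Command-line entry point
#'
#' Subcommands: `generate` (write a synthetic study),
#' `estimate` (per-cell lambda_max table from a manifest), `droplets`
#' (lambda_cut table), `compare` (comparison report), `eyemodel`
#' (sensitivity curves) and `run-all` (everything). Invoked by the
#' `inst/cli/mspfit` script; callable in-process for testing.
#'
#' @param args Character vector of command-line arguments, e.g.
#'   `c("run-all", "--manifest", dir, "--out", outdir)`.
#' @return Invisibly, the result of the subcommand.
#' @export
mspfit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop(paste("usage: mspfit <generate|estimate|droplets|compare|",
               "eyemodel|run-all> [--flags]", sep = ""), call. = FALSE)
  cmd <- args[[1L]]
  flags <- .cli_parse_flags(args[-1L])
  cfg_flags <- list()
  if (isTRUE(flags[["mask-populations"]]))
    cfg_flags$mask_populations <- TRUE
  config <- do.call(pipeline_config, cfg_flags)
  out <- switch(
    cmd,
    "generate" = {
      seed <- as.integer(.cli_need(flags, "seed"))
      study <- generate_study(study_design(), seed = seed)
      write_study(study, .cli_need(flags, "out"))
      study
    },
    "estimate" = {
      study <- read_study(.cli_need(flags, "manifest"))
      cells <- process_records(study$records, config = config)
      dir.create(.cli_need(flags, "out"), recursive = TRUE,
                 showWarnings = FALSE)
      utils::write.table(cells,
                         file.path(flags[["out"]], "cell_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(unclass(config),
                           file.path(flags[["out"]], "config.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      cells
    },
    "droplets" = {
      study <- read_study(.cli_need(flags, "manifest"))
      tab <- measure_droplets(study$droplet_records,
                              tangent_n = config$tangent_n)
      dir.create(.cli_need(flags, "out"), recursive = TRUE,
                 showWarnings = FALSE)
      utils::write.table(tab,
                         file.path(flags[["out"]], "droplet_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    },
    "compare" = {
      cells <- utils::read.delim(.cli_need(flags, "cells"))
      drops <- if (!is.null(flags[["droplets"]]))
        utils::read.delim(flags[["droplets"]]) else NULL
      rep <- comparison_report(cells, droplet_results = drops,
                               df_method = config$df_method,
                               alpha = config$alpha)
      dir.create(.cli_need(flags, "out"), recursive = TRUE,
                 showWarnings = FALSE)
      write_pipeline_outputs(list(report = rep, config = unclass(config)),
                             flags[["out"]])
      rep
    },
    "eyemodel" = {
      # rebuild the report from tables, then evaluate curves
      cells <- utils::read.delim(.cli_need(flags, "cells"))
      drops <- utils::read.delim(.cli_need(flags, "droplets"))
      rep <- comparison_report(cells, droplet_results = drops,
                               df_method = config$df_method,
                               alpha = config$alpha)
      eye <- population_eye_models(rep, cone_ratios = config$cone_ratios,
                                   normalize = config$normalize_mode)
      dir.create(.cli_need(flags, "out"), recursive = TRUE,
                 showWarnings = FALSE)
      utils::write.table(eye$curves,
                         file.path(flags[["out"]], "eye_model_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      eye
    },
    "run-all" = {
      run_pipeline(.cli_need(flags, "manifest"), config = config,
                   out_dir = .cli_need(flags, "out"))
    },
    stop(sprintf("unknown subcommand: %s", cmd), call. = FALSE))
  invisible(out)
}
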