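# Plain-text input/output: one tab-delimited file per scan (wavelength_nm,
# absorbance_od), a manifest table per study, and report writers.

#' Write a spectral scan to delimited text
#'
#' @param scan An `msp_scan`.
#' @param path Output path; tab-delimited with header
#'   `wavelength_nm  absorbance_od`.
#' @return The path, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "msp_scan"))
  utils::write.table(
    data.frame(wavelength_nm = scan$wavelengths,
               absorbance_od = scan$absorbance),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectral scan from delimited text
#'
#' Validates the header and the 2 nm grid on read.
#'
#' @param path Scan file with columns `wavelength_nm`, `absorbance_od`.
#' @param direction Scan direction, `"outward"` or `"return"`.
#' @return An `msp_scan`.
#' @export
read_scan <- function(path, direction = c("outward", "return")) {
  direction <- match.arg(direction)
  d <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("wavelength_nm", "absorbance_od") %in% names(d)))
    stop(sprintf("%s: expected columns wavelength_nm, absorbance_od", path),
         call. = FALSE)
  spectral_scan(d$wavelength_nm, d$absorbance_od, direction = direction)
}

#' Write a synthetic study to a directory
#'
#' Emits the exact formats the readers consume: `cells/` and `droplets/`
#' scan files, `manifest.tsv`, `droplet_manifest.tsv`, the ground-truth
#' tables, and `design.json` echoing the design and seed.
#'
#' @param study An `msp_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "msp_study"))
  cells_dir <- file.path(dir, "cells")
  drops_dir <- file.path(dir, "droplets")
  dir.create(cells_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(drops_dir, recursive = TRUE, showWarnings = FALSE)
  man <- lapply(study$records, function(r) {
    of <- file.path("cells", paste0(r$cell_id, "_outward.tsv"))
    rf <- file.path("cells", paste0(r$cell_id, "_return.tsv"))
    write_scan(r$outward, file.path(dir, of))
    write_scan(r$return_scan, file.path(dir, rf))
    pf <- ""
    if (!is.null(r$post_bleach)) {
      pf <- file.path("cells", paste0(r$cell_id, "_postbleach.tsv"))
      write_scan(r$post_bleach, file.path(dir, pf))
    }
    data.frame(cell_id = r$cell_id, bird_id = r$bird_id,
               population = r$population,
               putative_class = r$putative_class,
               outward_file = of, return_file = rf, postbleach_file = pf,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, man), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dman <- lapply(study$droplet_records, function(r) {
    f <- file.path("droplets", paste0(r$droplet_id, ".tsv"))
    utils::write.table(
      data.frame(wavelength_nm = r$spectrum$wavelengths,
                 absorbance_od = r$spectrum$mean_absorbance),
      file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    data.frame(droplet_id = r$droplet_id, bird_id = r$bird_id,
               population = r$population, droplet_type = r$droplet_type,
               spectrum_file = f, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, dman),
                     file.path(dir, "droplet_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth_cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth_droplets,
                     file.path(dir, "truth_droplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = study$seed,
                            n_birds = as.list(study$design$n_birds),
                            design = study$design[
                              setdiff(names(study$design),
                                      c("pigment_classes",
                                        "droplet_classes", "n_birds"))],
                            pigment_classes = study$design$pigment_classes,
                            droplet_classes = study$design$droplet_classes),
                       file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory back into records
#'
#' @param dir Directory written by [write_study()] (or assembled by hand in
#'   the same layout).
#' @return An `msp_study`-like list with `records` and `droplet_records`
#'   (ground truth tables included when present).
#' @export
read_study <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path))
    stop(sprintf("no manifest.tsv under %s", dir), call. = FALSE)
  man <- utils::read.delim(man_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "bird_id", "population", "putative_class",
            "outward_file", "return_file")
  if (!all(need %in% names(man)))
    stop(sprintf("manifest.tsv: missing columns %s",
                 paste(setdiff(need, names(man)), collapse = ", ")),
         call. = FALSE)
  records <- lapply(seq_len(nrow(man)), function(i) {
    pb <- NULL
    if (!is.null(man$postbleach_file) && nzchar(man$postbleach_file[i]) &&
        !is.na(man$postbleach_file[i]))
      pb <- read_scan(file.path(dir, man$postbleach_file[i]), "outward")
    msp_record(man$cell_id[i], man$bird_id[i], man$population[i],
               man$putative_class[i],
               read_scan(file.path(dir, man$outward_file[i]), "outward"),
               read_scan(file.path(dir, man$return_file[i]), "return"),
               post_bleach = pb)
  })
  names(records) <- man$cell_id
  droplets <- list()
  dman_path <- file.path(dir, "droplet_manifest.tsv")
  if (file.exists(dman_path)) {
    dman <- utils::read.delim(dman_path, stringsAsFactors = FALSE)
    droplets <- lapply(seq_len(nrow(dman)), function(i) {
      d <- utils::read.delim(file.path(dir, dman$spectrum_file[i]))
      merged <- structure(list(wavelengths = d$wavelength_nm,
                               mean_absorbance = d$absorbance_od,
                               baseline = NA_real_,
                               fractional = rep(NA_real_, nrow(d)),
                               transverse_density = NA_real_,
                               degenerate = NA),
                          class = "msp_merged")
      merged <- suppressWarnings(normalize_spectrum(merged,
                                                    peak_method = "max"))
      droplet_record(dman$droplet_id[i], dman$bird_id[i],
                     dman$population[i], dman$droplet_type[i], merged)
    })
    names(droplets) <- dman$droplet_id
  }
  truth_cells <- NULL
  if (file.exists(file.path(dir, "truth_cells.tsv")))
    truth_cells <- utils::read.delim(file.path(dir, "truth_cells.tsv"))
  truth_droplets <- NULL
  if (file.exists(file.path(dir, "truth_droplets.tsv")))
    truth_droplets <- utils::read.delim(file.path(dir, "truth_droplets.tsv"))
  structure(list(records = records, droplet_records = droplets,
                 truth_cells = truth_cells, truth_droplets = truth_droplets,
                 design = NULL, seed = NA_integer_),
            class = "msp_study")
}

#' Write pipeline outputs to a directory
#'
#' Writes the per-cell table, droplet table, comparison report (delimited
#' text plus JSON with full variance components and df metadata), eye model
#' curves and the resolved configuration.
#'
#' @param result A list from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) if (!is.null(x))
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(result$cells, "cell_results.tsv")
  wt(result$droplets, "droplet_results.tsv")
  if (!is.null(result$report)) {
    wt(result$report$pigments, "pigment_comparison.tsv")
    wt(result$report$droplets, "droplet_comparison.tsv")
    jsonlite::write_json(
      list(pigments = result$report$pigments,
           droplets = result$report$droplets,
           meta = result$report$meta),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  if (!is.null(result$eye_models) && !is.null(result$eye_models$curves))
    wt(result$eye_models$curves, "eye_model_curves.tsv")
  wt(result$qc_log, "qc_log.tsv")
  jsonlite::write_json(result$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
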