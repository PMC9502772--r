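# End-to-end orchestration: read -> normalize -> score -> summarize -> call
# -> group -> report, plus the simulate and reproduce entry points used by
# the command-line interface.

qc_error <- function(qc) {
  structure(class = c("macroscreen_qc_error", "error", "condition"),
            list(message = paste0(
              "control QC failed (EIPA ",
              if (qc$eipa_pass) "pass" else "FAIL", ", Torin1 ",
              if (qc$torin1_pass) "pass" else "FAIL",
              ") and qc_strict is TRUE"),
              call = NULL, qc = qc))
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[macroscreen] ", fmt), ...))
}

#' Run the full screen analysis
#'
#' Executes every stage on a measurement + annotation pair: per-plate DMSO
#' normalization, dose-response AUC scoring of the library, screen-wide
#' mean +/- SD thresholds, hit calling, target grouping, and control QC.
#' When `out_dir` is given, writes the report bundle (`summary.json`,
#' `auc_table.csv`, `hits.csv`, `target_groups.csv`) plus the intermediate
#' `viability.csv`, all re-readable by the package's own readers.
#'
#' @param measurements Measurement data.frame or path to `measurements.csv`.
#' @param annotations Annotation data.frame or path to `annotations.csv`.
#' @param out_dir Report directory, or `NULL` to skip writing.
#' @param grid Library concentration grid.
#' @param threshold_multiplier Hit threshold width in SD units.
#' @param sd_flavor `"sample"` or `"population"`.
#' @param qc_strict Abort (classed condition `macroscreen_qc_error`) when a
#'   control gate fails; otherwise the failure is recorded in the report and
#'   logged.
#' @param verbose Log one line per stage with record counts.
#' @return List with `viability`, `auc_table`, `summary`, `hits`,
#'   `target_groups`, `qc`.
#' @export
run_screen <- function(measurements, annotations, out_dir = NULL,
                       grid = default_grid(), threshold_multiplier = 1,
                       sd_flavor = "sample", qc_strict = FALSE,
                       verbose = TRUE) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  measurements <- validate_measurements(measurements)
  annotations <- validate_annotations(annotations)
  stage_log(verbose, "read: %d wells, %d annotated compounds",
            nrow(measurements), nrow(annotations))

  viability <- relative_viability(measurements)
  stage_log(verbose, "normalize: %d viability values over %d plates",
            nrow(viability), length(unique(viability$plate_id)))

  qc <- qc_controls(viability)
  stage_log(verbose, "qc: EIPA %s, Torin1 %s",
            if (qc$eipa_pass) "pass" else "FAIL",
            if (qc$torin1_pass) "pass" else "FAIL")
  if (qc_strict && !qc$pass) stop(qc_error(qc))

  auc_table <- score_screen(viability, grid = grid)
  stage_log(verbose, "score: %d compounds on a %d-point grid",
            nrow(auc_table), length(grid))

  summary <- summarize_screen(auc_table, multiplier = threshold_multiplier,
                              sd_flavor = sd_flavor)
  stage_log(verbose,
            "summarize: mean AUC %.3f, SD %.3f, thresholds (%.3f, %.3f)",
            summary$mean_auc, summary$sd_auc, summary$lower_threshold,
            summary$upper_threshold)

  hits <- call_hits(auc_table, summary)
  stage_log(verbose, "call: %d decrease, %d increase, %d none",
            sum(hits$direction == "DECREASE"),
            sum(hits$direction == "INCREASE"),
            sum(hits$direction == "NONE"))

  target_groups <- group_hits(hits, annotations)
  stage_log(verbose, "group: %d (target, direction) groups",
            nrow(target_groups))

  results <- list(viability = viability, auc_table = auc_table,
                  summary = summary, hits = hits,
                  target_groups = target_groups, qc = qc)
  if (!is.null(out_dir)) {
    write_report(results, out_dir)
    write_viability(viability, file.path(out_dir, "viability.csv"))
    stage_log(verbose, "report: written to %s", out_dir)
  }
  results
}

#' Generate and write a synthetic screen file set
#'
#' Writes `measurements.csv`, `annotations.csv`, `truth.csv` and a
#' `manifest.json` carrying the seed, the configuration, and MD5 checksums
#' of the three files (so a repeated seed is detectable as an identical
#' manifest).
#'
#' @param config A [screen_config()].
#' @param effects Planted effects; default [planted_effects()] sized to the
#'   config.
#' @param out_dir Output directory; created if absent.
#' @return The directory, invisibly.
#' @export
simulate_screen <- function(config = screen_config(),
                            effects = planted_effects(config$n_compounds),
                            out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  screen <- generate_screen(config, effects)
  write_measurements(screen$measurements, file.path(out_dir, "measurements.csv"))
  write_annotations(screen$annotations, file.path(out_dir, "annotations.csv"))
  write_table_exact(screen$truth, file.path(out_dir, "truth.csv"))
  files <- c("measurements.csv", "annotations.csv", "truth.csv")
  manifest <- list(
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "grid")],
    grid = as.numeric(config$grid),
    md5 = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Simulate then analyze with one seed
#'
#' Chains [simulate_screen()] and [run_screen()] for a fully reproducible
#' end-to-end run: the generated file set lands in `out_dir/simulated`, the
#' report bundle in `out_dir/report`.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param config Optional [screen_config()]; its seed is overridden by
#'   `seed`.
#' @param effects Planted effects (default [planted_effects()]).
#' @param ... Passed to [run_screen()].
#' @return The [run_screen()] result, invisibly.
#' @export
reproduce_screen <- function(seed, out_dir, config = NULL, effects = NULL,
                             ...) {
  if (is.null(config)) config <- screen_config(seed = seed)
  else config$seed <- as.integer(seed)
  if (is.null(effects)) effects <- planted_effects(config$n_compounds)
  sim_dir <- file.path(out_dir, "simulated")
  simulate_screen(config, effects, sim_dir)
  run_screen(file.path(sim_dir, "measurements.csv"),
             file.path(sim_dir, "annotations.csv"),
             out_dir = file.path(out_dir, "report"),
             grid = config$grid, ...)
}
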