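# Domain model: well measurements, compound annotations, concentration grids,
# and the CSV dialects used for every table the pipeline reads or writes.

#' Condition labels recognised by the pipeline
#'
#' `GLN_STARVED` is glutamine-free medium, `GLN_STARVED_BSA` the same medium
#' supplemented with 5\% albumin (the macropinocytosis-dependent condition the
#' screen runs in), and `COMPLETE` is glutamine-replete medium.
#'
#' @return Character vector of the three condition labels.
#' @export
screen_conditions <- function() {
  c("GLN_STARVED", "GLN_STARVED_BSA", "COMPLETE")
}

#' Sentinel compound identifiers
#'
#' Vehicle wells carry compound id `"DMSO"`; the per-plate control series are
#' `"EIPA"` (macropinocytosis inhibitor) and `"TORIN1"` (mTOR inhibitor that
#' enhances macropinocytosis-dependent growth).
#'
#' @return Named character vector with elements `vehicle`, `inhibitor`,
#'   `enhancer`.
#' @export
sentinel_ids <- function() {
  c(vehicle = "DMSO", inhibitor = "EIPA", enhancer = "TORIN1")
}

compound_roles <- function() {
  c("LIBRARY", "VEHICLE", "CONTROL_INHIBITOR", "CONTROL_ENHANCER")
}

measurement_columns <- function() {
  c("plate_id", "well", "compound_id", "concentration_um",
    "condition", "replicate", "luminescence")
}

annotation_columns <- function() {
  c("compound_id", "name", "targets", "role")
}

#' Default library concentration grid
#'
#' The four library treatment concentrations, in micromolar, produced by
#' diluting 1/5/25/125 uM intermediate stocks 10 uL into 40 uL of medium.
#'
#' @return A `concentration_grid` of (0.2, 1, 5, 25) uM.
#' @export
default_grid <- function() {
  concentration_grid(c(0.2, 1, 5, 25))
}

#' EIPA and Torin1 control dose series
#'
#' Final on-plate concentrations of the per-plate control compounds:
#' EIPA at 0.8/4/20/100 uM and Torin1 at 0.04/0.2/1/5 uM.
#'
#' @return Named list of two `concentration_grid`s, `EIPA` and `TORIN1`.
#' @export
control_grids <- function() {
  list(EIPA = concentration_grid(c(0.8, 4, 20, 100)),
       TORIN1 = concentration_grid(c(0.04, 0.2, 1, 5)))
}

#' Construct a concentration grid
#'
#' A strictly increasing vector of positive micromolar concentrations. All
#' AUC scoring anchors the grid at the implicit vehicle point
#' (0 uM, relative viability 1).
#'
#' @param levels Numeric vector of concentrations in uM.
#' @return Numeric vector with class `concentration_grid`.
#' @export
concentration_grid <- function(levels) {
  levels <- as.numeric(levels)
  if (length(levels) < 1L || anyNA(levels)) {
    stop("concentration grid must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  if (any(levels <= 0)) {
    stop("concentration grid levels must all be > 0 uM", call. = FALSE)
  }
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("concentration grid levels must be strictly increasing", call. = FALSE)
  }
  structure(levels, class = "concentration_grid")
}

as_concentration_grid <- function(grid) {
  if (inherits(grid, "concentration_grid")) grid else concentration_grid(grid)
}

# ---- validation ------------------------------------------------------------

#' Validate a table of well measurements
#'
#' Checks the long-format measurement table invariants: required columns,
#' non-negative luminescence and concentration, vehicle wells at 0 uM,
#' recognised condition labels, positive integer replicates, and uniqueness
#' of (plate_id, well). Errors name the first offending row.
#'
#' @param measurements A data.frame of well measurements.
#' @return The validated data.frame, invisibly unchanged apart from column
#'   type coercion.
#' @export
validate_measurements <- function(measurements) {
  measurements <- as.data.frame(measurements)
  missing_cols <- setdiff(measurement_columns(), names(measurements))
  if (length(missing_cols)) {
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  measurements$plate_id <- as.character(measurements$plate_id)
  measurements$well <- as.character(measurements$well)
  measurements$compound_id <- as.character(measurements$compound_id)
  measurements$condition <- as.character(measurements$condition)
  measurements$concentration_um <- as.numeric(measurements$concentration_um)
  measurements$replicate <- as.integer(measurements$replicate)
  measurements$luminescence <- as.numeric(measurements$luminescence)

  fail_row <- function(what, idx) {
    stop(sprintf("invalid measurement table: %s at row %d", what, idx[1L]),
         call. = FALSE)
  }
  bad <- which(!is.finite(measurements$luminescence) |
                 measurements$luminescence < 0)
  if (length(bad)) fail_row("negative or non-numeric luminescence", bad)
  bad <- which(!is.finite(measurements$concentration_um) |
                 measurements$concentration_um < 0)
  if (length(bad)) fail_row("negative or non-numeric concentration", bad)
  bad <- which(measurements$compound_id == sentinel_ids()[["vehicle"]] &
                 measurements$concentration_um != 0)
  if (length(bad)) fail_row("vehicle well with non-zero concentration", bad)
  bad <- which(!measurements$condition %in% screen_conditions())
  if (length(bad)) fail_row("unrecognised condition label", bad)
  bad <- which(is.na(measurements$replicate) | measurements$replicate < 1L)
  if (length(bad)) fail_row("replicate must be a positive integer", bad)
  dup <- which(duplicated(measurements[c("plate_id", "well")]))
  if (length(dup)) fail_row("duplicate (plate_id, well)", dup)
  invisible(measurements)
}

#' Validate a compound annotation table
#'
#' @param annotations A data.frame with columns `compound_id`, `name`,
#'   `targets` (semicolon-joined) and `role`.
#' @return The validated data.frame, invisibly.
#' @export
validate_annotations <- function(annotations) {
  annotations <- as.data.frame(annotations)
  missing_cols <- setdiff(annotation_columns(), names(annotations))
  if (length(missing_cols)) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in annotation_columns()) {
    annotations[[col]] <- as.character(annotations[[col]])
  }
  annotations$targets[is.na(annotations$targets)] <- ""
  dup <- annotations$compound_id[duplicated(annotations$compound_id)]
  if (length(dup)) {
    stop("duplicate compound_id in annotation table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_role <- which(!annotations$role %in% compound_roles())
  if (length(bad_role)) {
    stop(sprintf("unrecognised role %s for compound %s",
                 annotations$role[bad_role[1L]],
                 annotations$compound_id[bad_role[1L]]), call. = FALSE)
  }
  no_target <- annotations$role == "LIBRARY" &
    !nzchar(trimws(annotations$targets))
  if (any(no_target)) {
    stop("LIBRARY compound(s) without annotated target: ",
         paste(annotations$compound_id[no_target], collapse = ", "),
         call. = FALSE)
  }
  invisible(annotations)
}

#' Split a semicolon-joined target field into target names
#'
#' @param targets Character vector of semicolon-joined target strings.
#' @return List of character vectors, one per input element.
#' @export
split_targets <- function(targets) {
  lapply(strsplit(as.character(targets), ";", fixed = TRUE),
         function(x) trimws(x[nzchar(trimws(x))]))
}

# ---- readers ---------------------------------------------------------------

read_table_checked <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
}

#' Read a long-format measurement table
#'
#' Parses `measurements.csv` (comma-separated, header mandatory, one well per
#' row) and validates every invariant; parse failures name the offending row.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame of well measurements.
#' @export
read_measurements <- function(path) {
  validate_measurements(read_table_checked(path))
}

#' Read a compound annotation table
#'
#' @param path Path to `annotations.csv` with columns
#'   `compound_id,name,targets,role` (targets semicolon-joined).
#' @return A validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  validate_annotations(read_table_checked(path))
}

# ---- writers ---------------------------------------------------------------

# CSV numbers are written with 17 significant digits so that a write/read
# cycle reproduces every double bit-exactly.
format_full_precision <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      out <- sprintf("%.17g", df[[col]])
      out[is.na(df[[col]])] <- NA_character_
      df[[col]] <- out
    }
  }
  df
}

write_table_exact <- function(df, path) {
  utils::write.csv(format_full_precision(df), path,
                   row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Write a measurement table
#'
#' @param measurements Validated measurement data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  measurements <- validate_measurements(measurements)
  write_table_exact(measurements[measurement_columns()], path)
}

#' Write a compound annotation table
#'
#' @param annotations Validated annotation data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  write_table_exact(annotations[annotation_columns()], path)
}

#' Write the report bundle of a screen run
#'
#' Writes `summary.json` (screen summary and QC result), `auc_table.csv`,
#' `hits.csv` and `target_groups.csv` into `dir`. All numbers are written at
#' full double precision so that [read_report()] reproduces them bit-exactly.
#'
#' @param results A list with elements `summary` (a `screen_summary`),
#'   `auc_table`, `hits`, `target_groups` (data.frames) and optionally `qc`
#'   (a `qc_result`).
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  stopifnot(is.list(results))
  for (el in c("summary", "auc_table", "hits", "target_groups")) {
    if (is.null(results[[el]])) {
      stop("write_report: results is missing element '", el, "'",
           call. = FALSE)
    }
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create report directory: ", dir, call. = FALSE)
  }
  summary_payload <- list(summary = unclass(results$summary))
  if (!is.null(results$qc)) {
    qc <- results$qc
    summary_payload$qc <- list(
      eipa_pass = qc$eipa_pass, torin1_pass = qc$torin1_pass,
      pass = qc$pass, details = qc$details)
  }
  jsonlite::write_json(summary_payload, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_table_exact(results$auc_table, file.path(dir, "auc_table.csv"))
  write_table_exact(results$hits, file.path(dir, "hits.csv"))
  write_table_exact(results$target_groups, file.path(dir, "target_groups.csv"))
  invisible(dir)
}

#' Read a report bundle back
#'
#' @param dir Directory written by [write_report()].
#' @return List with `summary`, `qc` (or NULL), `auc_table`, `hits`,
#'   `target_groups`.
#' @export
read_report <- function(dir) {
  payload <- jsonlite::read_json(file.path(dir, "summary.json"),
                                 simplifyVector = TRUE)
  list(
    summary = payload$summary,
    qc = payload$qc,
    auc_table = utils::read.csv(file.path(dir, "auc_table.csv"),
                                stringsAsFactors = FALSE),
    hits = utils::read.csv(file.path(dir, "hits.csv"),
                           stringsAsFactors = FALSE),
    target_groups = utils::read.csv(file.path(dir, "target_groups.csv"),
                                    stringsAsFactors = FALSE)
  )
}
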