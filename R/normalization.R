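# Normalization of raw luminescence to per-plate DMSO vehicle wells, and the
# BSA-rescue fold-change comparison with Student's t-test.

#' Relative viability against per-plate DMSO controls
#'
#' Divides every well's luminescence by the mean DMSO luminescence of the same
#' plate and condition. Normalization is strictly per plate and per condition;
#' DMSO wells of any plate therefore average exactly 1 after normalization,
#' and multiplying all luminescence on a plate by a constant leaves every
#' relative viability unchanged.
#'
#' @param measurements Measurement data.frame (validated with
#'   [validate_measurements()]).
#' @return Data.frame with columns `plate_id`, `well`, `compound_id`,
#'   `replicate`, `concentration_um`, `condition`, `viability`.
#' @export
relative_viability <- function(measurements) {
  m <- validate_measurements(measurements)
  vehicle <- sentinel_ids()[["vehicle"]]
  key <- paste(m$plate_id, m$condition, sep = "\r")
  is_veh <- m$compound_id == vehicle
  plates <- unique(key)
  no_vehicle <- setdiff(plates, unique(key[is_veh]))
  if (length(no_vehicle)) {
    stop("plate(s) without DMSO vehicle wells: ",
         paste(sub("\r.*", "", no_vehicle), collapse = ", "), call. = FALSE)
  }
  dmso_mean <- tapply(m$luminescence[is_veh], key[is_veh], mean)
  out <- m[c("plate_id", "well", "compound_id", "replicate",
             "concentration_um", "condition")]
  out$viability <- m$luminescence / as.numeric(dmso_mean[key])
  rownames(out) <- NULL
  out
}

#' Write a viability table
#'
#' Emits `viability.csv` in the documented dialect
#' (`compound_id,replicate,concentration_um,condition,viability`).
#'
#' @param viability Output of [relative_viability()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_viability <- function(viability, path) {
  cols <- c("compound_id", "replicate", "concentration_um", "condition",
            "viability")
  write_table_exact(as.data.frame(viability)[cols], path)
}

fold_change_stat <- function(treated, reference, welch = FALSE) {
  treated <- as.numeric(treated)
  reference <- as.numeric(reference)
  if (length(treated) < 2L || length(reference) < 2L) {
    stop("fold_change requires >= 2 replicates in each group", call. = FALSE)
  }
  fold <- mean(treated) / mean(reference)
  delta <- mean(treated) - mean(reference)
  if (stats::var(treated) == 0 && stats::var(reference) == 0) {
    # zero-variance groups: flag rather than raise
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
    return(list(fold = fold, t_statistic = t_stat, p_value = NA_real_,
                degenerate = TRUE))
  }
  ht <- stats::t.test(treated, reference, var.equal = !welch,
                      alternative = "two.sided")
  list(fold = fold, t_statistic = unname(ht$statistic),
       p_value = ht$p.value, degenerate = FALSE)
}

#' Fold change in viability between two conditions
#'
#' Computes, per group, the fold increase in viability induced by BSA
#' supplementation: mean viability in the treated condition (default
#' `GLN_STARVED_BSA`) divided by the mean in the reference condition (default
#' `GLN_STARVED`), together with a two-sided two-sample Student's t-test on
#' the replicate values. The classical equal-variance test is the default;
#' set `welch = TRUE` for the Welch variant. Zero-variance groups yield a
#' degenerate result (infinite or zero t, `NA` p) flagged in the
#' `degenerate` column instead of an error.
#'
#' @param data Data.frame with a condition column, a numeric value column and
#'   optionally a grouping column (e.g. cell line).
#' @param group Name of the grouping column, or `NULL` for a single group.
#' @param value Name of the numeric value column (default `"viability"`).
#' @param condition Name of the condition column (default `"condition"`).
#' @param treated,reference Condition labels compared (treated / reference).
#' @param welch Use the Welch unequal-variance test instead of Student's.
#' @return Data.frame with columns `group`, `fold`, `t_statistic`, `p_value`,
#'   `n_treated`, `n_reference`, `degenerate`.
#' @export
fold_change <- function(data, group = NULL, value = "viability",
                        condition = "condition",
                        treated = "GLN_STARVED_BSA",
                        reference = "GLN_STARVED", welch = FALSE) {
  data <- as.data.frame(data)
  for (col in c(value, condition, group)) {
    if (!col %in% names(data)) {
      stop("fold_change: column not found: ", col, call. = FALSE)
    }
  }
  groups <- if (is.null(group)) rep("all", nrow(data)) else
    as.character(data[[group]])
  out <- lapply(unique(groups), function(g) {
    d <- data[groups == g, ]
    x <- d[[value]][d[[condition]] == treated]
    y <- d[[value]][d[[condition]] == reference]
    if (length(x) == 0L || length(y) == 0L) {
      stop("fold_change: group '", g, "' lacks one of the two conditions",
           call. = FALSE)
    }
    s <- fold_change_stat(x, y, welch = welch)
    data.frame(group = g, fold = s$fold, t_statistic = s$t_statistic,
               p_value = s$p_value, n_treated = length(x),
               n_reference = length(y), degenerate = s$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
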