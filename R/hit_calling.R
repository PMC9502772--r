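# Screen summary, mean +/- SD hit thresholds, hit classification, and the
# EIPA/Torin1 control quality gates.

#' Screen-wide AUC summary and hit thresholds
#'
#' Mean and standard deviation of the per-compound AUCs over library
#' compounds only (controls and vehicle never enter the statistics), with hit
#' thresholds at mean +/- `multiplier` x SD. Sample SD (n - 1 denominator) is
#' the default; with a 225-compound library the population flavor differs
#' negligibly, but both are exposed.
#'
#' @param auc_table Data.frame with columns `compound_id` and `auc` (output
#'   of [score_screen()]), or a bare numeric vector of AUCs.
#' @param multiplier Threshold width in SD units (default 1).
#' @param sd_flavor `"sample"` (n - 1) or `"population"` (n).
#' @return List of class `screen_summary` with `n_compounds`, `mean_auc`,
#'   `sd_auc`, `lower_threshold`, `upper_threshold`, `multiplier`,
#'   `sd_flavor`.
#' @export
summarize_screen <- function(auc_table, multiplier = 1,
                             sd_flavor = c("sample", "population")) {
  sd_flavor <- match.arg(sd_flavor)
  aucs <- if (is.data.frame(auc_table)) auc_table$auc else as.numeric(auc_table)
  if (length(aucs) < 2L || anyNA(aucs)) {
    stop("summarize_screen requires >= 2 complete AUC values", call. = FALSE)
  }
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0) {
    stop("threshold multiplier must be a single positive number",
         call. = FALSE)
  }
  n <- length(aucs)
  m <- mean(aucs)
  s <- stats::sd(aucs)
  if (sd_flavor == "population") s <- s * sqrt((n - 1) / n)
  structure(list(n_compounds = n, mean_auc = m, sd_auc = s,
                 lower_threshold = m - multiplier * s,
                 upper_threshold = m + multiplier * s,
                 multiplier = multiplier, sd_flavor = sd_flavor),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf(
    "Screen summary: %d compounds, mean AUC %.4g, SD %.4g\n  thresholds: decrease < %.4g, increase > %.4g (mean +/- %g x %s SD)\n",
    x$n_compounds, x$mean_auc, x$sd_auc, x$lower_threshold,
    x$upper_threshold, x$multiplier, x$sd_flavor))
  invisible(x)
}

#' Classify compounds against the screen thresholds
#'
#' Strict inequalities on both sides: AUC below the lower threshold is a
#' `DECREASE` hit (its target is a candidate positive regulator of
#' macropinocytosis-dependent growth), AUC above the upper threshold an
#' `INCREASE` hit (candidate negative regulator); a compound exactly at a
#' threshold is `NONE`. Thresholds are computed once and never recomputed
#' after removing hits.
#'
#' @param auc_table Data.frame with `compound_id` and `auc`.
#' @param summary A `screen_summary` from [summarize_screen()].
#' @return Data.frame with `compound_id`, `auc`, `direction`
#'   (DECREASE/NONE/INCREASE) and `regulator_class`
#'   (POSITIVE_REGULATOR_TARGET/NONE/NEGATIVE_REGULATOR_TARGET).
#' @export
call_hits <- function(auc_table, summary) {
  stopifnot(inherits(summary, "screen_summary"))
  auc_table <- as.data.frame(auc_table)
  direction <- rep("NONE", nrow(auc_table))
  direction[auc_table$auc < summary$lower_threshold] <- "DECREASE"
  direction[auc_table$auc > summary$upper_threshold] <- "INCREASE"
  regulator_class <- c(DECREASE = "POSITIVE_REGULATOR_TARGET",
                       NONE = "NONE",
                       INCREASE = "NEGATIVE_REGULATOR_TARGET")[direction]
  data.frame(compound_id = auc_table$compound_id, auc = auc_table$auc,
             direction = direction, regulator_class = unname(regulator_class),
             stringsAsFactors = FALSE)
}

#' Control-compound quality gates
#'
#' Checks that the per-plate control series behaved as the
#' macropinocytosis-dependent condition requires: EIPA must inhibit at its
#' top concentration (mean viability at the highest level below
#' `inhibition_fraction` of the mean at the lowest level, default 0.5), and
#' Torin1 must enhance in its mid-dose window (mean viability above
#' `enhancement_factor` x vehicle, default 1.2, at either of the two
#' concentrations below its top level; the top Torin1 dose is allowed to kill).
#'
#' @param viability Long viability table containing the control wells.
#' @param grids Named list of control dose series (default [control_grids()]).
#' @param inhibition_fraction EIPA gate fraction.
#' @param enhancement_factor Torin1 gate factor over vehicle (vehicle = 1 by
#'   normalization).
#' @return List of class `qc_result`: `eipa_pass`, `torin1_pass`, `pass`,
#'   and `details` (mean viability per control and concentration).
#' @export
qc_controls <- function(viability, grids = control_grids(),
                        inhibition_fraction = 0.5,
                        enhancement_factor = 1.2) {
  v <- as.data.frame(viability)
  ids <- sentinel_ids()
  series_means <- function(id, grid) {
    lv <- as.numeric(grid)
    d <- v[v$compound_id == id, ]
    mv <- vapply(lv, function(conc) {
      x <- d$viability[d$concentration_um == conc]
      if (length(x) == 0L) NA_real_ else mean(x)
    }, numeric(1))
    if (anyNA(mv)) {
      stop(sprintf("qc_controls: %s series incomplete (missing %g uM)",
                   id, lv[which(is.na(mv))[1L]]), call. = FALSE)
    }
    mv
  }
  eipa <- series_means(ids[["inhibitor"]], grids$EIPA)
  torin <- series_means(ids[["enhancer"]], grids$TORIN1)
  n_t <- length(torin)
  eipa_pass <- eipa[length(eipa)] < inhibition_fraction * eipa[1L]
  torin1_pass <- any(torin[c(n_t - 2L, n_t - 1L)] > enhancement_factor)
  details <- rbind(
    data.frame(control = ids[["inhibitor"]],
               concentration_um = as.numeric(grids$EIPA),
               mean_viability = eipa, stringsAsFactors = FALSE),
    data.frame(control = ids[["enhancer"]],
               concentration_um = as.numeric(grids$TORIN1),
               mean_viability = torin, stringsAsFactors = FALSE))
  rownames(details) <- NULL
  structure(list(eipa_pass = eipa_pass, torin1_pass = torin1_pass,
                 pass = eipa_pass && torin1_pass, details = details),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("Control QC: EIPA %s, Torin1 %s -> %s\n",
              if (x$eipa_pass) "pass" else "FAIL",
              if (x$torin1_pass) "pass" else "FAIL",
              if (x$pass) "pass" else "FAIL"))
  invisible(x)
}
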