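# Model-free dose-response AUC: trapezoidal area under the relative-viability
# curve on the linear uM axis, anchored at the vehicle point (0 uM, 1.0).
# A compound with no effect on the default 0.2-25 uM grid scores exactly 25.

#' Trapezoidal AUC of one dose-response replicate
#'
#' Area under the piecewise-linear relative-viability curve on the linear
#' concentration axis from 0 to the top tested concentration, with the fixed
#' vehicle anchor (0 uM, viability 1.0) prepended. Viability values are not
#' clipped: enhancers legitimately exceed 1 and push the AUC above the
#' no-effect calibration value (grid maximum, 25 on the default grid).
#'
#' @param viability Numeric vector of relative viabilities, one per grid
#'   level, in grid order. Missing or non-finite values are an error; the
#'   statistic is never rescaled to a partial grid.
#' @param grid Concentration grid (default [default_grid()]).
#' @return Single non-negative number, in uM x relative viability.
#' @export
auc_single <- function(viability, grid = default_grid()) {
  grid <- as_concentration_grid(grid)
  viability <- as.numeric(viability)
  if (length(viability) != length(grid)) {
    stop(sprintf(
      "auc_single: viability has %d value(s) but the grid has %d level(s)",
      length(viability), length(grid)), call. = FALSE)
  }
  if (any(!is.finite(viability))) {
    stop("auc_single: missing or non-finite viability value", call. = FALSE)
  }
  if (any(viability < 0)) {
    stop("auc_single: negative viability value", call. = FALSE)
  }
  x <- c(0, as.numeric(grid))
  y <- c(1, viability)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Average AUC of a compound across replicates
#'
#' Scores each replicate independently with [auc_single()] and averages;
#' because the trapezoid rule is linear in viability, this equals the AUC of
#' the per-level mean viability.
#'
#' @param viability_matrix Numeric matrix of relative viability, one row per
#'   replicate, one column per grid level (column order = grid order). Every
#'   cell must be present.
#' @param grid Concentration grid.
#' @param compound_id Optional identifier carried into the result.
#' @return List of class `auc_result` with `compound_id`, `auc` (mean),
#'   `replicate_aucs`, `n_replicates`, `grid_max`.
#' @export
auc_compound <- function(viability_matrix, grid = default_grid(),
                         compound_id = NA_character_) {
  grid <- as_concentration_grid(grid)
  viability_matrix <- as.matrix(viability_matrix)
  if (nrow(viability_matrix) < 1L) {
    stop("auc_compound: zero complete replicates", call. = FALSE)
  }
  reps <- apply(viability_matrix, 1L, auc_single, grid = grid)
  structure(list(compound_id = compound_id, auc = mean(reps),
                 replicate_aucs = unname(reps),
                 n_replicates = length(reps),
                 grid_max = max(as.numeric(grid))),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %s: %.4g (n = %d replicates, grid max %g uM)\n",
              x$compound_id, x$auc, x$n_replicates, x$grid_max))
  invisible(x)
}

#' Score every library compound of a viability table
#'
#' Pivots the long viability table into per-compound replicate-by-level
#' matrices and computes the averaged AUC for each. Vehicle and control
#' sentinels are excluded by default (controls run on their own dose series
#' and are judged by [qc_controls()], not scored). A compound missing any
#' (replicate, level) cell is rejected: partial grids would silently change
#' the no-effect calibration.
#'
#' @param viability Output of [relative_viability()], restricted to one
#'   condition (an error otherwise, since profiles would mix conditions).
#' @param grid Concentration grid the library compounds were tested on.
#' @param exclude Compound ids to skip (default the three sentinels).
#' @return Data.frame with `compound_id`, `auc`, `n_replicates`,
#'   `replicate_aucs` (semicolon-joined), ordered by `compound_id`.
#' @export
score_screen <- function(viability, grid = default_grid(),
                         exclude = unname(sentinel_ids())) {
  grid <- as_concentration_grid(grid)
  v <- as.data.frame(viability)
  v <- v[!v$compound_id %in% exclude, , drop = FALSE]
  if (nrow(v) == 0L) {
    stop("score_screen: no library wells to score", call. = FALSE)
  }
  if (length(unique(v$condition)) > 1L) {
    stop("score_screen: viability table mixes conditions; score one ",
         "condition at a time", call. = FALSE)
  }
  levels_um <- as.numeric(grid)
  ids <- sort(unique(v$compound_id))
  rows <- lapply(ids, function(id) {
    d <- v[v$compound_id == id, ]
    reps <- sort(unique(d$replicate))
    mat <- matrix(NA_real_, nrow = length(reps), ncol = length(levels_um))
    idx_rep <- match(d$replicate, reps)
    idx_lvl <- match(d$concentration_um, levels_um)
    if (anyNA(idx_lvl)) {
      stop(sprintf(
        "score_screen: compound %s measured at %g uM, not a grid level",
        id, d$concentration_um[which(is.na(idx_lvl))[1L]]), call. = FALSE)
    }
    if (anyDuplicated(cbind(idx_rep, idx_lvl))) {
      stop("score_screen: compound ", id,
           " has duplicate (replicate, level) wells", call. = FALSE)
    }
    mat[cbind(idx_rep, idx_lvl)] <- d$viability
    if (anyNA(mat)) {
      stop("score_screen: compound ", id,
           " is missing one or more (replicate, level) cells", call. = FALSE)
    }
    res <- auc_compound(mat, grid, compound_id = id)
    data.frame(compound_id = id, auc = res$auc,
               n_replicates = res$n_replicates,
               replicate_aucs = paste(sprintf("%.17g", res$replicate_aucs),
                                      collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
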