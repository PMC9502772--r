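# Aggregation of hit compounds by annotated target: the positive-regulator
# and negative-regulator target tables.

#' Group hit compounds by annotated target
#'
#' Builds one group per (target, direction) over the DECREASE and INCREASE
#' hits. Multi-target compounds count once in each of their annotated
#' targets, so the sum of `n_hits` over groups can exceed the number of hit
#' compounds. `n_in_library` counts the library compounds annotated to the
#' target, and `complete` is TRUE when every one of them is a hit in the
#' group's direction. Groups are sorted by `n_hits` descending, then target
#' name; singleton groups are retained but flagged (`multi_hit = FALSE`).
#' No enrichment statistics are computed: the screen reports raw overlap
#' counts.
#'
#' @param hits Data.frame from [call_hits()].
#' @param annotations Annotation data.frame; every hit compound must have a
#'   record (an error names the first compound without one).
#' @return Data.frame with `target`, `direction`, `n_hits`, `n_in_library`,
#'   `complete`, `multi_hit`, `compound_ids` (semicolon-joined).
#' @export
group_hits <- function(hits, annotations) {
  hits <- as.data.frame(hits)
  annotations <- validate_annotations(annotations)
  target_list <- split_targets(annotations$targets)
  names(target_list) <- annotations$compound_id
  lib_ids <- annotations$compound_id[annotations$role == "LIBRARY"]
  lib_long <- data.frame(
    compound_id = rep(lib_ids, lengths(target_list[lib_ids])),
    target = unlist(target_list[lib_ids], use.names = FALSE),
    stringsAsFactors = FALSE)
  n_in_library <- table(lib_long$target)

  hit_rows <- hits[hits$direction %in% c("DECREASE", "INCREASE"), ,
                   drop = FALSE]
  missing_ann <- setdiff(hit_rows$compound_id, annotations$compound_id)
  if (length(missing_ann)) {
    stop("hit compound without annotation record: ", missing_ann[1L],
         call. = FALSE)
  }
  if (nrow(hit_rows) == 0L) {
    return(data.frame(target = character(), direction = character(),
                      n_hits = integer(), n_in_library = integer(),
                      complete = logical(), multi_hit = logical(),
                      compound_ids = character(), stringsAsFactors = FALSE))
  }
  tl <- target_list[hit_rows$compound_id]
  expanded <- data.frame(
    compound_id = rep(hit_rows$compound_id, lengths(tl)),
    direction = rep(hit_rows$direction, lengths(tl)),
    target = unlist(tl, use.names = FALSE), stringsAsFactors = FALSE)
  keys <- unique(expanded[c("target", "direction")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- expanded$target == keys$target[i] &
      expanded$direction == keys$direction[i]
    ids <- sort(unique(expanded$compound_id[sel]))
    n_lib <- as.integer(n_in_library[keys$target[i]])
    if (is.na(n_lib)) n_lib <- 0L
    data.frame(target = keys$target[i], direction = keys$direction[i],
               n_hits = length(ids), n_in_library = n_lib,
               complete = length(ids) == n_lib && n_lib > 0L,
               multi_hit = length(ids) >= 2L,
               compound_ids = paste(ids, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_hits, out$target, out$direction), ]
  rownames(out) <- NULL
  out
}

#' Is a target group complete?
#'
#' TRUE when every library compound annotated to the group's target is a hit
#' in the group's direction (e.g. all five HDAC inhibitors in the library
#' scoring as AUC-decrease hits).
#'
#' @param group One row of the [group_hits()] table (or any list with
#'   `n_hits` and `n_in_library`).
#' @return Logical.
#' @export
completeness_flag <- function(group) {
  if (is.null(group$n_in_library) || any(is.na(group$n_in_library))) {
    stop("completeness_flag: n_in_library unknown", call. = FALSE)
  }
  group$n_hits == group$n_in_library & group$n_in_library > 0L
}

#' Write the target-group table
#'
#' @param groups Output of [group_hits()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_target_groups <- function(groups, path) {
  write_table_exact(as.data.frame(groups), path)
}
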