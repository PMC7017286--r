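#' Jaccard similarity between two interval sets
#'
#' Base-pair Jaccard index: bp of intersection over bp of union of the two
#' (internally merged) sets.
#'
#' @param set_a,set_b interval data.frames (`chrom`, `start`, `end`).
#' @return A value in `[0, 1]`. Both sets empty is an error (the index is
#'   undefined for an empty union).
#' @export
interval_jaccard <- function(set_a, set_b) {
  .check_interval_df(set_a, "set_a"); .check_interval_df(set_b, "set_b")
  union_bp <- .covered_bp(rbind(set_a[, c("chrom", "start", "end")],
                                set_b[, c("chrom", "start", "end")]))
  if (union_bp == 0) stop("Jaccard undefined: both sets are empty",
                          call. = FALSE)
  inter <- .intersect_intervals(set_a, set_b)
  sum(inter$end - inter$start) / union_bp
}

#' Pairwise Jaccard matrix over labelled interval sets
#'
#' Used to compare per-replicate peak calls across tissues: for each row the
#' most similar *other* set is reported, so one can check that a replicate's
#' best match is its own tissue's partner.
#'
#' @param sets named list of interval data.frames (>= 2, unique labels).
#' @return A symmetric numeric matrix of class `jaccard_matrix` with a
#'   `best_match` attribute (named character vector; per row, the label of
#'   the off-diagonal maximum).
#' @export
jaccard_matrix <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets", call. = FALSE)
  labs <- names(sets)
  if (is.null(labs) || anyDuplicated(labs))
    stop("sets must have unique labels", call. = FALSE)
  n <- length(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- interval_jaccard(sets[[i]], sets[[j]])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  best <- vapply(seq_len(n), function(i) {
    row <- m[i, -i]
    names(row)[which.max(row)]
  }, character(1))
  attr(m, "best_match") <- stats::setNames(best, labs)
  class(m) <- c("jaccard_matrix", class(m))
  m
}

#' Classify per-tissue consensus peaks as unique or shared
#'
#' A peak of one tissue is *unique* iff it overlaps zero base pairs of the
#' same mark's peaks in every other tissue (any overlap, however small,
#' makes it shared).
#'
#' @param sets named list (one interval data.frame per tissue, same mark;
#'   >= 2 tissues).
#' @return A list with `table` (data.frame: `tissue`, `unique_count`,
#'   `shared_count`, `unique_fraction`) and `unique` (named list of the
#'   unique-peak data.frames per tissue).
#' @export
unique_peaks <- function(sets) {
  if (length(sets) < 2L)
    stop("unique peaks need at least two tissues", call. = FALSE)
  labs <- names(sets)
  if (is.null(labs) || anyDuplicated(labs))
    stop("sets must have unique tissue labels", call. = FALSE)
  uniq <- lapply(labs, function(t) {
    mine <- sets[[t]]
    others <- do.call(rbind, lapply(sets[setdiff(labs, t)], function(d)
      d[, c("chrom", "start", "end")]))
    mine[!.overlaps_any(mine, others), , drop = FALSE]
  })
  names(uniq) <- labs
  tab <- data.frame(tissue = labs,
                    unique_count = vapply(uniq, nrow, integer(1)),
                    shared_count = vapply(labs, function(t)
                      nrow(sets[[t]]), integer(1)) -
                      vapply(uniq, nrow, integer(1)),
                    stringsAsFactors = FALSE)
  tab$unique_fraction <- ifelse(tab$unique_count + tab$shared_count > 0,
                                tab$unique_count /
                                  (tab$unique_count + tab$shared_count), 0)
  rownames(tab) <- NULL
  list(table = tab, unique = uniq)
}

#' Active enhancer intervals of one tissue
#'
#' Active enhancers are operationalized as the base-pair intersection of the
#' tissue's H3K4me1 and H3K27ac (merged) peak sets: regions primed as
#' enhancers and acetylated as active.
#'
#' @param me1_peaks,ac_peaks interval data.frames for H3K4me1 and H3K27ac
#'   consensus peaks of the same tissue.
#' @return data.frame of intersection intervals (`chrom`, `start`, `end`).
#' @export
active_enhancers <- function(me1_peaks, ac_peaks) {
  .check_interval_df(me1_peaks, "H3K4me1 peaks")
  .check_interval_df(ac_peaks, "H3K27ac peaks")
  .intersect_intervals(me1_peaks, ac_peaks)
}

#' Tissue-specific active enhancers
#'
#' An active enhancer of tissue `t` is tissue-specific iff it overlaps zero
#' base pairs of every *other* tissue's H3K4me1 peaks and every other
#' tissue's H3K27ac peaks (the strict raw-mark reading: overlap with either
#' mark anywhere else disqualifies it).
#'
#' @param enhancers named list of per-tissue active enhancer sets (from
#'   [active_enhancers()]).
#' @param me1_sets,ac_sets named lists of the per-tissue H3K4me1 and
#'   H3K27ac peak sets (same tissue names).
#' @return Named list of per-tissue tissue-specific enhancer data.frames.
#' @export
tissue_specific_enhancers <- function(enhancers, me1_sets, ac_sets) {
  labs <- names(enhancers)
  stopifnot(!is.null(labs), setequal(labs, names(me1_sets)),
            setequal(labs, names(ac_sets)))
  out <- lapply(labs, function(t) {
    enh <- enhancers[[t]]
    if (nrow(enh) == 0L) return(enh)
    others <- do.call(rbind, c(
      lapply(me1_sets[setdiff(labs, t)], function(d)
        d[, c("chrom", "start", "end")]),
      lapply(ac_sets[setdiff(labs, t)], function(d)
        d[, c("chrom", "start", "end")])))
    enh[!.overlaps_any(enh, others), , drop = FALSE]
  })
  names(out) <- labs
  out
}
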