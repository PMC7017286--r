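# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Hashes the labels onto the master seed with a 31-multiplier rolling hash so
#' that each (tissue, mark, replicate) library gets an independent, stable
#' stream: adding a library never perturbs the reads of another.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the stream.
#' @return An integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  mod <- 2147483629  # largest prime < 2^31
  h <- as.double(master %% mod)
  for (lab in list(...)) {
    for (ch in utf8ToInt(paste0(as.character(lab), "|"))) {
      h <- (h * 31 + ch) %% mod
    }
  }
  as.integer(h)
}

# 0-based half-open intervals -> IRanges (1-based closed)
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# IRanges -> data.frame of 0-based half-open intervals on one chromosome
.from_iranges <- function(ir, chrom) {
  data.frame(chrom = rep(chrom, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

# Split an interval data.frame by chromosome and reduce (merge overlapping,
# not abutting, when touch = FALSE) each piece; returns a data.frame.
.merge_intervals <- function(df, touch = TRUE) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  pieces <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(.as_iranges(d),
                          min.gapwidth = if (touch) 1L else 0L)
    .from_iranges(ir, d$chrom[1L])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Total bp covered by a (possibly overlapping) interval set.
.covered_bp <- function(df) {
  if (nrow(df) == 0L) return(0)
  m <- .merge_intervals(df)
  sum(m$end - m$start)
}

# bp of intersection between two interval sets.
.intersect_bp <- function(a, b) {
  sum(.intersect_intervals(a, b)$end - .intersect_intervals(a, b)$start)
}

# Interval-set intersection, returned as 0-based half-open data.frame.
.intersect_intervals <- function(a, b) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0L) return(empty)
  pieces <- lapply(chroms, function(ch) {
    ia <- IRanges::reduce(.as_iranges(a[a$chrom == ch, , drop = FALSE]))
    ib <- IRanges::reduce(.as_iranges(b[b$chrom == ch, , drop = FALSE]))
    .from_iranges(IRanges::intersect(ia, ib), ch)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Does any interval of `a` overlap (>= 1 bp) any interval of `b`? Vectorised
# over rows of `a`; returns a logical per row of `a`.
.overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  out <- rep(FALSE, nrow(a))
  for (ch in unique(a$chrom)) {
    sel <- a$chrom == ch
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0L) next
    hits <- IRanges::overlapsAny(.as_iranges(a[sel, , drop = FALSE]),
                                 .as_iranges(bb))
    out[sel] <- hits
  }
  out
}

.check_interval_df <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  if (nrow(df) > 0L && any(df$start >= df$end))
    stop(what, " has intervals with start >= end", call. = FALSE)
  invisible(df)
}

# Validate a chromosome sizes table (data.frame chrom/size or named vector).
.as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
    sz <- stats::setNames(as.numeric(chrom_sizes$size), chrom_sizes$chrom)
  } else {
    stopifnot(!is.null(names(chrom_sizes)))
    sz <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  if (any(sz <= 0)) stop("chromosome sizes must be positive", call. = FALSE)
  sz
}

`%||%` <- function(a, b) if (is.null(a)) b else a
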