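#' Read position frequency matrices in JASPAR text format
#'
#' Parses the JASPAR 2016/2018 dialect: a `>ID NAME` header followed by four
#' bracketed count rows (`A [ 1 2 3 ]` ...). Log-odds matrices are built
#' with [pwm_logodds()] under a uniform background.
#'
#' @param path JASPAR-format file.
#' @param pseudocount per-cell pseudocount for the log-odds transform.
#' @return A named list of `pwm` objects (fields `id`, `name`, `counts`
#'   4 x width, `logodds`, `width`, `max_score`).
#' @export
read_jaspar <- function(path, pseudocount = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no JASPAR records in ", path, call. = FALSE)
  out <- lapply(seq_along(heads), function(i) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 4L)
      stop("malformed JASPAR record (need 4 count rows): ",
           lines[heads[i]], call. = FALSE)
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    rows <- lapply(block, function(l) {
      s <- sub("^\\s*[ACGT]", "", l)
      as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("malformed JASPAR record: ragged count rows in ", parts[1],
           call. = FALSE)
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    make_pwm(counts, id = parts[1],
             name = if (length(parts) > 1L) parts[2] else parts[1],
             pseudocount = pseudocount)
  })
  names(out) <- vapply(out, function(p) p$id, character(1))
  out
}

#' Build a PWM object from a count matrix
#'
#' @param counts 4 x width numeric matrix, rows A, C, G, T.
#' @param id,name identifiers.
#' @param pseudocount per-cell pseudocount.
#' @param background base frequencies (uniform by default).
#' @return A list of class `pwm`.
#' @export
make_pwm <- function(counts, id = "motif", name = id, pseudocount = 0.25,
                     background = rep(0.25, 4)) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (ncol(counts) < 1L) stop("empty count matrix", call. = FALSE)
  if (any(colSums(counts) == 0))
    stop("PFM has an empty column (all-zero counts)", call. = FALSE)
  lo <- pwm_logodds(counts, pseudocount = pseudocount,
                    background = background)
  out <- list(id = id, name = name, counts = counts, logodds = lo,
              width = ncol(counts), max_score = sum(apply(lo, 2, max)))
  class(out) <- "pwm"
  out
}

#' Log-odds transform of a position frequency matrix
#'
#' Per cell: `log2((c + pseudocount) / (N + 4 * pseudocount) / background)`
#' where `N` is the column count sum.
#'
#' @param counts 4 x width count matrix.
#' @param pseudocount per-cell pseudocount (default 0.25).
#' @param background length-4 base frequencies.
#' @return The 4 x width log-odds matrix.
#' @export
pwm_logodds <- function(counts, pseudocount = 0.25,
                        background = rep(0.25, 4)) {
  freq <- sweep(counts + pseudocount, 2,
                colSums(counts) + 4 * pseudocount, "/")
  log2(freq / background)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s): width %d, max log-odds score %.2f\n",
              x$id, x$name, x$width, x$max_score))
  invisible(x)
}

#' Build a synthetic PWM from an IUPAC consensus
#'
#' Allowed bases at each position get equal counts; disallowed bases get
#' zero. Useful for planting and recovering a known consensus.
#'
#' @param consensus IUPAC string.
#' @param id,name identifiers (default: the consensus).
#' @param depth count assigned per allowed base.
#' @return A `pwm` object.
#' @export
consensus_pwm <- function(consensus, id = consensus, name = id, depth = 10) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  counts <- vapply(letters, function(l) {
    opts <- .iupac_map[[l]]
    if (is.null(opts)) stop("unknown IUPAC code: ", l, call. = FALSE)
    as.numeric(c("A", "C", "G", "T") %in% opts) * depth
  }, numeric(4))
  rownames(counts) <- c("A", "C", "G", "T")
  make_pwm(counts, id = id, name = name)
}

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

#' Scan sequences with a PWM on both strands
#'
#' Slides the log-odds matrix over each sequence and its reverse complement;
#' positions scoring at least `threshold` (a fraction of the matrix's
#' maximum achievable score by default) are reported. `N` scores as the
#' worst base of its column. Minus-strand hit offsets refer to the match
#' start on the forward sequence.
#'
#' @param seqs named character vector (or `DNAStringSet`) of sequences over
#'   ACGTN.
#' @param pwm a `pwm` object.
#' @param threshold absolute score cutoff, or `NULL` to use
#'   `rel_threshold * max_score`.
#' @param rel_threshold relative cutoff (default 0.8).
#' @return data.frame of hits: `seq`, `offset` (0-based), `strand`, `score`.
#'   Sequences shorter than the motif are skipped.
#' @export
scan_pwm <- function(seqs, pwm, threshold = NULL, rel_threshold = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  threshold <- threshold %||% (rel_threshold * pwm$max_score)
  # width x 5 score table: columns A, C, G, T and the worst base (for N)
  lo <- cbind(t(pwm$logodds), apply(pwm$logodds, 2, min))
  w <- pwm$width
  hits <- lapply(names(seqs), function(nm) {
    s <- toupper(seqs[[nm]])
    n <- nchar(s)
    if (n < w) return(NULL)
    fwd <- .BASE_CODE[strsplit(s, "")[[1]]]
    fwd[is.na(fwd)] <- 5L
    rev <- 5L - fwd
    rev[fwd == 5L] <- 5L
    rev <- base::rev(rev)  # reverse complement codes
    score_strand <- function(codes) {
      nw <- length(codes) - w + 1L
      sc <- numeric(nw)
      for (j in seq_len(w)) sc <- sc + lo[j, codes[j:(j + nw - 1L)]]
      sc
    }
    sf <- score_strand(fwd)
    sr <- score_strand(rev)
    res <- NULL
    hf <- which(sf >= threshold)
    if (length(hf))
      res <- data.frame(seq = nm, offset = hf - 1L, strand = "+",
                        score = sf[hf], stringsAsFactors = FALSE)
    hr <- which(sr >= threshold)
    if (length(hr))
      res <- rbind(res, data.frame(seq = nm, offset = n - w - (hr - 1L),
                                   strand = "-", score = sr[hr],
                                   stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, hits) %||%
    data.frame(seq = character(), offset = integer(), strand = character(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' First-order Markov (dinucleotide) shuffle of sequences
#'
#' Generates, for each sequence, `n` random sequences of the same length
#' from that sequence's own dinucleotide transition frequencies -- the
#' default background set for motif enrichment. Several shuffles per
#' foreground sequence give a steadier estimate of the chance hit rate.
#'
#' @param seqs named character vector of sequences.
#' @param seed integer seed.
#' @param n shuffles generated per input sequence.
#' @return Named character vector of `n * length(seqs)` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(seqs, seed = 1, n = 1) {
  set.seed(seed)
  if (n > 1) {
    seqs <- rep(seqs, times = n)
    names(seqs) <- paste0(names(seqs), "_sh",
                          rep(seq_len(n), each = length(seqs) / n))
  }
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    ch <- ch[ch %in% bases]
    n <- length(ch)
    if (n < 2L) return(paste(ch, collapse = ""))
    trans <- matrix(0.25, 4, 4, dimnames = list(bases, bases))
    tab <- table(factor(ch[-n], bases), factor(ch[-1], bases))
    trans <- (tab + 0.25) / rowSums(tab + 0.25)
    out <- character(n)
    out[1] <- sample(bases, 1, prob = table(factor(ch, bases)) / n)
    for (i in 2:n) out[i] <- sample(bases, 1, prob = trans[out[i - 1], ])
    paste(out, collapse = "")
  }, character(1))
}

#' Motif enrichment of foreground over background sequences
#'
#' For each motif, counts the sequences carrying at least one hit in the
#' foreground and background sets, tests foreground excess with a one-sided
#' Fisher exact test on the 2 x 2 presence table, adjusts across motifs
#' with Benjamini-Hochberg and ranks by adjusted p-value.
#'
#' @param fg_seqs foreground sequences (named character vector), e.g.
#'   tissue-specific enhancer sequences.
#' @param bg_seqs background sequences (e.g. [dinucleotide_shuffle()] of the
#'   foreground, or pooled other-tissue enhancers).
#' @param pwms list of `pwm` objects.
#' @param rel_threshold relative hit threshold passed to [scan_pwm()].
#' @return data.frame of class `motif_enrichment`: `rank`, `motif`, `name`,
#'   `fg_hits`, `fg_total`, `bg_hits`, `bg_total`, `p`, `adjusted_p`.
#' @export
motif_enrichment <- function(fg_seqs, bg_seqs, pwms, rel_threshold = 0.8) {
  if (length(fg_seqs) == 0L) stop("empty foreground", call. = FALSE)
  if (length(bg_seqs) == 0L) stop("empty background", call. = FALSE)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  rows <- lapply(pwms, function(pw) {
    fh <- length(unique(scan_pwm(fg_seqs, pw,
                                 rel_threshold = rel_threshold)$seq))
    bh <- length(unique(scan_pwm(bg_seqs, pw,
                                 rel_threshold = rel_threshold)$seq))
    tab <- matrix(c(fh, length(fg_seqs) - fh,
                    bh, length(bg_seqs) - bh), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(motif = pw$id, name = pw$name, fg_hits = fh,
               fg_total = length(fg_seqs), bg_hits = bh,
               bg_total = length(bg_seqs), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- bh_adjust(res$p)
  res <- res[order(res$adjusted_p, res$p, res$motif), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("motif_enrichment", "data.frame")
  res[, c("rank", "motif", "name", "fg_hits", "fg_total", "bg_hits",
          "bg_total", "p", "adjusted_p")]
}

#' Uniquely detected motifs across tissues
#'
#' A motif is uniquely detected in tissue `t` iff its adjusted p-value is at
#' or below `alpha` in `t` and above `alpha` in every other tissue.
#'
#' @param results named list (>= 2 tissues) of [motif_enrichment()] tables.
#' @param alpha significance cutoff on the adjusted p-value.
#' @return Named list: per tissue, the character vector of uniquely
#'   detected motif ids.
#' @export
uniquely_detected <- function(results, alpha = 0.05) {
  if (length(results) < 2L) stop("need at least two tissues", call. = FALSE)
  labs <- names(results)
  sig <- lapply(results, function(r) r$motif[r$adjusted_p <= alpha])
  out <- lapply(labs, function(t) {
    others <- unique(unlist(sig[setdiff(labs, t)]))
    setdiff(sig[[t]], others)
  })
  names(out) <- labs
  out
}

#' Extract interval sequences from a genome
#'
#' @param intervals interval data.frame (`chrom`, `start`, `end`, optional
#'   `name`).
#' @param genome a `DNAStringSet`.
#' @return Named character vector of sequences.
#' @export
interval_sequences <- function(intervals, genome) {
  .check_interval_df(intervals, "intervals")
  if (nrow(intervals) == 0L) return(stats::setNames(character(0), character(0)))
  out <- vapply(seq_len(nrow(intervals)), function(i) {
    as.character(Biostrings::subseq(genome[[intervals$chrom[i]]],
                                    intervals$start[i] + 1L,
                                    intervals$end[i]))
  }, character(1))
  names(out) <- intervals$name %||%
    sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
  out
}
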