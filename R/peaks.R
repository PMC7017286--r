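#' Per-mark peak calling configuration
#'
#' Default parameters per histone mark: q-value (FDR) cutoffs of 0.05
#' (H3K4me1), 0.01 (H3K4me3), 0.01 (H3K27ac) and 0.1 (H3K27me3); fragment
#' size 200 bp for all marks; and, for the broad mark's island caller,
#' window size 200 bp, gap size 4 windows and effective genome fraction
#' 0.63. The effective genome size default (2,409,143,234 bp) is the
#' mammalian-scale constant used for real-genome runs; desk-scale runs
#' compute rates from the chromosome sizes table they are given.
#'
#' @param mark mark name.
#' @param peak_type `"narrow"` or `"broad"`.
#' @param fdr_threshold significant-call q-value cutoff.
#' @param window_size tiling window (bp).
#' @param gap_size maximum run of ineligible windows bridged inside a broad
#'   island (in windows).
#' @param genome_fraction fraction of the genome treated as mappable in the
#'   global background rate (islands only; `NA` for narrow marks means 1).
#' @param effective_genome_size effective genome length (bp) recorded for
#'   real-scale runs.
#' @param fragment_size length tags are extended to (3' direction) before
#'   counting.
#' @param relaxed_q relaxed q-value defining "regions of enrichment" for
#'   candidate peaks entering replicate combination.
#' @param island_eligible_p per-window Poisson p-value below which a window
#'   is eligible for island membership.
#' @param local_background_bp width of the input-smoothing window used for
#'   the local background rate.
#' @return A list of class `mark_config`.
#' @export
mark_config <- function(mark = "H3K4me1",
                        peak_type = c("narrow", "broad"),
                        fdr_threshold = 0.05,
                        window_size = 200,
                        gap_size = 4,
                        genome_fraction = NA_real_,
                        effective_genome_size = 2409143234,
                        fragment_size = 200,
                        relaxed_q = 0.5,
                        island_eligible_p = 0.2,
                        local_background_bp = 5000) {
  peak_type <- match.arg(peak_type)
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must be in (0, 1)", call. = FALSE)
  if (window_size <= 0) stop("window_size must be positive", call. = FALSE)
  cfg <- list(mark = mark, peak_type = peak_type,
              fdr_threshold = fdr_threshold, window_size = as.integer(window_size),
              gap_size = as.integer(gap_size),
              genome_fraction = genome_fraction,
              effective_genome_size = effective_genome_size,
              fragment_size = as.integer(fragment_size),
              relaxed_q = relaxed_q, island_eligible_p = island_eligible_p,
              local_background_bp = as.integer(local_background_bp))
  class(cfg) <- "mark_config"
  cfg
}

#' Default per-mark configurations for the four FAANG histone marks
#'
#' @return Named list of [mark_config()] objects for H3K4me1, H3K4me3,
#'   H3K27ac (narrow) and H3K27me3 (broad island calling, genome fraction
#'   0.63, gap 4, window 200).
#' @export
default_mark_configs <- function() {
  list(
    H3K4me1 = mark_config("H3K4me1", "narrow", fdr_threshold = 0.05),
    H3K4me3 = mark_config("H3K4me3", "narrow", fdr_threshold = 0.01),
    H3K27ac = mark_config("H3K27ac", "narrow", fdr_threshold = 0.01),
    H3K27me3 = mark_config("H3K27me3", "broad", fdr_threshold = 0.1,
                           window_size = 200, gap_size = 4,
                           genome_fraction = 0.63)
  )
}

# Extend tags to fragment_size in the 3' direction and return the fragment
# midpoint (0-based), clamped inside the chromosome.
.fragment_mid <- function(tags, fragment_size, sz) {
  fs <- ifelse(tags$strand == "+", tags$start, tags$end - fragment_size)
  mid <- fs + fragment_size %/% 2L
  pmin(pmax(mid, 0), sz[tags$chrom] - 1)
}

#' Per-window fragment counts and Poisson enrichment p-values
#'
#' Tiles the genome at `window_size`; tags are extended to `fragment_size`
#' in the 3' direction and counted by fragment midpoint. The expected count
#' per window is the maximum of an input-derived local rate (input counts
#' smoothed over `local_background_bp`, scaled to ChIP depth) and the global
#' ChIP rate over the effective genome (`genome_fraction` x genome length).
#' The p-value is the upper tail of Poisson(lambda) at the observed count.
#'
#' @param chip_tags deduplicated ChIP tags.
#' @param input_tags deduplicated input tags (empty/`NULL` falls back to the
#'   global rate with a warning).
#' @param chrom_sizes chromosome sizes.
#' @param config a [mark_config()].
#' @return data.frame with one row per window: `chrom`, `start`, `end`,
#'   `count`, `lambda`, `p`.
#' @export
window_scores <- function(chip_tags, input_tags, chrom_sizes, config) {
  stopifnot(inherits(config, "mark_config"))
  sz <- .as_chrom_sizes(chrom_sizes)
  win <- config$window_size
  gf <- if (is.na(config$genome_fraction)) 1 else config$genome_fraction
  n_chip <- nrow(chip_tags)
  lambda_global <- n_chip * win / (gf * sum(sz))

  have_input <- !is.null(input_tags) && nrow(input_tags) > 0L
  if (!have_input)
    warning("empty input library: using the global background rate only")
  scale <- if (have_input) n_chip / nrow(input_tags) else NA_real_
  k <- max(1L, round(config$local_background_bp / win))

  mid_chip <- .fragment_mid(chip_tags, config$fragment_size, sz)
  if (have_input)
    mid_in <- .fragment_mid(input_tags, config$fragment_size, sz)

  out <- lapply(names(sz), function(ch) {
    nb <- as.integer(ceiling(sz[[ch]] / win))
    sel <- chip_tags$chrom == ch
    cnt <- tabulate(mid_chip[sel] %/% win + 1L, nb)
    if (have_input) {
      sel_i <- input_tags$chrom == ch
      icnt <- tabulate(mid_in[sel_i] %/% win + 1L, nb)
      local <- .running_mean(icnt, k) * scale
      lambda <- pmax(local, lambda_global)
    } else {
      lambda <- rep(lambda_global, nb)
    }
    data.frame(chrom = ch,
               start = (seq_len(nb) - 1L) * win,
               end = pmin(seq_len(nb) * win, sz[[ch]]),
               count = cnt, lambda = lambda,
               p = stats::ppois(cnt - 1L, lambda, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  ws <- do.call(rbind, out)
  rownames(ws) <- NULL
  attr(ws, "mark_config") <- config
  ws
}

# Centered running mean over a window of 2k+1 entries (edge-truncated).
.running_mean <- function(x, k) {
  if (k <= 0L || length(x) == 0L) return(as.numeric(x))
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (with monotonicity enforcement),
#' returned in input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call narrow peaks from window scores
#'
#' Adjusts window p-values (BH), keeps windows with q at or below the
#' relaxed threshold, merges runs of adjacent kept windows into candidate
#' peaks, and flags as significant the peaks whose best member q is at or
#' below the mark's FDR cutoff. The summit is the midpoint of the
#' highest-count member window. Candidate (sub-significant) peaks are
#' retained because replicate combination operates on regions of enrichment,
#' not only on significant calls.
#'
#' @param ws window scores from [window_scores()].
#' @param config a [mark_config()]; defaults to the one stored in `ws`.
#' @return data.frame of peaks: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `p`, `q`, `summit` (offset from `start`),
#'   `significant`.
#' @export
call_narrow <- function(ws, config = NULL) {
  config <- config %||% attr(ws, "mark_config")
  stopifnot(inherits(config, "mark_config"))
  q <- bh_adjust(ws$p)
  keep <- which(q <= config$relaxed_q)
  if (length(keep) == 0L) return(.empty_peaks(narrow = TRUE))
  win <- config$window_size
  idx <- ws$start[keep] %/% win
  grp <- cumsum(c(TRUE, ws$chrom[keep][-1] != ws$chrom[keep][-length(keep)] |
                    diff(idx) != 1L))
  pieces <- split(keep, grp)
  out <- lapply(pieces, function(rows) {
    best <- rows[which.max(ws$count[rows])]
    data.frame(chrom = ws$chrom[rows[1L]],
               start = ws$start[rows[1L]],
               end = ws$end[rows[length(rows)]],
               signal = max(ws$count[rows] / ws$lambda[rows]),
               p = min(ws$p[rows]), q = min(q[rows]),
               summit = (ws$start[best] + ws$end[best]) %/% 2L -
                 ws$start[rows[1L]],
               stringsAsFactors = FALSE)
  })
  pk <- do.call(rbind, out)
  pk$name <- sprintf("%s_peak_%d", config$mark, seq_len(nrow(pk)))
  pk$score <- .peak_score(pk$q)
  pk$strand <- "."
  pk$significant <- pk$q <= config$fdr_threshold
  rownames(pk) <- NULL
  pk[, c("chrom", "start", "end", "name", "score", "strand", "signal", "p",
         "q", "summit", "significant")]
}

.peak_score <- function(q) {
  as.integer(pmin(1000, round(-10 * log10(pmax(q, 1e-100)))))
}

.empty_peaks <- function(narrow = TRUE) {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = integer(), strand = character(),
             signal = numeric(), p = numeric(), q = numeric(),
             summit = integer(), significant = logical(),
             stringsAsFactors = FALSE)
}

#' Call broad islands from window scores (SICER-style)
#'
#' Windows with a Poisson p-value at or below `island_eligible_p` are
#' eligible; islands are maximal runs of eligible windows in which up to
#' `gap_size` consecutive ineligible windows may be bridged. The island
#' score is the sum of -log(p) over eligible member windows; an island
#' p-value comes from Fisher's combination (chi-squared with 2k degrees of
#' freedom) of those member p-values, and q-values from [bh_adjust()]
#' across islands.
#'
#' @param ws window scores from [window_scores()].
#' @param config a [mark_config()] with `peak_type = "broad"`.
#' @return data.frame of islands in the same layout as [call_narrow()],
#'   with `summit = -1`.
#' @export
call_islands <- function(ws, config = NULL) {
  config <- config %||% attr(ws, "mark_config")
  stopifnot(inherits(config, "mark_config"))
  elig <- which(ws$p <= config$island_eligible_p)
  if (length(elig) == 0L) return(.empty_peaks(narrow = FALSE))
  win <- config$window_size
  idx <- ws$start[elig] %/% win
  new_island <- c(TRUE, ws$chrom[elig][-1] != ws$chrom[elig][-length(elig)] |
                    diff(idx) - 1L > config$gap_size)
  grp <- cumsum(new_island)
  pieces <- split(elig, grp)
  out <- lapply(pieces, function(rows) {
    score <- sum(-log(pmax(ws$p[rows], 1e-300)))
    p_isl <- stats::pchisq(2 * score, df = 2 * length(rows),
                           lower.tail = FALSE)
    data.frame(chrom = ws$chrom[rows[1L]],
               start = ws$start[rows[1L]],
               end = ws$end[rows[length(rows)]],
               signal = max(ws$count[rows] / ws$lambda[rows]),
               p = p_isl, stringsAsFactors = FALSE)
  })
  pk <- do.call(rbind, out)
  pk$q <- bh_adjust(pk$p)
  pk$name <- sprintf("%s_island_%d", config$mark, seq_len(nrow(pk)))
  pk$score <- .peak_score(pk$q)
  pk$strand <- "."
  pk$summit <- -1L
  pk$significant <- pk$q <= config$fdr_threshold
  rownames(pk) <- NULL
  pk[, c("chrom", "start", "end", "name", "score", "strand", "signal", "p",
         "q", "summit", "significant")]
}

#' Combine replicate peak calls into consensus peaks
#'
#' Builds the overlap graph (>= 1 bp) between the two replicates' candidate
#' peaks. Each connected component that contains at least one peak from
#' *each* replicate and at least one member whose q-value passes the mark's
#' FDR threshold emits one consensus peak spanning the merged union of its
#' members; all other components are discarded. Because candidates include
#' sub-significant regions of enrichment, a consensus set can be larger
#' than the smaller replicate's significant call set.
#'
#' @param peaks_rep1,peaks_rep2 peak data.frames from [call_narrow()] or
#'   [call_islands()] (called at the relaxed threshold).
#' @param config a [mark_config()].
#' @return data.frame of class `consensus_peaks`: `chrom`, `start`, `end`,
#'   `name`, `q` (best member), `n_rep1`, `n_rep2`, `rep1_members`,
#'   `rep2_members` (comma-separated provenance ids).
#' @export
combine_replicates <- function(peaks_rep1, peaks_rep2, config) {
  stopifnot(inherits(config, "mark_config"))
  .check_interval_df(peaks_rep1, "replicate 1 peaks")
  .check_interval_df(peaks_rep2, "replicate 2 peaks")
  if (nrow(peaks_rep1) > 0L && nrow(peaks_rep2) > 0L &&
      length(intersect(unique(peaks_rep1$chrom),
                       unique(peaks_rep2$chrom))) == 0L)
    stop("replicate peak sets share no chromosome names", call. = FALSE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), q = numeric(),
                      n_rep1 = integer(), n_rep2 = integer(),
                      rep1_members = character(), rep2_members = character(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks_rep1) == 0L || nrow(peaks_rep2) == 0L) {
    class(empty) <- c("consensus_peaks", "data.frame")
    return(empty)
  }
  all_pk <- rbind(
    data.frame(chrom = peaks_rep1$chrom, start = peaks_rep1$start,
               end = peaks_rep1$end, q = peaks_rep1$q,
               name = peaks_rep1$name, rep = 1L, stringsAsFactors = FALSE),
    data.frame(chrom = peaks_rep2$chrom, start = peaks_rep2$start,
               end = peaks_rep2$end, q = peaks_rep2$q,
               name = peaks_rep2$name, rep = 2L, stringsAsFactors = FALSE))
  out <- lapply(split(all_pk, all_pk$chrom), function(d) {
    ir <- .as_iranges(d)
    comp <- IRanges::reduce(ir, min.gapwidth = 0L)  # overlap components
    hits <- IRanges::findOverlaps(ir, comp)
    ci <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    res <- lapply(seq_along(comp), function(i) {
      mem <- which(ci == i)
      r1 <- mem[d$rep[mem] == 1L]
      r2 <- mem[d$rep[mem] == 2L]
      if (length(r1) == 0L || length(r2) == 0L) return(NULL)
      if (min(d$q[mem]) > config$fdr_threshold) return(NULL)
      data.frame(chrom = d$chrom[1L],
                 start = IRanges::start(comp)[i] - 1L,
                 end = IRanges::end(comp)[i],
                 q = min(d$q[mem]),
                 n_rep1 = length(r1), n_rep2 = length(r2),
                 rep1_members = paste(d$name[r1], collapse = ","),
                 rep2_members = paste(d$name[r2], collapse = ","),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  cons <- do.call(rbind, out) %||% empty
  if (nrow(cons) > 0L) {
    cons <- cons[order(cons$chrom, cons$start), , drop = FALSE]
    cons$name <- sprintf("%s_consensus_%d", config$mark, seq_len(nrow(cons)))
    cons <- cons[, c("chrom", "start", "end", "name", "q", "n_rep1",
                     "n_rep2", "rep1_members", "rep2_members")]
    rownames(cons) <- NULL
  }
  class(cons) <- c("consensus_peaks", "data.frame")
  cons
}

#' Percent of the genome covered by a peak set
#'
#' @param peaks interval data.frame (`chrom`, `start`, `end`).
#' @param chrom_sizes chromosome sizes.
#' @return 100 x (union bp of peaks) / (total genome bp).
#' @export
genome_covered_percent <- function(peaks, chrom_sizes) {
  .check_interval_df(peaks, "peaks")
  sz <- .as_chrom_sizes(chrom_sizes)
  if (nrow(peaks) > 0L) {
    if (!all(peaks$chrom %in% names(sz)))
      stop("peak on unknown chromosome", call. = FALSE)
    if (any(peaks$end > sz[peaks$chrom]) || any(peaks$start < 0))
      stop("peak beyond chromosome end", call. = FALSE)
  }
  100 * .covered_bp(peaks) / sum(sz)
}

#' Call peaks for one library with the mark-appropriate caller
#'
#' @param chip_tags,input_tags deduplicated tags.
#' @param chrom_sizes chromosome sizes.
#' @param config a [mark_config()]; `peak_type` selects [call_narrow()] or
#'   [call_islands()].
#' @return A peak data.frame.
#' @export
call_peaks <- function(chip_tags, input_tags, chrom_sizes, config) {
  ws <- window_scores(chip_tags, input_tags, chrom_sizes, config)
  if (config$peak_type == "broad") call_islands(ws, config)
  else call_narrow(ws, config)
}
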