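#' Strict alignment filtering for ChIP-seq tags
#'
#' Removes tags that did not map, are secondary alignments, failed
#' platform/vendor quality checks, are optical duplicates, or have mapping
#' quality below `min_mapq`. Each removed tag is counted once, under the
#' first criterion (in that order) it meets.
#'
#' @param tags aligned-tag data.frame (see [simulate_library()] for the
#'   column contract).
#' @param min_mapq minimum mapping quality retained (default 30, strict
#'   filtering).
#' @return A list with `tags` (the retained rows) and `stats` (named counts
#'   of removals per criterion plus `retained`).
#' @export
filter_alignments <- function(tags, min_mapq = 30) {
  .check_tags(tags)
  n <- nrow(tags)
  if (n == 0L) {
    stats <- c(unmapped = 0L, secondary = 0L, qc_fail = 0L,
               optical_duplicate = 0L, low_mapq = 0L, retained = 0L)
    return(list(tags = tags, stats = stats))
  }
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & tags$unmapped] <- "unmapped"
  reason[is.na(reason) & tags$secondary] <- "secondary"
  reason[is.na(reason) & tags$qc_fail] <- "qc_fail"
  reason[is.na(reason) & tags$optical_duplicate] <- "optical_duplicate"
  reason[is.na(reason) & tags$mapq < min_mapq] <- "low_mapq"
  keep <- is.na(reason)
  stats <- vapply(c("unmapped", "secondary", "qc_fail", "optical_duplicate",
                    "low_mapq"),
                  function(r) sum(reason == r, na.rm = TRUE), integer(1))
  stats <- c(stats, retained = sum(keep))
  list(tags = tags[keep, , drop = FALSE], stats = stats)
}

.check_tags <- function(tags) {
  need <- c("chrom", "start", "end", "strand", "mapq", "unmapped",
            "secondary", "qc_fail", "optical_duplicate", "pcr_duplicate")
  if (!all(need %in% names(tags)))
    stop("tag table missing columns: ",
         paste(setdiff(need, names(tags)), collapse = ", "), call. = FALSE)
  invisible(tags)
}

# 5'-end position of each tag: start of a plus read, (half-open) end of a
# minus read. The plus/minus 5'-end distance for a fragment of length L is
# then exactly L, the quantity the cross-correlation estimator recovers.
.five_prime <- function(tags) {
  ifelse(tags$strand == "+", tags$start, tags$end)
}

.position_key <- function(tags) {
  paste0(tags$chrom, ":", .five_prime(tags), ":", tags$strand)
}

#' Mark PCR duplicates by (chromosome, 5'-end, strand)
#'
#' Among tags sharing a (chromosome, 5'-end position, strand) key, exactly
#' one -- the first in (chromosome, position, strand) sorted order -- remains
#' unflagged; all others get `pcr_duplicate = TRUE`. Idempotent.
#'
#' @param tags filtered tag data.frame.
#' @return The tags with the `pcr_duplicate` column set.
#' @export
mark_pcr_duplicates <- function(tags) {
  .check_tags(tags)
  if (nrow(tags) == 0L) return(tags)
  key <- .position_key(tags)
  ord <- order(tags$chrom, .five_prime(tags), tags$strand)
  dup <- logical(nrow(tags))
  dup[ord] <- duplicated(key[ord])
  tags$pcr_duplicate <- dup
  tags
}

#' Remove tags flagged as PCR duplicates
#' @param tags output of [mark_pcr_duplicates()].
#' @return The deduplicated tag data.frame.
#' @export
remove_duplicates <- function(tags) {
  .check_tags(tags)
  tags[!tags$pcr_duplicate, , drop = FALSE]
}

#' Library complexity metrics (NRF, PBC1, PBC2)
#'
#' Computed on filtered but *not* deduplicated tags, keyed by (chromosome,
#' 5'-end, strand): NRF = distinct positions / total tags; PBC1 = positions
#' seen once / distinct positions; PBC2 = positions seen once / positions
#' seen twice (`Inf` when no position is seen exactly twice).
#'
#' @param tags filtered tag data.frame (duplicates still present).
#' @return A list of class `complexity_report` with `total_tags`,
#'   `distinct_positions`, `m1`, `m2`, `nrf`, `pbc1`, `pbc2`.
#' @export
complexity_metrics <- function(tags) {
  .check_tags(tags)
  if (nrow(tags) == 0L)
    stop("complexity metrics undefined for an empty library", call. = FALSE)
  counts <- tabulate(as.integer(factor(.position_key(tags))))
  m_distinct <- length(counts)
  m1 <- sum(counts == 1L)
  m2 <- sum(counts == 2L)
  out <- list(total_tags = nrow(tags),
              distinct_positions = m_distinct,
              m1 = m1, m2 = m2,
              nrf = m_distinct / nrow(tags),
              pbc1 = m1 / m_distinct,
              pbc2 = if (m2 == 0L) Inf else m1 / m2)
  class(out) <- "complexity_report"
  out
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("library complexity: %d tags, %d distinct positions\n",
              x$total_tags, x$distinct_positions))
  cat(sprintf("  NRF = %.3f  PBC1 = %.3f  PBC2 = %s\n", x$nrf, x$pbc1,
              if (is.infinite(x$pbc2)) "Inf" else sprintf("%.3f", x$pbc2)))
  invisible(x)
}

#' Strand cross-correlation profile, NSC and RSC
#'
#' For each chromosome, plus-strand and minus-strand 5'-end count vectors are
#' correlated (Pearson, over the overlapping window) at every shift
#' `0..max_shift`; per-chromosome profiles are pooled by a
#' chromosome-length-weighted average. The fragment peak is the argmax of the
#' pooled profile outside the phantom-peak exclusion zone around the read
#' length; NSC = cc(fragment peak) / min(cc); RSC = (cc(fragment peak) -
#' min(cc)) / (cc(read length) - min(cc)).
#'
#' The computation is exact but runs on the sparse position tables, so it
#' scales with the number of distinct tag positions rather than genome
#' length.
#'
#' @param tags deduplicated tag data.frame.
#' @param chrom_sizes chromosome sizes (named vector or `chrom`/`size`
#'   data.frame).
#' @param max_shift largest shift evaluated (bp); must exceed the read
#'   length.
#' @param read_length read length; inferred from the tags when `NULL`.
#' @param exclusion_halfwidth half-width (bp) of the phantom exclusion zone
#'   `[read_length - h, read_length + h]`.
#' @param smooth_bp half-width of the moving average applied to the profile
#'   before locating the fragment peak (the reported `cc` stays raw);
#'   reduces the variance of the argmax over a broad peak.
#' @return A list of class `xcor_profile` with `shifts`, `cc`, `cc_min`,
#'   `phantom_shift`, `fragment_shift`, `nsc`, `rsc`.
#' @export
cross_correlation <- function(tags, chrom_sizes, max_shift = 500,
                              read_length = NULL, exclusion_halfwidth = 10,
                              smooth_bp = 15) {
  .check_tags(tags)
  sz <- .as_chrom_sizes(chrom_sizes)
  read_length <- read_length %||%
    as.integer(stats::median(tags$end - tags$start))
  if (max_shift <= read_length)
    stop("max_shift must exceed the read length", call. = FALSE)
  if (!any(tags$strand == "+") || !any(tags$strand == "-"))
    stop("no signal: a strand has zero tags", call. = FALSE)

  shifts <- 0:max_shift
  cc_sum <- numeric(length(shifts))
  w_sum <- 0
  for (ch in names(sz)) {
    sel <- tags$chrom == ch
    if (!any(sel)) next
    t_ch <- tags[sel, , drop = FALSE]
    plus <- .five_prime(t_ch[t_ch$strand == "+", , drop = FALSE])
    minus <- .five_prime(t_ch[t_ch$strand == "-", , drop = FALSE])
    if (length(plus) == 0L || length(minus) == 0L) next
    cc <- .xcor_chrom(plus, minus, sz[[ch]], shifts)
    cc_sum <- cc_sum + sz[[ch]] * cc
    w_sum <- w_sum + sz[[ch]]
  }
  if (w_sum == 0) stop("no signal: no chromosome carries both strands",
                       call. = FALSE)
  cc <- cc_sum / w_sum
  cc_min <- min(cc)
  zone <- abs(shifts - read_length) <= exclusion_halfwidth
  cc_smooth <- .triangular_smooth(cc, as.integer(smooth_bp))
  frag_idx <- which(!zone)[which.max(cc_smooth[!zone])]
  fragment_shift <- shifts[frag_idx]
  cc_frag <- cc[frag_idx]
  cc_phantom <- cc[shifts == read_length]
  out <- list(shifts = shifts, cc = cc, cc_min = cc_min,
              phantom_shift = read_length, fragment_shift = fragment_shift,
              nsc = cc_frag / cc_min,
              rsc = (cc_frag - cc_min) / (cc_phantom - cc_min))
  class(out) <- "xcor_profile"
  out
}

# Triangular-kernel moving average (half-width k); the kernel is peaked at
# the centre so an isolated spike keeps its argmax.
.triangular_smooth <- function(x, k) {
  if (k <= 0L) return(x)
  w <- k + 1L - abs(-k:k)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    ww <- w[(lo - i + k + 1L):(hi - i + k + 1L)]
    out[i] <- sum(x[lo:hi] * ww) / sum(ww)
  }
  out
}

# Exact truncated Pearson cross-correlation between the plus and minus
# 5'-end count vectors of one chromosome, evaluated sparsely. `plus` and
# `minus` are 0-based positions (with multiplicity); `n` the chromosome
# length. cc(d) correlates x[t] (t = 0..n-1-d) with y[t+d].
.xcor_chrom <- function(plus, minus, n, shifts) {
  px <- sort(unique(plus))
  ax <- as.numeric(tabulate(match(plus, px), length(px)))
  py <- sort(unique(minus))
  by <- as.numeric(tabulate(match(minus, py), length(py)))
  cax <- cumsum(ax); cax2 <- cumsum(ax^2)
  cby <- cumsum(by); cby2 <- cumsum(by^2)
  tot_y <- sum(by); tot_y2 <- sum(by^2)
  vapply(shifts, function(d) {
    m <- n - d
    if (m < 2L) return(NA_real_)
    # cross term: positions p with a minus tag at p + d
    idx <- match(px + d, py)
    hit <- !is.na(idx)
    s_xy <- sum(ax[hit] * by[idx[hit]])
    # truncated sums: x over [0, n-1-d], y over [d, n-1]
    ix <- findInterval(n - 1 - d, px)
    s_x <- if (ix > 0) cax[ix] else 0
    s_x2 <- if (ix > 0) cax2[ix] else 0
    iy <- findInterval(d - 1, py)
    s_y <- tot_y - (if (iy > 0) cby[iy] else 0)
    s_y2 <- tot_y2 - (if (iy > 0) cby2[iy] else 0)
    num <- s_xy - s_x * s_y / m
    den <- sqrt((s_x2 - s_x^2 / m) * (s_y2 - s_y^2 / m))
    if (den <= 0) return(NA_real_)
    num / den
  }, numeric(1))
}

#' @export
print.xcor_profile <- function(x, ...) {
  cat(sprintf("strand cross-correlation: fragment shift %d bp (phantom %d bp)\n",
              x$fragment_shift, x$phantom_shift))
  cat(sprintf("  NSC = %.3f  RSC = %.3f\n", x$nsc, x$rsc))
  invisible(x)
}

#' Plot a strand cross-correlation profile
#' @param x an `xcor_profile`.
#' @param ... passed to [plot()].
#' @export
plot.xcor_profile <- function(x, ...) {
  graphics::plot(x$shifts, x$cc, type = "l", xlab = "strand shift (bp)",
                 ylab = "cross-correlation", ...)
  graphics::abline(v = c(x$phantom_shift, x$fragment_shift),
                   lty = c(3, 2), col = c("grey40", "red"))
  invisible(x)
}

#' Jensen-Shannon distance fingerprint between a ChIP library and its input
#'
#' Tiles the genome into fixed-size bins, counts deduplicated tags per bin in
#' each library, forms the probability mass function over per-bin count
#' values for each, and reports the Jensen-Shannon distance (square root of
#' the Jensen-Shannon divergence, log base 2) between the two PMFs. 0 means
#' the ChIP is indistinguishable from background; well-enriched libraries
#' concentrate reads in few bins and diverge from their input.
#'
#' @param chip_tags,input_tags deduplicated tag data.frames.
#' @param chrom_sizes chromosome sizes.
#' @param bin_size bin width in bp (default 500).
#' @return A list of class `fingerprint_report` with `bin_size`,
#'   `chip_pmf`, `input_pmf` (named by count value) and `jsd`.
#' @export
jsd_fingerprint <- function(chip_tags, input_tags, chrom_sizes,
                            bin_size = 500) {
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  .check_tags(chip_tags); .check_tags(input_tags)
  if (nrow(chip_tags) == 0L || nrow(input_tags) == 0L)
    stop("both libraries must be non-empty", call. = FALSE)
  sz <- .as_chrom_sizes(chrom_sizes)
  c_chip <- .bin_counts(chip_tags, sz, bin_size)
  c_in <- .bin_counts(input_tags, sz, bin_size)
  kmax <- max(c_chip, c_in)
  p <- tabulate(c_chip + 1L, kmax + 1L); p <- p / sum(p)
  q <- tabulate(c_in + 1L, kmax + 1L); q <- q / sum(q)
  out <- list(bin_size = bin_size,
              chip_pmf = stats::setNames(p, 0:kmax),
              input_pmf = stats::setNames(q, 0:kmax),
              jsd = js_distance(p, q))
  class(out) <- "fingerprint_report"
  out
}

# Per-bin tag counts (by tag start position) over the genome tiling,
# concatenated across chromosomes.
.bin_counts <- function(tags, sz, bin_size) {
  unlist(lapply(names(sz), function(ch) {
    nb <- ceiling(sz[[ch]] / bin_size)
    sel <- tags$chrom == ch
    if (!any(sel)) return(integer(nb))
    tabulate(tags$start[sel] %/% bin_size + 1L, nb)
  }), use.names = FALSE)
}

#' Jensen-Shannon distance between two probability mass functions
#'
#' @param p,q numeric PMFs over a common support (each summing to 1).
#' @param base logarithm base (2 by default, so the distance lies in
#'   `[0, 1]`).
#' @return The Jensen-Shannon distance (square root of the divergence).
#' @export
js_distance <- function(p, q, base = 2) {
  stopifnot(length(p) == length(q))
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("PMFs must each sum to 1", call. = FALSE)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz], base = base))
  }
  sqrt(pmax(0, (kl(p, m) + kl(q, m)) / 2))
}

#' @export
print.fingerprint_report <- function(x, ...) {
  cat(sprintf("fingerprint: %d bp bins, JSD = %.3f\n", x$bin_size, x$jsd))
  invisible(x)
}

#' Quality thresholds for the six ChIP-seq metrics
#'
#' Defaults are the ENCODE pass bounds for the complexity and
#' cross-correlation metrics (NRF > 0.5, PBC1 > 0.5, PBC2 > 1, NSC > 1.05,
#' RSC > 0.8) and the FAANG consortium bound for the fingerprint distance
#' (JSD > 0.05). All comparisons are strict.
#'
#' @param nrf_min,pbc1_min,pbc2_min,nsc_min,rsc_min,jsd_min thresholds.
#' @return A named numeric vector of class `qc_thresholds`.
#' @export
qc_thresholds <- function(nrf_min = 0.5, pbc1_min = 0.5, pbc2_min = 1,
                          nsc_min = 1.05, rsc_min = 0.8, jsd_min = 0.05) {
  th <- c(nrf = nrf_min, pbc1 = pbc1_min, pbc2 = pbc2_min, nsc = nsc_min,
          rsc = rsc_min, jsd = jsd_min)
  if (any(th <= 0)) stop("thresholds must be positive", call. = FALSE)
  class(th) <- "qc_thresholds"
  th
}

#' Assemble the six QC metrics for one ChIP library
#'
#' Convenience wrapper: filters, computes complexity on the pre-dedup tags,
#' deduplicates, then computes the cross-correlation and fingerprint
#' metrics against the matched input.
#'
#' @param chip_tags,input_tags raw aligned tags for the ChIP library and its
#'   matched input.
#' @param chrom_sizes chromosome sizes.
#' @param bin_size fingerprint bin size (bp).
#' @param max_shift cross-correlation maximum shift (bp).
#' @return A one-row data.frame with columns `NRF`, `PBC1`, `PBC2`, `NSC`,
#'   `RSC`, `JSD`.
#' @export
qc_metrics <- function(chip_tags, input_tags, chrom_sizes, bin_size = 500,
                       max_shift = 500) {
  f_chip <- filter_alignments(chip_tags)$tags
  f_in <- filter_alignments(input_tags)$tags
  cx <- complexity_metrics(f_chip)
  d_chip <- remove_duplicates(mark_pcr_duplicates(f_chip))
  d_in <- remove_duplicates(mark_pcr_duplicates(f_in))
  xc <- cross_correlation(d_chip, chrom_sizes, max_shift = max_shift)
  fp <- jsd_fingerprint(d_chip, d_in, chrom_sizes, bin_size = bin_size)
  data.frame(NRF = cx$nrf, PBC1 = cx$pbc1, PBC2 = cx$pbc2,
             NSC = xc$nsc, RSC = xc$rsc, JSD = fp$jsd)
}

#' Pass/fail verdicts for QC metrics against thresholds
#'
#' Strict comparison (`metric > threshold`) per metric; `Inf` PBC2 (no
#' doubly-observed position) always passes.
#'
#' @param metrics a data.frame with columns `NRF`, `PBC1`, `PBC2`, `NSC`,
#'   `RSC`, `JSD` (one row per library), e.g. from [qc_metrics()].
#' @param thresholds a [qc_thresholds()] vector.
#' @return The metrics data.frame with added logical columns
#'   `NRF_pass` .. `JSD_pass` and an integer `n_failed`.
#' @export
qc_verdict <- function(metrics, thresholds = qc_thresholds()) {
  cols <- c("NRF", "PBC1", "PBC2", "NSC", "RSC", "JSD")
  if (!all(cols %in% names(metrics)))
    stop("incomplete QC report; missing: ",
         paste(setdiff(cols, names(metrics)), collapse = ", "),
         call. = FALSE)
  if (any(vapply(metrics[cols], function(x) any(is.na(x)), logical(1))))
    stop("incomplete QC report: NA metric value", call. = FALSE)
  th <- unclass(thresholds)[c("nrf", "pbc1", "pbc2", "nsc", "rsc", "jsd")]
  for (i in seq_along(cols)) {
    metrics[[paste0(cols[i], "_pass")]] <- metrics[[cols[i]]] > th[i]
  }
  metrics$n_failed <- rowSums(!as.matrix(
    metrics[paste0(cols, "_pass")]))
  metrics
}
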