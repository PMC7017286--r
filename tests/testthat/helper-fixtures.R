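# Shared fixture builders and brute-force oracles. Everything is generated
# in code under fixed seeds; no data files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal tag table; vectors are recycled.
make_tags <- function(chrom = "chr1", start = 0L, end = start + 50L,
                      strand = "+", mapq = 60L, unmapped = FALSE,
                      secondary = FALSE, qc_fail = FALSE,
                      optical_duplicate = FALSE, pcr_duplicate = FALSE) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, mapq = as.integer(mapq), unmapped = unmapped,
             secondary = secondary, qc_fail = qc_fail,
             optical_duplicate = optical_duplicate,
             pcr_duplicate = pcr_duplicate, stringsAsFactors = FALSE)
}

# Random interval set on a single chromosome of length `glen`.
random_intervals <- function(n, glen = 1e5, max_w = 2000, chrom = "chr1") {
  s <- sample.int(glen - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = chrom, start = s, end = pmin(s + w, glen),
             name = sprintf("iv%d", seq_len(n)),
             q = stats::runif(n), stringsAsFactors = FALSE)
}

# Per-base membership mask of an interval set (single chromosome).
interval_mask <- function(df, glen) {
  m <- logical(glen)
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > df$start[i]) m[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  m
}

oracle_jaccard <- function(a, b, glen) {
  ma <- interval_mask(a, glen); mb <- interval_mask(b, glen)
  sum(ma & mb) / sum(ma | mb)
}

# Mask -> sorted interval data.frame (0-based half-open).
mask_to_intervals <- function(m, chrom = "chr1") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

# Brute-force consensus combining: connected regions of the union mask that
# contain >= 1 interval from each replicate and a member with q <= thr.
oracle_consensus_mask <- function(r1, r2, glen, thr) {
  mu <- interval_mask(r1, glen) | interval_mask(r2, glen)
  comp <- mask_to_intervals(mu)
  keep <- logical(glen)
  ov <- function(df, s, e) df$start < e & df$end > s
  for (i in seq_len(nrow(comp))) {
    s <- comp$start[i]; e <- comp$end[i]
    in1 <- ov(r1, s, e); in2 <- ov(r2, s, e)
    if (any(in1) && any(in2) &&
        min(c(r1$q[in1], r2$q[in2])) <= thr) keep[(s + 1):e] <- TRUE
  }
  keep
}

# A small simulated study reused by several test files (built once).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, chrom_lengths = c(chr1 = 1e6),
                        reads_per_library = 50000, n_shared_elements = 5,
                        n_specific_elements_per_tissue = 3, n_tissues = 3,
                        marks = c("H3K4me1", "H3K27ac"), n_genes = 25,
                        motif_consensus = c("DAAAYA", "YTGCCCDBA",
                                            "VSAGCAGCTGSNN"))
      g <- make_genome(cfg)
      truth <- plant_elements(cfg, g, make_genes(cfg))
      cache <<- list(cfg = cfg, genome = g, truth = truth,
                     sizes = g$chrom_sizes)
    }
    cache
  }
})

dedup_library <- function(truth, tissue, mark, replicate, cfg = NULL) {
  tags <- simulate_library(truth, tissue, mark, replicate, cfg)
  remove_duplicates(mark_pcr_duplicates(filter_alignments(tags)$tags))
}
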