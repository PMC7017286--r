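test_that("window Poisson p-values match direct summation", {
  cfg <- mark_config("H3K4me1", "narrow")
  # one window with 10 fragments against a flat input
  chip <- make_tags(start = rep(20, 10), end = rep(70, 10))
  ws <- window_scores(chip, NULL, c(chr1 = 1000), cfg) |>
    suppressWarnings()
  # a zero-count window has p = 1
  expect_equal(ws$p[ws$count == 0][1], 1)
  # direct summation of the Poisson pmf: P(X >= 10 | lambda = 2)
  lam <- 2
  p_direct <- 1 - sum(exp(-lam) * lam^(0:9) / factorial(0:9))
  expect_equal(p_direct, 4.65e-5, tolerance = 1e-2)
  # the 10 tags all fall in window 1 and the global rate is 10*200/1000 = 2
  expect_equal(ws$count[1], 10)
  expect_equal(ws$lambda[1], 2)
  expect_equal(ws$p[1], p_direct, tolerance = 1e-12)
  # window size flows from the mark configuration
  cfg3 <- default_mark_configs()$H3K27me3
  ws3 <- suppressWarnings(window_scores(chip, NULL, c(chr1 = 1000), cfg3))
  expect_equal(unique(ws3$end - ws3$start)[1], 200)
})

test_that("empty input falls back to the global rate with a warning", {
  cfg <- mark_config()
  chip <- make_tags(start = c(0, 100, 220, 400))
  expect_warning(ws <- window_scores(chip, NULL, c(chr1 = 1000), cfg),
                 "input")
  expect_true(all(ws$lambda == ws$lambda[1]))
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

# Hand-built window score tables for the callers.
ws_table <- function(p, chrom = "chr1", win = 200, count = NULL) {
  n <- length(p)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * win,
             end = seq_len(n) * win,
             count = count %||% round(10 * (1 - p) + 1),
             lambda = 1, p = p, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("narrow calling merges adjacent enriched windows", {
  cfg <- mark_config("H3K4me3", "narrow", fdr_threshold = 0.01)
  # two adjacent strongly enriched windows, one isolated, background rest
  p <- rep(1, 20)
  p[c(5, 6)] <- 1e-8
  p[10] <- 1e-8
  pk <- call_narrow(ws_table(p), cfg)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$start, c(800, 1800))
  expect_equal(pk$end, c(1200, 2000))
  expect_true(all(pk$significant))
  # significance flag honours the mark's FDR cutoff
  p2 <- rep(1, 100)
  p2[50] <- 3e-4  # q = 0.03 > 0.01 -> peak called but not significant
  pk2 <- call_narrow(ws_table(p2), cfg)
  expect_equal(nrow(pk2), 1L)
  expect_false(pk2$significant)
  # nothing below the relaxed threshold -> empty set
  expect_equal(nrow(call_narrow(ws_table(rep(1, 10)), cfg)), 0L)
})

test_that("island calling bridges gaps up to gap_size windows", {
  cfg <- mark_config("H3K27me3", "broad", fdr_threshold = 0.1,
                     gap_size = 4, island_eligible_p = 0.2)
  # eligible at windows 1 and 4 with a 2-window gap -> one island
  p <- rep(1, 10)
  p[c(1, 4)] <- 0.01
  isl <- call_islands(ws_table(p), cfg)
  expect_equal(nrow(isl), 1L)
  expect_equal(c(isl$start, isl$end), c(0, 800))
  # a 5-window gap with gap_size 4 -> two islands
  p2 <- rep(1, 12)
  p2[c(1, 7)] <- 0.01
  isl2 <- call_islands(ws_table(p2), cfg)
  expect_equal(nrow(isl2), 2L)
  # no eligible window -> empty
  expect_equal(nrow(call_islands(ws_table(rep(1, 10)), cfg)), 0L)
  # gap_size 0 equals a run-merge of eligible windows (per-window oracle)
  set.seed(9)
  p3 <- ifelse(stats::runif(50) < 0.3, 0.01, 1)
  cfg0 <- mark_config("H3K27me3", "broad", gap_size = 0)
  isl3 <- call_islands(ws_table(p3), cfg0)
  runs <- rle(p3 <= 0.2)
  expect_equal(nrow(isl3), sum(runs$values))
})

peakdf <- function(start, end, q, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end,
             name = sprintf("p%d", seq_along(start)), q = q,
             stringsAsFactors = FALSE)
}

test_that("replicate combining follows the overlap-plus-significance rule", {
  cfg <- mark_config("H3K4me1", "narrow", fdr_threshold = 0.05)
  # one significant member suffices; the span is the merged union
  r1 <- peakdf(100, 300, 0.001)
  r2 <- peakdf(250, 400, 0.3)
  cons <- combine_replicates(r1, r2, cfg)
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$start, cons$end), c(100, 400))
  # overlapping but neither significant -> nothing
  expect_equal(nrow(combine_replicates(peakdf(100, 300, 0.2),
                                       peakdf(250, 400, 0.2), cfg)), 0L)
  # highly significant but present in only one replicate -> nothing
  expect_equal(nrow(combine_replicates(peakdf(100, 300, 1e-10),
                                       peakdf(1000, 1200, 0.2), cfg)), 0L)
  # symmetric in its arguments
  a <- peakdf(c(0, 500), c(200, 800), c(0.01, 0.3))
  b <- peakdf(c(150, 700), c(600, 900), c(0.4, 0.02))
  ab <- combine_replicates(a, b, cfg)
  ba <- combine_replicates(b, a, cfg)
  expect_equal(ab[, c("chrom", "start", "end", "q")],
               ba[, c("chrom", "start", "end", "q")])
  # disjoint chromosome namespaces are rejected
  expect_error(combine_replicates(peakdf(0, 10, 0.01),
                                  peakdf(0, 10, 0.01, chrom = "chrX"), cfg),
               "chromosome")
})

test_that("consensus can exceed the smaller replicate's significant count", {
  cfg <- mark_config("H3K4me1", "narrow", fdr_threshold = 0.05)
  # three regions; rep1 significant in two, rep2 in one; relaxed partners
  r1 <- peakdf(c(0, 1000, 2000), c(200, 1200, 2200), c(0.01, 0.01, 0.4))
  r2 <- peakdf(c(100, 1100, 2100), c(300, 1300, 2300), c(0.3, 0.3, 0.01))
  cons <- combine_replicates(r1, r2, cfg)
  n_sig1 <- sum(r1$q <= cfg$fdr_threshold)
  n_sig2 <- sum(r2$q <= cfg$fdr_threshold)
  expect_equal(nrow(cons), 3L)
  expect_gt(nrow(cons), min(n_sig1, n_sig2))
})

test_that("chained overlaps emit a single consensus peak", {
  cfg <- mark_config("H3K4me1", "narrow")
  r1 <- peakdf(c(0, 400), c(250, 700), c(0.01, 0.01))
  r2 <- peakdf(200, 450, 0.5)  # bridges both rep1 peaks
  cons <- combine_replicates(r1, r2, cfg)
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$start, cons$end), c(0, 700))
  expect_equal(cons$n_rep1, 2L)
})

test_that("genome coverage percentages use the union of peaks", {
  sz <- c(chr1 = 10000)
  expect_equal(genome_covered_percent(peakdf(1, 2, 0.5)[0, ], sz), 0)
  pk <- peakdf(c(0, 250), c(500, 1000), c(0.1, 0.1))
  expect_equal(genome_covered_percent(pk, sz), 10)
  expect_error(genome_covered_percent(peakdf(9000, 11000, 0.1), sz),
               "beyond")
})

test_that("consensus matches the per-base oracle on random fixtures", {
  cfg <- mark_config("H3K4me1", "narrow", fdr_threshold = 0.05)
  set.seed(77)
  glen <- 1e5
  for (i in 1:50) {
    r1 <- random_intervals(sample(3:12, 1), glen)
    r2 <- random_intervals(sample(3:12, 1), glen)
    cons <- combine_replicates(r1, r2, cfg)
    got <- interval_mask(cons, glen)
    want <- oracle_consensus_mask(r1, r2, glen, cfg$fdr_threshold)
    expect_identical(got, want)
  }
})
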