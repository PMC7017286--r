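test_that("strict filtering removes tags by the documented criteria", {
  # 10 tags: 2 unmapped, 1 secondary, 1 qc_fail, 2 low MAPQ, 4 clean
  tags <- make_tags(start = (0:9) * 100,
                    unmapped = c(TRUE, TRUE, rep(FALSE, 8)),
                    secondary = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
                    qc_fail = c(rep(FALSE, 3), TRUE, rep(FALSE, 6)),
                    mapq = c(rep(60, 4), 10, 10, rep(60, 4)))
  res <- filter_alignments(tags)
  expect_equal(nrow(res$tags), 4L)
  expect_equal(unname(res$stats[c("unmapped", "secondary", "qc_fail",
                                  "low_mapq", "retained")]),
               c(2L, 1L, 1L, 2L, 4L))
  # counted under the first matching criterion
  tags$qc_fail[1] <- TRUE  # unmapped tag also qc_fail -> counted unmapped
  res2 <- filter_alignments(tags)
  expect_equal(unname(res2$stats["unmapped"]), 2L)
  expect_equal(unname(res2$stats["qc_fail"]), 1L)
})

test_that("MAPQ threshold is a strict lower bound at 30", {
  tags <- make_tags(start = c(0, 100), mapq = c(29, 30))
  res <- filter_alignments(tags)
  expect_equal(res$tags$mapq, 30L)
})

test_that("filtering an empty library yields empty output and zero stats", {
  res <- filter_alignments(make_tags()[0, ])
  expect_equal(nrow(res$tags), 0L)
  expect_true(all(res$stats == 0L))
})

test_that("duplicate marking keys on (chromosome, 5'-end, strand)", {
  three <- make_tags(start = c(100, 100, 100))
  m <- mark_pcr_duplicates(three)
  expect_equal(sum(!m$pcr_duplicate), 1L)
  # opposite strands over the same span are distinct
  pair <- make_tags(start = c(100, 100), strand = c("+", "-"))
  expect_equal(sum(mark_pcr_duplicates(pair)$pcr_duplicate), 0L)
  # all distinct -> none flagged; and marking is idempotent
  dist <- make_tags(start = c(0, 60, 120))
  m1 <- mark_pcr_duplicates(dist)
  expect_equal(sum(m1$pcr_duplicate), 0L)
  expect_identical(mark_pcr_duplicates(m1), m1)
})

test_that("complexity metrics match hand counts and a brute-force tally", {
  # multiplicities (1,1,1,1,2,4) over 6 positions
  starts <- c(0, 100, 200, 300, 400, 400, rep(500, 4))
  cm <- complexity_metrics(make_tags(start = starts))
  expect_equal(cm$total_tags, 10L)
  expect_equal(cm$nrf, 0.6)
  expect_equal(cm$pbc1, 4 / 6)
  expect_equal(cm$pbc2, 4)
  # all distinct -> NRF 1, PBC1 1, PBC2 infinite
  cm2 <- complexity_metrics(make_tags(start = c(0, 60, 120)))
  expect_equal(cm2$nrf, 1)
  expect_equal(cm2$pbc1, 1)
  expect_true(is.infinite(cm2$pbc2))
  expect_error(complexity_metrics(make_tags()[0, ]), "empty")
  # randomized agreement with an independent sort-and-count oracle
  set.seed(42)
  for (i in 1:20) {
    tags <- make_tags(start = sample.int(50, 200, replace = TRUE) * 10,
                      strand = sample(c("+", "-"), 200, replace = TRUE))
    key <- paste(ifelse(tags$strand == "+", tags$start, tags$end),
                 tags$strand)
    counts <- as.integer(table(key))
    cm3 <- complexity_metrics(tags)
    expect_equal(cm3$distinct_positions, length(counts))
    expect_equal(cm3$nrf, length(counts) / 200)
    expect_equal(cm3$pbc1, sum(counts == 1) / length(counts))
  }
})

test_that("cross-correlation recovers an exact translation", {
  plus <- make_tags(start = c(100, 300, 700))
  minus <- make_tags(start = c(100, 300, 700) + 150, strand = "-")
  # minus 5' ends at start+200 => exact lag 200
  xc <- cross_correlation(rbind(plus, minus), c(chr1 = 2000),
                          max_shift = 300)
  expect_equal(xc$fragment_shift, 200L)
  expect_equal(xc$cc[xc$shifts == 200], 1, tolerance = 1e-12)
  expect_equal(xc$phantom_shift, 50L)
})

test_that("cross-correlation equals the direct Pearson formula on 4-vectors", {
  # plus counts (1,0,2,0), minus counts (0,1,0,2) on a 4 bp chromosome
  cc <- histomark:::.xcor_chrom(c(0, 2, 2), c(1, 3, 3), 4, 0:1)
  expect_equal(cc[1], stats::cor(c(1, 0, 2, 0), c(0, 1, 0, 2)),
               tolerance = 1e-12)
  # shift 1: x over t = 0..2 against y over t = 1..3
  expect_equal(cc[2], stats::cor(c(1, 0, 2), c(1, 0, 2)), tolerance = 1e-12)
})

test_that("cross-correlation input contracts are enforced", {
  plus_only <- make_tags(start = c(0, 100))
  expect_error(cross_correlation(plus_only, c(chr1 = 1000)), "strand")
  both <- rbind(plus_only, make_tags(start = 300, strand = "-"))
  expect_error(cross_correlation(both, c(chr1 = 1000), max_shift = 40),
               "max_shift")
})

test_that("JSD is zero for identical count distributions and matches the closed form", {
  chip <- make_tags(start = c(0, 600, 1200, 1800))
  fp <- jsd_fingerprint(chip, chip, c(chr1 = 2000), bin_size = 500)
  expect_equal(fp$jsd, 0)
  expect_error(jsd_fingerprint(chip, chip, c(chr1 = 2000), bin_size = 0),
               "bin_size")
  # direct evaluation of the divergence for p = (1,0), q = (.5,.5)
  expected <- sqrt((log2(4 / 3) + 0.5 * log2(2 / 3) + 0.5 * log2(2)) / 2)
  expect_equal(js_distance(c(1, 0), c(0.5, 0.5)), expected, tolerance = 1e-12)
  expect_equal(js_distance(c(1, 0), c(0.5, 0.5)), 0.558, tolerance = 1e-3)
  expect_error(js_distance(c(0.7, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("threshold verdicts are strict and complete", {
  # published per-library metric rows exercise both verdict outcomes
  good <- data.frame(NRF = 0.677, PBC1 = 0.673, PBC2 = 3.017, NSC = 1.068,
                     RSC = 1.249, JSD = 0.281)
  v <- qc_verdict(good)
  expect_equal(v$n_failed, 0)
  bad <- good
  bad$NRF <- 0.435
  expect_false(qc_verdict(bad)$NRF_pass)
  # metrics exactly at threshold all fail (strict inequality)
  at <- data.frame(NRF = 0.5, PBC1 = 0.5, PBC2 = 1, NSC = 1.05, RSC = 0.8,
                   JSD = 0.05)
  expect_equal(qc_verdict(at)$n_failed, 6)
  expect_error(qc_verdict(good[, -1]), "incomplete")
  # infinite PBC2 passes
  inf <- good
  inf$PBC2 <- Inf
  expect_true(qc_verdict(inf)$PBC2_pass)
})

test_that("raising duplication degrades NRF monotonically", {
  st <- small_study()
  nrf <- vapply(c(0.05, 0.3, 0.6), function(d) {
    cfg <- st$cfg
    cfg$duplication_rate <- d
    tags <- simulate_library(st$truth, "tissue1", "H3K4me1", 1, cfg)
    complexity_metrics(filter_alignments(tags)$tags)$nrf
  }, numeric(1))
  expect_true(all(diff(nrf) < 0))
})
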