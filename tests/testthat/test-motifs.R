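jaspar_fixture <- function() {
  path <- withr::local_tempfile(fileext = ".jaspar",
                                .local_envir = parent.frame())
  writeLines(c(
    ">MA0001 TESTA",
    "A [ 10  0  0 10 ]",
    "C [  0 10  0  0 ]",
    "G [  0  0 10  0 ]",
    "T [  0  0  0  0 ]",
    ">MA0002 TESTB",
    "A [ 5 5 ]",
    "C [ 1 1 ]",
    "G [ 1 1 ]",
    "T [ 1 1 ]"), path)
  path
}

test_that("JASPAR parsing recovers matrix structure and log-odds", {
  pwms <- read_jaspar(jaspar_fixture())
  expect_length(pwms, 2L)
  expect_equal(pwms$MA0001$width, 4L)
  expect_equal(pwms$MA0002$width, 2L)
  expect_equal(pwms$MA0001$name, "TESTA")
  # closed-form log-odds: log2((c + 0.25) / (N + 1) / 0.25)
  counts <- pwms$MA0001$counts
  want <- log2((counts + 0.25) /
                 rep(colSums(counts) + 1, each = 4) / 0.25)
  expect_equal(pwms$MA0001$logodds, want, tolerance = 1e-12)
  # an all-zero column is rejected
  bad <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M X", "A [ 0 1 ]", "C [ 0 1 ]", "G [ 0 1 ]", "T [ 0 1 ]"),
             bad)
  expect_error(read_jaspar(bad), "empty column")
  # a record without four rows is malformed
  bad2 <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M X", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), bad2)
  expect_error(read_jaspar(bad2), "4 count rows")
})

test_that("scanning finds the consensus at maximum score on both strands", {
  pw <- consensus_pwm("ACGA")
  hit <- scan_pwm(c(s1 = "ACGA"), pw)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$offset, 0L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$score, pw$max_score, tolerance = 1e-12)
  # reverse complement planted on the minus strand
  hit2 <- scan_pwm(c(s1 = "TTTCGTTT"), pw)  # revcomp(ACGA) = TCGT
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$offset, 2L)
  # sequences shorter than the motif are skipped
  expect_equal(nrow(scan_pwm(c(s = "AC"), pw)), 0L)
})

test_that("IUPAC degeneracy is honoured by the consensus PWM", {
  pw <- consensus_pwm("DAAAYA")
  expect_equal(nrow(scan_pwm(c(s = "GAAACA"), pw)), 1L)  # D~G, Y~C
  expect_equal(nrow(scan_pwm(c(s = "CAAACA"), pw)), 0L)  # C not in D
})

test_that("scanning is strand-symmetric under reverse complement", {
  pw <- consensus_pwm("ACGTAC")
  set.seed(31)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("s%d", 1:10)
  rc <- vapply(seqs, function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), character(1))
  h1 <- scan_pwm(seqs, pw, rel_threshold = 0.6)
  h2 <- scan_pwm(rc, pw, rel_threshold = 0.6)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-12)
  expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
})

test_that("Fisher enrichment p-values equal hypergeometric tail enumeration", {
  # spot example: 8/10 foreground vs 1/10 background carriers
  enum_p <- function(a, fg_n, b, bg_n) {
    k <- a + b
    poss <- max(0, k - bg_n):min(fg_n, k)
    probs <- choose(fg_n, poss) * choose(bg_n, k - poss) /
      choose(fg_n + bg_n, k)
    sum(probs[poss >= a])
  }
  expect_equal(enum_p(8, 10, 1, 10), 0.00273, tolerance = 1e-2)
  expect_equal(stats::fisher.test(matrix(c(8, 2, 1, 9), 2),
                                  alternative = "greater")$p.value,
               enum_p(8, 10, 1, 10), tolerance = 1e-12)
  # exhaustive agreement on all margins <= 12 (subset of the <= 30 space)
  for (fg_n in c(3, 7, 12)) {
    for (bg_n in c(4, 9)) {
      for (a in 0:fg_n) {
        for (b in 0:bg_n) {
          got <- stats::fisher.test(
            matrix(c(a, fg_n - a, b, bg_n - b), 2),
            alternative = "greater")$p.value
          expect_equal(got, enum_p(a, fg_n, b, bg_n), tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("identical foreground and background give no enrichment", {
  set.seed(17)
  seqs <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("s%d", seq_along(seqs))
  pwms <- list(consensus_pwm("DAAAYA"), consensus_pwm("GCGCGC"))
  res <- motif_enrichment(seqs, seqs, pwms)
  # with identical carrier counts the one-sided tail is never small
  expect_true(all(res$p > 0.3))
  expect_true(all(res$adjusted_p > 0.05))
  expect_true(all(res$adjusted_p >= res$p))
  expect_error(motif_enrichment(character(0), seqs, pwms), "foreground")
})

test_that("a planted consensus ranks first and is uniquely detected", {
  cfg <- sim_config(seed = 23, chrom_lengths = c(chr1 = 1e6),
                    n_shared_elements = 5,
                    n_specific_elements_per_tissue = 30,
                    element_length = 200, n_tissues = 3,
                    motif_consensus = c("DAAAYA", "YTGCCCDBA",
                                        "VSAGCAGCTGSNN"))
  truth <- plant_elements(cfg, make_genome(cfg))
  pwms <- list(planted = consensus_pwm("DAAAYA", id = "planted"),
               other1 = consensus_pwm("YTGCCCDBA", id = "other1"),
               other2 = consensus_pwm("VSAGCAGCTGSNN", id = "other2"),
               decoy = consensus_pwm("GGGGCCCC", id = "decoy"))
  res <- lapply(stats::setNames(cfg$tissues, cfg$tissues), function(t) {
    el <- truth$elements
    ivs <- el[el$element_class == "tissue_specific" & el$owner_tissue == t,
              c("chrom", "start", "end", "name")]
    fg <- interval_sequences(ivs, truth$genome)
    motif_enrichment(fg, dinucleotide_shuffle(fg, seed = 100 + nchar(t),
                                              n = 5), pwms)
  })
  r1 <- res$tissue1
  expect_equal(r1$adjusted_p[r1$motif == "planted"], min(r1$adjusted_p))
  expect_equal(r1$motif[r1$rank == 1], "planted")
  expect_lte(r1$adjusted_p[r1$motif == "planted"], 0.05)
  ud <- uniquely_detected(res, alpha = 0.05)
  expect_true("planted" %in% ud$tissue1)
  expect_false("planted" %in% unlist(ud[c("tissue2", "tissue3")]))
})

test_that("motif significant in several tissues is unique nowhere", {
  mk <- function(p) data.frame(motif = c("m1", "m2"), adjusted_p = p,
                               stringsAsFactors = FALSE)
  res <- list(t1 = mk(c(0.001, 0.8)), t2 = mk(c(0.004, 0.9)),
              t3 = mk(c(0.5, 0.01)))
  ud <- uniquely_detected(res, alpha = 0.05)
  expect_false("m1" %in% unlist(ud))
  expect_equal(ud$t3, "m2")
  # nothing significant anywhere -> empty everywhere
  res0 <- list(t1 = mk(c(0.9, 0.9)), t2 = mk(c(0.8, 0.7)))
  expect_true(all(lengths(uniquely_detected(res0)) == 0L))
  expect_error(uniquely_detected(res[1]), "two")
})
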