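test_that("genome generation is deterministic and respects the config", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 100000, chr2 = 50000),
                    n_genes = 5, n_shared_elements = 4,
                    n_specific_elements_per_tissue = 1, seed = 7)
  g1 <- make_genome(cfg)
  expect_equal(unname(Biostrings::width(g1$genome)), c(100000L, 50000L))
  expect_equal(g1$chrom_sizes$chrom, c("chr1", "chr2"))
  g2 <- make_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  cfg8 <- sim_config(chrom_lengths = c(chr1 = 100000, chr2 = 50000),
                     n_genes = 5, n_shared_elements = 4,
                     n_specific_elements_per_tissue = 1, seed = 8)
  g3 <- make_genome(cfg8)
  expect_equal(unname(Biostrings::width(g3$genome)),
               unname(Biostrings::width(g1$genome)))
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(chrom_lengths = c(chr1 = 0)), "positive")
  expect_error(sim_config(read_length = 300), "read_length")
  expect_error(sim_config(duplication_rate = 1), "duplication_rate")
  expect_error(sim_config(enrichment_fold = 0.5), "enrichment_fold")
})

test_that("planted elements honour counts, disjointness and motifs", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 200000), n_tissues = 2,
                    n_shared_elements = 5, n_specific_elements_per_tissue = 3,
                    element_length = 500, n_phantom_sites = 10, seed = 3)
  truth <- plant_elements(cfg, make_genome(cfg))
  el <- truth$elements
  expect_equal(sum(el$element_class == "shared"), 5L)
  expect_equal(sum(el$element_class == "tissue_specific"), 6L)
  expect_true(all(table(el$owner_tissue[el$element_class ==
                                          "tissue_specific"]) == 3L))
  # pairwise non-overlapping
  expect_false(any(histomark:::.self_overlapping(el)))
  # every element inside the genome
  expect_true(all(el$start >= 0 & el$end <= 200000))
  # every tissue-specific enhancer carries an IUPAC match of its consensus
  spec <- el[el$element_class == "tissue_specific", ]
  for (i in seq_len(nrow(spec))) {
    seq <- Biostrings::subseq(truth$genome[[spec$chrom[i]]],
                              spec$start[i] + 1L, spec$end[i])
    hits <- Biostrings::matchPattern("DAAAYA", seq, fixed = FALSE)
    rc <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString("DAAAYA")),
      seq, fixed = FALSE)
    expect_gte(length(hits) + length(rc), 1L)
  }
})

test_that("element placement fails loudly when the genome is too small", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 10000), n_tissues = 2,
                    n_shared_elements = 20,
                    n_specific_elements_per_tissue = 5,
                    element_length = 1000, seed = 1)
  expect_error(plant_elements(cfg, make_genome(cfg)), "too small")
})

test_that("simulated libraries have the contracted geometry", {
  st <- small_study()
  tags <- simulate_library(st$truth, "tissue1", "H3K4me1", 1)
  expect_equal(nrow(tags), st$cfg$reads_per_library)
  expect_true(all(tags$end - tags$start == st$cfg$read_length))
  expect_true(all(tags$mapq == 60L))
  # every tag fully inside its chromosome
  sz <- stats::setNames(st$sizes$size, st$sizes$chrom)
  expect_true(all(tags$start >= 0 & tags$end <= sz[tags$chrom]))
  # determinism and independence of streams
  again <- simulate_library(st$truth, "tissue1", "H3K4me1", 1)
  expect_identical(tags, again)
  other <- simulate_library(st$truth, "tissue1", "H3K4me1", 2)
  expect_false(identical(tags$start, other$start))
  expect_error(simulate_library(st$truth, "nope", "H3K4me1", 1), "tissue")
  expect_error(simulate_library(st$truth, "tissue1", "H3K9me3", 1), "mark")
})

test_that("input libraries are unenriched and dup-free libraries are complex", {
  st <- small_study()
  cfg0 <- st$cfg
  cfg0$duplication_rate <- 0
  inp <- simulate_library(st$truth, "tissue1", "input", 1, cfg0)
  cm <- complexity_metrics(filter_alignments(inp)$tags)
  expect_gt(cm$nrf, 0.95)
  # input depth inside elements matches background (no enrichment)
  el <- st$truth$elements
  in_el <- histomark:::.overlaps_any(
    inp[, c("chrom", "start", "end")], el[, c("chrom", "start", "end")])
  frac_el <- mean(in_el)
  frac_genome <- sum(el$end - el$start) / 1e6
  expect_lt(abs(frac_el - frac_genome), 3 * frac_genome)
})

test_that("enrichment fold is recovered from per-base depth", {
  st <- small_study()
  cfg <- st$cfg
  cfg$duplication_rate <- 0
  tags <- simulate_library(st$truth, "tissue1", "H3K4me1", 1, cfg)
  el <- st$truth$elements
  rel <- el[el$element_class == "shared" | el$owner_tissue == "tissue1", ]
  in_el <- histomark:::.overlaps_any(tags[, c("chrom", "start", "end")],
                                     rel[, c("chrom", "start", "end")])
  el_bp <- sum(rel$end - rel$start)
  depth_in <- sum(in_el) / el_bp
  depth_out <- sum(!in_el) / (1e6 - el_bp)
  ratio <- depth_in / depth_out
  # reads at element borders blur the ratio; 20x within a generous CI
  expect_gt(ratio, 12)
  expect_lt(ratio, 28)
})

test_that("MAPQ decoys are injected at the requested fraction", {
  st <- small_study()
  tags <- simulate_library(st$truth, "tissue1", "H3K4me1", 1,
                           decoy_fraction = 0.1)
  expect_equal(mean(tags$mapq < 30), 0.1, tolerance = 0.01)
  expect_true(all(tags$mapq[tags$mapq < 60] <= 29))
})

test_that("truth tables round-trip through TSV", {
  st <- small_study()
  dir <- withr::local_tempdir()
  paths <- write_truth(st$truth, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.table(paths[1], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(st$truth$elements))
  expect_equal(back$start, st$truth$elements$start)
})
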