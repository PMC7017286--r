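#' Simulation configuration for multi-tissue histone ChIP-seq libraries
#'
#' Builds the configuration object consumed by [make_genome()],
#' [make_genes()], [plant_elements()] and [simulate_library()]. The defaults
#' describe a desk-scale study that preserves the statistical structure of a
#' full histone ChIP-seq experiment: 50 bp single-end reads from ~200 bp
#' fragments, two biological replicates per tissue, four marks plus an input
#' per tissue, and a genome sized so that 200,000 reads give the same read
#' density as ~30 M reads on a mammalian genome. Planted regulatory elements
#' cover ~3% of the genome per mark, comparable to the genome fraction peaks
#' of an active mark occupy in real tissue.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_tissues number of tissues; tissue names are `tissue1..tissueN`.
#' @param marks histone mark names; tissue-specific elements always carry
#'   both H3K4me1 and H3K27ac so that they are active enhancers.
#' @param read_length read length in bp (single-end).
#' @param fragment_mean,fragment_sd fragment length distribution (truncated
#'   normal, truncated at `read_length`).
#' @param duplication_rate fraction of reads that are PCR copies of
#'   already-emitted reads, in `[0, 1)`.
#' @param enrichment_fold ratio of fragment-start rate inside an element
#'   carrying the immunoprecipitated mark to the background rate; >= 1.
#' @param background_rate background fragment-start rate in reads per bp; if
#'   `NULL`, implied by `reads_per_library` over the genome.
#' @param reads_per_library total tags emitted per library.
#' @param n_shared_elements number of elements shared by all tissues.
#' @param n_specific_elements_per_tissue tissue-specific active enhancers
#'   planted per tissue.
#' @param element_length planted element width (bp).
#' @param motif_consensus IUPAC consensus (or character vector, recycled
#'   over tissues) planted once inside every tissue-specific active
#'   enhancer; with one consensus per tissue, each motif has a single owner
#'   tissue and can be uniquely detected there.
#' @param tss_fraction fraction of shared elements anchored at gene
#'   transcription start sites (promoter-like placement) when gene models
#'   are supplied to [plant_elements()].
#' @param replicate_sdlog sd (log scale) of the lognormal factor that
#'   perturbs per-element rates between biological replicates.
#' @param n_phantom_sites,phantom_rate number of mappability-island hotspot
#'   positions and the fraction of reads drawn from them. Hotspot reads
#'   cover the identical interval on either strand, reproducing the
#'   "phantom peak" strand correlation at the read length that real aligned
#'   data show.
#' @param decoy_fraction fraction of tags re-assigned a low mapping quality
#'   (uniform in 0..29) to exercise the MAPQ filter; 0 by default.
#' @param n_genes number of gene models generated by [make_genes()].
#' @param seed master integer seed; all per-library streams derive from it.
#' @return A list of class `sim_config`.
#' @seealso [simulate_library()], [plant_elements()]
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 6e6, chr2 = 4e6),
                       n_tissues = 3,
                       marks = c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3"),
                       read_length = 50,
                       fragment_mean = 200,
                       fragment_sd = 20,
                       duplication_rate = 0.1,
                       enrichment_fold = 20,
                       background_rate = NULL,
                       reads_per_library = 200000,
                       n_shared_elements = 300,
                       n_specific_elements_per_tissue = 30,
                       element_length = 1000,
                       motif_consensus = "DAAAYA",
                       tss_fraction = 0.5,
                       replicate_sdlog = 0.25,
                       n_phantom_sites = 100,
                       phantom_rate = 0.005,
                       decoy_fraction = 0,
                       n_genes = 200,
                       seed = 1) {
  chrom_lengths <- .as_chrom_sizes(chrom_lengths)
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome", call. = FALSE)
  if (read_length > fragment_mean)
    stop("read_length must not exceed fragment_mean", call. = FALSE)
  if (duplication_rate < 0 || duplication_rate >= 1)
    stop("duplication_rate must be in [0, 1)", call. = FALSE)
  if (enrichment_fold < 1) stop("enrichment_fold must be >= 1", call. = FALSE)
  if (n_tissues < 1) stop("need at least one tissue", call. = FALSE)
  cfg <- list(chrom_lengths = chrom_lengths,
              n_tissues = as.integer(n_tissues),
              tissues = paste0("tissue", seq_len(n_tissues)),
              marks = marks,
              read_length = as.integer(read_length),
              fragment_mean = fragment_mean,
              fragment_sd = fragment_sd,
              duplication_rate = duplication_rate,
              enrichment_fold = enrichment_fold,
              background_rate = background_rate %||%
                (reads_per_library / sum(chrom_lengths)),
              reads_per_library = as.integer(reads_per_library),
              n_shared_elements = as.integer(n_shared_elements),
              n_specific_elements_per_tissue =
                as.integer(n_specific_elements_per_tissue),
              element_length = as.integer(element_length),
              motif_consensus = motif_consensus,
              tss_fraction = tss_fraction,
              replicate_sdlog = replicate_sdlog,
              n_phantom_sites = as.integer(n_phantom_sites),
              phantom_rate = phantom_rate,
              decoy_fraction = decoy_fraction,
              n_genes = as.integer(n_genes),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ChIP-seq simulation config\n")
  cat(sprintf("  genome: %d chromosome(s), %.3g bp total\n",
              length(x$chrom_lengths), sum(x$chrom_lengths)))
  cat(sprintf("  tissues: %d; marks: %s\n", x$n_tissues,
              paste(x$marks, collapse = ", ")))
  cat(sprintf("  reads/library: %d x %d bp; fragments ~N(%g, %g)\n",
              x$reads_per_library, x$read_length,
              x$fragment_mean, x$fragment_sd))
  cat(sprintf("  duplication %.2f, enrichment fold %g, elements %d shared + %d/tissue\n",
              x$duplication_rate, x$enrichment_fold,
              x$n_shared_elements, x$n_specific_elements_per_tissue))
  invisible(x)
}

#' Generate a random uniform-composition genome
#'
#' @param config a [sim_config()] object.
#' @return A list with `genome` (a [Biostrings::DNAStringSet]) and
#'   `chrom_sizes` (data.frame with columns `chrom`, `size`). Deterministic
#'   under `config$seed`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  seqs <- vapply(config$chrom_lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(config$chrom_lengths)
  list(genome = genome,
       chrom_sizes = data.frame(chrom = names(config$chrom_lengths),
                                size = as.integer(config$chrom_lengths),
                                stringsAsFactors = FALSE))
}

#' Generate random non-overlapping gene models
#'
#' Gene bodies (2-20 kb) with strand, used for metagene topology profiles
#' and as anchors for promoter-like element placement.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (0-based half-open).
#' @export
make_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genes"))
  sz <- config$chrom_lengths
  n <- config$n_genes
  lens <- round(stats::runif(n, 2000, 20000))
  placed <- .place_intervals(lens, sz, flank = 3500)
  data.frame(chrom = placed$chrom, start = placed$start, end = placed$end,
             name = sprintf("gene%04d", seq_len(nrow(placed))),
             strand = sample(c("+", "-"), nrow(placed), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Place intervals of the given lengths uniformly without overlap (rejection
# sampling with a per-interval `flank` bp clearance). Errors out when the
# genome cannot host them.
.place_intervals <- function(lens, chrom_sizes, flank = 0,
                             max_tries = 200L, occupied = NULL) {
  total <- sum(chrom_sizes)
  if (sum(lens + 2 * flank) > 0.8 * total)
    stop("genome too small to place the requested elements without overlap",
         call. = FALSE)
  occ <- lapply(chrom_sizes, function(x) IRanges::IRanges())
  if (!is.null(occupied) && nrow(occupied) > 0L) {
    for (ch in unique(occupied$chrom)) {
      occ[[ch]] <- .as_iranges(occupied[occupied$chrom == ch, , drop = FALSE])
    }
  }
  out <- vector("list", length(lens))
  cw <- chrom_sizes / total
  for (i in seq_along(lens)) {
    len <- lens[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(names(chrom_sizes), 1L, prob = cw)
      if (chrom_sizes[[ch]] < len + 2) next
      s <- floor(stats::runif(1, 0, chrom_sizes[[ch]] - len))
      cand <- IRanges::IRanges(s + 1 - flank, s + len + flank)
      if (length(occ[[ch]]) == 0L ||
          !any(IRanges::overlapsAny(cand, occ[[ch]]))) {
        occ[[ch]] <- c(occ[[ch]], IRanges::IRanges(s + 1, s + len))
        out[[i]] <- data.frame(chrom = ch, start = s, end = s + len,
                               stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("genome too small to place the requested elements without overlap",
           call. = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Sample one concrete base per IUPAC code position.
.iupac_map <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

.sample_iupac <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  out <- vapply(letters, function(l) {
    opts <- .iupac_map[[l]]
    if (is.null(opts)) stop("unknown IUPAC code: ", l, call. = FALSE)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = "")
}

#' Plant regulatory elements (and their motifs) into a genome
#'
#' Places non-overlapping elements of two classes: *shared* elements
#' carrying all marks in every tissue, and *tissue-specific active
#' enhancers* carrying H3K4me1 + H3K27ac in exactly one tissue. One
#' concrete instance of the tissue's motif consensus is substituted into
#' the genome sequence of each tissue-specific enhancer (random offset and
#' strand) and recorded. A set of phantom hotspot positions (mappability
#' islands) is also drawn. When gene models are supplied, a `tss_fraction`
#' of shared elements is anchored at gene starts, emulating promoters.
#'
#' @param config a [sim_config()] object.
#' @param genome result of [make_genome()] (list with `genome`,
#'   `chrom_sizes`), or a `DNAStringSet`.
#' @param genes optional gene models from [make_genes()].
#' @return A list of class `truth_set`: `elements` (data.frame with
#'   `chrom`, `start`, `end`, `name`, `element_class`, `owner_tissue`,
#'   `marks_present`), `motif_sites` (`chrom`, `pos`, `strand`,
#'   `consensus`, `instance`, `element`), `phantom_sites` (`chrom`, `pos`),
#'   and the updated `genome`.
#' @export
plant_elements <- function(config, genome, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  stopifnot(methods::is(genome, "DNAStringSet"))
  set.seed(derive_seed(config$seed, "elements"))
  sz <- config$chrom_lengths
  elen <- config$element_length
  n_shared <- config$n_shared_elements
  n_spec <- config$n_specific_elements_per_tissue * config$n_tissues

  tss_anchored <- NULL
  n_tss <- 0L
  if (!is.null(genes) && nrow(genes) > 0L && config$tss_fraction > 0) {
    n_tss <- min(round(config$tss_fraction * n_shared), nrow(genes))
    if (n_tss > 0L) {
      pick <- sample(nrow(genes), n_tss)
      tss <- ifelse(genes$strand[pick] == "+", genes$start[pick],
                    genes$end[pick])
      s <- pmax(0, pmin(tss - elen %/% 2, sz[genes$chrom[pick]] - elen))
      tss_anchored <- data.frame(chrom = genes$chrom[pick], start = s,
                                 end = s + elen, stringsAsFactors = FALSE)
      # drop placements that collide with one another
      keep <- !duplicated(paste(tss_anchored$chrom, tss_anchored$start)) &
        !.self_overlapping(tss_anchored)
      tss_anchored <- tss_anchored[keep, , drop = FALSE]
      n_tss <- nrow(tss_anchored)
    }
  }
  n_free <- n_shared - n_tss + n_spec
  free <- .place_intervals(rep(elen, n_free), sz, occupied = tss_anchored)
  shared <- rbind(tss_anchored,
                  free[seq_len(n_shared - n_tss), , drop = FALSE])
  specific <- free[seq_len(n_spec) + (n_shared - n_tss), , drop = FALSE]

  owner <- rep(config$tissues, each = config$n_specific_elements_per_tissue)
  elements <- rbind(
    data.frame(shared,
               element_class = "shared", owner_tissue = "all",
               marks_present = paste(config$marks, collapse = ","),
               stringsAsFactors = FALSE),
    data.frame(specific,
               element_class = "tissue_specific", owner_tissue = owner,
               marks_present = "H3K4me1,H3K27ac",
               stringsAsFactors = FALSE))
  elements$name <- sprintf("elem%04d", seq_len(nrow(elements)))
  rownames(elements) <- NULL

  # motif planting inside tissue-specific active enhancers; the consensus
  # vector is recycled over tissues so each tissue can own its own motif
  tissue_motif <- stats::setNames(
    rep(config$motif_consensus, length.out = config$n_tissues),
    config$tissues)
  seqs <- stats::setNames(as.character(genome), names(genome))
  spec_idx <- which(elements$element_class == "tissue_specific")
  motif_sites <- lapply(spec_idx, function(i) {
    consensus <- tissue_motif[[elements$owner_tissue[i]]]
    w <- nchar(consensus)
    off <- sample.int(elen - w, 1L)
    strand <- sample(c("+", "-"), 1L)
    inst <- .sample_iupac(consensus)
    if (strand == "-")
      inst <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(inst)))
    pos <- elements$start[i] + off
    data.frame(chrom = elements$chrom[i], pos = pos, strand = strand,
               consensus = consensus, instance = inst,
               element = elements$name[i], stringsAsFactors = FALSE)
  })
  motif_sites <- do.call(rbind, motif_sites) %||%
    data.frame(chrom = character(), pos = integer(), strand = character(),
               consensus = character(), instance = character(),
               element = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(motif_sites))) {
    ch <- motif_sites$chrom[i]
    w <- nchar(motif_sites$instance[i])
    substr(seqs[[ch]], motif_sites$pos[i] + 1L, motif_sites$pos[i] + w) <-
      motif_sites$instance[i]
  }
  genome <- Biostrings::DNAStringSet(seqs)

  phantom <- if (config$n_phantom_sites > 0L) {
    ch <- sample(names(sz), config$n_phantom_sites, replace = TRUE,
                 prob = sz / sum(sz))
    data.frame(chrom = ch,
               pos = floor(stats::runif(config$n_phantom_sites, 0,
                                        sz[ch] - config$read_length)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), pos = integer(), stringsAsFactors = FALSE)
  }

  out <- list(elements = elements, motif_sites = motif_sites,
              phantom_sites = phantom, genome = genome, config = config)
  class(out) <- "truth_set"
  out
}

.self_overlapping <- function(df) {
  if (nrow(df) < 2L) return(rep(FALSE, nrow(df)))
  out <- rep(FALSE, nrow(df))
  for (ch in unique(df$chrom)) {
    sel <- which(df$chrom == ch)
    ir <- .as_iranges(df[sel, , drop = FALSE])
    cnt <- IRanges::countOverlaps(ir, ir)
    out[sel] <- cnt > 1L
  }
  out
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth set: %d elements (%d shared, %d tissue-specific), %d motif sites\n",
              nrow(x$elements),
              sum(x$elements$element_class == "shared"),
              sum(x$elements$element_class == "tissue_specific"),
              nrow(x$motif_sites)))
  invisible(x)
}

#' Simulate one aligned ChIP or input library
#'
#' Draws fragments from a mixture of uniform genomic background and, for a
#' histone mark library, an `enrichment_fold`-elevated fragment-start rate
#' inside every element that carries the mark in this tissue (shared
#' elements and the tissue's own specific elements). Fragment lengths are
#' truncated normal; each fragment emits a single read of `read_length`
#' from a uniformly chosen strand (plus reads start at the fragment start,
#' minus reads end at the fragment end). A small fraction of reads
#' originates at phantom hotspot positions where either strand covers the
#' identical interval. Per-element rates are perturbed between replicates
#' by a lognormal factor. Finally a `duplication_rate` fraction of tags are
#' exact copies of already-emitted tags (PCR duplicates, unflagged).
#'
#' @param truth a `truth_set` from [plant_elements()].
#' @param tissue tissue name (e.g. `"tissue1"`).
#' @param mark a mark in `config$marks`, or `"input"`.
#' @param replicate replicate index (1 or 2 in a standard design).
#' @param config a [sim_config()]; defaults to the one stored in `truth`.
#' @param decoy_fraction overrides `config$decoy_fraction`; fraction of
#'   tags given MAPQ drawn uniformly in 0..29 (alignment-quality decoys).
#' @return A data.frame of aligned tags with columns `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `mapq`, and logical flag columns
#'   `unmapped`, `secondary`, `qc_fail`, `optical_duplicate`,
#'   `pcr_duplicate` (all `FALSE`; duplicates are only *marked* later by
#'   [mark_pcr_duplicates()]).
#' @export
simulate_library <- function(truth, tissue, mark, replicate, config = NULL,
                             decoy_fraction = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  config <- config %||% truth$config
  decoy_fraction <- decoy_fraction %||% config$decoy_fraction
  if (!(tissue %in% config$tissues))
    stop("unknown tissue: ", tissue, call. = FALSE)
  if (!(mark %in% c(config$marks, "input")))
    stop("unknown mark: ", mark, call. = FALSE)
  set.seed(derive_seed(config$seed, "lib", tissue, mark, replicate))

  sz <- config$chrom_lengths
  rl <- config$read_length
  n_total <- config$reads_per_library
  n_dup <- round(config$duplication_rate * n_total)
  n_new <- n_total - n_dup
  n_ph <- if (nrow(truth$phantom_sites) > 0L)
    round(config$phantom_rate * n_new) else 0L
  n_frag <- n_new - n_ph

  # mixture weights: genome background + relevant elements
  el <- truth$elements
  relevant <- if (mark == "input") el[0, , drop = FALSE] else {
    has_mark <- vapply(strsplit(el$marks_present, ","), function(m)
      mark %in% m, logical(1))
    el[has_mark & (el$element_class == "shared" | el$owner_tissue == tissue), ,
       drop = FALSE]
  }
  repfac <- if (nrow(relevant) > 0L)
    stats::rlnorm(nrow(relevant), 0, config$replicate_sdlog) else numeric(0)
  elw <- (config$enrichment_fold - 1) * (relevant$end - relevant$start) *
    repfac
  comp <- sample.int(1L + nrow(relevant), n_frag, replace = TRUE,
                     prob = c(sum(sz), elw))

  chrom <- character(n_frag)
  fstart <- numeric(n_frag)
  bg <- comp == 1L
  n_bg <- sum(bg)
  if (n_bg > 0L) {
    ch <- sample(names(sz), n_bg, replace = TRUE, prob = sz / sum(sz))
    chrom[bg] <- ch
    fstart[bg] <- floor(stats::runif(n_bg, 0, sz[ch]))
  }
  if (any(!bg)) {
    ei <- comp[!bg] - 1L
    chrom[!bg] <- relevant$chrom[ei]
    fstart[!bg] <- relevant$start[ei] +
      floor(stats::runif(sum(!bg), 0,
                         relevant$end[ei] - relevant$start[ei]))
  }
  flen <- pmax(rl, round(stats::rnorm(n_frag, config$fragment_mean,
                                      config$fragment_sd)))
  strand <- sample(c("+", "-"), n_frag, replace = TRUE)
  start <- ifelse(strand == "+", fstart, fstart + flen - rl)
  # keep every tag fully inside its chromosome
  start <- pmax(0, pmin(start, sz[chrom] - rl))

  if (n_ph > 0L) {
    ps <- truth$phantom_sites[sample.int(nrow(truth$phantom_sites), n_ph,
                                         replace = TRUE), , drop = FALSE]
    chrom <- c(chrom, ps$chrom)
    start <- c(start, ps$pos)
    strand <- c(strand, sample(c("+", "-"), n_ph, replace = TRUE))
  }

  if (n_dup > 0L) {
    src <- sample.int(length(chrom), n_dup, replace = TRUE)
    chrom <- c(chrom, chrom[src])
    start <- c(start, start[src])
    strand <- c(strand, strand[src])
  }

  mapq <- rep(60L, length(chrom))
  if (decoy_fraction > 0) {
    nd <- round(decoy_fraction * length(chrom))
    if (nd > 0L) {
      idx <- sample.int(length(chrom), nd)
      mapq[idx] <- sample(0:29, nd, replace = TRUE)
    }
  }

  tags <- data.frame(chrom = chrom, start = as.integer(start),
                     end = as.integer(start) + rl, strand = strand,
                     mapq = mapq, unmapped = FALSE, secondary = FALSE,
                     qc_fail = FALSE, optical_duplicate = FALSE,
                     pcr_duplicate = FALSE, stringsAsFactors = FALSE)
  attr(tags, "library") <- list(tissue = tissue, mark = mark,
                                replicate = replicate)
  tags
}

#' Write simulator truth tables to TSV
#'
#' @param truth a `truth_set`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written (elements, motif sites).
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "truth_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pe <- file.path(dir, "elements.tsv")
  pm <- file.path(dir, "motif_sites.tsv")
  utils::write.table(truth$elements, pe, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$motif_sites, pm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pe, pm))
}
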