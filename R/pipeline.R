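#' Full pipeline run configuration
#'
#' Bundles the simulation config, per-mark peak-calling configs, QC
#' thresholds and analysis parameters. Untouched defaults reproduce the
#' standard software parameters (per-mark FDR 0.05/0.01/0.01/0.1, fragment
#' size 200, island window 200 and gap 4, genome fraction 0.63, effective
#' genome size 2,409,143,234) and the QC threshold panel (0.5 / 0.5 / 1 /
#' 1.05 / 0.8 / 0.05).
#'
#' @param outdir output directory for all stages.
#' @param sim a [sim_config()].
#' @param marks named list of [mark_config()]s.
#' @param thresholds a [qc_thresholds()].
#' @param qc_bin_size fingerprint bin size (bp).
#' @param track_bin_size enrichment-track bin size (bp).
#' @param flank_bp,body_bins metagene geometry.
#' @param motif_alpha adjusted-p cutoff for motif detection.
#' @param motif_file JASPAR-format motif file scanned in the motifs stage
#'   (default: the synthetic motif set shipped with the package).
#' @param seed master seed (overrides `sim$seed` when given).
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir = "histomark_run",
                       sim = sim_config(),
                       marks = default_mark_configs(),
                       thresholds = qc_thresholds(),
                       qc_bin_size = 500,
                       track_bin_size = 50,
                       flank_bp = 3000,
                       body_bins = 100,
                       motif_alpha = 0.05,
                       motif_file = NULL,
                       seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(outdir = outdir, sim = sim, marks = marks,
              thresholds = thresholds, qc_bin_size = qc_bin_size,
              track_bin_size = track_bin_size, flank_bp = flank_bp,
              body_bins = body_bins, motif_alpha = motif_alpha,
              motif_file = motif_file %||%
                system.file("extdata", "motifs_synthetic.jaspar",
                            package = "histomark"))
  class(cfg) <- "run_config"
  cfg
}

# Library inventory for a config: every tissue x (mark x 2 replicates +
# one input).
.libraries <- function(config) {
  sim <- config$sim
  out <- expand.grid(tissue = sim$tissues, mark = sim$marks,
                     replicate = 1:2, stringsAsFactors = FALSE)
  inputs <- data.frame(tissue = sim$tissues, mark = "input", replicate = 1L,
                       stringsAsFactors = FALSE)
  rbind(out[order(out$tissue, out$mark, out$replicate), ], inputs)
}

.lib_file <- function(config, tissue, mark, replicate) {
  file.path(config$outdir, "tags",
            sprintf("%s_%s_rep%d.tagAlign", tissue, mark, replicate))
}

.need <- function(paths, stage_needed) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop(sprintf("missing upstream artifact %s: run stage '%s' first",
                 missing[1L], stage_needed), call. = FALSE)
  invisible(TRUE)
}

# Load a simulated library from disk after dedup-free filtering decisions
# are made by the caller.
.load_lib <- function(config, tissue, mark, replicate) {
  read_tagalign(.lib_file(config, tissue, mark, replicate))
}

.load_dedup <- function(config, tissue, mark, replicate) {
  tags <- filter_alignments(.load_lib(config, tissue, mark, replicate))$tags
  remove_duplicates(mark_pcr_duplicates(tags))
}

.chrom_sizes_path <- function(config) file.path(config$outdir, "sim",
                                                "chrom.sizes")

#' Run one pipeline stage
#'
#' Stages: `simulate`, `qc`, `callpeaks`, `combine`, `compare`, `profile`,
#' `motifs`, or `all`. Each stage reads the previous stages' files from
#' `config$outdir`, writes its outputs there, and appends an entry (inputs,
#' parameters, output checksums) to `manifest.json`. Re-running with an
#' identical config and seed reproduces identical checksums.
#'
#' @param stage stage name.
#' @param config a [run_config()].
#' @return Invisibly, the manifest entry (list) of the stage run (or of the
#'   last stage for `all`).
#' @export
run_stage <- function(stage = c("simulate", "qc", "callpeaks", "combine",
                                "compare", "profile", "motifs", "all"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  if (stage == "all") {
    for (s in c("simulate", "qc", "callpeaks", "combine", "compare",
                "profile", "motifs")) {
      entry <- run_stage(s, config)
    }
    return(invisible(entry))
  }
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  outputs <- switch(stage,
                    simulate = .stage_simulate(config),
                    qc = .stage_qc(config),
                    callpeaks = .stage_callpeaks(config),
                    combine = .stage_combine(config),
                    compare = .stage_compare(config),
                    profile = .stage_profile(config),
                    motifs = .stage_motifs(config))
  entry <- list(stage = stage,
                parameters = .manifest_parameters(config),
                outputs = lapply(stats::setNames(outputs, basename(outputs)),
                                 function(p) unname(tools::md5sum(p))))
  .append_manifest(config, entry)
  invisible(entry)
}

.manifest_parameters <- function(config) {
  marks <- lapply(config$marks, function(m)
    list(peak_type = m$peak_type, fdr = m$fdr_threshold,
         window_size = m$window_size, gap_size = m$gap_size,
         genome_fraction = m$genome_fraction,
         fragment_size = m$fragment_size))
  list(seed = config$sim$seed,
       fdr = vapply(config$marks, function(m) m$fdr_threshold, numeric(1)),
       fragment_size = unique(vapply(config$marks, function(m)
         m$fragment_size, integer(1))),
       window_size = config$marks[["H3K27me3"]]$window_size,
       gap_size = config$marks[["H3K27me3"]]$gap_size,
       genome_fraction = config$marks[["H3K27me3"]]$genome_fraction,
       genome_size = formatC(config$marks[[1]]$effective_genome_size,
                             format = "f", digits = 0, big.mark = ","),
       thresholds = as.numeric(config$thresholds),
       marks = marks)
}

.append_manifest <- function(config, entry) {
  path <- file.path(config$outdir, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  manifest[[entry$stage]] <- entry
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.stage_simulate <- function(config) {
  simdir <- file.path(config$outdir, "sim")
  tagdir <- file.path(config$outdir, "tags")
  for (d in c(simdir, tagdir)) if (!dir.exists(d)) dir.create(d)
  g <- make_genome(config$sim)
  genes <- make_genes(config$sim)
  truth <- plant_elements(config$sim, g, genes)
  fa <- file.path(simdir, "genome.fa")
  Biostrings::writeXStringSet(truth$genome, fa)
  cs <- .chrom_sizes_path(config)
  write_chrom_sizes(g$chrom_sizes, cs)
  gb <- file.path(simdir, "genes.bed")
  write_bed_genes(genes, gb)
  tr <- write_truth(truth, file.path(simdir, "truth"))
  libs <- .libraries(config)
  tag_files <- vapply(seq_len(nrow(libs)), function(i) {
    tags <- simulate_library(truth, libs$tissue[i], libs$mark[i],
                             libs$replicate[i], config$sim)
    write_tagalign(tags, .lib_file(config, libs$tissue[i], libs$mark[i],
                                   libs$replicate[i]))
  }, character(1))
  c(fa, cs, gb, tr, tag_files)
}

.stage_qc <- function(config) {
  .need(.chrom_sizes_path(config), "simulate")
  sz <- read_chrom_sizes(.chrom_sizes_path(config))
  libs <- .libraries(config)
  chips <- libs[libs$mark != "input", , drop = FALSE]
  rows <- lapply(seq_len(nrow(chips)), function(i) {
    t <- chips$tissue[i]
    .need(.lib_file(config, t, chips$mark[i], chips$replicate[i]),
          "simulate")
    chip <- .load_lib(config, t, chips$mark[i], chips$replicate[i])
    input <- .load_lib(config, t, "input", 1L)
    m <- qc_metrics(chip, input, sz, bin_size = config$qc_bin_size)
    cbind(data.frame(tissue = t, mark = chips$mark[i],
                     replicate = chips$replicate[i],
                     stringsAsFactors = FALSE),
          qc_verdict(m, config$thresholds))
  })
  report <- do.call(rbind, rows)
  qcdir <- file.path(config$outdir, "qc")
  if (!dir.exists(qcdir)) dir.create(qcdir)
  tsv <- file.path(qcdir, "qc_report.tsv")
  js <- file.path(qcdir, "qc_report.json")
  write_qc_report(report, tsv, js)
  c(tsv, js)
}

.stage_callpeaks <- function(config) {
  .need(.chrom_sizes_path(config), "simulate")
  sz <- read_chrom_sizes(.chrom_sizes_path(config))
  pdir <- file.path(config$outdir, "peaks")
  if (!dir.exists(pdir)) dir.create(pdir)
  libs <- .libraries(config)
  chips <- libs[libs$mark != "input", , drop = FALSE]
  vapply(seq_len(nrow(chips)), function(i) {
    t <- chips$tissue[i]; m <- chips$mark[i]; r <- chips$replicate[i]
    mc <- config$marks[[m]]
    pk <- call_peaks(.load_dedup(config, t, m, r),
                     .load_dedup(config, t, "input", 1L), sz, mc)
    if (mc$peak_type == "broad") {
      path <- file.path(pdir, sprintf("%s_%s_rep%d.broadPeak", t, m, r))
      write_broadpeak(pk, path)
    } else {
      path <- file.path(pdir, sprintf("%s_%s_rep%d.narrowPeak", t, m, r))
      write_narrowpeak(pk, path)
    }
    path
  }, character(1))
}

.peak_file <- function(config, tissue, mark, replicate) {
  ext <- if (config$marks[[mark]]$peak_type == "broad") "broadPeak"
  else "narrowPeak"
  file.path(config$outdir, "peaks",
            sprintf("%s_%s_rep%d.%s", tissue, mark, replicate, ext))
}

.read_peaks_for <- function(config, tissue, mark, replicate) {
  path <- .peak_file(config, tissue, mark, replicate)
  .need(path, "callpeaks")
  if (config$marks[[mark]]$peak_type == "broad") read_broadpeak(path)
  else read_narrowpeak(path)
}

#' Write / read consensus peaks as BED6+3 with provenance columns
#'
#' Columns 7-9 carry the best member q-value and the comma-separated ids of
#' the contributing peaks of each replicate.
#'
#' @param cons a `consensus_peaks` data.frame.
#' @param path file path.
#' @return `read_consensus` returns a `consensus_peaks` data.frame.
#' @export
write_consensus <- function(cons, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t%s\t%s", cons$chrom,
                   cons$start, cons$end, cons$name, .peak_score(cons$q),
                   sprintf("%.6g", cons$q),
                   cons$rep1_members, cons$rep2_members)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_consensus
#' @export
read_consensus <- function(path) {
  lines <- readLines(path)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), q = numeric(),
                      n_rep1 = integer(), n_rep2 = integer(),
                      rep1_members = character(), rep2_members = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    class(empty) <- c("consensus_peaks", "data.frame")
    return(empty)
  }
  f <- strsplit(lines, "\t")
  get <- function(i) vapply(f, `[[`, character(1), i)
  out <- data.frame(chrom = get(1), start = as.integer(get(2)),
                    end = as.integer(get(3)), name = get(4),
                    q = as.numeric(get(7)),
                    n_rep1 = lengths(strsplit(get(8), ",")),
                    n_rep2 = lengths(strsplit(get(9), ",")),
                    rep1_members = get(8), rep2_members = get(9),
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_peaks", "data.frame")
  out
}

.consensus_file <- function(config, tissue, mark) {
  file.path(config$outdir, "consensus",
            sprintf("%s_%s_consensus.bed", tissue, mark))
}

.stage_combine <- function(config) {
  cdir <- file.path(config$outdir, "consensus")
  if (!dir.exists(cdir)) dir.create(cdir)
  sim <- config$sim
  out <- character(0)
  for (t in sim$tissues) {
    for (m in sim$marks) {
      cons <- combine_replicates(.read_peaks_for(config, t, m, 1L),
                                 .read_peaks_for(config, t, m, 2L),
                                 config$marks[[m]])
      path <- .consensus_file(config, t, m)
      write_consensus(cons, path)
      out <- c(out, path)
    }
  }
  out
}

.stage_compare <- function(config) {
  sim <- config$sim
  dir <- file.path(config$outdir, "compare")
  if (!dir.exists(dir)) dir.create(dir)
  out <- character(0)
  # per-replicate significant calls: Jaccard across tissue x replicate
  for (m in sim$marks) {
    sets <- list()
    for (t in sim$tissues) {
      for (r in 1:2) {
        pk <- .read_peaks_for(config, t, m, r)
        sets[[sprintf("%s_rep%d", t, r)]] <-
          pk[pk$q <= config$marks[[m]]$fdr_threshold, , drop = FALSE]
      }
    }
    jm <- jaccard_matrix(sets)
    path <- file.path(dir, sprintf("jaccard_%s.tsv", m))
    utils::write.table(format(unclass(jm), digits = 6), path, sep = "\t",
                       quote = FALSE, col.names = NA)
    out <- c(out, path)
  }
  # unique peaks per mark, on consensus sets
  for (m in sim$marks) {
    sets <- lapply(stats::setNames(sim$tissues, sim$tissues), function(t) {
      p <- .consensus_file(config, t, m)
      .need(p, "combine")
      read_consensus(p)
    })
    up <- unique_peaks(sets)
    path <- file.path(dir, sprintf("unique_%s.tsv", m))
    utils::write.table(up$table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, path)
  }
  # active enhancers and tissue-specific enhancers
  me1 <- lapply(stats::setNames(sim$tissues, sim$tissues), function(t)
    read_consensus(.consensus_file(config, t, "H3K4me1")))
  ac <- lapply(stats::setNames(sim$tissues, sim$tissues), function(t)
    read_consensus(.consensus_file(config, t, "H3K27ac")))
  enh <- lapply(stats::setNames(sim$tissues, sim$tissues), function(t)
    active_enhancers(me1[[t]], ac[[t]]))
  spec <- tissue_specific_enhancers(enh, me1, ac)
  for (t in sim$tissues) {
    p1 <- file.path(dir, sprintf("%s_active_enhancers.bed", t))
    writeLines(sprintf("%s\t%d\t%d", enh[[t]]$chrom, enh[[t]]$start,
                       enh[[t]]$end), p1)
    p2 <- file.path(dir, sprintf("%s_specific_enhancers.bed", t))
    writeLines(sprintf("%s\t%d\t%d", spec[[t]]$chrom, spec[[t]]$start,
                       spec[[t]]$end), p2)
    out <- c(out, p1, p2)
  }
  out
}

.stage_profile <- function(config) {
  sim <- config$sim
  sz <- read_chrom_sizes(.chrom_sizes_path(config))
  genes_path <- file.path(config$outdir, "sim", "genes.bed")
  .need(genes_path, "simulate")
  genes <- read_bed_genes(genes_path)
  dir <- file.path(config$outdir, "profiles")
  if (!dir.exists(dir)) dir.create(dir)
  out <- character(0)
  for (t in sim$tissues) {
    input <- .load_dedup(config, t, "input", 1L)
    for (m in sim$marks) {
      track <- enrichment_track(.load_dedup(config, t, m, 1L),
                                .load_dedup(config, t, m, 2L),
                                input, sz,
                                bin_size = config$track_bin_size,
                                fragment_size = config$marks[[m]]$fragment_size)
      bg <- file.path(dir, sprintf("%s_%s.bedGraph", t, m))
      write_bedgraph(track, bg)
      mg <- metagene(track, genes, flank_bp = config$flank_bp,
                     body_bins = config$body_bins)
      pf <- file.path(dir, sprintf("%s_%s_metagene.tsv", t, m))
      utils::write.table(
        data.frame(column = seq_along(mg$profile),
                   mean_enrichment = signif(mg$profile, 6)),
        pf, sep = "\t", quote = FALSE, row.names = FALSE)
      out <- c(out, bg, pf)
    }
  }
  out
}

.stage_motifs <- function(config) {
  sim <- config$sim
  dir <- file.path(config$outdir, "motifs")
  if (!dir.exists(dir)) dir.create(dir)
  fa <- file.path(config$outdir, "sim", "genome.fa")
  .need(fa, "simulate")
  genome <- Biostrings::readDNAStringSet(fa)
  names(genome) <- sub("\\s.*", "", names(genome))
  pwms <- read_jaspar(config$motif_file)
  out <- character(0)
  results <- list()
  for (t in sim$tissues) {
    p <- file.path(config$outdir, "compare",
                   sprintf("%s_specific_enhancers.bed", t))
    .need(p, "compare")
    lines <- readLines(p)
    if (length(lines) == 0L) {
      results[[t]] <- NULL
      next
    }
    f <- strsplit(lines, "\t")
    iv <- data.frame(chrom = vapply(f, `[[`, character(1), 1),
                     start = as.integer(vapply(f, `[[`, character(1), 2)),
                     end = as.integer(vapply(f, `[[`, character(1), 3)),
                     stringsAsFactors = FALSE)
    fg <- interval_sequences(iv, genome)
    bg <- dinucleotide_shuffle(fg, seed = derive_seed(sim$seed, "shuffle", t),
                               n = 5)
    res <- motif_enrichment(fg, bg, pwms)
    results[[t]] <- res
    path <- file.path(dir, sprintf("%s_motif_enrichment.tsv", t))
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, path)
  }
  if (length(results) >= 2L) {
    ud <- uniquely_detected(results, alpha = config$motif_alpha)
    path <- file.path(dir, "uniquely_detected.tsv")
    tab <- data.frame(tissue = names(ud),
                      motifs = vapply(ud, paste, character(1),
                                      collapse = ","),
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, path)
  }
  out
}
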