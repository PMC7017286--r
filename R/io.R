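# Readers and writers for the text formats the pipeline exchanges.
# All BED-family coordinates are 0-based half-open on disk and in memory;
# GTF is 1-based closed on disk and converted at the boundary.

#' Write / read a chromosome sizes table (two-column TSV)
#' @param chrom_sizes named vector or `chrom`/`size` data.frame.
#' @param path file path.
#' @return `read_chrom_sizes` returns a data.frame `chrom`, `size`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  sz <- .as_chrom_sizes(chrom_sizes)
  writeLines(sprintf("%s\t%d", names(sz), as.integer(sz)), path)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", col.names = c("chrom", "size"),
                         stringsAsFactors = FALSE)
  d
}

#' Write / read aligned tags as tagAlign (BED6 dialect)
#'
#' Columns: chrom, start, end, name (`N`), score (= MAPQ), strand.
#'
#' @param tags tag data.frame.
#' @param path file path.
#' @return `read_tagalign` returns a tag data.frame with default (FALSE)
#'   status flags.
#' @export
write_tagalign <- function(tags, path) {
  .check_tags(tags)
  lines <- sprintf("%s\t%d\t%d\tN\t%d\t%s", tags$chrom, tags$start,
                   tags$end, tags$mapq, tags$strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tagalign
#' @export
read_tagalign <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"))
  data.frame(chrom = d$chrom, start = d$start, end = d$end,
             strand = d$strand, mapq = d$score, unmapped = FALSE,
             secondary = FALSE, qc_fail = FALSE, optical_duplicate = FALSE,
             pcr_duplicate = FALSE, stringsAsFactors = FALSE)
}

#' Write / read aligned tags as minimal SAM
#'
#' Writes an @HD/@SQ header and one line per tag with flags encoding
#' strand (0x10), unmapped (0x4), secondary (0x100), QC fail (0x200) and
#' duplicate (0x400); sequence and quality are emitted as `*`.
#'
#' @param tags tag data.frame.
#' @param chrom_sizes chromosome sizes for the header.
#' @param path file path.
#' @return `read_sam` returns a tag data.frame.
#' @export
write_sam <- function(tags, chrom_sizes, path) {
  .check_tags(tags)
  sz <- .as_chrom_sizes(chrom_sizes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(sz), as.integer(sz)), con)
  flag <- ifelse(tags$strand == "-", 16L, 0L) +
    ifelse(tags$unmapped, 4L, 0L) + ifelse(tags$secondary, 256L, 0L) +
    ifelse(tags$qc_fail, 512L, 0L) +
    ifelse(tags$optical_duplicate | tags$pcr_duplicate, 1024L, 0L)
  writeLines(sprintf("tag%d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                     seq_len(nrow(tags)), flag, tags$chrom,
                     tags$start + 1L, tags$mapq, tags$end - tags$start),
             con)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  start <- as.integer(get(4)) - 1L
  len <- as.integer(sub("M$", "", get(6)))
  data.frame(chrom = get(3), start = start, end = start + len,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mapq = as.integer(get(5)),
             unmapped = bitwAnd(flag, 4L) > 0L,
             secondary = bitwAnd(flag, 256L) > 0L,
             qc_fail = bitwAnd(flag, 512L) > 0L,
             optical_duplicate = FALSE,
             pcr_duplicate = bitwAnd(flag, 1024L) > 0L,
             stringsAsFactors = FALSE)
}

# -log10 with capping for serialization of p/q columns
.neglog10 <- function(p) {
  ifelse(p <= 0, 999, round(-log10(p), 5))
}

#' Write / read peaks in narrowPeak (10-column) format
#'
#' p and q values are serialized on the -log10 scale per the ENCODE
#' narrowPeak convention and converted back on read.
#'
#' @param peaks peak data.frame from [call_narrow()].
#' @param path file path.
#' @return `read_narrowpeak` returns a peak data.frame.
#' @export
write_narrowpeak <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   peaks$score, peaks$strand,
                   sprintf("%.6g", peaks$signal),
                   sprintf("%.6g", .neglog10(peaks$p)),
                   sprintf("%.6g", .neglog10(peaks$q)),
                   peaks$summit)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
read_narrowpeak <- function(path) {
  .read_peak_file(path, ncol = 10L)
}

#' Write / read peaks in broadPeak (9-column) format
#' @param peaks peak data.frame from [call_islands()].
#' @param path file path.
#' @return `read_broadpeak` returns a peak data.frame (`summit = -1`).
#' @export
write_broadpeak <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   peaks$score, peaks$strand,
                   sprintf("%.6g", peaks$signal),
                   sprintf("%.6g", .neglog10(peaks$p)),
                   sprintf("%.6g", .neglog10(peaks$q)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_broadpeak
#' @export
read_broadpeak <- function(path) {
  .read_peak_file(path, ncol = 9L)
}

.read_peak_file <- function(path, ncol) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(.empty_peaks())
  f <- strsplit(lines, "\t")
  bad <- which(lengths(f) != ncol)
  if (length(bad) > 0L)
    stop(sprintf("malformed peak line %d in %s: expected %d columns, got %d",
                 bad[1L], path, ncol, lengths(f)[bad[1L]]), call. = FALSE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  data.frame(chrom = get(1), start = as.integer(get(2)),
             end = as.integer(get(3)), name = get(4),
             score = as.integer(get(5)), strand = get(6),
             signal = as.numeric(get(7)),
             p = 10^(-as.numeric(get(8))),
             q = 10^(-as.numeric(get(9))),
             summit = if (ncol == 10L) as.integer(get(10)) else -1L,
             stringsAsFactors = FALSE)
}

#' Read gene models from BED12 (or BED6)
#'
#' Only the first six columns are used (gene span and strand).
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed_genes <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 6L) stop("gene BED needs at least 6 columns", call. = FALSE)
  data.frame(chrom = d[[1]], start = d[[2]], end = d[[3]], name = d[[4]],
             strand = d[[6]], stringsAsFactors = FALSE)
}

#' Write gene models as BED6
#' @param genes gene data.frame (`chrom`, `start`, `end`, `name`, `strand`).
#' @param path file path.
#' @export
write_bed_genes <- function(genes, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start,
                     genes$end, genes$name, genes$strand), path)
  invisible(path)
}

#' Read gene models from a minimal GTF
#'
#' Keeps `gene` features (or all features when none are typed `gene`);
#' 1-based closed GTF coordinates are converted to 0-based half-open.
#'
#' @param path GTF file path.
#' @return data.frame `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 9L)) stop("malformed GTF line", call. = FALSE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  feat <- get(3)
  keep <- if (any(feat == "gene")) feat == "gene" else rep(TRUE, length(f))
  id <- sub('.*gene_id[ "]+([^";]+).*', "\\1", get(9))
  data.frame(chrom = get(1)[keep],
             start = as.integer(get(4))[keep] - 1L,
             end = as.integer(get(5))[keep],
             name = id[keep], strand = get(7)[keep],
             stringsAsFactors = FALSE)
}

#' Write a binned track as bedGraph
#'
#' Adjacent bins with equal values are run-length merged; zero runs are
#' kept so the file round-trips losslessly at bin resolution.
#'
#' @param track a `binned_track`.
#' @param path file path.
#' @param drop_zero omit zero-valued runs (conventional for sparse tracks).
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  stopifnot(inherits(track, "binned_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(r$values))
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep] * bs,
                       ends[keep] * bs,
                       sprintf("%.6g", r$values[keep])),
               con)
  }
  invisible(path)
}

#' Write a QC report as TSV and JSON
#'
#' @param report a data.frame from [qc_verdict()] (with identifying columns
#'   such as tissue/mark/replicate prepended by the caller).
#' @param path_tsv,path_json output paths (`NULL` to skip one).
#' @export
write_qc_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(report, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(report, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
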