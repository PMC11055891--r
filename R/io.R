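#' Track input/output for Repli-seq and OK-seq data
#'
#' Readers for the two on-disk shapes a 16-fraction Repli-seq experiment
#' arrives in -- one bedGraph per S-phase fraction, or a single TSV matrix --
#' and for strand-specific OK-seq count bedGraphs, plus a bedGraph writer
#' for corrected-fraction tracks. bedGraph parsing goes through
#' \code{rtracklayer}.
#'
#' @name track_io
NULL

# per-bin values of a scored GRanges on a fixed grid (mean of overlapping
# scores weighted by overlap is overkill here; bedGraph inputs are expected
# to be bin-aligned, so the score of the covering interval is taken)
.bedgraph_to_bins <- function(gr, chrom, chrom_length, bin_size) {
  gr <- gr[as.character(seqnames(gr)) == chrom]
  grid <- bin_grid(chrom, chrom_length, bin_size)
  vals <- rep(0, length(grid))
  hits <- GenomicRanges::findOverlaps(grid, gr)
  vals[queryHits(hits)] <- mcols(gr)$score[subjectHits(hits)]
  vals
}

#' Read a 16-fraction Repli-seq matrix
#'
#' @param paths For \code{read_repliseq_bedgraphs}: 16 bedGraph paths in
#'   fraction order S1..S16.
#' @param path For \code{read_repliseq_tsv}: a TSV whose 16 columns are the
#'   fractions S1..S16 (header optional) and whose rows are consecutive
#'   genomic bins.
#' @param chrom Chromosome to extract.
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width (default 50000).
#' @param ... Passed to \code{\link{repliseq_matrix}}.
#' @return A raw-count \code{repliseq_matrix}.
#' @export
read_repliseq_bedgraphs <- function(paths, chrom, chrom_length,
                                    bin_size = 50000, ...) {
  stopifnot(length(paths) == 16)
  rows <- lapply(paths, function(p) {
    gr <- rtracklayer::import(p, format = "bedGraph")
    .bedgraph_to_bins(gr, chrom, chrom_length, bin_size)
  })
  repliseq_matrix(do.call(rbind, rows), chrom, bin_size, ...)
}

#' @rdname read_repliseq_bedgraphs
#' @export
read_repliseq_tsv <- function(path, chrom, bin_size = 50000, ...) {
  first <- readLines(path, n = 1)
  has_header <- any(is.na(suppressWarnings(as.numeric(
    strsplit(first, "\t")[[1]]))))
  m <- as.matrix(read.table(path, sep = "\t", header = has_header))
  if (ncol(m) != 16) stop("expected 16 fraction columns, found ", ncol(m))
  repliseq_matrix(t(m), chrom, bin_size, ...)
}

#' Read strand-specific OK-seq counts from two bedGraphs
#'
#' @param forward_path,reverse_path bedGraphs of forward- and reverse-strand
#'   Okazaki read counts.
#' @param chrom,chrom_length,bin_size Grid specification.
#' @return List with per-bin \code{F} and \code{R} count vectors, ready for
#'   \code{\link{compute_rfd}}.
#' @export
read_okseq_bedgraphs <- function(forward_path, reverse_path, chrom,
                                 chrom_length, bin_size = 50000) {
  f <- rtracklayer::import(forward_path, format = "bedGraph")
  r <- rtracklayer::import(reverse_path, format = "bedGraph")
  list(F = .bedgraph_to_bins(f, chrom, chrom_length, bin_size),
       R = .bedgraph_to_bins(r, chrom, chrom_length, bin_size))
}

#' Write a corrected-fraction track as bedGraph
#'
#' Missing (unmappable) bins are omitted from the output.
#'
#' @param track A \code{fraction_track}.
#' @param path Output bedGraph path.
#' @param chrom_length Optional chromosome length to clip the final bin.
#' @export
write_fraction_bedgraph <- function(track, path, chrom_length = NULL) {
  n <- length(track$fraction)
  bs <- track$bin_size
  keep <- !is.na(track$fraction)
  start0 <- as.integer((which(keep) - 1L) * bs)
  end0 <- start0 + bs
  if (!is.null(chrom_length)) end0 <- as.integer(pmin(end0, chrom_length))
  df <- data.frame(chrom = track$chrom, start = start0, end = end0,
                   score = track$fraction[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
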