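#' Translocation junction input, filtering and binning
#'
#' LAM-HTGTS recovers prey double-strand-break (DSB) ends genome-wide via a
#' bait DSB, preserving the orientation of each prey end: centromere-connected
#' ends (\code{Dcen}) arise at rightward-moving forks and telomere-connected
#' ends (\code{Dtel}) at leftward-moving forks. Junctions are represented as
#' width-1 \link[GenomicRanges]{GRanges} with metadata columns
#' \code{orientation} (\code{"Dcen"}/\code{"Dtel"}), \code{bait_chrom},
#' \code{library_id} and \code{condition}.
#'
#' @name junctions
NULL

.ORIENTATIONS <- c("Dcen", "Dtel")

# build a junction GRanges from parsed fields (pos is 1-based)
new_junctions <- function(chrom, pos, orientation, bait_chrom = NA_character_,
                          library_id = NA_character_, condition = NA_character_,
                          seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  mcols(gr)$orientation <- factor(orientation, levels = .ORIENTATIONS)
  mcols(gr)$bait_chrom <- rep_len(bait_chrom, length(gr))
  mcols(gr)$library_id <- rep_len(library_id, length(gr))
  mcols(gr)$condition <- rep_len(condition, length(gr))
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Read translocation junctions from a BED6 or TLX-like table
#'
#' Malformed records (wrong field count, non-numeric position, missing or
#' unrecognized strand) are rejected and counted rather than aborting the
#' read; rejected line numbers are attached as an attribute and reported via
#' a message.
#'
#' Orientation convention: a \code{"+"} prey strand maps to \code{Dcen} and
#' \code{"-"} to \code{Dtel} by default (\code{strand_is_dcen} flips it).
#' BED positions (0-based starts) are converted to the 1-based coordinates
#' used throughout; TLX \code{Junction} coordinates are 1-based already.
#'
#' @param path Path to the junction table.
#' @param dialect \code{"bed6"} (chrom, start, end, name, score, strand) or
#'   \code{"tlx"} (header with at least Rname, Junction, Strand; optional
#'   B_Rname for the bait chromosome; Strand may be +/- or 1/-1).
#' @param bait_chrom Bait chromosome for every record (TLX B_Rname wins when
#'   present).
#' @param library_id,condition Library metadata attached to every junction.
#' @param strand_is_dcen Strand symbol that maps to \code{Dcen}.
#' @return Width-1 \code{GRanges} of junctions with attributes
#'   \code{n_rejected} and \code{rejected_lines}.
#' @export
read_junctions <- function(path, dialect = c("bed6", "tlx"),
                           bait_chrom = NA_character_,
                           library_id = NA_character_,
                           condition = NA_character_,
                           strand_is_dcen = "+") {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  orient_of <- function(strand) {
    ifelse(strand == strand_is_dcen, "Dcen",
           ifelse(strand %in% c("+", "-"), "Dtel", NA_character_))
  }
  if (dialect == "bed6") {
    fields <- strsplit(lines, "\t| +")
    rows <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 6) return(NULL)
      start <- suppressWarnings(as.numeric(f[2]))
      if (is.na(start) || start < 0) return(NULL)
      ori <- orient_of(f[6])
      if (is.na(ori)) return(NULL)
      list(chrom = f[1], pos = start + 1, ori = ori)
    })
  } else {
    if (length(lines) == 0) {
      rows <- list()
    } else {
      hdr <- strsplit(lines[[1]], "\t")[[1]]
      need <- c("Rname", "Junction", "Strand")
      if (!all(need %in% hdr)) stop("TLX header must contain Rname, Junction, Strand")
      body <- lines[-1]
      fields <- strsplit(body, "\t")
      ic <- match(need, hdr)
      ib <- match("B_Rname", hdr)
      rows <- lapply(seq_along(fields), function(i) {
        f <- fields[[i]]
        if (length(f) < max(ic, ib, na.rm = TRUE)) return(NULL)
        pos <- suppressWarnings(as.numeric(f[ic[2]]))
        if (is.na(pos) || pos < 1) return(NULL)
        s <- f[ic[3]]
        s <- c("1" = "+", "-1" = "-", "+" = "+", "-" = "-")[s]
        if (is.na(s)) return(NULL)
        ori <- orient_of(unname(s))
        if (is.na(ori)) return(NULL)
        list(chrom = f[ic[1]], pos = pos, ori = ori,
             bait = if (!is.na(ib)) f[ib] else NA_character_)
      })
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  rejected <- which(!ok) + if (dialect == "tlx") 1L else 0L
  rows <- rows[ok]
  if (length(rows) == 0) {
    gr <- new_junctions(character(0), integer(0), character(0),
                        bait_chrom, library_id, condition)
  } else {
    bait <- vapply(rows, function(r) {
      b <- r$bait
      if (is.null(b) || is.na(b)) bait_chrom else b
    }, character(1))
    gr <- new_junctions(vapply(rows, `[[`, character(1), "chrom"),
                        vapply(rows, `[[`, numeric(1), "pos"),
                        vapply(rows, `[[`, character(1), "ori"),
                        bait, library_id, condition)
  }
  if (length(rejected) > 0) {
    message(length(rejected), " malformed record(s) rejected at line(s): ",
            paste(utils::head(rejected, 20), collapse = ", "))
  }
  attr(gr, "n_rejected") <- length(rejected)
  attr(gr, "rejected_lines") <- rejected
  gr
}

#' Write junctions as BED6
#'
#' Exact round-trip partner of \code{\link{read_junctions}} in the
#' \code{bed6} dialect: chrom, 0-based position, position+1, library id,
#' score 0, strand encoding the orientation.
#'
#' @param junctions Junction \code{GRanges}.
#' @param path Output path.
#' @param strand_is_dcen Strand symbol encoding \code{Dcen}.
#' @export
write_junctions_bed <- function(junctions, path, strand_is_dcen = "+") {
  other <- setdiff(c("+", "-"), strand_is_dcen)
  strand <- ifelse(as.character(mcols(junctions)$orientation) == "Dcen",
                   strand_is_dcen, other)
  name <- mcols(junctions)$library_id
  name[is.na(name)] <- "junction"
  df <- data.frame(chrom = as.character(seqnames(junctions)),
                   start = GenomicRanges::start(junctions) - 1L,
                   end = GenomicRanges::start(junctions),
                   name = name, score = 0L, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bundle junctions into a library object
#'
#' A library is one LAM-HTGTS experiment: one bait, one condition. The
#' interchromosomal total (junctions on non-bait chromosomes) is the
#' denominator for per-10k densities.
#'
#' @param junctions Junction \code{GRanges}.
#' @param library_id,bait_chrom,condition Metadata (defaults taken from the
#'   junctions when uniform).
#' @return An object of class \code{htgts_library}.
#' @export
htgts_library <- function(junctions, library_id = NULL, bait_chrom = NULL,
                          condition = NULL) {
  pick <- function(given, col) {
    if (!is.null(given)) return(given)
    v <- unique(as.character(mcols(junctions)[[col]]))
    v <- v[!is.na(v)]
    if (length(v) == 1) v else NA_character_
  }
  lib <- list(
    library_id = pick(library_id, "library_id"),
    bait_chrom = pick(bait_chrom, "bait_chrom"),
    condition = pick(condition, "condition"),
    junctions = junctions
  )
  lib$interchromosomal_total <-
    sum(as.character(seqnames(junctions)) != lib$bait_chrom)
  class(lib) <- "htgts_library"
  lib
}

#' @export
print.htgts_library <- function(x, ...) {
  cat(sprintf("htgts_library %s (bait %s, condition %s): %d junctions, %d interchromosomal\n",
              x$library_id, x$bait_chrom, x$condition,
              length(x$junctions), x$interchromosomal_total))
  invisible(x)
}

#' Drop junctions on the bait (viewpoint) chromosome
#'
#' Bait-chromosome junctions carry a 15-25\% orientation recovery bias, so
#' all statistics use interchromosomal junctions only. Idempotent.
#'
#' @param library An \code{htgts_library}.
#' @return The library with bait-chromosome junctions removed and the
#'   interchromosomal total updated.
#' @export
filter_viewpoint <- function(library) {
  stopifnot(inherits(library, "htgts_library"))
  if (is.na(library$bait_chrom)) stop("bait_chrom unknown; cannot filter viewpoint")
  keep <- as.character(seqnames(library$junctions)) != library$bait_chrom
  library$junctions <- library$junctions[keep]
  library$interchromosomal_total <- sum(keep)
  library
}

#' Default off-target normalization regions (mm10)
#'
#' CRISPR off-target cut sites where the DSB frequency is independent of the
#' aphidicolin dose, one per bait design; used to standardize library sizes
#' across conditions.
#'
#' @return \code{GRanges} of the four off-target regions.
#' @export
default_offtargets <- function() {
  GenomicRanges::GRanges(
    c("chr2", "chr4", "chr14", "chr12"),
    IRanges::IRanges(start = c(165364621L, 141559296L, 22764897L, 111040436L),
                     end = c(165369885L, 141560757L, 22769859L, 111040503L)),
    bait = c("chr5", "chr6", "chr8", "chr12")
  )
}

#' Off-target library-size weights per condition
#'
#' Junction counts inside dose-invariant off-target regions calibrate the
#' effective library size of each condition:
#' \code{weight[c] = mean(offtarget counts) / offtarget count of c}.
#' Multiplying condition \code{c}'s junction counts by \code{weight[c]}
#' equalizes off-target counts across conditions.
#'
#' @param libraries List of \code{htgts_library}, one or more per condition.
#' @param offtargets Off-target intervals (\code{GRanges}); defaults to
#'   \code{\link{default_offtargets}}.
#' @return Named numeric vector of weights, one per condition, with the
#'   off-target counts as attribute \code{offtarget_counts}.
#' @export
offtarget_weights <- function(libraries, offtargets = default_offtargets()) {
  stopifnot(length(libraries) >= 1)
  conds <- vapply(libraries, function(l) l$condition, character(1))
  counts <- vapply(libraries, function(l)
    sum(IRanges::overlapsAny(l$junctions, offtargets)), numeric(1))
  zero <- counts == 0
  if (any(zero)) {
    ids <- vapply(libraries[zero], function(l) l$library_id, character(1))
    stop("zero off-target junctions in library(ies): ",
         paste(ids, collapse = ", "), "; off-target normalization impossible")
  }
  by_cond <- tapply(counts, conds, sum)
  w <- mean(by_cond) / by_cond
  res <- as.numeric(w)
  names(res) <- names(w)
  attr(res, "offtarget_counts") <- by_cond
  res
}

#' Binned junction density track
#'
#' Counts junctions per fixed-width bin, optionally stratified by prey-end
#' orientation, and optionally scaled to DSBs per ten thousand
#' interchromosomal translocations (the display unit of the dose-response
#' figures).
#'
#' @param junctions Junction \code{GRanges} (one chromosome).
#' @param bin_size Bin width in bp.
#' @param chrom_length Chromosome length in bp.
#' @param orientation \code{"both"}, \code{"Dcen"} or \code{"Dtel"}.
#' @param per \code{"count"} for raw counts or
#'   \code{"per-10k-interchromosomal"}.
#' @param interchromosomal_total Library interchromosomal total (required for
#'   per-10k scaling).
#' @return \code{GRanges} bin grid with a \code{score} column (bedGraph
#'   ready, e.g. via \code{rtracklayer::export}).
#' @export
density_track <- function(junctions, bin_size, chrom_length,
                          orientation = c("both", "Dcen", "Dtel"),
                          per = c("count", "per-10k-interchromosomal"),
                          interchromosomal_total = NULL) {
  orientation <- match.arg(orientation)
  per <- match.arg(per)
  stopifnot(bin_size > 0)
  if (orientation != "both") {
    junctions <- junctions[as.character(mcols(junctions)$orientation) == orientation]
  }
  chroms <- unique(as.character(seqnames(junctions)))
  if (length(chroms) > 1) stop("density_track expects junctions from one chromosome")
  chrom <- if (length(chroms) == 1) chroms else "chrom"
  grid <- bin_grid(chrom, chrom_length, bin_size)
  counts <- GenomicRanges::countOverlaps(grid, junctions)
  if (per == "per-10k-interchromosomal") {
    if (is.null(interchromosomal_total) || interchromosomal_total <= 0) {
      stop("per-10k scaling requires a positive interchromosomal_total")
    }
    score <- counts * 1e4 / interchromosomal_total
  } else {
    score <- as.numeric(counts)
  }
  mcols(grid)$score <- score
  mcols(grid)$count <- counts
  grid
}
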