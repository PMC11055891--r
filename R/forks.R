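#' Directional replication fork segments and RDC classification
#'
#' Fork direction is reconstructed by connecting each initiation zone (IZ)
#' edge to the nearest termination meeting point on that side: the genome
#' right of an IZ up to the next termination anchor is replicated by a
#' rightward fork, the genome to the left by a leftward fork. Timing
#' transition regions contribute fork segments directly (their strand is the
#' fork direction). Segments shorter than one Repli-seq bin (50 kb) cannot
#' be resolved and are dropped. RDCs are then classified by the
#' configuration of consensus fork segments that overlap them: converging
#' pairs ("inward"), single-direction coverage ("unidirectional"),
#' diverging pairs ("outward"), three or more segments ("complex").
#'
#' @name fork_assembly
NULL

.fork_gr <- function(chrom, start, end, direction, source, replicate) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = ifelse(direction == "rightward", "+", "-"))
  mcols(gr)$direction <- direction
  mcols(gr)$source <- source
  mcols(gr)$replicate <- replicate
  gr
}

#' Assemble fork segments from IZs and termination anchors
#'
#' @param iz \code{GRanges} of initiation zones (one chromosome).
#' @param tz_pos Integer vector of termination meeting-point positions (bp).
#' @param ttr Optional \code{GRanges} of TTR features (direction in
#'   \code{mcols()$direction}); each contributes a fork segment.
#' @param min_len Minimum resolvable segment length in bp (default 50000).
#' @param replicate Replicate id attached to the segments.
#' @return \code{GRanges} of fork segments with \code{direction},
#'   \code{source}, \code{replicate} columns (strand encodes direction).
#' @export
assemble_forks <- function(iz, tz_pos, ttr = NULL, min_len = 50000,
                           replicate = NA_character_) {
  segs <- GenomicRanges::GRanges()
  chrom <- if (length(iz) > 0) as.character(seqnames(iz))[1] else
    if (!is.null(ttr) && length(ttr) > 0) as.character(seqnames(ttr))[1] else NA
  tz_pos <- sort(tz_pos)
  for (i in seq_along(iz)) {
    s <- GenomicRanges::start(iz)[i]
    e <- GenomicRanges::end(iz)[i]
    right <- tz_pos[tz_pos > e]
    left <- tz_pos[tz_pos < s]
    if (length(right) > 0) {
      segs <- c(segs, .fork_gr(chrom, e + 1L, min(right), "rightward",
                               "iz-to-tz", replicate))
    } else {
      warning("IZ at ", s, " has no termination anchor on the right; one-sided assembly")
    }
    if (length(left) > 0) {
      segs <- c(segs, .fork_gr(chrom, max(left), s - 1L, "leftward",
                               "iz-to-tz", replicate))
    } else {
      warning("IZ at ", s, " has no termination anchor on the left; one-sided assembly")
    }
  }
  if (!is.null(ttr) && length(ttr) > 0) {
    keep <- mcols(ttr)$kind == "TTR"
    t <- ttr[keep]
    if (length(t) > 0) {
      segs <- c(segs, .fork_gr(as.character(seqnames(t)),
                               GenomicRanges::start(t), GenomicRanges::end(t),
                               mcols(t)$direction, "ttr", replicate))
    }
  }
  segs[GenomicRanges::width(segs) >= min_len]
}

#' Consensus fork segments across technical repeats
#'
#' Base-pair-wise intersection keeping only positions where both replicates
#' assign the same direction; runs shorter than \code{min_len} are dropped.
#' Commutative in its two arguments.
#'
#' @param rep1,rep2 Fork segment \code{GRanges}.
#' @param min_len Minimum consensus run (default 50000 bp).
#' @return Consensus fork \code{GRanges}.
#' @export
consensus_forks <- function(rep1, rep2, min_len = 50000) {
  out <- GenomicRanges::GRanges()
  for (dir in c("rightward", "leftward")) {
    a <- GenomicRanges::reduce(rep1[mcols(rep1)$direction == dir])
    b <- GenomicRanges::reduce(rep2[mcols(rep2)$direction == dir])
    if (length(a) == 0 || length(b) == 0) next
    GenomeInfoDb::seqlevels(b) <- GenomeInfoDb::seqlevels(a) <-
      union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
    i <- GenomicRanges::intersect(a, b, ignore.strand = TRUE)
    if (length(i) == 0) next
    mcols(i)$direction <- dir
    mcols(i)$source <- "consensus"
    mcols(i)$replicate <- "consensus"
    GenomicRanges::strand(i) <- if (dir == "rightward") "+" else "-"
    out <- c(out, i)
  }
  out <- out[GenomicRanges::width(out) >= min_len]
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Classify an RDC by its overlapping fork configuration
#'
#' @param rdc A single-interval \code{GRanges} (one RDC call).
#' @param forks Consensus fork segments on the same chromosome.
#' @param features Replication features (for the TTR / broad late CTR flags).
#' @param min_overlap Minimum fork/RDC overlap to count, bp (default 50000).
#' @param broad_ctr_bp Broad late-CTR threshold, bp (default 500000).
#' @return List with \code{klass} (\code{inward}, \code{unidirectional},
#'   \code{outward}, \code{complex}, \code{undetermined}),
#'   \code{contains_ttr}, \code{contains_broad_lateCTR}, \code{n_forks} and
#'   the overlapping \code{forks}.
#' @export
classify_rdc <- function(rdc, forks, features = NULL, min_overlap = 50000,
                         broad_ctr_bp = 500000) {
  stopifnot(length(rdc) == 1)
  ov <- GenomicRanges::GRanges()
  if (length(forks) > 0) {
    hits <- GenomicRanges::findOverlaps(forks, rdc, ignore.strand = TRUE)
    cand <- forks[queryHits(hits)]
    if (length(cand) > 0) {
      ovw <- GenomicRanges::width(GenomicRanges::pintersect(
        cand, rep(rdc, length(cand)), ignore.strand = TRUE))
      ov <- cand[ovw >= min_overlap]
    }
  }
  n <- length(ov)
  dirs <- unique(mcols(ov)$direction)
  klass <- if (n == 0) {
    "undetermined"
  } else if (n >= 3) {
    "complex"
  } else if (length(dirs) == 1) {
    "unidirectional"
  } else {
    r <- ov[mcols(ov)$direction == "rightward"]
    l <- ov[mcols(ov)$direction == "leftward"]
    if (GenomicRanges::start(r)[1] <= GenomicRanges::start(l)[1]) "inward" else "outward"
  }
  contains_ttr <- FALSE
  contains_broad_ctr <- FALSE
  if (!is.null(features) && length(features) > 0) {
    fo <- features[IRanges::overlapsAny(features, rdc, ignore.strand = TRUE)]
    contains_ttr <- any(mcols(fo)$kind == "TTR")
    ctr <- fo[mcols(fo)$kind == "lateCTR"]
    contains_broad_ctr <- any(GenomicRanges::width(ctr) > broad_ctr_bp)
  }
  list(klass = klass,
       contains_ttr = contains_ttr,
       contains_broad_lateCTR = contains_broad_ctr,
       n_forks = n,
       forks = ov)
}
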