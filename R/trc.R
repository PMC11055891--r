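#' Transcription-replication conflict statistics
#'
#' Within an RDC, every fork-covered interval overlapping an actively
#' transcribed gene is a TRC compartment: head-on when fork and
#' transcription directions oppose, co-directional when they agree. The DSB
#' evidence for a compartment is the matched-orientation junction count --
#' centromere-connected ends (\code{Dcen}) for rightward forks,
#' telomere-connected ends (\code{Dtel}) for leftward forks -- and the
#' head-on proportion is \code{P_HO = 100 * N_HO / (N_HO + N_CD)} with
#' \code{P_CD = 100 - P_HO}.
#'
#' @name trc_stats
NULL

#' Assign head-on / co-directional compartments within an RDC
#'
#' @param rdc Single-interval \code{GRanges}.
#' @param forks Consensus fork segments (\code{direction} column).
#' @param genes Gene \code{GRanges} with strand and an \code{rpkm} metadata
#'   column (GRO-seq expression).
#' @param min_rpkm Active-transcription cutoff (default 0.05 RPKM).
#' @return \code{GRanges} of compartment intervals with \code{mode}
#'   (\code{head_on}/\code{co_directional}), \code{fork_direction},
#'   \code{tx_direction}, \code{matched_orientation}; empty when no active
#'   gene overlaps the RDC.
#' @export
assign_compartments <- function(rdc, forks, genes, min_rpkm = 0.05) {
  stopifnot(length(rdc) == 1)
  out <- GenomicRanges::GRanges()
  active <- genes[!is.na(mcols(genes)$rpkm) & mcols(genes)$rpkm >= min_rpkm]
  if (length(active) == 0 || length(forks) == 0) return(out)
  for (i in seq_along(forks)) {
    f <- forks[i]
    fi <- GenomicRanges::pintersect(f, rdc, ignore.strand = TRUE)
    if (length(fi) == 0 || GenomicRanges::width(fi) <= 0 ||
        !IRanges::overlapsAny(f, rdc, ignore.strand = TRUE)) next
    hits <- GenomicRanges::findOverlaps(fi, active, ignore.strand = TRUE)
    for (h in seq_along(hits)) {
      g <- active[subjectHits(hits)[h]]
      seg <- GenomicRanges::pintersect(fi, g, ignore.strand = TRUE)
      fdir <- mcols(f)$direction
      tdir <- if (as.character(GenomicRanges::strand(g)) == "+") "rightward" else "leftward"
      mode <- if (fdir == tdir) "co_directional" else "head_on"
      comp <- GenomicRanges::GRanges(seqnames(seg), IRanges::ranges(seg))
      mcols(comp)$mode <- mode
      mcols(comp)$fork_direction <- fdir
      mcols(comp)$tx_direction <- tdir
      mcols(comp)$matched_orientation <- if (fdir == "rightward") "Dcen" else "Dtel"
      out <- c(out, comp)
    }
  }
  out
}

#' Head-on and co-directional DSB proportions
#'
#' Counts matched-orientation junctions inside each compartment mode and
#' returns the percentages; junction weights (e.g. off-target library-size
#' weights) are applied when supplied. \code{P_HO + P_CD = 100} whenever the
#' matched total is positive.
#'
#' @param junctions Interchromosomal junction \code{GRanges}.
#' @param compartments Output of \code{\link{assign_compartments}}.
#' @param weights Optional per-junction numeric weights.
#' @return List with \code{P_HO}, \code{P_CD}, \code{N_HO}, \code{N_CD};
#'   \code{P_HO}/\code{P_CD} are \code{NA} when no matched junction exists.
#' @export
trc_proportions <- function(junctions, compartments, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(junctions))
  stopifnot(length(weights) == length(junctions))
  count_mode <- function(mode) {
    comp <- compartments[mcols(compartments)$mode == mode]
    total <- 0
    for (i in seq_along(comp)) {
      inside <- IRanges::overlapsAny(junctions, comp[i], ignore.strand = TRUE)
      matched <- as.character(mcols(junctions)$orientation) ==
        mcols(comp)$matched_orientation[i]
      total <- total + sum(weights[inside & matched])
    }
    total
  }
  n_ho <- count_mode("head_on")
  n_cd <- count_mode("co_directional")
  if (n_ho + n_cd == 0) {
    message("no matched-orientation junctions in any compartment; proportions undefined")
    return(list(P_HO = NA_real_, P_CD = NA_real_, N_HO = 0, N_CD = 0))
  }
  p_ho <- 100 * n_ho / (n_ho + n_cd)
  list(P_HO = p_ho, P_CD = 100 - p_ho, N_HO = n_ho, N_CD = n_cd)
}

#' Relative replication speed of a TRC compartment
#'
#' \code{Rs = (number of 50-kb bins in the compartment) / (number of distinct
#' corrected S-phase fractions spanned)}: bins traversed per fraction, a
#' unit-free speed proxy invariant to junction density.
#'
#' @param compartment Single-interval \code{GRanges}.
#' @param fractions A \code{fraction_track} covering the compartment.
#' @return \code{Rs} (positive scalar).
#' @export
relative_replication_speed <- function(compartment, fractions) {
  stopifnot(length(compartment) == 1)
  bs <- fractions$bin_size
  b1 <- pos_to_bin(GenomicRanges::start(compartment), bs)
  b2 <- pos_to_bin(GenomicRanges::end(compartment), bs)
  b2 <- min(b2, length(fractions$fraction))
  f <- fractions$fraction[b1:b2]
  nf <- length(unique(f[!is.na(f)]))
  if (nf == 0) stop("no corrected fractions span the compartment")
  (b2 - b1 + 1) / nf
}

#' Relative DSB counts across aphidicolin doses
#'
#' For one RDC with per-condition interchromosomal DSB counts
#' \code{P_RDC}, returns \code{log2(P_RDC / (sum(P_RDC) / n))} per condition
#' (n = 5 doses in the standard design). Zero counts take a pseudocount of
#' 0.5 in the numerator only.
#'
#' @param counts Named per-condition counts for one RDC.
#' @param pseudocount Replacement for zero numerators (default 0.5).
#' @return Named numeric vector of log2 ratios; all-zero input is an error.
#' @export
relative_dsb_count <- function(counts, pseudocount = 0.5) {
  total <- sum(counts)
  if (total == 0) stop("all-zero RDC counts; RDC excluded")
  denom <- total / length(counts)
  num <- ifelse(counts == 0, pseudocount, counts)
  res <- log2(num / denom)
  names(res) <- names(counts)
  res
}

#' Count dual-strand DNA:RNA hybrids and stratify RDCs
#'
#' A dual-strand hybrid is a positional overlap between a plus-strand and a
#' minus-strand DRIPc-seq peak. RDCs are grouped by their dual-strand counts:
#' \code{low} = 0-2 (the empirically anchored boundary), and the remaining
#' RDCs split into \code{mid}/\code{high} at the upper tertile of all counts.
#'
#' @param rdcs RDC \code{GRanges}.
#' @param plus_peaks,minus_peaks Strand-specific DRIPc peak \code{GRanges}.
#' @param low_max Upper bound of the low group (default 2).
#' @param tertile_p Quantile splitting mid from high (default 2/3).
#' @return data.frame with \code{count} and \code{group} per RDC.
#' @export
hybrid_stratify <- function(rdcs, plus_peaks, minus_peaks, low_max = 2,
                            tertile_p = 2 / 3) {
  pairs <- GenomicRanges::findOverlaps(plus_peaks, minus_peaks,
                                       ignore.strand = TRUE)
  dual <- GenomicRanges::pintersect(plus_peaks[queryHits(pairs)],
                                    minus_peaks[subjectHits(pairs)],
                                    ignore.strand = TRUE)
  counts <- GenomicRanges::countOverlaps(rdcs, dual, ignore.strand = TRUE)
  group <- rep("low", length(counts))
  if (length(counts) > 0) {
    thr <- stats::quantile(counts, tertile_p, names = FALSE, type = 7)
    group[counts > low_max & counts <= thr] <- "mid"
    group[counts > low_max & counts > thr] <- "high"
  }
  data.frame(count = as.integer(counts), group = group)
}

#' Compare DRIPc peak densities between gene sets
#'
#' Per-gene density = overlapping peaks per 100 kb of gene length; the two
#' density vectors are compared with a two-sided Mann-Whitney test
#' (mid-ranks under ties; exact for small untied samples).
#'
#' @param rdc_genes,nonrdc_genes Disjoint gene \code{GRanges}; the non-RDC
#'   set should already be restricted to active genes longer than 100 kb.
#' @param peaks Peak \code{GRanges}.
#' @return List with \code{density_rdc}, \code{density_nonrdc},
#'   \code{statistic} (Mann-Whitney U of the RDC set) and \code{p_value}.
#' @export
peak_density_compare <- function(rdc_genes, nonrdc_genes, peaks) {
  if (length(rdc_genes) == 0 || length(nonrdc_genes) == 0) {
    stop("both gene sets must be non-empty")
  }
  dens <- function(genes) {
    GenomicRanges::countOverlaps(genes, peaks, ignore.strand = TRUE) /
      (GenomicRanges::width(genes) / 1e5)
  }
  a <- dens(rdc_genes)
  b <- dens(nonrdc_genes)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(density_rdc = a, density_nonrdc = b,
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Two-group comparison (Student's t or Mann-Whitney)
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @param test \code{"t_test"} (unpaired, two-tailed, pooled variance) or
#'   \code{"mann_whitney"}.
#' @return Two-sided p-value.
#' @export
group_compare <- function(values_a, values_b,
                          test = c("t_test", "mann_whitney")) {
  test <- match.arg(test)
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (test == "t_test") {
    if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
      # degenerate: identical constants are indistinguishable (p = 1);
      # distinct constants are perfectly separated (p -> 0)
      return(if (mean(values_a) == mean(values_b)) 1 else 0)
    }
    stats::t.test(values_a, values_b, var.equal = TRUE,
                  alternative = "two.sided")$p.value
  } else {
    suppressWarnings(stats::wilcox.test(values_a, values_b,
                                        alternative = "two.sided"))$p.value
  }
}
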