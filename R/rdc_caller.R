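#' Negative-binomial island calling of recurrent DNA break clusters
#'
#' Junctions are extended 50 kb symmetrically, piled up on a fine bin grid
#' per (chromosome, condition, orientation) stratum, and compared to a
#' negative binomial background. Bins below p = 0.01 are joined into seeds
#' (gaps <= 10 kb), seeds into islands (gaps <= 100 kb), islands extended
#' through contiguous bins below p = 0.1, orientation-specific islands
#' merged, and candidates kept when they hold >= 100 kb below p = 0.01 and
#' span >= 300 kb.
#'
#' @name rdc_caller
NULL

#' Extend junctions and pile them up on a bin grid
#'
#' Each junction contributes a symmetric window of \code{2 * half_width} bp
#' (clipped to the chromosome); the pileup value of a bin is the number of
#' windows overlapping it.
#'
#' @param junctions Junction \code{GRanges} from one chromosome (already
#'   restricted to one orientation stratum, or all junctions for the
#'   \code{"both"} track).
#' @param chrom_length Chromosome length (bp).
#' @param half_width Symmetric extension in bp (default 50000).
#' @param bin_size Pileup grid resolution in bp (default 1000; fine enough
#'   that the 10-kb gap rule is exact).
#' @param orientation,condition Stratum labels carried on the track.
#' @param chrom Chromosome name to stamp on the track (inferred from the
#'   junctions when NULL; required to label empty strata).
#' @return A \code{pileup_track}: list with \code{chrom}, \code{bin_size},
#'   integer \code{values}, \code{chrom_length}, \code{orientation},
#'   \code{condition}.
#' @export
extend_and_pileup <- function(junctions, chrom_length, half_width = 50000,
                              bin_size = 1000, orientation = "both",
                              condition = NA_character_, chrom = NULL) {
  stopifnot(half_width > 0, bin_size > 0, chrom_length >= bin_size)
  chroms <- unique(as.character(seqnames(junctions)))
  if (length(chroms) > 1) stop("extend_and_pileup expects a single chromosome")
  if (is.null(chrom)) chrom <- if (length(chroms) == 1) chroms else "chrom"
  pos <- GenomicRanges::start(junctions)
  ext <- IRanges::IRanges(start = pmax(1L, pos - as.integer(half_width)),
                          end = pmin(as.integer(chrom_length),
                                     pos + as.integer(half_width) - 1L))
  nb <- n_bins(chrom_length, bin_size)
  starts <- seq.int(1L, by = bin_size, length.out = nb)
  grid <- IRanges::IRanges(start = starts,
                           end = pmin(starts + bin_size - 1L, as.integer(chrom_length)))
  values <- IRanges::countOverlaps(grid, ext)
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 values = as.integer(values),
                 chrom_length = as.integer(chrom_length),
                 orientation = orientation, condition = condition),
            class = "pileup_track")
}

#' Fit the negative binomial pileup background
#'
#' Method-of-moments fit on all bins of the stratum: \code{mu} is the sample
#' mean and the NB size parameter comes from
#' \code{var = mu + mu^2 / size}. When the sample variance does not exceed
#' the mean the NB is degenerate and a Poisson background is used instead.
#'
#' @param pileup A \code{pileup_track} (>= 100 bins).
#' @return An \code{nb_background}: list with \code{mean}, \code{size},
#'   \code{poisson} flag and the stratum labels.
#' @export
fit_background <- function(pileup) {
  v <- pileup$values
  if (length(v) < 100) stop("need at least 100 bins to fit a background")
  if (all(v == 0)) stop("all-zero pileup track: no background estimable")
  m <- mean(v)
  s2 <- stats::var(v)
  poisson <- s2 <= m
  size <- if (poisson) Inf else m^2 / (s2 - m)
  structure(list(mean = m, size = size, poisson = poisson,
                 chrom = pileup$chrom, orientation = pileup$orientation,
                 condition = pileup$condition),
            class = "nb_background")
}

#' Upper-tail p-values of pileup values under the fitted background
#'
#' \code{p = P(X >= observed)} under the fitted negative binomial (Poisson
#' when degenerate); an observed value of 0 gives p = 1.
#'
#' @param pileup A \code{pileup_track}.
#' @param bg Matching \code{nb_background}.
#' @return A \code{pvalue_track}: the pileup list with a \code{p} vector in
#'   (0, 1] added.
#' @export
pileup_pvalues <- function(pileup, bg) {
  v <- pileup$values
  p <- if (bg$poisson) {
    ppois(v - 1, lambda = bg$mean, lower.tail = FALSE)
  } else {
    pnbinom(v - 1, size = bg$size, mu = bg$mean, lower.tail = FALSE)
  }
  out <- pileup
  out$p <- pmin(pmax(p, .Machine$double.xmin), 1)
  class(out) <- c("pvalue_track", "pileup_track")
  out
}

# bins-with-p-below-threshold as an IRanges in bin index space
.sig_runs <- function(p, threshold) {
  idx <- which(p < threshold)
  if (length(idx) == 0) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(idx, idx))
}

# per-orientation island construction in bin index space
.orientation_islands <- function(p, p_seed, p_extend, seed_gap_bins, island_gap_bins) {
  seeds <- .sig_runs(p, p_seed)
  if (length(seeds) == 0) return(IRanges::IRanges())
  # join significant runs separated by <= seed_gap_bins into seeds
  seeds <- IRanges::reduce(seeds, min.gapwidth = seed_gap_bins + 1L)
  # join seeds separated by <= island_gap_bins into islands
  islands <- IRanges::reduce(seeds, min.gapwidth = island_gap_bins + 1L)
  # extend each island through contiguous flanking bins below p_extend
  loose <- .sig_runs(p, p_extend)
  ls <- IRanges::start(loose); le <- IRanges::end(loose)
  st <- IRanges::start(islands); en <- IRanges::end(islands)
  for (i in seq_along(islands)) {
    j <- which(ls <= st[i] & le >= st[i])
    if (length(j) == 1) st[i] <- ls[j]
    j <- which(ls <= en[i] & le >= en[i])
    if (length(j) == 1) en[i] <- le[j]
  }
  IRanges::reduce(IRanges::IRanges(st, en))
}

#' Call recurrent DNA break clusters from orientation-stratified p-values
#'
#' Implements the seed/island/extension/filter rules (see
#' \link{rdc_caller}) on three p-value tracks sharing one bin grid:
#' telomeric-only (\code{Dtel}), centromeric-only (\code{Dcen}) and all
#' junctions (\code{both}). Gap rules are strict "<=" in bp; islands that
#' touch end-to-start are merged.
#'
#' @param pvals Named list of \code{pvalue_track}s, names containing
#'   \code{Dcen}, \code{Dtel}, \code{both}.
#' @param p_seed Seed significance threshold (default 0.01).
#' @param p_extend Extension significance threshold (default 0.1).
#' @param seed_gap,island_gap Maximum joining gaps in bp (defaults 10 kb,
#'   100 kb).
#' @param min_sig Minimum bp below \code{p_seed} in any orientation
#'   (default 100 kb).
#' @param min_len Minimum extended call length in bp (default 300 kb).
#' @return \code{GRanges} of RDC calls with \code{sig_bp} metadata column;
#'   per-orientation islands are attached as \code{metadata(x)$islands}.
#' @export
call_rdc <- function(pvals, p_seed = 0.01, p_extend = 0.1,
                     seed_gap = 10000, island_gap = 100000,
                     min_sig = 100000, min_len = 300000) {
  need <- c("Dcen", "Dtel", "both")
  if (!all(need %in% names(pvals))) stop("pvals must contain Dcen, Dtel, both tracks")
  pvals <- pvals[need]
  bs <- unique(vapply(pvals, function(t) t$bin_size, numeric(1)))
  nb <- unique(vapply(pvals, function(t) length(t$p), numeric(1)))
  chrom <- unique(vapply(pvals, function(t) t$chrom, character(1)))
  if (length(bs) != 1 || length(nb) != 1 || length(chrom) != 1) {
    stop("p-value tracks are on mismatched grids")
  }
  bs <- as.integer(bs)
  sgb <- as.integer(floor(seed_gap / bs))
  igb <- as.integer(floor(island_gap / bs))
  islands <- lapply(pvals, function(t)
    .orientation_islands(t$p, p_seed, p_extend, sgb, igb))
  pooled <- IRanges::reduce(do.call(c, unname(islands)))
  if (length(pooled) == 0) {
    out <- GenomicRanges::GRanges()
    metadata(out)$islands <- islands
    return(out)
  }
  # bins significant in any orientation
  any_sig <- rep(FALSE, nb)
  for (t in pvals) any_sig <- any_sig | (t$p < p_seed)
  chrom_length <- pvals[[1]]$chrom_length
  bin_bp <- function(b) pmin(b * bs, chrom_length) - (b - 1L) * bs
  keep <- logical(length(pooled))
  sig_bp <- numeric(length(pooled))
  len_bp <- numeric(length(pooled))
  for (i in seq_along(pooled)) {
    b1 <- IRanges::start(pooled)[i]; b2 <- IRanges::end(pooled)[i]
    bins <- b1:b2
    sig_bp[i] <- sum(bin_bp(bins)[any_sig[bins]])
    len_bp[i] <- min(b2 * bs, chrom_length) - (b1 - 1L) * bs
    keep[i] <- sig_bp[i] >= min_sig && len_bp[i] >= min_len
  }
  pooled <- pooled[keep]
  sig_bp <- sig_bp[keep]
  if (length(pooled) == 0) {
    out <- GenomicRanges::GRanges()
    mcols(out)$sig_bp <- numeric(0)
    metadata(out)$islands <- islands
    return(out)
  }
  out <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(start = (IRanges::start(pooled) - 1L) * bs + 1L,
                     end = pmin(IRanges::end(pooled) * bs, chrom_length))
  )
  mcols(out)$sig_bp <- sig_bp
  mcols(out)$condition <- pvals[[1]]$condition
  metadata(out)$islands <- lapply(islands, function(ir) {
    if (length(ir) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom, IRanges::IRanges(
      start = (IRanges::start(ir) - 1L) * bs + 1L,
      end = pmin(IRanges::end(ir) * bs, chrom_length)))
  })
  out
}

#' One-call RDC scan for a junction set
#'
#' Convenience wrapper: builds the three orientation pileups, fits each
#' background, computes p-values and calls \code{\link{call_rdc}}.
#'
#' @param junctions Interchromosomal junction \code{GRanges}, one chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param half_width,bin_size See \code{\link{extend_and_pileup}}.
#' @param ... Passed to \code{\link{call_rdc}}.
#' @return \code{GRanges} of RDC calls.
#' @export
scan_rdc <- function(junctions, chrom_length, half_width = 50000,
                     bin_size = 1000, ...) {
  ori <- as.character(mcols(junctions)$orientation)
  chrom <- unique(as.character(seqnames(junctions)))
  if (length(chrom) != 1) chrom <- "chrom"
  tracks <- list(
    Dcen = extend_and_pileup(junctions[ori == "Dcen"], chrom_length,
                             half_width, bin_size, orientation = "Dcen",
                             chrom = chrom),
    Dtel = extend_and_pileup(junctions[ori == "Dtel"], chrom_length,
                             half_width, bin_size, orientation = "Dtel",
                             chrom = chrom),
    both = extend_and_pileup(junctions, chrom_length,
                             half_width, bin_size, orientation = "both",
                             chrom = chrom)
  )
  pvals <- lapply(tracks, function(t) {
    if (all(t$values == 0)) {
      out <- t; out$p <- rep(1, length(t$values))
      class(out) <- c("pvalue_track", "pileup_track")
      out
    } else {
      pileup_pvalues(t, fit_background(t))
    }
  })
  call_rdc(pvals, ...)
}
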