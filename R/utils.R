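#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits metadata metadata<-
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#' @importFrom stats rnbinom rpois rbinom runif dnorm pnbinom ppois
#'   loess predict wilcox.test t.test hclust cutree dist
#'   p.adjust ks.test
#' @importFrom utils read.table write.table head tail
#' @importFrom methods is
NULL

# number of fixed-width bins covering a chromosome
n_bins <- function(chrom_length, bin_size) as.integer(ceiling(chrom_length / bin_size))

# GRanges of the bin grid for one chromosome (1-based closed)
bin_grid <- function(chrom, chrom_length, bin_size) {
  nb <- n_bins(chrom_length, bin_size)
  starts <- seq.int(1L, by = bin_size, length.out = nb)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(
    start = starts,
    end = pmin(starts + bin_size - 1L, chrom_length)
  ))
}

# bin index (1-based) of a 1-based position
pos_to_bin <- function(pos, bin_size) as.integer(floor((pos - 1) / bin_size)) + 1L

# Gaussian smoothing of a numeric vector with a truncated, edge-renormalized
# kernel; sigma = 0 (or < 1e-12) is the identity. NAs propagate locally:
# missing values get weight zero and the kernel renormalizes.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 1e-12) return(x)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq.int(-r, r), sd = sigma)
  n <- length(x)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  num <- rep(0, n)
  den <- rep(0, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    valid <- src >= 1L & src <= n
    num[valid] <- num[valid] + k[j] * x0[src[valid]]
    den[valid] <- den[valid] + k[j] * ok[src[valid]]
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!ok] <- NA_real_
  out
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

#' EdU/BrdU labeling span per fork
#'
#' Distance a single replication fork travels during a pulse label, used to
#' justify the 50-kb Repli-seq bin: at the canonical mammalian fork speed of
#' 1.8 kb/min a 30-minute label covers 54 kb, so every labeled fork spans at
#' least one 50-kb bin.
#'
#' @param rate_kb_per_min Fork speed in kb per minute (default 1.8).
#' @param minutes Label duration in minutes (default 30).
#' @return Labeled span in kb.
#' @examples
#' fork_label_span()  # 54
#' @export
fork_label_span <- function(rate_kb_per_min = 1.8, minutes = 30) {
  stopifnot(rate_kb_per_min > 0, minutes > 0)
  rate_kb_per_min * minutes
}
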