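suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# junction GRanges shortcut
mk_junctions <- function(chrom, pos, ori, bait = "chrBait", lib = "L1",
                         cond = "untreated") {
  rdcscan:::new_junctions(chrom, pos, ori, bait_chrom = bait,
                          library_id = lib, condition = cond)
}

# p-value track shortcut (1-kb bins by default)
mk_pvtrack <- function(p, bin_size = 1000L, chrom = "chr1",
                       chrom_length = length(p) * bin_size) {
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 values = rep(1L, length(p)),
                 chrom_length = as.integer(chrom_length),
                 orientation = "x", condition = NA_character_, p = p),
            class = c("pvalue_track", "pileup_track"))
}

mk_fractions <- function(f, bin_size = 50000L, chrom = "chr1") {
  structure(list(fraction = f, cluster_id = seq_along(f), chrom = chrom,
                 bin_size = as.integer(bin_size)),
            class = "fraction_track")
}

mk_fork <- function(start, end, direction, chrom = "chr1", replicate = "r1") {
  g <- GRanges(chrom, IRanges(start, end),
               strand = if (direction == "rightward") "+" else "-")
  mcols(g)$direction <- direction
  mcols(g)$source <- "fixture"
  mcols(g)$replicate <- replicate
  g
}

mk_genes <- function(start, end, strand, rpkm, chrom = "chr1") {
  g <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(g)$rpkm <- rpkm
  g
}

pos_to_bin_test <- function(pos, bin_size = 50000) {
  as.integer(floor((pos - 1) / bin_size)) + 1L
}

bin_grid_test <- function(chrom, chrom_length, bin_size) {
  nb <- as.integer(ceiling(chrom_length / bin_size))
  starts <- seq.int(1L, by = bin_size, length.out = nb)
  GRanges(chrom, IRanges(starts, pmin(starts + bin_size - 1, chrom_length)))
}

# ---- independent brute-force oracle for the island caller -----------------
# Rules re-expressed on boolean bin arrays with rle/dilation primitives,
# deliberately avoiding the IRanges machinery of the implementation.

.fill_gaps <- function(member, max_gap_bins) {
  r <- rle(member)
  n <- length(r$values)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (!r$values[i] && r$lengths[i] <= max_gap_bins) r$values[i] <- TRUE
    }
  }
  inverse.rle(r)
}

.dilate_within <- function(member, allowed) {
  repeat {
    n <- length(member)
    grown <- member |
      (allowed & c(FALSE, member[-n])) |
      (allowed & c(member[-1], FALSE))
    if (identical(grown, member)) return(member)
    member <- grown
  }
}

.runs_of <- function(member) {
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

oracle_rdc <- function(p_list, bin_size, chrom_length = length(p_list[[1]]) * bin_size,
                       p_seed = 0.01, p_extend = 0.1, seed_gap = 10000,
                       island_gap = 100000, min_sig = 100000, min_len = 300000) {
  nbins <- length(p_list[[1]])
  sgb <- floor(seed_gap / bin_size)
  igb <- floor(island_gap / bin_size)
  member_any <- rep(FALSE, nbins)
  sig_any <- rep(FALSE, nbins)
  for (p in p_list) {
    sig <- p < p_seed
    sig_any <- sig_any | sig
    if (!any(sig)) next
    seeds <- .fill_gaps(sig, sgb)
    islands <- .fill_gaps(seeds, igb)
    ext <- .dilate_within(islands, p < p_extend)
    member_any <- member_any | ext
  }
  runs <- .runs_of(member_any)
  out <- NULL
  bin_bp <- function(b) pmin(b * bin_size, chrom_length) - (b - 1L) * bin_size
  for (i in seq_len(nrow(runs))) {
    b1 <- unname(runs[i, 1]); b2 <- unname(runs[i, 2])
    sig_bp <- sum(bin_bp(b1:b2)[sig_any[b1:b2]])
    len_bp <- min(b2 * bin_size, chrom_length) - (b1 - 1L) * bin_size
    if (sig_bp >= min_sig && len_bp >= min_len) {
      out <- rbind(out, c(start = (b1 - 1L) * bin_size + 1L,
                          end = min(b2 * bin_size, chrom_length),
                          sig_bp = sig_bp))
    }
  }
  out
}

# exhaustive Mann-Whitney oracle: U statistic of a, p by full enumeration of
# group assignments (no ties assumed)
oracle_mann_whitney <- function(a, b) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  pooled <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- length(a) * length(b) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}
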