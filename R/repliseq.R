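#' 16-fraction Repli-seq processing and replication feature calling
#'
#' High-resolution Repli-seq sorts S phase into 16 consecutive fractions
#' (S1 earliest ... S16 latest) and sequences newly replicated DNA from each,
#' yielding a 16 x N matrix of counts over 50-kb genomic bins. After depth
#' normalization, Gaussian smoothing along the genome and per-bin scaling,
#' each bin's 16-vector is a replication-timing profile. Bins are clustered
#' (BIRCH-style), each cluster's centroid argmax assigns a "corrected
#' fraction" in 1..16, and timing features are called from the corrected
#' fraction track: initiation zones (IZ, local timing minima), small
#' termination zones (small TZ, local maxima <= 100 kb), timing transition
#' regions (TTR, monotone runs tolerating plateaus of up to 3 bins) and late
#' constant timing regions (late CTR).
#'
#' @name repliseq
NULL

#' Construct a Repli-seq matrix object
#'
#' @param values 16 x N numeric matrix (rows S1..S16), non-negative.
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp (default 50000).
#' @param replicate_id,condition Metadata labels.
#' @return An object of class \code{repliseq_matrix}.
#' @export
repliseq_matrix <- function(values, chrom, bin_size = 50000,
                            replicate_id = NA_character_,
                            condition = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) != 16) stop("a repliseq_matrix has exactly 16 fraction rows")
  if (any(values < 0, na.rm = TRUE)) stop("negative Repli-seq values")
  structure(list(values = values, chrom = chrom,
                 bin_size = as.integer(bin_size),
                 replicate_id = replicate_id, condition = condition),
            class = "repliseq_matrix")
}

#' @export
print.repliseq_matrix <- function(x, ...) {
  cat(sprintf("repliseq_matrix: %s, %d bins x 16 fractions (%d bp bins)\n",
              x$chrom, ncol(x$values), x$bin_size))
  invisible(x)
}

#' Normalize and smooth a raw Repli-seq matrix
#'
#' Three steps: (1) each fraction row is scaled to a common sequencing depth
#' (reads-per-50M equivalent); (2) Gaussian smoothing along the genomic axis
#' within each fraction (s.d. \code{sigma_bins} bins; 0 = identity); (3)
#' each bin column is scaled to unit sum (all-zero columns stay zero,
#' marking unmappable bins).
#'
#' @param raw A \code{repliseq_matrix} of raw counts.
#' @param sigma_bins Gaussian s.d. along the genome, in bins.
#' @return The normalized \code{repliseq_matrix}.
#' @export
normalize_and_smooth <- function(raw, sigma_bins = 1) {
  m <- raw$values
  if (all(m == 0)) stop("all-zero Repli-seq matrix")
  rs <- rowSums(m)
  scale <- ifelse(rs > 0, 5e7 / rs, 0)
  m <- m * scale
  if (sigma_bins > 0) {
    for (i in seq_len(nrow(m))) m[i, ] <- gaussian_smooth(m[i, ], sigma_bins)
  }
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, cs[nz], "/")
  out <- raw
  out$values <- m
  out$normalized <- TRUE
  out
}

# BIRCH-style clustering of column vectors, deterministic in column order.
# Phase 1: sequential leaf absorption -- a point joins the nearest leaf
# centroid if within `threshold`, else founds a new leaf; when the leaf
# count exceeds `max_leaves` the threshold grows and the pass restarts
# (the classic rebuild). Phase 2: Ward agglomeration of leaf centroids
# down to n_clusters; cluster centroids are leaf-size-weighted means.
birch_cluster <- function(x, n_clusters, threshold = NULL, max_leaves = 1024) {
  n <- ncol(x)
  if (is.null(threshold)) {
    if (n > 1) {
      d <- sqrt(colSums((x[, -1, drop = FALSE] - x[, -n, drop = FALSE])^2))
      threshold <- 0.5 * stats::median(d[d > 0])
      if (!is.finite(threshold) || threshold <= 0) threshold <- 1e-3
    } else threshold <- 1e-3
  }
  repeat {
    cent <- matrix(0, nrow(x), 0)
    size <- integer(0)
    leaf <- integer(n)
    overflow <- FALSE
    for (i in seq_len(n)) {
      if (ncol(cent) == 0) {
        cent <- x[, i, drop = FALSE]; size <- 1L; leaf[i] <- 1L
        next
      }
      d2 <- colSums((cent - x[, i])^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) <= threshold) {
        cent[, j] <- (cent[, j] * size[j] + x[, i]) / (size[j] + 1L)
        size[j] <- size[j] + 1L
        leaf[i] <- j
      } else {
        cent <- cbind(cent, x[, i]); size <- c(size, 1L)
        leaf[i] <- length(size)
        if (length(size) > max_leaves) { overflow <- TRUE; break }
      }
    }
    if (!overflow) break
    threshold <- threshold * 1.5
  }
  k <- min(n_clusters, ncol(cent))
  if (k < n_clusters) {
    warning("fewer distinct leaves (", ncol(cent), ") than requested clusters (",
            n_clusters, "); using ", k)
  }
  if (ncol(cent) > k) {
    hc <- stats::hclust(stats::dist(t(cent)), method = "ward.D2")
    grp <- stats::cutree(hc, k = k)
  } else {
    grp <- seq_len(ncol(cent))
  }
  gc_cent <- matrix(0, nrow(x), k)
  for (g in seq_len(k)) {
    idx <- which(grp == g)
    w <- size[idx]
    gc_cent[, g] <- as.numeric(cent[, idx, drop = FALSE] %*% w / sum(w))
  }
  list(cluster = grp[leaf], centroids = gc_cent)
}

#' Corrected S-phase fractions via BIRCH-style clustering
#'
#' Non-zero bin columns are clustered by their 16-vector (default 80
#' clusters, sequential absorption in genomic order followed by Ward
#' agglomeration of leaf centroids); each cluster's corrected fraction is
#' the argmax over its centroid's 16 components (ties broken toward the
#' earliest fraction), and every bin inherits its cluster's corrected
#' fraction. Unmappable (all-zero) bins stay missing.
#'
#' @param matrix A normalized \code{repliseq_matrix}.
#' @param n_clusters Number of clusters (default 80).
#' @return A \code{fraction_track}: list with integer \code{fraction}
#'   (1..16, NA where unmappable), \code{cluster_id}, \code{chrom},
#'   \code{bin_size}.
#' @export
birch_fractions <- function(matrix, n_clusters = 80) {
  m <- matrix$values
  nzcol <- colSums(m) > 0
  frac <- rep(NA_integer_, ncol(m))
  clid <- rep(NA_integer_, ncol(m))
  if (sum(nzcol) == 0) stop("no mappable bins")
  fit <- birch_cluster(m[, nzcol, drop = FALSE], n_clusters)
  corrected <- apply(fit$centroids, 2, which.max) # ties -> earliest fraction
  frac[nzcol] <- as.integer(corrected[fit$cluster])
  clid[nzcol] <- fit$cluster
  structure(list(fraction = frac, cluster_id = clid,
                 chrom = matrix$chrom, bin_size = matrix$bin_size),
            class = "fraction_track")
}

# plateau (run-length) table of a fraction vector segment
.plateaus <- function(f) {
  r <- rle(f)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, len = r$lengths,
             start = ends - r$lengths + 1L, end = ends)
}

# features within one contiguous non-NA segment; returns a data.frame of
# (kind, start_bin, end_bin, direction, f1, f2) in segment-local bins
.segment_features <- function(f, max_plateau, late_fraction, small_tz_bins) {
  pl <- .plateaus(f)
  np <- nrow(pl)
  out <- list()
  claimed <- rep(FALSE, length(f))
  add <- function(kind, b1, b2, dir = "none", f1 = NA, f2 = NA) {
    out[[length(out) + 1L]] <<- data.frame(
      kind = kind, start_bin = b1, end_bin = b2, direction = dir,
      f1 = f1, f2 = f2)
    claimed[b1:b2] <<- TRUE
  }
  left <- c(NA, pl$value[-np])
  right <- c(pl$value[-1], NA)
  # extrema first: IZ (local minima), small TZ (local maxima <= small_tz_bins)
  for (i in seq_len(np)) {
    lo <- !is.na(left[i]) && left[i] > pl$value[i]
    hi <- !is.na(right[i]) && right[i] > pl$value[i]
    if (lo && hi) add("IZ", pl$start[i], pl$end[i], f1 = pl$value[i], f2 = pl$value[i])
    lo2 <- !is.na(left[i]) && left[i] < pl$value[i]
    hi2 <- !is.na(right[i]) && right[i] < pl$value[i]
    if (lo2 && hi2 && pl$len[i] <= small_tz_bins) {
      add("smallTZ", pl$start[i], pl$end[i], f1 = pl$value[i], f2 = pl$value[i])
    }
  }
  # late CTR: long constant runs at late fractions (unclaimed by extrema)
  for (i in seq_len(np)) {
    if (pl$len[i] > max_plateau && pl$value[i] >= late_fraction &&
        !any(claimed[pl$start[i]:pl$end[i]])) {
      add("lateCTR", pl$start[i], pl$end[i], f1 = pl$value[i], f2 = pl$value[i])
    }
  }
  # TTR: maximal monotone chains of short (<= max_plateau) plateaus. Long
  # plateaus, and plateaus already claimed as IZ/smallTZ/lateCTR extrema,
  # break the chain but lend their value to the fraction span when they
  # continue the trend. Chains must involve a real transition: >= 2 plateaus,
  # or 1 plateau flanked by a trend-continuing blocked plateau.
  blocked <- pl$len > max_plateau |
    vapply(seq_len(np), function(i) any(claimed[pl$start[i]:pl$end[i]]), logical(1))
  i <- 1L
  while (i <= np) {
    if (blocked[i]) { i <- i + 1L; next }
    # grow a monotone chain of unblocked plateaus starting at i
    j <- i
    dir <- 0L
    while (j < np && !blocked[j + 1L]) {
      step <- sign(pl$value[j + 1L] - pl$value[j])
      if (dir == 0L) dir <- step else if (step != dir) break
      j <- j + 1L
    }
    f1 <- pl$value[i]; f2 <- pl$value[j]
    if (dir == 0L) {
      # single plateau: direction comes from flanking blocked plateaus
      dl <- if (i > 1L) sign(pl$value[i] - pl$value[i - 1L]) else 0L
      dr <- if (j < np) sign(pl$value[j + 1L] - pl$value[j]) else 0L
      dir <- if (dl != 0L) dl else dr
    }
    # extend fraction span into adjacent blocked plateaus continuing the trend
    ext_l <- i > 1L && blocked[i - 1L] && dir != 0L &&
      sign(pl$value[i] - pl$value[i - 1L]) == dir
    ext_r <- j < np && blocked[j + 1L] && dir != 0L &&
      sign(pl$value[j + 1L] - pl$value[j]) == dir
    if (dir != 0L && (j > i || ext_l || ext_r)) {
      if (ext_l) f1 <- pl$value[i - 1L]
      if (ext_r) f2 <- pl$value[j + 1L]
      add("TTR", pl$start[i], pl$end[j],
          dir = if (dir > 0) "rightward" else "leftward", f1 = f1, f2 = f2)
    }
    i <- j + 1L
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Call replication timing features from corrected fractions
#'
#' See \link{repliseq} for the feature definitions. Missing (unmappable)
#' bins break all features. Where rules overlap, extrema (IZ/small TZ) win
#' over late CTR, which wins over TTR, so returned intervals are disjoint.
#'
#' @param track A \code{fraction_track}.
#' @param late_fraction Corrected fraction at or above which a long constant
#'   run is a late CTR (default 12).
#' @param max_plateau Longest equal-fraction plateau tolerated inside a TTR,
#'   in bins (default 3).
#' @param small_tz_max_bp Maximum small-TZ span in bp (default 100 kb).
#' @return \code{GRanges} with metadata columns \code{kind}
#'   (\code{IZ}/\code{smallTZ}/\code{TTR}/\code{lateCTR}), \code{direction}
#'   (TTR only; also encoded in the strand), \code{fraction_start},
#'   \code{fraction_end}.
#' @export
call_features <- function(track, late_fraction = 12, max_plateau = 3,
                          small_tz_max_bp = 100000) {
  f <- track$fraction
  bs <- track$bin_size
  small_tz_bins <- max(1L, as.integer(floor(small_tz_max_bp / bs)))
  segs <- .sig_runs(ifelse(is.na(f), 1, 0), 0.5) # runs of non-NA bins
  rows <- list()
  for (i in seq_along(segs)) {
    a <- IRanges::start(segs)[i]; b <- IRanges::end(segs)[i]
    df <- .segment_features(f[a:b], max_plateau, late_fraction, small_tz_bins)
    if (!is.null(df)) {
      df$start_bin <- df$start_bin + a - 1L
      df$end_bin <- df$end_bin + a - 1L
      rows[[length(rows) + 1L]] <- df
    }
  }
  if (length(rows) == 0) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$kind <- character(0)
    return(gr)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start_bin), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(start = (df$start_bin - 1L) * bs + 1L,
                     end = df$end_bin * bs),
    strand = ifelse(df$direction == "rightward", "+",
                    ifelse(df$direction == "leftward", "-", "*"))
  )
  mcols(gr)$kind <- df$kind
  mcols(gr)$direction <- df$direction
  mcols(gr)$fraction_start <- df$f1
  mcols(gr)$fraction_end <- df$f2
  gr
}

#' Fraction of the covered genome occupied by each feature kind
#'
#' @param features Feature \code{GRanges} from \code{\link{call_features}}.
#' @param covered_bp Total bp with defined corrected fractions (denominator).
#' @return Named numeric vector of genome fractions (0..1) per feature kind.
#' @export
genome_feature_fractions <- function(features, covered_bp) {
  stopifnot(covered_bp > 0)
  kinds <- c("IZ", "TTR", "lateCTR", "smallTZ")
  bp <- vapply(kinds, function(k)
    sum(GenomicRanges::width(features[mcols(features)$kind == k])), numeric(1))
  bp / covered_bp
}
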