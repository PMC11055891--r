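#' Termination-zone prediction from 16-fraction Repli-seq
#'
#' Corrected-fraction feature calling cannot resolve termination zones wider
#' than about 100 kb, so termination meeting points are predicted directly
#' from the normalized Repli-seq matrix by a small fully convolutional
#' network (see \code{\link{dice_loss}} and the architecture notes in the
#' methods vignette). Reference labels come from OK-seq RFD zero-crossings
#' (\code{\link{reference_iz_tz}}); training windows span 30 bins at both
#' the native 50-kb and a 2x-merged 100-kb scale, tiled with stride 24 so
#' that consecutive windows share 6 bins of context and only the central 24
#' bins are scored.
#'
#' @name termination_net
NULL

# merge adjacent bin pairs of a normalized matrix (genomic 2x downscale)
downscale_matrix <- function(m) {
  n2 <- floor(ncol(m) / 2)
  if (n2 < 1) return(m[, 0, drop = FALSE])
  mm <- m[, seq_len(2 * n2), drop = FALSE]
  out <- mm[, seq(1, 2 * n2, by = 2), drop = FALSE] +
    mm[, seq(2, 2 * n2, by = 2), drop = FALSE]
  cs <- colSums(out)
  nz <- cs > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, cs[nz], "/")
  out
}

#' Build training windows from a Repli-seq matrix and IZ/TZ labels
#'
#' @param matrix A normalized \code{repliseq_matrix}.
#' @param labels List with \code{iz_bins} and \code{tz_bins} (bin indices on
#'   the matrix grid), e.g. from \code{\link{reference_iz_tz}}.
#' @param window Window length in bins (default 30).
#' @param stride Tiling stride in bins (default 24; 6 shared context bins).
#' @param scales Genomic downscale factors to pool (default \code{c(1, 2)}).
#' @param core Width of the scored central region (default 24 bins).
#' @return List of windows; each has \code{x} (16 x window), binary \code{y},
#'   \code{core} (index vector), \code{scale}, \code{start} (bin on that
#'   scale's grid).
#' @export
make_training_windows <- function(matrix, labels, window = 30L, stride = 24L,
                                  scales = c(1L, 2L), core = 24L) {
  stopifnot(window > core)
  flank <- (window - core) %/% 2L
  out <- list()
  for (sc in scales) {
    m <- matrix$values
    iz <- labels$iz_bins
    tz <- labels$tz_bins
    if (sc > 1) {
      for (i in seq_len(round(log2(sc)))) m <- downscale_matrix(m)
      iz <- unique(ceiling(iz / sc))
      tz <- unique(ceiling(tz / sc))
    }
    n <- ncol(m)
    if (n < window) next
    starts <- seq(1L, n - window + 1L, by = stride)
    for (s in starts) {
      bins <- s:(s + window - 1L)
      has_iz <- any(iz %in% bins)
      has_tz <- any(tz %in% bins)
      if (!has_iz || !has_tz) next
      y <- as.numeric(bins %in% tz)
      out[[length(out) + 1L]] <- list(
        x = m[, bins, drop = FALSE], y = y,
        core = (flank + 1L):(flank + core),
        scale = sc, start = s)
    }
  }
  out
}

#' Train the termination-zone network
#'
#' Adam on the Dice loss masked to the core bins, mini-batches of
#' \code{batch_size}, inverted dropout on the inception concat layer.
#' Deterministic given \code{seed} (single-threaded base-R linear algebra).
#'
#' @param windows Training windows from \code{\link{make_training_windows}}.
#' @param seed RNG seed.
#' @param epochs Training epochs (default 60).
#' @param lr Learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param dropout Dropout rate on the concat layer (default 0.9).
#' @param verbose Print per-epoch loss.
#' @return A trained \code{tz_model} with a \code{history} of epoch losses.
#' @export
train_tz_model <- function(windows, seed = 1, epochs = 60, lr = 1e-3,
                           batch_size = 32, dropout = 0.9, verbose = FALSE) {
  if (length(windows) < 1) stop("no training windows")
  if (all(vapply(windows, function(w) sum(w$y) == 0, logical(1)))) {
    stop("degenerate labels: every window is all-zero")
  }
  L <- length(windows[[1]]$y)
  core <- windows[[1]]$core
  model <- tznet_init(seed = seed)
  st <- list(t = 0L, m = list(), v = list())
  keep <- 1 - dropout
  set.seed(derive_seed(seed, 202))
  history <- numeric(epochs)
  n <- length(windows)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (i0 in seq(1, n, by = batch_size)) {
      idx <- ord[i0:min(i0 + batch_size - 1L, n)]
      B <- length(idx)
      x <- array(0, c(16, L, B))
      y <- matrix(0, L, B)
      for (j in seq_len(B)) {
        x[, , j] <- windows[[idx[j]]]$x
        y[, j] <- windows[[idx[j]]]$y
      }
      dm <- NULL
      if (dropout > 0) {
        dm <- array(stats::rbinom(model$arch$concat * L * B, 1, keep) / keep,
                    c(model$arch$concat, L, B))
      }
      fw <- tznet_forward(model, x, cache = TRUE, drop_mask = dm)
      dl <- dice_loss(fw$prob, y, mask = core)
      g <- tznet_backward(model, fw$cache, dl$dprob)
      up <- adam_step(model$params, g, st, lr = lr)
      model$params <- up$params
      st <- up$st
      ep_loss <- ep_loss + dl$loss; nb <- nb + 1L
    }
    history[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d dice loss %.4f", ep, history[ep]))
  }
  model$trained <- TRUE
  model$history <- history
  model
}

#' Predict termination meeting points
#'
#' Runs the fully convolutional network over a track of any length
#' (>= 30 bins), then reports local probability maxima above
#' \code{threshold} as single-bin meeting-point anchors.
#'
#' @param model A trained \code{tz_model}.
#' @param matrix A normalized \code{repliseq_matrix} (or bare 16 x N matrix).
#' @param threshold Anchor probability threshold (default 0.5).
#' @return List with per-bin \code{prob} and integer \code{anchors} (bin
#'   indices).
#' @export
predict_tz <- function(model, matrix, threshold = 0.5) {
  m <- if (inherits(matrix, "repliseq_matrix")) matrix$values else matrix
  n <- ncol(m)
  x <- array(m, c(16, n, 1))
  prob <- tznet_forward(model, x)$prob[, 1]
  up <- c(TRUE, prob[-1] >= prob[-n])
  down <- c(prob[-n] >= prob[-1], TRUE)
  anchors <- which(up & down & prob > threshold)
  # collapse flat maxima to their first bin
  if (length(anchors) > 1) {
    anchors <- anchors[c(TRUE, diff(anchors) > 1)]
  }
  list(prob = prob, anchors = anchors)
}

# recall/precision of predicted anchors vs true TZ bins at a bin tolerance
.match_stats <- function(pred, truth, tol) {
  tp_r <- sum(vapply(truth, function(b) any(abs(pred - b) <= tol), logical(1)))
  tp_p <- sum(vapply(pred, function(b) any(abs(truth - b) <= tol), logical(1)))
  c(n_true = length(truth), n_pred = length(pred), tp_r = tp_r, tp_p = tp_p)
}

#' K-fold cross-validation of the termination-zone network
#'
#' Windows are split into folds (seeded), the model is retrained on each
#' training split, and held-out windows are scored on their core bins:
#' recall = matched true TZ bins / true TZ bins, precision = matched
#' predicted anchors / predicted anchors, both at \code{tolerance_bins}.
#'
#' @param windows Training windows.
#' @param folds Number of folds (default 10).
#' @param tolerance_bins Matching tolerance (default 1 bin = 50 kb).
#' @param threshold Anchor threshold (default 0.5).
#' @inheritParams train_tz_model
#' @return List with per-fold data.frame \code{folds} and pooled
#'   \code{recall} and \code{precision}.
#' @export
cross_validate_tz <- function(windows, folds = 10, seed = 1, epochs = 60,
                              lr = 1e-3, batch_size = 32, dropout = 0.9,
                              tolerance_bins = 1, threshold = 0.5) {
  n <- length(windows)
  stopifnot(n >= folds)
  set.seed(derive_seed(seed, 303))
  fold_of <- sample(rep_len(seq_len(folds), n))
  per <- matrix(0, folds, 4,
                dimnames = list(NULL, c("n_true", "n_pred", "tp_r", "tp_p")))
  for (f in seq_len(folds)) {
    tr <- windows[fold_of != f]
    te <- windows[fold_of == f]
    model <- train_tz_model(tr, seed = derive_seed(seed, f), epochs = epochs,
                            lr = lr, batch_size = batch_size, dropout = dropout)
    for (w in te) {
      pr <- predict_tz(model, w$x, threshold = threshold)
      core <- w$core
      pred <- pr$anchors[pr$anchors %in% core]
      truth <- intersect(which(w$y == 1), core)
      per[f, ] <- per[f, ] + .match_stats(pred, truth, tolerance_bins)
    }
  }
  df <- as.data.frame(per)
  df$fold <- seq_len(folds)
  df$recall <- ifelse(df$n_true > 0, df$tp_r / df$n_true, NA)
  df$precision <- ifelse(df$n_pred > 0, df$tp_p / df$n_pred, NA)
  list(folds = df,
       recall = sum(df$tp_r) / sum(df$n_true),
       precision = sum(df$tp_p) / sum(df$n_pred))
}
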