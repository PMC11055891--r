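# Minimal fully convolutional network over genomic tracks.
#
# All tensors are R arrays of dim (channels, length, batch). Convolutions are
# 1-D along the genomic axis with zero "same" padding; forward/backward passes
# and the Adam optimizer are written out directly for the fixed architecture
# used by the termination-zone predictor (an inception block with 5/7/9
# kernels and a max-pool branch, each behind a 1x1 reduction, followed by
# 1x1, 1x1 and 1x9 convolutions; SELU activations, sigmoid output).

.SELU_LAMBDA <- 1.0507009873554805
.SELU_ALPHA <- 1.6732632423543772

selu <- function(x) {
  .SELU_LAMBDA * ifelse(x > 0, x, .SELU_ALPHA * (exp(x) - 1))
}

selu_grad <- function(x) {
  .SELU_LAMBDA * ifelse(x > 0, 1, .SELU_ALPHA * exp(x))
}

# (C,L,B) -> (C*k, L*B) patch matrix, zero padded
im2col <- function(x, k) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  h <- (k - 1L) %/% 2L
  a <- array(0, c(C, k, L, B))
  for (j in seq_len(k)) {
    off <- j - 1L - h
    dst <- max(1L, 1L - off):min(L, L - off)
    a[, j, dst, ] <- x[, dst + off, , drop = FALSE]
  }
  dim(a) <- c(C * k, L * B)
  a
}

# scatter-add the patch-matrix gradient back to input shape
col2im <- function(dcol, C, k, L, B) {
  dim(dcol) <- c(C, k, L, B)
  h <- (k - 1L) %/% 2L
  dx <- array(0, c(C, L, B))
  for (j in seq_len(k)) {
    off <- j - 1L - h
    dst <- max(1L, 1L - off):min(L, L - off)
    add <- dcol[, j, dst, , drop = FALSE]
    dim(add) <- c(C, length(dst), B)
    dx[, dst + off, ] <- dx[, dst + off, , drop = FALSE] + add
  }
  dx
}

conv_fwd <- function(x, W, b, k) {
  d <- dim(x); L <- d[2]; B <- d[3]
  xcol <- im2col(x, k)
  y <- W %*% xcol + b
  dim(y) <- c(nrow(W), L, B)
  list(y = y, xcol = xcol)
}

conv_bwd <- function(dy, W, xcol, k, C_in, L, B) {
  dim(dy) <- c(nrow(W), L * B)
  dW <- dy %*% t(xcol)
  db <- rowSums(dy)
  dxcol <- t(W) %*% dy
  dx <- col2im(dxcol, C_in, k, L, B)
  list(dW = dW, db = db, dx = dx)
}

# width-3 max pooling, stride 1, same padding; winners recorded for backprop
maxpool3_fwd <- function(x) {
  d <- dim(x); L <- d[2]
  neg <- -Inf
  left <- x; left[, , ] <- neg
  right <- left
  if (L > 1) {
    left[, 2:L, ] <- x[, 1:(L - 1), , drop = FALSE]
    right[, 1:(L - 1), ] <- x[, 2:L, , drop = FALSE]
  }
  y <- pmax(left, x, right)
  win <- array(1L, d)               # -1, 0, +1 offset of the winner
  win[left == y] <- -1L             # tie priority: centre, then left
  win[x == y] <- 0L
  list(y = y, win = win)
}

maxpool3_bwd <- function(dy, win) {
  d <- dim(dy); L <- d[2]
  dx <- array(0, d)
  for (off in c(-1L, 0L, 1L)) {
    src <- max(1L, 1L - off):min(L, L - off)   # positions l with l+off valid
    m <- (win == off) * dy
    dx[, src + off, ] <- dx[, src + off, , drop = FALSE] +
      m[, src, , drop = FALSE]
  }
  dx
}

# Lecun-normal initialization (the SELU-appropriate scheme)
.init_W <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = 1 / sqrt(n_in)), n_out, n_in)
}

#' Initialize the termination-zone network
#'
#' @param in_channels Input channels (16 S-phase fractions).
#' @param reduce Channels after each 1x1 reduction (default 6).
#' @param branch Channels per inception branch (default 8).
#' @param kernels Inception kernel widths (default 5, 7, 9).
#' @param seed RNG seed for the weight initialization.
#' @return A \code{tz_model} parameter list (untrained).
#' @keywords internal
tznet_init <- function(in_channels = 16, reduce = 6, branch = 8,
                       kernels = c(5L, 7L, 9L), seed = 1) {
  set.seed(derive_seed(seed, 101))
  p <- list()
  for (k in kernels) {
    nm <- paste0("b", k)
    p[[paste0(nm, "_rW")]] <- .init_W(reduce, in_channels)
    p[[paste0(nm, "_rb")]] <- rep(0, reduce)
    p[[paste0(nm, "_cW")]] <- .init_W(branch, reduce * k)
    p[[paste0(nm, "_cb")]] <- rep(0, branch)
  }
  p$pool_W <- .init_W(branch, in_channels)
  p$pool_b <- rep(0, branch)
  cc <- branch * (length(kernels) + 1L)
  p$h1_W <- .init_W(16, cc); p$h1_b <- rep(0, 16)
  p$h2_W <- .init_W(8, 16); p$h2_b <- rep(0, 8)
  p$out_W <- .init_W(1, 8 * 9); p$out_b <- 0
  structure(list(params = p,
                 arch = list(in_channels = in_channels, reduce = reduce,
                             branch = branch, kernels = kernels,
                             concat = cc, out_kernel = 9L),
                 trained = FALSE),
            class = "tz_model")
}

# forward pass; returns per-bin probabilities and (if cache=TRUE) the
# intermediate values needed for backprop. drop_mask: NULL or an array of
# inverted-dropout multipliers over the concat layer.
tznet_forward <- function(model, x, cache = FALSE, drop_mask = NULL) {
  p <- model$params
  a <- model$arch
  d <- dim(x); L <- d[2]; B <- d[3]
  cc <- list()
  branches <- list()
  for (k in a$kernels) {
    nm <- paste0("b", k)
    r <- conv_fwd(x, p[[paste0(nm, "_rW")]], p[[paste0(nm, "_rb")]], 1L)
    ra <- selu(r$y)
    cv <- conv_fwd(ra, p[[paste0(nm, "_cW")]], p[[paste0(nm, "_cb")]], k)
    ca <- selu(cv$y)
    branches[[nm]] <- ca
    if (cache) cc[[nm]] <- list(r = r, ra = ra, cv = cv)
  }
  mp <- maxpool3_fwd(x)
  pv <- conv_fwd(mp$y, p$pool_W, p$pool_b, 1L)
  pa <- selu(pv$y)
  branches$pool <- pa
  if (cache) cc$pool <- list(mp = mp, pv = pv)
  z <- array(0, c(a$concat, L, B))
  at <- 0L
  for (br in branches) {
    nb <- dim(br)[1]
    z[at + seq_len(nb), , ] <- br
    at <- at + nb
  }
  if (!is.null(drop_mask)) z <- z * drop_mask
  h1 <- conv_fwd(z, p$h1_W, p$h1_b, 1L)
  h1a <- selu(h1$y)
  h2 <- conv_fwd(h1a, p$h2_W, p$h2_b, 1L)
  h2a <- selu(h2$y)
  o <- conv_fwd(h2a, p$out_W, p$out_b, a$out_kernel)
  prob <- 1 / (1 + exp(-o$y))
  dim(prob) <- c(L, B)
  if (!cache) return(list(prob = prob))
  cc$x <- x; cc$z <- z; cc$h1 <- h1; cc$h1a <- h1a
  cc$h2 <- h2; cc$h2a <- h2a; cc$o <- o; cc$prob <- prob
  cc$drop_mask <- drop_mask
  list(prob = prob, cache = cc)
}

# backward pass from d(loss)/d(prob); returns gradient list matching params
tznet_backward <- function(model, cc, dprob) {
  p <- model$params
  a <- model$arch
  L <- dim(cc$x)[2]; B <- dim(cc$x)[3]
  g <- list()
  dlogit <- dprob * cc$prob * (1 - cc$prob)
  dim(dlogit) <- c(1, L, B)
  bw <- conv_bwd(dlogit, p$out_W, cc$o$xcol, a$out_kernel, 8L, L, B)
  g$out_W <- bw$dW; g$out_b <- bw$db
  dh2 <- bw$dx * selu_grad(cc$h2$y)
  bw <- conv_bwd(dh2, p$h2_W, cc$h2$xcol, 1L, 16L, L, B)
  g$h2_W <- bw$dW; g$h2_b <- bw$db
  dh1 <- bw$dx * selu_grad(cc$h1$y)
  bw <- conv_bwd(dh1, p$h1_W, cc$h1$xcol, 1L, a$concat, L, B)
  g$h1_W <- bw$dW; g$h1_b <- bw$db
  dz <- bw$dx
  if (!is.null(cc$drop_mask)) dz <- dz * cc$drop_mask
  dx <- array(0, dim(cc$x))
  at <- 0L
  for (k in a$kernels) {
    nm <- paste0("b", k)
    dca <- dz[at + seq_len(a$branch), , , drop = FALSE]
    at <- at + a$branch
    dcv <- dca * selu_grad(cc[[nm]]$cv$y)
    bw <- conv_bwd(dcv, p[[paste0(nm, "_cW")]], cc[[nm]]$cv$xcol, k,
                   a$reduce, L, B)
    g[[paste0(nm, "_cW")]] <- bw$dW; g[[paste0(nm, "_cb")]] <- bw$db
    dra <- bw$dx * selu_grad(cc[[nm]]$r$y)
    bw <- conv_bwd(dra, p[[paste0(nm, "_rW")]], cc[[nm]]$r$xcol, 1L,
                   a$in_channels, L, B)
    g[[paste0(nm, "_rW")]] <- bw$dW; g[[paste0(nm, "_rb")]] <- bw$db
    dx <- dx + bw$dx
  }
  dpa <- dz[at + seq_len(a$branch), , , drop = FALSE]
  dpv <- dpa * selu_grad(cc$pool$pv$y)
  bw <- conv_bwd(dpv, p$pool_W, cc$pool$pv$xcol, 1L, a$in_channels, L, B)
  g$pool_W <- bw$dW; g$pool_b <- bw$db
  dx <- dx + maxpool3_bwd(bw$dx, cc$pool$mp$win)
  g
}

#' Dice loss of per-bin probabilities against binary labels
#'
#' \code{1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)} per sample,
#' averaged over the batch; a perfect hard prediction scores 0 and a fully
#' wrong one scores 1. Bins outside \code{mask} are ignored.
#'
#' @param prob L x B probability matrix (or vector).
#' @param y Matching binary labels.
#' @param mask Integer indices of the bins that count (default all).
#' @param eps Smoothing constant.
#' @return List with \code{loss} and the gradient \code{dprob}.
#' @export
dice_loss <- function(prob, y, mask = NULL, eps = 1e-6) {
  prob <- as.matrix(prob); y <- as.matrix(y)
  L <- nrow(prob); B <- ncol(prob)
  if (is.null(mask)) mask <- seq_len(L)
  loss <- 0
  dprob <- matrix(0, L, B)
  for (b in seq_len(B)) {
    pm <- prob[mask, b]; ym <- y[mask, b]
    I <- sum(pm * ym); S <- sum(pm) + sum(ym)
    loss <- loss + 1 - (2 * I + eps) / (S + eps)
    dprob[mask, b] <- -(2 * ym * (S + eps) - (2 * I + eps)) / (S + eps)^2 / B
  }
  list(loss = loss / B, dprob = dprob)
}

# one Adam step; st holds m/v moments and the step counter
adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    if (is.null(st$m[[nm]])) {
      st$m[[nm]] <- gmat * 0
      st$v[[nm]] <- gmat * 0
    }
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gmat
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, st = st)
}
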