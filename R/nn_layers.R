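# Native implementation of the small network blocks the encoders are built
# from (1-D convolution, batch normalisation, LSTM, dense), each with an
# explicit backward pass. Shapes follow a batch-first convention; sequence
# batches are N x L x 4 arrays. Everything is plain double-precision matrix
# algebra so gradients can be finite-difference checked.

sigmoid <- function(x) 1 / (1 + exp(-x))

init_mat <- function(nr, nc, fan_in) {
  a <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

init_vec <- function(n, fan_in) {
  a <- 1 / sqrt(fan_in)
  stats::runif(n, -a, a)
}

# ---- encoder: conv(4 -> F, kernel 2, pad 2) -> BN -> ReLU -> LSTM(H) ->
#      final hidden -> BN -> dense(H -> d) ----------------------------------

init_encoder <- function(cfg) {
  Fl <- cfg$conv_filters; H <- cfg$lstm_hidden; d <- cfg$repr_dim
  k_in <- 4L * cfg$conv_kernel
  lstm_b <- init_vec(4L * H, H)
  # forget-gate bias starts at 1 so the cell state can carry motif evidence
  # across the window at initialisation instead of decaying geometrically
  lstm_b[(H + 1L):(2L * H)] <- 1
  list(
    conv = list(W = init_mat(k_in, Fl, k_in), b = init_vec(Fl, k_in)),
    bn1 = list(gamma = rep(1, Fl), beta = rep(0, Fl),
               running_mean = rep(0, Fl), running_var = rep(1, Fl)),
    lstm = list(Wx = init_mat(Fl, 4L * H, H), Wh = init_mat(H, 4L * H, H),
                b = lstm_b),
    bn2 = list(gamma = rep(1, H), beta = rep(0, H),
               running_mean = rep(0, H), running_var = rep(1, H)),
    fc = list(W = init_mat(H, d, H), b = init_vec(d, H))
  )
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Batch normalisation over columns of a 2-D matrix. In training mode batch
# statistics are used (and running statistics updated in the caller via the
# returned `new_running`); in eval mode the stored running statistics are
# frozen, the standard train/eval contract.
bn_forward <- function(x, p, training) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    new_running <- list(
      mean = (1 - BN_MOMENTUM) * p$running_mean + BN_MOMENTUM * mu,
      var = (1 - BN_MOMENTUM) * p$running_var + BN_MOMENTUM * v
    )
  } else {
    mu <- p$running_mean
    v <- p$running_var
    new_running <- NULL
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(x, 2, mu), 2, invstd, `*`)
  out <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(out = out, cache = list(xhat = xhat, invstd = invstd, training = training),
       new_running = new_running)
}

bn_backward <- function(dout, p, cache) {
  ggamma <- colSums(dout * cache$xhat)
  gbeta <- colSums(dout)
  scale <- p$gamma * cache$invstd
  if (cache$training) {
    n <- nrow(dout)
    m1 <- colMeans(dout)
    m2 <- colMeans(dout * cache$xhat)
    dx <- sweep(sweep(dout, 2, m1) - sweep(cache$xhat, 2, m2, `*`),
                2, scale, `*`)
  } else {
    dx <- sweep(dout, 2, scale, `*`)
  }
  list(dx = dx, grads = list(gamma = ggamma, beta = gbeta))
}

# Build the (B*T) x (4*kernel) patch matrix for a 1-D convolution with
# symmetric zero padding. Row (t-1)*B + b holds the kernel-window of sample b
# at output position t (t-major layout so per-step LSTM slices are cheap).
conv_patches <- function(X, kernel, pad) {
  B <- dim(X)[1]; L <- dim(X)[2]
  Lp <- L + 2L * pad
  T_ <- Lp - kernel + 1L
  Xp <- array(0, dim = c(B, Lp, 4L))
  Xp[, (pad + 1L):(pad + L), ] <- X
  cols <- vector("list", kernel)
  for (k in seq_len(kernel)) {
    slice <- Xp[, k:(k + T_ - 1L), , drop = FALSE]  # B x T x 4
    dim(slice) <- c(B * T_, 4L)
    cols[[k]] <- slice
  }
  list(P = do.call(cbind, cols), B = B, T_ = T_, L = L, pad = pad)
}

# Scatter patch gradients back onto the (unpadded) input array.
conv_patches_backward <- function(dP, B, T_, L, pad, kernel) {
  Lp <- L + 2L * pad
  dXp <- array(0, dim = c(B, Lp, 4L))
  for (k in seq_len(kernel)) {
    dM <- dP[, (4L * (k - 1L) + 1L):(4L * k), drop = FALSE]
    dim(dM) <- c(B, T_, 4L)
    dXp[, k:(k + T_ - 1L), ] <- dXp[, k:(k + T_ - 1L), , drop = FALSE] + dM
  }
  dXp[, (pad + 1L):(pad + L), , drop = FALSE]
}

lstm_forward <- function(A, p, B, T_) {
  out <- lstm_forward_cpp(A, p$Wx, p$Wh, p$b, B, T_)
  list(h = out$h, cache = out)
}

lstm_backward <- function(dh_final, A, p, cache, B, T_) {
  out <- lstm_backward_cpp(dh_final, A, p$Wx, p$Wh, cache$I, cache$F,
                           cache$G, cache$O, cache$TC, cache$Hprev,
                           cache$Cprev, B, T_)
  list(dA = out$dA,
       grads = list(Wx = out$Wx, Wh = out$Wh, b = as.numeric(out$b)))
}

encoder_forward <- function(params, X, cfg, training = TRUE) {
  pc <- conv_patches(X, cfg$conv_kernel, cfg$conv_padding)
  Z <- pc$P %*% params$conv$W +
    matrix(params$conv$b, nrow(pc$P), length(params$conv$b), byrow = TRUE)
  bn1 <- bn_forward(Z, params$bn1, training)
  A <- pmax(bn1$out, 0)
  ls <- lstm_forward(A, params$lstm, pc$B, pc$T_)
  bn2 <- bn_forward(ls$h, params$bn2, training)
  h <- bn2$out %*% params$fc$W +
    matrix(params$fc$b, pc$B, length(params$fc$b), byrow = TRUE)
  drop_mask <- NULL
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    drop_mask <- matrix(stats::runif(length(h)) < keep, nrow(h), ncol(h)) / keep
    h <- h * drop_mask
  }
  list(h = h,
       cache = list(pc = pc, bn1 = bn1, A = A, relu_mask = bn1$out > 0,
                    lstm = ls, bn2 = bn2, bn2_in = ls$h,
                    drop_mask = drop_mask),
       new_running = list(bn1 = bn1$new_running, bn2 = bn2$new_running))
}

encoder_backward <- function(params, cache, dh, cfg) {
  B <- cache$pc$B
  if (!is.null(cache$drop_mask)) dh <- dh * cache$drop_mask
  gfc <- list(W = crossprod(cache$bn2$out, dh), b = colSums(dh))
  dbn2out <- dh %*% t(params$fc$W)
  bn2b <- bn_backward(dbn2out, params$bn2, cache$bn2$cache)
  lb <- lstm_backward(bn2b$dx, cache$A, params$lstm, cache$lstm$cache,
                      B, cache$pc$T_)
  dA <- lb$dA
  dA[!cache$relu_mask] <- 0
  bn1b <- bn_backward(dA, params$bn1, cache$bn1$cache)
  gconv <- list(W = crossprod(cache$pc$P, bn1b$dx), b = colSums(bn1b$dx))
  dP <- bn1b$dx %*% t(params$conv$W)
  dX <- conv_patches_backward(dP, B, cache$pc$T_, cache$pc$L,
                              cfg$conv_padding, cfg$conv_kernel)
  list(dX = dX,
       grads = list(conv = gconv, bn1 = bn1b$grads, lstm = lb$grads,
                    bn2 = bn2b$grads, fc = gfc))
}

# ---- generic nested-parameter helpers -------------------------------------

par_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- par_map2(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}

par_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- par_map(a[[nm]], f)
    out
  } else {
    f(a)
  }
}

par_reduce <- function(a, f, init = 0) {
  acc <- init
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else acc <<- f(acc, x)
    invisible(NULL)
  }
  walk(a)
  acc
}

zero_like <- function(a) par_map(a, function(x) x * 0)

global_grad_norm <- function(grads) {
  sqrt(par_reduce(grads, function(acc, x) acc + sum(x^2)))
}
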