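# The composite training objective:
#   L = alpha * L_recon + beta * L_difference + gamma * L_similarity
#       + L_source + delta * L_target
# Each term is implemented as a pure function returning the scalar, with an
# internal companion returning analytic gradients (finite-difference checked
# in the test suite).

#' Loss-term weights of the composite objective
#'
#' Defaults are the tuned weights used throughout: `alpha` scales the
#' reconstruction term, `beta` the shared/private orthogonality term, `gamma`
#' the cross-domain similarity term; the source classification term has unit
#' weight and `delta` scales the target classification term (only active in
#' dual-classifier mode).
#'
#' @param alpha,beta,gamma,delta Non-negative weights.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 0.02, beta = 0.075, gamma = 0.25, delta = 1.0) {
  w <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(unlist(w) < 0)) abort("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

#' Reconstruction loss between input windows and decoder output
#'
#' `"simse"` (the default) is the scale-invariant mean squared error: per
#' sample, the mean squared elementwise error minus the squared mean error,
#' which ignores a constant offset of the reconstruction. `"mse"` is the
#' plain mean squared error. Either is averaged over the batch.
#'
#' @param x Input batch: `N x L x 4` array (or matrix of flattened windows).
#' @param x_hat Reconstruction with the same shape.
#' @param variant `"simse"` or `"mse"`.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(x, x_hat, variant = c("simse", "mse")) {
  recon_loss_grad(x, x_hat, match.arg(variant))$loss
}

recon_loss_grad <- function(x, x_hat, variant) {
  x <- as_flat_matrix(x); x_hat <- as_flat_matrix(x_hat)
  if (!all(dim(x) == dim(x_hat))) abort("x and x_hat shapes differ")
  B <- nrow(x); k <- ncol(x)
  e <- x_hat - x
  if (variant == "mse") {
    loss <- mean(e^2)
    dxhat <- 2 * e / (B * k)
  } else {
    row_means <- rowMeans(e)
    loss <- mean(rowMeans(e^2) - row_means^2)
    dxhat <- (2 / (B * k)) * (e - row_means)
  }
  list(loss = loss, dxhat = dxhat)
}

as_flat_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(x, nrow = d[1], ncol = prod(d[-1]))
}

#' Soft subspace orthogonality (difference) loss
#'
#' Pushes a domain's shared and private representations apart: both matrices
#' are column-mean-centred, rows are L2-normalised (zero rows stay zero), and
#' the loss is the squared Frobenius norm of the cross-product
#' `t(H_c) %*% H_p`. Zero when every shared row is orthogonal to every
#' private row.
#'
#' @param h_shared,h_private `batch x d` representation matrices.
#' @param center Column-mean-centre before normalising (default `TRUE`).
#' @return Non-negative scalar.
#' @export
difference_loss <- function(h_shared, h_private, center = TRUE) {
  difference_loss_grad(h_shared, h_private, center)$loss
}

difference_loss_grad <- function(h_shared, h_private, center = TRUE) {
  if (!all(dim(h_shared) == dim(h_private))) {
    abort("h_shared and h_private must have identical shape")
  }
  prep <- function(H) {
    H1 <- if (center && nrow(H) > 1) sweep(H, 2, colMeans(H)) else H
    norms <- sqrt(rowSums(H1^2))
    safe <- ifelse(norms > 0, norms, 1)
    list(Hn = H1 / safe, norms = norms, safe = safe)
  }
  pc <- prep(h_shared); pp <- prep(h_private)
  A <- crossprod(pc$Hn, pp$Hn)
  loss <- sum(A^2)
  unprep <- function(G, p) {
    # back through row normalisation then centring
    dot <- rowSums(G * p$Hn)
    dH1 <- (G - p$Hn * dot) / p$safe
    dH1[p$norms == 0, ] <- 0
    if (center && nrow(dH1) > 1) sweep(dH1, 2, colMeans(dH1)) else dH1
  }
  list(loss = loss,
       d_shared = unprep(2 * pp$Hn %*% t(A), pc),
       d_private = unprep(2 * pc$Hn %*% A, pp))
}

#' Cross-domain similarity loss on shared representations
#'
#' The default `"mmd"` variant is the unbiased squared maximum mean
#' discrepancy under a fixed mixture of RBF kernels with bandwidths
#' `{1, 2, 4, 8, 16}` times a base scale (median pairwise squared distance of
#' the pooled batch; during training the base is frozen at the first batch).
#' Negative values of the unbiased estimator are clamped to zero. The
#' `"dann"` variant is adversarial: the cross-entropy of a small domain
#' classifier whose gradient is *negated* on its way into the encoder
#' (gradient reversal), so the encoder learns domain-indistinguishable
#' representations.
#'
#' @param h_source,h_target `batch x d` shared-representation matrices
#'   (batches of at least 2 each for `"mmd"`).
#' @param variant `"mmd"` or `"dann"`.
#' @param bandwidth_base Optional frozen base scale for the RBF mixture;
#'   computed from the pooled batch when `NULL`.
#' @param domain_classifier For `"dann"`: list with `W` (`d x 2`) and `b`.
#' @return Non-negative scalar.
#' @export
similarity_loss <- function(h_source, h_target, variant = c("mmd", "dann"),
                            bandwidth_base = NULL, domain_classifier = NULL) {
  variant <- match.arg(variant)
  if (variant == "mmd") {
    mmd_loss_grad(h_source, h_target, bandwidth_base)$loss
  } else {
    if (is.null(domain_classifier)) abort("'dann' variant needs a domain_classifier")
    dann_loss_grad(h_source, h_target, domain_classifier)$loss
  }
}

MMD_BANDWIDTH_MULTIPLIERS <- c(1, 2, 4, 8, 16)

cross_sqdist <- function(X, Y) {
  sx <- rowSums(X^2); sy <- rowSums(Y^2)
  d2 <- outer(sx, sy, `+`) - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

mmd_bandwidth_base <- function(h_source, h_target) {
  pooled <- rbind(h_source, h_target)
  d2 <- cross_sqdist(pooled, pooled)
  base <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(base) || base <= 0) base <- 1
  base
}

mmd_loss_grad <- function(h_source, h_target, bandwidth_base = NULL) {
  m <- nrow(h_source); n <- nrow(h_target)
  if (m < 2 || n < 2) {
    abort("mmd needs at least 2 samples per domain; use a larger batch")
  }
  if (ncol(h_source) != ncol(h_target)) abort("representation dims differ")
  base <- bandwidth_base %||% mmd_bandwidth_base(h_source, h_target)
  bws <- MMD_BANDWIDTH_MULTIPLIERS * base
  kern <- function(D2) {
    K <- 0; E <- 0
    for (bw in bws) {
      ek <- exp(-D2 / bw)
      K <- K + ek
      E <- E + ek / bw
    }
    list(K = K / length(bws), E = E / length(bws))
  }
  xx <- kern(cross_sqdist(h_source, h_source))
  yy <- kern(cross_sqdist(h_target, h_target))
  xy <- kern(cross_sqdist(h_source, h_target))
  loss_raw <- (sum(xx$K) - sum(diag(xx$K))) / (m * (m - 1)) +
    (sum(yy$K) - sum(diag(yy$K))) / (n * (n - 1)) -
    2 * mean(xy$K)
  if (!is.finite(loss_raw)) {
    # overflowed representations; report the non-finite term and let the
    # training loop abort with its diagnostic
    return(list(loss = NaN, d_source = h_source * 0, d_target = h_target * 0,
                bandwidth_base = base))
  }
  if (loss_raw <= 0) {
    zs <- h_source * 0; zt <- h_target * 0
    return(list(loss = 0, d_source = zs, d_target = zt, bandwidth_base = base))
  }
  Exx <- xx$E; diag(Exx) <- 0
  Eyy <- yy$E; diag(Eyy) <- 0
  ds <- -(4 / (m * (m - 1))) * (h_source * rowSums(Exx) - Exx %*% h_source) +
    (4 / (m * n)) * (h_source * rowSums(xy$E) - xy$E %*% h_target)
  dt <- -(4 / (n * (n - 1))) * (h_target * rowSums(Eyy) - Eyy %*% h_target) +
    (4 / (m * n)) * (h_target * colSums(xy$E) - t(xy$E) %*% h_source)
  list(loss = loss_raw, d_source = ds, d_target = dt, bandwidth_base = base)
}

# Adversarial similarity: domain-classifier cross-entropy; the returned
# representation gradients are negated (gradient reversal) while the
# classifier's own parameter gradients are standard.
dann_loss_grad <- function(h_source, h_target, clf) {
  H <- rbind(h_source, h_target)
  y <- c(rep(0L, nrow(h_source)), rep(1L, nrow(h_target)))
  logits <- H %*% clf$W + matrix(clf$b, nrow(H), 2, byrow = TRUE)
  nl <- nll_loss_grad(logits, y)
  dH <- nl$dlogits %*% t(clf$W)
  list(loss = nl$loss,
       d_source = -dH[seq_len(nrow(h_source)), , drop = FALSE],
       d_target = -dH[nrow(h_source) + seq_len(nrow(h_target)), , drop = FALSE],
       d_clf = list(W = crossprod(H, nl$dlogits), b = colSums(nl$dlogits)))
}

#' Classification loss (mean negative log-likelihood)
#'
#' @param logits `batch x 2` matrix of unnormalised class scores
#'   (column 1 = negative class, column 2 = positive class).
#' @param labels Integer vector of 0/1 labels.
#' @return Non-negative scalar.
#' @export
classification_loss <- function(logits, labels) {
  nll_loss_grad(logits, labels)$loss
}

nll_loss_grad <- function(logits, labels) {
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  if (nrow(logits) != length(labels)) abort("logits/labels length mismatch")
  B <- nrow(logits)
  mx <- pmax(logits[, 1], logits[, 2])
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  picked <- p[cbind(seq_len(B), labels + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  onehot <- matrix(0, B, 2)
  onehot[cbind(seq_len(B), labels + 1L)] <- 1
  list(loss = loss, dlogits = (p - onehot) / B, prob = p)
}

#' Combine loss terms into the weighted training objective
#'
#' `total = alpha * recon + beta * difference + gamma * similarity +
#' source_cls + delta * target_cls`; in single-classifier mode
#' (`"source_only_classifier"`) the target term is absent and contributes 0.
#'
#' @param parts List with `recon`, `difference`, `similarity`, `source_cls`
#'   and (dual mode) `target_cls` scalars.
#' @param weights A [loss_weights()].
#' @param mode `"source_only_classifier"` or `"dual_classifier"`.
#' @return A `loss_breakdown` list: the parts plus `total`.
#' @export
total_loss <- function(parts, weights = loss_weights(),
                       mode = c("dual_classifier", "source_only_classifier")) {
  mode <- match.arg(mode)
  vals <- unlist(parts[c("recon", "difference", "similarity", "source_cls")])
  if (any(!is.finite(vals))) abort("loss parts must be finite")
  target_cls <- if (mode == "dual_classifier") {
    if (is.null(parts$target_cls)) abort("dual mode needs a target_cls part")
    parts$target_cls
  } else {
    NULL
  }
  total <- weights$alpha * parts$recon + weights$beta * parts$difference +
    weights$gamma * parts$similarity + parts$source_cls +
    if (is.null(target_cls)) 0 else weights$delta * target_cls
  structure(list(recon = parts$recon, difference = parts$difference,
                 similarity = parts$similarity, source_cls = parts$source_cls,
                 target_cls = target_cls, total = total),
            class = "loss_breakdown")
}
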