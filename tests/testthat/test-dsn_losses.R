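test_that("reconstruction loss: perfect reconstruction is zero; toy case hand-checked", {
  x <- random_onehot_batch(3, L = 9, seed = 1)
  expect_equal(reconstruction_loss(x, x, "mse"), 0)
  expect_equal(reconstruction_loss(x, x, "simse"), 0)

  # 1 x 2 toy: x all ones, x_hat zeros -> mse 1; simse 1 - 1 = 0 (offset-only
  # error is invisible to the scale-invariant form)
  x1 <- matrix(1, 1, 2)
  expect_equal(reconstruction_loss(x1, x1 * 0, "mse"), 1)
  expect_equal(reconstruction_loss(x1, x1 * 0, "simse"), 0)

  set.seed(2)
  xh <- x + array(rnorm(length(x)), dim = dim(x))
  expect_gte(reconstruction_loss(x, xh, "mse"), 0)
  expect_gte(reconstruction_loss(x, xh, "simse"), 0)
  expect_error(reconstruction_loss(x, matrix(0, 2, 2)), "shapes differ")
})

test_that("difference loss is zero on orthogonal inputs and one on the unit-norm identity case", {
  # orthogonality is over the batch dimension: every shared feature column
  # is orthogonal (as a batch vector) to every private feature column
  hc <- matrix(c(1, 1, 1, -1), 2) / sqrt(2)   # columns span (1,1)/(1,-1)
  hp <- matrix(c(1, -1, -1, 1), 2) / sqrt(2)  # columns both along (1,-1)
  hc[, 2] <- c(1, 1) / sqrt(2)
  expect_equal(difference_loss(hc, hp, center = FALSE), 0)

  # single unit-norm sample against itself: ||h h^T||_F^2 = ||h||^4 = 1
  h <- matrix(c(0.6, 0.8), 1)
  expect_equal(difference_loss(h, h, center = FALSE), 1)

  expect_error(difference_loss(matrix(0, 2, 3), matrix(0, 2, 4)), "shape")
})

test_that("difference loss is invariant to joint row permutation", {
  set.seed(4)
  hc <- matrix(rnorm(40), 8); hp <- matrix(rnorm(40), 8)
  perm <- sample(8)
  expect_equal(difference_loss(hc, hp),
               difference_loss(hc[perm, ], hp[perm, ]))
})

test_that("mmd is zero on identical samples, symmetric, large across separated clouds", {
  set.seed(5)
  h <- matrix(rnorm(64 * 2), 64)
  expect_equal(similarity_loss(h, h), 0)

  a <- matrix(rnorm(64 * 2, mean = -5), 64)
  b <- matrix(rnorm(64 * 2, mean = 5), 64)
  expect_gt(similarity_loss(a, b), 0.5)
  expect_equal(similarity_loss(a, b), similarity_loss(b, a))
  expect_error(similarity_loss(h[1, , drop = FALSE], h), "larger batch|at least 2")
})

test_that("classification loss: confident-correct near 0, uniform exactly ln 2", {
  logits_good <- rbind(c(-20, 20), c(20, -20))
  expect_lt(classification_loss(logits_good, c(1, 0)), 1e-6)

  logits_unif <- matrix(0, 4, 2)
  expect_equal(classification_loss(logits_unif, c(0, 1, 0, 1)), log(2))

  # raising the correct logit lowers the loss
  l1 <- rbind(c(0.3, 0.1)); l2 <- rbind(c(0.4, 0.1))
  expect_lt(classification_loss(l2, 0), classification_loss(l1, 0))
  expect_error(classification_loss(logits_unif, c(0, 1, 2, 1)), "0/1")
})

test_that("total loss weights the parts per the published coefficients", {
  parts <- list(recon = 1, difference = 1, similarity = 1,
                source_cls = 1, target_cls = 1)
  lb <- total_loss(parts, loss_weights(), mode = "dual_classifier")
  expect_equal(lb$total, 0.02 + 0.075 + 0.25 + 1 + 1)

  lb1 <- total_loss(parts, loss_weights(), mode = "source_only_classifier")
  expect_equal(lb1$total, lb$total - 1)
  expect_null(lb1$target_cls)

  zero <- total_loss(list(recon = 3, difference = 2, similarity = 1,
                          source_cls = 0),
                     loss_weights(0, 0, 0, 0), mode = "source_only_classifier")
  expect_equal(zero$total, 0)
  expect_error(total_loss(list(recon = NaN, difference = 1, similarity = 1,
                               source_cls = 1), loss_weights()),
               "finite")
})

test_that("analytic loss gradients match finite differences", {
  set.seed(6)
  eps <- 1e-6
  fd_check <- function(f_loss, X, dX, label) {
    for (probe in 1:4) {
      i <- sample(length(X), 1)
      Xp <- X; Xp[i] <- Xp[i] + eps
      Xm <- X; Xm[i] <- Xm[i] - eps
      fd <- (f_loss(Xp) - f_loss(Xm)) / (2 * eps)
      expect_equal(dX[i], fd, tolerance = 1e-5, label = label)
    }
  }
  hc <- matrix(rnorm(24), 6); hp <- matrix(rnorm(24), 6)
  g <- rnadsn:::difference_loss_grad(hc, hp)
  fd_check(function(h) difference_loss(h, hp), hc, g$d_shared, "difference/shared")
  fd_check(function(h) difference_loss(hc, h), hp, g$d_private, "difference/private")

  a <- matrix(rnorm(20, 1), 5); b <- matrix(rnorm(20), 5)
  gm <- rnadsn:::mmd_loss_grad(a, b, bandwidth_base = 2)
  fd_check(function(h) similarity_loss(h, b, bandwidth_base = 2), a,
           gm$d_source, "mmd/source")
  fd_check(function(h) similarity_loss(a, h, bandwidth_base = 2), b,
           gm$d_target, "mmd/target")

  x <- matrix(rnorm(12), 3); xh <- matrix(rnorm(12), 3)
  gr <- rnadsn:::recon_loss_grad(x, xh, "simse")
  fd_check(function(h) reconstruction_loss(x, h, "simse"), xh, gr$dxhat,
           "simse")
})

test_that("dann variant reverses the gradient into the encoder", {
  set.seed(7)
  clf <- list(W = matrix(rnorm(8), 4), b = rnorm(2))
  hs <- matrix(rnorm(20), 5); ht <- matrix(rnorm(20), 5)
  g <- rnadsn:::dann_loss_grad(hs, ht, clf)
  # representation gradient is the negation of the classifier's input grad
  nl <- rnadsn:::nll_loss_grad(rbind(hs, ht) %*% clf$W +
                                 matrix(clf$b, 10, 2, byrow = TRUE),
                               c(rep(0, 5), rep(1, 5)))
  dH <- nl$dlogits %*% t(clf$W)
  expect_equal(g$d_source, -dH[1:5, ])
  expect_equal(g$d_target, -dH[6:10, ])
  expect_equal(similarity_loss(hs, ht, "dann", domain_classifier = clf),
               g$loss)
})
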