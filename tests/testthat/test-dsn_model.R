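test_that("initialisation is seed-deterministic and mode-aware", {
  cfg <- tiny_model_config()
  m1 <- init_model(cfg, mode = "dual_classifier", seed = 5)
  m2 <- init_model(cfg, mode = "dual_classifier", seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- init_model(cfg, mode = "dual_classifier", seed = 6)
  expect_false(identical(m1$params$enc_shared$conv$W,
                         m3$params$enc_shared$conv$W))

  mode1 <- init_model(cfg, mode = "source_only_classifier", seed = 5)
  expect_null(mode1$params$clf_target)
  # shared and private encoders share architecture but never parameters
  expect_false(identical(m1$params$enc_shared$lstm$Wx,
                         m1$params$enc_priv_source$lstm$Wx))
})

test_that("forward pass produces correctly shaped representations and a valid breakdown", {
  cfg <- tiny_model_config()
  model <- init_model(cfg, mode = "dual_classifier", seed = 2)
  xs <- random_onehot_batch(3, L = 9, seed = 1)
  xt <- random_onehot_batch(3, L = 9, seed = 2)
  fwd <- dsn_forward(model, xs, xt, c(0, 1, 0), c(1, 0, 1), training = TRUE)
  expect_equal(dim(fwd$h_c_s), c(3, 5))
  expect_equal(dim(fwd$h_p_t), c(3, 5))
  expect_equal(dim(fwd$xhat_s), c(3, 36))
  lb <- fwd$losses
  w <- model$weights
  expect_equal(lb$total,
               w$alpha * lb$recon + w$beta * lb$difference +
                 w$gamma * lb$similarity + lb$source_cls +
                 w$delta * lb$target_cls)
  expect_true(all(c(lb$recon, lb$difference, lb$similarity,
                    lb$source_cls, lb$target_cls) >= 0))
})

test_that("analytic parameter gradients match finite differences everywhere", {
  cfg <- tiny_model_config()
  model <- init_model(cfg, mode = "dual_classifier", seed = 3)
  # freeze the MMD bandwidth so the objective is smooth in the parameters
  model$mmd_bandwidth_base <- 1
  set.seed(42)
  xs <- random_onehot_batch(5, L = 9, seed = 11)
  xt <- random_onehot_batch(5, L = 9, seed = 12)
  ys <- c(0, 1, 1, 0, 1); yt <- c(1, 0, 0, 1, 0)
  loss_of <- function(m) {
    rnadsn:::dsn_forward_full(m, xs, xt, ys, yt, training = TRUE)$losses$total
  }
  fwd <- rnadsn:::dsn_forward_full(model, xs, xt, ys, yt, training = TRUE)
  grads <- rnadsn:::dsn_backward(model, fwd)
  paths <- list(c("enc_shared", "conv", "W"), c("enc_shared", "bn1", "gamma"),
                c("enc_shared", "lstm", "Wx"), c("enc_shared", "lstm", "Wh"),
                c("enc_shared", "lstm", "b"), c("enc_shared", "bn2", "beta"),
                c("enc_shared", "fc", "W"),
                c("enc_priv_source", "conv", "W"),
                c("enc_priv_target", "lstm", "Wx"),
                c("dec_source", "W"), c("dec_target", "b"),
                c("clf_source", "W"), c("clf_target", "b"))
  eps <- 1e-5
  for (pth in paths) {
    leaf <- Reduce(`[[`, pth, model$params)
    idx <- sample(length(leaf), 1)
    bump <- function(delta) {
      m <- model
      expr <- paste0("m$params$", paste(pth, collapse = "$"), "[idx] <- ",
                     "leaf[idx] + delta")
      eval(parse(text = expr))
      m
    }
    fd <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
    an <- Reduce(`[[`, pth, grads)[idx]
    expect_equal(an, fd, tolerance = 1e-4,
                 label = paste(pth, collapse = "$"))
  }
})

test_that("gradient routing honours the architecture contract", {
  cfg <- tiny_model_config()
  xs <- random_onehot_batch(6, L = 9, seed = 21)
  # a compositionally different target batch keeps the MMD term strictly
  # positive, so the similarity gradient is non-trivial
  xt <- array(0, dim = c(6, 9, 4))
  for (i in 1:6) xt[i, , ] <- one_hot_encode(strrep(c("A", "G")[1 + i %% 2], 9))
  ys <- rep(0:1, 3); yt <- rep(1:0, 3)
  grads_with <- function(alpha, beta, gamma) {
    model <- init_model(cfg, mode = "dual_classifier", seed = 4,
                        weights = loss_weights(alpha, beta, gamma, 1))
    model$mmd_bandwidth_base <- 0.5
    fwd <- rnadsn:::dsn_forward_full(model, xs, xt, ys, yt, training = TRUE)
    expect_gt(fwd$losses$similarity, 0)
    rnadsn:::dsn_backward(model, fwd)
  }
  norm_of <- function(g) sqrt(rnadsn:::par_reduce(g, function(a, x) a + sum(x^2)))

  # classification alone reaches only the shared encoder and classifiers
  g_cls <- grads_with(0, 0, 0)
  expect_equal(norm_of(g_cls$enc_priv_source), 0)
  expect_equal(norm_of(g_cls$enc_priv_target), 0)
  expect_equal(norm_of(g_cls$dec_source), 0)
  expect_gt(norm_of(g_cls$enc_shared), 0)
  expect_gt(norm_of(g_cls$clf_source), 0)

  # adding the difference term reaches private AND shared encoders
  g_diff <- grads_with(0, 1, 0)
  expect_gt(norm_of(g_diff$enc_priv_source), 0)
  expect_gt(norm_of(g_diff$enc_priv_target), 0)

  # the similarity term's extra gradient touches only the shared encoder
  g_sim <- grads_with(0, 0, 1)
  delta_priv <- rnadsn:::par_map2(g_sim$enc_priv_source,
                                  g_cls$enc_priv_source, `-`)
  expect_equal(norm_of(delta_priv), 0)
  delta_shared <- rnadsn:::par_map2(g_sim$enc_shared, g_cls$enc_shared, `-`)
  expect_gt(norm_of(delta_shared), 0)

  # reconstruction reaches decoders and both encoder families
  g_rec <- grads_with(1, 0, 0)
  expect_gt(norm_of(g_rec$dec_source), 0)
  expect_gt(norm_of(g_rec$enc_priv_source), 0)
})

test_that("checkpoints round-trip with config sidecar", {
  model <- init_model(tiny_model_config(), mode = "dual_classifier", seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  rt <- load_checkpoint(path)
  expect_identical(rt$params, model$params)
  sidecar <- sub("\\.rds$", ".json", path)
  meta <- jsonlite::read_json(sidecar)
  expect_equal(meta$mode, "dual_classifier")
  expect_equal(meta$weights$beta, 0.075)
})

test_that("predict returns positive-class probabilities with provenance", {
  cfg <- synth_preset("easy", seed = 13, n_source_pos = 8, n_source_neg = 8,
                      n_target_pos = 8, n_target_neg = 8)
  pair <- generate_domain_pair(cfg)
  model <- init_model(model_config(), mode = "source_only_classifier",
                      seed = 13)
  out <- predict(model, pair$target, classifier = "source")
  expect_equal(nrow(out), 16)
  expect_true(all(out$score >= 0 & out$score <= 1))
  expect_equal(out$label, pair$target$labels)
  expect_error(predict(model, pair$target, classifier = "target"),
               "no clf_target")
})
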