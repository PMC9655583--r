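#' Network architecture configuration
#'
#' One encoder pipeline (used, with separate parameters, by the shared
#' encoder and both private encoders) is: 1-D convolution over the 4-channel
#' one-hot sequence (kernel length 2 along the sequence, symmetric zero
#' padding of 2 per side), batch normalisation, ReLU, an LSTM whose final
#' hidden state summarises the window, a second batch normalisation, and a
#' dense projection to the `repr_dim`-dimensional representation. Decoders
#' are a dense map back to `L x 4`; classifiers a dense map from the shared
#' representation to 2 log-probabilities.
#'
#' @param window_length Input window length `L` (default 41).
#' @param conv_filters Convolution output channels (default 16).
#' @param conv_kernel Kernel length along the sequence (default 2).
#' @param conv_padding Zero padding per side (default 2; output length `L+3`).
#' @param lstm_hidden LSTM hidden size (default 8).
#' @param repr_dim Representation dimension `d`, identical for shared and
#'   private encoders (default 16).
#' @param dropout Dropout probability on the representation during training
#'   (default 0 = off).
#' @return A `model_config` list.
#' @export
model_config <- function(window_length = 41, conv_filters = 16,
                         conv_kernel = 2, conv_padding = 2,
                         lstm_hidden = 8, repr_dim = 16, dropout = 0) {
  cfg <- list(window_length = as.integer(window_length),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              conv_padding = as.integer(conv_padding),
              lstm_hidden = as.integer(lstm_hidden),
              repr_dim = as.integer(repr_dim),
              dropout = dropout)
  if (any(unlist(cfg[1:6]) <= 0)) abort("all architecture sizes must be positive")
  if (cfg$dropout < 0 || cfg$dropout >= 1) abort("dropout must be in [0, 1)")
  structure(cfg, class = "model_config")
}

#' Initialise a domain-separation network
#'
#' Builds the shared encoder, the two domain-private encoders (same
#' architecture, never shared parameters), per-domain decoders, the source
#' classifier and — in `"dual_classifier"` mode — the target classifier.
#' Classifiers read *only* the shared representation. Initialisation is
#' deterministic given the seed.
#'
#' @param config A [model_config()].
#' @param mode `"source_only_classifier"` (operating mode 1: target domain
#'   provides sequence context only) or `"dual_classifier"` (mode 2: target
#'   labels add a second supervision head).
#' @param seed Integer seed.
#' @param similarity `"mmd"` or `"dann"` similarity-loss variant.
#' @param recon `"simse"` or `"mse"` reconstruction-loss variant.
#' @param weights A [loss_weights()].
#' @param combiner How decoders combine private and shared representations:
#'   `"sum"` (default) or `"concat"`.
#' @return A `dsn_model` object.
#' @export
init_model <- function(config = model_config(),
                       mode = c("source_only_classifier", "dual_classifier"),
                       seed = 1,
                       similarity = c("mmd", "dann"),
                       recon = c("simse", "mse"),
                       weights = loss_weights(),
                       combiner = c("sum", "concat")) {
  mode <- match.arg(mode)
  similarity <- match.arg(similarity)
  recon <- match.arg(recon)
  combiner <- match.arg(combiner)
  d <- config$repr_dim
  dec_in <- if (combiner == "concat") 2L * d else d
  out_dim <- 4L * config$window_length
  params <- with_seed(seed, {
    p <- list(
      enc_shared = init_encoder(config),
      enc_priv_source = init_encoder(config),
      enc_priv_target = init_encoder(config),
      dec_source = list(W = init_mat(dec_in, out_dim, dec_in),
                        b = init_vec(out_dim, dec_in)),
      dec_target = list(W = init_mat(dec_in, out_dim, dec_in),
                        b = init_vec(out_dim, dec_in)),
      clf_source = list(W = init_mat(d, 2L, d), b = init_vec(2L, d))
    )
    if (mode == "dual_classifier") {
      p$clf_target <- list(W = init_mat(d, 2L, d), b = init_vec(2L, d))
    }
    if (similarity == "dann") {
      p$clf_domain <- list(W = init_mat(d, 2L, d), b = init_vec(2L, d))
    }
    p
  })
  structure(list(params = params, config = config, mode = mode,
                 similarity = similarity, recon = recon,
                 combiner = combiner, weights = weights, seed = seed,
                 mmd_bandwidth_base = NULL),
            class = "dsn_model")
}

#' @export
print.dsn_model <- function(x, ...) {
  n_par <- par_reduce(x$params, function(acc, p) acc + length(p))
  cat(sprintf(
    "<dsn_model> mode=%s similarity=%s recon=%s | L=%d d=%d | %d parameters\n",
    x$mode, x$similarity, x$recon, x$config$window_length,
    x$config$repr_dim, n_par))
  invisible(x)
}

combine_repr <- function(h_private, h_shared, combiner) {
  if (combiner == "concat") cbind(h_private, h_shared) else h_private + h_shared
}

dense_forward <- function(h, p) {
  h %*% p$W + matrix(p$b, nrow(h), length(p$b), byrow = TRUE)
}

#' Run the network forward on a paired batch
#'
#' Computes private and shared representations for both domains, the
#' per-domain reconstructions (decoder input is the combination of the
#' domain's private and shared representations), classifier outputs, and the
#' full loss breakdown.
#'
#' @param model A `dsn_model`.
#' @param x_source,x_target `batch x L x 4` one-hot arrays.
#' @param y_source 0/1 labels for the source batch.
#' @param y_target 0/1 labels for the target batch; ignored (and never read)
#'   in `"source_only_classifier"` mode.
#' @param training Use batch statistics and dropout (`TRUE`) or frozen
#'   statistics (`FALSE`).
#' @return List with representations (`h_c_s`, `h_p_s`, `h_c_t`, `h_p_t`),
#'   reconstructions, logits, and `losses` (a `loss_breakdown`).
#' @export
dsn_forward <- function(model, x_source, x_target, y_source,
                        y_target = NULL, training = FALSE) {
  fwd <- dsn_forward_full(model, x_source, x_target, y_source, y_target,
                          training)
  fwd[c("h_c_s", "h_p_s", "h_c_t", "h_p_t", "xhat_s", "xhat_t",
        "logits_s", "logits_t", "losses")]
}

dsn_forward_full <- function(model, x_source, x_target, y_source,
                             y_target = NULL, training = FALSE) {
  p <- model$params; cfg <- model$config
  ec_s <- encoder_forward(p$enc_shared, x_source, cfg, training)
  ec_t <- encoder_forward(p$enc_shared, x_target, cfg, training)
  ep_s <- encoder_forward(p$enc_priv_source, x_source, cfg, training)
  ep_t <- encoder_forward(p$enc_priv_target, x_target, cfg, training)

  comb_s <- combine_repr(ep_s$h, ec_s$h, model$combiner)
  comb_t <- combine_repr(ep_t$h, ec_t$h, model$combiner)
  xhat_s <- dense_forward(comb_s, p$dec_source)
  xhat_t <- dense_forward(comb_t, p$dec_target)

  rl_s <- recon_loss_grad(x_source, xhat_s, model$recon)
  rl_t <- recon_loss_grad(x_target, xhat_t, model$recon)
  dl_s <- difference_loss_grad(ec_s$h, ep_s$h)
  dl_t <- difference_loss_grad(ec_t$h, ep_t$h)
  sim <- if (model$similarity == "mmd") {
    mmd_loss_grad(ec_s$h, ec_t$h, model$mmd_bandwidth_base)
  } else {
    dann_loss_grad(ec_s$h, ec_t$h, p$clf_domain)
  }

  logits_s <- dense_forward(ec_s$h, p$clf_source)
  cls_s <- nll_loss_grad(logits_s, y_source)
  logits_t <- NULL; cls_t <- NULL
  if (model$mode == "dual_classifier") {
    if (is.null(y_target)) abort("dual_classifier mode needs target labels")
    logits_t <- dense_forward(ec_t$h, p$clf_target)
    cls_t <- nll_loss_grad(logits_t, y_target)
  }

  # The orthogonality term enters the objective at per-entry scale of the
  # d x d cross-correlation matrix (Frobenius sum / d^2), the convention the
  # published weight beta = 0.075 was tuned against; the standalone
  # difference_loss() keeps the raw Frobenius-norm definition.
  diff_scale <- 1 / cfg$repr_dim^2
  parts <- list(recon = rl_s$loss + rl_t$loss,
                difference = (dl_s$loss + dl_t$loss) * diff_scale,
                similarity = sim$loss,
                source_cls = cls_s$loss,
                target_cls = if (is.null(cls_t)) NULL else cls_t$loss)
  losses <- total_loss(parts, model$weights, model$mode)

  list(h_c_s = ec_s$h, h_p_s = ep_s$h, h_c_t = ec_t$h, h_p_t = ep_t$h,
       xhat_s = xhat_s, xhat_t = xhat_t,
       logits_s = logits_s, logits_t = logits_t, losses = losses,
       caches = list(ec_s = ec_s, ec_t = ec_t, ep_s = ep_s, ep_t = ep_t,
                     comb_s = comb_s, comb_t = comb_t,
                     rl_s = rl_s, rl_t = rl_t, dl_s = dl_s, dl_t = dl_t,
                     sim = sim, cls_s = cls_s, cls_t = cls_t),
       x_source = x_source, x_target = x_target)
}

# Split a decoder-input gradient back into (private, shared) parts.
split_comb_grad <- function(dcomb, d, combiner) {
  if (combiner == "concat") {
    list(private = dcomb[, seq_len(d), drop = FALSE],
         shared = dcomb[, d + seq_len(d), drop = FALSE])
  } else {
    list(private = dcomb, shared = dcomb)
  }
}

# Full backward pass: returns parameter gradients mirroring model$params.
# Loss routing follows the architecture contract: classification and
# similarity gradients reach only the shared encoder (+ their own heads);
# difference and reconstruction gradients reach shared and private encoders.
dsn_backward <- function(model, fwd) {
  p <- model$params; w <- model$weights; cfg <- model$config
  ca <- fwd$caches
  d <- cfg$repr_dim

  # decoder heads
  dxhat_s <- w$alpha * ca$rl_s$dxhat
  dxhat_t <- w$alpha * ca$rl_t$dxhat
  g_dec_s <- list(W = crossprod(ca$comb_s, dxhat_s), b = colSums(dxhat_s))
  g_dec_t <- list(W = crossprod(ca$comb_t, dxhat_t), b = colSums(dxhat_t))
  dcomb_s <- split_comb_grad(dxhat_s %*% t(p$dec_source$W), d, model$combiner)
  dcomb_t <- split_comb_grad(dxhat_t %*% t(p$dec_target$W), d, model$combiner)

  # classifier heads
  dlog_s <- ca$cls_s$dlogits
  g_clf_s <- list(W = crossprod(fwd$h_c_s, dlog_s), b = colSums(dlog_s))
  d_hc_s <- dlog_s %*% t(p$clf_source$W)
  d_hc_t <- matrix(0, nrow(fwd$h_c_t), d)
  grads <- list()
  if (model$mode == "dual_classifier") {
    dlog_t <- ca$cls_t$dlogits * w$delta
    grads$clf_target <- list(W = crossprod(fwd$h_c_t, dlog_t),
                             b = colSums(dlog_t))
    d_hc_t <- d_hc_t + dlog_t %*% t(p$clf_target$W)
  }

  # similarity term into the shared encoder only
  d_hc_s <- d_hc_s + w$gamma * ca$sim$d_source
  d_hc_t <- d_hc_t + w$gamma * ca$sim$d_target
  if (model$similarity == "dann") {
    grads$clf_domain <- list(W = w$gamma * ca$sim$d_clf$W,
                             b = w$gamma * ca$sim$d_clf$b)
  }

  # difference term into shared and private encoders (per-entry scale, as in
  # the forward pass)
  beta_eff <- w$beta / cfg$repr_dim^2
  d_hc_s <- d_hc_s + beta_eff * ca$dl_s$d_shared
  d_hp_s <- beta_eff * ca$dl_s$d_private
  d_hc_t <- d_hc_t + beta_eff * ca$dl_t$d_shared
  d_hp_t <- beta_eff * ca$dl_t$d_private

  # reconstruction into both encoders via the combiner
  d_hc_s <- d_hc_s + dcomb_s$shared
  d_hp_s <- d_hp_s + dcomb_s$private
  d_hc_t <- d_hc_t + dcomb_t$shared
  d_hp_t <- d_hp_t + dcomb_t$private

  eb_cs <- encoder_backward(p$enc_shared, ca$ec_s$cache, d_hc_s, cfg)
  eb_ct <- encoder_backward(p$enc_shared, ca$ec_t$cache, d_hc_t, cfg)
  eb_ps <- encoder_backward(p$enc_priv_source, ca$ep_s$cache, d_hp_s, cfg)
  eb_pt <- encoder_backward(p$enc_priv_target, ca$ep_t$cache, d_hp_t, cfg)

  grads$enc_shared <- par_map2(eb_cs$grads, eb_ct$grads, `+`)
  grads$enc_priv_source <- eb_ps$grads
  grads$enc_priv_target <- eb_pt$grads
  grads$dec_source <- g_dec_s
  grads$dec_target <- g_dec_t
  grads$clf_source <- g_clf_s
  grads
}

# Refresh batch-norm running statistics from an encoder forward pass.
absorb_running <- function(enc_params, new_running) {
  if (!is.null(new_running$bn1)) {
    enc_params$bn1$running_mean <- new_running$bn1$mean
    enc_params$bn1$running_var <- new_running$bn1$var
  }
  if (!is.null(new_running$bn2)) {
    enc_params$bn2$running_mean <- new_running$bn2$mean
    enc_params$bn2$running_var <- new_running$bn2$var
  }
  enc_params
}

#' Score windows with a trained model
#'
#' Runs the shared encoder in evaluation mode (frozen batch statistics) and
#' returns the positive-class probability from the requested classifier.
#'
#' @param object A `dsn_model`.
#' @param encoded `N x L x 4` one-hot array, or a `domain_dataset`.
#' @param classifier `"auto"` (target head when present, else source),
#'   `"source"`, or `"target"`.
#' @param ... Unused.
#' @return Tibble with `score` (P(positive)) and, when a `domain_dataset`
#'   was given, its `id` and `label` columns.
#' @export
predict.dsn_model <- function(object, encoded,
                              classifier = c("auto", "source", "target"), ...) {
  classifier <- match.arg(classifier)
  ds <- NULL
  if (inherits(encoded, "domain_dataset")) {
    ds <- encoded
    encoded <- ds$encoded
  }
  head_name <- switch(classifier,
    auto = if (!is.null(object$params$clf_target)) "clf_target" else "clf_source",
    source = "clf_source",
    target = "clf_target")
  if (is.null(object$params[[head_name]])) {
    abort(sprintf("model has no %s head", head_name))
  }
  enc <- encoder_forward(object$params$enc_shared, encoded, object$config,
                         training = FALSE)
  logits <- dense_forward(enc$h, object$params[[head_name]])
  mx <- pmax(logits[, 1], logits[, 2])
  ex <- exp(logits - mx)
  score <- ex[, 2] / rowSums(ex)
  out <- tibble(score = as.numeric(score))
  if (!is.null(ds)) {
    out$id <- ds$provenance$id
    out$label <- ds$labels
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the weights together with the
#' architecture config, loss weights, variant flags and seed; a JSON sidecar
#' duplicates the configuration for inspection without loading the archive.
#'
#' @param model A `dsn_model`.
#' @param path Checkpoint path (an `.rds` archive; the sidecar gets `.json`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  sidecar <- paste0(sub("\\.rds$", "", path), ".json")
  jsonlite::write_json(
    list(config = unclass(model$config), mode = model$mode,
         similarity = model$similarity, recon = model$recon,
         combiner = model$combiner, weights = unclass(model$weights),
         seed = model$seed),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dsn_model")) abort("not a dsn_model checkpoint")
  model
}
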