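#' Training configuration
#'
#' Defaults are the tuned settings used for the reported models: SGD with
#' momentum 0.9, base learning rate 0.005 decayed by a factor 0.9 every 600
#' optimisation steps, 20 epochs, paired batches of 64 per domain, and
#' best-epoch selection by validation average precision on a slice carved
#' from the *training* data (never the test fold).
#'
#' @param lr Base learning rate.
#' @param decay_step Steps between learning-rate decays.
#' @param decay_weight Multiplicative decay factor in `(0, 1]`.
#' @param epochs Training epochs.
#' @param batch_size Records per domain per step.
#' @param optimizer `"sgd_momentum"` or `"adam"`.
#' @param momentum Momentum coefficient for SGD.
#' @param seed Integer seed governing all training randomness.
#' @param selection_metric `"ap"` or `"auc"` for best-epoch selection.
#' @param val_fraction Fraction per class per domain held out for validation.
#' @param clip_norm Global gradient-norm clip; `Inf` disables.
#' @param log_every Emit a progress message every this many steps (`Inf` =
#'   silent).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.005, decay_step = 600, decay_weight = 0.9,
                         epochs = 20, batch_size = 64,
                         optimizer = c("sgd_momentum", "adam"),
                         momentum = 0.9, seed = 1,
                         selection_metric = c("ap", "auc"),
                         val_fraction = 0.1, clip_norm = 5, log_every = Inf) {
  optimizer <- match.arg(optimizer)
  selection_metric <- match.arg(selection_metric)
  if (lr <= 0) abort("lr must be positive")
  if (decay_weight <= 0 || decay_weight > 1) abort("decay_weight must be in (0, 1]")
  assert_scalar_int(epochs, "epochs", min = 1)
  structure(list(lr = lr, decay_step = as.integer(decay_step),
                 decay_weight = decay_weight, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 momentum = momentum, seed = as.integer(seed),
                 selection_metric = selection_metric,
                 val_fraction = val_fraction, clip_norm = clip_norm,
                 log_every = log_every),
            class = "train_config")
}

#' Step-decay learning-rate schedule
#'
#' `lr = base * decay_weight ^ floor(step / decay_step)` — e.g. a base rate
#' of 0.005 becomes 0.0045 at step 600 and 0.00405 at step 1200.
#'
#' @param base Base learning rate.
#' @param step 0-based optimisation step.
#' @param decay_step Steps per decay.
#' @param decay_weight Decay factor.
#' @return The learning rate at `step`.
#' @export
lr_at_step <- function(base, step, decay_step = 600, decay_weight = 0.9) {
  if (any(step < 0)) abort("step must be >= 0")
  base * decay_weight^floor(step / decay_step)
}

# One optimiser update, walking the gradient structure (parameters without
# gradients, e.g. batch-norm running statistics, are untouched).
optim_update <- function(params, grads, state, lr, config) {
  if (config$optimizer == "sgd_momentum") {
    state$v <- state$v %||% zero_like(grads)
    state$v <- par_map2(state$v, grads, function(v, g) config$momentum * v + g)
    params <- apply_grads(params, state$v, function(p, v) p - lr * v)
  } else {
    state$m <- state$m %||% zero_like(grads)
    state$u <- state$u %||% zero_like(grads)
    state$t <- (state$t %||% 0) + 1
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$m <- par_map2(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
    state$u <- par_map2(state$u, grads, function(u, g) b2 * u + (1 - b2) * g^2)
    corr <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
    step_amt <- par_map2(state$m, state$u,
                         function(m, u) corr * m / (sqrt(u) + eps))
    params <- apply_grads(params, step_amt, function(p, s) p - s)
  }
  list(params = params, state = state)
}

# Apply f(param, grad) for every leaf present in `grads`, leaving other
# parameter entries (running statistics) untouched.
apply_grads <- function(params, grads, f) {
  for (nm in names(grads)) {
    if (is.list(grads[[nm]])) {
      params[[nm]] <- apply_grads(params[[nm]], grads[[nm]], f)
    } else {
      params[[nm]] <- f(params[[nm]], grads[[nm]])
    }
  }
  params
}

# Held-out validation indices, stratified per class.
val_split_indices <- function(labels, fraction, seed) {
  val <- integer(0)
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    n_val <- floor(length(idx) * fraction)
    if (n_val > 0) {
      val <- c(val, with_seed(derive_seed(seed, 7L + lab), sample(idx, n_val)))
    }
  }
  sort(val)
}

#' Train a domain-separation network on paired domains
#'
#' Carves a stratified validation slice from each domain's training data,
#' balances classes by upsampling positives to the negative count, upsamples
#' the target domain to the source's size, and optimises the composite loss
#' with the configured schedule. In `"source_only_classifier"` mode the
#' target domain contributes sequence context only: positives are excluded
#' before pairing and target labels are never read. After every epoch the
#' validation slice is scored and the parameters of the best epoch (by the
#' selection metric, ties to the earliest epoch) are the ones returned.
#'
#' @param model A `dsn_model` from [init_model()].
#' @param source,target `domain_dataset` objects.
#' @param config A [train_config()].
#' @return A `dsn_fit`: list with `model` (best checkpoint), `history`
#'   (per-step losses and per-epoch validation metrics), `best_epoch`.
#' @export
train_dsn <- function(model, source, target, config = train_config()) {
  mode1 <- model$mode == "source_only_classifier"
  t_pool_idx <- if (mode1) which(target$labels == 0L) else
    seq_along(target$labels)
  if (length(t_pool_idx) == 0) abort("target domain has no usable records")

  # validation slices (never upsampled, never trained on)
  s_val <- val_split_indices(source$labels, config$val_fraction, config$seed)
  t_val_local <- val_split_indices(target$labels[t_pool_idx],
                                   config$val_fraction, derive_seed(config$seed, 11L))
  t_val <- t_pool_idx[t_val_local]
  s_train_idx <- setdiff(seq_along(source$labels), s_val)
  t_train_idx <- setdiff(t_pool_idx, t_val)

  # class balancing: upsample positives to the negative count per domain
  balance <- function(data, idx, seed) {
    pos <- idx[data$labels[idx] == 1L]
    neg <- idx[data$labels[idx] == 0L]
    if (length(pos) > 0 && length(pos) < length(neg)) {
      pos <- upsample_to_match(pos, length(neg), seed)
    }
    c(pos, neg)
  }
  s_train <- dataset_subset(source, balance(source, s_train_idx,
                                            derive_seed(config$seed, 21L)))
  t_train <- dataset_subset(target, balance(target, t_train_idx,
                                            derive_seed(config$seed, 22L)))

  opt_state <- list()
  step <- 0L
  n_steps_max <- config$epochs *
    ceiling(length(s_train$labels) / config$batch_size)
  step_log <- matrix(NA_real_, n_steps_max, 9,
                     dimnames = list(NULL, c("epoch", "step", "lr", "recon",
                                             "difference", "similarity",
                                             "source_cls", "target_cls",
                                             "total")))
  epoch_reports <- list()
  val_metric <- numeric(0)
  best <- NULL

  for (epoch in seq_len(config$epochs)) {
    stream <- pair_domains(s_train, t_train, config$batch_size,
                           seed = derive_seed(config$seed, 100L + epoch))
    for (b in stream$batches) {
      xs <- s_train$encoded[b$source_idx, , , drop = FALSE]
      xt <- t_train$encoded[b$target_idx, , , drop = FALSE]
      ys <- s_train$labels[b$source_idx]
      yt <- if (mode1) NULL else t_train$labels[b$target_idx]
      fwd <- with_seed(derive_seed(config$seed, 10000L + step),
                       dsn_forward_full(model, xs, xt, ys, yt, training = TRUE))
      if (!is.finite(fwd$losses$total)) {
        parts <- unlist(fwd$losses[c("recon", "difference", "similarity",
                                     "source_cls", "target_cls")])
        bad <- names(parts)[!is.finite(parts)]
        abort(sprintf("non-finite loss at step %d (term: %s)", step,
                      paste(bad, collapse = ", ")))
      }
      if (is.null(model$mmd_bandwidth_base) && model$similarity == "mmd") {
        model$mmd_bandwidth_base <- fwd$caches$sim$bandwidth_base
      }
      grads <- dsn_backward(model, fwd)
      gn <- global_grad_norm(grads)
      if (is.finite(config$clip_norm) && gn > config$clip_norm) {
        grads <- par_map(grads, function(g) g * (config$clip_norm / gn))
      }
      lr <- lr_at_step(config$lr, step, config$decay_step, config$decay_weight)
      upd <- optim_update(model$params, grads, opt_state, lr, config)
      model$params <- upd$params
      opt_state <- upd$state
      model$params$enc_shared <- absorb_running(model$params$enc_shared,
                                                fwd$caches$ec_s$new_running)
      model$params$enc_shared <- absorb_running(model$params$enc_shared,
                                                fwd$caches$ec_t$new_running)
      model$params$enc_priv_source <- absorb_running(
        model$params$enc_priv_source, fwd$caches$ep_s$new_running)
      model$params$enc_priv_target <- absorb_running(
        model$params$enc_priv_target, fwd$caches$ep_t$new_running)
      step_log[step + 1L, ] <- c(
        epoch, step, lr, fwd$losses$recon, fwd$losses$difference,
        fwd$losses$similarity, fwd$losses$source_cls,
        fwd$losses$target_cls %||% NA_real_, fwd$losses$total)
      if (is.finite(config$log_every) && step %% config$log_every == 0) {
        message(sprintf("step %d (epoch %d): total=%.4f cls=%.4f", step,
                        epoch, fwd$losses$total, fwd$losses$source_cls))
      }
      step <- step + 1L
    }

    rep <- validation_report(model, source, target, s_val, t_val, mode1)
    epoch_reports[[epoch]] <- dplyr::mutate(rep, epoch = epoch,
                                            .before = 1)
    val_metric[epoch] <- rep[[config$selection_metric]]
    if (!is.na(val_metric[epoch]) &&
        (is.null(best) || val_metric[epoch] > best$metric)) {
      best <- list(metric = val_metric[epoch], epoch = epoch, params = model$params,
                   mmd_bandwidth_base = model$mmd_bandwidth_base)
    }
  }

  if (is.null(best)) {
    warn("no usable validation metrics; keeping the last epoch's parameters")
    best <- list(metric = NA_real_, epoch = config$epochs,
                 params = model$params,
                 mmd_bandwidth_base = model$mmd_bandwidth_base)
  }
  model$params <- best$params
  model$mmd_bandwidth_base <- best$mmd_bandwidth_base
  history <- structure(
    list(steps = as_tibble(step_log[seq_len(step), , drop = FALSE]),
         epochs = dplyr::bind_rows(epoch_reports),
         selection_metric = config$selection_metric,
         best_epoch = best$epoch),
    class = "dsn_history")
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 config = config),
            class = "dsn_fit")
}

# Validation scoring: target head on the target slice in dual mode; in
# source-only mode the target slice carries a single class, so the source
# head is scored on the source slice instead.
validation_report <- function(model, source, target, s_val, t_val, mode1) {
  if (!mode1 && length(t_val) > 0 &&
      length(unique(target$labels[t_val])) == 2) {
    ds <- dataset_subset(target, t_val)
    scores <- predict(model, ds$encoded, classifier = "target")$score
    return(compute_metrics(scores, ds$labels))
  }
  if (length(s_val) > 0 && length(unique(source$labels[s_val])) == 2) {
    ds <- dataset_subset(source, s_val)
    scores <- predict(model, ds$encoded, classifier = "source")$score
    return(compute_metrics(scores, ds$labels))
  }
  compute_metrics(numeric(0), integer(0))
}

#' Pick the best epoch from a training history
#'
#' @param history A `dsn_history` (or numeric vector of per-epoch metric
#'   values).
#' @param metric Metric column to maximise (default: the history's selection
#'   metric).
#' @return 1-based epoch index of the maximum; ties resolve to the earliest
#'   epoch.
#' @export
select_best_checkpoint <- function(history, metric = NULL) {
  vals <- if (is.numeric(history)) {
    history
  } else {
    metric <- metric %||% history$selection_metric
    history$epochs[[metric]]
  }
  if (length(vals) == 0 || all(is.na(vals))) abort("no validation metrics available")
  which.max(vals)
}

#' @export
print.dsn_fit <- function(x, ...) {
  cat(sprintf("<dsn_fit> %d epochs, best epoch %d (val %s = %.4f)\n",
              x$config$epochs, x$best_epoch,
              x$config$selection_metric,
              x$history$epochs[[x$config$selection_metric]][x$best_epoch]))
  invisible(x)
}

#' @export
predict.dsn_fit <- function(object, encoded, ...) {
  predict(object$model, encoded, ...)
}
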