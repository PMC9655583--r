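# Shared fixtures, built in code. Heavy trained models are cached per
# (preset, seed, mode) within a test run so acceptance checks can share them.

random_window <- function(L = 41, seed = NULL, alphabet = c("A", "C", "G", "U")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

random_onehot_batch <- function(n, L = 9, seed = 1) {
  set.seed(seed)
  arr <- array(0, dim = c(n, L, 4))
  for (i in seq_len(n)) arr[i, , ] <- one_hot_encode(random_window(L))
  arr
}

tiny_model_config <- function() {
  model_config(window_length = 9, conv_filters = 4, lstm_hidden = 3,
               repr_dim = 5)
}

# Count of motif hits with at most `max_mismatch` mismatches, scanning all
# offsets: the brute-force scanner used as an oracle for the generator.
motif_scan_score <- function(window, motif, max_mismatch = 1) {
  k <- nchar(motif)
  L <- nchar(window)
  mchars <- strsplit(motif, "")[[1]]
  best <- 0
  for (s in 1:(L - k + 1)) {
    matches <- sum(strsplit(substr(window, s, s + k - 1), "")[[1]] == mchars)
    best <- max(best, matches)
  }
  best
}

.model_cache <- new.env(parent = emptyenv())

# Train (or fetch) a model on the confounded preset. Training settings are
# the package's synthetic-experiment defaults: the published schedule scaled
# to the generator's corpus size (see the methods vignette).
cached_confounded_fit <- function(seed, mode) {
  key <- paste0("confounded_", seed, "_", mode)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  pair <- cached_confounded_pair(seed)
  model <- init_model(model_config(), mode = mode, seed = seed)
  fit <- train_dsn(model, pair$source, pair$target,
                   synthetic_train_config(seed))
  .model_cache[[key]] <- fit
  fit
}

cached_confounded_pair <- function(seed) {
  key <- paste0("pair_", seed)
  if (is.null(.model_cache[[key]])) {
    .model_cache[[key]] <- generate_domain_pair(synth_preset("confounded",
                                                             seed = seed))
  }
  .model_cache[[key]]
}

synthetic_train_config <- function(seed) {
  train_config(lr = 0.05, seed = seed, clip_norm = Inf)
}
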