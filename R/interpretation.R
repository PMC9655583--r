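# Integrated Gradients over input windows, plus a deliberately simple
# seqlet -> cluster -> align aggregation that turns per-window attribution
# into position frequency matrices.

# Internal generic: batch scores and input gradients of the attribution
# target. Implemented for the trained network and for a linear surrogate
# used to verify IG against its closed form.
ig_score_grad <- function(model, X, ...) UseMethod("ig_score_grad")

#' @export
ig_score_grad.dsn_model <- function(model, X, classifier = "auto", ...) {
  head_name <- switch(classifier,
    auto = if (!is.null(model$params$clf_target)) "clf_target" else "clf_source",
    source = "clf_source", target = "clf_target")
  if (is.null(model$params[[head_name]])) {
    abort(sprintf("model has no %s head", head_name))
  }
  enc <- encoder_forward(model$params$enc_shared, X, model$config,
                         training = FALSE)
  logits <- dense_forward(enc$h, model$params[[head_name]])
  mx <- pmax(logits[, 1], logits[, 2])
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  # d P(positive) / d logits for each sample
  dlogits <- cbind(-p[, 2] * p[, 1], p[, 2] * (1 - p[, 2]))
  dh <- dlogits %*% t(model$params[[head_name]]$W)
  eb <- encoder_backward(model$params$enc_shared, enc$cache, dh, model$config)
  list(values = p[, 2], grads = eb$dX)
}

#' A linear scorer for verifying attribution methods
#'
#' `f(x) = sum(w * x) + b` on an `L x 4` window. Because the gradient is the
#' constant `w`, Integrated Gradients from a zero baseline must equal
#' `w * x` exactly at any number of steps — the closed-form oracle used in
#' the tests.
#'
#' @param w `L x 4` weight matrix.
#' @param b Intercept.
#' @return A `linear_scorer` usable with [integrated_gradients()].
#' @export
linear_scorer <- function(w, b = 0) {
  structure(list(w = w, b = b), class = "linear_scorer")
}

#' @export
ig_score_grad.linear_scorer <- function(model, X, ...) {
  B <- dim(X)[1]
  flat <- as_flat_matrix(X)
  values <- as.numeric(flat %*% as.numeric(model$w)) + model$b
  grads <- array(rep(as.numeric(model$w), each = B), dim = dim(X))
  list(values = values, grads = grads)
}

#' Integrated Gradients attribution for one window
#'
#' Attributes the positive-class score to each input position/channel by
#' averaging gradients along the straight path from a baseline to the input:
#' `attr_i = (x_i - baseline_i) * mean_k grad_i(baseline + k/steps * (x -
#' baseline))`. The default baseline is the all-zero matrix — the same
#' convention as an `N` (no-information) position. The completeness residual
#' `|sum(attr) - (f(x) - f(baseline))|` is reported as `convergence_gap` and
#' shrinks as `steps` grows.
#'
#' @param model A trained `dsn_model` (attribution flows through the shared
#'   encoder and the designated classifier head) or a [linear_scorer()].
#' @param x `L x 4` one-hot window (or a window string).
#' @param baseline Same-shape baseline matrix; default all zeros.
#' @param steps Number of path points (Riemann steps).
#' @param classifier Head to attribute: `"auto"`, `"source"`, `"target"`.
#' @return An `attribution_map`: list with `attributions` (`L x 4`),
#'   `window`, `prediction`, `baseline_value`, `convergence_gap`, `steps`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 50,
                                 classifier = "auto") {
  assert_scalar_int(steps, "steps", min = 1)
  window <- NULL
  if (is.character(x)) {
    window <- x
    x <- one_hot_encode(x)
  }
  baseline <- baseline %||% (x * 0)
  if (!all(dim(baseline) == dim(x))) abort("baseline shape must match x")
  L <- nrow(x)
  diffs <- x - baseline
  alphas <- seq_len(steps) / steps
  Xpath <- array(0, dim = c(steps, L, 4L))
  for (k in seq_len(steps)) Xpath[k, , ] <- baseline + alphas[k] * diffs
  sg <- ig_score_grad(model, Xpath, classifier = classifier)
  mean_grad <- apply(sg$grads, c(2, 3), mean)
  attributions <- diffs * mean_grad
  ends_arr <- array(0, dim = c(2L, L, 4L))
  ends_arr[1, , ] <- x
  ends_arr[2, , ] <- baseline
  ends <- ig_score_grad(model, ends_arr, classifier = classifier)
  f_x <- ends$values[1]; f_base <- ends$values[2]
  structure(list(attributions = attributions,
                 window = window %||% decode_one_hot(round(x)),
                 prediction = f_x, baseline_value = f_base,
                 convergence_gap = abs(sum(attributions) - (f_x - f_base)),
                 steps = steps),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %d nt, prediction %.4f, completeness gap %.2e\n",
              nrow(x$attributions), x$prediction, x$convergence_gap))
  invisible(x)
}

#' Export an attribution map as TSV
#'
#' One row per position: the four channel attributions, the realised base
#' and its attribution weight.
#'
#' @param map An `attribution_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_attribution_tsv <- function(map, path) {
  a <- map$attributions
  df <- tibble(position = seq_len(nrow(a)) - 1L,
               A = a[, 1], C = a[, 2], G = a[, 3], U = a[, 4],
               base = strsplit(map$window, "")[[1]],
               weight = rowSums(a))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Extract high-attribution seqlets from attribution maps
#'
#' Per map, each position's weight is the attribution of the realised base
#' (channels sum; zero-channel positions contribute nothing). All length-`k`
#' windows whose summed weight strictly exceeds the map's mean `k`-window
#' weight are candidates; overlapping candidates within one map are merged,
#' keeping the highest-weight one. Maps whose prediction is below 0.5 are
#' dropped with a warning — seqlets are mined from positive predictions.
#'
#' @param maps List of `attribution_map` objects (one is accepted too).
#' @param k Seqlet length.
#' @return Tibble with `map`, `start` (0-based), `seq`, `weight`.
#' @export
extract_seqlets <- function(maps, k = 6) {
  if (inherits(maps, "attribution_map")) maps <- list(maps)
  L <- nrow(maps[[1]]$attributions)
  if (k > L) abort("seqlet length k exceeds the window length")
  preds <- purrr::map_dbl(maps, "prediction")
  if (any(preds < 0.5)) {
    warn(sprintf("dropping %d map(s) with prediction < 0.5", sum(preds < 0.5)))
    maps <- maps[preds >= 0.5]
  }
  out <- purrr::imap(maps, function(m, i) {
    w <- rowSums(m$attributions)
    ws <- as.numeric(stats::filter(w, rep(1, k), sides = 1))[k:L]
    starts <- seq_along(ws)  # 1-based start of each k-window
    keep <- which(ws > mean(ws))
    if (length(keep) == 0) return(NULL)
    keep <- keep[order(ws[keep], decreasing = TRUE)]
    chosen <- integer(0)
    for (s in keep) {
      if (all(abs(s - chosen) >= k)) chosen <- c(chosen, s)
    }
    tibble(map = i, start = sort(chosen) - 1L,
           seq = substring(m$window, sort(chosen), sort(chosen) + k - 1L),
           weight = ws[sort(chosen)])
  })
  dplyr::bind_rows(out)
}

seqlet_onehot <- function(seqs) lapply(seqs, one_hot_encode)

# Best placement of a one-hot seqlet against an accumulating count matrix:
# offsets are scanned outward from zero so ties resolve to the smallest
# shift. Returns the padding needed and the target row range.
align_to_counts <- function(counts, seqlet, min_overlap = 3) {
  W <- nrow(counts); k <- nrow(seqlet)
  offs <- seq(-(k - min_overlap), W - min_overlap)
  offs <- offs[order(abs(offs))]
  best_score <- -Inf; best_off <- 0L
  for (off in offs) {
    ic <- max(1L, 1L + off); is_ <- max(1L, 1L - off)
    len <- min(W - ic, k - is_) + 1L
    if (len < min_overlap) next
    sc <- sum(counts[ic:(ic + len - 1L), ] * seqlet[is_:(is_ + len - 1L), ])
    if (sc > best_score) { best_score <- sc; best_off <- off }
  }
  prepend <- max(0L, -best_off)
  append <- max(0L, best_off + k - W)
  rows <- (1L + best_off + prepend):(k + best_off + prepend)
  list(offset = best_off, prepend = prepend, append = append, rows = rows)
}

# Max cross-correlation (match count at the best offset) of two one-hot
# seqlets, requiring at least `min_overlap` aligned positions.
seqlet_similarity <- function(a, b, min_overlap = 3) {
  ka <- nrow(a); kb <- nrow(b)
  best <- 0; best_off <- 0L
  for (off in seq(-(kb - min_overlap), ka - min_overlap)) {
    ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
    len <- min(ka - ia, kb - ib) + 1L
    if (len < min_overlap) next
    sc <- sum(a[ia:(ia + len - 1L), ] * b[ib:(ib + len - 1L), ])
    if (sc > best) { best <- sc; best_off <- off }
  }
  list(score = best, offset = best_off)
}

#' Cluster seqlets and align them into motifs
#'
#' Greedy aggregation: pairwise seqlet similarity is the maximum
#' cross-correlation of their one-hot matrices over alignment offsets; pairs
#' scoring above `similarity * k` are linked and connected components form
#' clusters. Each cluster's members are aligned to its highest-weight seqlet
#' at their best offsets; aligned columns with at least half the cluster's
#' support become the motif, as a position frequency matrix with pseudocount
#' 0.25. Clusters below `min_support` are dropped; motifs are sorted by mean
#' seqlet weight.
#'
#' Aligned columns are finally trimmed to the contiguous informative block
#' (information content at least `min_ic` bits), so weakly supported,
#' compositionally mixed flank columns do not enter the consensus.
#'
#' @param seqlets Tibble from [extract_seqlets()].
#' @param min_support Minimum seqlets per reported motif.
#' @param similarity Linking threshold as a fraction of the seqlet length.
#' @param min_ic Information-content trim threshold in bits; trimming is
#'   skipped if fewer than 3 columns would remain.
#' @return List of `rnadsn_motif` objects (possibly empty, with a warning):
#'   each has `pfm` (width x 4, rows sum to 1), `consensus`, `support`,
#'   `mean_weight`.
#' @export
cluster_and_align <- function(seqlets, min_support = 5, similarity = 0.7,
                              min_ic = 0.5) {
  n <- nrow(seqlets)
  if (n < min_support) {
    warn("fewer seqlets than min_support; no motifs")
    return(list())
  }
  oh <- seqlet_onehot(seqlets$seq)
  k <- nrow(oh[[1]])
  thresh <- similarity * k
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (seqlet_similarity(oh[[i]], oh[[j]])$score > thresh) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  motifs <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) < min_support) next
    seed <- members[which.max(seqlets$weight[members])]
    # progressive alignment: members join in order of similarity to the
    # seed, each at its best offset against the accumulating count matrix,
    # so shifted copies chain together instead of mis-anchoring on the seed
    sims <- vapply(members, function(i) {
      seqlet_similarity(oh[[seed]], oh[[i]])$score
    }, numeric(1))
    ordered <- members[order(-sims, members)]
    # counts and coverage are attribution-weighted: true motif instances
    # carry the largest weights, so weak pattern-matching seqlets cannot
    # drag the supported core off the motif
    w1 <- seqlets$weight[ordered[1]]
    counts <- oh[[ordered[1]]] * w1
    coverage <- rep(w1, k)
    for (i in ordered[-1]) {
      al <- align_to_counts(counts, oh[[i]], min_overlap = 3)
      if (al$prepend > 0) {
        counts <- rbind(matrix(0, al$prepend, 4), counts)
        coverage <- c(rep(0, al$prepend), coverage)
      }
      if (al$append > 0) {
        counts <- rbind(counts, matrix(0, al$append, 4))
        coverage <- c(coverage, rep(0, al$append))
      }
      rows <- al$rows
      counts[rows, ] <- counts[rows, ] + oh[[i]] * seqlets$weight[i]
      coverage[rows] <- coverage[rows] + seqlets$weight[i]
    }
    core <- which(coverage >= sum(seqlets$weight[members]) / 2)
    core <- min(core):max(core)
    pfm <- counts[core, , drop = FALSE] + 0.25
    pfm <- pfm / rowSums(pfm)
    ic <- 2 + rowSums(pfm * log2(pfm))
    informative <- which(ic >= min_ic)
    if (length(informative) >= 3) {
      pfm <- pfm[min(informative):max(informative), , drop = FALSE]
    }
    colnames(pfm) <- RNA_BASES
    motifs[[length(motifs) + 1L]] <- structure(
      list(pfm = pfm,
           consensus = paste(RNA_BASES[max.col(pfm)], collapse = ""),
           support = length(members),
           mean_weight = mean(seqlets$weight[members])),
      class = "rnadsn_motif")
  }
  if (length(motifs) == 0) {
    warn("no cluster reached min_support; no motifs")
    return(list())
  }
  motifs[order(purrr::map_dbl(motifs, "mean_weight"), decreasing = TRUE)]
}

#' @export
print.rnadsn_motif <- function(x, ...) {
  cat(sprintf("<motif> %s (support %d, mean weight %.4f)\n",
              x$consensus, x$support, x$mean_weight))
  invisible(x)
}

#' Mismatches between two consensus strings at their best alignment
#'
#' Slides the shorter string along the longer (full containment) and returns
#' the minimum Hamming mismatch count.
#'
#' @param a,b Consensus strings over `ACGU`.
#' @return Integer mismatch count at the best offset.
#' @export
consensus_mismatches <- function(a, b) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- length(cb)
  for (off in 0:(length(ca) - length(cb))) {
    mm <- sum(ca[off + seq_along(cb)] != cb)
    best <- min(best, mm)
  }
  best
}

#' Export motifs in MEME minimal format
#'
#' @param motifs List of `rnadsn_motif` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 U 0.25", ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(sprintf("MOTIF %s motif_%d", m$consensus, i), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(m$pfm), m$support), con)
    utils::write.table(format(m$pfm, digits = 6), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' End-to-end motif mining from a trained model
#'
#' Scores the dataset, runs Integrated Gradients on the windows predicted
#' positive, extracts seqlets and aggregates them into motifs.
#'
#' @param model Trained `dsn_model` (or `dsn_fit`).
#' @param dataset A `domain_dataset` to interpret.
#' @param steps IG steps.
#' @param k Seqlet length.
#' @param min_support Minimum cluster support.
#' @param max_windows Cap on the number of positive-predicted windows
#'   attributed (highest scores first), to bound runtime.
#' @param classifier Attribution head.
#' @return List with `maps`, `seqlets`, `motifs`.
#' @export
interpret_model <- function(model, dataset, steps = 50, k = 6,
                            min_support = 5, max_windows = 100,
                            classifier = "auto") {
  if (inherits(model, "dsn_fit")) model <- model$model
  scores <- predict(model, dataset$encoded, classifier = classifier)$score
  idx <- which(scores >= 0.5)
  if (length(idx) == 0) {
    warn("no window predicted positive; nothing to interpret")
    return(list(maps = list(), seqlets = tibble(), motifs = list()))
  }
  idx <- idx[order(scores[idx], decreasing = TRUE)]
  idx <- utils::head(idx, max_windows)
  maps <- lapply(idx, function(i) {
    m <- integrated_gradients(model, dataset$encoded[i, , ], steps = steps,
                              classifier = classifier)
    m$window <- dataset$provenance$window[i] %||% m$window
    m$id <- dataset$provenance$id[i]
    m
  })
  seqlets <- extract_seqlets(maps, k = k)
  if (nrow(seqlets) > 0) seqlets$id <- purrr::map_chr(maps, "id")[seqlets$map]
  motifs <- if (nrow(seqlets) >= min_support) {
    cluster_and_align(seqlets, min_support = min_support)
  } else {
    list()
  }
  list(maps = maps, seqlets = seqlets, motifs = motifs)
}
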