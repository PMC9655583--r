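# Brute-force oracles: AUC as the all-pairs comparison statistic (ties count
# one half) and AP as precision averaged at positive ranks.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

ap_bruteforce <- function(scores, labels) {
  # step-wise AP with tied scores grouped into single thresholds
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  uniq <- unique(s)
  ctp <- 0; cn <- 0; ap <- 0; total_pos <- sum(labels == 1)
  for (u in uniq) {
    sel <- s == u
    new_tp <- sum(y[sel])
    ctp <- ctp + new_tp; cn <- cn + sum(sel)
    ap <- ap + (new_tp / total_pos) * (ctp / cn)
  }
  ap
}

test_that("metric formulas match hand-computed values on fixed counts", {
  # TP=9 FN=1 TN=99 FP=1 at threshold 0.5
  scores <- c(rep(0.9, 9), 0.1, rep(0.05, 99), 0.95)
  labels <- c(rep(1, 10), rep(0, 100))
  m <- compute_metrics(scores, labels)
  expect_equal(m$acc, 108 / 110)
  expect_equal(m$spe, 0.99)
  expect_equal(m$pre, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(9, 99, 1, 1))
})

test_that("count metrics match definitions on an exhaustive small grid", {
  for (tp in 0:4) for (tn in 0:4) for (fp in 0:4) for (fn in 0:4) {
    n <- tp + tn + fp + fn
    if (n == 0) next
    scores <- c(rep(0.9, tp), rep(0.1, fn), rep(0.9, fp), rep(0.1, tn))
    labels <- c(rep(1, tp + fn), rep(0, fp + tn))
    m <- suppressWarnings(compute_metrics(scores, labels))
    expect_equal(m$acc, (tp + tn) / n)
    if (tn + fp > 0) expect_equal(m$spe, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$pre, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
  }
})

test_that("auc and ap match brute-force oracles on random instances", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- if (rep %% 3 == 0) {
      sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    } else {
      runif(n)
    }
    m <- compute_metrics(scores, labels)
    expect_equal(m$auc, auc_bruteforce(scores, labels), tolerance = 1e-9)
    expect_equal(m$ap, ap_bruteforce(scores, labels), tolerance = 1e-9)
  }
})

test_that("auc agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  labels <- sample(0:1, 300, replace = TRUE, prob = c(0.8, 0.2))
  labels[1:2] <- c(0, 1)
  scores <- runif(300) + 0.3 * labels
  m <- compute_metrics(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$auc, ref, tolerance = 1e-9)
})

test_that("degenerate scores behave sensibly", {
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$ap, 1)
  shuffled <- withr::with_seed(33, {
    labels <- sample(0:1, 10000, replace = TRUE)
    compute_metrics(runif(10000), labels)
  })
  expect_lt(abs(shuffled$auc - 0.5), 0.02)
  expect_warning(compute_metrics(c(0.2, 0.8), c(1, 1)), "single-class")
})

test_that("score curves trace ROC and PR coordinates", {
  scores <- c(0.9, 0.8, 0.7, 0.6)
  labels <- c(1, 0, 1, 0)
  cur <- score_curves(scores, labels)
  expect_equal(cur$tpr, c(0.5, 0.5, 1, 1))
  expect_equal(cur$fpr, c(0, 0.5, 0.5, 1))
  expect_equal(cur$precision, c(1, 0.5, 2 / 3, 0.5))
})

test_that("baselines run on flattened one-hot features and are seeded", {
  cfg <- synth_preset("easy", seed = 21, n_source_pos = 120,
                      n_source_neg = 120, n_target_pos = 60,
                      n_target_neg = 60, motif_prob = 1, jitter = 0)
  pair <- generate_domain_pair(cfg)
  # un-jittered planted motif: linearly separable by construction, so
  # logistic regression must separate well
  rep <- run_baseline("logistic", pair$source, pair$target, seed = 1)
  expect_gt(rep$auc, 0.95)

  # constant features carry no signal
  const <- pair$target
  const$encoded[] <- 0
  const$encoded[, , 4] <- 1
  rep0 <- run_baseline("logistic", pair$source, const, seed = 1)
  expect_lt(abs(rep0$auc - 0.5), 0.1)

  r1 <- run_baseline("random_forest", pair$source, pair$target, seed = 5)
  r2 <- run_baseline("random_forest", pair$source, pair$target, seed = 5)
  expect_equal(r1$auc, r2$auc)

  expect_error(run_baseline("nonesuch", pair$source, pair$target),
               "naive_bayes")
})

test_that("every named baseline produces a usable report", {
  cfg <- synth_preset("easy", seed = 22, n_source_pos = 60, n_source_neg = 60,
                      n_target_pos = 30, n_target_neg = 30, motif_prob = 1)
  pair <- generate_domain_pair(cfg)
  for (nm in c("naive_bayes", "logistic", "knn", "svm", "random_forest",
               "xgboost")) {
    rep <- run_baseline(nm, pair$source, pair$target, seed = 2)
    expect_true(is.finite(rep$auc), label = nm)
    expect_true(rep$auc >= 0 && rep$auc <= 1, label = nm)
  }
})

test_that("cross-validation trains per fold and averages the reports", {
  cfg <- synth_preset("easy", seed = 41, n_source_pos = 40, n_source_neg = 40,
                      n_target_pos = 24, n_target_neg = 24)
  pair <- generate_domain_pair(cfg)
  ids <- pair$target$provenance$id
  plan <- make_cv_plan(ids[pair$target$labels == 1L],
                       ids[pair$target$labels == 0L], groups = 2, seed = 41)
  res <- run_cross_validation(
    pair$source, pair$target, plan,
    model_config = model_config(window_length = 41, conv_filters = 2,
                                lstm_hidden = 2, repr_dim = 3),
    train_config = train_config(seed = 41, epochs = 1, batch_size = 16),
    mode = "dual_classifier", seed = 41)
  expect_equal(nrow(res$folds), 4)
  expect_equal(res$mean$auc, mean(res$folds$auc))
  expect_equal(res$mean$ap, mean(res$folds$ap))
  # every fold's test set is the planned quarter of the target data
  expect_true(all(res$folds$tp + res$folds$tn + res$folds$fp +
                    res$folds$fn == 24))
})
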