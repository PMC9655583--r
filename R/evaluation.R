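#' Classification metrics for site prediction
#'
#' Computes the full report used throughout: accuracy, specificity,
#' precision, recall, F1 (all at the given threshold, default 0.5), the area
#' under the ROC curve, and average precision, plus the confusion counts.
#' AUC is the trapezoid area over score-sorted thresholds with tied scores
#' grouped (equivalent to the rank statistic with ties counted 1/2); AP is
#' the step-wise average precision
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} over distinct-score thresholds, without
#' interpolation. Scores are oriented as the probability of the positive
#' class.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or positive/negative) labels.
#' @param threshold Decision threshold for the count-based metrics.
#' @return One-row tibble: `acc`, `spe`, `pre`, `recall`, `f1`, `auc`, `ap`,
#'   `threshold`, `tp`, `tn`, `fp`, `fn`. Ranking metrics are `NA` (with a
#'   warning) when only one class is present.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) abort("scores/labels length mismatch")
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(normalize_labels(labels) == "positive")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  pre <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(pre) || is.na(recall) || pre + recall == 0) NA_real_ else
    2 * pre * recall / (pre + recall)
  if (n_pos == 0 || n_neg == 0) {
    if (length(labels) > 0) warn("single-class labels: auc/ap undefined")
    auc <- NA_real_; ap <- NA_real_
  } else {
    auc <- auc_trapezoid(scores, labels)
    ap <- average_precision(scores, labels)
  }
  tibble(acc = safe_div(tn + tp, length(labels)),
         spe = safe_div(tn, tn + fp),
         pre = pre, recall = recall, f1 = f1,
         auc = auc, ap = ap, threshold = threshold,
         tp = tp, tn = tn, fp = fp, fn = fn)
}

# Trapezoid ROC area with tied scores collapsed into single thresholds.
auc_trapezoid <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  ctp <- cumsum(tp_g); cfp <- cumsum(n_g - tp_g)
  tpr <- c(0, ctp / sum(labels == 1L))
  fpr <- c(0, cfp / sum(labels == 0L))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Step-wise average precision over distinct-score thresholds.
average_precision <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  ctp <- cumsum(tp_g); cn <- cumsum(n_g)
  precision <- ctp / cn
  recall <- ctp / sum(labels == 1L)
  sum(diff(c(0, recall)) * precision)
}

#' ROC and precision-recall curve points
#'
#' Raw curve coordinates (one row per distinct score threshold) for plotting
#' or export.
#'
#' @inheritParams compute_metrics
#' @return Tibble with `threshold`, `fpr`, `tpr`, `precision`, `recall`.
#' @export
score_curves <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- as.integer(labels)[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  ctp <- cumsum(y); cfp <- cumsum(1 - y)
  tibble(threshold = s[keep],
         fpr = cfp[keep] / max(1, sum(y == 0)),
         tpr = ctp[keep] / max(1, sum(y == 1)),
         precision = ctp[keep] / (ctp[keep] + cfp[keep]),
         recall = ctp[keep] / max(1, sum(y == 1)))
}

#' Run the full cross-validation over a fold plan
#'
#' For each fold of the plan: the fold's test records are removed from the
#' target domain, a fresh network is initialised and trained on the full
#' source domain plus the remaining target records (class balancing and
#' target upsampling happen inside training, after the exclusion, so no test
#' record influences training or checkpoint selection), and the held-out
#' fold is scored. Fold seeds derive from `seed + fold`.
#'
#' @param source,target `domain_dataset` objects; the plan's ids must refer
#'   to target records.
#' @param plan A [make_cv_plan()] over the target record ids.
#' @param model_config A [model_config()].
#' @param train_config A [train_config()].
#' @param mode Operating mode passed to [init_model()].
#' @param weights Loss weights.
#' @param seed Master seed; fold f trains with seed `seed + f`.
#' @return List with `folds` (tibble of per-fold metric reports) and `mean`
#'   (one-row tibble of unweighted arithmetic means across folds).
#' @export
run_cross_validation <- function(source, target, plan,
                                 model_config = model_config(),
                                 train_config = train_config(),
                                 mode = c("dual_classifier",
                                          "source_only_classifier"),
                                 weights = loss_weights(), seed = 1) {
  mode <- match.arg(mode)
  ids <- target$provenance$id
  if (!all(plan$assignment$id %in% ids)) {
    abort("plan ids are not a subset of the target dataset's ids")
  }
  reports <- list()
  for (f in plan$folds$fold) {
    fi <- cv_fold_ids(plan, f)
    test_idx <- which(ids %in% fi$test)
    train_idx <- which(ids %in% fi$train)
    stopifnot(length(intersect(test_idx, train_idx)) == 0)
    test_ds <- dataset_subset(target, test_idx)
    if (length(unique(test_ds$labels)) < 2) {
      warn(sprintf("fold %d has a single-class test set; skipped", f))
      next
    }
    fold_seed <- derive_seed(seed, 500L + f)
    tc <- train_config; tc$seed <- fold_seed
    model <- init_model(model_config, mode = mode, seed = fold_seed,
                        weights = weights)
    fit <- train_dsn(model, source, dataset_subset(target, train_idx), tc)
    clf <- if (mode == "dual_classifier") "target" else "source"
    scores <- predict(fit$model, test_ds$encoded, classifier = clf)$score
    reports[[length(reports) + 1L]] <-
      dplyr::mutate(compute_metrics(scores, test_ds$labels), fold = f,
                    .before = 1)
  }
  if (length(reports) == 0) abort("no fold produced a usable test set")
  folds <- dplyr::bind_rows(reports)
  metric_cols <- c("acc", "spe", "pre", "recall", "f1", "auc", "ap")
  mean_row <- dplyr::summarise(folds, dplyr::across(dplyr::all_of(metric_cols),
                                                    ~ mean(.x, na.rm = TRUE)))
  list(folds = folds, mean = mean_row)
}

#' Fit a classical baseline on flattened one-hot features
#'
#' The source-only comparison harness: the named off-the-shelf classifier is
#' fitted on the training domain's flattened `L x 4` one-hot windows and
#' scored on the test domain. Available baselines: naive Bayes and SVM
#' (e1071), ridge-penalised logistic regression (glmnet), k-nearest
#' neighbours (class), random forest (ranger) and gradient-boosted trees
#' (xgboost).
#'
#' @param name One of `"naive_bayes"`, `"logistic"`, `"knn"`, `"svm"`,
#'   `"random_forest"`, `"xgboost"`.
#' @param train,test `domain_dataset` objects.
#' @param seed Integer seed for the stochastic learners.
#' @return One-row metrics tibble (see [compute_metrics()]) with a `model`
#'   column.
#' @export
run_baseline <- function(name, train, test, seed = 1) {
  known <- c("naive_bayes", "logistic", "knn", "svm", "random_forest",
             "xgboost")
  if (!name %in% known) {
    abort(sprintf("unknown baseline '%s'; options: %s", name,
                  paste(known, collapse = ", ")))
  }
  scores <- baseline_scores(name, train, test, seed)
  dplyr::mutate(compute_metrics(scores, test$labels), model = name,
                .before = 1)
}

baseline_scores <- function(name, train, test, seed = 1) {
  Xtr <- as_flat_matrix(train$encoded)
  Xte <- as_flat_matrix(test$encoded)
  ytr <- factor(train$labels, levels = c(0, 1))
  with_seed(seed, switch(name,
    naive_bayes = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      as.numeric(stats::predict(fit, Xte, type = "raw")[, "1"])
    },
    logistic = {
      fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                            lambda = 1e-3)
      as.numeric(stats::predict(fit, Xte, type = "response"))
    },
    knn = {
      pr <- class::knn(Xtr, Xte, ytr, k = 5, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    },
    svm = {
      # constant (all-zero) one-hot columns trip e1071's internal scaling
      fit <- suppressWarnings(
        e1071::svm(Xtr, ytr, kernel = "radial", probability = TRUE))
      suppressWarnings(
        attr(stats::predict(fit, Xte, probability = TRUE),
             "probabilities")[, "1"])
    },
    random_forest = {
      df <- as.data.frame(Xtr)
      fit <- ranger::ranger(x = df, y = ytr, probability = TRUE,
                            num.trees = 300, seed = seed)
      stats::predict(fit, as.data.frame(Xte))$predictions[, "1"]
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(Xtr, label = train$labels)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 4,
                      eta = 0.3, nthread = 1, seed = seed),
        data = dtrain, nrounds = 100, verbose = 0)
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(Xte)))
    }
  ))
}
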