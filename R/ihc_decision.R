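# Slide-level IHC-request decision: split protocol, gradient-boosted trees,
# ROC metrics, agreement with annotators, and operating-point selection.

#' Build the three training/test splits
#'
#' Each of `n_folds` splits draws a stratified training set of distinct
#' slides holding the control:ordered ratio at `control_ratio`, and assigns
#' every slide outside the split to that fold's test set. For the reference
#' corpus size of 299 slides this gives 200 train (57 control : 143
#' ordered) and 99 test slides per fold. Scaled-down corpora keep the same
#' 200/299 train fraction and ratio. Deterministic per seed.
#'
#' @param manifest Manifest data frame with `slide_id` and `role` columns
#'   (`ordered` / `control`; validation slides are ignored).
#' @param seed Integer seed.
#' @param n_folds Number of independent splits (default 3).
#' @param control_ratio Control:ordered ratio in the training set.
#' @param train_size Training-set size; default scales 200/299 to the
#'   corpus.
#' @return Object of class `split_plan`: list of folds, each with
#'   `train_ids` and `test_ids`.
#' @export
make_splits <- function(manifest, seed = 0L, n_folds = 3L,
                        control_ratio = 0.4, train_size = NULL) {
  dev <- manifest[manifest$role %in% c("ordered", "control"), , drop = FALSE]
  n <- nrow(dev)
  if (is.null(train_size)) train_size <- round(n * 200 / 299)
  n_ctrl_train <- round(train_size * control_ratio / (1 + control_ratio))
  n_ord_train <- train_size - n_ctrl_train
  ctrl_ids <- dev$slide_id[dev$role == "control"]
  ord_ids <- dev$slide_id[dev$role == "ordered"]
  if (length(ctrl_ids) < n_ctrl_train || length(ord_ids) < n_ord_train) {
    abort(sprintf(
      "corpus cannot satisfy the split: need %d control and %d ordered slides in training, have %d and %d",
      n_ctrl_train, n_ord_train, length(ctrl_ids), length(ord_ids)),
      "ihctriage_config_error")
  }
  folds <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    set.seed(derive_seed(seed, k))
    train <- c(sample(ctrl_ids, n_ctrl_train), sample(ord_ids, n_ord_train))
    folds[[k]] <- list(train_ids = sort(train),
                       test_ids = sort(setdiff(dev$slide_id, train)))
  }
  structure(list(folds = folds, seed = seed, control_ratio = control_ratio,
                 train_size = train_size), class = "split_plan")
}

#' Decision model configuration
#'
#' Gradient-boosted trees hyperparameters.
#'
#' @param n_trees Boosting rounds (>= 1).
#' @param max_depth Tree depth.
#' @param learning_rate Shrinkage eta.
#' @param subsample Row subsampling fraction per round.
#' @param colsample Feature subsampling fraction per tree — the "random" in
#'   random-boosted trees; with ~8D + 6 features and desk-scale slide
#'   counts it keeps single spurious statistics from dominating.
#' @param seed RNG seed.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(n_trees = 200L, max_depth = 3L,
                            learning_rate = 0.1, subsample = 0.8,
                            colsample = 0.5, seed = 0L) {
  if (n_trees < 1) abort("n_trees must be >= 1", "ihctriage_config_error")
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, subsample = subsample,
                 colsample = colsample, seed = as.integer(seed)),
            class = "decision_config")
}

decision_feature_matrix <- function(features) {
  cols <- setdiff(names(features), "slide_id")
  as.matrix(features[, cols, drop = FALSE])
}

#' Train the IHC-request decision model
#'
#' Fits gradient-boosted trees on slide feature vectors to predict whether
#' IHC should be ordered. Reproducible per seed (single-threaded).
#'
#' @param features Slide feature table ([slide_feature_table()] format,
#'   `slide_id` column optional).
#' @param labels 0/1 (or logical) vector: IHC requested.
#' @param config A [decision_config()].
#' @return Object of class `ihc_decision_model`.
#' @export
train_decision <- function(features, labels, config = decision_config()) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) {
    abort("both classes must be present to train the decision model",
          "ihctriage_input_error")
  }
  X <- decision_feature_matrix(features)
  set.seed(config$seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = labels, nthread = 1L)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = config$max_depth,
                  eta = config$learning_rate,
                  subsample = config$subsample,
                  colsample_bytree = config$colsample,
                  nthread = 1L,
                  seed = config$seed),
    data = dtrain,
    nrounds = config$n_trees
  )
  structure(list(booster = booster, feature_names = colnames(X),
                 config = config),
            class = "ihc_decision_model")
}

#' Predict per-slide IHC-request probabilities
#'
#' @param model An `ihc_decision_model`.
#' @param features Feature table with the training schema.
#' @return Numeric vector of probabilities in `[0, 1]` (empty for empty
#'   input).
#' @export
predict_decision <- function(model, features) {
  if (nrow(features) == 0L) return(numeric(0))
  X <- decision_feature_matrix(features)
  missing <- setdiff(model$feature_names, colnames(X))
  if (length(missing)) {
    abort(paste("feature columns missing:", paste(missing, collapse = ", ")),
          "ihctriage_schema_error")
  }
  X <- X[, model$feature_names, drop = FALSE]
  as.numeric(stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1L)))
}

#' Accuracy, AUC and ROC curve for binary scores
#'
#' AUC is the probability that a random positive outscores a random
#' negative with ties counted 0.5 (the Mann-Whitney statistic, equal to the
#' trapezoidal area under the ROC). Accuracy is computed at `threshold`
#' with the rule "positive if score >= threshold". With single-class labels
#' the accuracy is still returned and the AUC is `NA` with a warning.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) labels.
#' @param threshold Decision threshold for accuracy.
#' @return List with `accuracy`, `auc`, and `roc` (data frame of
#'   `threshold`, `sensitivity`, `specificity`, sorted by threshold
#'   descending).
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  acc <- mean((scores >= threshold) == (labels == 1L))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: labels contain a single class")
    return(list(accuracy = acc, auc = NA_real_,
                roc = data.frame(threshold = numeric(0), sensitivity = numeric(0),
                                 specificity = numeric(0))))
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos, numeric(1)),
    specificity = vapply(thr, function(t) sum(scores < t & labels == 0L) / n_neg, numeric(1))
  )
  list(accuracy = acc, auc = auc, roc = roc)
}

#' Per-annotator validation agreement reference values
#'
#' Accuracy and AUC of the slide-level decision against each of the three
#' annotating pathologists on the clinical validation audit. These are
#' fixed reference inputs (the clinical cohort itself is not distributable);
#' [agreement_summary()] recomputes the summary means from them.
#'
#' @return Data frame with `pathologist`, `accuracy`, `auc`.
#' @export
validation_agreement_table <- function() {
  data.frame(pathologist = 1:3,
             accuracy = c(0.979, 0.764, 0.674),
             auc = c(0.977, 0.737, 0.681))
}

#' Mean agreement across annotators
#'
#' Arithmetic means of per-annotator accuracy and AUC; reported at 2
#' decimals, full precision retained.
#'
#' @param per_pathologist Data frame with `accuracy` and `auc` columns.
#' @return List with `mean_accuracy`, `mean_auc` (full precision) and
#'   `reported` (2-decimal rounding of each).
#' @export
agreement_summary <- function(per_pathologist = validation_agreement_table()) {
  if (!nrow(per_pathologist)) abort("need at least one annotator", "ihctriage_input_error")
  ma <- mean(per_pathologist$accuracy)
  mu <- mean(per_pathologist$auc)
  list(mean_accuracy = ma, mean_auc = mu,
       reported = c(mean_accuracy = round_half_up(ma * 100) / 100,
                    mean_auc = round_half_up(mu * 100) / 100))
}

#' Select ROC operating points at target specificities
#'
#' For each target specificity picks the smallest threshold on the curve
#' whose specificity is at least the target (the most sensitive point
#' meeting the specificity floor). When annotator reference label sets are
#' supplied, the average false-positive rate at the chosen threshold is the
#' mean over sets of FP / (total slides).
#'
#' @param curve ROC data frame from [binary_metrics()].
#' @param target_specificities Numeric vector of specificity floors.
#' @param scores Slide scores (needed for `avg_false_positive_rate`).
#' @param annotator_labels List of 0/1 label vectors, one per annotator.
#' @return Data frame of operating points: `label`, `target_specificity`,
#'   `threshold`, `sensitivity`, `specificity`, and
#'   `avg_false_positive_rate` when reference sets are given.
#' @export
select_operating_points <- function(curve, target_specificities,
                                    scores = NULL, annotator_labels = NULL) {
  if (!nrow(curve)) abort("empty ROC curve", "ihctriage_input_error")
  out <- vector("list", length(target_specificities))
  for (i in seq_along(target_specificities)) {
    s <- target_specificities[i]
    ok <- curve[curve$specificity >= s, , drop = FALSE]
    if (!nrow(ok)) {
      abort(sprintf("specificity %.3f unreachable; maximum achievable is %.3f",
                    s, max(curve$specificity)), "ihctriage_input_error")
    }
    pick <- ok[which.min(ok$threshold), , drop = FALSE]
    row <- data.frame(label = sprintf("point_%d", i), target_specificity = s,
                      threshold = pick$threshold, sensitivity = pick$sensitivity,
                      specificity = pick$specificity)
    if (!is.null(scores) && !is.null(annotator_labels)) {
      fprs <- vapply(annotator_labels, function(lab) {
        lab <- as.integer(as.logical(lab))
        sum(scores >= pick$threshold & lab == 0L) / length(lab)
      }, numeric(1))
      row$avg_false_positive_rate <- mean(fprs)
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Evaluate the decision model over a split plan
#'
#' Trains one decision model per fold on the training slides and reports
#' per-fold accuracy and AUC on the held-out slides, plus their means.
#'
#' @param features Slide feature table with `slide_id`.
#' @param labels Named 0/1 vector of IHC-requested labels (names =
#'   slide ids).
#' @param plan A `split_plan`.
#' @param config A [decision_config()].
#' @return List with `per_fold` (data frame) and `mean_accuracy`,
#'   `mean_auc`.
#' @export
evaluate_decision <- function(features, labels, plan,
                              config = decision_config()) {
  per <- vector("list", length(plan$folds))
  for (k in seq_along(plan$folds)) {
    f <- plan$folds[[k]]
    tr <- features[match(f$train_ids, features$slide_id), , drop = FALSE]
    te <- features[match(f$test_ids, features$slide_id), , drop = FALSE]
    model <- train_decision(tr, labels[f$train_ids], config)
    sc <- predict_decision(model, te)
    met <- binary_metrics(sc, labels[f$test_ids])
    per[[k]] <- data.frame(fold = k, accuracy = met$accuracy, auc = met$auc)
  }
  per <- do.call(rbind, per)
  list(per_fold = per, mean_accuracy = mean(per$accuracy), mean_auc = mean(per$auc))
}
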