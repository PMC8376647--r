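synthetic_manifest <- function(n_ordered = 219, n_control = 80) {
  data.frame(
    slide_id = sprintf("s%03d", seq_len(n_ordered + n_control)),
    image_path = "x.png", annotation_path = "x.geojson",
    role = c(rep("ordered", n_ordered), rep("control", n_control)),
    ihc_needed = c(rep(1L, n_ordered), rep(0L, n_control)),
    diagnosis = "unknown", um_per_px = 4, stringsAsFactors = FALSE)
}

test_that("splits honour the 200/99 partition and the 0.4 control ratio", {
  m <- synthetic_manifest()
  plan <- make_splits(m, seed = 1)
  expect_length(plan$folds, 3L)
  for (f in plan$folds) {
    expect_length(f$train_ids, 200L)
    expect_length(f$test_ids, 99L)
    expect_length(intersect(f$train_ids, f$test_ids), 0L)
    expect_setequal(c(f$train_ids, f$test_ids), m$slide_id)
    roles <- m$role[match(f$train_ids, m$slide_id)]
    expect_equal(sum(roles == "control"), 57L)
    expect_equal(sum(roles == "ordered"), 143L)
  }
  # deterministic per seed, different across seeds
  expect_identical(make_splits(m, seed = 1), plan)
  expect_false(identical(make_splits(m, seed = 2)$folds[[1]]$train_ids,
                         plan$folds[[1]]$train_ids))
  expect_error(make_splits(synthetic_manifest(10, 1)), "cannot satisfy")
})

test_that("accuracy and AUC follow the pairwise definition with ties at 0.5", {
  m <- binary_metrics(c(0.9, 0.8, 0.4), c(1, 1, 0))
  expect_equal(m$auc, 1.0)
  expect_equal(m$accuracy, 1.0)
  expect_equal(binary_metrics(c(0.9, 0.8, 0.8, 0.1), c(1, 0, 1, 0))$auc, 0.875)
  expect_equal(binary_metrics(c(0.1, 0.2, 0.9), c(1, 1, 0))$auc, 0.0)
  expect_warning(s <- binary_metrics(c(0.2, 0.9), c(1, 1)), "single class")
  expect_true(is.na(s$auc))
  expect_equal(s$accuracy, 0.5)
  # ROC invariants
  roc <- binary_metrics(runif(20), rbinom(20, 1, 0.5) | c(1, rep(0, 19)))$roc
  expect_true(all(diff(roc$threshold) <= 0))
  expect_true(all(diff(roc$sensitivity) >= 0))
})

test_that("trapezoidal/rank AUC equals the brute-force pair oracle exactly", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_identical(binary_metrics(scores, labels)$auc,
                     pairwise_auc(scores, labels))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- runif(50); labels <- rbinom(50, 1, 0.4)
  labels[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(binary_metrics(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("agreement means reproduce the reference summary", {
  s <- agreement_summary(validation_agreement_table())
  expect_equal(unname(s$reported["mean_accuracy"]), 0.81)
  expect_equal(unname(s$reported["mean_auc"]), 0.80)
  one <- agreement_summary(data.frame(accuracy = 0.7, auc = 0.6))
  expect_equal(one$mean_accuracy, 0.7)
  expect_equal(one$mean_auc, 0.6)
  expect_error(agreement_summary(data.frame(accuracy = numeric(0), auc = numeric(0))),
               "at least one")
})

test_that("operating points match an exhaustive threshold scan", {
  scores <- c(0.95, 0.9, 0.7, 0.6, 0.4, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0)
  met <- binary_metrics(scores, labels)
  # brute-force oracle over every candidate threshold
  scan <- function(s_target) {
    cand <- c(Inf, sort(unique(scores), decreasing = TRUE))
    best <- NULL
    for (t in cand) {
      spec <- sum(scores < t & labels == 0) / sum(labels == 0)
      if (spec >= s_target && (is.null(best) || t < best)) best <- t
    }
    best
  }
  for (s in c(0, 0.5, 0.75, 1)) {
    op <- select_operating_points(met$roc, s)
    expect_equal(op$threshold, scan(s), label = paste("target", s))
  }
  # perfect classifier keeps sensitivity 1 at specificity 0.9
  perfect <- binary_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(select_operating_points(perfect$roc, 0.9)$sensitivity, 1.0)
  # target 0 picks the lowest threshold and maximal sensitivity
  low <- select_operating_points(met$roc, 0)
  expect_equal(low$threshold, min(met$roc$threshold))
  expect_equal(low$sensitivity, max(met$roc$sensitivity))
  # monotone: sensitivity non-increasing in target specificity
  sens <- select_operating_points(met$roc, c(0, 0.4, 0.7, 1))$sensitivity
  expect_true(all(diff(sens) <= 0))
  expect_error(select_operating_points(met$roc[met$roc$specificity < 0.9, ], 0.95),
               "unreachable")
  # average false-positive rate over annotator reference sets
  ann <- list(c(1, 1, 0, 1, 0, 0), c(1, 0, 0, 1, 0, 0))
  op <- select_operating_points(met$roc, 0.5, scores = scores, annotator_labels = ann)
  t <- op$threshold
  fprs <- sapply(ann, function(l) sum(scores >= t & l == 0) / length(l))
  expect_equal(op$avg_false_positive_rate, mean(fprs))
})

test_that("decision model separates the shifted fixture and not the null one", {
  fx <- make_tile_feature_fixture(n_slides = 200, tiles_per_slide = 20, D = 8,
                                  delta = 6, seed = 2)
  preds <- fixture_slide_predictions(fx)
  tab <- slide_feature_table(preds)
  lab <- attr(preds, "ihc_needed")[tab$slide_id]
  idx <- seq_len(120)
  model <- train_decision(tab[idx, ], lab[idx], decision_config(seed = 1))
  p_tr <- predict_decision(model, tab[idx, ])
  expect_gte(binary_metrics(p_tr, lab[idx])$auc, 0.99)
  expect_gte(mean((p_tr >= 0.5) == lab[idx]), 0.99)
  p_te <- predict_decision(model, tab[-idx, ])
  expect_gte(binary_metrics(p_te, lab[-idx])$auc, 0.95)
  # null fixture: held-out AUC hovers around chance
  fx0 <- make_tile_feature_fixture(n_slides = 200, tiles_per_slide = 20, D = 8,
                                   delta = 0, seed = 2)
  preds0 <- fixture_slide_predictions(fx0)
  tab0 <- slide_feature_table(preds0)
  lab0 <- attr(preds0, "ihc_needed")[tab0$slide_id]
  model0 <- train_decision(tab0[idx, ], lab0[idx], decision_config(seed = 1))
  p0 <- predict_decision(model0, tab0[-idx, ])
  a0 <- binary_metrics(p0, lab0[-idx])$auc
  expect_gte(a0, 0.35); expect_lte(a0, 0.65)
})

test_that("decision predictions are pure, schema-checked and reproducible", {
  fx <- make_tile_feature_fixture(n_slides = 30, tiles_per_slide = 8, D = 4,
                                  delta = 3, seed = 4)
  preds <- fixture_slide_predictions(fx)
  tab <- slide_feature_table(preds)
  lab <- attr(preds, "ihc_needed")[tab$slide_id]
  m1 <- train_decision(tab, lab, decision_config(seed = 7))
  m2 <- train_decision(tab, lab, decision_config(seed = 7))
  expect_identical(predict_decision(m1, tab), predict_decision(m2, tab))
  expect_equal(predict_decision(m1, tab[integer(0), ]), numeric(0))
  dup <- predict_decision(m1, tab[c(3, 3), ])
  expect_identical(dup[1], dup[2])
  expect_error(predict_decision(m1, tab[, 1:10]), "missing")
  expect_error(train_decision(tab, rep(1, nrow(tab)), decision_config()),
               "both classes")
  p <- predict_decision(m1, tab)
  expect_true(all(p >= 0 & p <= 1))
})
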