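test_that("mean probabilities, labels, entropy and uncertainty follow closed forms", {
  p <- hand_predictions(cbind(0.1, 0.3, 0.2))
  expect_equal(as.numeric(p$mean_probs), c(0.8, 0.2))
  expect_equal(p$label, "certain")
  # tie at 0.5 resolves to ambiguous
  tie <- hand_predictions(cbind(0.5))
  expect_equal(tie$label, "ambiguous")
  expect_equal(tie$entropy, 1.0)
  sure <- hand_predictions(cbind(0, 0, 0))
  expect_equal(sure$entropy, 0.0)
  expect_equal(sure$member_variance, 0.0)
  # member variance is zero exactly when members agree
  agree <- hand_predictions(cbind(0.3, 0.3, 0.3))
  expect_identical(agree$member_variance, 0)
  disagree <- hand_predictions(cbind(0.2, 0.4))
  expect_gt(disagree$member_variance, 0)
  expect_equal(disagree$member_variance, mean((c(0.2, 0.4) - 0.3)^2))
  # surrogate loss is the cross-entropy of the mean row against its argmax
  expect_equal(p$surrogate_loss, -log(0.8))
  expect_equal(tie$surrogate_loss, -log(0.5))
})

test_that("softmax normalization survives every averaging step", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:6, 1); k <- sample(1:4, 1)
    p_amb <- matrix(runif(n * k), n, k)
    preds <- hand_predictions(p_amb)
    expect_true(all(abs(rowSums(preds$mean_probs) - 1) < 1e-6))
    for (m in preds$member_probs) expect_true(all(abs(rowSums(m) - 1) < 1e-6))
    expect_true(all(preds$member_variance >= 0))
    expect_true(all(preds$entropy >= 0 & preds$entropy <= 1 + 1e-12))
    # label maps through the monotone 0.5 threshold
    expect_identical(preds$label == "ambiguous", preds$mean_probs[, 2] >= 0.5)
  }
  expect_error(tile_predictions(cbind(0.4, 0.4), matrix(0, 1, 2)), "summing to 1")
})

test_that("focus aggregation averages tiles and ignores their order", {
  bundle_free <- hand_predictions(cbind(c(0.1, 0.6)))  # tiles (0.9,0.1), (0.4,0.6)
  fp <- predict_focus(NULL, bundle_free)
  expect_equal(as.numeric(fp$mean_probs), c(0.65, 0.35))
  expect_equal(fp$label, "certain")
  single <- bundle_free[1]
  fps <- predict_focus(NULL, single)
  expect_equal(as.numeric(fps$mean_probs), as.numeric(single$mean_probs[1, ]))
  perm <- bundle_free[c(2, 1)]
  expect_identical(predict_focus(NULL, perm)$mean_probs, fp$mean_probs)
  expect_error(predict_focus(NULL, bundle_free[integer(0)]), "at least one tile")
})

test_that("training is deterministic, validates labels, and a lone member has zero variance", {
  ts <- labelled_gland_tiles(24)
  cfg <- ensemble_config(n_members = 2L, epochs = 2L, seed = 9)
  b1 <- train_ensemble(ts$tiles, ts$labels, cfg, augmentation_config())
  b2 <- train_ensemble(ts$tiles, ts$labels, cfg, augmentation_config())
  expect_identical(b1$train_log, b2$train_log)
  expect_identical(b1$members, b2$members)
  expect_equal(nrow(b1$train_log), 4L)  # member x epoch
  expect_error(train_ensemble(ts$tiles, rep("certain", length(ts$tiles)),
                              cfg, augmentation_config()), "both classes")
  solo <- train_ensemble(ts$tiles, ts$labels,
                         ensemble_config(n_members = 1L, epochs = 2L, seed = 9),
                         augmentation_config())
  p <- predict_tiles(solo, ts$tiles[1:4])
  expect_true(all(p$member_variance == 0))
  expect_error(ensemble_config(n_members = 2, member_seeds = c(1L, 1L)), "distinct")
})

test_that("ensemble recovers ambiguous-vs-certain morphology on held-out tiles", {
  tr <- labelled_gland_tiles(160, seed = 5)
  te <- labelled_gland_tiles(60, seed = 6)
  cfg <- ensemble_config(n_members = 2L, epochs = 10L, seed = 1)
  bundle <- train_ensemble(tr$tiles, tr$labels, cfg)
  preds <- predict_tiles(bundle, te$tiles)
  acc <- mean(preds$label == te$labels)
  expect_gte(acc, 0.85)
  m <- binary_metrics(preds$mean_probs[, 2], te$labels == "ambiguous")
  expect_gte(m$auc, 0.9)
  expect_equal(ncol(preds$embedding), cfg$embedding_dim)
  # empty tile list is an empty prediction, not an error
  empty <- predict_tiles(bundle, list())
  expect_equal(empty$n, 0L)
})

test_that("bundles round-trip through disk", {
  ts <- labelled_gland_tiles(16)
  cfg <- ensemble_config(n_members = 2L, epochs = 2L, seed = 4)
  bundle <- train_ensemble(ts$tiles, ts$labels, cfg, augmentation_config())
  dir <- tempfile()
  save_bundle(bundle, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  expect_true(file.exists(file.path(dir, "train_log.csv")))
  back <- load_bundle(dir)
  p1 <- predict_tiles(bundle, ts$tiles[1:3])
  p2 <- predict_tiles(back, ts$tiles[1:3])
  expect_equal(p2$mean_probs, p1$mean_probs, tolerance = 1e-12)
  expect_equal(p2$embedding, p1$embedding, tolerance = 1e-12)
})
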