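# End-to-end orchestration: synthesize -> mask -> tile -> train -> features
# -> decide -> evaluate -> econ, from one config with one master seed.

PIPELINE_STAGES <- c("synth", "mask", "tile", "train", "features",
                     "decide", "evaluate", "econ")

#' Pipeline run configuration
#'
#' One config object with per-stage sections and a single master seed from
#' which all stage and member seeds are derived.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param stages Stages to execute; must be a prefix of
#'   `synth, mask, tile, train, features, decide, evaluate, econ`.
#' @param synth A [synth_config()] (seed is overridden by the master seed).
#' @param grid A [tile_grid()].
#' @param ensemble An [ensemble_config()].
#' @param decision A [decision_config()].
#' @param econ An [econ_params()].
#' @param phi Focus-overlap fraction defining focus tiles in training
#'   and evaluation (0.5: tiles dominated by the focus).
#' @param max_certain_ratio Optional cap on the certain:ambiguous
#'   training-tile ratio (default uncapped: all labelled tiles are used).
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 0L, stages = PIPELINE_STAGES,
                       synth = synth_config(), grid = tile_grid(),
                       ensemble = ensemble_config(), decision = decision_config(),
                       econ = econ_params(), phi = 0.5, max_certain_ratio = Inf) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown)) {
    abort(paste("unknown stage(s):", paste(unknown, collapse = ", ")),
          "ihctriage_config_error")
  }
  if (!identical(stages, PIPELINE_STAGES[seq_along(stages)])) {
    abort("stages must form a prefix of the pipeline order", "ihctriage_config_error")
  }
  synth$seed <- as.integer(seed)
  ensemble$seed <- derive_seed(seed, 2)
  ensemble$member_seeds <- vapply(seq_len(ensemble$n_members),
                                  function(m) derive_seed(ensemble$seed, 100 + m),
                                  integer(1))
  decision$seed <- derive_seed(seed, 3)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 synth = synth, grid = grid, ensemble = ensemble,
                 decision = decision, econ = econ, phi = phi,
                 max_certain_ratio = max_certain_ratio),
            class = "run_config")
}

slide_record_from_manifest <- function(row, dir, dims) {
  slide_record(row$slide_id, file.path(dir, row$image_path), row$um_per_px, dims)
}

load_truth_mask <- function(row, dir) {
  m <- png::readPNG(file.path(dir, row$tissue_mask_path))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(list(mask = (m > 0.5) * 1L, um_per_px = row$um_per_px),
            class = "tissue_mask")
}

#' Run the triage pipeline
#'
#' Executes the configured stage prefix in order, persisting every
#' intermediate artifact under `config$out_dir` and returning (and writing)
#' a run report with per-stage timings, artifact paths and metric
#' summaries. A rerun with the same config and seed reproduces the
#' deterministic artifacts bit-exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, the run report (list); also written to `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list(), artifacts = list(),
                 metrics = list(),
                 config = list(n_slides = config$synth$n_slides,
                               tile_px = config$grid$tile_px,
                               n_members = config$ensemble$n_members,
                               epochs = config$ensemble$epochs))
  state <- new.env(parent = emptyenv())
  for (stage in config$stages) {
    t0 <- Sys.time()
    ok <- tryCatch({
      do.call(paste0("stage_", stage), list(config, state, report))
    }, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "ihctriage_stage_error")
    })
    report <- ok
    report$stages[[stage]] <- list(
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  }
  write_report(report, file.path(config$out_dir, "report.json"))
  invisible(report)
}

stage_synth <- function(config, state, report) {
  synth_dir <- file.path(config$out_dir, "synth")
  res <- generate_cohort(config$synth, synth_dir)
  state$manifest <- res$manifest
  state$synth_dir <- synth_dir
  report$artifacts$manifest <- file.path("synth", "manifest.csv")
  report
}

stage_mask <- function(config, state, report) {
  mask_dir <- file.path(config$out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  m <- state$manifest
  state$masks <- list(); state$images <- list()
  ious <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    img <- read_slide_image(file.path(state$synth_dir, m$image_path[i]))
    mask <- segment_tissue(img, um_per_px = m$um_per_px[i])
    truth <- load_truth_mask(m[i, ], state$synth_dir)
    inter <- sum(mask$mask & truth$mask); uni <- sum(mask$mask | truth$mask)
    ious[i] <- if (uni > 0) inter / uni else 1
    png::writePNG(mask$mask * 1.0, file.path(mask_dir, paste0(m$slide_id[i], ".png")))
    state$masks[[m$slide_id[i]]] <- mask
  }
  report$metrics$tissue_iou_mean <- mean(ious)
  report$metrics$tissue_iou_min <- min(ious)
  report$artifacts$masks <- "masks"
  report
}

stage_tile <- function(config, state, report) {
  m <- state$manifest
  tiles <- vector("list", nrow(m))
  state$slides <- list()
  for (i in seq_len(nrow(m))) {
    sl <- slide_record_from_manifest(m[i, ], state$synth_dir, config$synth$image_size)
    state$slides[[m$slide_id[i]]] <- sl
    tiles[[i]] <- extract_tiles(sl, state$masks[[m$slide_id[i]]], config$grid)
  }
  state$tiles <- do.call(rbind, tiles)
  utils::write.csv(state$tiles, file.path(config$out_dir, "tiles.csv"),
                   row.names = FALSE)
  report$artifacts$tiles <- "tiles.csv"
  report
}

# Collect labelled training tiles for one set of slide ids: focus tiles are
# ambiguous, non-focus tissue tiles (and all control tissue tiles) certain.
collect_labelled_tiles <- function(config, state, ids, cap_certain = TRUE) {
  m <- state$manifest
  tiles <- list(); labels <- character(0)
  certain_pool <- list()
  for (id in ids) {
    row <- m[m$slide_id == id, ]
    sl <- state$slides[[id]]
    img <- read_slide_image(sl$image_path)
    foci <- read_annotations(file.path(state$synth_dir, row$annotation_path))
    slide_tiles <- state$tiles[state$tiles$slide_id == id, , drop = FALSE]
    focus_keys <- character(0)
    for (f in foci) {
      ft <- tiles_for_focus(f, sl, config$grid, phi = config$phi)
      for (j in seq_len(nrow(ft))) {
        key <- paste(ft$x[j], ft$y[j])
        if (key %in% focus_keys) next
        focus_keys <- c(focus_keys, key)
        tiles[[length(tiles) + 1L]] <- load_tile(ft[j, ], sl, image = img)
        labels <- c(labels, "ambiguous")
      }
    }
    for (j in seq_len(nrow(slide_tiles))) {
      key <- paste(slide_tiles$x[j], slide_tiles$y[j])
      if (key %in% focus_keys) next
      certain_pool[[length(certain_pool) + 1L]] <-
        load_tile(slide_tiles[j, ], sl, image = img)
    }
  }
  n_amb <- sum(labels == "ambiguous")
  n_cert <- length(certain_pool)
  if (cap_certain && n_amb > 0 && n_cert > config$max_certain_ratio * n_amb) {
    keep <- sort(sample.int(n_cert, ceiling(config$max_certain_ratio * n_amb)))
    certain_pool <- certain_pool[keep]
  }
  list(tiles = c(tiles, certain_pool),
       labels = c(labels, rep("certain", length(certain_pool))))
}

stage_train <- function(config, state, report) {
  m <- state$manifest
  plan <- make_splits(m, seed = derive_seed(config$seed, 4))
  state$plan <- plan
  fold <- plan$folds[[1]]
  set.seed(derive_seed(config$seed, 5))
  train_set <- collect_labelled_tiles(config, state, fold$train_ids)
  if (length(unique(train_set$labels)) < 2L) {
    abort("training tile set is single-class", "ihctriage_input_error")
  }
  state$bundle <- train_ensemble(train_set$tiles, train_set$labels,
                                 config$ensemble)
  save_bundle(state$bundle, file.path(config$out_dir, "bundle"))
  report$artifacts$bundle <- "bundle"
  report$metrics$n_training_tiles <- length(train_set$labels)
  report
}

stage_features <- function(config, state, report) {
  m <- state$manifest
  preds <- list()
  for (id in m$slide_id) {
    sl <- state$slides[[id]]
    img <- read_slide_image(sl$image_path)
    slide_tiles <- state$tiles[state$tiles$slide_id == id, , drop = FALSE]
    if (nrow(slide_tiles) == 0L) next
    rasters <- lapply(seq_len(nrow(slide_tiles)),
                      function(j) load_tile(slide_tiles[j, ], sl, image = img))
    preds[[id]] <- predict_tiles(state$bundle, rasters, tile_refs = slide_tiles)
  }
  state$preds <- preds
  state$features <- slide_feature_table(preds)
  utils::write.csv(state$features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)
  report$artifacts$features <- "features.csv"
  report
}

stage_decide <- function(config, state, report) {
  m <- state$manifest
  labels <- stats::setNames(m$ihc_needed, m$slide_id)
  fold <- state$plan$folds[[1]]
  tr <- state$features[state$features$slide_id %in% fold$train_ids, , drop = FALSE]
  model <- train_decision(tr, labels[tr$slide_id], config$decision)
  state$model <- model
  scores <- predict_decision(model, state$features)
  state$decisions <- data.frame(slide_id = state$features$slide_id,
                                p_ihc = scores,
                                ihc_needed = labels[state$features$slide_id],
                                in_train = state$features$slide_id %in% fold$train_ids)
  utils::write.csv(state$decisions, file.path(config$out_dir, "decisions.csv"),
                   row.names = FALSE)
  report$artifacts$decisions <- "decisions.csv"
  report
}

stage_evaluate <- function(config, state, report) {
  fold <- state$plan$folds[[1]]
  # slide-level metrics on held-out slides
  te <- state$decisions[!state$decisions$in_train, , drop = FALSE]
  slide_met <- binary_metrics(te$p_ihc, te$ihc_needed)
  # tile-level metrics on held-out slides: focus tiles vs control tissue
  m <- state$manifest
  scores <- numeric(0); lab <- integer(0)
  for (id in fold$test_ids) {
    row <- m[m$slide_id == id, ]
    p <- state$preds[[id]]
    if (is.null(p)) next
    if (row$role == "control") {
      scores <- c(scores, p$mean_probs[, 2]); lab <- c(lab, rep(0L, p$n))
    } else {
      sl <- state$slides[[id]]
      foci <- read_annotations(file.path(state$synth_dir, row$annotation_path))
      keys <- paste(p$tiles$x, p$tiles$y)
      fkeys <- character(0)
      for (f in foci) {
        ft <- tiles_for_focus(f, sl, config$grid, phi = config$phi)
        fkeys <- union(fkeys, paste(ft$x, ft$y))
      }
      sel <- keys %in% fkeys
      scores <- c(scores, p$mean_probs[sel, 2]); lab <- c(lab, rep(1L, sum(sel)))
    }
  }
  tile_met <- binary_metrics(scores, lab)
  report$metrics$slide_auc <- slide_met$auc
  report$metrics$slide_accuracy <- slide_met$accuracy
  report$metrics$tile_auc <- tile_met$auc
  report$metrics$tile_accuracy <- tile_met$accuracy
  report$metrics$n_test_tiles <- length(lab)
  report$metrics$n_test_slides <- nrow(te)
  state$roc <- slide_met$roc
  utils::write.csv(slide_met$roc, file.path(config$out_dir, "roc.csv"),
                   row.names = FALSE)
  report$artifacts$roc <- "roc.csv"
  report
}

stage_econ <- function(config, state, report) {
  tab <- econ_table(config$econ)
  utils::write.csv(tab, file.path(config$out_dir, "econ_table.csv"),
                   row.names = FALSE)
  diffs <- audit_differences()
  agree <- agreement_summary()
  report$metrics$turnaround_diff_hours <- diffs$turnaround_diff_hours
  report$metrics$reporting_diff_minutes <- diffs$reporting_diff_minutes
  report$metrics$mean_validation_accuracy <- agree$reported[["mean_accuracy"]]
  report$metrics$mean_validation_auc <- agree$reported[["mean_auc"]]
  report$artifacts$econ_table <- "econ_table.csv"
  report
}

#' Write or read a run report
#'
#' Reports are plain JSON; artifact paths are relative to the run's output
#' directory so the report stays portable.
#'
#' @param report Report list from [run_pipeline()].
#' @param path JSON path.
#' @return `write_report`: `path` invisibly; `read_report`: the report list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
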