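# Shared fixtures, built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# A small synthetic cohort for I/O, tiling and label-consistency tests.
small_cohort <- function(n = 16L, seed = 11L) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    dir <- file.path(tempdir(), paste0("ihctriage_", key))
    cfg <- synth_config(n_slides = n, seed = seed)
    res <- generate_cohort(cfg, dir)
    .fixtures[[key]] <- list(config = cfg, manifest = res$manifest, dir = dir)
  }
  .fixtures[[key]]
}

cohort_slide <- function(cohort, i) {
  row <- cohort$manifest[i, ]
  slide_record(row$slide_id, file.path(cohort$dir, row$image_path),
               row$um_per_px, cohort$config$image_size)
}

# Hand-built tile predictions from explicit member ambiguous-probabilities.
# `p_amb` is an n x n_members matrix; embeddings default to standard normal.
hand_predictions <- function(p_amb, embedding = NULL, seed = 1L) {
  p_amb <- as.matrix(p_amb)
  member_probs <- lapply(seq_len(ncol(p_amb)),
                         function(m) cbind(1 - p_amb[, m], p_amb[, m]))
  if (is.null(embedding)) {
    set.seed(seed)
    embedding <- matrix(rnorm(nrow(p_amb) * 2L), nrow(p_amb), 2L)
  }
  tile_predictions(member_probs, embedding)
}

# Mann-Whitney AUC by brute force over all positive-negative pairs (tie = 0.5).
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Labelled gland-field tiles at ambiguous (mid) vs certain (extreme) alpha.
labelled_gland_tiles <- function(n, seed = 5L) {
  set.seed(seed)
  tiles <- vector("list", n); labels <- character(n)
  for (i in seq_len(n)) {
    amb <- i %% 2L == 0L
    a <- if (amb) runif(1, 0.35, 0.65)
         else if (runif(1) < 0.5) runif(1, 0.03, 0.15) else runif(1, 0.85, 0.97)
    tiles[[i]] <- render_gland_field(a)
    labels[i] <- if (amb) "ambiguous" else "certain"
  }
  list(tiles = tiles, labels = labels)
}
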