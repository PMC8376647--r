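# Slide-level feature aggregation.
#
# A slide is summarized by distribution statistics (median, mean, variance,
# excess kurtosis) of the tile embeddings, computed separately for tiles
# labelled ambiguous and for tiles labelled certain, plus the variance of
# the mean ambiguous-class probability and of the surrogate loss across all
# tiles of the slide. Slides can legitimately contain no tiles of one label,
# so empty groups are zero-filled and flagged.

#' Population excess kurtosis
#'
#' Uncorrected fourth-moment kurtosis `m4 / m2^2 - 3`, which is 0 for a
#' normal population. A constant sample (zero variance) returns 0 by
#' convention rather than 0/0.
#'
#' @param values Non-empty numeric sample.
#' @return Excess kurtosis.
#' @examples
#' kurtosis_excess(c(1, 2, 3, 4))   # -1.36
#' @export
kurtosis_excess <- function(values) {
  if (!length(values)) abort("empty sample", "ihctriage_input_error")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 < 1e-24) return(0)
  mean((values - m)^4) / m2^2 - 3
}

# Population variance (divides by n); 0 for a single observation.
var_pop <- function(values) {
  m <- mean(values)
  mean((values - m)^2)
}

group_block <- function(emb) {
  D <- ncol(emb)
  if (nrow(emb) == 0L) {
    return(list(stats = rep(0, 4 * D), flag = 1L, n = 0L))
  }
  med <- apply(emb, 2, stats::median)
  mu <- colMeans(emb)
  va <- apply(emb, 2, var_pop)
  ku <- apply(emb, 2, kurtosis_excess)
  list(stats = c(med, mu, va, ku), flag = 0L, n = nrow(emb))
}

#' Column names of the slide feature vector
#'
#' @param D Embedding dimension.
#' @return Character vector of length `8 * D + 6`.
#' @export
slide_feature_names <- function(D) {
  idx <- seq_len(D) - 1L
  block <- function(prefix) {
    c(paste0(prefix, "_median_", idx), paste0(prefix, "_mean_", idx),
      paste0(prefix, "_var_", idx), paste0(prefix, "_kurt_", idx))
  }
  c(block("amb"), block("cert"), "prob_var", "loss_var",
    "n_amb", "n_cert", "flag_amb_empty", "flag_cert_empty")
}

#' Compress tile predictions into the slide feature vector
#'
#' Computes the 4-statistic block (median, mean, population variance,
#' population excess kurtosis) per embedding dimension over the
#' ambiguous-labelled tiles and over the certain-labelled tiles, the
#' variance across all tiles of the mean ambiguous-class probability, the
#' variance of the surrogate loss, group counts and empty-group flags.
#' Permutation invariant and deterministic; vector length `8 * D + 6`.
#'
#' @param preds A `tile_predictions` object with at least one tile.
#' @return Named numeric vector (class `slide_feature_vector`).
#' @export
compute_slide_features <- function(preds) {
  stopifnot(inherits(preds, "tile_predictions"))
  if (preds$n < 1L) abort("a slide needs at least one tile prediction", "ihctriage_input_error")
  D <- ncol(preds$embedding)
  amb <- group_block(preds$embedding[preds$label == "ambiguous", , drop = FALSE])
  cert <- group_block(preds$embedding[preds$label == "certain", , drop = FALSE])
  out <- c(amb$stats, cert$stats,
           var_pop(preds$mean_probs[, 2]),
           var_pop(preds$surrogate_loss),
           amb$n, cert$n, amb$flag, cert$flag)
  names(out) <- slide_feature_names(D)
  class(out) <- c("slide_feature_vector", class(out))
  out
}

#' Build a slide feature table from per-slide predictions
#'
#' @param pred_list Named list of `tile_predictions`, one entry per slide.
#' @return Data frame with `slide_id` plus one column per feature.
#' @export
slide_feature_table <- function(pred_list) {
  rows <- lapply(pred_list, function(p) as.numeric(compute_slide_features(p)))
  D <- ncol(pred_list[[1]]$embedding)
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- slide_feature_names(D)
  cbind(data.frame(slide_id = names(pred_list) %||% as.character(seq_along(pred_list)),
                   stringsAsFactors = FALSE), tab)
}

#' Convert a tile-feature fixture into per-slide predictions
#'
#' Reshapes the table produced by [make_tile_feature_fixture()] into the
#' `tile_predictions` objects the slide-feature stage consumes. Tile labels
#' are taken from the member-mean probability (ties to "ambiguous"), as at
#' inference time.
#'
#' @param fixture Fixture data frame.
#' @return Named list of `tile_predictions` with an `ihc_needed` attribute.
#' @export
fixture_slide_predictions <- function(fixture) {
  emb_cols <- grep("^emb_", names(fixture), value = TRUE)
  mp_cols <- grep("^member_prob_", names(fixture), value = TRUE)
  ids <- unique(fixture$slide_id)
  out <- vector("list", length(ids)); names(out) <- ids
  labels <- integer(length(ids)); names(labels) <- ids
  for (id in ids) {
    rows <- fixture[fixture$slide_id == id, , drop = FALSE]
    member_probs <- lapply(mp_cols, function(cn) {
      p <- rows[[cn]]
      cbind(1 - p, p)
    })
    out[[id]] <- tile_predictions(member_probs, as.matrix(rows[, emb_cols]))
    labels[id] <- rows$ihc_needed[1]
  }
  attr(out, "ihc_needed") <- labels
  out
}
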