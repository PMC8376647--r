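test_that("largest-remainder apportionment matches hand computation", {
  expect_equal(largest_remainder(10, c(0.4, 0.3, 0.3)), c(4L, 3L, 3L))
  expect_equal(largest_remainder(0, c(0.4, 0.3, 0.3)), c(0L, 0L, 0L))
  expect_equal(largest_remainder(7, c(0.5, 0.5)), c(4L, 3L))  # tie to first
  # counts always sum to n and never deviate from quota by >= 1
  set.seed(3)
  for (i in 1:25) {
    fr <- runif(4); fr <- fr / sum(fr)
    n <- sample(0:50, 1)
    cnt <- largest_remainder(n, fr)
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - n * fr) < 1))
  }
})

test_that("empty cohort yields an empty manifest and no slide files", {
  dir <- file.path(tempdir(), "ihctriage_empty")
  res <- generate_cohort(synth_config(n_slides = 0, seed = 1), dir)
  expect_equal(nrow(res$manifest), 0L)
  expect_equal(list.files(dir, pattern = "\\.png$"), character(0))
})

test_that("invalid generator configurations are refused", {
  expect_error(synth_config(class_mix = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(synth_config(ambiguity_interval = c(0.5, 1.2)), "sub-interval")
  expect_error(generate_cohort(synth_config(n_slides = 1, image_size = c(20, 20)),
                               tempfile()), "too small")
})

test_that("identical config and seed give byte-identical output files", {
  d1 <- file.path(tempdir(), "ihctriage_det1")
  d2 <- file.path(tempdir(), "ihctriage_det2")
  cfg <- synth_config(n_slides = 4, seed = 42)
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = paste("bytes of", f))
  }
})

test_that("cohort labels are consistent with stored foci and the ambiguity interval", {
  co <- small_cohort()
  cfg <- co$config
  min_px <- cfg$min_focus_area_mm2 * (1000 / cfg$um_per_px)^2
  for (i in seq_len(nrow(co$manifest))) {
    row <- co$manifest[i, ]
    foci <- read_annotations(file.path(co$dir, row$annotation_path))
    recomputed <- any(vapply(foci, function(f) {
      f$alpha >= cfg$ambiguity_interval[1] && f$alpha <= cfg$ambiguity_interval[2] &&
        polygon_area(f$polygon) >= min_px
    }, logical(1)))
    expect_equal(as.integer(recomputed), row$ihc_needed, label = row$slide_id)
    if (row$role == "control") expect_length(foci, 0L)
    # focus vertices lie inside the ground-truth tissue mask
    if (length(foci)) {
      tr <- png::readPNG(file.path(co$dir, row$tissue_mask_path)) > 0.5
      for (f in foci) {
        vx <- pmin(pmax(round(f$polygon[, 1]) + 1L, 1L), ncol(tr))
        vy <- pmin(pmax(round(f$polygon[, 2]) + 1L, 1L), nrow(tr))
        expect_true(all(tr[cbind(vy, vx)]), label = paste(row$slide_id, "focus in tissue"))
      }
    }
  }
})

test_that("rendered gland fields honour shape, domain and determinism contracts", {
  img <- render_gland_field(0.5, size = c(96, 96), seed = 1)
  expect_equal(dim(img), c(96L, 96L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  img2 <- render_gland_field(0.5, size = c(96, 96), seed = 1)
  expect_identical(img, img2)
  set.seed(10); a <- render_gland_field(0.5)
  set.seed(11); b <- render_gland_field(0.5)
  expect_false(identical(a, b))
  expect_error(render_gland_field(-0.1), "\\[0, 1\\]")
  expect_error(render_gland_field(1.1), "\\[0, 1\\]")
})

test_that("gland size decreases and nuclear density increases with alpha", {
  mean_lumen_area <- function(alpha, n = 20) {
    mean(vapply(seq_len(n), function(i) {
      img <- render_gland_field(alpha, seed = 300 + i)
      lum <- img[, , 1] > 0.9 & img[, , 2] > 0.9 & img[, , 3] > 0.9
      lab <- EBImage::bwlabel(lum)
      k <- max(lab)
      if (k == 0) 0 else sum(lum) / k
    }, numeric(1)))
  }
  dark_fraction <- function(alpha, n = 20) {
    mean(vapply(seq_len(n), function(i) {
      img <- render_gland_field(alpha, seed = 600 + i)
      mean(img[, , 1] < 0.3 & img[, , 3] < 0.5)
    }, numeric(1)))
  }
  l0 <- mean_lumen_area(0); l1 <- mean_lumen_area(1)
  expect_gte(l0, 4 * l1)
  # gland-size statistic strictly decreasing across the alpha ladder
  ladder <- vapply(c(0, 0.25, 0.5, 0.75, 1), mean_lumen_area, numeric(1))
  expect_true(all(diff(ladder) < 0))
  expect_gt(dark_fraction(1), dark_fraction(0))
})

test_that("tile-feature fixture has the declared schema and row count", {
  fx <- make_tile_feature_fixture(n_slides = 10, tiles_per_slide = 7, D = 4,
                                  delta = 2, seed = 3)
  expect_equal(nrow(fx), 70L)
  expect_true(all(c("slide_id", "ihc_needed", "tile_label",
                    paste0("emb_", 1:4), paste0("member_prob_", 1:3)) %in% names(fx)))
  # ambiguous fraction higher in IHC-needed slides
  frac <- tapply(fx$tile_label == "ambiguous", fx$ihc_needed, mean)
  expect_gt(frac[["1"]], frac[["0"]])
  expect_error(make_tile_feature_fixture(5, 0, 4, 1), "tiles_per_slide")
})
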