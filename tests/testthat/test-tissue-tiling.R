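test_that("segmentation handles blank input, wrong channels and flips", {
  white <- array(1, dim = c(64, 64, 3))
  expect_equal(sum(segment_tissue(white, um_per_px = 4)$mask), 0)
  expect_error(segment_tissue(matrix(0.5, 64, 64)), "RGB")
  co <- small_cohort()
  img <- read_slide_image(file.path(co$dir, co$manifest$image_path[1]))
  m1 <- segment_tissue(img, um_per_px = 4)$mask
  flipped <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  m2 <- segment_tissue(flipped, um_per_px = 4)$mask
  expect_identical(m1, m2[rev(seq_len(nrow(m2))), ])
})

test_that("tissue mask matches generator ground truth", {
  co <- small_cohort()
  for (i in 1:4) {
    row <- co$manifest[i, ]
    img <- read_slide_image(file.path(co$dir, row$image_path))
    mask <- segment_tissue(img, um_per_px = row$um_per_px)$mask
    tr <- png::readPNG(file.path(co$dir, row$tissue_mask_path)) > 0.5
    iou <- sum(mask & tr) / sum(mask | tr)
    expect_gte(iou, 0.9)
  }
})

full_mask <- function(n, um = 4) {
  structure(list(mask = matrix(1L, n, n), um_per_px = um), class = "tissue_mask")
}

test_that("tile enumeration follows the grid contract", {
  sl <- slide_record("s", "none.png", um_per_px = 4, dims = c(100, 100))
  g <- tile_grid(tile_px = 50, stride_px = 50, target_um_per_px = 4,
                 tissue_fraction_min = 0.5)
  t1 <- extract_tiles(sl, full_mask(100), g)
  expect_equal(nrow(t1), 4L)
  # row-major: y varies slowest
  expect_equal(t1$x, c(0L, 50L, 0L, 50L))
  expect_equal(t1$y, c(0L, 0L, 50L, 50L))
  # left half tissue only -> the x = 0 column survives tau = 0.5
  half <- full_mask(100); half$mask[, 51:100] <- 0L
  t2 <- extract_tiles(sl, half, g)
  expect_equal(nrow(t2), 2L)
  expect_true(all(t2$x == 0L))
  # tau = 0 disables filtering even on an all-background mask
  none <- full_mask(100); none$mask[] <- 0L
  g0 <- tile_grid(tile_px = 50, stride_px = 50, target_um_per_px = 4,
                  tissue_fraction_min = 0)
  expect_equal(nrow(extract_tiles(sl, none, g0)), 4L)
  # partial edge tiles are dropped, not padded
  sl2 <- slide_record("s", "none.png", um_per_px = 4, dims = c(120, 120))
  expect_equal(nrow(extract_tiles(sl2, full_mask(120), g)), 4L)
  expect_error(tile_grid(tissue_fraction_min = 1.5), "\\[0, 1\\]")
})

test_that("tile count is non-increasing in the tissue-fraction threshold", {
  sl <- slide_record("s", "none.png", um_per_px = 4, dims = c(120, 120))
  set.seed(21)
  for (rep in 1:5) {
    m <- full_mask(120)
    m$mask <- matrix(as.integer(runif(120 * 120) <
                                  matrix(runif(1, 0.2, 0.8), 120, 120)), 120, 120)
    counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(tau) {
      nrow(extract_tiles(sl, m, tile_grid(tile_px = 40, stride_px = 40,
                                          target_um_per_px = 4,
                                          tissue_fraction_min = tau)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    # every returned tile lies inside the slide
    tl <- extract_tiles(sl, m, tile_grid(tile_px = 40, stride_px = 40,
                                         target_um_per_px = 4,
                                         tissue_fraction_min = 0.3))
    expect_true(all(tl$x >= 0 & tl$y >= 0 &
                      tl$x + tl$tile_px_base <= 120 & tl$y + tl$tile_px_base <= 120))
  }
})

test_that("focus-tile selection follows the overlap rule", {
  sl <- slide_record("s", "none.png", um_per_px = 4, dims = c(100, 100))
  g <- tile_grid(tile_px = 50, stride_px = 50, target_um_per_px = 4)
  # polygon exactly equal to one grid tile -> that single tile
  one <- focus_annotation("s", rbind(c(0, 0), c(50, 0), c(50, 50), c(0, 50)), 1)
  ft <- tiles_for_focus(one, sl, g, phi = 0.25)
  expect_equal(nrow(ft), 1L)
  expect_equal(c(ft$x, ft$y), c(0L, 0L))
  # square straddling four tiles with 9% overlap each -> empty at phi 0.25
  small <- focus_annotation("s", rbind(c(35, 35), c(65, 35), c(65, 65), c(35, 65)), 1)
  expect_equal(nrow(tiles_for_focus(small, sl, g, phi = 0.25)), 0L)
  expect_equal(nrow(tiles_for_focus(small, sl, g, phi = 0.08)), 4L)
  # phi = 0 includes tiles the polygon merely touches
  expect_equal(nrow(tiles_for_focus(small, sl, g, phi = 0)), 4L)
  out <- focus_annotation("s", rbind(c(90, 90), c(150, 90), c(150, 150)), 1)
  expect_error(tiles_for_focus(out, sl, g), "outside")
})

test_that("focus tiles are a subset of tissue tiles when foci lie in tissue", {
  co <- small_cohort()
  ordered <- which(co$manifest$role == "ordered" & co$manifest$ihc_needed == 1)
  row <- co$manifest[ordered[1], ]
  sl <- cohort_slide(co, ordered[1])
  tr <- png::readPNG(file.path(co$dir, row$tissue_mask_path)) > 0.5
  mask <- structure(list(mask = tr * 1L, um_per_px = row$um_per_px),
                    class = "tissue_mask")
  g <- tile_grid()
  all_tiles <- extract_tiles(sl, mask, g)
  foci <- read_annotations(file.path(co$dir, row$annotation_path))
  for (f in foci) {
    ft <- tiles_for_focus(f, sl, g, phi = 0.25)
    keys <- paste(ft$x, ft$y)
    expect_true(all(keys %in% paste(all_tiles$x, all_tiles$y)))
  }
})
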