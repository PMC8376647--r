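# Tissue segmentation and tile enumeration.

#' Tile grid specification
#'
#' @param tile_px Tile side length in pixels at the working resolution.
#' @param stride_px Step between tile origins (default: non-overlapping).
#' @param target_um_per_px Working resolution for analysis tiles.
#' @param tissue_fraction_min Minimum tissue fraction tau in `[0, 1]` for a
#'   tile to be kept.
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(tile_px = 96L, stride_px = tile_px,
                      target_um_per_px = 4.0, tissue_fraction_min = 0.5) {
  if (tile_px <= 0 || stride_px <= 0) {
    abort("tile_px and stride_px must be positive", "ihctriage_config_error")
  }
  if (tissue_fraction_min < 0 || tissue_fraction_min > 1) {
    abort("tissue_fraction_min must lie in [0, 1]", "ihctriage_config_error")
  }
  structure(list(tile_px = as.integer(tile_px), stride_px = as.integer(stride_px),
                 target_um_per_px = target_um_per_px,
                 tissue_fraction_min = tissue_fraction_min),
            class = "tile_grid")
}

#' Segment tissue from background
#'
#' Deterministic classical pipeline: the HSV saturation channel is
#' thresholded by Otsu's method, the binary mask is morphologically closed
#' then opened with a disc of radius `r_px`, enclosed holes (gland lumina)
#' are filled, and connected components smaller than `min_area_mm2` are
#' removed. A learned segmenter can be swapped in behind the same contract
#' via the `mask_fun` argument.
#'
#' @param image RGB array (h x w x 3) in `[0, 1]`.
#' @param um_per_px Resolution of `image`.
#' @param r_px Radius of the morphological structuring element.
#' @param min_area_mm2 Minimum connected-component area kept.
#' @param sat_cap Saturation values are clipped to this cap before Otsu so
#'   that the threshold separates background from tissue rather than pale
#'   stroma from strongly stained epithelium (H&E tissue is multimodal in
#'   saturation; background is not).
#' @param mask_fun Optional replacement `function(image) -> 0/1 matrix`
#'   applied instead of the saturation-Otsu step (morphology still applies).
#' @return List of class `tissue_mask` with elements `mask` (0/1 integer
#'   matrix) and `um_per_px`.
#' @export
segment_tissue <- function(image, um_per_px = 4, r_px = 4L,
                           min_area_mm2 = 0.01, mask_fun = NULL,
                           sat_cap = 0.2) {
  stopifnot_rgb(image)
  if (is.null(mask_fun)) {
    mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
    mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
    sat <- pmin(ifelse(mx > 0, (mx - mn) / mx, 0), sat_cap)
    if (max(sat) - min(sat) < 1e-3) {
      bin <- matrix(0L, nrow(sat), ncol(sat))  # featureless image: no tissue
    } else {
      thr <- EBImage::otsu(EBImage::Image(sat), range = c(0, 1))
      bin <- (sat > thr) * 1L
    }
  } else {
    bin <- (mask_fun(image) > 0) * 1L
  }
  if (any(bin > 0)) {
    brush <- EBImage::makeBrush(2L * as.integer(r_px) + 1L, shape = "disc")
    m <- EBImage::Image(bin)
    m <- EBImage::closing(m, brush)
    m <- EBImage::fillHull(m)
    m <- EBImage::opening(m, brush)
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(as.integer(lab))
    min_px <- min_area_mm2 * (1000 / um_per_px)^2
    keep <- which(sizes >= min_px)
    bin <- matrix(as.integer(as.integer(lab) %in% keep & as.integer(lab) > 0),
                  nrow(bin), ncol(bin))
  }
  structure(list(mask = bin, um_per_px = um_per_px), class = "tissue_mask")
}

# Fraction of mask inside each half-open tile rectangle, via an integral
# image; rect coordinates are 0-based pixels at mask resolution.
mask_fraction <- function(mask, x, y, w, h) {
  ii <- matrix(0, nrow(mask) + 1L, ncol(mask) + 1L)
  cs <- apply(mask, 2, cumsum)
  ii[-1, -1] <- t(apply(cs, 1, cumsum))
  s <- ii[y + h + 1L + (x + w) * (nrow(mask) + 1L)] -
    ii[y + 1L + (x + w) * (nrow(mask) + 1L)] -
    ii[y + h + 1L + x * (nrow(mask) + 1L)] +
    ii[y + 1L + x * (nrow(mask) + 1L)]
  s / (as.numeric(w) * h)
}

#' Enumerate analysis tiles over the tissue mask
#'
#' Returns every grid tile whose tissue fraction is at least
#' `grid$tissue_fraction_min`, in row-major order (y then x). Tile origins
#' are expressed in base-level pixels; partial tiles at the right/bottom
#' edge are dropped rather than padded.
#'
#' @param slide A [slide_record()].
#' @param mask A `tissue_mask` from [segment_tissue()] (or ground truth).
#' @param grid A [tile_grid()].
#' @return Data frame of tile references with columns `slide_id`, `x`, `y`,
#'   `tile_px_base`, `tile_px`, `um_per_px`, `tissue_fraction`.
#' @export
extract_tiles <- function(slide, mask, grid) {
  tau <- grid$tissue_fraction_min
  scale <- grid$target_um_per_px / slide$um_per_px   # base px per working px
  tile_base <- as.integer(round(grid$tile_px * scale))
  stride_base <- as.integer(round(grid$stride_px * scale))
  w <- slide$dims[1]; h <- slide$dims[2]
  xs <- seq(0L, w - tile_base, by = stride_base)
  ys <- seq(0L, h - tile_base, by = stride_base)
  if (!length(xs) || !length(ys)) return(empty_tiles(slide, grid, tile_base))
  # mask may be at a different resolution from base level
  mscale <- slide$um_per_px / mask$um_per_px         # mask px per base px
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  fr <- mask_fraction(mask$mask,
                      as.integer(round(gx * mscale)),
                      as.integer(round(gy * mscale)),
                      as.integer(round(tile_base * mscale)),
                      as.integer(round(tile_base * mscale)))
  keep <- fr >= tau
  n <- sum(keep)
  data.frame(slide_id = rep(slide$slide_id, n), x = gx[keep], y = gy[keep],
             tile_px_base = rep(tile_base, n), tile_px = rep(grid$tile_px, n),
             um_per_px = rep(grid$target_um_per_px, n), tissue_fraction = fr[keep],
             stringsAsFactors = FALSE)
}

empty_tiles <- function(slide, grid, tile_base) {
  data.frame(slide_id = character(0), x = integer(0), y = integer(0),
             tile_px_base = integer(0), tile_px = integer(0),
             um_per_px = numeric(0), tissue_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' Tiles overlapping an annotated focus
#'
#' Returns the grid tiles whose geometric overlap with the focus polygon is
#' at least `phi` of the tile area, in row-major order.
#'
#' @param focus A [focus_annotation()].
#' @param slide A [slide_record()].
#' @param grid A [tile_grid()].
#' @param phi Minimum overlap fraction of the tile area (default 0.25).
#' @return Tile reference data frame (as [extract_tiles()], with an
#'   `overlap_fraction` column instead of `tissue_fraction`).
#' @export
tiles_for_focus <- function(focus, slide, grid, phi = 0.25) {
  poly <- focus$polygon
  if (any(poly[, 1] < 0 | poly[, 1] > slide$dims[1] |
          poly[, 2] < 0 | poly[, 2] > slide$dims[2])) {
    abort("focus polygon lies outside the slide", "ihctriage_bounds_error")
  }
  scale <- grid$target_um_per_px / slide$um_per_px
  tile_base <- as.integer(round(grid$tile_px * scale))
  stride_base <- as.integer(round(grid$stride_px * scale))
  w <- slide$dims[1]; h <- slide$dims[2]
  xs <- seq(0L, w - tile_base, by = stride_base)
  ys <- seq(0L, h - tile_base, by = stride_base)
  bb <- c(range(poly[, 1]), range(poly[, 2]))
  out <- list()
  tile_area <- as.numeric(tile_base)^2
  for (y in ys) {
    if (y + tile_base <= bb[3] || y >= bb[4]) next
    for (x in xs) {
      if (x + tile_base <= bb[1] || x >= bb[2]) next
      ov <- polygon_rect_overlap(poly, c(x, y, tile_base, tile_base))
      frac <- ov / tile_area
      keep <- if (phi > 0) frac >= phi else ov > 0 || touches_rect(poly, c(x, y, tile_base, tile_base))
      if (keep) {
        out[[length(out) + 1L]] <- data.frame(
          slide_id = slide$slide_id, x = x, y = y,
          tile_px_base = tile_base, tile_px = grid$tile_px,
          um_per_px = grid$target_um_per_px, overlap_fraction = frac,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    df <- empty_tiles(slide, grid, tile_base)
    names(df)[names(df) == "tissue_fraction"] <- "overlap_fraction"
    return(df)
  }
  do.call(rbind, out)
}

# Does the polygon boundary touch the rectangle at all (zero-area contact)?
touches_rect <- function(poly, rect) {
  nrow(clip_polygon_rect(poly, rect)) > 0
}

#' Crop the raster for one tile reference
#'
#' @param tile One row of a tile reference data frame.
#' @param slide A [slide_record()].
#' @param image Optional pre-loaded slide raster.
#' @return RGB array of side `tile$tile_px` at the tile's working resolution.
#' @export
load_tile <- function(tile, slide, image = NULL) {
  load_region(slide, c(tile$x, tile$y, tile$tile_px_base, tile$tile_px_base),
              target_um_per_px = tile$um_per_px, image = image)
}
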