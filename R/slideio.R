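# Slide, annotation and manifest I/O.
#
# Coordinate convention for the whole package: 0-based base-level pixel
# coordinates, x rightward, y downward, rectangles half-open
# [x, x + w) x [y, y + h). Annotation polygons are stored at base level
# regardless of the magnification at which they were drawn.

#' Reason codes for ordering IHC on prostate core biopsies
#'
#' The eight-category taxonomy of ambiguous prostate gland foci that prompt
#' an IHC request, with the number of foci identified in each category in
#' the audited clinical corpus and the number confirmed as cancer after IHC.
#'
#' @return A data frame with columns `code` (1-8), `description`,
#'   `n_foci`, `n_cancer`.
#' @examples
#' sum(reason_code_table()$n_foci)
#' @export
reason_code_table <- function() {
  data.frame(
    code = 1:8,
    description = c(
      paste("A short length of cancer (e.g., <1 mm) of any glands that show",
            "convincing cancer morphologically but need confirming with IHC",
            "for completeness"),
      paste("Foci that are suspicious of cancer but only consist of a couple",
            "of glands such that we are unlikely to definitively call the",
            "focus cancer, but if lack basal cells we may consider a",
            "differential diagnosis of ASAP"),
      "Unusual morphology glands that are difficult to classify",
      paste("A longer length of cancer which has an unusual appearance",
            "(e.g., well differentiated cancer or cancer with very few well",
            "differentiated glands widely spaced by benign/stroma.) Or",
            "variant/unusual tumour (e.g., clear cell change/atrophic",
            "variant/PIN like adenocarcinoma)"),
      "Foci that are atypical but probably benign (e.g., atrophy)",
      "Small glands around PIN? small foci of invasion or ASAP/PIN",
      paste("Diffuse cells where the differential diagnosis lies between",
            "inflammation or Gleason pattern 5 cancer"),
      "Other—glands that do not easily fit into the above"
    ),
    n_foci = c(187L, 67L, 100L, 44L, 144L, 64L, 32L, 3L),
    n_cancer = c(168L, 20L, 7L, 42L, 6L, 6L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Slide record
#'
#' Geometry of one whole-slide image: identifier, image path, base-level
#' resolution and pixel dimensions.
#'
#' @param slide_id Character identifier.
#' @param image_path Path to the slide raster (PNG or TIFF).
#' @param um_per_px Microns per pixel at base level (> 0).
#' @param dims Integer `c(w, h)` in pixels.
#' @return An object of class `slide_record`.
#' @export
slide_record <- function(slide_id, image_path, um_per_px, dims) {
  if (!is.numeric(um_per_px) || um_per_px <= 0) {
    abort("um_per_px must be > 0", "ihctriage_validation_error")
  }
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims <= 0)) {
    abort("dims must be positive c(w, h)", "ihctriage_validation_error")
  }
  structure(
    list(slide_id = as.character(slide_id), image_path = image_path,
         um_per_px = as.numeric(um_per_px), dims = dims),
    class = "slide_record"
  )
}

#' Focus annotation
#'
#' One hand-drawn region that prompted an IHC order, with its reason code.
#' Self-touching outlines (repeated vertices, duplicated closing vertex) are
#' repaired; genuinely self-crossing outlines are rejected.
#'
#' @param slide_id Slide the focus belongs to.
#' @param polygon n x 2 matrix of base-level (x, y) pixel vertices, n >= 3.
#' @param reason Integer reason code in 1..8 (see [reason_code_table()]).
#' @param annotator_id Character id of the annotating pathologist.
#' @param alpha Optional morphology parameter recorded by the synthetic
#'   generator (NA for real annotations).
#' @return An object of class `focus_annotation`.
#' @export
focus_annotation <- function(slide_id, polygon, reason, annotator_id = "anon",
                             alpha = NA_real_) {
  if (!is_count(reason, min = 1) || reason > 8) {
    abort(sprintf("reason code must be an integer in 1..8, got %s", format(reason)),
          "ihctriage_validation_error")
  }
  polygon <- clean_polygon(as_polygon(polygon))
  if (nrow(polygon) < 3L) {
    abort("focus polygon has fewer than 3 distinct vertices", "ihctriage_validation_error")
  }
  if (polygon_self_intersects(polygon)) {
    abort("focus polygon is self-crossing and cannot be repaired", "ihctriage_validation_error")
  }
  structure(
    list(slide_id = as.character(slide_id), polygon = polygon,
         reason = as.integer(reason), annotator_id = as.character(annotator_id),
         alpha = as.numeric(alpha)),
    class = "focus_annotation"
  )
}

#' Read focus annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with properties
#' `reason`, `annotator`, `slide_id` (and optionally `alpha`). Feature
#' order is preserved.
#'
#' @param path GeoJSON file path.
#' @return List of [focus_annotation()] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste("no such annotation file:", path), "ihctriage_io_error")
  gj <- tryCatch(jsonlite::read_json(path),
                 error = function(e) abort(paste("malformed GeoJSON:", conditionMessage(e)),
                                           "ihctriage_parse_error"))
  feats <- gj$features %||% list()
  out <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties %||% list()
    reason <- props$reason
    if (is.null(reason) || !is_count(reason, min = 1) || reason > 8) {
      abort(sprintf("feature %d: reason code must be in 1..8", i), "ihctriage_validation_error")
    }
    ring <- f$geometry$coordinates[[1]]
    if (length(ring) < 3L) {
      abort(sprintf("feature %d: polygon needs >= 3 vertices", i), "ihctriage_validation_error")
    }
    poly <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    out[[i]] <- focus_annotation(
      slide_id = props$slide_id %||% NA_character_,
      polygon = poly,
      reason = reason,
      annotator_id = props$annotator %||% "anon",
      alpha = as.numeric(props$alpha %||% NA_real_)
    )
  }
  out
}

#' Write focus annotations to GeoJSON
#'
#' Inverse of [read_annotations()]: coordinates are written unmodified, with
#' the GeoJSON ring closed by repeating the first vertex.
#'
#' @param foci List of [focus_annotation()] objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(foci, path) {
  for (f in foci) {
    if (!inherits(f, "focus_annotation")) {
      abort("write_annotations expects focus_annotation objects", "ihctriage_validation_error")
    }
  }
  features <- lapply(foci, function(f) {
    ring <- rbind(f$polygon, f$polygon[1, ])
    coords <- lapply(seq_len(nrow(ring)), function(i) list(ring[i, 1], ring[i, 2]))
    props <- list(reason = f$reason, annotator = f$annotator_id, slide_id = f$slide_id)
    if (!is.na(f$alpha)) props$alpha <- f$alpha
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write slide manifests
#'
#' The manifest is a CSV with columns `slide_id`, `image_path`,
#' `annotation_path`, `role` (ordered/control/validation), `ihc_needed`
#' (0/1), `diagnosis` (benign/malignant/unknown), `um_per_px`.
#'
#' @param path CSV path.
#' @return `read_manifest`: a data frame; `write_manifest`: `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("slide_id", "image_path", "annotation_path", "role",
                "ihc_needed", "diagnosis", "um_per_px")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    abort(paste("manifest missing columns:", paste(missing, collapse = ", ")),
          "ihctriage_validation_error")
  }
  m
}

#' @rdname read_manifest
#' @param manifest Manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a slide raster from disk
#'
#' @param path PNG or TIFF file.
#' @return h x w x 3 numeric array in `[0, 1]`.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste("unsupported image format:", ext), "ihctriage_io_error")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Write a slide raster to disk
#'
#' @param img h x w x 3 numeric array in `[0, 1]`.
#' @param path Output path (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_slide_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(img, 0), 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    abort(paste("unsupported image format:", ext), "ihctriage_io_error")
  )
  invisible(path)
}

# Area-average resampling of one channel to out_h x out_w. Each output pixel
# averages the input pixels its footprint covers, with fractional edge
# weights, so constant inputs stay exactly constant.
resample_area <- function(mat, out_h, out_w) {
  in_h <- nrow(mat); in_w <- ncol(mat)
  if (out_h == in_h && out_w == in_w) return(mat)
  # integral image with a zero border
  ii <- matrix(0, in_h + 1L, in_w + 1L)
  cs <- apply(mat, 2, cumsum)
  ii[-1, -1] <- t(apply(cs, 1, cumsum))
  # linear interpolation of the integral image at fractional positions
  interp_rows <- function(pos) {
    lo <- pmin(floor(pos), in_h); hi <- pmin(lo + 1, in_h)
    fr <- pos - lo
    ii[lo + 1L, , drop = FALSE] * (1 - fr) + ii[hi + 1L, , drop = FALSE] * fr
  }
  ys <- seq(0, in_h, length.out = out_h + 1L)
  xs <- seq(0, in_w, length.out = out_w + 1L)
  rows <- interp_rows(ys)                      # (out_h+1) x (in_w+1)
  interp_cols <- function(m, pos) {
    lo <- pmin(floor(pos), in_w); hi <- pmin(lo + 1, in_w)
    fr <- pos - lo
    m[, lo + 1L, drop = FALSE] * rep(1 - fr, each = nrow(m)) +
      m[, hi + 1L, drop = FALSE] * rep(fr, each = nrow(m))
  }
  grid <- interp_cols(rows, xs)                # (out_h+1) x (out_w+1)
  area <- (diff(ys)) %o% (diff(xs))
  sums <- grid[-1, -1] - grid[-nrow(grid), -1] - grid[-1, -ncol(grid)] +
    grid[-nrow(grid), -ncol(grid)]
  sums / area
}

#' Load a region of a slide at a target resolution
#'
#' Reads the base-level rectangle `rect` and downsamples it to
#' `target_um_per_px` by area averaging. The output size is
#' `floor(rect_size * um_per_px / target_um_per_px)`.
#'
#' @param slide A [slide_record()].
#' @param rect Base-level pixel rectangle `c(x, y, w, h)` (half-open).
#' @param target_um_per_px Target resolution, >= the slide's `um_per_px`.
#' @param image Optional pre-loaded slide raster (avoids re-reading).
#' @return RGB array at the target resolution.
#' @export
load_region <- function(slide, rect, target_um_per_px = slide$um_per_px,
                        image = NULL) {
  if (target_um_per_px < slide$um_per_px) {
    abort("target_um_per_px must be >= the slide's base resolution (no upsampling)",
          "ihctriage_validation_error")
  }
  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]
  if (x < 0 || y < 0 || x + w > slide$dims[1] || y + h > slide$dims[2]) {
    abort("requested rectangle lies outside the slide", "ihctriage_bounds_error")
  }
  if (is.null(image)) image <- read_slide_image(slide$image_path)
  sub <- image[(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE]
  k <- slide$um_per_px / target_um_per_px
  out_w <- floor(w * k); out_h <- floor(h * k)
  if (out_w == w && out_h == h) return(sub)
  out <- array(0, dim = c(out_h, out_w, 3L))
  for (c in 1:3) out[, , c] <- resample_area(sub[, , c], out_h, out_w)
  out
}
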