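# Synthetic needle-biopsy generator.
#
# Slides are stylized H&E rasters: a curved tissue band of glands on a white
# background. A single morphology parameter alpha in [0, 1] drives the
# benign -> ambiguous -> malignant continuum: as alpha grows, glands shrink,
# lumina close, gland outlines become irregular and nuclear density rises.
# Mid-range alpha is "ambiguous" morphology (the kind that prompts an IHC
# order); the extremes are "certain" benign/malignant.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of the clinical training corpus: the
#' class mix is 40:40:219 (benign control : malignant control : IHC-needed)
#' scaled to `n_slides`, IHC-needed slides carry 1-3 annotated ambiguous
#' foci, and ambiguity is the middle of the morphology continuum.
#'
#' @param n_slides Number of slides to generate.
#' @param image_size Pixel size `c(w, h)` of each slide raster.
#' @param um_per_px Resolution in microns per pixel (desk default 4.0).
#' @param class_mix Fractions over (no-IHC benign, no-IHC malignant,
#'   IHC-needed); must sum to 1.
#' @param ambiguity_interval Sub-interval of `[0, 1]` of the morphology
#'   parameter alpha treated as ambiguous.
#' @param foci_per_slide Integer range `c(min, max)` of foci on IHC-needed
#'   slides.
#' @param gland_density Glands per square millimetre.
#' @param nucleus_diameter Nucleus diameter in microns.
#' @param stain_jitter Per-channel Gaussian stain noise (sd, intensity units).
#' @param min_focus_area_mm2 Minimum focus area for a focus to count toward
#'   the slide-level IHC-needed label.
#' @param n_validation Additional slides generated with role "validation".
#' @param seed Master seed; identical configs and seeds give byte-identical
#'   output files.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_slides = 90L,
                         image_size = c(480L, 480L),
                         um_per_px = 4.0,
                         class_mix = c(benign = 40, malignant = 40, ihc_needed = 219) / 299,
                         ambiguity_interval = c(0.35, 0.65),
                         foci_per_slide = c(1L, 3L),
                         gland_density = 60,
                         nucleus_diameter = 6,
                         stain_jitter = 0.02,
                         min_focus_area_mm2 = 0.01,
                         n_validation = 0L,
                         seed = 0L) {
  if (abs(sum(class_mix) - 1) > 1e-9) {
    abort("class_mix must sum to 1", "ihctriage_config_error")
  }
  if (length(ambiguity_interval) != 2L || ambiguity_interval[1] < 0 ||
      ambiguity_interval[2] > 1 || ambiguity_interval[1] >= ambiguity_interval[2]) {
    abort("ambiguity_interval must be a sub-interval of [0, 1]", "ihctriage_config_error")
  }
  if (!is_count(n_slides)) abort("n_slides must be a non-negative count", "ihctriage_config_error")
  structure(
    list(n_slides = as.integer(n_slides), image_size = as.integer(image_size),
         um_per_px = um_per_px, class_mix = class_mix,
         ambiguity_interval = ambiguity_interval,
         foci_per_slide = as.integer(foci_per_slide),
         gland_density = gland_density, nucleus_diameter = nucleus_diameter,
         stain_jitter = stain_jitter, min_focus_area_mm2 = min_focus_area_mm2,
         n_validation = as.integer(n_validation), seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Largest-remainder apportionment
#'
#' Distributes `n` items over classes proportionally to `fractions`, giving
#' each class the floor of its quota and handing remaining items to the
#' largest fractional remainders (ties to earlier classes).
#'
#' @param n Total count.
#' @param fractions Non-negative fractions summing to 1.
#' @return Integer vector of per-class counts summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# H&E-ish palette
.synth_colors <- list(
  background = c(0.985, 0.985, 0.985),
  stroma     = c(0.90, 0.72, 0.80),
  epithelium = c(0.48, 0.32, 0.60),
  lumen      = c(0.96, 0.96, 0.96),
  nucleus    = c(0.22, 0.12, 0.42)
)

# Core raster painter. alpha_fun(x, y) returns the local morphology parameter
# for a gland centred at (x, y) (1-based pixel coordinates). tissue is an
# h x w logical matrix (NULL = everything is tissue). Uses the current RNG
# stream; callers fix the seed.
render_field <- function(w, h, alpha_fun, tissue = NULL, um_per_px = 4,
                         gland_density = 60, nucleus_diameter = 6,
                         stain_jitter = 0.02) {
  col <- .synth_colors
  img <- array(0, dim = c(h, w, 3L))
  in_tissue <- if (is.null(tissue)) matrix(TRUE, h, w) else tissue
  for (c in 1:3) {
    img[, , c] <- ifelse(in_tissue, col$stroma[c], col$background[c])
  }
  px_per_mm <- 1000 / um_per_px
  spacing <- px_per_mm / sqrt(gland_density)          # lattice pitch, px
  gx <- seq(spacing / 2, w, by = spacing)
  gy <- seq(spacing / 2, h, by = spacing)
  centers <- expand.grid(x = gx, y = gy)
  centers$x <- centers$x + stats::runif(nrow(centers), -spacing / 4, spacing / 4)
  centers$y <- centers$y + stats::runif(nrow(centers), -spacing / 4, spacing / 4)
  r_base <- spacing * 0.40
  nuc_r <- nucleus_diameter / 2 / um_per_px
  paint_disc <- function(cx, cy, test, colors) {
    x0 <- max(1L, floor(cx - test$rmax)); x1 <- min(w, ceiling(cx + test$rmax))
    y0 <- max(1L, floor(cy - test$rmax)); y1 <- min(h, ceiling(cy + test$rmax))
    if (x0 > x1 || y0 > y1) return(invisible())
    xs <- matrix(rep(x0:x1, each = y1 - y0 + 1L), y1 - y0 + 1L)
    ys <- matrix(rep(y0:y1, x1 - x0 + 1L), y1 - y0 + 1L)
    sel <- test$fn(xs - cx, ys - cy)
    local_tissue <- in_tissue[y0:y1, x0:x1]
    sel$epi <- sel$epi & local_tissue
    if (!is.null(sel$lum)) sel$lum <- sel$lum & local_tissue
    for (c in 1:3) {
      block <- img[y0:y1, x0:x1, c]
      block[sel$epi] <- colors$epi[c]
      if (!is.null(sel$lum)) block[sel$lum] <- colors$lum[c]
      img[y0:y1, x0:x1, c] <<- block
    }
    invisible()
  }
  mean_alpha <- 0; n_glands <- 0L
  for (i in seq_len(nrow(centers))) {
    cx <- centers$x[i]; cy <- centers$y[i]
    cxi <- min(max(round(cx), 1L), w); cyi <- min(max(round(cy), 1L), h)
    if (!in_tissue[cyi, cxi]) next
    a <- alpha_fun(cx, cy)
    mean_alpha <- mean_alpha + a; n_glands <- n_glands + 1L
    r0 <- r_base * (1 - 0.58 * a) * stats::runif(1, 0.85, 1.15)
    irr <- 0.45 * a
    k <- sample(3:6, 1); ph <- stats::runif(1, 0, 2 * pi)
    lum_frac <- 0.62 - 0.52 * a
    rmax <- r0 * (1 + irr)
    paint_disc(cx, cy, list(
      rmax = rmax,
      fn = function(dx, dy) {
        rr <- sqrt(dx^2 + dy^2)
        rb <- r0 * (1 + irr * sin(k * atan2(dy, dx) + ph))
        list(epi = rr <= rb, lum = rr <= rb * lum_frac)
      }),
      list(epi = col$epithelium, lum = col$lumen))
  }
  mean_alpha <- if (n_glands > 0) mean_alpha / n_glands else 0.5
  # scattered nuclei; density rises with the local alpha
  area_tiles <- (w * h) / (96 * 96)
  n_nuc <- stats::rpois(1, area_tiles * (40 + 160 * mean_alpha))
  if (n_nuc > 0) {
    nx <- stats::runif(n_nuc, 1, w); ny <- stats::runif(n_nuc, 1, h)
    keep <- stats::runif(n_nuc) <= vapply(seq_len(n_nuc), function(i) {
      (40 + 160 * alpha_fun(nx[i], ny[i])) / (40 + 160 * max(mean_alpha, 1e-9))
    }, numeric(1))
    for (i in which(keep)) {
      nr <- nuc_r * stats::runif(1, 0.8, 1.2)
      paint_disc(nx[i], ny[i], list(
        rmax = nr,
        fn = function(dx, dy) list(epi = dx^2 + dy^2 <= nr^2, lum = NULL)),
        list(epi = col$nucleus))
    }
  }
  if (stain_jitter > 0) {
    img <- img + array(stats::rnorm(length(img), 0, stain_jitter), dim = dim(img))
  }
  pmin(pmax(img, 0), 1)
}

#' Render a uniform gland field
#'
#' Draws a square patch of synthetic glandular tissue at a single morphology
#' parameter. As `alpha` increases, glands shrink, lumina close and nuclear
#' density increases (monotone in expectation).
#'
#' @param alpha Morphology parameter in `[0, 1]`: 0 = clearly benign,
#'   1 = clearly malignant, mid-range = ambiguous.
#' @param size Output size `c(w, h)` in pixels.
#' @param um_per_px Resolution (microns per pixel).
#' @param gland_density Glands per square millimetre.
#' @param nucleus_diameter Nucleus diameter in microns.
#' @param stain_jitter Gaussian stain noise sd.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return h x w x 3 RGB array in `[0, 1]`.
#' @export
render_gland_field <- function(alpha, size = c(96L, 96L), um_per_px = 4,
                               gland_density = 60, nucleus_diameter = 6,
                               stain_jitter = 0.02, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("alpha must be a single value in [0, 1]", "ihctriage_domain_error")
  }
  run <- function() {
    render_field(size[1], size[2], function(x, y) alpha,
                 um_per_px = um_per_px, gland_density = gland_density,
                 nucleus_diameter = nucleus_diameter, stain_jitter = stain_jitter)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Curved tissue band (simulated needle core) across the image.
make_tissue_band <- function(w, h) {
  x <- seq_len(w)
  yc <- h / 2 + stats::runif(1, -0.08, 0.08) * h +
    stats::runif(1, 0.04, 0.10) * h * sin(2 * pi * x / stats::runif(1, 0.9, 1.6) / w + stats::runif(1, 0, 2 * pi))
  half_w <- stats::runif(1, 0.21, 0.26) * h *
    (1 + 0.10 * sin(2 * pi * x / stats::runif(1, 0.4, 0.8) / w + stats::runif(1, 0, 2 * pi)))
  ys <- matrix(rep(seq_len(h), w), h, w)
  abs(ys - rep(yc, each = h)) <= rep(half_w, each = h)
}

# Irregular 16-gon focus outline around (cx, cy); 0-based coordinates.
make_focus_polygon <- function(cx, cy, radius) {
  th <- seq(0, 2 * pi, length.out = 17L)[-17]
  r <- radius * (1 + stats::runif(16, -0.12, 0.12))
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Generate a synthetic cohort of slides
#'
#' Writes slide rasters (PNG), ground-truth tissue masks, GeoJSON focus
#' annotations and a manifest CSV into `out_dir`. Per-class counts follow
#' the configured mix by largest-remainder apportionment; IHC-needed slides
#' carry foci whose morphology parameter lies inside the ambiguity interval,
#' controls are uniformly "certain" benign or malignant (50:50). Output is
#' byte-identical for identical `(config, seed)`.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `manifest` (data frame, also written to
#'   `manifest.csv`) and `out_dir`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- config$image_size[1]; h <- config$image_size[2]
  px_per_mm <- 1000 / config$um_per_px
  spacing <- px_per_mm / sqrt(config$gland_density)
  if (w < 2 * spacing || h < 2 * spacing) {
    abort("image_size is too small to host a gland at the configured density",
          "ihctriage_generation_error")
  }
  min_focus_px <- config$min_focus_area_mm2 * px_per_mm^2

  roles <- character(0); classes <- integer(0)
  if (config$n_slides > 0) {
    counts <- largest_remainder(config$n_slides, config$class_mix)
    classes <- rep(1:3, counts)
    roles <- ifelse(classes == 3L, "ordered", "control")
  }
  if (config$n_validation > 0) {
    vc <- largest_remainder(config$n_validation, config$class_mix)
    classes <- c(classes, rep(1:3, vc))
    roles <- c(roles, rep("validation", config$n_validation))
  }

  rows <- vector("list", length(classes))
  reason_weights <- reason_code_table()$n_foci
  for (i in seq_along(classes)) {
    set.seed(derive_seed(config$seed, i))
    cls <- classes[i]
    slide_id <- sprintf("slide_%03d", i)
    tissue <- make_tissue_band(w, h)
    diagnosis <- switch(cls, "benign", "malignant",
                        if (stats::runif(1) < 0.5) "benign" else "malignant")
    base_alpha <- if (diagnosis == "benign") stats::runif(1, 0.03, 0.15) else stats::runif(1, 0.85, 0.97)
    foci <- list()
    if (cls == 3L) {
      n_foci <- sample(seq(config$foci_per_slide[1], config$foci_per_slide[2]), 1)
      band_rows <- which(apply(tissue, 1, any))
      for (k in seq_len(n_foci)) {
        a_f <- stats::runif(1, config$ambiguity_interval[1], config$ambiguity_interval[2])
        radius <- stats::runif(1, 50, 70)
        for (try in 1:20) {
          cx <- stats::runif(1, 0.15 * w, 0.85 * w)
          cols_here <- which(tissue[, min(max(round(cx), 1), w)])
          if (!length(cols_here)) next
          cy <- mean(range(cols_here)) + stats::runif(1, -0.15, 0.15) * diff(range(cols_here))
          poly <- make_focus_polygon(cx, cy, radius)
          vx <- pmin(pmax(round(poly[, 1]) + 1L, 1L), w)
          vy <- pmin(pmax(round(poly[, 2]) + 1L, 1L), h)
          ok <- all(tissue[cbind(vy, vx)]) &&
            all(poly[, 1] >= 0 & poly[, 1] < w & poly[, 2] >= 0 & poly[, 2] < h)
          if (ok) {
            foci[[length(foci) + 1L]] <- focus_annotation(
              slide_id, poly,
              reason = sample(1:8, 1, prob = reason_weights),
              annotator_id = sprintf("synth_%d", 1 + (i %% 3)),
              alpha = a_f)
            break
          }
          radius <- radius * 0.85
        }
      }
    }
    ihc_needed <- any(vapply(foci, function(f) {
      f$alpha >= config$ambiguity_interval[1] &&
        f$alpha <= config$ambiguity_interval[2] &&
        polygon_area(f$polygon) >= min_focus_px
    }, logical(1)))
    alpha_fun <- function(x, y) {
      for (f in foci) {
        ctr <- colMeans(f$polygon)
        rad <- sqrt(polygon_area(f$polygon) / pi)
        if ((x - 1 - ctr[1])^2 + (y - 1 - ctr[2])^2 <= rad^2) return(f$alpha)
      }
      base_alpha
    }
    img <- render_field(w, h, alpha_fun, tissue = tissue,
                        um_per_px = config$um_per_px,
                        gland_density = config$gland_density,
                        nucleus_diameter = config$nucleus_diameter,
                        stain_jitter = config$stain_jitter)
    image_path <- file.path(out_dir, paste0(slide_id, ".png"))
    mask_path <- file.path(out_dir, paste0(slide_id, "_tissue.png"))
    ann_path <- file.path(out_dir, paste0(slide_id, ".geojson"))
    write_slide_image(img, image_path)
    png::writePNG(tissue * 1.0, mask_path)
    write_annotations(foci, ann_path)
    rows[[i]] <- data.frame(
      slide_id = slide_id,
      image_path = basename(image_path),
      annotation_path = basename(ann_path),
      tissue_mask_path = basename(mask_path),
      role = roles[i],
      ihc_needed = as.integer(ihc_needed),
      diagnosis = diagnosis,
      um_per_px = config$um_per_px,
      stringsAsFactors = FALSE
    )
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else data.frame(
    slide_id = character(0), image_path = character(0),
    annotation_path = character(0), tissue_mask_path = character(0),
    role = character(0), ihc_needed = integer(0), diagnosis = character(0),
    um_per_px = numeric(0), stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(list(manifest = manifest, out_dir = out_dir))
}

#' Tabular tile-feature fixture
#'
#' Generates a synthetic table of per-tile embeddings and ensemble member
#' probabilities without training any network, so the slide-feature and
#' decision stages can be exercised in isolation. Embeddings are drawn from
#' two isotropic Gaussians separated by `delta` along the first embedding
#' axis (certain at 0, ambiguous at `delta`); the ambiguous-tile fraction is
#' `amb_frac_ihc` in IHC-needed slides and `amb_frac_ctrl` in the rest.
#'
#' @param n_slides Number of slides (alternating IHC-needed / control).
#' @param tiles_per_slide Tiles per slide (> 0).
#' @param D Embedding dimension.
#' @param delta Class mean shift (>= 0).
#' @param seed RNG seed.
#' @param n_members Ensemble members to simulate.
#' @param amb_frac_ihc,amb_frac_ctrl Ambiguous-tile fractions by slide class.
#' @return Data frame with columns `slide_id`, `ihc_needed`, `tile_label`,
#'   `emb_1..emb_D`, `member_prob_1..member_prob_n`.
#' @export
make_tile_feature_fixture <- function(n_slides, tiles_per_slide, D, delta,
                                      seed = 0L, n_members = 3L,
                                      amb_frac_ihc = 0.40, amb_frac_ctrl = 0.08) {
  if (!is_count(tiles_per_slide, min = 1)) {
    abort("tiles_per_slide must be >= 1", "ihctriage_config_error")
  }
  if (D < 1 || delta < 0) abort("need D >= 1 and delta >= 0", "ihctriage_config_error")
  set.seed(seed)
  rows <- vector("list", n_slides)
  for (s in seq_len(n_slides)) {
    ihc <- s %% 2L == 1L
    frac <- if (ihc) amb_frac_ihc else amb_frac_ctrl
    amb <- stats::runif(tiles_per_slide) < frac
    emb <- matrix(stats::rnorm(tiles_per_slide * D), tiles_per_slide, D)
    emb[, 1] <- emb[, 1] + ifelse(amb, delta, 0)
    # member probabilities track the projection onto the separating axis
    proj <- (emb[, 1] - delta / 2) * (if (delta > 0) 2 / max(delta, 1) else 0)
    mp <- matrix(0, tiles_per_slide, n_members)
    for (m in seq_len(n_members)) {
      mp[, m] <- stats::plogis(proj + stats::rnorm(tiles_per_slide, 0, 0.3))
    }
    df <- data.frame(slide_id = sprintf("fix_%04d", s),
                     ihc_needed = as.integer(ihc),
                     tile_label = ifelse(amb, "ambiguous", "certain"),
                     stringsAsFactors = FALSE)
    colnames(emb) <- paste0("emb_", seq_len(D))
    colnames(mp) <- paste0("member_prob_", seq_len(n_members))
    rows[[s]] <- cbind(df, emb, mp)
  }
  do.call(rbind, rows)
}
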