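#' Synthetic soma image generation
#'
#' Real two-photon datasets of GCaMP6s-expressing neurons are expensive to
#' annotate exhaustively, so training images are synthesized by the
#' copy-paste-blend strategy: background tiles cut from real (or rendered)
#' images are shuffled into full synthetic backgrounds, and annotated cell
#' crops are pasted onto them with feathered alpha blending, yielding
#' images with exhaustive per-instance ground-truth masks.
#'
#' @name simulate
NULL

#' Background tile
#'
#' A rectangular crop of non-somatic (neuropil) background, the unit from
#' which synthetic backgrounds are mosaicked.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param source_id identifier of the image of origin.
#' @param box rectangle in source coordinates as `c(row, col, height,
#'   width)`, 0-based, half-open.
#' @return an object of class `background_tile`.
#' @export
background_tile <- function(pixels, source_id = "synthetic", box = NULL) {
  assert_unit_image(pixels, "pixels")
  if (is.null(box)) box <- c(0L, 0L, nrow(pixels), ncol(pixels))
  if (length(box) != 4L || box[3L] != nrow(pixels) || box[4L] != ncol(pixels))
    stop_somaswin("tile box dimensions must match pixel dimensions")
  structure(list(pixels = pixels, source_id = source_id,
                 box = as.integer(box)),
            class = "background_tile")
}

#' Annotated cell crop
#'
#' A cropped soma image with its binary support mask and the perfusion
#' condition it was imaged under. The condition tag matters because GCaMP6s
#' brightness is activity dependent: NMDA perfusion gives bright somas,
#' washout mid-high, baseline aCSF the dimmest.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param mask logical matrix, same shape, the soma support; must be a
#'   single nonempty connected component.
#' @param condition one of `"baseline"`, `"nmda"`, `"washout"`.
#' @return an object of class `annotated_cell`.
#' @export
annotated_cell <- function(pixels, mask,
                           condition = c("baseline", "nmda", "washout")) {
  condition <- match.arg(condition)
  assert_unit_image(pixels, "pixels")
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), dim(pixels)))
    stop_somaswin("mask shape must equal pixel shape")
  if (!any(mask)) stop_somaswin("cell mask must contain at least one pixel")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (max(lab) != 1L)
    stop_somaswin("cell mask must be a single connected component")
  structure(list(pixels = pixels, mask = mask, condition = condition),
            class = "annotated_cell")
}

#' Generator configuration
#'
#' Study conditions of the synthetic dataset. Defaults emulate the imaging
#' setup the package targets: 512 x 512 frames with 5-20 somas each, three
#' perfusion regimes mixed equally, light instance overlap allowed.
#'
#' @param n_images number of images to generate.
#' @param image_size `c(height, width)` in pixels.
#' @param cells_per_image inclusive integer range `c(min, max)`.
#' @param max_pairwise_overlap_iou maximum IoU tolerated between any two
#'   pasted instance masks, in `[0, 1)`.
#' @param feather_width feather band half-width in pixels for alpha
#'   blending of pasted cells (0 = hard paste).
#' @param noise_density salt-and-pepper corruption density in `[0, 1]`.
#' @param condition_mix probability triple over (baseline, nmda, washout);
#'   must sum to 1.
#' @param radius_range soma mean-radius range in pixels for the parametric
#'   cell renderer.
#' @param eccentricity_range minor/major axis ratio range in `(0, 1]`.
#' @param seed master RNG seed; per-image seeds are derived from it.
#' @param max_retries placement attempts per cell before it is skipped.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_images = 1L,
                             image_size = c(512L, 512L),
                             cells_per_image = c(5L, 20L),
                             max_pairwise_overlap_iou = 0.1,
                             feather_width = 3,
                             noise_density = 0,
                             condition_mix = c(baseline = 1/3, nmda = 1/3,
                                               washout = 1/3),
                             radius_range = c(6, 14),
                             eccentricity_range = c(0.6, 1),
                             seed = 1L,
                             max_retries = 50L) {
  image_size <- unlist(image_size)
  cells_per_image <- unlist(cells_per_image)
  condition_mix <- unlist(condition_mix)
  radius_range <- unlist(radius_range)
  eccentricity_range <- unlist(eccentricity_range)
  if (n_images < 1L) stop_somaswin("n_images must be >= 1")
  if (length(image_size) != 2L || any(image_size < 8))
    stop_somaswin("image_size must be two values >= 8")
  if (cells_per_image[1L] > cells_per_image[2L] || cells_per_image[1L] < 0)
    stop_somaswin("cells_per_image must be a nonempty nonnegative range")
  if (max_pairwise_overlap_iou < 0 || max_pairwise_overlap_iou >= 1)
    stop_somaswin("max_pairwise_overlap_iou must be in [0, 1)")
  if (noise_density < 0 || noise_density > 1)
    stop_somaswin("noise_density must be in [0, 1]")
  if (abs(sum(condition_mix) - 1) > 1e-8)
    stop_somaswin("condition_mix probabilities must sum to 1")
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 cells_per_image = as.integer(cells_per_image),
                 max_pairwise_overlap_iou = max_pairwise_overlap_iou,
                 feather_width = feather_width,
                 noise_density = noise_density,
                 condition_mix = condition_mix,
                 radius_range = radius_range,
                 eccentricity_range = eccentricity_range,
                 seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "generator_config")
}

#' Extract background tiles from an image
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param boxes list of rectangles `c(row, col, height, width)`, 0-based,
#'   half-open, each fully inside the image.
#' @param source_id identifier recorded on each tile.
#' @return list of [background_tile] objects, one per box, each a verbatim
#'   copy of the boxed region.
#' @export
extract_tiles <- function(image, boxes, source_id = "image") {
  assert_unit_image(image)
  lapply(seq_along(boxes), function(i) {
    b <- boxes[[i]]
    if (length(b) != 4L || b[1L] < 0 || b[2L] < 0 || b[3L] < 1 || b[4L] < 1 ||
        b[1L] + b[3L] > nrow(image) || b[2L] + b[4L] > ncol(image))
      stop_somaswin("box %d (%s) is out of bounds for a %dx%d image",
                    i, paste(b, collapse = ","), nrow(image), ncol(image))
    background_tile(image[(b[1L] + 1L):(b[1L] + b[3L]),
                          (b[2L] + 1L):(b[2L] + b[4L]), drop = FALSE],
                    source_id = source_id, box = b)
  })
}

# feathered weight map of a tile: ramps from the border inwards
tile_weight <- function(h, w, feather = 8) {
  f <- max(feather, 1)
  dr <- pmin(seq_len(h), h - seq_len(h) + 1L)
  dc <- pmin(seq_len(w), w - seq_len(w) + 1L)
  pmin(outer(dr, dc, pmin) / f, 1)
}

#' Compose a synthetic background from tiles
#'
#' Tiles are placed (shuffled, at randomised offsets) until the canvas is
#' fully covered, then blended with normalized feathered weights so that
#' tile seams are continuous. Deterministic given the RNG seed.
#'
#' @param tiles nonempty list of [background_tile] objects, none larger
#'   than `size`.
#' @param size output size `c(height, width)`.
#' @param seed RNG seed.
#' @param feather feather ramp width (pixels) used for seam blending.
#' @param n_extra additional random placements layered on top of the
#'   covering pass, for mosaic variety.
#' @return numeric matrix of the requested size with values in `[0, 1]`.
#' @export
compose_background <- function(tiles, size, seed = 1L, feather = 8,
                               n_extra = 2L * length(tiles)) {
  if (length(tiles) == 0L)
    stop_somaswin("compose_background requires at least one tile")
  h <- size[1L]; w <- size[2L]
  for (t in tiles)
    if (nrow(t$pixels) > h || ncol(t$pixels) > w)
      stop_somaswin("tile larger than the target size")
  acc <- matrix(0, h, w); wacc <- matrix(0, h, w)
  place <- function(ti, r0, c0) {
    px <- tiles[[ti]]$pixels
    th <- nrow(px); tw <- ncol(px)
    wt <- tile_weight(th, tw, feather)
    rr <- r0:(r0 + th - 1L); cc <- c0:(c0 + tw - 1L)
    acc[rr, cc] <<- acc[rr, cc] + px * wt
    wacc[rr, cc] <<- wacc[rr, cc] + wt
  }
  with_seed(seed, {
    covered <- matrix(FALSE, h, w)
    while (!all(covered)) {
      first <- which(!covered)[1L]
      fr <- ((first - 1L) %% h) + 1L
      fc <- ((first - 1L) %/% h) + 1L
      ti <- sample.int(length(tiles), 1L)
      th <- nrow(tiles[[ti]]$pixels); tw <- ncol(tiles[[ti]]$pixels)
      # offset so the tile covers the first uncovered pixel, jittered
      r0 <- max(1L, min(fr - sample.int(th, 1L) + 1L, h - th + 1L))
      c0 <- max(1L, min(fc - sample.int(tw, 1L) + 1L, w - tw + 1L))
      if (r0 > fr) r0 <- max(1L, fr - th + 1L)
      if (c0 > fc) c0 <- max(1L, fc - tw + 1L)
      place(ti, r0, c0)
      covered[r0:(r0 + th - 1L), c0:(c0 + tw - 1L)] <- TRUE
    }
    for (k in seq_len(n_extra)) {
      ti <- sample.int(length(tiles), 1L)
      th <- nrow(tiles[[ti]]$pixels); tw <- ncol(tiles[[ti]]$pixels)
      place(ti, sample.int(h - th + 1L, 1L), sample.int(w - tw + 1L, 1L))
    }
  })
  clamp01(acc / wacc)
}

# default peak-intensity regimes per perfusion condition (nmda >= washout
# >= baseline, all above the neuropil background mean of ~0.15)
condition_peak_ranges <- function() {
  list(baseline = c(0.30, 0.60), nmda = c(0.60, 1.00),
       washout = c(0.45, 0.80))
}

#' Render a parametric annotated cell
#'
#' Renders an elliptical soma with a smooth Gaussian-falloff intensity
#' profile, standing in for manually traced cell crops. The binary mask is
#' the region where the profile exceeds half the peak, which for an axis
#' ratio of 1 is a disc of the nominal radius.
#'
#' @param radius_range soma mean-radius range in pixels (>= 2).
#' @param eccentricity_range minor/major axis ratio range in `(0, 1]`
#'   (1 = circular).
#' @param condition perfusion condition controlling the peak-intensity
#'   range; see [annotated_cell].
#' @param peak_range optional explicit peak-intensity range overriding the
#'   condition default; must lie within `(0, 1]`.
#' @param seed RNG seed.
#' @return an [annotated_cell].
#' @export
render_cell <- function(radius_range = c(6, 14),
                        eccentricity_range = c(0.6, 1),
                        condition = c("baseline", "nmda", "washout"),
                        peak_range = NULL, seed = 1L) {
  condition <- match.arg(condition)
  if (min(radius_range) < 2)
    stop_somaswin("soma radius must be >= 2 px")
  if (min(eccentricity_range) <= 0 || max(eccentricity_range) > 1)
    stop_somaswin("eccentricity (axis ratio) must be in (0, 1]")
  pk <- peak_range %||% condition_peak_ranges()[[condition]]
  if (min(pk) <= 0 || max(pk) > 1)
    stop_somaswin("peak intensity range must lie within (0, 1]")
  with_seed(seed, {
    r <- runif(1, radius_range[1L], radius_range[2L])
    q <- runif(1, eccentricity_range[1L], eccentricity_range[2L])
    theta <- runif(1, 0, pi)
    peak <- runif(1, pk[1L], pk[2L])
    a <- r / sqrt(q)  # semi-major
    b <- r * sqrt(q)  # semi-minor; area pi*a*b = pi*r^2
    half <- ceiling(a) + 2L
    s <- 2L * half + 1L
    ctr <- half + 1L
    x <- matrix(rep(seq_len(s) - ctr, each = s), s, s)  # col offsets
    y <- matrix(rep(seq_len(s) - ctr, times = s), s, s) # row offsets
    u <- (x * cos(theta) + y * sin(theta)) / a
    v <- (-x * sin(theta) + y * cos(theta)) / b
    d2 <- u^2 + v^2
    px <- peak * exp(-log(2) * d2)  # half the peak at the nominal boundary
    mask <- d2 <= 1
    annotated_cell(clamp01(px), mask, condition)
  })
}

#' Render a bank of parametric cells
#'
#' @param n number of cells.
#' @param cfg a [generator_config] supplying radius, eccentricity and
#'   condition-mix defaults.
#' @param seed master seed; each cell gets a derived child seed.
#' @return list of [annotated_cell] objects.
#' @export
render_cell_bank <- function(n, cfg = generator_config(), seed = cfg$seed) {
  conds <- with_seed(derive_seed(seed, 0L),
                     sample(names(cfg$condition_mix), n, replace = TRUE,
                            prob = cfg$condition_mix))
  lapply(seq_len(n), function(i)
    render_cell(cfg$radius_range, cfg$eccentricity_range, conds[i],
                seed = derive_seed(seed, i)))
}

#' Render a bank of textured neuropil background tiles
#'
#' Each tile is low-amplitude smoothed noise around a dim mean, emulating
#' the dense low-contrast neuropil signal that surrounds somas.
#'
#' @param n number of tiles.
#' @param tile_size `c(height, width)` of each tile.
#' @param mean_intensity mean background level (below baseline soma peaks).
#' @param texture_sd standard deviation of the smoothed texture.
#' @param seed master seed.
#' @return list of [background_tile] objects.
#' @export
render_tile_bank <- function(n, tile_size = c(96L, 96L),
                             mean_intensity = 0.15, texture_sd = 0.04,
                             seed = 1L) {
  lapply(seq_len(n), function(i) with_seed(derive_seed(seed, i), {
    sigma <- 3
    pad <- 2L * ceiling(3 * sigma) + 2L # render beyond the crop so the
    ph <- tile_size[1L] + 2L * pad      # blur kernel always fits
    pw <- tile_size[2L] + 2L * pad
    raw <- matrix(rnorm(ph * pw), ph, pw)
    sm <- EBImage::gblur(EBImage::Image(raw), sigma = sigma)
    sm <- as.matrix(EBImage::imageData(sm))
    sm <- sm[(pad + 1L):(pad + tile_size[1L]),
             (pad + 1L):(pad + tile_size[2L])]
    sm <- sm / max(stats::sd(sm), 1e-12) * texture_sd
    background_tile(clamp01(mean_intensity + sm),
                    source_id = sprintf("neuropil_%03d", i))
  }))
}

# signed-distance feathered alpha: 1 at depth >= feather inside the mask,
# 0 at distance >= feather outside, linear across the band
feather_alpha <- function(mask, feather) {
  if (feather <= 0) return(mask * 1)
  din <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1))))
  dout <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image((!mask) * 1))))
  s <- ifelse(mask, din, -dout)
  clamp01((s + feather) / (2 * feather))
}

mask_iou_boxed <- function(m1, m2) {
  inter <- sum(m1 & m2)
  if (inter == 0L) return(0)
  inter / sum(m1 | m2)
}

#' Paste annotated cells onto a background
#'
#' Each cell is placed at a uniformly sampled in-bounds offset; a placement
#' is rejected and resampled if the instance mask would overlap an already
#' placed instance with IoU above `cfg$max_pairwise_overlap_iou`. After
#' `cfg$max_retries` failures the cell is skipped and recorded as such in
#' the provenance. The cell interior is composited with feathered alpha
#' (hard paste when `feather_width` is 0).
#'
#' @param background numeric matrix in `[0, 1]`.
#' @param cells list of [annotated_cell] objects.
#' @param cfg a [generator_config].
#' @param seed RNG seed for offsets.
#' @return an object of class `synthetic_image`: fields `pixels`,
#'   `instances` (list of logical masks, one per successfully pasted
#'   cell), `provenance` (one row per requested cell: cell id, offset,
#'   placed flag, condition), `rng_seed`.
#' @export
paste_cells <- function(background, cells, cfg = generator_config(),
                        seed = 1L) {
  assert_unit_image(background, "background")
  h <- nrow(background); w <- ncol(background)
  pixels <- background
  instances <- list()
  prov <- data.frame(cell = integer(0), row = integer(0), col = integer(0),
                     placed = logical(0), condition = character(0),
                     stringsAsFactors = FALSE)
  with_seed(seed, {
    for (k in seq_along(cells)) {
      cell <- cells[[k]]
      ch <- nrow(cell$pixels); cw <- ncol(cell$pixels)
      if (ch > h || cw > w)
        stop_somaswin("cell %d (%dx%d) does not fit in a %dx%d image",
                      k, ch, cw, h, w)
      placed <- FALSE; r0 <- NA_integer_; c0 <- NA_integer_
      for (try in seq_len(cfg$max_retries)) {
        r0 <- sample.int(h - ch + 1L, 1L)
        c0 <- sample.int(w - cw + 1L, 1L)
        full <- matrix(FALSE, h, w)
        full[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L)] <- cell$mask
        ok <- all(vapply(instances, function(m)
          mask_iou_boxed(m, full) <= cfg$max_pairwise_overlap_iou,
          logical(1)))
        if (ok) {
          alpha <- feather_alpha(cell$mask, cfg$feather_width)
          rr <- r0:(r0 + ch - 1L); cc <- c0:(c0 + cw - 1L)
          pixels[rr, cc] <- alpha * cell$pixels +
            (1 - alpha) * pixels[rr, cc]
          instances[[length(instances) + 1L]] <- full
          placed <- TRUE
          break
        }
      }
      prov <- rbind(prov, data.frame(
        cell = k, row = if (placed) r0 - 1L else NA_integer_,
        col = if (placed) c0 - 1L else NA_integer_,
        placed = placed, condition = cell$condition,
        stringsAsFactors = FALSE))
    }
  })
  structure(list(pixels = clamp01(pixels), instances = instances,
                 provenance = prov, rng_seed = as.integer(seed)),
            class = "synthetic_image")
}

#' Corrupt an image with salt-and-pepper noise
#'
#' Each pixel is independently replaced, with probability `density`, by 0
#' or 1 with equal odds; all other pixels are unchanged.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param density corruption probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return corrupted matrix, same shape.
#' @export
add_salt_pepper <- function(image, density, seed = 1L) {
  assert_unit_image(image)
  if (length(density) != 1L || is.na(density) || density < 0 || density > 1)
    stop_somaswin("density must be a single value in [0, 1]")
  if (density == 0) return(image)
  with_seed(seed, {
    hit <- runif(length(image)) < density
    val <- as.numeric(runif(length(image)) < 0.5)
    out <- image
    out[hit] <- val[hit]
    out
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `cfg$n_images` composed images plus one COCO-style annotation
#' file and a manifest. Re-running with the same configuration reproduces
#' byte-identical files.
#'
#' @param cfg a [generator_config].
#' @param cell_bank nonempty list of [annotated_cell] objects.
#' @param tile_bank nonempty list of [background_tile] objects.
#' @param out_dir output directory (created if needed; must be writable).
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit).
#' @return the manifest, invisibly: configuration, file names, per-image
#'   seeds and instance counts, and the annotation file name.
#' @export
generate_dataset <- function(cfg, cell_bank, tile_bank, out_dir,
                             format = c("png", "tiff")) {
  format <- match.arg(format)
  if (length(cell_bank) == 0L || length(tile_bank) == 0L)
    stop_somaswin("cell_bank and tile_bank must be nonempty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop_somaswin("output path '%s' is not writable", out_dir)
  unlink(probe)

  ext <- if (format == "png") "png" else "tif"
  files <- character(cfg$n_images)
  seeds <- integer(cfg$n_images)
  counts <- integer(cfg$n_images)
  records <- vector("list", cfg$n_images)
  for (i in seq_len(cfg$n_images)) {
    si <- derive_seed(cfg$seed, i)
    seeds[i] <- si
    lo <- cfg$cells_per_image[1L]; hi <- cfg$cells_per_image[2L]
    k <- with_seed(derive_seed(si, 1L),
                   lo + sample.int(hi - lo + 1L, 1L) - 1L)
    cells <- if (k > 0L)
      with_seed(derive_seed(si, 2L),
                cell_bank[sample.int(length(cell_bank), k, replace = TRUE)])
    else list()
    bg <- compose_background(tile_bank, cfg$image_size,
                             seed = derive_seed(si, 3L))
    syn <- paste_cells(bg, cells, cfg, seed = derive_seed(si, 4L))
    img <- syn$pixels
    if (cfg$noise_density > 0)
      img <- add_salt_pepper(img, cfg$noise_density,
                             seed = derive_seed(si, 5L))
    files[i] <- sprintf("img_%05d.%s", i, ext)
    write_image(file.path(out_dir, files[i]), img,
                bits = if (format == "png") 8L else 16L)
    counts[i] <- length(syn$instances)
    records[[i]] <- list(file = files[i], height = nrow(img),
                         width = ncol(img), masks = syn$instances,
                         scores = NULL)
  }
  ann_file <- file.path(out_dir, "annotations.json")
  write_annotations(ann_file, records)
  manifest <- list(config = unclass(cfg), files = files, seeds = seeds,
                   n_instances = counts, format = format,
                   annotations = "annotations.json")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
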