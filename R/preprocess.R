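#' Z-stack and MIP preprocessing
#'
#' Raw two-photon Z-series are converted to the network's 2D inputs in
#' four steps, applied in this order: background subtraction and median
#' smoothing on every slice, maximum-intensity projection over windows of
#' 10 slices (20 um at a 2-um step, capturing each soma's maximal area),
#' then CLAHE on each projection.
#'
#' @name preprocess
NULL

#' Construct a Z-stack
#'
#' @param slices list of same-shape numeric matrices, ordered by depth.
#' @param z_step_um axial spacing in micrometres (> 0).
#' @param pixel_size_um lateral scale in micrometres per pixel.
#' @return an object of class `z_stack`.
#' @export
z_stack <- function(slices, z_step_um = 2, pixel_size_um = 1) {
  if (length(slices) < 1L) stop_somaswin("a z_stack needs at least one slice")
  d <- dim(slices[[1L]])
  for (i in seq_along(slices)) {
    assert_image(slices[[i]], sprintf("slice %d", i))
    if (!identical(dim(slices[[i]]), d))
      stop_somaswin("slice %d shape differs from slice 1", i)
  }
  if (z_step_um <= 0) stop_somaswin("z_step_um must be > 0")
  structure(list(slices = slices, z_step_um = z_step_um,
                 pixel_size_um = pixel_size_um),
            class = "z_stack")
}

#' Subtract large-scale background
#'
#' Rolling-ball-style background removal: the background estimate is the
#' grayscale morphological opening with a disc structuring element of the
#' given radius, subtracted and clipped at zero. Structures wider than the
#' disc are treated as background; somas (much smaller than the default
#' 50 px radius) are preserved.
#'
#' @param image numeric matrix.
#' @param radius structuring-element radius in pixels (>= 1, smaller than
#'   the image).
#' @return matrix of the same shape, nonnegative.
#' @export
subtract_background <- function(image, radius = 50L) {
  assert_image(image)
  if (radius < 1) stop_somaswin("radius must be >= 1")
  if (2L * radius + 1L > min(dim(image)))
    stop_somaswin("radius %d exceeds the image size %dx%d", radius,
                  nrow(image), ncol(image))
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- EBImage::opening(EBImage::Image(image), kern)
  pmax(image - as.matrix(EBImage::imageData(bg)), 0)
}

disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Median smoothing over a disc neighborhood
#'
#' Each pixel is replaced by the median over the disc of the given radius
#' centred on it; image borders are handled by reflection.
#'
#' @param image numeric matrix.
#' @param radius neighborhood radius in pixels (default 2, a 13-pixel
#'   disc).
#' @return matrix of the same shape.
#' @export
median_filter <- function(image, radius = 2L) {
  assert_image(image)
  if (radius < 1) stop_somaswin("radius must be >= 1")
  off <- disc_offsets(radius)
  pad <- pad_reflect(image, radius)
  h <- nrow(image); w <- ncol(image)
  nb <- matrix(0, h * w, nrow(off))
  for (k in seq_len(nrow(off))) {
    nb[, k] <- pad[(radius + 1L + off$dr[k]):(radius + h + off$dr[k]),
                   (radius + 1L + off$dc[k]):(radius + w + off$dc[k])]
  }
  matrix(matrixStats::rowMedians(nb), h, w)
}

#' Maximum-intensity projection over slice windows
#'
#' Consecutive windows of `window` slices (advancing by `stride`,
#' default non-overlapping) are reduced by the per-pixel maximum. A
#' trailing partial window is kept and flagged rather than dropped.
#'
#' @param stack a [z_stack].
#' @param window slices per projection (default 10, i.e. 20 um at a 2-um
#'   step).
#' @param stride slices between window starts (default `window`).
#' @return list of `mip_image` objects: `pixels`, `z_range` (1-based
#'   first/last slice), `depth_um`, `partial` flag.
#' @export
mip <- function(stack, window = 10L, stride = window) {
  if (!inherits(stack, "z_stack")) stop_somaswin("'stack' must be a z_stack")
  if (window < 1L || stride < 1L)
    stop_somaswin("window and stride must be >= 1")
  n <- length(stack$slices)
  starts <- seq(1L, n, by = stride)
  lapply(starts, function(s) {
    e <- min(s + window - 1L, n)
    px <- stack$slices[[s]]
    for (i in seq(s, e)) px <- pmax(px, stack$slices[[i]])
    structure(list(pixels = px, z_range = c(s, e),
                   depth_um = (e - s + 1L) * stack$z_step_um,
                   partial = (e - s + 1L) < window),
              class = "mip_image")
  })
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local histogram equalization over a grid of tiles with a clip limit
#' that bounds contrast amplification. Output is rescaled to `[0, 1]`.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param clip_limit normalized clip limit (fraction of the tile's pixels
#'   allowed in one of 256 histogram bins); default 0.01.
#' @param tile_grid `c(nx, ny)` tiles; default 8 x 8.
#' @return matrix in `[0, 1]`.
#' @export
clahe <- function(image, clip_limit = 0.01, tile_grid = c(8L, 8L)) {
  assert_unit_image(image)
  if (any(tile_grid < 1L)) stop_somaswin("tile_grid must be >= 1x1")
  if (clip_limit <= 0) stop_somaswin("clip_limit must be > 0")
  if (max(image) - min(image) < .Machine$double.eps)
    return(image) # no contrast to enhance
  bins <- 256L
  out <- EBImage::clahe(EBImage::Image(image), nx = tile_grid[1L],
                        ny = tile_grid[2L], bins = bins,
                        limit = clip_limit * bins)
  clamp01(as.matrix(EBImage::imageData(out)))
}

#' Preprocessing configuration
#'
#' @param subtract_background enable background subtraction (per slice).
#' @param background_radius structuring radius in pixels.
#' @param median_filter enable median smoothing (per slice).
#' @param median_radius disc radius in pixels.
#' @param window,stride MIP window / stride in slices.
#' @param clahe enable CLAHE (per projection).
#' @param clahe_clip_limit,clahe_tile_grid CLAHE parameters.
#' @return a named list of class `preprocess_config`.
#' @export
preprocess_config <- function(subtract_background = TRUE,
                              background_radius = 50L,
                              median_filter = TRUE, median_radius = 2L,
                              window = 10L, stride = window,
                              clahe = TRUE, clahe_clip_limit = 0.01,
                              clahe_tile_grid = c(8L, 8L)) {
  structure(list(subtract_background = subtract_background,
                 background_radius = background_radius,
                 median_filter = median_filter,
                 median_radius = median_radius,
                 window = as.integer(window), stride = as.integer(stride),
                 clahe = clahe, clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = clahe_tile_grid),
            class = "preprocess_config")
}

#' Full stack preprocessing pipeline
#'
#' Applies, in order: background subtraction and median smoothing on each
#' slice, maximum-intensity projection, CLAHE on each projection. Each
#' returned projection carries the applied parameters in its
#' `provenance` field.
#'
#' @param stack a [z_stack].
#' @param cfg a [preprocess_config].
#' @return list of `mip_image` objects.
#' @export
preprocess_stack <- function(stack, cfg = preprocess_config()) {
  if (!inherits(stack, "z_stack")) stop_somaswin("'stack' must be a z_stack")
  slices <- stack$slices
  if (isTRUE(cfg$subtract_background))
    slices <- lapply(slices, subtract_background, radius = cfg$background_radius)
  if (isTRUE(cfg$median_filter))
    slices <- lapply(slices, median_filter, radius = cfg$median_radius)
  st <- z_stack(slices, stack$z_step_um, stack$pixel_size_um)
  mips <- mip(st, window = cfg$window, stride = cfg$stride)
  lapply(mips, function(m) {
    if (isTRUE(cfg$clahe))
      m$pixels <- clahe(clamp01(m$pixels), cfg$clahe_clip_limit,
                        cfg$clahe_tile_grid)
    m$provenance <- unclass(cfg)
    m
  })
}
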