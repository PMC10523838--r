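#' File formats
#'
#' Images travel as single-page grayscale PNG (8-bit) or TIFF (16-bit),
#' stacks as multi-page TIFF, and instance annotations as COCO-style JSON
#' with uncompressed column-major RLE masks (bit-exact round trips). All
#' rectangle coordinates are 0-based, row-major, half-open.
#'
#' @name io
NULL

#' Encode a binary mask as uncompressed RLE
#'
#' Column-major run lengths starting with the count of leading background
#' pixels (COCO convention), so the first run may be 0.
#'
#' @param mask logical matrix.
#' @return integer vector of run lengths summing to `length(mask)`.
#' @export
rle_encode <- function(mask) {
  v <- as.integer(mask)
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1L] != 0L) counts <- c(0L, counts)
  as.integer(counts)
}

#' Decode uncompressed RLE into a binary mask
#'
#' @param counts integer run lengths (see [rle_encode]).
#' @param h,w mask dimensions.
#' @return logical matrix of dimension `h` x `w`.
#' @export
rle_decode <- function(counts, h, w) {
  counts <- as.integer(counts)
  if (sum(counts) != h * w)
    stop_somaswin("RLE counts sum to %d, expected %d", sum(counts), h * w)
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  matrix(as.logical(vals), h, w)
}

#' Write a grayscale image
#'
#' @param path output path; extension selects nothing, `bits` does.
#' @param image numeric matrix in `[0, 1]`.
#' @param bits 8 (PNG) or 16 (uncompressed TIFF).
#' @export
write_image <- function(path, image, bits = 8L) {
  assert_unit_image(image)
  if (bits == 8L) {
    png::writePNG(image, path)
  } else if (bits == 16L) {
    tiff::writeTIFF(image, path, bits.per.sample = 16L,
                    compression = "none")
  } else stop_somaswin("bits must be 8 or 16")
  invisible(path)
}

#' Read a grayscale image
#'
#' @param path PNG or TIFF file.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_somaswin("image file '%s' not found", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else tiff::readTIFF(path)
  to_gray(img, path)
}

to_gray <- function(img, path) {
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] > 1L)
      stop_somaswin("'%s' is not grayscale (%d channels)", path,
                    dim(img)[3L])
    img <- img[, , 1L]
  }
  if (!is.matrix(img)) stop_somaswin("'%s' is not a 2D image", path)
  img
}

#' Read a multi-page TIFF Z-stack
#'
#' @param path multi-page TIFF of same-shape grayscale slices.
#' @param z_step_um axial spacing between slices in micrometres.
#' @param pixel_size_um lateral scale in micrometres per pixel.
#' @return a [z_stack].
#' @export
read_stack <- function(path, z_step_um = 2, pixel_size_um = 1) {
  if (!file.exists(path)) stop_somaswin("stack file '%s' not found", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(seq_along(pages), function(i) to_gray(pages[[i]], path))
  z_stack(slices, z_step_um = z_step_um, pixel_size_um = pixel_size_um)
}

#' Write a Z-stack as a multi-page TIFF
#'
#' @param path output path.
#' @param stack a [z_stack].
#' @export
write_stack <- function(path, stack) {
  tiff::writeTIFF(stack$slices, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write COCO-style instance annotations
#'
#' One record per image: `file`, `height`, `width`, a list of binary
#' `masks` and optional per-instance `scores`. Written as a COCO-style
#' JSON with `images`, `annotations` (RLE segmentation, bbox, area,
#' optional score) and a single category `neuron_soma`.
#'
#' @param path output JSON path.
#' @param records list of per-image records as above.
#' @export
write_annotations <- function(path, records) {
  images <- list(); annotations <- list(); aid <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    images[[i]] <- list(id = i, file_name = rec$file,
                        height = rec$height, width = rec$width)
    for (j in seq_along(rec$masks)) {
      m <- rec$masks[[j]]
      if (!identical(dim(m), c(rec$height, rec$width)) ||
          nrow(m) != rec$height)
        stop_somaswin("image %d, instance %d: mask shape differs from the image",
                      i, j)
      aid <- aid + 1L
      ann <- list(id = aid, image_id = i, category_id = 1L,
                  segmentation = list(size = c(rec$height, rec$width),
                                      counts = rle_encode(m)),
                  area = sum(m), bbox = mask_bbox(m), iscrowd = 0L)
      if (!is.null(rec$scores)) ann$score <- rec$scores[[j]]
      annotations[[aid]] <- ann
    }
  }
  obj <- list(images = images, annotations = annotations,
              categories = list(list(id = 1L, name = "neuron_soma")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read COCO-style instance annotations
#'
#' @param path JSON file written by [write_annotations] (or compatible).
#' @return list of per-image records (`file`, `height`, `width`, `masks`,
#'   `scores` — `NULL` when absent), in image-id order.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_somaswin("annotation file '%s' not found", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$images))
    stop_somaswin("'%s' has no 'images' block", path)
  recs <- lapply(obj$images, function(im)
    list(id = im$id, file = im$file_name, height = im$height,
         width = im$width, masks = list(), scores = NULL))
  ids <- vapply(obj$images, function(im) as.integer(im$id), integer(1))
  for (k in seq_along(obj$annotations)) {
    ann <- obj$annotations[[k]]
    pos <- match(as.integer(ann$image_id), ids)
    if (is.na(pos))
      stop_somaswin("'%s': annotation %d references unknown image id %s",
                    path, k, ann$image_id)
    rec <- recs[[pos]]
    counts <- unlist(ann$segmentation$counts)
    if (sum(counts) != rec$height * rec$width)
      stop_somaswin("'%s': annotation %d mask does not fit a %dx%d image",
                    path, k, rec$height, rec$width)
    rec$masks[[length(rec$masks) + 1L]] <-
      rle_decode(counts, rec$height, rec$width)
    if (!is.null(ann$score))
      rec$scores <- c(rec$scores, as.numeric(ann$score))
    recs[[pos]] <- rec
  }
  recs
}

#' Read and validate a run configuration
#'
#' A YAML file with any of the blocks `simulate`, `preprocess`,
#' `backbone`, `detector`, `evaluate` plus optional top-level `seed`,
#' `output` and `log_level`. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_somaswin("config file '%s' not found", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c("simulate", "preprocess", "backbone", "detector",
               "evaluate", "seed", "output", "log_level")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L)
    stop_somaswin("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg
}

#' Write the resolved configuration beside run outputs
#'
#' @param cfg named list.
#' @param out_dir directory receiving `resolved_config.yaml`.
#' @export
write_resolved_config <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  invisible(file.path(out_dir, "resolved_config.yaml"))
}
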