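#' Soma instance detector
#'
#' The detector couples the frozen hierarchical Swin backbone (a
#' deterministic feature extractor) with a trainable dense-prediction
#' head: every pixel gets a feature vector made of its raw and locally
#' smoothed intensity plus the upsampled backbone features of the token
#' covering it, and a logistic scoring layer maps that vector to a
#' foreground probability. Instances are the connected components of the
#' thresholded probability map; each component's confidence score is its
#' mean foreground probability, and inference-time confidence
#' thresholding trades recall against precision exactly as a detection
#' score cutoff does.
#'
#' @name detector
NULL

#' Head configuration
#'
#' @param feature_stages backbone stages whose (upsampled) features feed
#'   the head; default stages 1-2.
#' @param min_area smallest connected component kept as an instance, in
#'   pixels.
#' @param mask_prob probability cutoff binarizing the foreground map.
#' @param smooth_sigma Gaussian sigma (pixels) of the smoothed-intensity
#'   input channel.
#' @return an object of class `head_config`.
#' @export
head_config <- function(feature_stages = c(1L, 2L), min_area = 9L,
                        mask_prob = 0.5, smooth_sigma = 2) {
  if (any(feature_stages < 1L | feature_stages > 4L))
    stop_somaswin("feature_stages must be within 1..4")
  if (mask_prob <= 0 || mask_prob >= 1)
    stop_somaswin("mask_prob must be in (0, 1)")
  structure(list(feature_stages = as.integer(feature_stages),
                 min_area = as.integer(min_area), mask_prob = mask_prob,
                 smooth_sigma = smooth_sigma),
            class = "head_config")
}

#' Training configuration
#'
#' @param epochs passes over the training set.
#' @param lr Adam learning rate.
#' @param lr_schedule `"constant"` or `"cosine"` (decay to 0 over the
#'   run).
#' @param pos_weight weight of foreground pixels in the loss; `NULL`
#'   balances classes per image (capped at 20).
#' @param augment_flips random horizontal/vertical flips.
#' @param augment_salt_pepper salt-and-pepper density applied to a random
#'   half of the training views (0 disables).
#' @param seed RNG seed, recorded in checkpoints.
#' @param checkpoint_every write a checkpoint every this many epochs when
#'   a path is given (0 = only at the end).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, lr = 0.05,
                         lr_schedule = c("cosine", "constant"),
                         pos_weight = NULL, augment_flips = FALSE,
                         augment_salt_pepper = 0, seed = 1L,
                         checkpoint_every = 0L) {
  lr_schedule <- match.arg(lr_schedule)
  if (epochs < 1L) stop_somaswin("epochs must be >= 1")
  if (lr <= 0) stop_somaswin("lr must be > 0")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 lr_schedule = lr_schedule, pos_weight = pos_weight,
                 augment_flips = isTRUE(augment_flips),
                 augment_salt_pepper = augment_salt_pepper,
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

head_n_features <- function(backbone_cfg, head_cfg) {
  2L + sum(backbone_cfg$embed_dim * 2L^(head_cfg$feature_stages - 1L))
}

#' Build a detector model
#'
#' Initializes the backbone weights (frozen) and a zero-initialized
#' logistic head over the configured feature stages.
#'
#' @param backbone_cfg a [backbone_config].
#' @param head_cfg a [head_config].
#' @param seed RNG seed for the backbone initialization; two builds with
#'   the same seed have identical weights.
#' @return an object of class `soma_model`.
#' @export
build_model <- function(backbone_cfg = backbone_config(),
                        head_cfg = head_config(), seed = 1L) {
  backbone <- init_backbone(backbone_cfg, seed)
  nf <- head_n_features(backbone_cfg, head_cfg)
  structure(list(backbone_cfg = backbone_cfg, head_cfg = head_cfg,
                 backbone = backbone,
                 head = list(w = rep(0, nf), b = 0),
                 seed = as.integer(seed)),
            class = "soma_model")
}

upsample_nn <- function(mat_tokens, ht, wt, factor, h, w) {
  ri <- rep(seq_len(ht), each = factor)[seq_len(h)] # token row per pixel row
  ci <- rep(seq_len(wt), each = factor)[seq_len(w)] # token col per pixel col
  # mat_tokens: (ht*wt) x D, column-major over (row, col); expand to all
  # pixels in column-major order (pixel rows fastest)
  idx <- rep(ri, times = w) + (rep(ci, each = h) - 1L) * ht
  mat_tokens[idx, , drop = FALSE]
}

#' Per-pixel feature matrix of an image
#'
#' @param model a `soma_model`.
#' @param image grayscale matrix in `[0, 1]`.
#' @return `(npix x n_features)` matrix (pixels column-major).
#' @export
image_features <- function(model, image) {
  assert_unit_image(image)
  h <- nrow(image); w <- ncol(image)
  sm <- as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(image),
                   sigma = model$head_cfg$smooth_sigma)))
  feats <- list(as.vector(image), as.vector(sm))
  outs <- backbone_forward(image, model$backbone_cfg, model$backbone)
  p <- model$backbone_cfg$patch_size
  for (s in model$head_cfg$feature_stages) {
    g <- outs[[s]]
    d <- grid_dims(g)
    up <- upsample_nn(grid_to_mat(g$tokens), d[1L], d[2L],
                      p * 2L^(s - 1L), h, w)
    feats[[length(feats) + 1L]] <- up
  }
  do.call(cbind, feats)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Foreground probability map
#'
#' @param model a `soma_model`.
#' @param image grayscale matrix in `[0, 1]`.
#' @param features optional precomputed [image_features] matrix.
#' @return matrix of per-pixel foreground probabilities.
#' @export
predict_probability <- function(model, image, features = NULL) {
  if (is.null(features)) features <- image_features(model, image)
  matrix(sigmoid(as.vector(features %*% model$head$w) + model$head$b),
         nrow(image), ncol(image))
}

instance_prediction <- function(mask, score) {
  structure(list(mask = mask, score = score, box = mask_bbox(mask)),
            class = "instance_prediction")
}

#' Predict soma instances in an image
#'
#' Thresholds the foreground probability map at the head's mask cutoff,
#' labels connected components, discards components below the minimum
#' area, scores each instance by its mean foreground probability, and
#' keeps instances with score at or above `threshold`, sorted by
#' descending score.
#'
#' @param model a `soma_model`.
#' @param image grayscale matrix in `[0, 1]`.
#' @param threshold confidence cutoff in `[0, 1]`; the default 0.05
#'   favors recall, higher values trade detections for precision.
#' @param features optional precomputed [image_features] matrix.
#' @return list of `instance_prediction` objects (`mask`, `score`,
#'   `box`).
#' @export
predict_image <- function(model, image, threshold = 0.05,
                          features = NULL) {
  if (length(threshold) != 1L || threshold < 0 || threshold > 1)
    stop_somaswin("threshold must be a single value in [0, 1]")
  prob <- predict_probability(model, image, features)
  lab <- EBImage::bwlabel(EBImage::Image(prob >= model$head_cfg$mask_prob))
  lab <- as.matrix(EBImage::imageData(lab))
  preds <- list()
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      m <- lab == k
      if (sum(m) < model$head_cfg$min_area) next
      preds[[length(preds) + 1L]] <-
        instance_prediction(m, mean(prob[m]))
    }
  }
  if (length(preds) > 1L)
    preds <- preds[order(-vapply(preds, function(p) p$score, numeric(1)))]
  filter_by_score(preds, threshold)
}

#' Filter predictions by confidence score
#'
#' Keeps exactly the predictions with `score >= threshold`, preserving
#' order.
#'
#' @param preds list of `instance_prediction` objects.
#' @param threshold confidence cutoff.
#' @return filtered list.
#' @export
filter_by_score <- function(preds, threshold) {
  keep <- vapply(preds, function(p) p$score >= threshold, logical(1))
  preds[keep]
}

#' Load a generated dataset into memory
#'
#' @param data_dir directory written by [generate_dataset] (containing
#'   `manifest.json` and the annotation file).
#' @return list with `images` (matrices), `targets` (union ground-truth
#'   masks), `records` (per-image annotation records), `manifest`.
#' @export
load_dataset <- function(data_dir) {
  mf_path <- file.path(data_dir, "manifest.json")
  if (!file.exists(mf_path))
    stop_somaswin("no manifest.json under '%s'", data_dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  recs <- read_annotations(file.path(data_dir, manifest$annotations))
  images <- lapply(manifest$files, function(f)
    read_image(file.path(data_dir, f)))
  targets <- lapply(seq_along(images), function(i) {
    t <- matrix(FALSE, nrow(images[[i]]), ncol(images[[i]]))
    for (m in recs[[i]]$masks) t <- t | m
    t
  })
  list(images = images, targets = targets, records = recs,
       manifest = manifest)
}

#' Train the detector head
#'
#' Minimizes the class-weighted binary cross-entropy of the per-pixel
#' foreground probabilities against the union of ground-truth instance
#' masks, by Adam on the head parameters (the backbone stays frozen, so
#' per-image features are computed once and cached). One step = one
#' image; the per-step loss is logged. Training aborts with a diagnostic
#' if the loss turns non-finite.
#'
#' @param model a `soma_model`.
#' @param data a dataset directory (see [generate_dataset]) or the list
#'   returned by [load_dataset].
#' @param cfg a [train_config].
#' @param checkpoint_path optional path receiving checkpoints.
#' @return list with the trained `model`, the per-step `loss_log`
#'   (epoch, step, loss), and `cfg`.
#' @export
train_model <- function(model, data, cfg = train_config(),
                        checkpoint_path = NULL) {
  if (is.character(data)) data <- load_dataset(data)
  n <- length(data$images)
  if (n == 0L) stop_somaswin("the training dataset is empty")
  for (i in seq_len(n))
    if (!identical(dim(data$images[[i]]), dim(data$targets[[i]])))
      stop_somaswin("image %d: mask shape differs from the image", i)

  feats <- vector("list", n)
  ys <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) {
    img <- data$images[[i]]
    feats[[i]] <- image_features(model, img)
    y <- as.numeric(as.vector(data$targets[[i]]))
    pw <- cfg$pos_weight %||%
      min(max(sum(y == 0) / max(sum(y == 1), 1), 1), 20)
    ys[[i]] <- y
    wts[[i]] <- ifelse(y == 1, pw, 1)
  }

  np <- length(model$head$w) + 1L
  theta <- c(model$head$w, model$head$b)
  m1 <- numeric(np); m2 <- numeric(np)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  total_steps <- cfg$epochs * n
  loss_log <- data.frame(epoch = integer(0), step = integer(0),
                         loss = numeric(0))
  step <- 0L
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        step <- step + 1L
        Fm <- feats[[i]]; y <- ys[[i]]; wt <- wts[[i]]
        eta <- as.vector(Fm %*% theta[-np]) + theta[np]
        p <- sigmoid(eta)
        loss <- -mean(wt * (y * log(pmax(p, 1e-12)) +
                              (1 - y) * log(pmax(1 - p, 1e-12))))
        if (!is.finite(loss))
          stop_somaswin("non-finite loss at epoch %d step %d", ep, step)
        g_eta <- wt * (p - y) / length(y)
        grad <- c(as.vector(crossprod(Fm, g_eta)), sum(g_eta))
        lr <- if (cfg$lr_schedule == "cosine")
          cfg$lr * 0.5 * (1 + cos(pi * (step - 1L) / total_steps))
        else cfg$lr
        m1 <- b1 * m1 + (1 - b1) * grad
        m2 <- b2 * m2 + (1 - b2) * grad^2
        mh <- m1 / (1 - b1^step); vh <- m2 / (1 - b2^step)
        theta <- theta - lr * mh / (sqrt(vh) + eps)
        loss_log <- rbind(loss_log,
                          data.frame(epoch = ep, step = step, loss = loss))
      }
      if (!is.null(checkpoint_path) && cfg$checkpoint_every > 0L &&
          ep %% cfg$checkpoint_every == 0L) {
        model$head <- list(w = theta[-np], b = theta[np])
        save_checkpoint(checkpoint_path, model, cfg, loss_log)
      }
    }
  })
  model$head <- list(w = theta[-np], b = theta[np])
  if (!is.null(checkpoint_path))
    save_checkpoint(checkpoint_path, model, cfg, loss_log)
  list(model = model, loss_log = loss_log, cfg = cfg)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds all weights, both configurations, the training
#' seed and the loss log; loading restores bit-identical predictions.
#'
#' @param path checkpoint file.
#' @param model a `soma_model`.
#' @param train_cfg the [train_config] used (if any).
#' @param loss_log per-step loss data frame.
#' @return `save_checkpoint` returns the path invisibly;
#'   `load_checkpoint` returns the checkpoint list (`model`,
#'   `train_cfg`, `loss_log`).
#' @export
save_checkpoint <- function(path, model, train_cfg = NULL,
                            loss_log = NULL) {
  saveRDS(list(model = model, train_cfg = train_cfg,
               loss_log = loss_log, format_version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_somaswin("checkpoint '%s' not found", path)
  ck <- readRDS(path)
  if (is.null(ck$model)) stop_somaswin("'%s' is not a somaswin checkpoint", path)
  ck
}

#' Write predictions as COCO-style JSON
#'
#' @param path output file.
#' @param preds list of `instance_prediction` objects.
#' @param image the image the predictions refer to (for dimensions).
#' @param file image file name recorded in the JSON.
#' @export
write_predictions <- function(path, preds, image, file = "image") {
  write_annotations(path, list(list(
    file = file, height = nrow(image), width = ncol(image),
    masks = lapply(preds, function(p) p$mask),
    scores = vapply(preds, function(p) p$score, numeric(1)))))
}
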