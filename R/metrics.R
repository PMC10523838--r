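#' Quantitative evaluation protocol
#'
#' Pixel-overlap scores (Dice, IoU), one-to-one instance matching against
#' ground truth with TP/FP/FN verdicts and FP sub-typing, precision,
#' recall, yield rate, somatic areas and their agreement with manual
#' tracings, and confidence-threshold sweeps.
#'
#' @name metrics
NULL

check_mask_pair <- function(X, Y) {
  if (!is.logical(X)) X <- X > 0
  if (!is.logical(Y)) Y <- Y > 0
  if (!identical(dim(X), dim(Y)))
    stop_somaswin("masks must share the same shape")
  if (!any(X) && !any(Y))
    stop_somaswin("overlap of two empty masks is undefined")
  list(X = X, Y = Y)
}

#' Dice coefficient of two masks
#'
#' `2|X intersect Y| / (|X| + |Y|)`; symmetric, in `[0, 1]`.
#'
#' @param X,Y binary masks of the same shape, not both empty.
#' @return the Dice coefficient.
#' @export
dice <- function(X, Y) {
  m <- check_mask_pair(X, Y)
  2 * sum(m$X & m$Y) / (sum(m$X) + sum(m$Y))
}

#' Intersection over union (Jaccard index) of two masks
#'
#' `|X intersect Y| / |X union Y|`; symmetric, in `[0, 1]`, and related
#' to Dice by `dice = 2*iou / (1 + iou)`.
#'
#' @param X,Y binary masks of the same shape, not both empty.
#' @return the IoU.
#' @export
iou <- function(X, Y) {
  m <- check_mask_pair(X, Y)
  sum(m$X & m$Y) / sum(m$X | m$Y)
}

#' Match predicted instances to ground truth
#'
#' Each ground-truth soma is paired with the still-unassigned prediction
#' of highest Dice (the closest-overlapping detection); ground truths are
#' processed in descending order of their best Dice, ties broken by
#' lowest index, and assignment is one-to-one. A pairing is a true
#' positive when its IoU exceeds `iou_threshold`; otherwise the ground
#' truth is a false negative and the candidate is left unconsumed.
#' Unmatched predictions are false positives, sub-typed as doublets
#' (overlapping at least two ground truths with IoU above
#' `doublet_iou` each), wrong boundaries (best IoU with some ground
#' truth in `(0, iou_threshold]`), or background detections.
#'
#' @param gt_masks list of ground-truth binary masks (one per soma).
#' @param pred_masks list of predicted binary masks.
#' @param iou_threshold IoU above which a pairing counts as correct
#'   (default 0.5).
#' @param doublet_iou minimum per-ground-truth IoU for the doublet
#'   verdict (default 0.2).
#' @return an object of class `match_result`: data frames `gt` (matched
#'   prediction, dice, iou, verdict TP/FN) and `pred` (verdict TP /
#'   FP_wrong_boundary / FP_doublet / FP_background, matched ground
#'   truth), and counts `tp`, `fp`, `fn`.
#' @export
match_instances <- function(gt_masks, pred_masks, iou_threshold = 0.5,
                            doublet_iou = 0.2) {
  ng <- length(gt_masks); np <- length(pred_masks)
  all_masks <- c(gt_masks, pred_masks)
  if (length(all_masks) > 0L) {
    ref <- dim(all_masks[[1L]])
    for (m in all_masks)
      if (!identical(dim(m), ref))
        stop_somaswin("all masks must share the image shape")
  }
  D <- matrix(0, ng, np); U <- matrix(0, ng, np)
  if (ng > 0 && np > 0)
    for (i in seq_len(ng)) for (j in seq_len(np)) {
      inter <- sum(gt_masks[[i]] & pred_masks[[j]])
      if (inter > 0) {
        D[i, j] <- 2 * inter / (sum(gt_masks[[i]]) + sum(pred_masks[[j]]))
        U[i, j] <- inter / sum(gt_masks[[i]] | pred_masks[[j]])
      }
    }
  gt_match <- rep(NA_integer_, ng)
  gt_dice <- numeric(ng); gt_iou <- numeric(ng)
  assigned <- logical(np)
  if (ng > 0 && np > 0) {
    best <- apply(D, 1L, max)
    order_gt <- order(-best, seq_len(ng))
    for (i in order_gt) {
      avail <- which(!assigned)
      if (length(avail) == 0L) break
      j <- avail[which.max(D[i, avail])]
      if (D[i, j] <= 0) next
      if (U[i, j] > iou_threshold) {
        gt_match[i] <- j
        gt_dice[i] <- D[i, j]; gt_iou[i] <- U[i, j]
        assigned[j] <- TRUE
      }
    }
  }
  gt_verdict <- ifelse(is.na(gt_match), "FN", "TP")
  pred_verdict <- character(np)
  matched_gt <- rep(NA_integer_, np)
  for (j in seq_len(np)) {
    i <- match(j, gt_match)
    if (!is.na(i)) {
      pred_verdict[j] <- "TP"; matched_gt[j] <- i
    } else if (ng > 0 && sum(U[, j] > doublet_iou) >= 2L) {
      pred_verdict[j] <- "FP_doublet"
    } else if (ng > 0 && max(U[, j]) > 0 &&
               max(U[, j]) <= iou_threshold) {
      pred_verdict[j] <- "FP_wrong_boundary"
    } else {
      pred_verdict[j] <- "FP_background"
    }
  }
  tp <- sum(gt_verdict == "TP")
  structure(list(
    gt = data.frame(gt = seq_len(ng), pred = gt_match, dice = gt_dice,
                    iou = gt_iou, verdict = gt_verdict,
                    stringsAsFactors = FALSE),
    pred = data.frame(pred = seq_len(np), gt = matched_gt,
                      verdict = pred_verdict, stringsAsFactors = FALSE),
    tp = tp, fp = np - tp, fn = ng - tp,
    iou_threshold = iou_threshold),
    class = "match_result")
}

check_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop_somaswin("'%s' must be a single nonnegative integer", name)
  as.numeric(x)
}

#' Precision of a detection set
#'
#' `TP / (TP + FP)`.
#'
#' @param tp,fp true / false positive counts.
#' @return precision in `[0, 1]`; an error when `tp + fp` is zero
#'   (undefined).
#' @export
precision <- function(tp, fp) {
  tp <- check_count(tp, "tp"); fp <- check_count(fp, "fp")
  if (tp + fp == 0) stop_somaswin("precision undefined: no detections")
  tp / (tp + fp)
}

#' Recall of a detection set
#'
#' `TP / (TP + FN)`.
#'
#' @param tp,fn true positive / false negative counts.
#' @return recall in `[0, 1]`; an error when `tp + fn` is zero
#'   (undefined).
#' @export
recall <- function(tp, fn) {
  tp <- check_count(tp, "tp"); fn <- check_count(fn, "fn")
  if (tp + fn == 0) stop_somaswin("recall undefined: no ground truths")
  tp / (tp + fn)
}

#' Yield rate
#'
#' Fraction of ground-truth neurons correctly detected.
#'
#' @param n_correct correctly detected neurons (`<= n_gt`).
#' @param n_gt total ground-truth neurons (`> 0`).
#' @return `n_correct / n_gt`.
#' @export
yield_rate <- function(n_correct, n_gt) {
  n_correct <- check_count(n_correct, "n_correct")
  n_gt <- check_count(n_gt, "n_gt")
  if (n_gt == 0) stop_somaswin("yield rate undefined: no ground truths")
  if (n_correct > n_gt)
    stop_somaswin("n_correct (%d) exceeds n_gt (%d)", n_correct, n_gt)
  n_correct / n_gt
}

#' Somatic area of a mask
#'
#' @param mask binary mask.
#' @param pixel_size_um lateral scale in micrometres per pixel (> 0).
#' @return area in square micrometres.
#' @export
soma_area <- function(mask, pixel_size_um) {
  if (pixel_size_um <= 0) stop_somaswin("pixel_size_um must be > 0")
  sum(mask > 0) * pixel_size_um^2
}

#' Agreement between predicted and manual somatic areas
#'
#' Mean and SD of the per-soma difference (predicted minus manual),
#' ordinary least-squares regression of predicted on manual, and the
#' squared Pearson correlation.
#'
#' @param paired_areas two-column matrix or data frame of
#'   `(predicted, manual)` areas, at least 3 pairs.
#' @return list with `mean_diff`, `sd_diff`, `slope`, `intercept`,
#'   `r_squared` (`NA` with a warning-free `constant` flag when the
#'   manual areas are constant and the correlation is undefined).
#' @export
area_agreement <- function(paired_areas) {
  pa <- as.matrix(paired_areas)
  if (nrow(pa) < 3L) stop_somaswin("need at least 3 area pairs")
  pred <- pa[, 1L]; man <- pa[, 2L]
  diffs <- pred - man
  constant <- stats::var(man) < .Machine$double.eps
  if (constant) {
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
  } else {
    fit <- stats::lm(pred ~ man)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    r2 <- if (stats::var(pred) < .Machine$double.eps) NA_real_
          else stats::cor(pred, man)^2
  }
  list(mean_diff = mean(diffs), sd_diff = stats::sd(diffs), slope = slope,
       intercept = intercept, r_squared = r2, constant_manual = constant)
}

#' Confidence-threshold sweep
#'
#' For each ascending confidence threshold, filters every image's
#' predictions, matches them to ground truth, and tabulates the total
#' detections with the percentage that are correct (TP), wrong-boundary
#' FPs, and background-or-doublet FPs — the layout of a detector
#' threshold-performance table.
#'
#' @param predictions_by_image list (one entry per image) of
#'   `instance_prediction` lists.
#' @param gt_by_image list (same length) of ground-truth mask lists.
#' @param thresholds ascending confidence thresholds.
#' @param iou_threshold IoU cutoff for a correct detection.
#' @return data frame with one row per threshold: `threshold`,
#'   `total_detected`, `pct_correct`, `pct_wrong_boundary`,
#'   `pct_background_doublet`, plus `tp`, `fp`, `fn`, `precision`,
#'   `recall`.
#' @export
threshold_sweep <- function(predictions_by_image, gt_by_image, thresholds,
                            iou_threshold = 0.5) {
  if (length(predictions_by_image) != length(gt_by_image))
    stop_somaswin("prediction and ground-truth lists differ in length")
  if (is.unsorted(thresholds))
    stop_somaswin("thresholds must be sorted ascending")
  rows <- lapply(thresholds, function(th) {
    tot <- 0L; tp <- 0L; wb <- 0L; bgd <- 0L; fn <- 0L
    for (i in seq_along(predictions_by_image)) {
      kept <- filter_by_score(predictions_by_image[[i]], th)
      tot <- tot + length(kept)
      mr <- match_instances(gt_by_image[[i]],
                            lapply(kept, function(p) p$mask),
                            iou_threshold)
      tp <- tp + mr$tp; fn <- fn + mr$fn
      wb <- wb + sum(mr$pred$verdict == "FP_wrong_boundary")
      bgd <- bgd + sum(mr$pred$verdict %in%
                         c("FP_background", "FP_doublet"))
    }
    data.frame(threshold = th, total_detected = tot,
               pct_correct = if (tot > 0) 100 * tp / tot else NA_real_,
               pct_wrong_boundary = if (tot > 0) 100 * wb / tot else NA_real_,
               pct_background_doublet = if (tot > 0) 100 * bgd / tot
                                        else NA_real_,
               tp = tp, fp = wb + bgd, fn = fn,
               precision = if (tot > 0) tp / tot else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Evaluate predictions against ground truth
#'
#' Convenience wrapper: matches every image, pools the counts, and
#' reports precision, recall, yield rate and mean Dice/IoU over true
#' positives.
#'
#' @param predictions_by_image list of `instance_prediction` lists.
#' @param gt_by_image list of ground-truth mask lists.
#' @param iou_threshold IoU cutoff for a correct detection.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `yield_rate`, `mean_dice`, `mean_iou`, and per-image
#'   `match_results`.
#' @export
evaluate_detections <- function(predictions_by_image, gt_by_image,
                                iou_threshold = 0.5) {
  mrs <- lapply(seq_along(gt_by_image), function(i)
    match_instances(gt_by_image[[i]],
                    lapply(predictions_by_image[[i]], function(p) p$mask),
                    iou_threshold))
  tp <- sum(vapply(mrs, function(m) m$tp, numeric(1)))
  fp <- sum(vapply(mrs, function(m) m$fp, numeric(1)))
  fn <- sum(vapply(mrs, function(m) m$fn, numeric(1)))
  dvals <- unlist(lapply(mrs, function(m) m$gt$dice[m$gt$verdict == "TP"]))
  uvals <- unlist(lapply(mrs, function(m) m$gt$iou[m$gt$verdict == "TP"]))
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       yield_rate = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       mean_dice = if (length(dvals)) mean(dvals) else NA_real_,
       mean_iou = if (length(uvals)) mean(uvals) else NA_real_,
       match_results = mrs)
}
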