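# Independent brute-force oracles and shared fixtures. Everything here is
# deliberately written as plain scalar loops over pixel sets, separate
# from the package's vectorized code paths.

# ---- overlap oracles (explicit pixel-set arithmetic) ----

naive_dice <- function(X, Y) {
  xs <- which(X); ys <- which(Y)
  2 * length(intersect(xs, ys)) / (length(xs) + length(ys))
}

naive_iou <- function(X, Y) {
  xs <- which(X); ys <- which(Y)
  length(intersect(xs, ys)) / length(union(xs, ys))
}

# scalar reimplementation of the per-GT greedy matching rule: ground
# truths in descending best-Dice order, candidate = unassigned prediction
# of highest Dice (ties -> lowest index), TP iff IoU > threshold
oracle_match <- function(gt, pred, iou_thr = 0.5) {
  ng <- length(gt); np <- length(pred)
  best <- numeric(ng)
  for (i in seq_len(ng)) {
    b <- 0
    for (j in seq_len(np)) b <- max(b, naive_dice(gt[[i]], pred[[j]]))
    best[i] <- b
  }
  taken <- rep(FALSE, np)
  match_of <- rep(NA_integer_, ng)
  for (i in order(-best, seq_len(ng))) {
    cand <- NA_integer_; cd <- 0
    for (j in seq_len(np)) {
      if (taken[j]) next
      d <- naive_dice(gt[[i]], pred[[j]])
      if (d > cd) { cd <- d; cand <- j }
    }
    if (!is.na(cand) && cd > 0 && naive_iou(gt[[i]], pred[[cand]]) > iou_thr) {
      match_of[i] <- cand
      taken[cand] <- TRUE
    }
  }
  tp <- sum(!is.na(match_of))
  list(match_of = match_of, tp = tp, fp = np - tp, fn = ng - tp)
}

# exhaustive maximum bipartite matching on the IoU > thr graph (upper
# bound on any one-to-one TP count); recursion over ground truths
max_matching_tp <- function(gt, pred, iou_thr = 0.5) {
  ng <- length(gt); np <- length(pred)
  ok <- matrix(FALSE, ng, np)
  for (i in seq_len(ng)) for (j in seq_len(np))
    ok[i, j] <- naive_iou(gt[[i]], pred[[j]]) > iou_thr
  rec <- function(i, used) {
    if (i > ng) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_len(np)) {
      if (ok[i, j] && !used[j]) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, np))
}

# naive unwindowed multihead self-attention over every token in the grid
naive_global_attention <- function(tokens_mat, heads, w) {
  d <- ncol(tokens_mat)
  q <- sweep(tokens_mat %*% w$Wq, 2, w$bq, "+")
  k <- sweep(tokens_mat %*% w$Wk, 2, w$bk, "+")
  v <- sweep(tokens_mat %*% w$Wv, 2, w$bv, "+")
  hd <- d / heads
  att <- matrix(0, nrow(tokens_mat), d)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * hd + 1):(h * hd)
    lg <- q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) / sqrt(hd)
    lg <- exp(lg - apply(lg, 1, max))
    att[, cols] <- (lg / rowSums(lg)) %*% v[, cols, drop = FALSE]
  }
  sweep(att %*% w$Wo, 2, w$bo, "+")
}

rand_attn_weights <- function(d, seed = 1) {
  withr::with_seed(seed, list(
    Wq = matrix(rnorm(d * d), d, d) * 0.3, bq = rnorm(d) * 0.1,
    Wk = matrix(rnorm(d * d), d, d) * 0.3, bk = rnorm(d) * 0.1,
    Wv = matrix(rnorm(d * d), d, d) * 0.3, bv = rnorm(d) * 0.1,
    Wo = matrix(rnorm(d * d), d, d) * 0.3, bo = rnorm(d) * 0.1,
    bias_table = NULL))
}

# ---- fixture builders ----

# random filled ellipse mask on an h x w grid (possibly empty is avoided
# by a minimum radius)
random_ellipse_mask <- function(h, w) {
  cy <- runif(1, 3, h - 3); cx <- runif(1, 3, w - 3)
  ry <- runif(1, 1.5, h / 3); rx <- runif(1, 1.5, w / 3)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  x <- matrix(rep(seq_len(w), each = h), h, w)
  ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

rect_mask <- function(h, w, r0, c0, rh, rw) {
  m <- matrix(FALSE, h, w)
  m[r0:(r0 + rh - 1), c0:(c0 + rw - 1)] <- TRUE
  m
}

tiny_backbone_cfg <- function() {
  backbone_config(embed_dim = 32L, depths = c(1L, 1L, 1L, 1L),
                  num_heads = c(2L, 4L, 8L, 16L), window_size = 4L)
}

# a small study: bright (NMDA-regime) disjoint somas on neuropil tiles
smoke_gen_cfg <- function(n_images = 16L, seed = 11L) {
  generator_config(n_images = n_images, image_size = c(64L, 64L),
                   cells_per_image = c(2L, 4L),
                   max_pairwise_overlap_iou = 0,
                   radius_range = c(4, 7),
                   condition_mix = c(baseline = 0, nmda = 1, washout = 0),
                   seed = seed)
}

smoke_dataset_dir <- function(dir, n_images = 16L, seed = 11L) {
  cfg <- smoke_gen_cfg(n_images, seed)
  bank <- render_cell_bank(24L, cfg, seed = derive_seed(seed, 501L))
  tiles <- render_tile_bank(6L, tile_size = c(32L, 32L),
                            seed = derive_seed(seed, 502L))
  generate_dataset(cfg, bank, tiles, dir)
  dir
}
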