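#' Hierarchical shifted-window (Swin) transformer backbone
#'
#' A four-stage hierarchical vision transformer. The input image is cut
#' into non-overlapping 4 x 4 patches (tokens), linearly embedded to C
#' channels (C = 96 in the reference configuration), and processed by
#' pairs of transformer blocks whose self-attention is computed within
#' local M x M token windows — alternating between a regular partition
#' (W-MSA) and one cyclically shifted by floor(M/2) (SW-MSA), which lets
#' information cross window boundaries while keeping cost linear in image
#' size. Between stages, patch merging concatenates 2 x 2 neighboring
#' tokens (4C channels) and projects to 2C, halving resolution, so the
#' four stages produce feature maps at H/4, H/8, H/16, H/32 with C, 2C,
#' 4C, 8C channels.
#'
#' @name swin
NULL

#' Backbone configuration
#'
#' @param patch_size patch side in pixels (default 4).
#' @param embed_dim C, stage-1 channel dimension (default 96).
#' @param depths transformer blocks per stage (length 4; default
#'   `c(2, 2, 6, 2)`).
#' @param num_heads attention heads per stage (length 4; default
#'   `c(3, 6, 12, 24)`, keeping the per-head dimension at 32).
#' @param window_size M, attention window side in tokens (default 7).
#' @param mlp_ratio hidden-layer expansion of the per-token MLP.
#' @param use_relative_position_bias add a learned relative-position bias
#'   to attention logits.
#' @return an object of class `backbone_config`.
#' @export
backbone_config <- function(patch_size = 4L, embed_dim = 96L,
                            depths = c(2L, 2L, 6L, 2L),
                            num_heads = c(3L, 6L, 12L, 24L),
                            window_size = 7L, mlp_ratio = 4,
                            use_relative_position_bias = TRUE) {
  if (length(depths) != 4L) stop_somaswin("depths must have length 4")
  if (length(num_heads) != 4L) stop_somaswin("num_heads must have length 4")
  if (embed_dim < 1L) stop_somaswin("embed_dim must be positive")
  for (s in 1:4) {
    d <- embed_dim * 2^(s - 1L)
    if (d %% num_heads[s] != 0L)
      stop_somaswin("stage %d channel dim %d is not divisible by %d heads",
                    s, d, num_heads[s])
  }
  structure(list(patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 depths = as.integer(depths),
                 num_heads = as.integer(num_heads),
                 window_size = as.integer(window_size),
                 mlp_ratio = mlp_ratio,
                 use_relative_position_bias = isTRUE(use_relative_position_bias)),
            class = "backbone_config")
}

#' Token grid
#'
#' @param tokens 3D array `(token rows, token cols, channels)`.
#' @param stage stage index 1-4 (0 for the raw, pre-embedding grid).
#' @return an object of class `token_grid`.
#' @export
token_grid <- function(tokens, stage = 1L) {
  if (length(dim(tokens)) != 3L)
    stop_somaswin("tokens must be a 3D array (rows, cols, channels)")
  structure(list(tokens = tokens, stage = as.integer(stage)),
            class = "token_grid")
}

grid_dims <- function(grid) dim(grid$tokens)

grid_to_mat <- function(tokens) {
  d <- dim(tokens)
  dim(tokens) <- c(d[1L] * d[2L], d[3L])
  tokens
}

array3 <- function(mat, h, w, d) { dim(mat) <- c(h, w, d); mat }

#' Partition an image into patch tokens
#'
#' Zero-pads the image on the bottom/right to multiples of `patch_size`
#' and flattens each non-overlapping `patch_size` x `patch_size` patch
#' (column-major within the patch) into one token of dimension
#' `patch_size^2`.
#'
#' @param image numeric matrix (H x W).
#' @param patch_size patch side in pixels.
#' @return a [token_grid] of shape `(ceiling(H/p), ceiling(W/p), p^2)`,
#'   stage 0.
#' @export
patch_partition <- function(image, patch_size = 4L) {
  assert_image(image)
  p <- as.integer(patch_size)
  if (nrow(image) < p || ncol(image) < p)
    stop_somaswin("image (%dx%d) smaller than the patch size %d",
                  nrow(image), ncol(image), p)
  ht <- ceiling(nrow(image) / p); wt <- ceiling(ncol(image) / p)
  img <- pad_zero_br(image, ht * p, wt * p)
  tok <- array(0, c(ht, wt, p * p))
  for (pr in seq_len(p)) for (pc in seq_len(p)) {
    ch <- (pc - 1L) * p + pr # column-major within the patch
    tok[, , ch] <- img[seq(pr, by = p, length.out = ht),
                       seq(pc, by = p, length.out = wt)]
  }
  token_grid(tok, stage = 0L)
}

#' Invert a patch partition
#'
#' Re-tiles a stage-0 token grid into the (padded) image; the round trip
#' through [patch_partition] is exact.
#'
#' @param grid stage-0 [token_grid] with `p^2` channels.
#' @param patch_size patch side in pixels.
#' @return numeric matrix of the padded image.
#' @export
patch_unpartition <- function(grid, patch_size = 4L) {
  p <- as.integer(patch_size)
  d <- grid_dims(grid)
  if (d[3L] != p * p) stop_somaswin("token dim %d != patch_size^2", d[3L])
  img <- matrix(0, d[1L] * p, d[2L] * p)
  for (pr in seq_len(p)) for (pc in seq_len(p)) {
    ch <- (pc - 1L) * p + pr
    img[seq(pr, by = p, length.out = d[1L]),
        seq(pc, by = p, length.out = d[2L])] <- grid$tokens[, , ch]
  }
  img
}

#' Linearly embed raw patch tokens
#'
#' One affine map, shared across all token positions, projecting the
#' flattened-patch features to the backbone channel dimension C.
#'
#' @param grid stage-0 [token_grid].
#' @param weights list with `W` (`p^2` x C) and `b` (length C).
#' @return stage-1 [token_grid] with C channels.
#' @export
linear_embed <- function(grid, weights) {
  d <- grid_dims(grid)
  if (d[3L] != nrow(weights$W))
    stop_somaswin("token dim %d does not match embedding input dim %d",
                  d[3L], nrow(weights$W))
  m <- grid_to_mat(grid$tokens) %*% weights$W
  m <- sweep(m, 2L, weights$b, "+")
  token_grid(array3(m, d[1L], d[2L], ncol(weights$W)), stage = 1L)
}

#' Cyclically shift a token grid
#'
#' Rolls the grid so that the token at (0-based) position `p` moves to
#' `(p + shift) mod dims`; a shift of `-shift` inverts it exactly.
#'
#' @param grid a [token_grid].
#' @param shift integer `c(rows, cols)`; may be negative.
#' @return shifted [token_grid].
#' @export
cyclic_shift <- function(grid, shift) {
  d <- grid_dims(grid)
  if (any(abs(shift) >= d[1:2]))
    stop_somaswin("|shift| must be smaller than the grid dimensions")
  ri <- ((seq_len(d[1L]) - 1L - shift[1L]) %% d[1L]) + 1L
  ci <- ((seq_len(d[2L]) - 1L - shift[2L]) %% d[2L]) + 1L
  token_grid(grid$tokens[ri, ci, , drop = FALSE], stage = grid$stage)
}

# region labels of the (rolled) canvas used to forbid attention between
# tokens that were not neighbors before the cyclic shift
shift_region_labels <- function(hp, wp, m, s) {
  lab1d <- function(n) {
    if (s == 0L) return(rep(0L, n))
    breaks <- c(n - m, n - s)
    ifelse(seq_len(n) <= breaks[1L], 0L,
           ifelse(seq_len(n) <= breaks[2L], 1L, 2L))
  }
  outer(lab1d(hp), lab1d(wp), function(a, b) a * 3L + b)
}

#' Partition a token grid into attention windows
#'
#' Pads the grid to multiples of the window size, applies the cyclic
#' shift, and cuts it into M x M windows. Each window carries a boolean
#' attention mask: with a nonzero shift, tokens that wrapped around from
#' non-adjacent regions of the unshifted grid (and all padded positions)
#' are mutually masked.
#'
#' @param grid a [token_grid].
#' @param window_size M, window side in tokens.
#' @param shift scalar cyclic shift applied to both dimensions before
#'   partitioning (0 for W-MSA, `floor(M/2)` for SW-MSA).
#' @return an object of class `attention_window_set`: `windows`
#'   (`M^2` x D x nW array), `mask` (`M^2` x `M^2` x nW allowed-attention
#'   array), `shift`, and layout metadata for [window_reverse].
#' @export
window_partition <- function(grid, window_size, shift = 0L) {
  m <- as.integer(window_size)
  d <- grid_dims(grid)
  h <- d[1L]; w <- d[2L]; dd <- d[3L]
  hp <- as.integer(ceiling(h / m) * m); wp <- as.integer(ceiling(w / m) * m)
  tok <- array(0, c(hp, wp, dd))
  tok[seq_len(h), seq_len(w), ] <- grid$tokens
  padded <- matrix(TRUE, hp, wp)
  padded[seq_len(h), seq_len(w)] <- FALSE
  s <- as.integer(shift) %% m
  if (s > 0L) {
    g <- cyclic_shift(token_grid(tok), c(-s, -s))
    tok <- g$tokens
    ri <- ((seq_len(hp) - 1L + s) %% hp) + 1L
    ci <- ((seq_len(wp) - 1L + s) %% wp) + 1L
    padded <- padded[ri, ci, drop = FALSE]
  }
  labels <- shift_region_labels(hp, wp, m, s)
  labels[padded] <- 9L # padded tokens attend only among themselves
  nwr <- hp %/% m; nwc <- wp %/% m; nw <- nwr * nwc
  windows <- array(0, c(m * m, dd, nw))
  mask <- array(TRUE, c(m * m, m * m, nw))
  k <- 0L
  for (wc in seq_len(nwc)) for (wr in seq_len(nwr)) {
    k <- k + 1L
    rr <- ((wr - 1L) * m + 1L):(wr * m)
    cc <- ((wc - 1L) * m + 1L):(wc * m)
    blk <- tok[rr, cc, , drop = FALSE]
    windows[, , k] <- grid_to_mat(blk)
    lv <- as.vector(labels[rr, cc])
    mask[, , k] <- outer(lv, lv, "==")
  }
  structure(list(windows = windows, mask = mask, shift = s,
                 window_size = m, h = h, w = w, hp = hp, wp = wp,
                 nwr = nwr, nwc = nwc, stage = grid$stage),
            class = "attention_window_set")
}

#' Reassemble a token grid from attention windows
#'
#' Inverts [window_partition]: windows are tiled back, the cyclic shift
#' is undone, and the padding is cropped.
#'
#' @param ws an `attention_window_set`.
#' @return the reassembled [token_grid].
#' @export
window_reverse <- function(ws) {
  m <- ws$window_size
  dd <- dim(ws$windows)[2L]
  tok <- array(0, c(ws$hp, ws$wp, dd))
  k <- 0L
  for (wc in seq_len(ws$nwc)) for (wr in seq_len(ws$nwr)) {
    k <- k + 1L
    rr <- ((wr - 1L) * m + 1L):(wr * m)
    cc <- ((wc - 1L) * m + 1L):(wc * m)
    tok[rr, cc, ] <- array3(ws$windows[, , k], m, m, dd)
  }
  if (ws$shift > 0L)
    tok <- cyclic_shift(token_grid(tok), c(ws$shift, ws$shift))$tokens
  token_grid(tok[seq_len(ws$h), seq_len(ws$w), , drop = FALSE],
             stage = ws$stage)
}

softmax_rows <- function(x) {
  x <- x - matrixStats::rowMaxs(x)
  e <- exp(x)
  e / rowSums(e)
}

# relative-position index (M^2 x M^2) into a (2M-1)^2 bias table, for the
# column-major within-window token order
relative_position_index <- function(m) {
  r <- rep(seq_len(m), times = m); c <- rep(seq_len(m), each = m)
  dr <- outer(r, r, "-") + m - 1L
  dc <- outer(c, c, "-") + m - 1L
  dr * (2L * m - 1L) + dc + 1L
}

#' Windowed multihead self-attention
#'
#' Scaled dot-product multihead self-attention computed independently
#' within each window; masked token pairs receive `-Inf` logits, and an
#' optional learned relative-position bias is added to the logits.
#'
#' @param ws an `attention_window_set` from [window_partition].
#' @param heads number of attention heads (must divide the channel dim).
#' @param weights list with projections `Wq, bq, Wk, bk, Wv, bv, Wo, bo`
#'   and optionally `bias_table` (`(2M-1)^2` x heads).
#' @return the window set with attended token features.
#' @export
window_attention <- function(ws, heads, weights) {
  dims <- dim(ws$windows)
  n <- dims[1L]; dd <- dims[2L]; nw <- dims[3L]
  if (dd %% heads != 0L)
    stop_somaswin("channel dim %d is not divisible by %d heads", dd, heads)
  hd <- dd %/% heads
  scale <- 1 / sqrt(hd)
  bias <- NULL
  if (!is.null(weights$bias_table)) {
    idx <- relative_position_index(ws$window_size)
    bias <- lapply(seq_len(heads), function(h)
      matrix(weights$bias_table[idx, h], n, n))
  }
  out <- ws$windows
  for (k in seq_len(nw)) {
    x <- ws$windows[, , k]
    if (n == 1L) dim(x) <- c(1L, dd)
    q <- sweep(x %*% weights$Wq, 2L, weights$bq, "+")
    kk <- sweep(x %*% weights$Wk, 2L, weights$bk, "+")
    v <- sweep(x %*% weights$Wv, 2L, weights$bv, "+")
    allowed <- ws$mask[, , k]
    if (n == 1L) dim(allowed) <- c(1L, 1L)
    att <- matrix(0, n, dd)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * hd + 1L):(h * hd)
      logits <- q[, cols, drop = FALSE] %*%
        t(kk[, cols, drop = FALSE]) * scale
      if (!is.null(bias)) logits <- logits + bias[[h]]
      logits[!allowed] <- -Inf
      att[, cols] <- softmax_rows(logits) %*% v[, cols, drop = FALSE]
    }
    out[, , k] <- sweep(att %*% weights$Wo, 2L, weights$bo, "+")
  }
  ws$windows <- out
  ws
}

#' Layer normalization
#'
#' Normalizes each token to zero mean and unit variance across its
#' channels, then applies a learned per-channel affine transform.
#'
#' @param x matrix (tokens x channels).
#' @param gamma,beta per-channel scale and offset.
#' @param eps variance floor.
#' @return normalized matrix, same shape.
#' @export
layer_norm <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  va <- rowMeans((x - mu)^2)
  xn <- (x - mu) / sqrt(va + eps)
  sweep(sweep(xn, 2L, gamma, "*"), 2L, beta, "+")
}

gelu <- function(x) x * stats::pnorm(x)

#' One Swin transformer block
#'
#' `x + MSA(LN(x))` followed by `x + MLP(LN(x))`, with the self-attention
#' computed over regular windows (`shifted = FALSE`, W-MSA) or windows
#' cyclically shifted by `floor(M/2)` with the cross-boundary mask
#' (`shifted = TRUE`, SW-MSA). Spatial and channel dimensions are
#' preserved.
#'
#' @param grid a [token_grid].
#' @param shifted logical; use the shifted window partition.
#' @param params block parameters: `norm1`, `attn`, `norm2`, `mlp`
#'   (see [init_backbone]).
#' @param cfg a [backbone_config] (window size and head count come from
#'   the grid's stage).
#' @return a [token_grid] of identical shape.
#' @export
swin_block <- function(grid, shifted, params, cfg) {
  d <- grid_dims(grid)
  m <- cfg$window_size
  heads <- cfg$num_heads[max(grid$stage, 1L)]
  s <- if (isTRUE(shifted)) m %/% 2L else 0L
  x <- grid_to_mat(grid$tokens)
  h1 <- layer_norm(x, params$norm1$gamma, params$norm1$beta)
  ws <- window_partition(token_grid(array3(h1, d[1L], d[2L], d[3L]),
                                    stage = grid$stage), m, shift = s)
  ws <- window_attention(ws, heads, params$attn)
  att <- grid_to_mat(window_reverse(ws)$tokens)
  x <- x + att
  h2 <- layer_norm(x, params$norm2$gamma, params$norm2$beta)
  mlp <- sweep(gelu(sweep(h2 %*% params$mlp$W1, 2L, params$mlp$b1, "+")) %*%
                 params$mlp$W2, 2L, params$mlp$b2, "+")
  x <- x + mlp
  token_grid(array3(x, d[1L], d[2L], d[3L]), stage = grid$stage)
}

#' Merge 2 x 2 neighboring tokens
#'
#' Concatenates each 2 x 2 group of neighboring tokens into a 4D-channel
#' vector (zero-padding odd grid dimensions), layer-normalizes, and
#' linearly projects to 2D channels: spatial resolution halves, the token
#' count drops by a factor of 4, channels double.
#'
#' @param grid a [token_grid] with D channels.
#' @param params list with `norm` (`gamma`, `beta`, length 4D) and `W`
#'   (4D x 2D).
#' @return a [token_grid] at the next stage.
#' @export
patch_merge <- function(grid, params) {
  d <- grid_dims(grid)
  h2 <- as.integer(ceiling(d[1L] / 2)); w2 <- as.integer(ceiling(d[2L] / 2))
  tok <- array(0, c(2L * h2, 2L * w2, d[3L]))
  tok[seq_len(d[1L]), seq_len(d[2L]), ] <- grid$tokens
  ro <- seq(1L, 2L * h2, by = 2L); co <- seq(1L, 2L * w2, by = 2L)
  cat4 <- array(0, c(h2, w2, 4L * d[3L]))
  cat4[, , seq_len(d[3L])] <- tok[ro, co, , drop = FALSE]
  cat4[, , d[3L] + seq_len(d[3L])] <- tok[ro + 1L, co, , drop = FALSE]
  cat4[, , 2L * d[3L] + seq_len(d[3L])] <- tok[ro, co + 1L, , drop = FALSE]
  cat4[, , 3L * d[3L] + seq_len(d[3L])] <- tok[ro + 1L, co + 1L, , drop = FALSE]
  m <- layer_norm(grid_to_mat(cat4), params$norm$gamma, params$norm$beta)
  m <- m %*% params$W
  token_grid(array3(m, h2, w2, ncol(params$W)), stage = grid$stage + 1L)
}

trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(runif(n, lo, hi)) * sd
}

tn_mat <- function(nr, nc, sd = 0.02) matrix(trunc_normal(nr * nc, sd), nr, nc)

#' Initialize backbone weights
#'
#' Truncated-normal (sd 0.02) weight matrices, zero biases, unit-gain
#' layer norms — deterministic given the seed.
#'
#' @param cfg a [backbone_config].
#' @param seed RNG seed.
#' @return nested weight list: `embed` plus four `stages`, each with an
#'   optional `merge` and a list of `blocks`.
#' @export
init_backbone <- function(cfg, seed = 1L) {
  m <- cfg$window_size
  with_seed(seed, {
    mk_block <- function(dd, heads) list(
      norm1 = list(gamma = rep(1, dd), beta = rep(0, dd)),
      attn = list(Wq = tn_mat(dd, dd), bq = rep(0, dd),
                  Wk = tn_mat(dd, dd), bk = rep(0, dd),
                  Wv = tn_mat(dd, dd), bv = rep(0, dd),
                  Wo = tn_mat(dd, dd), bo = rep(0, dd),
                  bias_table = if (cfg$use_relative_position_bias)
                    tn_mat((2L * m - 1L)^2, heads) else NULL),
      norm2 = list(gamma = rep(1, dd), beta = rep(0, dd)),
      mlp = list(W1 = tn_mat(dd, round(cfg$mlp_ratio * dd)),
                 b1 = rep(0, round(cfg$mlp_ratio * dd)),
                 W2 = tn_mat(round(cfg$mlp_ratio * dd), dd),
                 b2 = rep(0, dd)))
    p2 <- cfg$patch_size^2
    w <- list(embed = list(W = tn_mat(p2, cfg$embed_dim),
                           b = rep(0, cfg$embed_dim),
                           norm = list(gamma = rep(1, cfg$embed_dim),
                                       beta = rep(0, cfg$embed_dim))),
              stages = vector("list", 4L))
    for (s in 1:4) {
      dd <- cfg$embed_dim * 2L^(s - 1L)
      merge <- NULL
      if (s > 1L) {
        din <- cfg$embed_dim * 2L^(s - 2L)
        merge <- list(norm = list(gamma = rep(1, 4L * din),
                                  beta = rep(0, 4L * din)),
                      W = tn_mat(4L * din, 2L * din))
      }
      w$stages[[s]] <- list(
        merge = merge,
        blocks = lapply(seq_len(cfg$depths[s]), function(b)
          mk_block(dd, cfg$num_heads[s])))
    }
    w
  })
}

#' Count backbone parameters
#' @param weights an [init_backbone] weight list (or any nested numeric
#'   list).
#' @return total number of scalar parameters.
#' @export
n_parameters <- function(weights) {
  if (is.numeric(weights)) return(length(weights))
  if (is.list(weights))
    return(sum(vapply(weights, n_parameters, numeric(1))))
  0
}

#' Full backbone forward pass
#'
#' Patch partition, linear embedding (with layer norm), then four stages
#' of Swin blocks (alternating W-MSA / SW-MSA) separated by patch
#' merging. Deterministic given the weights.
#'
#' @param image preprocessed grayscale matrix in `[0, 1]` (smaller inputs
#'   are zero-padded as needed).
#' @param cfg a [backbone_config].
#' @param weights weights from [init_backbone] (initialized from
#'   `seed` when omitted).
#' @param seed seed used when `weights` is missing.
#' @return list of four [token_grid]s at resolutions H/4, H/8, H/16,
#'   H/32 with channels C, 2C, 4C, 8C.
#' @export
backbone_forward <- function(image, cfg = backbone_config(),
                             weights = NULL, seed = 1L) {
  if (is.null(weights)) weights <- init_backbone(cfg, seed)
  grid <- patch_partition(image, cfg$patch_size)
  grid <- linear_embed(grid, weights$embed)
  d <- grid_dims(grid)
  x <- layer_norm(grid_to_mat(grid$tokens), weights$embed$norm$gamma,
                  weights$embed$norm$beta)
  grid <- token_grid(array3(x, d[1L], d[2L], d[3L]), stage = 1L)
  outs <- vector("list", 4L)
  for (s in 1:4) {
    if (s > 1L) grid <- patch_merge(grid, weights$stages[[s]]$merge)
    blocks <- weights$stages[[s]]$blocks
    for (b in seq_along(blocks))
      grid <- swin_block(grid, shifted = (b %% 2L == 0L), blocks[[b]], cfg)
    outs[[s]] <- grid
  }
  outs
}
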