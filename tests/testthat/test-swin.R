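test_that("patch partition tiles, flattens and round-trips exactly", {
  img <- matrix(runif(64 * 64), 64, 64)
  g <- patch_partition(img, 4L)
  expect_identical(dim(g$tokens), c(16L, 16L, 16L))

  const <- matrix(0.3, 32, 32)
  gc <- patch_partition(const, 4L)
  flat <- matrix(gc$tokens, 64, 16)
  expect_true(all(apply(flat, 1L, function(t) all(t == flat[1L, ]))))

  # round trip, including a padded (non-multiple) image
  odd <- matrix(runif(30 * 34), 30, 34)
  go <- patch_partition(odd, 4L)
  expect_identical(dim(go$tokens), c(8L, 9L, 16L))
  rec <- patch_unpartition(go, 4L)
  expect_equal(rec[1:30, 1:34], odd)
  expect_true(all(rec[31:32, ] == 0))
})

test_that("linear embedding is a position-shared affine map to C channels", {
  g <- patch_partition(matrix(runif(32 * 32), 32, 32), 4L)
  w <- init_backbone(backbone_config(), seed = 2L)$embed
  e <- linear_embed(g, w)
  expect_identical(dim(e$tokens)[3L], 96L)
  expect_identical(dim(e$tokens)[1:2], dim(g$tokens)[1:2])

  # zero tokens + zero bias -> zero output
  gz <- token_grid(array(0, c(4L, 4L, 16L)), 0L)
  expect_true(all(linear_embed(gz, w)$tokens == 0))

  # permuting token positions commutes with the embedding
  perm_r <- sample(4L); perm_c <- sample(4L)
  g4 <- patch_partition(matrix(runif(16 * 16), 16, 16), 4L)
  a <- linear_embed(token_grid(g4$tokens[perm_r, perm_c, ], 0L), w)$tokens
  b <- linear_embed(g4, w)$tokens[perm_r, perm_c, ]
  expect_equal(a, b)
})

test_that("cyclic shift rolls indices exactly and inverts", {
  tok <- array(seq_len(4 * 4 * 2), c(4L, 4L, 2L))
  g <- token_grid(tok, 1L)
  expect_identical(cyclic_shift(g, c(0L, 0L))$tokens, tok)
  s <- cyclic_shift(cyclic_shift(g, c(-2L, -1L)), c(2L, 1L))
  expect_identical(s$tokens, tok)
  # 0-based (2,2) -> (0,0) under shift (-2,-2)
  sh <- cyclic_shift(g, c(-2L, -2L))
  expect_identical(sh$tokens[1L, 1L, ], tok[3L, 3L, ])
  expect_error(cyclic_shift(g, c(4L, 0L)), "shift")
})

test_that("window partition and reverse are a bijection on token positions", {
  for (dims in list(c(8L, 8L), c(9L, 11L), c(6L, 13L))) {
    tok <- array(runif(prod(dims) * 5L), c(dims, 5L))
    g <- token_grid(tok, 2L)
    for (shift in c(0L, 2L)) {
      ws <- window_partition(g, window_size = 4L, shift = shift)
      back <- window_reverse(ws)
      expect_identical(back$tokens, tok)
    }
  }
})

test_that("windowed attention matches a naive global oracle and honors the mask", {
  # window covering the whole grid, no shift == global attention
  d <- 12L; heads <- 3L
  tok <- array(rnorm(5 * 6 * d), c(5L, 6L, d))
  w <- rand_attn_weights(d, seed = 31)
  ws <- window_partition(token_grid(tok, 1L), window_size = 6L, shift = 0L)
  out <- window_reverse(window_attention(ws, heads, w))
  oracle <- naive_global_attention(matrix(tok, 30, d), heads, w)
  expect_lt(max(abs(matrix(out$tokens, 30, d) - oracle)), 1e-5)

  # single-token windows: softmax over one element -> pure value path
  ws1 <- window_partition(token_grid(tok, 1L), window_size = 1L, shift = 0L)
  out1 <- window_reverse(window_attention(ws1, heads, w))
  vp <- sweep(sweep(matrix(tok, 30, d) %*% w$Wv, 2, w$bv, "+") %*% w$Wo,
              2, w$bo, "+")
  expect_equal(matrix(out1$tokens, 30, d), vp, tolerance = 1e-12)

  # uniform tokens: attention weights are uniform over unmasked positions,
  # so the output is position independent
  toku <- array(rep(rnorm(d), each = 64), c(8L, 8L, d))
  wsu <- window_partition(token_grid(toku, 1L), window_size = 4L, shift = 0L)
  outu <- matrix(window_reverse(window_attention(wsu, heads, w))$tokens, 64, d)
  expect_lt(max(abs(sweep(outu, 2, outu[1L, ]))), 1e-10)

  # SW-MSA mask correctness: attention across non-adjacent pre-shift
  # regions is exactly zero. Probe: value = region label everywhere,
  # identity value/output projections -> each token must reproduce its own
  # region label exactly (any leak across regions would shift the mean).
  m <- 4L; s <- m %/% 2L; h8 <- 8L
  labels <- somaswin:::shift_region_labels(h8, h8, m, s)
  dl <- 2L
  tokl <- array(0, c(h8, h8, dl))
  tokl[, , 1L] <- labels; tokl[, , 2L] <- labels
  wid <- list(Wq = matrix(0, dl, dl), bq = rep(0, dl),
              Wk = matrix(0, dl, dl), bk = rep(0, dl),
              Wv = diag(dl), bv = rep(0, dl),
              Wo = diag(dl), bo = rep(0, dl), bias_table = NULL)
  # partition the already-shifted canvas directly (shift argument applies
  # the roll internally; here we feed labels that live in the rolled frame)
  wsl <- window_partition(token_grid(tokl, 1L), window_size = m, shift = 0L)
  # impose the SW-MSA mask computed for the shifted partition
  wsl$mask <- window_partition(token_grid(array(0, c(h8, h8, 1L)), 1L),
                               window_size = m, shift = s)$mask
  outl <- window_reverse(window_attention(wsl, 1L, wid))
  expect_equal(outl$tokens[, , 1L], labels, tolerance = 1e-12)
})

test_that("a Swin block preserves shape and is bit-stable", {
  cfg <- tiny_backbone_cfg()
  w <- init_backbone(cfg, seed = 3L)
  tok <- array(rnorm(12 * 10 * 32), c(12L, 10L, 32L))
  g <- token_grid(tok, 1L)
  for (shifted in c(FALSE, TRUE)) {
    out <- swin_block(g, shifted, w$stages[[1L]]$blocks[[1L]], cfg)
    expect_identical(dim(out$tokens), dim(tok))
    out2 <- swin_block(g, shifted, w$stages[[1L]]$blocks[[1L]], cfg)
    expect_identical(out$tokens, out2$tokens)
  }
})

test_that("patch merging halves resolution and doubles channels", {
  w <- init_backbone(backbone_config(), seed = 4L)
  tok <- array(rnorm(8 * 8 * 96), c(8L, 8L, 96L))
  out <- patch_merge(token_grid(tok, 1L), w$stages[[2L]]$merge)
  expect_identical(dim(out$tokens), c(4L, 4L, 192L))
  expect_identical(prod(dim(tok)[1:2]) / prod(dim(out$tokens)[1:2]), 4)

  # constant grid -> constant merged grid (position symmetry)
  tokc <- array(rep(rnorm(96), each = 64), c(8L, 8L, 96L))
  outc <- patch_merge(token_grid(tokc, 1L), w$stages[[2L]]$merge)
  flat <- matrix(outc$tokens, 16, 192)
  expect_lt(max(abs(sweep(flat, 2, flat[1L, ]))), 1e-10)
})

test_that("backbone forward obeys the hierarchical shape schedule", {
  cfg <- tiny_backbone_cfg()
  outs <- backbone_forward(matrix(runif(64 * 64), 64, 64), cfg, seed = 5L)
  for (s in 1:4)
    expect_identical(dim(outs[[s]]$tokens),
                     as.integer(c(64 / (4 * 2^(s - 1)), 64 / (4 * 2^(s - 1)),
                                  32 * 2^(s - 1))))

  # zero image with zero-initialized biases gives zero features everywhere
  outz <- backbone_forward(matrix(0, 64, 64), cfg, seed = 5L)
  for (s in 1:4) expect_equal(max(abs(outz[[s]]$tokens)), 0)

  # doubling H and W doubles every stage's token rows and cols
  outs2 <- backbone_forward(matrix(runif(128 * 128), 128, 128), cfg, seed = 5L)
  for (s in 1:4)
    expect_identical(dim(outs2[[s]]$tokens)[1:2],
                     2L * dim(outs[[s]]$tokens)[1:2])
})
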