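test_that("extract_tiles copies boxed regions verbatim and rejects bad boxes", {
  const <- matrix(0.4, 48, 48)
  tl <- extract_tiles(const, list(c(0L, 0L, 48L, 48L)))
  expect_length(tl, 1L)
  expect_true(all(tl[[1L]]$pixels == 0.4))

  grad <- outer(seq_len(40), seq_len(40), function(r, c) (r + c) / 100)
  boxes <- list(c(0L, 0L, 32L, 32L), c(8L, 5L, 32L, 32L))
  tl <- extract_tiles(grad, boxes)
  expect_length(tl, 2L)
  expect_identical(dim(tl[[2L]]$pixels), c(32L, 32L))
  # elementwise copy at box offsets
  expect_identical(tl[[2L]]$pixels, grad[9:40, 6:37])

  expect_error(extract_tiles(grad, list(c(20L, 20L, 32L, 32L))),
               "box 1.*out of bounds")
})

test_that("compose_background covers the canvas, blends constants exactly and is deterministic", {
  expect_error(compose_background(list(), c(32L, 32L)), "at least one tile")

  # single full-size tile reproduces itself
  grad <- outer(seq_len(32), seq_len(32), function(r, c) (r + c) / 80)
  t1 <- background_tile(grad)
  out <- compose_background(list(t1), c(32L, 32L), seed = 5)
  expect_equal(out, grad, tolerance = 1e-12)

  # constant tiles of different sizes blend to the same constant
  tiles <- list(background_tile(matrix(0.3, 10, 14)),
                background_tile(matrix(0.3, 17, 9)),
                background_tile(matrix(0.3, 8, 8)))
  out <- compose_background(tiles, c(40L, 40L), seed = 2)
  expect_true(all(abs(out - 0.3) < 1e-12))

  # bit-identical under the same seed, full coverage always
  tiles2 <- render_tile_bank(4L, tile_size = c(16L, 16L), seed = 9L)
  a <- compose_background(tiles2, c(48L, 48L), seed = 7)
  b <- compose_background(tiles2, c(48L, 48L), seed = 7)
  expect_identical(a, b)
  expect_true(all(is.finite(a)) && min(a) >= 0 && max(a) <= 1)
})

test_that("render_cell produces calibrated elliptical somas", {
  # circular cell: mask is a disc of the nominal radius
  for (r in c(5, 8, 12)) {
    cell <- render_cell(radius_range = c(r, r),
                        eccentricity_range = c(1, 1),
                        condition = "nmda", seed = 3L)
    expect_lt(abs(sum(cell$mask) - pi * r^2) / (pi * r^2), 0.15)
  }

  # collapsed peak range: the brightest pixel equals the requested peak
  cell <- render_cell(peak_range = c(0.77, 0.77), condition = "nmda",
                      seed = 4L)
  expect_equal(max(cell$pixels), 0.77, tolerance = 1e-12)

  # determinism
  c1 <- render_cell(seed = 42L); c2 <- render_cell(seed = 42L)
  expect_identical(c1, c2)

  # nmda >= washout >= baseline peak regimes (upper bounds of defaults)
  peaks <- vapply(c("baseline", "washout", "nmda"), function(cond)
    max(render_cell(condition = cond, peak_range = NULL, seed = 8L)$pixels),
    numeric(1))
  expect_true(peaks[["nmda"]] >= peaks[["washout"]])
  expect_true(peaks[["washout"]] >= peaks[["baseline"]])

  expect_error(render_cell(radius_range = c(1, 1)), "radius")
})

test_that("paste_cells composites cells with exact bookkeeping", {
  cfg <- smoke_gen_cfg()
  bg <- matrix(0.15, 64, 64)

  # zero cells: identity
  syn <- paste_cells(bg, list(), cfg, seed = 1L)
  expect_length(syn$instances, 0L)
  expect_equal(syn$pixels, bg)

  # feather 0: pixels inside the mask equal the cell pixels exactly
  cfg0 <- cfg; cfg0$feather_width <- 0
  cell <- render_cell(radius_range = c(5, 5), condition = "nmda", seed = 2L)
  syn <- paste_cells(bg, list(cell), cfg0, seed = 3L)
  expect_length(syn$instances, 1L)
  m <- syn$instances[[1L]]
  expect_equal(syn$pixels[m], cell$pixels[cell$mask])

  # counting contract and disjointness at overlap 0
  cells <- lapply(1:4, function(i)
    render_cell(radius_range = c(4, 5), condition = "nmda",
                seed = 100L + i))
  syn <- paste_cells(bg, cells, cfg, seed = 5L)
  expect_length(syn$instances, 4L)
  expect_equal(sum(syn$provenance$placed), 4L)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(sum(syn$instances[[i]] & syn$instances[[j]]), 0L)

  # no orphan masks: every instance pixel received pasted intensity
  changed <- abs(syn$pixels - bg) > 0
  for (m in syn$instances) expect_true(all(changed[m]))
})

test_that("salt-and-pepper corruption follows its binomial contract", {
  img <- matrix(runif(100), 10, 10)
  expect_identical(add_salt_pepper(img, 0, seed = 1L), img)

  out <- add_salt_pepper(img, 1, seed = 1L)
  expect_true(all(out %in% c(0, 1)))

  big <- matrix(0.5, 1000, 1000)
  out <- add_salt_pepper(big, 0.1, seed = 2L)
  frac <- mean(out != 0.5)
  sd3 <- 3 * sqrt(0.1 * 0.9 / 1e6)
  expect_lt(abs(frac - 0.1), sd3 + 1e-9) # corrupted-to-0.5 collisions impossible
  expect_error(add_salt_pepper(img, 1.5), "density")
})

test_that("generate_dataset writes the configured counts reproducibly", {
  dir1 <- withr::local_tempdir()
  cfg <- smoke_gen_cfg(n_images = 5L, seed = 21L)
  bank <- render_cell_bank(12L, cfg, seed = 31L)
  tiles <- render_tile_bank(4L, tile_size = c(32L, 32L), seed = 32L)
  mf <- generate_dataset(cfg, bank, tiles, dir1)
  expect_length(mf$files, 5L)
  expect_true(all(file.exists(file.path(dir1, mf$files))))
  recs <- read_annotations(file.path(dir1, "annotations.json"))
  expect_length(recs, 5L)
  expect_identical(vapply(recs, function(r) length(r$masks), integer(1)),
                   as.integer(mf$n_instances))

  # a fixed cell count with permissive overlap always lands all cells
  cfg3 <- cfg; cfg3$cells_per_image <- c(3L, 3L)
  cfg3$max_pairwise_overlap_iou <- 0.9
  dir3 <- withr::local_tempdir()
  mf3 <- generate_dataset(cfg3, bank, tiles, dir3)
  expect_true(all(mf3$n_instances == 3L))

  # byte-identical rerun from the same configuration
  dir2 <- withr::local_tempdir()
  generate_dataset(cfg, bank, tiles, dir2)
  for (f in c(mf$files, "annotations.json", "manifest.json")) {
    h1 <- unname(tools::md5sum(file.path(dir1, f)))
    h2 <- unname(tools::md5sum(file.path(dir2, f)))
    expect_identical(h1, h2)
  }
})
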