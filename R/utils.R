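#' @importFrom stats rnorm runif median setNames lm coef cor var
#' @importFrom utils modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_somaswin <- function(...) stop(sprintf(...), call. = FALSE)

#' Clamp values to the unit interval
#'
#' @param x numeric vector, matrix or array.
#' @return `x` with every element forced into `[0, 1]`.
#' @keywords internal
clamp01 <- function(x) pmin(pmax(x, 0), 1)

assert_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop_somaswin("'%s' must be a nonempty numeric matrix", name)
  if (anyNA(img)) stop_somaswin("'%s' contains NA values", name)
  invisible(img)
}

assert_unit_image <- function(img, name = "image") {
  assert_image(img, name)
  if (min(img) < 0 || max(img) > 1)
    stop_somaswin("'%s' must have values in [0, 1]", name)
  invisible(img)
}

#' Derive a reproducible child seed
#'
#' Deterministically expands one master seed into per-item seeds so that
#' every image in a dataset (or every stochastic stage of a run) gets its
#' own stream while the whole run stays reproducible from a single
#' integer. The result is always a valid 31-bit positive integer.
#'
#' @param seed master seed (single number).
#' @param index child index (single number, e.g. image number).
#' @return a single integer in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  i <- (abs(as.numeric(index)) %% m)
  # two rounds of a Lehmer-style mix; all intermediates stay below 2^53
  x <- (s * 48271 + i + 1) %% m
  x <- (x * 69621 + 113) %% m
  as.integer(x + 1)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# reflect-pad a matrix by `r` pixels on every side
pad_reflect <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  if (r >= h || r >= w)
    stop_somaswin("padding radius %d too large for a %dx%d image", r, h, w)
  ri <- c(rev(seq_len(r) + 1L), seq_len(h), h - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(w), w - seq_len(r))
  img[ri, ci, drop = FALSE]
}

# zero-pad a matrix on the bottom/right to the given dimensions
pad_zero_br <- function(img, h, w) {
  if (nrow(img) == h && ncol(img) == w) return(img)
  out <- matrix(0, h, w)
  out[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  out
}

# tight bounding box of a logical mask: (row0, col0, height, width), 0-based
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(0L, 0L, 0L, 0L))
  r <- range(idx[, 1L]); c <- range(idx[, 2L])
  c(r[1L] - 1L, c[1L] - 1L, r[2L] - r[1L] + 1L, c[2L] - c[1L] + 1L)
}
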