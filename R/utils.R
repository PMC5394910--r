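# Shared low-level helpers.

.boundaryCode <- function(boundary) {
  boundary <- match.arg(boundary, c("symmetric", "periodic", "zero", "replicate"))
  switch(boundary, zero = 0L, symmetric = 1L, periodic = 2L, replicate = 3L)
}

.assertImage <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) < 1L || ncol(x) < 1L)
    stop(sprintf("'%s' must be a non-empty 2-D numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  invisible(TRUE)
}

.assertSameShape <- function(a, b, na = "A", nb = "B") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s is %s, %s is %s", na,
                 paste(dim(a), collapse = "x"), nb,
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Padded 2-D correlation
#'
#' Correlates an image with an odd-sized kernel under an explicit boundary
#' mode. `out[i,j] = sum_{a,b} kernel[a,b] * x[i+a-cr, j+b-cc]` with the
#' kernel center at `cr = (nrow+1)/2`, `cc = (ncol+1)/2`. All built-in NSCT,
#' feature and energy kernels are point-symmetric, for which correlation and
#' convolution coincide.
#'
#' @param x Numeric matrix.
#' @param kernel Odd-sized numeric kernel.
#' @param boundary `"symmetric"` (half-sample mirror, default), `"periodic"`,
#'   `"zero"` or `"replicate"`.
#' @return Matrix of `dim(x)`.
#' @export
conv2d <- function(x, kernel, boundary = "symmetric") {
  .assertImage(x, "x")
  if (!is.matrix(kernel) || any(dim(kernel) %% 2L == 0L))
    stop("'kernel' must be an odd-sized numeric matrix", call. = FALSE)
  .conv2Pad(x, kernel, .boundaryCode(boundary))
}

# index folding mirroring the C++ boundary handling, for R-side shifts
.foldIdx <- function(i, n, boundary) {
  switch(boundary,
    periodic = ((i - 1L) %% n) + 1L,
    replicate = pmin(pmax(i, 1L), n),
    symmetric = {
      p <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
      ifelse(p < n, p + 1L, 2L * n - p)
    },
    stop("unsupported boundary for index folding"))
}

# neighbour image x[i+dr, j+dc] under a boundary mode
.neighbor <- function(x, dr, dc, boundary = "symmetric") {
  m <- nrow(x); n <- ncol(x)
  x[.foldIdx(seq_len(m) + dr, m, boundary),
    .foldIdx(seq_len(n) + dc, n, boundary), drop = FALSE]
}

#' Min-max normalization to the unit interval
#'
#' Rescales a matrix linearly to `[0,1]`; a constant input (zero range)
#' maps to all zeros.
#'
#' @param x Numeric matrix.
#' @return Matrix in `[0,1]`.
#' @export
normalize01 <- function(x) {
  .assertImage(x, "x")
  rng <- range(x)
  if (rng[2] == rng[1]) return(array(0, dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Peak signal-to-noise ratio
#'
#' @param ref Reference image.
#' @param x Test image, same shape.
#' @param peak Peak intensity of the dynamic range (default 1 for unit-range
#'   images).
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(ref, x, peak = 1) {
  .assertSameShape(ref, x, "ref", "x")
  mse <- mean((ref - x)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# Deterministic noise image from a Lehmer generator; used for build-time
# filter-bank validation so the global RNG stream is never touched.
.noiseMatrix <- function(nr, nc, seed = 1L) {
  n <- nr * nc
  state <- as.double((seed %% 2147483646) + 1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- state / 2147483647
  }
  matrix(out - 0.5, nr, nc)
}
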