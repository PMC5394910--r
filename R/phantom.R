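# Seeded co-registered CT-like / PET-like phantom pairs, so every pipeline
# stage is testable without clinical data.

# mask of an axis-aligned ellipse, optionally rotated
.ellipseMask <- function(size, cr, cc, ar, ac, angle = 0) {
  r <- row(matrix(0, size, size)) - cr
  c <- col(matrix(0, size, size)) - cc
  if (angle != 0) {
    rr <- cos(angle) * r - sin(angle) * c
    cc2 <- sin(angle) * r + cos(angle) * c
    r <- rr; c <- cc2
  }
  (r / ar)^2 + (c / ac)^2 <= 1
}

# Bilinear upsampling by an integer factor under block-mean geometry:
# coarse pixel k covers full pixels f*k-f+1 .. f*k, so its center sits at
# full-resolution coordinate f*k - (f-1)/2 (for f = 4: 4k - 1.5); a full
# pixel at index idx therefore has coarse coordinate (idx + (f-1)/2) / f.
.upsampleBilinear <- function(x, f) {
  m <- nrow(x); n <- ncol(x)
  coord <- function(idx) (idx + (f - 1) / 2) / f  # full -> coarse coords
  interpAxis <- function(sizeFull, sizeCoarse) {
    g <- coord(seq_len(sizeFull))
    lo <- pmin(pmax(floor(g), 1L), sizeCoarse)
    hi <- pmin(lo + 1L, sizeCoarse)
    wHi <- pmin(pmax(g - lo, 0), 1)
    list(lo = lo, hi = hi, w = wHi)
  }
  ri <- interpAxis(m * f, m); ci <- interpAxis(n * f, n)
  a <- x[ri$lo, ci$lo, drop = FALSE]; b <- x[ri$hi, ci$lo, drop = FALSE]
  cc <- x[ri$lo, ci$hi, drop = FALSE]; d <- x[ri$hi, ci$hi, drop = FALSE]
  wr <- matrix(ri$w, m * f, n * f); wc <- matrix(ci$w, m * f, n * f, byrow = TRUE)
  (1 - wr) * (1 - wc) * a + wr * (1 - wc) * b + (1 - wr) * wc * cc + wr * wc * d
}

#' Generate a co-registered synthetic PET/CT phantom pair
#'
#' The CT-like image is sharp piecewise-constant anatomy inside a body
#' ellipse — soft-tissue ellipses, a bright spine, rib-like bone spots —
#' plus low-amplitude pixel texture. The PET-like image is a dim body mask
#' with smooth Gaussian hotspots, rendered at quarter resolution and
#' bilinearly upsampled to emulate the low intrinsic resolution of PET.
#' Hotspot centers are snapped to coarse-grid sample positions so each
#' rendered maximum falls within one pixel of its recorded truth center.
#'
#' Deterministic for a given seed: the generator pins R's Mersenne-Twister
#' RNG (`normal.kind = "Inversion"`, `sample.kind = "Rejection"`) and
#' restores the caller's RNG state on exit.
#'
#' @param seed Integer seed.
#' @param size Image side length, a multiple of 4, at least 32 (default
#'   128).
#' @param nHotspots Number of PET hotspots (default 3).
#' @return A [PhantomPair-class]; access with [ctImage()], [petImage()],
#'   [phantomTruth()].
#' @examples
#' ph <- makePhantomPair(7, size = 64)
#' range(ctImage(ph)); phantomTruth(ph)$centers
#' @export
makePhantomPair <- function(seed, size = 128L, nHotspots = 3L) {
  size <- as.integer(size)
  if (size < 32L) stop("'size' must be at least 32", call. = FALSE)
  if (size %% 4L != 0L) stop("'size' must be a multiple of 4", call. = FALSE)
  if (nHotspots < 1L) stop("'nHotspots' must be at least 1", call. = FALSE)

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  ctr <- (size + 1) / 2
  bodyAr <- 0.36 * size; bodyAc <- 0.42 * size
  body <- .ellipseMask(size, ctr, ctr, bodyAr, bodyAc)

  ## ---- CT: sharp piecewise-constant anatomy -----------------------------
  ct <- matrix(0.02, size, size)
  ct[body] <- 0.30
  nTissue <- 7L
  for (i in seq_len(nTissue)) {
    ec <- ctr + c(runif(1, -0.55, 0.55) * bodyAr, runif(1, -0.55, 0.55) * bodyAc)
    ax <- runif(2, 0.05, 0.16) * size
    m <- .ellipseMask(size, ec[1], ec[2], ax[1], ax[2], runif(1, 0, pi)) & body
    ct[m] <- runif(1, 0.25, 0.60)
  }
  spine <- .ellipseMask(size, ctr + 0.22 * bodyAr, ctr, 0.05 * size,
                        0.045 * size) & body
  ct[spine] <- 0.95
  for (i in 1:3) {  # rib-like bone spots near the body boundary
    ang <- runif(1, 0, 2 * pi)
    ec <- ctr + 0.85 * c(bodyAr * sin(ang), bodyAc * cos(ang))
    m <- .ellipseMask(size, ec[1], ec[2], 0.022 * size, 0.022 * size) & body
    ct[m] <- runif(1, 0.85, 0.95)
  }
  tex <- matrix(runif(size * size, -0.015, 0.015), size, size)
  ct[body] <- ct[body] + tex[body]
  ct <- .clamp01(ct)

  ## ---- PET: smooth hotspots at quarter resolution -----------------------
  cs <- size %/% 4L
  cctr <- (cs + 1) / 2
  cbody <- .ellipseMask(cs, cctr, cctr, bodyAr / 4, bodyAc / 4)
  inner <- .ellipseMask(cs, cctr, cctr, 0.7 * bodyAr / 4, 0.7 * bodyAc / 4)
  candidates <- which(inner, arr.ind = TRUE)
  minSep <- max(4, cs / 6)
  centers <- matrix(0, 0L, 2L)
  guard <- 0L
  while (nrow(centers) < nHotspots && guard < 10000L) {
    guard <- guard + 1L
    cand <- candidates[sample.int(nrow(candidates), 1L), ]
    if (nrow(centers) == 0L ||
        min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2L,
                                           byrow = TRUE))^2))) >= minSep)
      centers <- rbind(centers, cand)
  }
  if (nrow(centers) < nHotspots)
    stop("could not place hotspots with the required separation; reduce nHotspots",
         call. = FALSE)
  sigma <- runif(nHotspots, 1.2, 2.2)          # coarse-grid pixels
  amp <- runif(nHotspots, 0.55, 0.85)
  pet <- matrix(0.01, cs, cs)
  pet[cbody] <- 0.15
  rr <- row(pet); cc <- col(pet)
  for (h in seq_len(nHotspots)) {
    pet <- pet + amp[h] *
      exp(-((rr - centers[h, 1])^2 + (cc - centers[h, 2])^2) / (2 * sigma[h]^2))
  }
  pet <- .clamp01(.upsampleBilinear(pet, 4L))

  truth <- list(
    centers = cbind(4 * centers[, 1] - 1.5, 4 * centers[, 2] - 1.5),
    sigma = 4 * sigma,
    amplitude = amp,
    body = list(center = c(ctr, ctr), semiAxes = c(bodyAr, bodyAc)))
  new("PhantomPair", ct = ct, pet = pet, truth = truth,
      seed = as.integer(seed))
}

#' Circularly shift an image
#'
#' Shifts by `(dy, dx)` with wrap-around; `circShift(circShift(x, s), -s)`
#' is the identity, and the shifted image is a pixel permutation of the
#' original. Used together with the `"periodic"` boundary mode to verify
#' shift invariance of the transform and the fusion pipeline.
#'
#' @param image Matrix.
#' @param shift Integer `(dy, dx)`: positive values move content down/right.
#' @return Shifted matrix.
#' @export
circShift <- function(image, shift = c(0L, 0L)) {
  .assertImage(image)
  dy <- as.integer(shift[1]); dx <- as.integer(shift[2])
  m <- nrow(image); n <- ncol(image)
  image[((seq_len(m) - 1L - dy) %% m) + 1L,
        ((seq_len(n) - 1L - dx) %% n) + 1L, drop = FALSE]
}
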