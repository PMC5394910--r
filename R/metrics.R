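# Seven fusion-quality metrics with documented histogram and windowing
# conventions.
#
# Conventions shared by the histogram metrics: each image is independently
# min-max rescaled to [0, L-1] and rounded (a constant image maps to level
# 0); L = 256 by default. Windowed metrics (IQI, Q_E) use 8x8 sliding
# windows with stride 1 and population (1/n) moments.

#' Average gradient
#'
#' `G = 1/((m-1)(n-1)) * sum sqrt[((C(i,j)-C(i+1,j))^2 +
#' (C(i,j)-C(i,j+1))^2) / 2]`, summed over the pixels where both forward
#' differences exist. Higher values indicate a crisper image.
#'
#' @param C Image matrix, at least 2x2.
#' @return Non-negative scalar.
#' @export
averageGradient <- function(C) {
  .assertImage(C, "C")
  m <- nrow(C); n <- ncol(C)
  if (m < 2L || n < 2L) stop("image must be at least 2x2", call. = FALSE)
  g1 <- (C[-m, -n] - C[-1L, -n])^2
  g2 <- (C[-m, -n] - C[-m, -1L])^2
  sum(sqrt((g1 + g2) / 2)) / ((m - 1) * (n - 1))
}

#' Quantize an image to integer gray levels
#'
#' Min-max rescales to `[0, L-1]` and rounds; a constant image maps to all
#' zeros. This is the quantization convention of all histogram metrics here.
#'
#' @param C Image matrix.
#' @param L Number of gray levels (default 256).
#' @return Integer matrix in `0..L-1`.
#' @export
quantizeGray <- function(C, L = 256L) {
  .assertImage(C, "C")
  rng <- range(C)
  if (rng[2] == rng[1]) return(array(0L, dim(C)))
  array(as.integer(round((C - rng[1]) / (rng[2] - rng[1]) * (L - 1L))), dim(C))
}

.grayProb <- function(C, L) {
  q <- quantizeGray(C, L)
  tabulate(as.vector(q) + 1L, nbins = L) / length(q)
}

#' Shannon entropy of an image
#'
#' `EN = -sum P_i log2 P_i` over the quantized gray-level histogram
#' (see [quantizeGray()]). Bounded by `log2(L)`.
#'
#' @param C Image matrix.
#' @param L Number of gray levels.
#' @return Entropy in bits.
#' @export
shannonEntropy <- function(C, L = 256L) {
  p <- .grayProb(C, L)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Joint entropy of two images
#'
#' `H(F,A) = -sum P_{i,j} log2 P_{i,j}` over the joint gray-level histogram
#' of the quantized images. Symmetric in its arguments. The fusion report's
#' JE for a triple is `(H(F,A) + H(F,B)) / 2` (see [evaluateFusion()]).
#'
#' @param F,A Same-shape image matrices.
#' @param L Number of gray levels.
#' @return Joint entropy in bits.
#' @export
jointEntropy <- function(F, A, L = 256L) {
  .assertSameShape(F, A, "F", "A")
  qf <- quantizeGray(F, L); qa <- quantizeGray(A, L)
  p <- tabulate(as.vector(qf) * L + as.vector(qa) + 1L, nbins = L * L) /
    length(qf)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Cross entropy of a fused image against its sources
#'
#' Mean relative entropy of the source histograms from the fused histogram:
#' `CE = (D(h_A || h_F) + D(h_B || h_F)) / 2` with
#' `D(p||q) = sum p_i log2(p_i / q_i)`. Bins with `p_i = 0` contribute
#' nothing; `q` is floored at `1e-12` so that sources containing levels
#' absent from F give a large finite penalty.
#'
#' @param A,B,F Same-shape image matrices.
#' @param L Number of gray levels.
#' @return Non-negative scalar (0 when all histograms coincide).
#' @export
crossEntropy <- function(A, B, F, L = 256L) {
  .assertSameShape(A, F, "A", "F"); .assertSameShape(B, F, "B", "F")
  hf <- pmax(.grayProb(F, L), 1e-12)
  rel <- function(p) { i <- p > 0; sum(p[i] * log2(p[i] / hf[i])) }
  (rel(.grayProb(A, L)) + rel(.grayProb(B, L))) / 2
}

# Sliding-window sums via integral images; returns (m-w+1) x (n-w+1).
.boxSum <- function(x, w) {
  cs <- apply(x, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = nrow(x))
  cs <- rbind(0, cs)
  v <- cs[(w + 1L):nrow(cs), , drop = FALSE] -
       cs[seq_len(nrow(cs) - w), , drop = FALSE]
  cs2 <- t(apply(v, 1L, cumsum))
  if (nrow(v) == 1L) cs2 <- matrix(cs2, nrow = 1L)
  cs2 <- cbind(0, cs2)
  cs2[, (w + 1L):ncol(cs2), drop = FALSE] -
    cs2[, seq_len(ncol(cs2) - w), drop = FALSE]
}

# Per-window population moments of a pair of images.
.windowStats <- function(x, y, w) {
  n <- w * w
  mx <- .boxSum(x, w) / n
  my <- .boxSum(y, w) / n
  vx <- pmax(.boxSum(x * x, w) / n - mx^2, 0)
  vy <- pmax(.boxSum(y * y, w) / n - my^2, 0)
  cxy <- .boxSum(x * y, w) / n - mx * my
  list(mx = mx, my = my, vx = vx, vy = vy, cxy = cxy)
}

# Wang-Bovik quality index per window, with documented degenerate-window
# conventions: identical constant windows give 1; zero-variance windows
# fall back to the luminance factor; zero-mean windows to the
# correlation-contrast factor. A variance sum below 1e-12 counts as zero
# (unit-range images).
.qualityIndexMap <- function(x, y, w = 8L) {
  s <- .windowStats(x, y, w)
  dMean <- s$mx^2 + s$my^2
  dVar <- s$vx + s$vy
  zVar <- dVar < 1e-12
  zMean <- dMean < 1e-24
  q <- array(1, dim(dMean))
  i <- !zVar & !zMean
  q[i] <- (4 * s$cxy[i] * s$mx[i] * s$my[i]) / (dVar[i] * dMean[i])
  i <- zVar & !zMean
  q[i] <- 2 * s$mx[i] * s$my[i] / dMean[i]
  i <- !zVar & zMean
  q[i] <- 2 * s$cxy[i] / dVar[i]
  q
}

#' Image quality index (IQI)
#'
#' Wang-Bovik universal image quality index: the product of correlation,
#' luminance and contrast similarity, computed in 8x8 sliding windows
#' (stride 1, population moments) and averaged. `iqi(x, x) == 1`; values
#' lie in `[-1, 1]`.
#'
#' @param x,y Same-shape image matrices, at least `window` in each
#'   dimension.
#' @param window Sliding-window size (default 8).
#' @return Scalar in `[-1, 1]`.
#' @export
iqi <- function(x, y, window = 8L) {
  .assertImage(x, "x"); .assertImage(y, "y")
  .assertSameShape(x, y, "x", "y")
  if (any(dim(x) < window))
    stop(sprintf("images must be at least %dx%d", window, window), call. = FALSE)
  mean(.qualityIndexMap(x, y, window))
}

#' Fusion IQI of a source pair and fused image
#'
#' `IQI(A,B,F) = (iqi(A,F) + iqi(B,F)) / 2`.
#'
#' @param A,B,F Same-shape image matrices.
#' @param window Sliding-window size.
#' @return Scalar in `[-1, 1]`.
#' @export
iqiFusion <- function(A, B, F, window = 8L) {
  (iqi(A, F, window) + iqi(B, F, window)) / 2
}

# Sobel gradient magnitude (symmetric padding).
.sobel <- function(x) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)
  gx <- conv2d(x, sx, "symmetric")
  gy <- conv2d(x, t(sx), "symmetric")
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# saliency-weighted windowed IQI (the Q_W inner sum of Q_E)
.qWindowed <- function(A, B, F, window) {
  qa <- .qualityIndexMap(A, F, window)
  qb <- .qualityIndexMap(B, F, window)
  sa <- .windowStats(A, A, window)$vx
  sb <- .windowStats(B, B, window)$vx
  tot <- sa + sb
  lam <- array(0.5, dim(sa))
  i <- tot > 0
  lam[i] <- sa[i] / tot[i]
  cw <- pmax(sa, sb)
  if (sum(cw) == 0) cw <- array(1, dim(cw))  # all-constant inputs: uniform
  cw <- cw / sum(cw)
  sum(cw * (lam * qa + (1 - lam) * qb))
}

#' Edge-dependent fusion quality Q_E
#'
#' Saliency-weighted windowed IQI of the intensity images multiplied by the
#' same quantity on their edge images:
#' `Q_E = Q_W(A,B,F) * Q_W(A',B',F')^alpha`, where `Q_W` weights each 8x8
#' window's IQI terms by `lambda(w) = s(A|w)/(s(A|w)+s(B|w))` (saliency
#' `s` = window variance) and normalized overall saliency
#' `c(w) = max(s_A, s_B) / sum`. Edge images are Sobel gradient magnitudes.
#' Windows with zero total saliency get `lambda = 0.5`; all-constant inputs
#' get uniform window weights.
#'
#' @param A,B,F Same-shape image matrices.
#' @param alpha Contribution of the edge images in `[0,1]` (default 1;
#'   `alpha = 0` drops the edge term).
#' @param window Sliding-window size.
#' @return Scalar, at most 1.
#' @export
qe <- function(A, B, F, alpha = 1, window = 8L) {
  .assertImage(A, "A"); .assertImage(B, "B"); .assertImage(F, "F")
  .assertSameShape(A, F, "A", "F"); .assertSameShape(B, F, "B", "F")
  qw <- .qWindowed(A, B, F, window)
  if (alpha == 0) return(qw)
  qwe <- .qWindowed(.sobel(A)$mag, .sobel(B)$mag, .sobel(F)$mag, window)
  qw * qwe^alpha
}

# Per-pixel edge preservation of X into F (Xydeas-Petrovic sigmoids).
.edgePreservation <- function(sX, sF, combine) {
  G <- array(1, dim(sX$mag))
  hi <- pmax(sX$mag, sF$mag)
  i <- hi > 0
  G[i] <- pmin(sX$mag, sF$mag)[i] / hi[i]
  aX <- atan2(sX$gy, sX$gx); aX[aX > pi / 2] <- aX[aX > pi / 2] - pi
  aX[aX <= -pi / 2] <- aX[aX <= -pi / 2] + pi
  aF <- atan2(sF$gy, sF$gx); aF[aF > pi / 2] <- aF[aF > pi / 2] - pi
  aF[aF <= -pi / 2] <- aF[aF <= -pi / 2] + pi
  Aor <- 1 - abs(aX - aF) / (pi / 2)
  Qg <- 0.9994 / (1 + exp(-15 * (G - 0.5)))
  Qa <- 0.9879 / (1 + exp(-22 * (Aor - 0.8)))
  if (combine == "product") Qg * Qa else Qg + Qa
}

#' Edge-information preservation Q^AB/F
#'
#' Sobel edge strength `g` and orientation `alpha` are extracted from each
#' source and the fused image; strength and orientation preservation are
#' mapped through the standard sigmoids (`Gamma_g = 0.9994`,
#' `kappa_g = -15`, `sigma_g = 0.5`; `Gamma_a = 0.9879`, `kappa_a = -22`,
#' `sigma_a = 0.8`); per-pixel preservation is their product (the
#' `combine = "sum"` variant adds them instead, and is then not bounded by
#' 1); the result is the edge-strength-weighted mean over both sources,
#' with weights `w^A = g_A`, `w^B = g_B`. Returns 0 for edge-free
#' (all-constant) inputs.
#'
#' @param A,B,F Same-shape image matrices.
#' @param combine `"product"` (default) or `"sum"` of the strength and
#'   orientation preservation factors.
#' @return Scalar in `[0, 1]` for `combine = "product"`.
#' @export
qabf <- function(A, B, F, combine = c("product", "sum")) {
  .assertImage(A, "A"); .assertImage(B, "B"); .assertImage(F, "F")
  .assertSameShape(A, F, "A", "F"); .assertSameShape(B, F, "B", "F")
  combine <- match.arg(combine)
  sA <- .sobel(A); sB <- .sobel(B); sF <- .sobel(F)
  qaf <- .edgePreservation(sA, sF, combine)
  qbf <- .edgePreservation(sB, sF, combine)
  den <- sum(sA$mag + sB$mag)
  if (den == 0) return(0)
  sum(qaf * sA$mag + qbf * sB$mag) / den
}

#' Evaluate all seven fusion metrics
#'
#' Computes average gradient and Shannon entropy of the fused image, mean
#' joint entropy of the fused image with each source, cross entropy, fusion
#' IQI, Q_E and Q^AB/F for a source pair and fused image. Deterministic.
#'
#' @param A,B Source images (same shape).
#' @param F Fused image (same shape).
#' @param L Gray levels for the histogram metrics.
#' @return A [MetricsReport-class]; extract values with [metricsValues()].
#' @export
evaluateFusion <- function(A, B, F, L = 256L) {
  .assertImage(A, "A"); .assertImage(B, "B"); .assertImage(F, "F")
  .assertSameShape(A, F, "A", "F"); .assertSameShape(B, F, "B", "F")
  new("MetricsReport",
      ag = averageGradient(F),
      en = shannonEntropy(F, L),
      je = (jointEntropy(F, A, L) + jointEntropy(F, B, L)) / 2,
      ce = crossEntropy(A, B, F, L),
      iqi = iqiFusion(A, B, F),
      qe = qe(A, B, F),
      qabf = qabf(A, B, F))
}
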