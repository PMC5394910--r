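# Simplified pulse-coupled neural network with adaptive linking strength.

#' Default PCNN linking kernel
#'
#' 3x3 inverse-Euclidean-distance weights with a zero center: axial
#' neighbours weigh 1, diagonal neighbours `1/sqrt(2)`.
#'
#' @return A 3x3 matrix.
#' @export
defaultLinkKernel <- function() {
  d <- 1 / sqrt(2)
  matrix(c(d, 1, d, 1, 0, 1, d, 1, d), 3L, 3L)
}

#' Construct PCNN parameters
#'
#' The source publication leaves all PCNN constants open; the defaults here
#' are conventional simplified-PCNN settings: slow linking decay
#' (`alphaL = 0.06931`, i.e. half-life 10 iterations), threshold decay
#' `alphaTheta = 0.2`, unit linking gain, a large post-fire threshold kick
#' (`Vtheta = 20`) so each neuron fires sparsely, 200 iterations and an
#' initial threshold of 1 (the top of the normalized input range).
#'
#' @param alphaL,alphaTheta Decay constants per iteration (positive).
#' @param VL,Vtheta Linking and threshold normalizing constants (positive).
#' @param linkKernel Odd-sized non-negative linking weights with zero
#'   center; default [defaultLinkKernel()].
#' @param nIter Iteration count.
#' @param thetaInit Initial threshold.
#' @return A [PCNNParams-class] object.
#' @export
pcnnParams <- function(alphaL = 0.06931, alphaTheta = 0.2, VL = 1,
                       Vtheta = 20, linkKernel = defaultLinkKernel(),
                       nIter = 200L, thetaInit = 1) {
  new("PCNNParams", alphaL = as.numeric(alphaL),
      alphaTheta = as.numeric(alphaTheta), VL = as.numeric(VL),
      Vtheta = as.numeric(Vtheta), linkKernel = linkKernel,
      nIter = as.integer(nIter), thetaInit = as.numeric(thetaInit))
}

#' Region-average-gradient linking strength
#'
#' Per-pixel adaptive linking strength for the PCNN: the 3x3 neighbourhood
#' mean of `sqrt((g1 + g2)/2)`, where `g1` and `g2` are the squared forward
#' differences down rows and along columns. Higher local gradient means
#' higher clarity, so the corresponding neuron links more strongly and
#' ignites earlier.
#'
#' Forward differences at the last row/column use replicated edges (the
#' difference is 0 there); with `boundary = "periodic"` they wrap instead,
#' which makes the map exactly shift-equivariant.
#'
#' @param C Input map (here, the PCNN external-input feature map).
#' @param boundary Boundary mode for both the differences and the 3x3 mean.
#' @return Non-negative matrix of `dim(C)`.
#' @export
linkingStrengthMap <- function(C, boundary = c("symmetric", "periodic")) {
  .assertImage(C, "C")
  boundary <- match.arg(boundary)
  diffMode <- if (boundary == "periodic") "periodic" else "replicate"
  g1 <- (C - .neighbor(C, 1L, 0L, diffMode))^2
  g2 <- (C - .neighbor(C, 0L, 1L, diffMode))^2
  conv2d(sqrt((g1 + g2) / 2), matrix(1 / 9, 3L, 3L), boundary)
}

#' Run the simplified PCNN
#'
#' Iterates the simplified PCNN recursion for `nIter` steps from `L = 0`,
#' `Y = 0`, `theta = thetaInit`. The feeding input has no memory
#' (`F[n] = S` at every step); internal activity is `U = S (1 + beta L)`;
#' the threshold decays by `exp(-alphaTheta)` each step, a neuron fires when
#' `U` meets the decayed threshold, and firing kicks the threshold up by
#' `Vtheta`. Fully deterministic.
#'
#' @param S External input, normalized to `[0,1]` by the caller (values
#'   outside by more than 1e-9 raise an error, guarding against a missed
#'   normalization).
#' @param beta Non-negative linking-strength map, same shape as `S` (see
#'   [linkingStrengthMap()]). A scalar is recycled.
#' @param params [PCNNParams-class].
#' @param boundary Linking-neighbourhood boundary: `"zero"` (default;
#'   border neurons have fewer neighbours) or `"periodic"`.
#' @return Integer matrix of per-pixel cumulative firing counts in
#'   `[0, nIter]`.
#' @examples
#' S <- matrix(0.5, 1, 1)
#' runPCNN(S, matrix(0, 1, 1), pcnnParams(nIter = 10))  # fires once, at n = 4
#' @export
runPCNN <- function(S, beta, params = pcnnParams(),
                    boundary = c("zero", "periodic")) {
  .assertImage(S, "S")
  boundary <- match.arg(boundary)
  if (min(S) < -1e-9 || max(S) > 1 + 1e-9)
    stop("external input S must be normalized to [0,1]", call. = FALSE)
  if (length(beta) == 1L) beta <- array(as.numeric(beta), dim(S))
  .assertImage(beta, "beta")
  .assertSameShape(S, beta, "S", "beta")
  if (min(beta) < 0) stop("beta must be non-negative", call. = FALSE)
  validObject(params)
  .pcnnRun(S, beta, params@linkKernel, params@alphaL, params@alphaTheta,
           params@VL, params@Vtheta, params@thetaInit, params@nIter,
           if (boundary == "periodic") 2L else 0L)
}
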