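# External-input feature maps for the PCNN: NSML for the low-pass band,
# EOE for the directional high-pass bands.

# Center-weighted window template: weight (window - |a| - |b|), normalized.
# For window = 3 this is the printed template [1 2 1; 2 3 2; 1 2 1] / 15.
.nsmlWeights <- function(window) {
  r <- (window - 1L) / 2L
  w <- outer(-r:r, -r:r, function(a, b) window - abs(a) - abs(b))
  w / sum(w)
}

#' Novel sum-modified Laplacian (NSML) feature map
#'
#' Clarity/edge feature for low-pass subbands. The modified Laplacian
#' `M(i,j) = |2C - C(i-1,j) - C(i+1,j)| + |2C - C(i,j-1) - C(i,j+1)|` is
#' squared and summed over a center-weighted window: for the default 3x3
#' window the weights are `[1 2 1; 2 3 2; 1 2 1] / 15`.
#'
#' @param C Subband coefficients (matrix).
#' @param window Odd window size, one of 3 (default), 5, 7. Larger windows
#'   use the analogous center-weighted template.
#' @param boundary Padding mode, `"symmetric"` by default.
#' @return Non-negative feature map of `dim(C)`.
#' @export
nsmlMap <- function(C, window = 3L, boundary = c("symmetric", "periodic")) {
  .assertImage(C, "C")
  boundary <- match.arg(boundary)
  if (window %% 2L == 0L) stop("'window' must be odd", call. = FALSE)
  if (!window %in% c(3L, 5L, 7L)) stop("'window' must be 3, 5 or 7", call. = FALSE)
  M <- abs(2 * C - .neighbor(C, -1L, 0L, boundary) - .neighbor(C, 1L, 0L, boundary)) +
       abs(2 * C - .neighbor(C, 0L, -1L, boundary) - .neighbor(C, 0L, 1L, boundary))
  conv2d(M^2, .nsmlWeights(as.integer(window)), boundary)
}

#' Directional edge operators of the EOE feature
#'
#' The three 3x3 operators picking up horizontal, vertical and diagonal
#' edge energy.
#'
#' @return `list(E1, E2, E3)` of 3x3 matrices.
#' @export
eoeOperators <- function() {
  list(
    E1 = matrix(c(-1, 2, -1, -1, 2, -1, -1, 2, -1), 3L, 3L),  # rows -1;2;-1
    E2 = matrix(c(-1, -1, -1, 2, 2, 2, -1, -1, -1), 3L, 3L),  # cols -1,2,-1
    E3 = matrix(c(-1, 0, -1, 0, 4, 0, -1, 0, -1), 3L, 3L))
}

#' Energy-of-edge (EOE) feature map
#'
#' Edge feature for high-pass subbands: local energy
#' `LE = (E1*C)^2 + (E2*C)^2 + (E3*C)^2` from the three directional
#' operators of [eoeOperators()], accumulated over a 3x3 weighted
#' neighbourhood.
#'
#' @param C Subband coefficients (matrix).
#' @param W 3x3 weight template; defaults to the same normalized
#'   center-weighted template as [nsmlMap()].
#' @param boundary Padding mode.
#' @return Non-negative feature map of `dim(C)`.
#' @export
eoeMap <- function(C, W = .nsmlWeights(3L),
                   boundary = c("symmetric", "periodic")) {
  .assertImage(C, "C")
  boundary <- match.arg(boundary)
  if (!is.matrix(W) || !all(dim(W) == c(3L, 3L)))
    stop("'W' must be a 3x3 weight template", call. = FALSE)
  ops <- eoeOperators()
  LE <- conv2d(C, ops$E1, boundary)^2 + conv2d(C, ops$E2, boundary)^2 +
        conv2d(C, ops$E3, boundary)^2
  conv2d(LE, W, boundary)
}
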