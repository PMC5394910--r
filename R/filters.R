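# Kernel algebra and filter-bank construction for the NSCT.
#
# Perfect reconstruction is obtained structurally: every two-channel split
# uses a complementary analysis pair (high = delta - low, fan complement
# likewise) with identity (delta) synthesis kernels, so synthesis is the sum
# of the channels and analysis-then-synthesis is the identity for any
# lowpass kernel and any boundary mode. This is the a-trous-style
# nonsubsampled construction.

# full 2-D convolution of two small kernels
.kconv <- function(a, b) {
  out <- matrix(0, nrow(a) + nrow(b) - 1L, ncol(a) + ncol(b) - 1L)
  for (j in seq_len(ncol(b))) {
    for (i in seq_len(nrow(b))) {
      if (b[i, j] == 0) next
      ri <- i:(i + nrow(a) - 1L); rj <- j:(j + ncol(a) - 1L)
      out[ri, rj] <- out[ri, rj] + a * b[i, j]
    }
  }
  out
}

.kdelta <- function() matrix(1, 1L, 1L)

# embed a centered kernel into a larger odd-sized frame
.kpadTo <- function(k, nr, nc) {
  out <- matrix(0, nr, nc)
  r0 <- (nr - nrow(k)) %/% 2L
  c0 <- (nc - ncol(k)) %/% 2L
  out[r0 + seq_len(nrow(k)), c0 + seq_len(ncol(k))] <- k
  out
}

# delta - k, keeping k's frame
.kcomplement <- function(k) {
  out <- -k
  ctr <- (dim(k) + 1L) %/% 2L
  out[ctr[1], ctr[2]] <- out[ctr[1], ctr[2]] + 1
  out
}

# Upsample a kernel on the lattice given by an integer matrix M: a tap at
# offset n from the center moves to offset M %*% n. M = s*I gives a-trous
# dilation; M = quincunx gives the checkerboard lattice used by the
# directional tree.
.kupsample <- function(k, M) {
  if (identical(M, diag(2))) return(k)
  ctr <- (dim(k) + 1L) %/% 2L
  idx <- which(k != 0, arr.ind = TRUE)
  rel <- cbind(idx[, 1] - ctr[1], idx[, 2] - ctr[2]) %*% t(M)
  rmax <- max(abs(rel[, 1]), 0); cmax <- max(abs(rel[, 2]), 0)
  out <- matrix(0, 2L * rmax + 1L, 2L * cmax + 1L)
  for (t in seq_len(nrow(idx)))
    out[rel[t, 1] + rmax + 1L, rel[t, 2] + cmax + 1L] <- k[idx[t, 1], idx[t, 2]]
  out
}

# quincunx sampling matrix of the directional tree
.QUINCUNX <- matrix(c(1, -1, 1, 1), 2L, 2L)

# Maximally-flat (binomial) separable lowpass kernels.
.binomial1d <- function(order) {
  b <- choose(order, 0:order)
  b / sum(b)
}

# Diamond-shaped lowpass via the McClellan transform of the degree-3
# maximally-flat halfband H(x) = 1/2 + (3/4) x - (1/4) x^3 evaluated at
# x = (cos w1 + cos w2)/2, i.e. a zero-phase halfband whose passband is the
# diamond |w1| + |w2| < pi.
.diamondKernel <- function() {
  Tk <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3L, 3L) / 4
  T3 <- .kconv(.kconv(Tk, Tk), Tk)
  k <- .kpadTo(.kdelta(), 7L, 7L) / 2
  k <- k + 0.75 * .kpadTo(Tk, 7L, 7L)
  k - 0.25 * T3
}

# Fan lowpass: modulate the diamond by (-1)^row, shifting the row frequency
# by pi. Passband is the fan (bow-tie) around the horizontal axis.
.fanKernel <- function() {
  d <- .diamondKernel()
  ctr <- (nrow(d) + 1L) / 2L
  d * (-1)^(row(d) - ctr)
}

.filterBankPresets <- c("maxflat", "binomial3")

#' Build a named NSCT filter-bank preset
#'
#' Constructs the analysis/synthesis kernel pairs used by [nsctForward()]
#' and [nsctInverse()] and verifies perfect reconstruction of both pairs on
#' a deterministic noise image at build time.
#'
#' Presets: `"maxflat"` (default) pairs a 5x5 maximally-flat binomial
#' pyramid lowpass with a 7x7 fan filter derived from a degree-3
#' maximally-flat diamond halfband via the McClellan transform;
#' `"binomial3"` uses a lighter 3x3 pyramid lowpass with the same fan pair.
#' In both, the high/complement analysis kernel is `delta - low` and the
#' synthesis kernels are deltas, so reconstruction is the channel sum and is
#' exact under every boundary mode.
#'
#' @param name Preset identifier.
#' @return A [FilterBank-class] object.
#' @examples
#' buildFilterBank()
#' @export
buildFilterBank <- function(name = "maxflat") {
  if (!is.character(name) || length(name) != 1L || !name %in% .filterBankPresets)
    stop(sprintf("unknown filter bank '%s' (available: %s)",
                 as.character(name)[1], paste(.filterBankPresets, collapse = ", ")),
         call. = FALSE)
  b <- switch(name, maxflat = .binomial1d(4L), binomial3 = .binomial1d(2L))
  h0 <- outer(b, b)
  fan <- .fanKernel()
  bank <- new("FilterBank", name = name,
              pyramidAnalysis = list(h0, .kcomplement(h0)),
              pyramidSynthesis = list(.kdelta(), .kdelta()),
              fanAnalysis = list(fan, .kcomplement(fan)),
              fanSynthesis = list(.kdelta(), .kdelta()))
  .checkPerfectReconstruction(bank)
  bank
}

# analysis-then-synthesis of a fixed noise image must return the input
.checkPerfectReconstruction <- function(bank, tol = 1e-6) {
  x <- .noiseMatrix(32L, 32L, seed = 7L)
  pr <- function(a, s) {
    rec <- conv2d(conv2d(x, a[[1]], "symmetric"), s[[1]], "symmetric") +
           conv2d(conv2d(x, a[[2]], "symmetric"), s[[2]], "symmetric")
    max(abs(rec - x))
  }
  if (pr(bank@pyramidAnalysis, bank@pyramidSynthesis) >= tol)
    stop("pyramid filter pair fails perfect reconstruction", call. = FALSE)
  if (pr(bank@fanAnalysis, bank@fanSynthesis) >= tol)
    stop("fan filter pair fails perfect reconstruction", call. = FALSE)
  invisible(TRUE)
}

# Directional-tree kernels at depth t (1..4). Orientation alternates between
# the fan and its transpose; the upsampling lattice follows the equivalent
# sampling of a two-level quincunx tree: I, Q, then the dyadic products
# 2I = Q1 %*% Q2 and 2Q. The shearing resampling matrices of the fully
# resampled directional filter bank are not applied; wedge alignment is
# approximate but reconstruction stays exact (complement construction).
.fanAtDepth <- function(bank, depth, synthesis = FALSE) {
  if (depth < 1L || depth > 4L)
    stop("directional depth must be between 1 and 4", call. = FALSE)
  pair <- if (synthesis) bank@fanSynthesis else bank@fanAnalysis
  if (depth %% 2L == 0L) pair <- lapply(pair, t)
  M <- switch(depth, diag(2), .QUINCUNX, 2 * diag(2), 2 * .QUINCUNX)
  lapply(pair, .kupsample, M = M)
}

# pyramid kernels at stage k: a-trous dilation by 2^(k-1)
.pyramidAtStage <- function(bank, stage, synthesis = FALSE) {
  pair <- if (synthesis) bank@pyramidSynthesis else bank@pyramidAnalysis
  lapply(pair, .kupsample, M = 2^(stage - 1L) * diag(2))
}
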