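# Central S4 containers. Images themselves are plain numeric matrices
# (rows = y, cols = x); the classes hold structured aggregates.

#' Decomposition specification for the NSCT
#'
#' Describes how many nonsubsampled pyramid stages to run and how many
#' directional subbands (a power of two) to extract from the high-pass band
#' of each stage.
#'
#' @slot levels Number of pyramid stages (positive integer).
#' @slot directionsPerLevel Integer vector of length `levels`; stage `k`
#'   yields `2^directionsPerLevel[k]` directional subbands. A value of 0
#'   keeps the stage's high-pass band undirected.
#' @export
setClass("DecompositionSpec",
  representation(levels = "integer", directionsPerLevel = "integer"),
  validity = function(object) {
    if (length(object@levels) != 1L || is.na(object@levels) || object@levels < 1L)
      return("'levels' must be a single positive integer")
    if (length(object@directionsPerLevel) != object@levels)
      return("length(directionsPerLevel) must equal levels")
    if (anyNA(object@directionsPerLevel) ||
        any(object@directionsPerLevel < 0L) || any(object@directionsPerLevel > 4L))
      return("each entry of directionsPerLevel must be in 0..4")
    TRUE
  })

#' Construct a DecompositionSpec
#'
#' @param levels Number of pyramid stages.
#' @param directionsPerLevel Directional depth per stage; stage `k` yields
#'   `2^directionsPerLevel[k]` subbands. Defaults to a 3-stage decomposition
#'   with 4, 4 and 8 directions.
#' @return A [DecompositionSpec-class] object.
#' @examples
#' decompositionSpec(2, c(2, 3))
#' @export
decompositionSpec <- function(levels = 3L, directionsPerLevel = c(2L, 2L, 3L)) {
  new("DecompositionSpec", levels = as.integer(levels),
      directionsPerLevel = as.integer(directionsPerLevel))
}

#' Two-channel filter bank for the NSCT
#'
#' Analysis/synthesis kernel pairs for the nonsubsampled pyramid and for the
#' fan (directional) split. Each pair is a list of two odd-sized numeric
#' matrices. Banks built by [buildFilterBank()] are verified to reconstruct
#' perfectly at build time.
#'
#' @slot name Preset identifier.
#' @slot pyramidAnalysis,pyramidSynthesis Low/high kernel pairs for the
#'   multiscale stage.
#' @slot fanAnalysis,fanSynthesis Kernel pairs for the directional stage.
#' @export
setClass("FilterBank",
  representation(name = "character",
                 pyramidAnalysis = "list", pyramidSynthesis = "list",
                 fanAnalysis = "list", fanSynthesis = "list"),
  validity = function(object) {
    ok <- function(p) is.list(p) && length(p) == 2L &&
      all(vapply(p, function(k) is.matrix(k) && is.numeric(k) &&
                   nrow(k) %% 2L == 1L && ncol(k) %% 2L == 1L, logical(1)))
    if (!ok(object@pyramidAnalysis)) return("pyramidAnalysis must be two odd-sized kernels")
    if (!ok(object@pyramidSynthesis)) return("pyramidSynthesis must be two odd-sized kernels")
    if (!ok(object@fanAnalysis)) return("fanAnalysis must be two odd-sized kernels")
    if (!ok(object@fanSynthesis)) return("fanSynthesis must be two odd-sized kernels")
    TRUE
  })

#' NSCT subband decomposition
#'
#' One low-pass band plus, per pyramid stage, a list of directional
#' high-pass bands. Every band has the same size as the source image (the
#' transform uses no down-sampling).
#'
#' @slot low Low-pass band (matrix).
#' @slot high List of length `levels`; element `k` is a list of
#'   `2^directionsPerLevel[k]` matrices.
#' @slot spec The [DecompositionSpec-class] used.
#' @slot sourceShape Integer `(rows, cols)` of the source image.
#' @slot boundary Boundary mode the forward transform used
#'   (`"symmetric"` or `"periodic"`); the inverse reuses it.
#' @export
setClass("SubbandDecomposition",
  representation(low = "matrix", high = "list", spec = "DecompositionSpec",
                 sourceShape = "integer", boundary = "character"),
  validity = function(object) {
    sh <- object@sourceShape
    if (length(sh) != 2L) return("sourceShape must be (rows, cols)")
    if (!identical(dim(object@low), sh)) return("low band shape != sourceShape")
    if (length(object@high) != object@spec@levels)
      return("high must have one entry per level")
    for (k in seq_along(object@high)) {
      bands <- object@high[[k]]
      if (length(bands) != 2L^object@spec@directionsPerLevel[k])
        return(sprintf("level %d must hold 2^d_k bands", k))
      for (b in bands) if (!identical(dim(b), sh))
        return("all high-pass bands must match sourceShape")
    }
    TRUE
  })

#' Simplified PCNN parameters
#'
#' Constants of the simplified pulse-coupled neural network. All decay and
#' normalizing constants are positive; the linking kernel's center entry is
#' zero (a neuron does not link to itself).
#'
#' @slot alphaL Linking decay constant per iteration.
#' @slot alphaTheta Threshold decay constant per iteration.
#' @slot VL Linking normalizing constant.
#' @slot Vtheta Threshold normalizing constant (post-fire kick).
#' @slot linkKernel 3x3 non-negative linking weights, zero center.
#' @slot nIter Iteration count.
#' @slot thetaInit Initial threshold.
#' @export
setClass("PCNNParams",
  representation(alphaL = "numeric", alphaTheta = "numeric", VL = "numeric",
                 Vtheta = "numeric", linkKernel = "matrix", nIter = "integer",
                 thetaInit = "numeric"),
  validity = function(object) {
    pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
    if (!pos(object@alphaL)) return("alphaL must be a single positive value")
    if (!pos(object@alphaTheta)) return("alphaTheta must be a single positive value")
    if (!pos(object@VL)) return("VL must be a single positive value")
    if (!pos(object@Vtheta)) return("Vtheta must be a single positive value")
    if (!pos(object@thetaInit)) return("thetaInit must be a single positive value")
    if (length(object@nIter) != 1L || object@nIter < 1L) return("nIter must be >= 1")
    k <- object@linkKernel
    if (!is.matrix(k) || any(dim(k) %% 2L == 0L)) return("linkKernel must be odd-sized")
    if (any(k < 0)) return("linkKernel must be non-negative")
    if (k[(nrow(k) + 1L) / 2L, (ncol(k) + 1L) / 2L] != 0)
      return("linkKernel center entry must be 0")
    TRUE
  })

#' Fusion pipeline configuration
#'
#' Bundles the decomposition spec, filter-bank preset, PCNN constants,
#' energy templates and feature choices of the fusion pipeline. Defaults
#' reproduce the package's reference configuration.
#'
#' @slot spec [DecompositionSpec-class].
#' @slot bankName Filter-bank preset name for [buildFilterBank()].
#' @slot pcnn [PCNNParams-class].
#' @slot lowTemplate,highTemplate 3x3 non-negative region-energy templates
#'   for the low-pass and high-pass bands.
#' @slot lowFeature,highFeature Feature map driving the PCNN in the low-
#'   (`"NSML"`) and high-pass (`"EOE"`) bands.
#' @slot boundary Boundary mode for all spatial operators (`"symmetric"`
#'   default; `"periodic"` makes the whole pipeline exactly shift-equivariant).
#' @export
setClass("FusionConfig",
  representation(spec = "DecompositionSpec", bankName = "character",
                 pcnn = "PCNNParams", lowTemplate = "matrix",
                 highTemplate = "matrix", lowFeature = "character",
                 highFeature = "character", boundary = "character"),
  validity = function(object) {
    tpl <- function(w) is.matrix(w) && all(dim(w) == c(3L, 3L)) &&
      all(w >= 0) && sum(w) > 0
    if (!tpl(object@lowTemplate)) return("lowTemplate must be 3x3, non-negative, positive sum")
    if (!tpl(object@highTemplate)) return("highTemplate must be 3x3, non-negative, positive sum")
    if (!identical(object@lowFeature, "NSML")) return("lowFeature must be 'NSML'")
    if (!identical(object@highFeature, "EOE")) return("highFeature must be 'EOE'")
    if (!object@boundary %in% c("symmetric", "periodic"))
      return("boundary must be 'symmetric' or 'periodic'")
    TRUE
  })

#' Result of the fusion pipeline
#'
#' @slot fused Fused image (matrix, source-sized).
#' @slot decompositionA,decompositionB,fusedDecomposition Retained
#'   [SubbandDecomposition-class] objects (or `NULL` when not kept).
#' @slot selectionMasks `list(low = <logical matrix>, high = <list of lists>)`;
#'   `TRUE` marks coefficients taken from source A.
#' @slot firingMapsA,firingMapsB PCNN firing-count maps per band, same
#'   structure as the masks.
#' @slot config The [FusionConfig-class] used.
#' @export
setClass("FusionResult",
  representation(fused = "matrix", decompositionA = "ANY",
                 decompositionB = "ANY", fusedDecomposition = "ANY",
                 selectionMasks = "list", firingMapsA = "list",
                 firingMapsB = "list", config = "FusionConfig"))

#' Seven-metric fusion quality report
#'
#' Scalar quality metrics for one (A, B, F) triple: average gradient of F,
#' Shannon entropy of F, mean joint entropy of F with each source, cross
#' entropy (mean relative entropy of the source histograms from F's),
#' image quality index, edge-dependent quality Q_E, and edge-information
#' preservation Q^AB/F.
#'
#' @slot ag,en,je,ce,iqi,qe,qabf Scalar metric values.
#' @export
setClass("MetricsReport",
  representation(ag = "numeric", en = "numeric", je = "numeric",
                 ce = "numeric", iqi = "numeric", qe = "numeric",
                 qabf = "numeric"))

#' Co-registered synthetic PET/CT phantom pair
#'
#' @slot ct CT-like image in `[0,1]`: sharp piecewise-constant anatomy with
#'   fine texture.
#' @slot pet PET-like image in `[0,1]`: smooth hotspots rendered at quarter
#'   resolution and bilinearly upsampled over a dim body mask.
#' @slot truth List with hotspot `centers` (n x 2, full-resolution row/col),
#'   `sigma` (full-resolution), `amplitude`, and the body-ellipse parameters.
#' @slot seed Integer seed that generated the pair.
#' @export
setClass("PhantomPair",
  representation(ct = "matrix", pet = "matrix", truth = "list", seed = "integer"),
  validity = function(object) {
    if (!identical(dim(object@ct), dim(object@pet)))
      return("ct and pet must have identical shape")
    rng <- range(object@ct, object@pet)
    if (rng[1] < 0 || rng[2] > 1) return("phantom intensities must lie in [0,1]")
    TRUE
  })

#' A grayscale image loaded from disk
#'
#' @slot pixels Image matrix rescaled to `[0,1]`.
#' @slot sourceDtype Storage type in the file (e.g. `"uint8"`, `"uint16"`,
#'   `"float"`).
#' @slot sourcePath Path the image was read from.
#' @slot format One of `"PNG"`, `"TIFF"`, `"NIfTI"`.
#' @slot sourceRange Original intensity range before rescaling, so outputs
#'   can be written back at source scale.
#' @export
setClass("LoadedImage",
  representation(pixels = "matrix", sourceDtype = "character",
                 sourcePath = "character", format = "character",
                 sourceRange = "numeric"))

## ---- show methods -------------------------------------------------------

setMethod("show", "DecompositionSpec", function(object) {
  cat(sprintf("DecompositionSpec: %d level(s), directions 2^{%s} = {%s}\n",
              object@levels,
              paste(object@directionsPerLevel, collapse = ","),
              paste(2L^object@directionsPerLevel, collapse = ",")))
})

setMethod("show", "FilterBank", function(object) {
  d <- function(k) paste(dim(k), collapse = "x")
  cat(sprintf("FilterBank '%s': pyramid %s/%s, fan %s/%s (analysis lo/hi)\n",
              object@name,
              d(object@pyramidAnalysis[[1]]), d(object@pyramidAnalysis[[2]]),
              d(object@fanAnalysis[[1]]), d(object@fanAnalysis[[2]])))
})

setMethod("show", "SubbandDecomposition", function(object) {
  nb <- 1L + sum(lengths(object@high))
  cat(sprintf("SubbandDecomposition: %dx%d source, %d level(s), %d band(s), boundary '%s'\n",
              object@sourceShape[1], object@sourceShape[2],
              object@spec@levels, nb, object@boundary))
})

setMethod("show", "PCNNParams", function(object) {
  cat(sprintf(paste0("PCNNParams: alphaL=%.5g alphaTheta=%.5g VL=%.5g ",
                     "Vtheta=%.5g thetaInit=%.5g nIter=%d\n"),
              object@alphaL, object@alphaTheta, object@VL, object@Vtheta,
              object@thetaInit, object@nIter))
})

setMethod("show", "FusionConfig", function(object) {
  cat("FusionConfig\n")
  cat(sprintf("  bank: %s, boundary: %s\n", object@bankName, object@boundary))
  show(object@spec)
  show(object@pcnn)
  cat(sprintf("  features: low=%s high=%s\n", object@lowFeature, object@highFeature))
})

setMethod("show", "FusionResult", function(object) {
  cat(sprintf("FusionResult: fused %dx%d image (bank '%s')\n",
              nrow(object@fused), ncol(object@fused), object@config@bankName))
})

setMethod("show", "MetricsReport", function(object) {
  v <- metricsValues(object)
  lab <- c("AG", "EN", "JE", "CE", "IQI", "Q_E", "Q_ABF")
  cat("MetricsReport\n")
  for (i in seq_along(v))
    cat(sprintf("  %-6s %10.5f\n", lab[i], v[i]))
})

setMethod("show", "PhantomPair", function(object) {
  cat(sprintf("PhantomPair: %dx%d, %d hotspot(s), seed %d\n",
              nrow(object@ct), ncol(object@ct),
              nrow(object@truth$centers), object@seed))
})

setMethod("show", "LoadedImage", function(object) {
  cat(sprintf("LoadedImage [%s, %s]: %dx%d from '%s'\n", object@format,
              object@sourceDtype, nrow(object@pixels), ncol(object@pixels),
              object@sourcePath))
})
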