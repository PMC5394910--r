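# Accessor generics for the S4 containers.

#' @rdname accessors
#' @export
setGeneric("lowBand", function(x) standardGeneric("lowBand"))

#' @rdname accessors
#' @export
setGeneric("highBands", function(x) standardGeneric("highBands"))

#' @rdname accessors
#' @export
setGeneric("bandCount", function(x) standardGeneric("bandCount"))

#' @rdname accessors
#' @export
setGeneric("sourceShape", function(x) standardGeneric("sourceShape"))

#' @rdname accessors
#' @export
setGeneric("fusedImage", function(x) standardGeneric("fusedImage"))

#' @rdname accessors
#' @export
setGeneric("selectionMasks", function(x) standardGeneric("selectionMasks"))

#' @rdname accessors
#' @export
setGeneric("firingMaps", function(x, which = c("A", "B")) standardGeneric("firingMaps"))

#' @rdname accessors
#' @export
setGeneric("ctImage", function(x) standardGeneric("ctImage"))

#' @rdname accessors
#' @export
setGeneric("petImage", function(x) standardGeneric("petImage"))

#' @rdname accessors
#' @export
setGeneric("phantomTruth", function(x) standardGeneric("phantomTruth"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("metricsValues", function(x) standardGeneric("metricsValues"))

#' Accessors for nsctfusion classes
#'
#' `lowBand()`/`highBands()` return the bands of a
#' [SubbandDecomposition-class]; `bandCount()` its total band count and
#' `sourceShape()` its source size. `fusedImage()`, `selectionMasks()` and
#' `firingMaps()` unpack a [FusionResult-class]. `ctImage()`, `petImage()`
#' and `phantomTruth()` unpack a [PhantomPair-class]. `pixels()` returns the
#' `[0,1]` matrix of a [LoadedImage-class]. `metricsValues()` returns the
#' seven metrics of a [MetricsReport-class] as a named numeric vector.
#'
#' @param x The object to access.
#' @param which For `firingMaps()`, which source's maps to return.
#' @name accessors
NULL

#' @rdname accessors
setMethod("lowBand", "SubbandDecomposition", function(x) x@low)

#' @rdname accessors
setMethod("highBands", "SubbandDecomposition", function(x) x@high)

#' @rdname accessors
setMethod("bandCount", "SubbandDecomposition",
          function(x) 1L + sum(lengths(x@high)))

#' @rdname accessors
setMethod("sourceShape", "SubbandDecomposition", function(x) x@sourceShape)

#' @rdname accessors
setMethod("fusedImage", "FusionResult", function(x) x@fused)

#' @rdname accessors
setMethod("selectionMasks", "FusionResult", function(x) x@selectionMasks)

#' @rdname accessors
setMethod("firingMaps", "FusionResult", function(x, which = c("A", "B")) {
  if (match.arg(which) == "A") x@firingMapsA else x@firingMapsB
})

#' @rdname accessors
setMethod("ctImage", "PhantomPair", function(x) x@ct)

#' @rdname accessors
setMethod("petImage", "PhantomPair", function(x) x@pet)

#' @rdname accessors
setMethod("phantomTruth", "PhantomPair", function(x) x@truth)

#' @rdname accessors
setMethod("pixels", "LoadedImage", function(x) x@pixels)

#' @rdname accessors
setMethod("metricsValues", "MetricsReport", function(x) {
  c(ag = x@ag, en = x@en, je = x@je, ce = x@ce,
    iqi = x@iqi, qe = x@qe, qabf = x@qabf)
})
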