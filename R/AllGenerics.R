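#' Accessors for sweep and morphology objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a SweepRecording, SweepSet, NeuronMorphology or PSPRecord
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sweepTime", function(x) standardGeneric("sweepTime"))
#' @rdname accessors
#' @export
setGeneric("sweepVoltage", function(x) standardGeneric("sweepVoltage"))
#' @rdname accessors
#' @export
setGeneric("stepAmplitude", function(x) standardGeneric("stepAmplitude"))
#' @rdname accessors
#' @export
setGeneric("stepWindow", function(x) standardGeneric("stepWindow"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("morphNodes", function(x) standardGeneric("morphNodes"))
#' @rdname accessors
#' @export
setGeneric("somaCenter", function(x) standardGeneric("somaCenter"))
#' @rdname accessors
#' @export
setGeneric("dendriteCoords", function(x, dims = 3) standardGeneric("dendriteCoords"))
#' @rdname accessors
#' @export
setGeneric("icSide", function(x) standardGeneric("icSide"))
#' @rdname accessors
#' @export
setGeneric("pspTrace", function(x) standardGeneric("pspTrace"))
#' @rdname accessors
#' @export
setGeneric("pspCondition", function(x) standardGeneric("pspCondition"))

#' @rdname accessors
#' @export
setMethod("sweepTime", "SweepRecording", function(x) x@time)
#' @rdname accessors
#' @export
setMethod("sweepVoltage", "SweepRecording", function(x) x@voltage)
#' @rdname accessors
#' @export
setMethod("stepAmplitude", "SweepRecording", function(x) x@stepAmplitude)
#' @rdname accessors
#' @export
setMethod("stepWindow", "SweepRecording",
          function(x) c(onset = x@stepOnset, offset = x@stepOffset))
#' @rdname accessors
#' @export
setMethod("samplingRate", "SweepRecording", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("stepAmplitude", "SweepSet",
          function(x) vapply(x@listData, stepAmplitude, numeric(1)))

#' @rdname accessors
#' @export
setMethod("morphNodes", "NeuronMorphology", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("somaCenter", "NeuronMorphology", function(x) {
  nd <- x@nodes[x@nodes$type == 1, , drop = FALSE]
  if (!nrow(nd)) stop("no soma node (type 1) in morphology")
  c(x = mean(nd$x), y = mean(nd$y), z = mean(nd$z))
})
#' @rdname accessors
#' @export
setMethod("dendriteCoords", "NeuronMorphology", function(x, dims = 3) {
  nd <- x@nodes[x@nodes$type == 3, , drop = FALSE]
  m <- as.matrix(nd[, c("x", "y", "z")[seq_len(dims)], drop = FALSE])
  rownames(m) <- NULL
  m
})
#' @rdname accessors
#' @export
setMethod("icSide", "NeuronMorphology", function(x) x@side)
#' @rdname accessors
#' @export
setMethod("pspTrace", "PSPRecord", function(x) x@trace)
#' @rdname accessors
#' @export
setMethod("pspCondition", "PSPRecord", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("sweepTime", "PSPRecord", function(x) x@time)
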