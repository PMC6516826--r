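#' @import methods
#' @importFrom S4Vectors SimpleList
NULL

#' SweepRecording: one current-clamp sweep
#'
#' Container for a single current-clamp sweep: a regularly sampled membrane
#' voltage trace (assumed already corrected for the liquid junction
#' potential), the amplitude of the command current step, and the step
#' timing. Time is in ms, voltage in mV, current in pA, sampling rate in kHz.
#'
#' @slot time numeric, strictly increasing time base (ms)
#' @slot voltage numeric, membrane potential (mV), same length as time
#' @slot stepAmplitude numeric(1), command step amplitude (pA)
#' @slot stepOnset numeric(1), step onset (ms)
#' @slot stepOffset numeric(1), step offset (ms)
#' @slot samplingRate numeric(1), sampling rate (kHz)
#'
#' @export
setClass("SweepRecording",
  slots = c(time = "numeric", voltage = "numeric",
            stepAmplitude = "numeric", stepOnset = "numeric",
            stepOffset = "numeric", samplingRate = "numeric"))

setValidity("SweepRecording", function(object) {
  msg <- character()
  if (length(object@time) != length(object@voltage))
    msg <- c(msg, "time and voltage must have the same length")
  if (length(object@time) > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(object@stepAmplitude) != 1 || !is.finite(object@stepAmplitude))
    msg <- c(msg, "stepAmplitude must be a single finite number")
  if (length(object@time) &&
      (object@stepOnset >= object@stepOffset ||
       object@stepOffset > object@time[length(object@time)] + 1e-9))
    msg <- c(msg, "need stepOnset < stepOffset <= end of trace")
  if (object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SweepRecording
#'
#' @param time time base in ms (strictly increasing)
#' @param voltage membrane potential in mV
#' @param stepAmplitude command current step amplitude in pA
#' @param stepOnset,stepOffset step timing in ms
#' @param samplingRate sampling rate in kHz; inferred from `time` if missing
#' @return a [SweepRecording-class] object
#' @examples
#' sw <- SweepRecording(time = seq(0, 100, by = 0.02),
#'                      voltage = rep(-70, 5001),
#'                      stepAmplitude = -50, stepOnset = 20, stepOffset = 80)
#' sw
#' @export
SweepRecording <- function(time, voltage, stepAmplitude, stepOnset, stepOffset,
                           samplingRate = NULL) {
  if (is.null(samplingRate))
    samplingRate <- 1 / stats::median(diff(time))
  new("SweepRecording", time = as.numeric(time), voltage = as.numeric(voltage),
      stepAmplitude = as.numeric(stepAmplitude),
      stepOnset = as.numeric(stepOnset), stepOffset = as.numeric(stepOffset),
      samplingRate = as.numeric(samplingRate))
}

setMethod("show", "SweepRecording", function(object) {
  cat("SweepRecording:", length(object@time), "samples @",
      format(object@samplingRate), "kHz\n")
  cat("  step:", object@stepAmplitude, "pA over [",
      object@stepOnset, ",", object@stepOffset, "] ms\n")
})

#' SweepSet: an ordered collection of sweeps from one neuron
#'
#' A `SimpleList` of [SweepRecording-class] objects, typically one step
#' family recorded from a single neuron.
#'
#' @export
setClass("SweepSet", contains = "SimpleList")

setValidity("SweepSet", function(object) {
  ok <- vapply(object@listData, is, logical(1), class2 = "SweepRecording")
  if (all(ok)) TRUE else "all elements must be SweepRecording objects"
})

#' Construct a SweepSet
#'
#' @param ... SweepRecording objects, or a single list of them
#' @return a [SweepSet-class]
#' @export
SweepSet <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is(args[[1]], "SweepRecording"))
    args <- args[[1]]
  new("SweepSet", SimpleList(args))
}

setMethod("show", "SweepSet", function(object) {
  amps <- vapply(object@listData, function(s) s@stepAmplitude, numeric(1))
  cat("SweepSet of", length(amps), "sweeps; step amplitudes (pA):",
      paste(format(amps, trim = TRUE), collapse = ", "), "\n")
})

#' NeuronMorphology: an SWC-style reconstruction
#'
#' Rooted-tree reconstruction of a neuron in SWC node form. Coordinates are
#' in µm in the package's coronal convention: x runs medial to lateral
#' (positive lateral), y dorsal to ventral (positive ventral), z along the
#' rostro-caudal axis. Structure types follow SWC: 1 = soma, 3 = dendrite.
#'
#' @slot nodes data.frame with columns id, type, x, y, z, radius, parent
#' @slot side "left" or "right" (hemisphere of the IC)
#' @slot subdivision one of "ICc", "ICd", "IClc" or NA
#'
#' @export
setClass("NeuronMorphology",
  slots = c(nodes = "data.frame", side = "character",
            subdivision = "character"))

setValidity("NeuronMorphology", function(object) {
  nd <- object@nodes
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  if (!all(is.finite(nd$x) & is.finite(nd$y) & is.finite(nd$z)))
    return("non-finite coordinates")
  known <- nd$parent == -1 | nd$parent %in% nd$id
  if (!all(known)) return("orphan nodes: parent ids not present")
  # acyclicity: walk each node up to a root, bounded by tree size
  idx <- match(nd$parent, nd$id)
  for (i in seq_len(nrow(nd))) {
    j <- i; steps <- 0
    while (!is.na(idx[j])) {
      j <- idx[j]; steps <- steps + 1
      if (steps > nrow(nd)) return("cyclic parent references")
    }
  }
  if (!object@side %in% c("left", "right", NA_character_))
    return("side must be 'left' or 'right'")
  TRUE
})

#' Construct a NeuronMorphology
#'
#' @param nodes data.frame with SWC columns id, type, x, y, z, radius, parent
#' @param side "left" or "right"
#' @param subdivision IC subdivision annotation ("ICc", "ICd", "IClc" or NA)
#' @return a [NeuronMorphology-class]
#' @export
NeuronMorphology <- function(nodes, side = NA_character_,
                             subdivision = NA_character_) {
  nodes <- as.data.frame(nodes)
  new("NeuronMorphology", nodes = nodes, side = as.character(side),
      subdivision = as.character(subdivision))
}

setMethod("show", "NeuronMorphology", function(object) {
  nd <- object@nodes
  cat("NeuronMorphology:", nrow(nd), "nodes (",
      sum(nd$type == 1), "soma,", sum(nd$type == 3), "dendrite ), side:",
      object@side, ", subdivision:", object@subdivision, "\n")
})

#' PSPRecord: an averaged evoked postsynaptic potential
#'
#' Averaged optogenetically- or electrically-evoked postsynaptic potential
#' from one cell under one pharmacological condition.
#'
#' @slot time numeric time base (ms)
#' @slot trace numeric averaged, baseline-subtracted membrane potential (mV)
#' @slot condition character(1), e.g. "control", "gabazine", "NBQX"
#' @slot stimOnset numeric(1) stimulus onset (ms)
#' @slot polarity "EPSP" or "IPSP"
#' @slot nSweeps integer(1) number of sweeps averaged
#'
#' @export
setClass("PSPRecord",
  slots = c(time = "numeric", trace = "numeric", condition = "character",
            stimOnset = "numeric", polarity = "character",
            nSweeps = "integer"))

setValidity("PSPRecord", function(object) {
  msg <- character()
  if (length(object@time) != length(object@trace))
    msg <- c(msg, "time and trace must have the same length")
  if (!object@polarity %in% c("EPSP", "IPSP"))
    msg <- c(msg, "polarity must be 'EPSP' or 'IPSP'")
  if (object@nSweeps < 1L || object@nSweeps > 1000L)
    msg <- c(msg, "nSweeps must be in [1, 1000]")
  if (length(msg)) msg else TRUE
})

#' Construct a PSPRecord
#'
#' @param time time base (ms)
#' @param trace averaged baseline-subtracted trace (mV)
#' @param condition pharmacological condition label
#' @param stimOnset stimulus onset (ms)
#' @param polarity "EPSP" or "IPSP"
#' @param nSweeps number of sweeps averaged
#' @return a [PSPRecord-class]
#' @export
PSPRecord <- function(time, trace, condition = "control", stimOnset = 0,
                      polarity = "EPSP", nSweeps = 1L) {
  new("PSPRecord", time = as.numeric(time), trace = as.numeric(trace),
      condition = as.character(condition), stimOnset = as.numeric(stimOnset),
      polarity = as.character(polarity), nSweeps = as.integer(nSweeps))
}

setMethod("show", "PSPRecord", function(object) {
  cat("PSPRecord (", object@polarity, ", ", object@condition, "): ",
      length(object@time), " samples, stim at ", object@stimOnset,
      " ms, n = ", object@nSweeps, " sweeps\n", sep = "")
})
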