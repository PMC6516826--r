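#' Classify the firing pattern of a neuron
#'
#' Applies the spike-frequency-adaptation (SFA) classification to a
#' depolarizing step family. The classification sweep is the suprathreshold
#' sweep whose spike count is closest to `targetSpikes` (default 10, ties
#' resolved to the lower current amplitude). Classes:
#'
#' * `single_spike` - every suprathreshold sweep fired exactly one spike;
#' * `transient` - at the classification sweep, the last spike precedes the
#'   step offset by more than half the step duration (firing stopped well
#'   before the end of the step);
#' * `sustained` - SFA < 2;
#' * `adapting` - SFA >= 2.
#'
#' @param sweeps a [SweepSet-class] or list of [SweepRecording-class]
#' @param targetSpikes target spike count for the classification sweep
#' @param thresholdSlope dV/dt spike-detection threshold (mV/ms)
#' @return list with `firingClass`, `sfa`, `stepAmplitude` (pA of the
#'   classification sweep), `nSpikes` and `spikeTimes`
#' @export
classifyFiring <- function(sweeps, targetSpikes = 10, thresholdSlope = 20) {
  sweeps <- as.list(sweeps)
  amps <- vapply(sweeps, stepAmplitude, numeric(1))
  dep <- which(amps > 0)
  spikes <- lapply(dep, function(i) detectSpikes(sweeps[[i]], thresholdSlope))
  counts <- lengths(spikes)
  supra <- counts >= 1
  if (!any(supra)) stop("not classifiable: no suprathreshold depolarizing sweep")
  if (all(counts[supra] == 1)) {
    i <- dep[supra][1]
    return(list(firingClass = "single_spike", sfa = NA_real_,
                stepAmplitude = amps[i], nSpikes = 1L,
                spikeTimes = spikes[[which(supra)[1]]]))
  }
  # closest-to-target rule, ties to the lower current
  cand <- which(supra)
  d <- abs(counts[cand] - targetSpikes)
  best <- cand[order(d, amps[dep][cand])][1]
  sw <- sweeps[[dep[best]]]
  st <- spikes[[best]]
  w <- stepWindow(sw); dur <- w[["offset"]] - w[["onset"]]
  if (w[["offset"]] - max(st) > 0.5 * dur) {
    cls <- "transient"; sfa <- if (length(st) >= 3) computeSFA(st) else NA_real_
  } else if (length(st) < 3) {
    cls <- "sustained"; sfa <- NA_real_
  } else {
    sfa <- computeSFA(st)
    cls <- if (sfa < 2) "sustained" else "adapting"
  }
  list(firingClass = cls, sfa = sfa, stepAmplitude = amps[dep[best]],
       nSpikes = counts[best], spikeTimes = st)
}

#' Full intrinsic-physiology profile of one neuron
#'
#' Convenience wrapper running the whole intrinsic analysis on one step
#' family: resting potential, peak/steady-state input resistance, membrane
#' time constant, sag ratios at -91 and -111 mV, rheobase, SFA and firing
#' class. Components that cannot be computed from the supplied family (for
#' example a missing -111 mV sweep) are returned as NA.
#'
#' @param sweeps a [SweepSet-class]: the step family of one neuron
#' @param tauSweeps optional second [SweepSet-class] of repeated small
#'   (1-3 mV) hyperpolarizing steps for the time-constant estimate; if NULL
#'   the qualifying sweeps of `sweeps` are used
#' @param sagTargets target peak potentials for the sag ratios (mV)
#' @param targetSpikes target spike count for firing classification
#' @param thresholdSlope dV/dt spike-detection threshold (mV/ms)
#' @return one-row data.frame with columns vRest, rPk, rSs, tauM, rheobase,
#'   sagRatio91, sagRatio111, sfa, firingClass, nSpikesClassification
#' @export
intrinsicProfile <- function(sweeps, tauSweeps = NULL,
                             sagTargets = c(-91, -111), targetSpikes = 10,
                             thresholdSlope = 20) {
  tryNA <- function(expr) tryCatch(suppressWarnings(expr),
                                   error = function(e) NA_real_)
  rin <- tryCatch(fitInputResistance(sweeps), error = function(e) NULL)
  cls <- tryCatch(classifyFiring(sweeps, targetSpikes, thresholdSlope),
                  error = function(e) NULL)
  data.frame(
    vRest = restingPotential(sweeps),
    rPk = if (is.null(rin)) NA_real_ else rin$rPk,
    rSs = if (is.null(rin)) NA_real_ else rin$rSs,
    tauM = tryNA(estimateTau(if (is.null(tauSweeps)) sweeps else tauSweeps)),
    rheobase = tryNA(rheobase(sweeps, thresholdSlope)),
    sagRatio91 = tryNA(sagRatio(sweeps, sagTargets[1])),
    sagRatio111 = tryNA(sagRatio(sweeps, sagTargets[2])),
    sfa = if (is.null(cls)) NA_real_ else cls$sfa,
    firingClass = if (is.null(cls)) NA_character_ else cls$firingClass,
    nSpikesClassification = if (is.null(cls)) NA_integer_ else as.integer(cls$nSpikes))
}
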