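#' Detect action potentials in a sweep
#'
#' Spikes are detected as upward crossings of a dV/dt threshold that are
#' followed within 2 ms by a positive-going voltage peak above -20 mV, with
#' a 1 ms refractory floor between accepted events. The slope criterion
#' (default 20 mV/ms) is far above passive charging slopes but well below
#' action-potential upstrokes.
#'
#' @param sweep a [SweepRecording-class]
#' @param thresholdSlope dV/dt threshold in mV/ms (default 20)
#' @return numeric vector of spike times (ms), possibly empty
#' @export
detectSpikes <- function(sweep, thresholdSlope = 20) {
  stopifnot(is(sweep, "SweepRecording"))
  if (samplingRate(sweep) < 5)
    stop("sampling rate below 5 kHz: too coarse for spike detection")
  v <- sweepVoltage(sweep); tt <- sweepTime(sweep)
  if (!all(is.finite(v))) stop("non-finite voltage trace")
  dvdt <- diff(v) / diff(tt)
  up <- dvdt >= thresholdSlope
  # anchor on action-potential peaks (>= -20 mV), then walk back to the
  # final sustained slope-threshold crossing; this keeps noise-induced
  # slope blips just before the upstroke from registering as spikes
  cand <- which(v >= -20)
  if (!length(cand)) return(numeric())
  grp <- cumsum(c(TRUE, diff(tt[cand]) > 1))  # events >= 1 ms apart
  win <- max(1L, round(2 * samplingRate(sweep)))  # 2 ms lookback
  times <- numeric()
  for (g in split(cand, grp)) {
    pk <- g[which.max(v[g])]
    lo <- max(1L, pk - win)
    seg <- lo:max(lo, pk - 1L)
    isOnset <- up[seg] & (seg == 1L | !up[pmax(seg - 1L, 1L)])
    onsets <- seg[isOnset]
    if (!length(onsets)) next
    ti <- tt[max(onsets)]
    if (length(times) && ti - times[length(times)] < 1) next
    times <- c(times, ti)
  }
  times
}

#' Spike-frequency adaptation ratio
#'
#' SFA = last interspike interval divided by the first, conventionally
#' evaluated at a depolarizing step eliciting about ten spikes. Requires at
#' least three spikes (two ISIs).
#'
#' @param spikeTimes spike times in ms (any monotone units)
#' @return SFA ratio (unitless), or NA_real_ with a warning if < 3 spikes
#' @examples
#' computeSFA(c(0, 5, 13, 25, 45))  # ISIs 5 ... 20 -> 4
#' @export
computeSFA <- function(spikeTimes) {
  if (length(spikeTimes) < 3) {
    warning("SFA undefined: fewer than 3 spikes")
    return(NA_real_)
  }
  isi <- diff(sort(spikeTimes))
  isi[length(isi)] / isi[1]
}
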