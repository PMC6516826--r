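# Passive-property extraction from hyperpolarizing step families.
# Conventions shared across these functions:
#  - V_rest = mean voltage over the 50 ms preceding step onset, averaged
#    across the sweeps supplied;
#  - peak deflection = most negative voltage during the step;
#  - steady state = mean of the last 10 ms of the step.

vRestOfSweep <- function(sweep, windowMs = 50) {
  tt <- sweepTime(sweep); w <- stepWindow(sweep)
  sel <- tt >= w[["onset"]] - windowMs & tt < w[["onset"]]
  if (!any(sel)) sel <- tt < w[["onset"]]
  mean(sweepVoltage(sweep)[sel])
}

stepMeasures <- function(sweep) {
  tt <- sweepTime(sweep); v <- sweepVoltage(sweep); w <- stepWindow(sweep)
  on <- tt >= w[["onset"]] & tt < w[["offset"]]
  ss <- tt >= w[["offset"]] - 10 & tt < w[["offset"]]
  rest <- vRestOfSweep(sweep)
  idx <- which(on)
  pkIdx <- idx[which.min(v[idx])]
  list(rest = rest, vPeak = v[pkIdx], tPeak = tt[pkIdx],
       vSs = mean(v[ss]),
       dPeak = v[pkIdx] - rest, dSs = mean(v[ss]) - rest,
       amp = stepAmplitude(sweep))
}

#' Resting membrane potential
#'
#' Mean voltage over the 50 ms preceding step onset, averaged across sweeps.
#'
#' @param sweeps a [SweepSet-class] or list of sweeps
#' @param windowMs baseline window before onset (ms)
#' @return resting potential (mV)
#' @export
restingPotential <- function(sweeps, windowMs = 50) {
  mean(vapply(as.list(sweeps), vRestOfSweep, numeric(1), windowMs = windowMs))
}

#' Peak and steady-state input resistance
#'
#' Fits least-squares lines to the peak and steady-state voltage deflections
#' versus injected current over hyperpolarizing sweeps whose peak deflection
#' lies between 0 and -15 mV relative to rest; sweeps hyperpolarizing past
#' -15 mV (or depolarizing) are excluded. Slopes in mV/pA are returned in
#' MΩ (1 mV/pA = 1000 MΩ).
#'
#' @param sweeps a [SweepSet-class] or list of [SweepRecording-class]
#' @return list with `rPk` and `rSs` (MΩ), `nQualifying`, and the per-sweep
#'   deflection table used for the fits
#' @export
fitInputResistance <- function(sweeps) {
  ms <- lapply(as.list(sweeps), stepMeasures)
  tab <- do.call(rbind, lapply(ms, function(m)
    data.frame(amp = m$amp, dPeak = m$dPeak, dSs = m$dSs)))
  qual <- tab$amp < 0 & tab$dPeak < 0 & tab$dPeak >= -15
  if (sum(qual) < 2)
    stop("insufficient data: need >= 2 hyperpolarizing sweeps with peak ",
         "deflection between 0 and -15 mV relative to rest")
  q <- tab[qual, ]
  rPk <- unname(stats::coef(stats::lm(dPeak ~ amp, data = q))["amp"]) * 1000
  rSs <- unname(stats::coef(stats::lm(dSs ~ amp, data = q))["amp"]) * 1000
  list(rPk = rPk, rSs = rSs, nQualifying = sum(qual), table = tab)
}

#' Membrane time constant
#'
#' Fits a single exponential to the onset of each small hyperpolarizing
#' response (from step onset to the time of peak deflection) and returns the
#' median time constant across sweeps. Only sweeps whose steady-state
#' deflection is between `deflectionRange[1]` and `deflectionRange[2]` mV
#' below rest are used (default 1-3 mV), mirroring the convention of
#' repeating a just-subthreshold small step many times.
#'
#' @param sweeps a [SweepSet-class] or list of sweeps
#' @param deflectionRange absolute steady-state deflection window (mV)
#' @return median membrane time constant (ms)
#' @export
estimateTau <- function(sweeps, deflectionRange = c(1, 3)) {
  sweeps <- as.list(sweeps)
  ms <- lapply(sweeps, stepMeasures)
  ok <- vapply(ms, function(m)
    m$amp < 0 && -m$dSs >= deflectionRange[1] && -m$dSs <= deflectionRange[2],
    logical(1))
  if (!any(ok)) stop("no qualifying small hyperpolarizing sweeps")
  fits <- vapply(which(ok), function(i) {
    sw <- sweeps[[i]]; m <- ms[[i]]
    tt <- sweepTime(sw); v <- sweepVoltage(sw); w <- stepWindow(sw)
    sel <- tt >= w[["onset"]] & tt <= m$tPeak
    fitExpOnset(tt[sel] - w[["onset"]], v[sel], m$rest)
  }, numeric(1))
  if (mean(is.na(fits)) > 0.5)
    stop("exponential fit failed on more than half of the sweeps")
  stats::median(fits, na.rm = TRUE)
}

# Single-exponential fit V(t) = rest + A (exp(-t/tau) - 1); returns tau or NA.
fitExpOnset <- function(t, v, rest) {
  d <- v - rest
  dEnd <- d[length(d)]
  if (abs(dEnd) < 1e-9) return(NA_real_)
  # start value: time to reach 63% of final deflection
  frac <- d / dEnd
  i63 <- which(frac >= 0.632)[1]
  tau0 <- if (is.na(i63) || t[i63] <= 0) max(t) / 3 else t[i63]
  fit <- tryCatch(suppressWarnings(
    stats::nls(d ~ A * (exp(-t / tau) - 1),
               start = list(A = -dEnd, tau = tau0),
               control = stats::nls.control(warnOnly = TRUE, maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  tau <- stats::coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) NA_real_ else tau
}

#' Voltage sag ratio at a target peak potential
#'
#' Selects the sweep whose peak hyperpolarized potential is closest to
#' `targetPeak` (within +/- `toleranceMv`, default 3 mV; no interpolation)
#' and returns (V_ss - V_rest) / (V_pk - V_rest). Values below 1 indicate
#' sag (I_h); 1 means none.
#'
#' @param sweeps a [SweepSet-class] or list of sweeps
#' @param targetPeak target peak potential (mV), e.g. -91 or -111
#' @param toleranceMv admissible distance from the target (mV)
#' @return sag ratio (unitless), or NA_real_ with a warning if no sweep
#'   peaks within tolerance
#' @export
sagRatio <- function(sweeps, targetPeak = -91, toleranceMv = 3) {
  ms <- lapply(as.list(sweeps), stepMeasures)
  hyp <- Filter(function(m) m$amp < 0, ms)
  if (!length(hyp)) {
    warning("no hyperpolarizing sweeps")
    return(NA_real_)
  }
  dist <- vapply(hyp, function(m) abs(m$vPeak - targetPeak), numeric(1))
  if (min(dist) > toleranceMv) {
    warning(sprintf("no sweep peaks within +/-%g mV of %g mV", toleranceMv,
                    targetPeak))
    return(NA_real_)
  }
  m <- hyp[[which.min(dist)]]
  (m$vSs - m$rest) / (m$vPeak - m$rest)
}

#' Rheobase
#'
#' Smallest command amplitude that evokes at least one spike, at the
#' resolution of the step protocol.
#'
#' @param sweeps a [SweepSet-class] or list of sweeps
#' @param thresholdSlope dV/dt spike-detection threshold (mV/ms)
#' @return rheobase (pA), or NA_real_ with a warning if no sweep spikes
#' @export
rheobase <- function(sweeps, thresholdSlope = 20) {
  sweeps <- as.list(sweeps)
  amps <- vapply(sweeps, stepAmplitude, numeric(1))
  dep <- order(amps)
  for (i in dep) {
    if (amps[i] <= 0) next
    if (length(detectSpikes(sweeps[[i]], thresholdSlope)) >= 1)
      return(amps[i])
  }
  warning("no suprathreshold sweep: rheobase undefined")
  NA_real_
}
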