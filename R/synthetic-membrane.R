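#' Membrane model configuration
#'
#' Parameters of the synthetic single-compartment neuron used to generate
#' current-clamp sweeps. The model is a leaky threshold-reset neuron with two
#' optional currents: a first-order sag current (I_h-like and
#' hyperpolarization-activated: it relaxes toward
#' `sagConductance * min(V - leakReversal, 0)` with time constant
#' `sagTimeConstant`, producing the depolarizing "sag" after the peak of a
#' hyperpolarizing step while remaining silent above rest)
#' and a spike-triggered adaptation current (incremented by
#' `adaptationIncrement` pA at every spike, decaying with
#' `adaptationTimeConstant`), which produces spike-frequency adaptation.
#'
#' Emergent passive properties: with no sag, the input resistance is
#' `1/leakConductance` (GΩ when conductance is in nS and deflections in
#' mV/pA) and the membrane time constant is `capacitance/leakConductance`.
#' With sag, peak resistance stays near `1/leakConductance` while the
#' steady-state resistance drops to `1/(leakConductance + sagConductance)`.
#'
#' @param capacitance membrane capacitance (pF), > 0
#' @param leakConductance leak conductance (nS), > 0
#' @param leakReversal leak reversal = resting potential (mV)
#' @param sagConductance sag conductance (nS), >= 0 (0 disables sag)
#' @param sagTimeConstant sag activation time constant (ms)
#' @param spikeThreshold spike threshold (mV)
#' @param resetPotential post-spike reset potential (mV)
#' @param adaptationIncrement adaptation current increment per spike (pA), >= 0
#' @param adaptationTimeConstant adaptation decay time constant (ms)
#' @param noiseSd additive Gaussian recording noise on the voltage trace (mV)
#' @param samplingRate sampling rate (kHz)
#' @return a list of class `MembraneConfig`
#' @examples
#' cfg <- membraneConfig(capacitance = 150, leakConductance = 5)
#' @export
membraneConfig <- function(capacitance = 150, leakConductance = 5,
                           leakReversal = -69.5,
                           sagConductance = 0, sagTimeConstant = 40,
                           spikeThreshold = -53, resetPotential = -62,
                           adaptationIncrement = 0,
                           adaptationTimeConstant = 120,
                           noiseSd = 0, samplingRate = 50) {
  cfg <- list(capacitance = capacitance, leakConductance = leakConductance,
              leakReversal = leakReversal, sagConductance = sagConductance,
              sagTimeConstant = sagTimeConstant,
              spikeThreshold = spikeThreshold,
              resetPotential = resetPotential,
              adaptationIncrement = adaptationIncrement,
              adaptationTimeConstant = adaptationTimeConstant,
              noiseSd = noiseSd, samplingRate = samplingRate)
  if (!all(vapply(cfg, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), logical(1))))
    stop("all membrane parameters must be single finite numbers")
  if (capacitance <= 0) stop("capacitance must be > 0")
  if (leakConductance <= 0) stop("leakConductance must be > 0")
  if (sagConductance < 0) stop("sagConductance must be >= 0")
  if (adaptationIncrement < 0) stop("adaptationIncrement must be >= 0")
  if (samplingRate <= 0) stop("samplingRate must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(cfg, class = "MembraneConfig")
}

#' Simulate a current-step protocol
#'
#' Generates one [SweepRecording-class] per command amplitude by integrating
#' the membrane model of [membraneConfig()] with fixed-step exponential
#' Euler at the configured sampling rate. Spikes are threshold-reset events
#' with a stylized action-potential waveform painted into the trace (1 ms
#' wide, peaking at +25 mV) so slope-based spike detection behaves as it
#' would on real recordings. Output is deterministic given `seed`.
#'
#' @param config a `MembraneConfig`
#' @param stepAmplitudes command step amplitudes (pA), one sweep each
#' @param stepDuration step duration (ms), default 100
#' @param seed integer seed for the recording noise (ignored if noiseSd = 0)
#' @param preMs,postMs baseline before / tail after the step (ms)
#' @return a [SweepSet-class]; each sweep carries attribute
#'   `"trueSpikeTimes"` with the simulator's internal reset times (ms)
#' @examples
#' cfg <- membraneConfig(capacitance = 150, leakConductance = 5)
#' sw <- simulateStepProtocol(cfg, c(-50, 100), seed = 1)
#' @export
simulateStepProtocol <- function(config, stepAmplitudes, stepDuration = 100,
                                 seed = 1, preMs = 100, postMs = 100) {
  stopifnot(inherits(config, "MembraneConfig"))
  if (!length(stepAmplitudes)) stop("stepAmplitudes must be non-empty")
  if (stepDuration <= 0) stop("stepDuration must be > 0")
  dt <- 1 / config$samplingRate
  n <- round((preMs + stepDuration + postMs) / dt) + 1L
  tvec <- (seq_len(n) - 1L) * dt
  onIdx <- tvec >= preMs & tvec < preMs + stepDuration
  up <- max(1L, round(0.2 / dt)); down <- max(1L, round(0.3 / dt))
  noise <- config$noiseSd > 0
  if (noise) {
    noiseMat <- local({
      set.seed(as.integer(seed))
      matrix(stats::rnorm(n * length(stepAmplitudes), 0, config$noiseSd),
             nrow = n)
    })
  }
  sweeps <- lapply(seq_along(stepAmplitudes), function(k) {
    amp <- stepAmplitudes[[k]]
    iinj <- numeric(n); iinj[onIdx] <- amp
    sim <- integrate_membrane_cpp(
      n = n, dt = dt, C = config$capacitance, gL = config$leakConductance,
      EL = config$leakReversal, gsag = config$sagConductance,
      tausag = config$sagTimeConstant, vth = config$spikeThreshold,
      vreset = config$resetPotential, vpeak = 25,
      aInc = config$adaptationIncrement, tauA = config$adaptationTimeConstant,
      iinj = iinj, upSamples = up, downSamples = down,
      v0 = config$leakReversal)
    v <- sim$voltage
    if (noise) v <- v + noiseMat[, k]
    sw <- SweepRecording(time = tvec, voltage = v, stepAmplitude = amp,
                         stepOnset = preMs, stepOffset = preMs + stepDuration,
                         samplingRate = config$samplingRate)
    attr(sw, "trueSpikeTimes") <- sim$spike_times
    sw
  })
  SweepSet(sweeps)
}

#' Closed-form subthreshold step response of the membrane model
#'
#' Analytic solution of the linear (subthreshold) two-current system - leak
#' plus first-order sag current - for a constant current step, evaluated on
#' a dense time grid. Used to derive the emergent ground-truth passive
#' properties of a configuration: the peak (most negative for
#' hyperpolarizing steps) and steady-state deflection per unit current.
#'
#' @param config a `MembraneConfig`
#' @param current step amplitude (pA)
#' @param durationMs step duration (ms)
#' @param dt evaluation grid step (ms)
#' @return list with `dPeak`, `dSs` (mV deflections), `tPeak` (ms),
#'   `rPk`, `rSs` (MΩ, deflection-per-current slopes), `sagRatio`
#'   (dSs/dPeak) and `trace` (data.frame of t and deflection u)
#' @export
subthresholdResponse <- function(config, current = -100, durationMs = 100,
                                 dt = 0.02) {
  C <- config$capacitance; gL <- config$leakConductance
  gs <- config$sagConductance; tw <- config$sagTimeConstant
  if (gs > 0 && current > 0)
    stop("closed form is valid for hyperpolarizing steps only ",
         "(the sag current is hyperpolarization-activated)")
  tt <- seq(0, durationMs, by = dt)
  if (gs <= 0) {
    u <- current / gL * (1 - exp(-tt * gL / C))
  } else {
    A <- matrix(c(-gL / C, gs / tw, -1 / C, -1 / tw), 2, 2)
    uStar <- current / (gL + gs)
    xStar <- c(uStar, gs * uStar)
    eg <- eigen(A)
    co <- solve(eg$vectors, as.complex(-xStar))  # x(0) = 0
    w <- as.complex(eg$vectors[1, ]) * co
    u <- Re(as.vector(w %*% exp(outer(as.complex(eg$values), tt)))) + uStar
  }
  iPk <- which.max(abs(u))
  ssSel <- tt >= durationMs - 10
  dSs <- mean(u[ssSel])
  list(dPeak = u[iPk], dSs = dSs, tPeak = tt[iPk],
       trace = data.frame(t = tt, u = u),
       rPk = 1000 * u[iPk] / current, rSs = 1000 * dSs / current,
       sagRatio = dSs / u[iPk])
}
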