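# Cohort-level simulators. These encode the study conditions for the VIP
# neuron population: per-neuron membrane parameters are drawn so that the
# emergent measured features reproduce the reported population statistics
# (peak input resistance 242.1 +/- 139.4 MOhm, steady-state resistance
# ~240 MOhm, membrane time constant 15.0 +/- 8.8 ms, sag ratio 0.87 +/-
# 0.16, rheobase ~68 pA, resting potential -69.5 +/- 4.4 mV, SFA ratio
# tightly clustered near 1.47 with ~90% of neurons below the sustained/
# adapting boundary of 2).

lognormFromMeanSd <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Population distribution of VIP-neuron membrane parameters
#'
#' Defaults reproduce the reported VIP population statistics (see the
#' methods vignette for the calibration). Adaptation increments are drawn
#' from a lognormal whose scale sets the population SFA distribution; a
#' small fraction of neurons receives strong, slowly decaying adaptation
#' and fires transiently.
#'
#' @param rPkMean,rPkSd peak input resistance (MΩ)
#' @param tauMean,tauSd membrane time constant (ms)
#' @param sagMean,sagSd sag ratio (steady-state over peak deflection)
#' @param vRestMean,vRestSd resting potential (mV)
#' @param thresholdMean,thresholdSd spike threshold above rest (mV)
#' @param adaptMeanlog,adaptSdlog lognormal of the adaptation increment,
#'   expressed as a fraction of the neuron's threshold current
#' @param transientFraction fraction of strongly adapting, transiently
#'   firing neurons
#' @param noiseSd recording noise (mV)
#' @return list of population parameters
#' @export
vipPopulation <- function(rPkMean = 242.1, rPkSd = 139.4,
                          tauMean = 15.0, tauSd = 8.8,
                          sagMean = 0.87, sagSd = 0.16,
                          vRestMean = -69.5, vRestSd = 4.4,
                          thresholdMean = 16, thresholdSd = 3,
                          adaptMeanlog = log(0.075), adaptSdlog = 0.6,
                          transientFraction = 0.013,
                          noiseSd = 0.2) {
  list(rPk = lognormFromMeanSd(rPkMean, rPkSd),
       tau = lognormFromMeanSd(tauMean, tauSd),
       sagMean = sagMean, sagSd = sagSd,
       vRestMean = vRestMean, vRestSd = vRestSd,
       thresholdMean = thresholdMean, thresholdSd = thresholdSd,
       adaptMeanlog = adaptMeanlog, adaptSdlog = adaptSdlog,
       transientFraction = transientFraction, noiseSd = noiseSd)
}

#' Draw one neuron's membrane configuration from the population
#'
#' @param pop a [vipPopulation()] list
#' @param sagRatioOverride optional target sag ratio for this neuron
#'   (used by the topography cohort, which imposes a location-dependent
#'   sag gradient)
#' @return list with `config` (a `MembraneConfig`) and `true` (the drawn
#'   ground-truth parameters)
#' @export
drawNeuron <- function(pop, sagRatioOverride = NULL) {
  rPk <- stats::rlnorm(1, pop$rPk$meanlog, pop$rPk$sdlog)
  rPk <- min(max(rPk, 40), 900)
  tau <- stats::rlnorm(1, pop$tau$meanlog, pop$tau$sdlog)
  tau <- min(max(tau, 4), 60)
  sag <- if (is.null(sagRatioOverride))
    rtruncnorm1(1, pop$sagMean, pop$sagSd, 0.45, 1) else
    min(max(sagRatioOverride, 0.45), 1)
  # calibrate conductances so the *measured* peak resistance and sag ratio
  # (closed-form two-current response, peak + last-10-ms steady state over a
  # 100 ms step) equal the drawn targets
  gL <- 1000 / rPk; sTrue <- sag
  for (it in 1:5) {
    gSag <- if (sTrue >= 0.999) 0 else gL * (1 / sTrue - 1)
    cfg0 <- membraneConfig(capacitance = tau * gL, leakConductance = gL,
                           sagConductance = gSag, sagTimeConstant = 40)
    resp <- subthresholdResponse(cfg0, current = -100, dt = 0.05)
    gL <- gL * resp$rPk / rPk
    sTrue <- min(0.999, max(0.2, sTrue * sag / resp$sagRatio))
  }
  gSag <- if (sTrue >= 0.999) 0 else gL * (1 / sTrue - 1)
  C <- tau * gL                         # pF
  # emergent ground truth of the final configuration (closed form)
  cfgF <- membraneConfig(capacitance = C, leakConductance = gL,
                         sagConductance = gSag, sagTimeConstant = 40)
  respF <- subthresholdResponse(cfgF, current = -100, dt = 0.05)
  # emergent time constant: the noise-free small-step onset fit over the
  # onset-to-peak window (the sag current makes this differ from C/gL)
  respT <- subthresholdResponse(cfgF, current = -2 * gL, dt = 0.02)
  selT <- respT$trace$t <= respT$tPeak
  tauEmergent <- fitExpOnset(respT$trace$t[selT], respT$trace$u[selT],
                             rest = 0)
  vRest <- stats::rnorm(1, pop$vRestMean, pop$vRestSd)
  dTh <- rtruncnorm1(1, pop$thresholdMean, pop$thresholdSd, 8, 28)
  transient <- stats::runif(1) < pop$transientFraction
  # adaptation increment drawn relative to the neuron's suprathreshold drive
  # margin at the ~10-spike step (threshold current iTh times the margin
  # factor for a 10 ms interspike interval), so the population SFA
  # distribution is not confounded by input resistance or time constant
  iTh <- dTh * 1000 / rPk
  mFac <- exp(-10 / tau) / (1 - exp(-10 / tau))
  aInc <- iTh * mFac * if (transient) stats::runif(1, 1.5, 2.5) else
    stats::rlnorm(1, pop$adaptMeanlog, pop$adaptSdlog)
  tauA <- if (transient) 400 else 120
  cfg <- membraneConfig(
    capacitance = C, leakConductance = gL, leakReversal = vRest,
    sagConductance = gSag, sagTimeConstant = 40,
    spikeThreshold = vRest + dTh, resetPotential = vRest,
    adaptationIncrement = aInc, adaptationTimeConstant = tauA,
    noiseSd = pop$noiseSd)
  list(config = cfg,
       true = list(rPk = respF$rPk, rSs = respF$rSs, tau = tauEmergent,
                   tauMembrane = tau,
                   sagRatio = respF$sagRatio, vRest = vRest,
                   thresholdAboveRest = dTh, adaptationIncrement = aInc,
                   transient = transient))
}

# Per-neuron adaptive step protocol, mirroring the convention of
# incrementing hyperpolarizing steps until the peak passes -110 mV and
# depolarizing steps spanning sub- to suprathreshold firing.
neuronProtocol <- function(true) {
  # hyperpolarizing: peaks targeted from small deflections to ~ -115 mV
  peakTargets <- c(-3, -6, -9, -12, seq(-16, -115 - true$vRest, by = -5))
  hyp <- peakTargets * (1000 / true$rPk)      # pA = mV * gPk(nS)
  # depolarizing: multiples of the predicted threshold current (peak-based)
  iTh <- true$thresholdAboveRest * 1000 / true$rPk
  dep <- iTh * c(0.9, 1.02, 1.15, 1.3, 1.5, 1.8, 2.2, 2.7, 3.3)
  c(hyp, dep)
}

#' Simulate a VIP-like neuron cohort and extract intrinsic profiles
#'
#' Draws `n` neurons from the population, simulates each neuron's step
#' family with per-neuron adaptive amplitudes, and runs the full intrinsic
#' analysis ([intrinsicProfile()]) on the simulated sweeps. The
#' time-constant protocol (repeated small steps) is only simulated when
#' `withTau` is TRUE because it dominates run time.
#'
#' @param n cohort size
#' @param seed integer seed
#' @param pop population parameters ([vipPopulation()])
#' @param withTau also simulate the repeated small-step protocol and
#'   estimate the membrane time constant
#' @param nTauSweeps repeats of the small step (study convention: 50)
#' @return data.frame: one row per neuron with the measured profile plus
#'   ground-truth columns (prefix `true`)
#' @export
simulateVIPCohort <- function(n = 237, seed = 1, pop = vipPopulation(),
                              withTau = FALSE, nTauSweeps = 50) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(as.integer(seed) + 7 * i)
    dn <- drawNeuron(pop)
    amps <- neuronProtocol(dn$true)
    sweeps <- simulateStepProtocol(dn$config, amps, stepDuration = 100,
                                   seed = as.integer(seed) + 7 * i + 1)
    tauSweeps <- NULL
    if (withTau) {
      smallAmp <- -2 * dn$config$leakConductance  # ~2 mV deflection
      tauSweeps <- simulateStepProtocol(dn$config,
                                        rep(smallAmp, nTauSweeps),
                                        stepDuration = 100,
                                        seed = as.integer(seed) + 7 * i + 2)
    }
    prof <- intrinsicProfile(sweeps, tauSweeps = tauSweeps)
    prof$id <- i
    prof$trueRPk <- dn$true$rPk
    prof$trueRSs <- dn$true$rSs
    prof$trueTau <- dn$true$tau
    prof$trueSagRatio <- dn$true$sagRatio
    prof$trueVRest <- dn$true$vRest
    prof$trueTransient <- dn$true$transient
    rows[[i]] <- prof
  }
  do.call(rbind, rows)
}

#' Simulate the topography cohort: sag ratio varying with ICc position
#'
#' Places `n` neurons at uniform positions in a standardized left-ICc
#' coronal frame and imposes a linear plane on the mean sag ratio along the
#' dorsolateral -> ventromedial diagonal (sag ratio higher, i.e. less sag,
#' ventromedially), with residual scatter chosen so the expected multiple
#' correlation of the plane fit matches `targetR`. Each neuron's sag ratio
#' is then measured from simulated sweeps, and the plane is fit to the
#' measured values.
#'
#' @param n neurons (study convention: 60)
#' @param seed integer seed
#' @param targetR expected multiple correlation of sag ratio vs position
#' @param sagMean,sagSd population mean and total SD of the sag ratio
#' @param pop population for the remaining parameters
#' @return list with `data` (ml, dv, sagRatio measured), `fit` (the
#'   [fitPlane()] row)
#' @export
simulateLocationCohort <- function(n = 60, seed = 1, targetR = 0.536,
                                   sagMean = 0.87, sagSd = 0.16,
                                   pop = vipPopulation()) {
  set.seed(as.integer(seed))
  ml <- stats::runif(n, 500, 1700)   # µm from midline
  dv <- stats::runif(n, 200, 1500)   # µm from dorsal edge
  # diagonal covariate, unit SD
  diag <- (-(ml - mean(ml)) + (dv - mean(dv)))
  diag <- diag / stats::sd(diag)
  sigSd <- sagSd * targetR
  resSd <- sagSd * sqrt(1 - targetR^2)
  target <- sagMean + sigSd * diag + stats::rnorm(n, 0, resSd)
  measured <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(as.integer(seed) + 13 * i)
    dn <- drawNeuron(pop, sagRatioOverride = target[i])
    peakV <- seq(-83, -105, by = -2.5)
    amps <- (peakV - dn$true$vRest) * (1000 / dn$true$rPk)
    sweeps <- simulateStepProtocol(dn$config, amps, stepDuration = 100,
                                   seed = as.integer(seed) + 13 * i + 1)
    measured[i] <- sagRatio(sweeps, targetPeak = -91)
  }
  ok <- is.finite(measured)
  fit <- fitPlane(ml[ok], dv[ok], measured[ok], parameterName = "sagRatio91")
  list(data = data.frame(ml = ml, dv = dv, sagRatio = measured), fit = fit)
}

#' Simulate the feedforward-inhibition experiment
#'
#' Five cells receive an EPSP plus a delayed IPSP of cell-specific strength
#' (fixed relative IPSP amplitudes spanning weak to strong inhibition, the
#' condition under which halfwidth reductions from ~20% to ~70% arise).
#' For each cell the control (EPSP + IPSP) and gabazine (EPSP only)
#' conditions are simulated, averaged, measured, and the halfwidth
#' reduction computed with the gabazine denominator.
#'
#' @param seed integer seed
#' @param ipspRatios IPSP/EPSP amplitude ratios, one cell each
#' @param epspAmplitude EPSP amplitude (mV)
#' @param nSweeps sweeps per condition
#' @param noiseSd per-sample noise (mV)
#' @return data.frame: one row per cell with halfwidths and reductions
#' @export
simulateFFIExperiment <- function(seed = 1,
                                  ipspRatios = c(0.33, 0.39, 0.47, 0.60, 0.83),
                                  epspAmplitude = 2.85, nSweeps = 25,
                                  noiseSd = 0.15) {
  rows <- lapply(seq_along(ipspRatios), function(i) {
    cfg <- pspConfig(epspAmplitude = epspAmplitude,
                     epspRiseTau = 4.4, epspDecayTau = 14.3,
                     ipspAmplitude = -epspAmplitude * ipspRatios[i],
                     ipspLatency = 2.5, ipspRiseTau = 4, ipspDecayTau = 35,
                     nSweeps = nSweeps, noiseSd = noiseSd,
                     conditions = c("control", "gabazine"))
    sw <- simulatePSPSweeps(cfg, seed = as.integer(seed) + 31 * i)
    ctl <- averageSweeps(sw$control, condition = "control")
    gbz <- averageSweeps(sw$gabazine, condition = "gabazine")
    red <- ffiHalfwidthReduction(ctl, gbz)
    data.frame(cell = i, ipspRatio = ipspRatios[i],
               halfwidthControl = red$halfwidthControl,
               halfwidthGabazine = red$halfwidthDisinhibited,
               reductionPct = red$reductionPct)
  })
  do.call(rbind, rows)
}
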