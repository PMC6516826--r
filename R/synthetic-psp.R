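#' PSP sweep-generator configuration
#'
#' Configuration of the synthetic evoked-PSP generator. Each sweep is
#' baseline + EPSP + (conditionally) a delayed IPSP + Gaussian noise. Both
#' components are differences of exponentials normalized to unit peak and
#' scaled to the configured amplitudes; the IPSP onset follows the EPSP
#' onset by `ipspLatency` ms (disynaptic feedforward latency, typically
#' 2-3 ms).
#'
#' Condition semantics: `control` contains both components; `gabazine`
#' removes the IPSP (GABA_A block); `strychnine` leaves both (no glycinergic
#' component is modeled); `AP5` leaves both (the synthetic EPSP has a single
#' AMPA-like component); `NBQX` removes the EPSP; `TTX` removes everything
#' evoked.
#'
#' @param epspAmplitude EPSP peak amplitude (mV, >= 0)
#' @param epspRiseTau,epspDecayTau EPSP kinetics (ms), rise < decay
#' @param ipspAmplitude IPSP peak amplitude (mV, <= 0; 0 disables)
#' @param ipspLatency IPSP onset delay after EPSP onset (ms)
#' @param ipspRiseTau,ipspDecayTau IPSP kinetics (ms), rise < decay
#' @param nSweeps sweeps per condition (typically 20-50)
#' @param noiseSd per-sample Gaussian noise SD (mV)
#' @param conditions character vector of conditions to simulate
#' @param samplingRate sampling rate (kHz)
#' @return list of class `PSPConfig`
#' @export
pspConfig <- function(epspAmplitude = 2.85, epspRiseTau = 4.4,
                      epspDecayTau = 14.3, ipspAmplitude = 0,
                      ipspLatency = 2.5, ipspRiseTau = 4, ipspDecayTau = 35,
                      nSweeps = 25, noiseSd = 0.25,
                      conditions = c("control", "gabazine"),
                      samplingRate = 50) {
  if (epspRiseTau >= epspDecayTau || ipspRiseTau >= ipspDecayTau)
    stop("rise tau must be smaller than decay tau")
  if (nSweeps < 1) stop("nSweeps must be >= 1")
  if (ipspAmplitude > 0) stop("ipspAmplitude must be <= 0")
  if (ipspLatency < 0) stop("ipspLatency must be >= 0")
  structure(list(epspAmplitude = epspAmplitude, epspRiseTau = epspRiseTau,
                 epspDecayTau = epspDecayTau, ipspAmplitude = ipspAmplitude,
                 ipspLatency = ipspLatency, ipspRiseTau = ipspRiseTau,
                 ipspDecayTau = ipspDecayTau, nSweeps = as.integer(nSweeps),
                 noiseSd = noiseSd, conditions = conditions,
                 samplingRate = samplingRate),
            class = "PSPConfig")
}

#' Unit-peak difference-of-exponentials kernel
#'
#' `exp(-t/decay) - exp(-t/rise)`, zero for t < 0, normalized so the peak
#' equals 1.
#'
#' @param t time since onset (ms)
#' @param riseTau,decayTau kinetics (ms), rise < decay
#' @return kernel values
#' @export
pspKernel <- function(t, riseTau, decayTau) {
  tPk <- log(decayTau / riseTau) * riseTau * decayTau / (decayTau - riseTau)
  pk <- exp(-tPk / decayTau) - exp(-tPk / riseTau)
  out <- ifelse(t < 0, 0, exp(-t / decayTau) - exp(-t / riseTau))
  out / pk
}

# Noise-free composite waveform for a condition.
pspWaveform <- function(config, t, stimOnset, condition) {
  w <- numeric(length(t))
  hasE <- !condition %in% c("NBQX", "TTX")
  hasI <- config$ipspAmplitude < 0 && !condition %in% c("gabazine", "TTX")
  if (hasE)
    w <- w + config$epspAmplitude *
      pspKernel(t - stimOnset, config$epspRiseTau, config$epspDecayTau)
  if (hasI)
    w <- w + config$ipspAmplitude *
      pspKernel(t - stimOnset - config$ipspLatency, config$ipspRiseTau,
                config$ipspDecayTau)
  w
}

#' Simulate evoked-PSP sweep sets
#'
#' Generates `nSweeps` noisy sweeps per condition around the noise-free
#' composite waveform (see [pspConfig()] for the condition semantics).
#'
#' @param config a `PSPConfig`
#' @param seed integer seed
#' @param stimOnset stimulus onset (ms)
#' @param durationMs sweep duration (ms)
#' @return named list (one element per condition) of matrices
#'   (time x sweep), with attributes `time` (ms) and `stimOnset`
#' @export
simulatePSPSweeps <- function(config, seed = 1, stimOnset = 100,
                              durationMs = 400) {
  stopifnot(inherits(config, "PSPConfig"))
  set.seed(as.integer(seed))
  dt <- 1 / config$samplingRate
  t <- seq(0, durationMs, by = dt)
  out <- lapply(config$conditions, function(cond) {
    clean <- pspWaveform(config, t, stimOnset, cond)
    m <- matrix(stats::rnorm(length(t) * config$nSweeps, 0, config$noiseSd),
                nrow = length(t)) + clean
    attr(m, "time") <- t
    attr(m, "stimOnset") <- stimOnset
    m
  })
  names(out) <- config$conditions
  out
}
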