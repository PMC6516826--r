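# Independent oracles, written without reference to the package internals.

# Fine-step forward-Euler integration of the membrane equations (leak +
# rectified first-order sag + spike-triggered adaptation, threshold-reset).
# `refine` divides the configured sampling interval. Voltage is held at the
# reset potential for `holdMs` after each spike, mirroring the stylized
# action-potential interval of the generator (valid for comparisons when
# resetPotential == leakReversal, where the painted waveform does not feed
# back into the sag current).
oracleIntegrate <- function(config, amp, stepDuration = 100, preMs = 100,
                            postMs = 100, refine = 10) {
  dtCoarse <- 1 / config$samplingRate
  holdMs <- (1 + round(0.2 / dtCoarse) + round(0.3 / dtCoarse)) * dtCoarse
  dt <- dtCoarse / refine
  total <- preMs + stepDuration + postMs
  n <- round(total / dt) + 1
  v <- config$leakReversal; Iw <- 0; Ia <- 0
  holdLeft <- 0
  spikes <- numeric()
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    if (holdLeft > 0) {
      holdLeft <- holdLeft - dt
      Iw <- Iw + dt * (config$sagConductance *
                         min(v - config$leakReversal, 0) - Iw) /
        config$sagTimeConstant
      Ia <- Ia - dt * Ia / config$adaptationTimeConstant
      next
    }
    iinj <- if (t >= preMs && t < preMs + stepDuration) amp else 0
    dv <- (-config$leakConductance * (v - config$leakReversal) - Iw - Ia +
             iinj) / config$capacitance
    v <- v + dt * dv
    Iw <- Iw + dt * (config$sagConductance *
                       min(v - config$leakReversal, 0) - Iw) /
      config$sagTimeConstant
    Ia <- Ia - dt * Ia / config$adaptationTimeConstant
    if (v >= config$spikeThreshold) {
      spikes <- c(spikes, t)
      Ia <- Ia + config$adaptationIncrement
      v <- config$resetPotential
      holdLeft <- holdMs
    }
  }
  spikes
}

# Subthreshold (hyperpolarizing) step response via a general-purpose ODE
# solver - independent of the package's eigen-decomposition closed form.
oracleSubthreshold <- function(config, current, durationMs = 100) {
  f <- function(t, y, parms) {
    u <- y[1]; Iw <- y[2]
    du <- (-config$leakConductance * u - Iw + current) / config$capacitance
    dw <- (config$sagConductance * min(u, 0) - Iw) / config$sagTimeConstant
    list(c(du, dw))
  }
  tt <- seq(0, durationMs, by = 0.02)
  sol <- deSolve::lsoda(c(0, 0), tt, f, NULL, rtol = 1e-10, atol = 1e-10)
  u <- sol[, 2]
  iPk <- which.max(abs(u))
  dSs <- mean(u[tt >= durationMs - 10])
  list(dPeak = u[iPk], dSs = dSs, sagRatio = dSs / u[iPk],
       rPk = 1000 * u[iPk] / current, rSs = 1000 * dSs / current)
}

# Brute-force PCA through the SVD of the centered coordinate matrix.
oraclePCA <- function(pts) {
  pts <- as.matrix(pts)
  centered <- sweep(pts, 2, colMeans(pts))
  sv <- svd(centered)
  values <- sv$d^2 / (nrow(pts) - 1)
  rot <- centered %*% sv$v
  extents <- apply(rot, 2, function(col) max(col) - min(col))
  list(vectors = sv$v, values = values, extents = extents)
}

# Dense-grid evaluation of PSP metrics on a closed-form waveform function.
oraclePSPMetrics <- function(waveFun, tMax = 300, dt = 5e-4) {
  t <- seq(0, tMax, by = dt)
  y <- waveFun(t)
  pk <- which.max(y)
  amp <- y[pk]
  firstAt <- function(level, idx) idx[which(y[idx] >= level)[1]]
  t10 <- t[firstAt(0.1 * amp, 1:pk)]
  t90 <- t[firstAt(0.9 * amp, 1:pk)]
  tHalfUp <- t[firstAt(0.5 * amp, 1:pk)]
  post <- pk:length(t)
  tHalfDown <- t[post[which(y[post] <= 0.5 * amp)[1]]]
  t20 <- t[post[which(y[post] <= 0.2 * amp)[1]]]
  sel <- t >= t[pk] & t <= t20 & y > 0
  lf <- stats::lm(log(y[sel]) ~ t[sel])
  list(amplitude = amp, rise1090 = t90 - t10,
       halfwidth = tHalfDown - tHalfUp,
       decayTau = unname(-1 / coef(lf)[2]))
}

# Exhaustive-enumeration two-sided rank-sum p-value (no ties assumed).
oracleRankSum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  allRanks <- seq_len(n1 + n2)
  wAll <- apply(combos, 2, function(idx) sum(allRanks[idx])) -
    n1 * (n1 + 1) / 2
  pLe <- mean(wAll <= wObs); pGe <- mean(wAll >= wObs)
  list(statistic = wObs, p = min(1, 2 * min(pLe, pGe)))
}

# Brute-force optical-disector filter: explicit per-point rule check.
oracleFrameCount <- function(points, x0, y0, s, zLo, zHi) {
  nTot <- 0; nLab <- 0; nDbl <- 0
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    inX <- p$x_um > x0 && p$x_um <= x0 + s
    inY <- p$y_um > y0 && p$y_um <= y0 + s
    inZ <- p$z_um > zLo && p$z_um <= zHi
    if (inX && inY && inZ) {
      if (p$marker == 1) nTot <- nTot + 1
      if (p$labeled == 1) nLab <- nLab + 1
      if (p$marker == 1 && p$labeled == 1) nDbl <- nDbl + 1
    }
  }
  c(nTotal = nTot, nLabeled = nLab, nDouble = nDbl)
}

# Build a sweep containing a flat baseline with stylized action potentials
# inserted at the requested times (for spike-detection and classification
# fixtures).
makeSpikeTrainSweep <- function(spikeTimes, stepAmplitude = 100,
                                stepOnset = 20, stepOffset = 120,
                                totalMs = 200, rate = 50, baseline = -70) {
  tt <- seq(0, totalMs, by = 1 / rate)
  v <- rep(baseline, length(tt))
  for (ts in spikeTimes) {
    upIdx <- tt >= ts & tt < ts + 0.3
    dnIdx <- tt >= ts + 0.3 & tt < ts + 0.6
    v[upIdx] <- baseline + (20 - baseline) * (tt[upIdx] - ts) / 0.3
    v[dnIdx] <- 20 + (baseline - 20) * (tt[dnIdx] - ts - 0.3) / 0.3
  }
  SweepRecording(time = tt, voltage = v, stepAmplitude = stepAmplitude,
                 stepOnset = stepOnset, stepOffset = stepOffset,
                 samplingRate = rate)
}

# Analytic single-exponential (RC) charging sweep toward a target
# deflection, for input-resistance and tau fixtures.
makeOhmicSweep <- function(amp, rMohm = 200, tauMs = 5, stepOnset = 50,
                           stepOffset = 150, totalMs = 250, rate = 50,
                           rest = -70, noiseSd = 0) {
  tt <- seq(0, totalMs, by = 1 / rate)
  dInf <- amp * rMohm / 1000
  v <- rep(rest, length(tt))
  on <- tt >= stepOnset & tt < stepOffset
  v[on] <- rest + dInf * (1 - exp(-(tt[on] - stepOnset) / tauMs))
  off <- tt >= stepOffset
  vEnd <- rest + dInf * (1 - exp(-(stepOffset - stepOnset) / tauMs))
  v[off] <- rest + (vEnd - rest) * exp(-(tt[off] - stepOffset) / tauMs)
  if (noiseSd > 0) v <- v + stats::rnorm(length(v), 0, noiseSd)
  SweepRecording(time = tt, voltage = v, stepAmplitude = amp,
                 stepOnset = stepOnset, stepOffset = stepOffset,
                 samplingRate = rate)
}

# Morphology whose dendrite nodes are exactly the supplied display-space
# coordinates (x lateral, yUp dorsal); converts to the package's
# internal y (dorsal -> ventral) convention.
makeMorphFromPoints <- function(xyDisplay, z = NULL, side = "left") {
  xyDisplay <- as.matrix(xyDisplay)
  n <- nrow(xyDisplay)
  if (is.null(z)) z <- rep(0, n)
  nodes <- data.frame(
    id = seq_len(n + 1), type = c(1, rep(3, n)),
    x = c(mean(xyDisplay[, 1]), xyDisplay[, 1]),
    y = c(-mean(xyDisplay[, 2]), -xyDisplay[, 2]),
    z = c(mean(z), z), radius = c(8, rep(1, n)),
    parent = c(-1, 1, seq_len(max(0, n - 1)) + 1))
  NeuronMorphology(nodes, side = side)
}
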