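test_that("spike detection handles flat traces, inserted spikes and noise", {
  flat <- makeSpikeTrainSweep(numeric())
  expect_identical(detectSpikes(flat), numeric())
  one <- makeSpikeTrainSweep(50)
  st <- detectSpikes(one)
  expect_length(st, 1)
  expect_lt(abs(st - 50), 0.2)
  # simulated adapting neuron with recording noise: detected count matches
  # the simulator's internal reset count
  cfg <- membraneConfig(capacitance = 75, leakConductance = 5,
                        leakReversal = -70, spikeThreshold = -54,
                        resetPotential = -70, adaptationIncrement = 25,
                        adaptationTimeConstant = 120, noiseSd = 0.25)
  sw <- simulateStepProtocol(cfg, 220, seed = 3)[[1]]
  expect_equal(length(detectSpikes(sw)), length(attr(sw, "trueSpikeTimes")))
  expect_error(detectSpikes(SweepRecording(seq(0, 10, 0.5), rep(-70, 21),
                                           0, 2, 8, samplingRate = 2)),
               "5 kHz")
})

test_that("SFA is last ISI over first and is invariant to time rescaling", {
  expect_equal(computeSFA(seq(0, 90, by = 10)), 1)
  expect_equal(computeSFA(cumsum(c(0, 5, 8, 12, 20))), 4)
  expect_warning(v <- computeSFA(c(1, 2)), "fewer than 3")
  expect_true(is.na(v))
  st <- cumsum(c(0, 4, 6, 9, 13))
  expect_equal(computeSFA(st * 3.7), computeSFA(st))
})

test_that("firing classification applies the SFA and transient rules", {
  # last/first ISI = 19.9/10 -> sustained; 20/10 -> adapting
  sust <- makeSpikeTrainSweep(30 + cumsum(c(0, 10, 12, 14, 16, 19.9)))
  adpt <- makeSpikeTrainSweep(30 + cumsum(c(0, 10, 12, 14, 16, 20.0)))
  clS <- classifyFiring(list(sust))
  clA <- classifyFiring(list(adpt))
  expect_equal(clS$firingClass, "sustained")
  expect_equal(clS$sfa, 1.99, tolerance = 0.02)
  expect_equal(clA$firingClass, "adapting")
  expect_gte(clA$sfa, 2)
  # firing stops at 15% of the step -> transient
  tr <- classifyFiring(list(makeSpikeTrainSweep(c(25, 30, 35))))
  expect_equal(tr$firingClass, "transient")
  # every suprathreshold sweep fires exactly once -> single_spike
  ss <- classifyFiring(list(makeSpikeTrainSweep(30, stepAmplitude = 100),
                            makeSpikeTrainSweep(25, stepAmplitude = 150)))
  expect_equal(ss$firingClass, "single_spike")
  expect_error(classifyFiring(list(makeSpikeTrainSweep(numeric()))),
               "not classifiable")
})

test_that("classification sweep is the one closest to 10 spikes, ties low", {
  mk <- function(n, amp) makeSpikeTrainSweep(30 + (seq_len(n) - 1) * 8,
                                             stepAmplitude = amp)
  cl <- classifyFiring(list(mk(4, 50), mk(8, 100), mk(12, 150)))
  expect_equal(cl$stepAmplitude, 100)  # 8 spikes beats 12 (tie -> lower amp)
  expect_equal(cl$nSpikes, 8L)
})

test_that("input resistance uses only sweeps peaking between 0 and -15 mV", {
  sweeps <- list(makeOhmicSweep(-25), makeOhmicSweep(-50),
                 makeOhmicSweep(-100))  # peaks -5, -10, -20 mV
  fit <- fitInputResistance(sweeps)
  expect_equal(fit$nQualifying, 2)
  expect_equal(fit$rPk, 200, tolerance = 1e-3)
  expect_equal(fit$rSs, 200, tolerance = 1e-3)
  expect_error(fitInputResistance(list(makeOhmicSweep(-100))),
               "insufficient")
})

test_that("resistances and sag ratio of a sag neuron match closed form", {
  cfg <- membraneConfig(capacitance = 100, leakConductance = 5,
                        leakReversal = -70, sagConductance = 2,
                        sagTimeConstant = 40, noiseSd = 0)
  # qualifying small steps plus one peaking near -91 mV
  # amplitude whose closed-form peak deflection is -21 mV (peak V = -91)
  big <- -21 / (subthresholdResponse(cfg, -100)$dPeak / -100)
  sw <- simulateStepProtocol(cfg, c(-20, -40, -60, big), seed = 1)
  fit <- fitInputResistance(sw)
  orc <- oracleSubthreshold(cfg, -40)
  expect_equal(fit$rPk, orc$rPk, tolerance = 0.01)
  expect_equal(fit$rSs, orc$rSs, tolerance = 0.01)
  expect_equal(sagRatio(sw, targetPeak = -91), orc$sagRatio,
               tolerance = 0.02)
  expect_warning(v <- sagRatio(sw, targetPeak = -111), "no sweep")
  expect_true(is.na(v))
})

test_that("membrane time constant is recovered from small steps", {
  cfg <- membraneConfig(capacitance = 150, leakConductance = 10,
                        leakReversal = -70, noiseSd = 0)   # tau = 15 ms
  sw <- simulateStepProtocol(cfg, rep(-20, 3), seed = 1)   # -2 mV steps
  expect_equal(estimateTau(sw), 15, tolerance = 0.1 / 15)
  cfgN <- membraneConfig(capacitance = 150, leakConductance = 10,
                         leakReversal = -70, noiseSd = 0.3)
  swN <- simulateStepProtocol(cfgN, rep(-20, 50), seed = 2)
  expect_equal(estimateTau(swN), 15, tolerance = 0.05)
})

test_that("rheobase is the smallest spiking amplitude within one increment", {
  cfg <- membraneConfig(capacitance = 75, leakConductance = 5,
                        leakReversal = -70, spikeThreshold = -54,
                        resetPotential = -70, noiseSd = 0)
  sw <- simulateStepProtocol(cfg, seq(0, 300, by = 25), seed = 1)
  rh <- rheobase(sw)
  expect_lte(abs(rh - 16 * 5), 25)  # analytic threshold: dTh * gL = 80 pA
  sub <- simulateStepProtocol(cfg, c(25, 50), seed = 1)
  expect_warning(v <- rheobase(sub), "no suprathreshold")
  expect_true(is.na(v))
})

test_that("cohort parameter recovery stays within tolerance", {
  coh <- simulateVIPCohort(n = 30, seed = 7, withTau = TRUE, nTauSweeps = 10)
  relErr <- function(est, truth) median(abs(est - truth) / truth,
                                        na.rm = TRUE)
  expect_lt(relErr(coh$rPk, coh$trueRPk), 0.05)
  expect_lt(relErr(coh$rSs, coh$trueRSs), 0.05)
  expect_lt(relErr(coh$tauM, coh$trueTau), 0.05)
  expect_lt(median(abs(coh$sagRatio91 - coh$trueSagRatio), na.rm = TRUE),
            0.03)
})

test_that("classification recovers a generated firing-pattern mixture", {
  lowPop <- vipPopulation(adaptMeanlog = log(0.04), adaptSdlog = 0.2,
                          transientFraction = 0)
  highPop <- vipPopulation(adaptMeanlog = log(0.45), adaptSdlog = 0.2,
                           transientFraction = 0)
  low <- simulateVIPCohort(n = 40, seed = 21, pop = lowPop)
  high <- simulateVIPCohort(n = 10, seed = 22, pop = highPop)
  cls <- c(low$firingClass, high$firingClass)
  pAdapting <- mean(cls == "adapting")
  # generating mixture is 20% high-adaptation; binomial 3 SD at n = 50
  expect_lt(abs(pAdapting - 0.2), 3 * sqrt(0.2 * 0.8 / 50) + 1e-9)
})
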