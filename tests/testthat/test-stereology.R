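test_that("labeled fractions of 0 and 1 give none / all labeled", {
  cfg0 <- fieldConfig(labeledFractionCaudal = 0, labeledFractionRostral = 0)
  expect_equal(sum(generateCellField(cfg0, seed = 1)$labeled), 0)
  cfg1 <- fieldConfig(labeledFractionCaudal = 1, labeledFractionRostral = 1)
  f1 <- generateCellField(cfg1, seed = 1)
  expect_equal(sum(f1$labeled), nrow(f1))
  expect_error(fieldConfig(labeledFractionCaudal = 1.2), "fractions")
  expect_error(fieldConfig(regionExtent = c(-1, 10, 10)), "positive")
})

test_that("labeled fraction per slab follows the linear gradient", {
  cfg <- fieldConfig(labeledFractionCaudal = 0.058,
                     labeledFractionRostral = 0.015)
  f <- generateCellField(cfg, seed = 8)
  edges <- seq(0, cfg$regionExtent[3], length.out = 7)
  for (k in seq_len(6)) {
    sel <- f$z_um > edges[k] & f$z_um <= edges[k + 1]
    n <- sum(sel)
    pExp <- expectedLabeledFraction(cfg, (edges[k] + edges[k + 1]) / 2)
    pObs <- mean(f$labeled[sel])
    expect_lt(abs(pObs - pExp), 3 * sqrt(pExp * (1 - pExp) / n) + 1e-12)
  }
})

test_that("grid sites are anchors of grid squares overlapping the region", {
  sq <- cbind(c(0, 740, 740, 0), c(0, 0, 740, 740))
  sites <- placeGrid(sq, spacing = 370, origin = c(0, 0))
  expect_equal(nrow(sites), 4)
  expect_setequal(paste(sites$x, sites$y),
                  paste(c(0, 370, 0, 370), c(0, 0, 370, 370)))
  tiny <- cbind(c(100, 110, 110, 100), c(100, 100, 110, 110))
  s2 <- placeGrid(tiny, spacing = 370, origin = c(150, 150))
  expect_true(nrow(s2) >= 0)  # may legitimately be empty
  expect_equal(nrow(placeGrid(sq[1:2, ], 370, seed = 1)), 0)
})

test_that("sampling inclusion probability is uniform across the region", {
  mask <- cbind(c(0, 1110, 1110, 0), c(0, 0, 1110, 1110))
  pts <- rbind(c(500, 500), c(650, 720), c(820, 400))
  nSeed <- 150
  hit <- matrix(FALSE, nSeed, nrow(pts))
  for (s in seq_len(nSeed)) {
    sites <- placeGrid(mask, spacing = 370, seed = s)
    for (j in seq_len(nrow(pts))) {
      hit[s, j] <- any(pts[j, 1] > sites$x & pts[j, 1] <= sites$x + 184 &
                       pts[j, 2] > sites$y & pts[j, 2] <= sites$y + 184)
    }
  }
  pExp <- (184 / 370)^2
  tol <- 3 * sqrt(pExp * (1 - pExp) / nSeed)
  for (j in seq_len(nrow(pts)))
    expect_lt(abs(mean(hit[, j]) - pExp), tol + 1e-12)
})

test_that("counting frame applies inclusion/exclusion borders and guards", {
  fr <- countingFrame(c(100, 100), frameSize = 184, zTop = 25, zBottom = 0,
                      guard = 5, countingDepth = 15)
  mkPt <- function(x, y, z) data.frame(x_um = x, y_um = y, z_um = z,
                                       labeled = 1L, marker = 1L)
  onLeft <- countInFrame(mkPt(100, 150, 12), fr)      # left border: out
  onRight <- countInFrame(mkPt(284, 150, 12), fr)     # right border: in
  onBottom <- countInFrame(mkPt(150, 100, 12), fr)    # bottom border: out
  onTop <- countInFrame(mkPt(150, 284, 12), fr)       # top border: in
  expect_equal(onLeft$nTotal, 0)
  expect_equal(onRight$nTotal, 1)
  expect_equal(onBottom$nTotal, 0)
  expect_equal(onTop$nTotal, 1)
  # 25 µm slice with 5 µm guards -> counting window is the central 15 µm
  inGuard <- countInFrame(mkPt(150, 150, 4), fr)
  inWindow <- countInFrame(mkPt(150, 150, 6), fr)
  expect_equal(inGuard$nTotal, 0)
  expect_equal(inWindow$nTotal, 1)
  expect_error(countingFrame(c(0, 0), zTop = 20, zBottom = 0, guard = 5,
                             countingDepth = 15), "too thin")
  expect_error(countingFrame(c(0, 0), guard = 1), "at least 2")
})

test_that("frame counts equal a brute-force point filter", {
  cfg <- fieldConfig(regionExtent = c(600, 600, 40), totalDensity = 4e5,
                     labeledFractionCaudal = 0.3,
                     labeledFractionRostral = 0.3)
  f <- generateCellField(cfg, seed = 4)
  fr <- countingFrame(c(120, 250), frameSize = 184, zTop = 32, zBottom = 7,
                      guard = 2, countingDepth = 15)
  got <- countInFrame(f, fr)
  zMid <- (32 + 7) / 2
  orc <- oracleFrameCount(f, 120, 250, 184, zMid - 7.5, zMid + 7.5)
  expect_equal(got$nTotal, unname(orc["nTotal"]))
  expect_equal(got$nLabeled, unname(orc["nLabeled"]))
  expect_equal(got$nDouble, unname(orc["nDouble"]))
})

test_that("fraction estimates report sample means, SEM and pooled counts", {
  one <- data.frame(nTotal = 793, nLabeled = 10, nDouble = 10,
                    x = 0, y = 0, region = NA, slicePlane = NA)
  est <- estimateFraction(one)
  expect_equal(round(est$pooledPct, 1), 1.3)
  all <- data.frame(nTotal = c(50, 80), nLabeled = c(50, 80),
                    nDouble = c(50, 80), x = 0, y = 0, region = NA,
                    slicePlane = NA)
  expect_equal(estimateFraction(all)$meanPct, 100)
  withZero <- rbind(one, within(one, nTotal <- 0))
  expect_warning(ez <- estimateFraction(withZero), "zero total")
  expect_equal(ez$nSamples, 1)
})

test_that("fractionator estimate is unbiased on a uniform field", {
  cfg <- fieldConfig(regionExtent = c(1110, 1110, 900),
                     totalDensity = 1.5e5,
                     labeledFractionCaudal = 0.035,
                     labeledFractionRostral = 0.035)
  ests <- vapply(1:12, function(s) {
    f <- generateCellField(cfg, seed = 100 + s)
    smp <- fractionatorSurvey(f, cfg, sectionZ = c(mid = 450), seed = s)
    estimateFraction(smp)$meanPct
  }, numeric(1))
  mc <- mean(ests)
  expect_lt(abs(mc - 3.5), 3 * stats::sd(ests) / sqrt(length(ests)))
})

test_that("every labeled cell is marker-positive and counted at most once", {
  cfg <- fieldConfig(regionExtent = c(1110, 1110, 900))
  f <- generateCellField(cfg, seed = 9)
  smp <- fractionatorSurvey(f, cfg, sectionZ = c(mid = 450), seed = 2)
  expect_true(all(smp$nDouble == smp$nLabeled))
  expect_true(all(smp$nDouble <= pmin(smp$nTotal, smp$nLabeled)))
  # non-overlapping frames: each cell is claimed by at most one frame
  claims <- rep(0, nrow(f))
  for (i in seq_len(nrow(smp))) {
    inF <- f$x_um > smp$x[i] & f$x_um <= smp$x[i] + 184 &
           f$y_um > smp$y[i] & f$y_um <= smp$y[i] + 184
    claims[inF] <- claims[inF] + 1
  }
  expect_lte(max(claims), 1)
})

test_that("one-way ANOVA across planes matches hand-computed arithmetic", {
  smp <- data.frame(nTotal = rep(100, 9),
                    nDouble = c(6, 5, 7, 4, 3, 5, 1, 2, 3),
                    nLabeled = 0, x = 0, y = 0, region = NA,
                    slicePlane = rep(c("caudal", "middle", "rostral"),
                                     each = 3))
  gt <- gradientTest(smp)
  pct <- 100 * smp$nDouble / smp$nTotal
  groups <- split(pct, smp$slicePlane)
  grand <- mean(pct)
  ssB <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssW <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  fHand <- (ssB / 2) / (ssW / 6)
  expect_equal(gt$anova$F, fHand, tolerance = 1e-12)
  expect_equal(gt$anova$df1, 2)
  expect_equal(gt$anova$df2, 6)
  flat <- within(smp, nDouble <- rep(c(3, 5, 4), 3))
  gtFlat <- gradientTest(flat)
  expect_lt(gtFlat$anova$F, 1e-20)
  expect_gt(gtFlat$anova$p, 0.99)
  expect_error(gradientTest(smp[c(1, 4), ]), "groups")
})

test_that("the caudal-rostral gradient is detected at study sample sizes", {
  # endpoints chosen so the sampled caudal/rostral sections carry labeled
  # fractions of ~5.8% and ~1.5%
  cfg <- fieldConfig(labeledFractionCaudal = 0.0672,
                     labeledFractionRostral = 0.0058)
  hits <- 0; nSeed <- 10
  for (s in seq_len(nSeed)) {
    f <- generateCellField(cfg, seed = 400 + s)
    smp <- fractionatorSurvey(f, cfg, seed = 40 + s)
    gt <- gradientTest(smp)
    pc <- gt$tukey$pAdj[grepl("caudal", gt$tukey$comparison) &
                        grepl("rostral", gt$tukey$comparison)]
    if (length(pc) && pc < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
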