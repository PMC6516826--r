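test_that("SWC round-trips and malformed files are reported with line", {
  swc <- tempfile(fileext = ".swc")
  writeLines(c("# minimal", "1 1 0 0 0 8 -1", "2 3 10 0 0 1 1",
               "3 3 20 0 0 1 2"), swc)
  m <- readSWC(swc)
  expect_equal(nrow(morphNodes(m)), 3)
  expect_equal(countPrimaryDendrites(m), 1)
  cfg <- arborConfig(nPrimaryDendrites = 4, pointsPerDendrite = 15)
  gen <- generateMorphology(cfg, seed = 3)
  out <- tempfile(fileext = ".swc")
  writeSWC(gen, out)
  back <- readSWC(out, side = "left")
  expect_equal(morphNodes(back)$x, morphNodes(gen)$x, tolerance = 1e-6)
  expect_equal(morphNodes(back)$parent, morphNodes(gen)$parent)
  bad <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 8 -1", "2 3 1 1 1 1 99"), bad)
  expect_error(readSWC(bad), "line 2")
})

test_that("right-side neurons are mirrored about the soma sagittal axis", {
  nodes <- data.frame(id = 1:2, type = c(1, 3), x = c(100, 150),
                      y = c(0, 10), z = 0, radius = c(8, 1),
                      parent = c(-1, 1))
  right <- NeuronMorphology(nodes, side = "right")
  m <- mirrorToLeft(right)
  expect_equal(morphNodes(m)$x, c(100, 50))  # reflected about soma x = 100
  expect_equal(icSide(m), "left")
  left <- NeuronMorphology(nodes, side = "left")
  expect_identical(morphNodes(mirrorToLeft(left)), morphNodes(left))
  # reflecting the already-mirrored neuron again is the identity
  expect_equal(morphNodes(mirrorToLeft(m)), morphNodes(m))
  expect_error(mirrorToLeft(NeuronMorphology(nodes)), "side unknown")
})

test_that("principal axes handle degenerate and rectangular fixtures", {
  onAxis <- cbind(seq(-50, 50, length.out = 100), 0)
  ax <- principalAxes(makeMorphFromPoints(onAxis), dims = 2)
  expect_true(ax$degenerate)
  expect_equal(abs(ax$vectors[, 1]), c(1, 0), tolerance = 1e-9)
  expect_equal(ax$extents[2], 0, tolerance = 1e-9)
  # axis-aligned 300 x 100 rectangle boundary
  xs <- seq(-150, 150, by = 10); ys <- seq(-50, 50, by = 10)
  rect <- rbind(cbind(xs, -50), cbind(xs, 50), cbind(-150, ys),
                cbind(150, ys))
  axR <- principalAxes(makeMorphFromPoints(rect), dims = 2)
  expect_equal(axR$extents[1], 300, tolerance = 1e-9)
  expect_equal(axR$extents[2], 100, tolerance = 1e-9)
  expect_equal(classifyShape(axR$extents)$ratio, 3)
  expect_equal(classifyShape(axR$extents)$shapeClass, "disc_shaped")
})

test_that("principal axes equal a brute-force SVD oracle on a random cloud", {
  set.seed(42)
  pts <- cbind(rnorm(400, 0, 120), rnorm(400, 0, 45), rnorm(400, 0, 20))
  m <- makeMorphFromPoints(pts[, 1:2], z = pts[, 3])
  ax <- principalAxes(m, dims = 3)
  orc <- oraclePCA(dendriteCoords(m, 3))
  expect_equal(ax$values, orc$values, tolerance = 1e-9)
  expect_equal(ax$extents, orc$extents, tolerance = 1e-9)
  for (j in 1:3)
    expect_equal(abs(sum(ax$vectors[, j] * orc$vectors[, j])), 1,
                 tolerance = 1e-9)
})

test_that("shape classification thresholds at a length-width ratio of 3", {
  expect_equal(classifyShape(c(2.99, 1))$shapeClass, "stellate")
  expect_equal(classifyShape(c(3.00, 1))$shapeClass, "disc_shaped")
  line <- classifyShape(c(100, 0))
  expect_equal(line$shapeClass, "disc_shaped")
  expect_true(is.infinite(line$ratio))
  # strongly elongated generator arbors classify disc-shaped across seeds
  cfg <- arborConfig(nPrimaryDendrites = 5, pointsPerDendrite = 200,
                     axisLengths = c(400, 100, 100))
  cls <- vapply(1:20, function(s)
    classifyShape(generateMorphology(cfg, seed = s))$shapeClass,
    character(1))
  expect_gte(mean(cls == "disc_shaped"), 0.95)
})

test_that("isotropic and anisotropic generator clouds give expected ratios", {
  iso <- generateMorphology(arborConfig(axisLengths = c(100, 100, 100),
                                        pointsPerDendrite = 300), seed = 1)
  expect_lt(classifyShape(iso)$ratio, 1.25)
  an <- generateMorphology(arborConfig(axisLengths = c(300, 100, 50),
                                       pointsPerDendrite = 100,
                                       nPrimaryDendrites = 5), seed = 2)
  orc <- oraclePCA(dendriteCoords(an, 3))
  expect_equal(classifyShape(an)$ratio, orc$extents[1] / orc$extents[2],
               tolerance = 1e-9)
  expect_equal(classifyShape(an)$ratio, 3, tolerance = 0.25)
  expect_equal(countPrimaryDendrites(an), 5)
})

test_that("orientation angle is CCW from the ML axis in the dorsal-up view", {
  horiz <- makeMorphFromPoints(cbind(seq(-100, 100, 5),
                                     0.01 * seq(-100, 100, 5)^2 / 100))
  expect_equal(orientationAngle(horiz)$angleDeg, 0, tolerance = 1)
  diag45 <- cbind(seq(-100, 100, 5), seq(-100, 100, 5) +
                    0.1 * sin(seq(-100, 100, 5)))
  o45 <- orientationAngle(makeMorphFromPoints(diag45))
  expect_equal(o45$angleDeg, 45, tolerance = 1)
  expect_true(o45$withinLamina)
  # rotated anisotropic cloud recovers the rotation angle
  set.seed(7)
  base <- cbind(rnorm(500, 0, 100), rnorm(500, 0, 25))
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- base %*% t(R)
  o30 <- orientationAngle(makeMorphFromPoints(rot))
  expect_equal(o30$angleDeg, 30, tolerance = 2)
  expect_true(o30$withinLamina)
})

test_that("laminar spread is the range perpendicular to the 45-degree plane", {
  inPlane <- makeMorphFromPoints(cbind(seq(0, 70.7, length.out = 50),
                                       seq(0, 70.7, length.out = 50)))
  expect_equal(laminarSpread(inPlane), 0, tolerance = 1e-9)
  s <- 100 / sqrt(2)
  perp <- makeMorphFromPoints(cbind(seq(0, -s, length.out = 50),
                                    seq(0, s, length.out = 50)))
  expect_equal(laminarSpread(perp), 100, tolerance = 1e-9)
  set.seed(5)
  cloud <- cbind(rnorm(200, 0, 80), rnorm(200, 0, 40))
  m <- makeMorphFromPoints(cloud)
  nrm <- c(sin(pi / 4), cos(pi / 4))
  proj <- dendriteCoords(m, 2) %*% nrm
  expect_equal(laminarSpread(m), max(proj) - min(proj), tolerance = 1e-9)
})

test_that("descriptors are rotation-equivariant and translation-invariant", {
  set.seed(11)
  base <- cbind(rnorm(300, 0, 90), rnorm(300, 0, 30))
  m0 <- makeMorphFromPoints(base)
  a0 <- orientationAngle(m0)$angleDeg
  r0 <- classifyShape(principalAxes(m0, 2)$extents[1:2] / 1)$ratio
  for (th in c(25, 80, 140)) {
    Rm <- matrix(c(cos(th * pi / 180), sin(th * pi / 180),
                   -sin(th * pi / 180), cos(th * pi / 180)), 2)
    mR <- makeMorphFromPoints(base %*% t(Rm))
    expect_equal(orientationAngle(mR)$angleDeg %% 180, (a0 + th) %% 180,
                 tolerance = 1e-6)
    ax <- principalAxes(mR, 2)
    expect_equal(ax$extents[1] / ax$extents[2],
                 principalAxes(m0, 2)$extents[1] /
                   principalAxes(m0, 2)$extents[2], tolerance = 1e-6)
  }
  mT <- makeMorphFromPoints(sweep(base, 2, c(-500, 321), "+"))
  expect_equal(orientationAngle(mT)$angleDeg, a0, tolerance = 1e-9)
  expect_equal(laminarSpread(mT), laminarSpread(m0), tolerance = 1e-9)
})

test_that("mirroring maps orientation to its supplement and keeps ratio", {
  set.seed(13)
  base <- cbind(rnorm(300, 500, 80), rnorm(300, 0, 30))
  th <- 35 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m <- makeMorphFromPoints(sweep(base %*% t(Rm), 2, c(800, 0), "+"),
                           side = "right")
  a <- orientationAngle(m)$angleDeg
  mm <- mirrorToLeft(m)
  expect_equal(orientationAngle(mm)$angleDeg, (180 - a) %% 180,
               tolerance = 1e-6)
  expect_equal(classifyShape(principalAxes(mm, 2)$extents[1:2])$ratio,
               classifyShape(principalAxes(m, 2)$extents[1:2])$ratio,
               tolerance = 1e-9)
  expect_equal(laminarSpread(mm, 45), laminarSpread(m, 135),
               tolerance = 1e-6)
})

test_that("a 39:3 ratio cohort reports 93% stellate", {
  ratios <- c(rep(1.8, 39), rep(4, 3))
  shapes <- vapply(ratios, function(r)
    classifyShape(c(r * 100, 100))$shapeClass, character(1))
  rep93 <- proportionReport(sum(shapes == "stellate"), length(shapes),
                            digits = 0)
  expect_equal(rep93$percent, 93)
})
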