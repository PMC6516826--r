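# Design-based stereology: systematic random sampling, optical-fractionator
# counting rules, and labeled-fraction estimation.

#' Place a systematic random sampling grid
#'
#' Overlays a square grid of the given spacing on a section, with the grid
#' origin drawn uniformly in [0, spacing)^2, and returns one site per grid
#' square that falls over the region: the square's anchor intersection (its
#' corner with the smallest x and y). Overlap between a grid square and the
#' region mask is assessed on a 5 x 5 lattice of probe points spanning the
#' square's interior.
#'
#' @param regionMask two-column matrix or data.frame of polygon vertices
#'   (µm), in order
#' @param spacing grid spacing (µm), default 370
#' @param seed integer seed for the random grid origin
#' @param origin optional explicit grid origin (length-2), overriding the
#'   random draw
#' @return data.frame of site origins (x, y), possibly empty
#' @export
placeGrid <- function(regionMask, spacing = 370, seed = 1, origin = NULL) {
  regionMask <- as.matrix(regionMask)
  if (nrow(regionMask) < 3) return(data.frame(x = numeric(), y = numeric()))
  if (spacing <= 0) stop("spacing must be > 0")
  if (is.null(origin)) {
    set.seed(as.integer(seed))
    origin <- stats::runif(2, 0, spacing)
  }
  rx <- range(regionMask[, 1]); ry <- range(regionMask[, 2])
  gx <- seq(origin[1] + spacing * (floor((rx[1] - origin[1]) / spacing) - 1),
            rx[2] + spacing, by = spacing)
  gy <- seq(origin[2] + spacing * (floor((ry[1] - origin[2]) / spacing) - 1),
            ry[2] + spacing, by = spacing)
  g <- expand.grid(x = gx, y = gy)
  probe <- seq(0.05, 0.95, length.out = 5) * spacing
  keep <- vapply(seq_len(nrow(g)), function(i) {
    px <- g$x[i] + probe
    py <- g$y[i] + probe
    pp <- expand.grid(px = px, py = py)
    any(pracma::inpolygon(pp$px, pp$py, regionMask[, 1], regionMask[, 2],
                          boundary = FALSE))
  }, logical(1))
  out <- g[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define a counting frame
#'
#' @param siteOrigin length-2 numeric, frame anchor (µm)
#' @param frameSize frame side length (µm), default 184
#' @param zTop,zBottom slice surfaces (µm, zTop > zBottom)
#' @param guard guard-zone thickness at each surface (µm, >= 2)
#' @param countingDepth thickness of the central counting window (µm)
#' @return list of class `CountingFrame`
#' @export
countingFrame <- function(siteOrigin, frameSize = 184, zTop = 25,
                          zBottom = 0, guard = 2, countingDepth = 15) {
  if (guard < 2) stop("guard zones must be at least 2 µm")
  if (zTop - zBottom < countingDepth + 2 * guard)
    stop("slice too thin: need zTop - zBottom >= countingDepth + 2*guard")
  structure(list(siteOrigin = siteOrigin, frameSize = frameSize,
                 zTop = zTop, zBottom = zBottom, guard = guard,
                 countingDepth = countingDepth),
            class = "CountingFrame")
}

#' Count cells in a counting frame (optical fractionator rules)
#'
#' Counts cells whose top (their z coordinate) lies inside the central
#' counting window (`countingDepth` µm centered between the guard zones)
#' and whose (x, y) obeys the unbiased-frame border rule: cells on the right
#' and top borders are counted, cells on the left and bottom borders are
#' not (inclusion region `x in (x0, x0 + size]`, `y in (y0, y0 + size]`).
#' Labeled and total-marker tallies are made independently; the double count
#' is their conjunction.
#'
#' @param points data.frame with x_um, y_um, z_um, labeled, marker columns
#'   ([generateCellField()] format)
#' @param frame a [countingFrame()]
#' @param region,slicePlane optional annotations carried into the output
#' @return one-row data.frame (a `StereoSample`): nTotal, nLabeled, nDouble,
#'   x, y, region, slicePlane
#' @export
countInFrame <- function(points, frame, region = NA_character_,
                         slicePlane = NA_character_) {
  stopifnot(inherits(frame, "CountingFrame"))
  x0 <- frame$siteOrigin[1]; y0 <- frame$siteOrigin[2]; s <- frame$frameSize
  zMid <- (frame$zTop + frame$zBottom) / 2
  zLo <- zMid - frame$countingDepth / 2
  zHi <- zMid + frame$countingDepth / 2
  if (zLo < frame$zBottom + frame$guard - 1e-9 ||
      zHi > frame$zTop - frame$guard + 1e-9)
    stop("counting window violates guard zones")
  inXY <- points$x_um > x0 & points$x_um <= x0 + s &
          points$y_um > y0 & points$y_um <= y0 + s
  inZ <- points$z_um > zLo & points$z_um <= zHi
  sel <- inXY & inZ
  nTotal <- sum(sel & points$marker == 1)
  nLabeled <- sum(sel & points$labeled == 1)
  nDouble <- sum(sel & points$marker == 1 & points$labeled == 1)
  data.frame(nTotal = nTotal, nLabeled = nLabeled, nDouble = nDouble,
             x = x0, y = y0, region = region, slicePlane = slicePlane)
}

#' Labeled-fraction estimate per group
#'
#' Per-sample percentage is `100 * nDouble / nTotal`; the group estimate is
#' the mean with SEM across samples (matching the convention of reporting
#' mean +/- SEM over systematic random samples) together with the pooled
#' counts. Samples with zero total are dropped with a warning.
#'
#' @param samples data.frame of `StereoSample` rows ([countInFrame()])
#' @param grouping optional factor/character vector (length nrow(samples));
#'   NULL pools everything into one group
#' @return data.frame with group, meanPct, semPct, nSamples, pooledLabeled,
#'   pooledTotal, pooledPct
#' @export
estimateFraction <- function(samples, grouping = NULL) {
  if (!nrow(samples)) stop("no samples")
  if (is.null(grouping)) grouping <- rep("all", nrow(samples))
  zero <- samples$nTotal == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero total count excluded")
    samples <- samples[!zero, , drop = FALSE]
    grouping <- grouping[!zero]
  }
  pct <- 100 * samples$nDouble / samples$nTotal
  out <- lapply(split(seq_len(nrow(samples)), grouping), function(idx) {
    p <- pct[idx]
    data.frame(meanPct = mean(p),
               semPct = if (length(p) > 1) stats::sd(p) / sqrt(length(p))
                        else NA_real_,
               nSamples = length(p),
               pooledLabeled = sum(samples$nDouble[idx]),
               pooledTotal = sum(samples$nTotal[idx]),
               pooledPct = 100 * sum(samples$nDouble[idx]) /
                 sum(samples$nTotal[idx]))
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}

#' Test a rostro-caudal gradient of labeled fractions
#'
#' One-way ANOVA across slice planes on the per-sample percentages, with
#' Tukey honest-significant-difference pairwise comparisons.
#'
#' @param samples data.frame of `StereoSample` rows with a `slicePlane`
#'   column (or supply `plane`)
#' @param plane optional explicit grouping vector
#' @return list with `anova` (data.frame: F, df1, df2, p) and `tukey`
#'   (data.frame of pairwise diff, lwr, upr, pAdj)
#' @export
gradientTest <- function(samples, plane = NULL) {
  if (is.null(plane)) plane <- samples$slicePlane
  keep <- samples$nTotal > 0
  samples <- samples[keep, , drop = FALSE]; plane <- plane[keep]
  pct <- 100 * samples$nDouble / samples$nTotal
  tab <- table(plane)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each")
  d <- data.frame(pct = pct, plane = factor(plane))
  fit <- stats::aov(pct ~ plane, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$plane
  list(anova = data.frame(F = an[1, "F value"], df1 = an[1, "Df"],
                          df2 = an[2, "Df"], p = an[1, "Pr(>F)"]),
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          pAdj = tk[, "p adj"], row.names = NULL))
}

#' Fractionator survey of a synthetic cell field
#'
#' End-to-end convenience: cuts sections perpendicular to the rostro-caudal
#' (z) axis at the requested positions, overlays a systematic random grid on
#' each section, applies the optical-fractionator counting rules at every
#' site, and returns the per-site samples.
#'
#' @param field data.frame from [generateCellField()]
#' @param config the `FieldConfig` used to build the field
#' @param sectionZ named numeric vector of section centers along z (µm);
#'   names become slicePlane labels
#' @param sectionThickness mounted section thickness (µm)
#' @param spacing grid spacing (µm)
#' @param frameSize counting-frame side (µm)
#' @param guard guard-zone thickness (µm)
#' @param countingDepth central counting depth (µm)
#' @param seed integer seed for grid placement
#' @return data.frame of `StereoSample` rows
#' @export
fractionatorSurvey <- function(field, config,
                               sectionZ = NULL, sectionThickness = 25,
                               spacing = 370, frameSize = 184, guard = 2,
                               countingDepth = 15, seed = 1) {
  ext <- config$regionExtent
  if (is.null(sectionZ))
    sectionZ <- c(caudal = 0.15, middle = 0.5, rostral = 0.85) * ext[3]
  mask <- cbind(c(0, ext[1], ext[1], 0), c(0, 0, ext[2], ext[2]))
  out <- list()
  for (k in seq_along(sectionZ)) {
    zc <- sectionZ[k]
    zBottom <- zc - sectionThickness / 2
    zTop <- zc + sectionThickness / 2
    sec <- field[field$z_um > zBottom & field$z_um <= zTop, , drop = FALSE]
    sites <- placeGrid(mask, spacing = spacing,
                       seed = as.integer(seed) + k)
    for (i in seq_len(nrow(sites))) {
      fr <- countingFrame(c(sites$x[i], sites$y[i]), frameSize = frameSize,
                          zTop = zTop, zBottom = zBottom, guard = guard,
                          countingDepth = countingDepth)
      out[[length(out) + 1]] <-
        countInFrame(sec, fr, slicePlane = names(sectionZ)[k])
    }
  }
  do.call(rbind, out)
}
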