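# Dendritic-arbor morphometry by principal component analysis.
#
# Coordinate convention (coronal view of the left IC): x runs medial ->
# lateral, y runs dorsal -> ventral (positive ventral). Orientation angles
# are reported counter-clockwise from the medial-lateral (horizontal) axis
# as seen in the standard anatomical view with dorsal up, i.e. the angle of
# the vector (vx, -vy), mapped to [0, 180). The 45-degree isofrequency
# lamina runs dorsolateral -> ventromedial in that view.

#' Principal axes of a dendritic arbor
#'
#' Eigen-decomposition of the covariance of the dendrite node coordinates
#' (soma nodes excluded, nodes unweighted). Axes are ordered by decreasing
#' eigenvalue; per-axis extents are the coordinate ranges (max - min) after
#' rotating the points into the eigenbasis. The sign of each eigenvector is
#' fixed by making its medial-lateral (x) component non-negative.
#'
#' @param m a [NeuronMorphology-class], or a numeric coordinate matrix
#' @param dims 2 (x, y: coronal-plane PCA) or 3 (x, y, z)
#' @return list with `vectors` (columns = axes), `values` (eigenvalues),
#'   `extents` (µm ranges along each axis) and `degenerate` (TRUE when the
#'   point set does not span `dims` dimensions)
#' @export
principalAxes <- function(m, dims = 3) {
  stopifnot(dims %in% c(2, 3))
  pts <- if (is(m, "NeuronMorphology")) dendriteCoords(m, dims) else
    as.matrix(m)[, seq_len(dims), drop = FALSE]
  minPts <- dims + 1
  degenerate <- FALSE
  if (nrow(pts) < minPts) degenerate <- TRUE
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  tol <- max(eg$values, 0) * 1e-12
  if (sum(eg$values > tol) < dims) degenerate <- TRUE
  vec <- eg$vectors
  for (j in seq_len(ncol(vec))) {
    if (vec[1, j] < 0) vec[, j] <- -vec[, j]
  }
  centered <- sweep(pts, 2, colMeans(pts))
  rot <- centered %*% vec
  extents <- apply(rot, 2, function(col) diff(range(col)))
  list(vectors = vec, values = eg$values, extents = extents,
       degenerate = degenerate)
}

#' Stellate versus disc-shaped classification
#'
#' Ratio of the first to second extent from 3D PCA of the dendritic arbor;
#' neurons with a length-to-width ratio < 3 are stellate, those with ratio
#' >= 3 are disc-shaped. A zero second extent (a perfect line) is classified
#' disc-shaped with an infinite ratio.
#'
#' @param extents per-axis extents in decreasing-eigenvalue order, or a
#'   [NeuronMorphology-class] (3D PCA is then computed internally)
#' @return list with `ratio` and `shapeClass`
#' @export
classifyShape <- function(extents) {
  if (is(extents, "NeuronMorphology"))
    extents <- principalAxes(extents, dims = 3)$extents
  if (length(extents) < 2 || extents[1] <= 0)
    stop("invalid extents: need first extent > 0")
  ratio <- if (extents[2] <= 0) Inf else extents[1] / extents[2]
  list(ratio = ratio,
       shapeClass = if (ratio < 3) "stellate" else "disc_shaped")
}

#' Orientation of the long axis in the coronal plane
#'
#' Angle of the first 2D principal direction, counter-clockwise from the
#' medial-lateral axis in the anatomical view (dorsal up), mapped to
#' [0, 180). Also reports whether the long axis lies within +/- 15 degrees
#' of the 45-degree laminar plane. Near-isotropic arbors (first two
#' eigenvalues equal within relative 1e-9) are flagged indeterminate and
#' return NA.
#'
#' @param axes output of [principalAxes()] with dims = 2, or a
#'   [NeuronMorphology-class]
#' @param laminaAngleDeg laminar-plane angle (degrees, default 45)
#' @param withinDeg half-width of the "laminar" band (degrees, default 15)
#' @return list with `angleDeg`, `withinLamina`, `indeterminate`
#' @export
orientationAngle <- function(axes, laminaAngleDeg = 45, withinDeg = 15) {
  if (is(axes, "NeuronMorphology")) axes <- principalAxes(axes, dims = 2)
  if (axes$degenerate)
    return(list(angleDeg = NA_real_, withinLamina = NA, indeterminate = TRUE))
  if (length(axes$values) >= 2 && axes$values[1] > 0 &&
      (axes$values[1] - axes$values[2]) / axes$values[1] < 1e-9)
    return(list(angleDeg = NA_real_, withinLamina = NA, indeterminate = TRUE))
  v <- axes$vectors[, 1]
  ang <- atan2(-v[2], v[1]) * 180 / pi  # y is dorsal->ventral; view dorsal-up
  ang <- ang %% 180
  dAng <- abs(ang - laminaAngleDeg)
  dAng <- min(dAng, 180 - dAng)
  list(angleDeg = ang, withinLamina = dAng <= withinDeg,
       indeterminate = FALSE)
}

#' Dendritic spread perpendicular to the laminar plane
#'
#' Range of the dendrite coordinates projected onto the unit normal of the
#' laminar line in the coronal plane. With the default 45-degree lamina this
#' measures how far the arbor extends across isofrequency laminae.
#'
#' @param m a [NeuronMorphology-class] or a 2-column coordinate matrix (x,
#'   y with y positive ventral)
#' @param laminaAngleDeg laminar-plane angle in the anatomical view
#'   (degrees CCW from the medial-lateral axis, default 45)
#' @return spread in µm
#' @export
laminarSpread <- function(m, laminaAngleDeg = 45) {
  pts <- if (is(m, "NeuronMorphology")) dendriteCoords(m, 2) else
    as.matrix(m)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2) stop("need at least 2 dendrite points")
  th <- laminaAngleDeg * pi / 180
  # lamina direction in internal coords (y positive ventral): (cos, -sin);
  # its normal: (sin, cos)
  nrm <- c(sin(th), cos(th))
  proj <- pts %*% nrm
  diff(range(proj))
}

#' Number of primary dendrites
#'
#' Counts dendritic stems whose parent is a soma node.
#'
#' @param m a [NeuronMorphology-class]
#' @return integer stem count
#' @export
countPrimaryDendrites <- function(m) {
  stopifnot(is(m, "NeuronMorphology"))
  nd <- morphNodes(m)
  somaIds <- nd$id[nd$type == 1]
  if (!length(somaIds)) stop("no soma node (type 1) in morphology")
  sum(nd$type == 3 & nd$parent %in% somaIds)
}

#' Morphometric profile of one neuron
#'
#' Runs the full arbor morphometry: 3D PCA extents and stellate/disc
#' classification, 2D orientation and laminar membership, laminar spread,
#' and primary dendrite count. Right-side neurons are mirrored into the
#' left IC first when the side is known.
#'
#' @param m a [NeuronMorphology-class]
#' @param laminaAngleDeg laminar-plane angle (degrees)
#' @param spiny optional spininess annotation (logical), passed through
#' @return one-row data.frame
#' @export
morphometricProfile <- function(m, laminaAngleDeg = 45, spiny = NA) {
  if (!is.na(icSide(m)) && icSide(m) == "right") m <- mirrorToLeft(m)
  ax3 <- principalAxes(m, dims = 3)
  shp <- classifyShape(ax3$extents)
  ori <- orientationAngle(m, laminaAngleDeg = laminaAngleDeg)
  data.frame(
    firstAxisLength = ax3$extents[1],
    secondAxisLength = ax3$extents[2],
    lengthWidthRatio = shp$ratio,
    shapeClass = shp$shapeClass,
    orientationDeg = ori$angleDeg,
    withinLamina = ori$withinLamina,
    laminarSpread = laminarSpread(m, laminaAngleDeg),
    nPrimaryDendrites = countPrimaryDendrites(m),
    spiny = spiny)
}
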