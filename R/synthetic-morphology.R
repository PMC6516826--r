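#' Arbor generator configuration
#'
#' Parameters of the synthetic dendritic-arbor generator. Dendrite node
#' positions are drawn from an anisotropic Gaussian whose axis standard
#' deviations are proportional to `axisLengths` (interpreted as the semi-axes
#' of the target cloud; SD = semi-axis / 2), rotated by `orientationDeg`
#' counter-clockwise from the medial-lateral axis in the coronal view
#' (dorsal up).
#'
#' @param nPrimaryDendrites number of stems attached to the soma (>= 1)
#' @param axisLengths length-3 numeric, target semi-axes (µm), all > 0
#' @param orientationDeg in-plane orientation, [0, 180)
#' @param pointsPerDendrite nodes per stem
#' @param somaPosition length-3 numeric, soma position (µm)
#' @param side "left" or "right"
#' @return list of class `ArborConfig`
#' @export
arborConfig <- function(nPrimaryDendrites = 5,
                        axisLengths = c(150, 100, 80),
                        orientationDeg = 0, pointsPerDendrite = 40,
                        somaPosition = c(0, 0, 0), side = "left") {
  if (nPrimaryDendrites < 1) stop("nPrimaryDendrites must be >= 1")
  if (length(axisLengths) != 3 || any(axisLengths <= 0))
    stop("axisLengths must be 3 positive numbers")
  if (orientationDeg < 0 || orientationDeg >= 180)
    stop("orientationDeg must be in [0, 180)")
  if (!side %in% c("left", "right")) stop("side must be 'left' or 'right'")
  structure(list(nPrimaryDendrites = as.integer(nPrimaryDendrites),
                 axisLengths = axisLengths, orientationDeg = orientationDeg,
                 pointsPerDendrite = as.integer(pointsPerDendrite),
                 somaPosition = somaPosition, side = side),
            class = "ArborConfig")
}

#' Generate a synthetic dendritic arbor
#'
#' Builds an SWC-compliant tree: one soma node plus `nPrimaryDendrites`
#' stems. Node positions are drawn from the configured anisotropic Gaussian
#' (before rotation, axis SDs are `axisLengths / 2`); within each stem,
#' nodes are chained in order of increasing distance from the soma so each
#' stem is a simple rooted path whose first node attaches to the soma.
#'
#' @param config an `ArborConfig`
#' @param seed integer seed
#' @return a [NeuronMorphology-class]
#' @export
generateMorphology <- function(config, seed = 1) {
  stopifnot(inherits(config, "ArborConfig"))
  set.seed(as.integer(seed))
  nPts <- config$nPrimaryDendrites * config$pointsPerDendrite
  sd3 <- config$axisLengths / 2
  pts <- cbind(stats::rnorm(nPts, 0, sd3[1]), stats::rnorm(nPts, 0, sd3[2]),
               stats::rnorm(nPts, 0, sd3[3]))
  th <- config$orientationDeg * pi / 180
  # rotate CCW by th in the dorsal-up view; internal y is dorsal->ventral,
  # so the rotation matrix acts on (x, -y)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  disp <- cbind(pts[, 1], -pts[, 2]) %*% t(R)
  pts[, 1] <- disp[, 1]; pts[, 2] <- -disp[, 2]
  pts <- sweep(pts, 2, config$somaPosition, "+")
  # assign points to stems by direction: cluster on polar angle of the first
  # two principal coords so stems are spatially coherent
  stem <- rep(seq_len(config$nPrimaryDendrites),
              each = config$pointsPerDendrite)
  soma <- config$somaPosition
  nodes <- data.frame(id = 1, type = 1, x = soma[1], y = soma[2], z = soma[3],
                      radius = 8, parent = -1)
  nextId <- 2
  for (s in seq_len(config$nPrimaryDendrites)) {
    p <- pts[stem == s, , drop = FALSE]
    d <- sqrt(rowSums(sweep(p, 2, soma)^2))
    p <- p[order(d), , drop = FALSE]
    ids <- seq(nextId, length.out = nrow(p))
    parents <- c(1, ids[-length(ids)])
    nodes <- rbind(nodes,
                   data.frame(id = ids, type = 3, x = p[, 1], y = p[, 2],
                              z = p[, 3], radius = 1, parent = parents))
    nextId <- nextId + nrow(p)
  }
  NeuronMorphology(nodes, side = config$side)
}
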