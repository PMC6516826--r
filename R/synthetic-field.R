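#' Labeled cell-field configuration
#'
#' Configuration of the synthetic 3D labeled point field used to validate
#' the stereology module. Cells form a homogeneous Poisson process in a box;
#' each cell is labeled independently with a probability interpolated
#' linearly along `gradientAxis` between the caudal and rostral labeled
#' fractions (caudal = coordinate 0).
#'
#' @param regionExtent length-3 numeric, box extent (µm): x, y in-section,
#'   z along the rostro-caudal axis
#' @param totalDensity total cell density (cells/mm^3)
#' @param labeledFractionCaudal labeled fraction at the caudal end, in [0, 1]
#' @param labeledFractionRostral labeled fraction at the rostral end, in [0, 1]
#' @param gradientAxis axis along which the labeled fraction varies
#' @return list of class `FieldConfig`
#' @export
fieldConfig <- function(regionExtent = c(1110, 1110, 1800),
                        totalDensity = 1.5e5,
                        labeledFractionCaudal = 0.058,
                        labeledFractionRostral = 0.015,
                        gradientAxis = c("z", "x", "y")) {
  gradientAxis <- match.arg(gradientAxis)
  if (any(regionExtent <= 0)) stop("regionExtent must be positive")
  if (totalDensity <= 0) stop("totalDensity must be > 0")
  fr <- c(labeledFractionCaudal, labeledFractionRostral)
  if (any(fr < 0 | fr > 1)) stop("labeled fractions must be in [0, 1]")
  structure(list(regionExtent = regionExtent, totalDensity = totalDensity,
                 labeledFractionCaudal = labeledFractionCaudal,
                 labeledFractionRostral = labeledFractionRostral,
                 gradientAxis = gradientAxis),
            class = "FieldConfig")
}

#' Generate a labeled 3D cell field
#'
#' Draws a Poisson number of cells uniformly in the configured box and
#' labels each cell with the position-dependent probability. Each cell's z
#' coordinate is treated as the top of the cell for optical-disector
#' counting.
#'
#' @param config a `FieldConfig`
#' @param seed integer seed
#' @return data.frame with columns x_um, y_um, z_um, labeled (0/1), marker
#'   (always 1: every cell carries the pan-neuronal marker)
#' @export
generateCellField <- function(config, seed = 1) {
  stopifnot(inherits(config, "FieldConfig"))
  set.seed(as.integer(seed))
  ext <- config$regionExtent
  volMm3 <- prod(ext) * 1e-9  # µm^3 -> mm^3
  n <- stats::rpois(1, config$totalDensity * volMm3)
  pts <- data.frame(x_um = stats::runif(n, 0, ext[1]),
                    y_um = stats::runif(n, 0, ext[2]),
                    z_um = stats::runif(n, 0, ext[3]))
  axisVal <- pts[[paste0(config$gradientAxis, "_um")]]
  axisLen <- ext[match(config$gradientAxis, c("x", "y", "z"))]
  p <- config$labeledFractionCaudal +
    (config$labeledFractionRostral - config$labeledFractionCaudal) *
    axisVal / axisLen
  pts$labeled <- as.integer(stats::runif(n) < p)
  pts$marker <- 1L
  pts
}

#' Expected labeled fraction along the gradient
#'
#' Analytic labeled probability at a given coordinate along the gradient
#' axis (linear interpolation between the caudal and rostral fractions).
#'
#' @param config a `FieldConfig`
#' @param at coordinate along the gradient axis (µm)
#' @return expected labeled fraction
#' @export
expectedLabeledFraction <- function(config, at) {
  axisLen <- config$regionExtent[match(config$gradientAxis,
                                       c("x", "y", "z"))]
  config$labeledFractionCaudal +
    (config$labeledFractionRostral - config$labeledFractionCaudal) *
    at / axisLen
}

#' Write / read a point field as TSV
#'
#' @param field data.frame from [generateCellField()]
#' @param path file path
#' @return `path` (write) or the field data.frame (read)
#' @export
writeCellField <- function(field, path) {
  utils::write.table(field, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeCellField
#' @export
readCellField <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
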