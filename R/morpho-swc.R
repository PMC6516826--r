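#' Read an SWC reconstruction
#'
#' Parses a standard SWC file (columns: id, type, x, y, z, radius, parent;
#' `#` comment lines allowed) into a [NeuronMorphology-class]. Malformed
#' rows, orphan parent references and cyclic parent chains are reported with
#' the offending line number.
#'
#' @param path path to an SWC file
#' @param side hemisphere annotation ("left"/"right"), optional
#' @param subdivision IC subdivision annotation, optional
#' @return a [NeuronMorphology-class]
#' @export
readSWC <- function(path, side = NA_character_, subdivision = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineNo <- which(keep)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop("malformed SWC row at line ", lineNo[bad[1]],
         ": expected 7 fields, got ", lengths(fields)[bad[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7,
              byrow = TRUE)
  nas <- which(apply(m, 1, function(r) any(is.na(r))))
  if (length(nas))
    stop("non-numeric SWC field at line ", lineNo[nas[1]])
  nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7])
  orphan <- which(!(nodes$parent == -1 | nodes$parent %in% nodes$id))
  if (length(orphan))
    stop("orphan node at line ", lineNo[orphan[1]], ": parent id ",
         nodes$parent[orphan[1]], " not present")
  NeuronMorphology(nodes, side = side, subdivision = subdivision)
}

#' Write an SWC reconstruction
#'
#' @param m a [NeuronMorphology-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSWC <- function(m, path) {
  stopifnot(is(m, "NeuronMorphology"))
  nd <- morphNodes(m)
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   as.integer(nd$id), as.integer(nd$type), nd$x, nd$y, nd$z,
                   nd$radius, as.integer(nd$parent))
  writeLines(c("# SWC generated by icneuro", lines), path)
  invisible(path)
}

#' Mirror a right-side reconstruction into the left IC
#'
#' Reconstructions from the right IC are reflected about the soma's sagittal
#' (dorsal-ventral) axis - the medial-lateral coordinate is negated about
#' the soma x - so that all neurons appear as if in the left IC.
#' Left-side neurons are returned unchanged.
#'
#' @param m a [NeuronMorphology-class] with a known side
#' @return a [NeuronMorphology-class] with side "left"
#' @export
mirrorToLeft <- function(m) {
  stopifnot(is(m, "NeuronMorphology"))
  if (is.na(icSide(m))) stop("side unknown: cannot mirror")
  if (icSide(m) == "left") return(m)
  nd <- morphNodes(m)
  sx <- somaCenter(m)[["x"]]
  nd$x <- 2 * sx - nd$x
  NeuronMorphology(nd, side = "left", subdivision = m@subdivision)
}
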