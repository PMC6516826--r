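# Topographic analysis: standardized IC coordinates and plane fits of
# intrinsic physiology versus position in the coronal plane.

#' Normalize coordinates of right-IC neurons
#'
#' Neurons recorded in the right IC are combined with left-IC neurons by
#' negating their medial-lateral coordinate; the operation is idempotent
#' (already-normalized rows are tagged and left alone).
#'
#' @param coords data.frame with columns `ml` (µm from midline), `dv`
#'   (µm from the dorsal edge) and `side` ("left"/"right")
#' @return the data.frame with `ml` sign-normalized and a `normalized`
#'   column set to TRUE
#' @export
normalizeSide <- function(coords) {
  need <- c("ml", "dv", "side")
  if (!all(need %in% names(coords)))
    stop("coords needs columns: ", paste(need, collapse = ", "))
  if (isTRUE(attr(coords, "sideNormalized"))) return(coords)
  if (any(!coords$side %in% c("left", "right")))
    stop("unknown side value(s)")
  coords$ml <- ifelse(coords$side == "right", -coords$ml, coords$ml)
  attr(coords, "sideNormalized") <- TRUE
  coords
}

#' Fit a plane to a physiological parameter versus IC position
#'
#' Least-squares fit of `value = a + b*ml + c*dv` using the
#' Levenberg-Marquardt algorithm (minpack.lm). Because the model is linear
#' the optimum coincides with the normal-equations solution; the LM route
#' mirrors the original analysis workflow. Fit quality is summarized by the
#' multiple correlation `r = cor(observed, fitted)` and the adjusted R^2
#' for two predictors, `1 - (1 - r^2)(n - 1)/(n - 3)`. The primary p-value
#' is the overall-regression F test; a legacy chi-squared tail probability
#' (`pchisq(RSS, n - 3, lower = FALSE)`, unit-variance weights) is also
#' reported for comparison with older workflows.
#'
#' @param ml,dv coordinates (µm); ml should already be side-normalized
#' @param value parameter values
#' @param parameterName label carried into the output
#' @return one-row data.frame: parameter, intercept, slopeMl, slopeDv, r,
#'   r2Adj, p, pLegacyChisq, n
#' @export
fitPlane <- function(ml, dv, value, parameterName = "parameter") {
  ok <- is.finite(ml) & is.finite(dv) & is.finite(value)
  ml <- ml[ok]; dv <- dv[ok]; value <- value[ok]
  n <- length(value)
  if (n < 4) stop("need at least 4 finite observations")
  if (stats::sd(ml) == 0 || stats::sd(dv) == 0 ||
      abs(stats::cor(ml, dv)) > 1 - 1e-12)
    stop("collinear predictors: plane is not identifiable")
  resFun <- function(p) value - (p[1] + p[2] * ml + p[3] * dv)
  start <- c(mean(value), 0, 0)
  lmFit <- minpack.lm::nls.lm(
    par = start, fn = resFun,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 500))
  cf <- lmFit$par
  fitted <- cf[1] + cf[2] * ml + cf[3] * dv
  r <- stats::cor(value, fitted)
  if (!is.finite(r)) r <- 0
  r <- max(r, 0)  # multiple correlation is non-negative
  r2adj <- adjustedR2(r, n, predictors = 2)
  ssr <- sum((fitted - mean(value))^2)
  sse <- sum((value - fitted)^2)
  Fstat <- (ssr / 2) / (sse / (n - 3))
  p <- stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)
  pLegacy <- stats::pchisq(sse, df = n - 3, lower.tail = FALSE)
  data.frame(parameter = parameterName, intercept = cf[1], slopeMl = cf[2],
             slopeDv = cf[3], r = r, r2Adj = r2adj, p = p,
             pLegacyChisq = pLegacy, n = n)
}

#' Adjusted R-squared from a multiple correlation
#'
#' `1 - (1 - r^2)(n - 1)/(n - 1 - k)` for `k` predictors (default 2, the
#' plane fit).
#'
#' @param r multiple correlation coefficient
#' @param n number of observations
#' @param predictors number of predictors k
#' @return adjusted R^2
#' @examples
#' adjustedR2(0.536, 60)  # ~0.262
#' @export
adjustedR2 <- function(r, n, predictors = 2) {
  1 - (1 - r^2) * (n - 1) / (n - 1 - predictors)
}

#' Summary table of topographic plane fits
#'
#' Combines plane fits into one table and reports, per parameter, the sign
#' of the gradient along the dorsolateral -> ventromedial diagonal (the
#' tonotopic axis): the projection of (slopeMl, slopeDv) on the 45-degree
#' direction `(cos45 along -ml toward medial, sin45 along +dv toward
#' ventral)`. A positive projection means values increase ventromedially
#' ("slower ventromedially" for time-like parameters).
#'
#' @param fits list of one-row data.frames from [fitPlane()], or a
#'   data.frame of stacked fits
#' @return data.frame with the fit columns plus `diagonalSlope` and
#'   `gradientDirection`
#' @export
tonotopyReport <- function(fits) {
  if (is.data.frame(fits)) fits <- split(fits, seq_len(nrow(fits)))
  if (!length(fits)) stop("need at least one fit")
  rows <- lapply(fits, function(f) {
    diag <- (-f$slopeMl + f$slopeDv) / sqrt(2)
    f$diagonalSlope <- diag
    f$gradientDirection <- if (diag > 0) "higher_ventromedial" else
      if (diag < 0) "higher_dorsolateral" else "flat"
    f
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plane fits for several parameters at once
#'
#' Fits [fitPlane()] for each named parameter column of a per-neuron table
#' and returns the combined [tonotopyReport()]. Empty or all-missing
#' parameter columns are omitted with a warning.
#'
#' @param coords data.frame with `ml`, `dv` and the parameter columns
#' @param parameters character vector of column names to fit
#' @return data.frame, one row per fitted parameter
#' @export
planeFitTable <- function(coords, parameters) {
  rows <- list()
  for (p in parameters) {
    v <- coords[[p]]
    if (is.null(v) || !any(is.finite(v))) {
      warning("parameter column '", p, "' empty or all missing; omitted")
      next
    }
    rows[[p]] <- fitPlane(coords$ml, coords$dv, v, parameterName = p)
  }
  if (!length(rows)) stop("no fittable parameter columns")
  tonotopyReport(rows)
}
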