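# Evoked-PSP analysis: sweep averaging, kinetic metrics, pharmacological
# condition comparisons, and feedforward-inhibition quantification.

#' Average PSP sweeps with baseline subtraction
#'
#' Pointwise mean across sweeps after subtracting each sweep's baseline
#' (mean over the `baselineMs` window preceding the stimulus).
#'
#' @param sweeps matrix (time x sweep) with attributes `time` and
#'   `stimOnset` ([simulatePSPSweeps()] format), or a plain matrix plus
#'   explicit `time`/`stimOnset`
#' @param time time base (ms); taken from attributes if NULL
#' @param stimOnset stimulus onset (ms); taken from attributes if NULL
#' @param baselineMs baseline window before the stimulus (ms)
#' @param condition,polarity annotations for the returned record
#' @return a [PSPRecord-class] with the averaged, baseline-subtracted trace
#' @export
averageSweeps <- function(sweeps, time = NULL, stimOnset = NULL,
                          baselineMs = 50, condition = "control",
                          polarity = "EPSP") {
  if (is.null(time)) time <- attr(sweeps, "time")
  if (is.null(stimOnset)) stimOnset <- attr(sweeps, "stimOnset")
  sweeps <- as.matrix(sweeps)
  if (!ncol(sweeps)) stop("no sweeps to average")
  if (is.null(time) || length(time) != nrow(sweeps))
    stop("time base missing or mismatched with sweep length")
  base <- time >= stimOnset - baselineMs & time < stimOnset
  if (!any(base)) base <- time < stimOnset
  centered <- sweep(sweeps, 2, colMeans(sweeps[base, , drop = FALSE]))
  PSPRecord(time = time, trace = rowMeans(centered), condition = condition,
            stimOnset = stimOnset, polarity = polarity,
            nSweeps = ncol(sweeps))
}

# Linear interpolation of the time at which y crosses `level` between
# samples i and i+1 scanning in the given index range.
crossTime <- function(t, y, level, idx, rising = TRUE) {
  for (k in idx) {
    y0 <- y[k]; y1 <- y[k + 1]
    hit <- if (rising) (y0 < level && y1 >= level) else
      (y0 >= level && y1 < level)
    if (hit) return(t[k] + (level - y0) / (y1 - y0) * (t[k + 1] - t[k]))
  }
  NA_real_
}

#' Kinetic metrics of an averaged PSP
#'
#' Computes, on a baseline-subtracted trace: amplitude (signed extremum
#' relative to the pre-stimulus baseline), 10-90% rise time, full width at
#' half amplitude (linear interpolation between samples), and the decay
#' time constant from a single-exponential fit from the peak to the
#' return-to-20%-of-amplitude point (the 20% cutoff avoids contamination by
#' delayed inhibitory components in mixed traces).
#'
#' @param x a [PSPRecord-class], or a numeric trace (then supply `time`,
#'   `stimOnset`, `polarity`)
#' @param time,stimOnset,polarity used when `x` is a plain trace
#' @param baselineMs baseline window before the stimulus (ms)
#' @return list with `amplitude` (mV), `rise1090` (ms), `halfwidth` (ms),
#'   `decayTau` (ms), `peakTime` (ms); all NA (with class "no_event") when
#'   the trace never crosses half amplitude
#' @export
pspMetrics <- function(x, time = NULL, stimOnset = NULL, polarity = "EPSP",
                       baselineMs = 50) {
  if (is(x, "PSPRecord")) {
    time <- sweepTime(x); stimOnset <- x@stimOnset; polarity <- x@polarity
    trace <- pspTrace(x)
  } else trace <- as.numeric(x)
  stopifnot(length(time) == length(trace))
  sgn <- if (polarity == "IPSP") -1 else 1
  y <- sgn * trace
  base <- time >= stimOnset - baselineMs & time < stimOnset
  if (!any(base)) base <- time < stimOnset
  y <- y - mean(y[base])
  win <- which(time >= stimOnset)
  if (!length(win)) stop("no samples after stimOnset")
  pkIdx <- win[which.max(y[win])]
  amp <- y[pkIdx]
  noEvent <- function() structure(list(amplitude = NA_real_,
                                       rise1090 = NA_real_,
                                       halfwidth = NA_real_,
                                       decayTau = NA_real_,
                                       peakTime = NA_real_),
                                  class = "no_event")
  if (!is.finite(amp) || amp <= 0) return(noEvent())
  up <- win[win <= pkIdx]; down <- seq(pkIdx, length(time) - 1)
  tHalfUp <- crossTime(time, y, amp / 2, head(up, -1), rising = TRUE)
  tHalfDown <- crossTime(time, y, amp / 2, down, rising = FALSE)
  if (is.na(tHalfUp) || is.na(tHalfDown)) return(noEvent())
  t10 <- crossTime(time, y, 0.1 * amp, head(up, -1), rising = TRUE)
  t90 <- crossTime(time, y, 0.9 * amp, head(up, -1), rising = TRUE)
  t20 <- crossTime(time, y, 0.2 * amp, down, rising = FALSE)
  if (is.na(t20)) t20 <- time[length(time)]
  dSel <- time >= time[pkIdx] & time <= t20
  decayTau <- fitDecayTau(time[dSel] - time[pkIdx], y[dSel])
  list(amplitude = sgn * amp, rise1090 = t90 - t10,
       halfwidth = tHalfDown - tHalfUp, decayTau = decayTau,
       peakTime = time[pkIdx])
}

# Single-exponential decay fit y = A exp(-t/tau); log-linear start, nls refine.
fitDecayTau <- function(t, y) {
  pos <- y > 0
  if (sum(pos) < 3) return(NA_real_)
  lf <- stats::lm(log(y[pos]) ~ t[pos])
  tau0 <- -1 / stats::coef(lf)[2]
  if (!is.finite(tau0) || tau0 <= 0) return(NA_real_)
  fit <- tryCatch(suppressWarnings(
    stats::nls(y ~ A * exp(-t / tau),
               start = list(A = max(y), tau = tau0),
               control = stats::nls.control(warnOnly = TRUE, maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(unname(tau0))
  tau <- stats::coef(fit)[["tau"]]
  if (is.finite(tau) && tau > 0) tau else unname(tau0)
}

#' Compare PSP metrics across pharmacological conditions
#'
#' Paired comparison of one metric across conditions within cells. With two
#' conditions a paired two-tailed t-test is run; with three or more, a
#' repeated-measures ANOVA (cell as block: `aov(value ~ cell + condition)`)
#' with Tukey HSD post-hoc comparisons. A Bonferroni-corrected critical p
#' (default 0.0125) is attached for workflows testing four metrics.
#'
#' @param values data.frame with columns `cell`, `condition`, `value`;
#'   every cell must have every condition (paired design)
#' @param metricName label
#' @param bonferroniCriticalP critical p after Bonferroni correction
#' @return list with `test` ("paired_t" or "rm_anova_tukey"), `statistic`,
#'   `p`, `pairwise` (Tukey table or NULL), `significant` (p < critical p),
#'   `metric`
#' @export
compareConditions <- function(values, metricName = "metric",
                              bonferroniCriticalP = 0.0125) {
  need <- c("cell", "condition", "value")
  if (!all(need %in% names(values)))
    stop("values needs columns: ", paste(need, collapse = ", "))
  tab <- table(values$cell, values$condition)
  if (any(tab != 1)) stop("unpaired data: every cell needs every condition")
  conds <- unique(values$condition)
  if (length(conds) < 2) stop("need at least 2 conditions")
  if (nrow(tab) < 3) stop("need at least 3 cells")
  if (length(conds) == 2) {
    wide <- split(values, values$condition)
    a <- wide[[conds[1]]]; b <- wide[[conds[2]]]
    a <- a[order(a$cell), ]; b <- b[order(b$cell), ]
    if (stats::sd(a$value - b$value) == 0) {
      # degenerate paired differences: identical samples give t = 0, p = 1;
      # a constant nonzero shift is unboundedly significant
      d <- mean(a$value - b$value)
      res <- list(test = "paired_t", statistic = if (d == 0) 0 else
                    sign(d) * Inf,
                  p = if (d == 0) 1 else 0, pairwise = NULL)
    } else {
      tt <- stats::t.test(a$value, b$value, paired = TRUE)
      res <- list(test = "paired_t", statistic = unname(tt$statistic),
                  p = tt$p.value, pairwise = NULL)
    }
  } else {
    d <- data.frame(cell = factor(values$cell),
                    condition = factor(values$condition),
                    value = values$value)
    fit <- stats::aov(value ~ cell + condition, data = d)
    an <- summary(fit)[[1]]
    i <- which(trimws(rownames(an)) == "condition")
    tk <- stats::TukeyHSD(fit, "condition")$condition
    res <- list(test = "rm_anova_tukey", statistic = an[i, "F value"],
                p = an[i, "Pr(>F)"],
                pairwise = data.frame(comparison = rownames(tk),
                                      diff = tk[, "diff"],
                                      pAdj = tk[, "p adj"],
                                      row.names = NULL))
  }
  res$significant <- res$p < bonferroniCriticalP
  res$metric <- metricName
  res
}

#' Feedforward-inhibition halfwidth reduction
#'
#' Percent by which intact feedforward inhibition shortens the EPSP
#' halfwidth, relative to the disinhibited (gabazine) condition:
#' `100 * (hw_disinhibited - hw_control) / hw_disinhibited`.
#'
#' @param control [PSPRecord-class] (or metrics list) with inhibition intact
#' @param disinhibited [PSPRecord-class] (or metrics list) under GABA_A
#'   block
#' @return list with `reductionPct` (gabazine denominator, primary),
#'   `reductionPctControlDenom` (control denominator, for comparison), and
#'   the two halfwidths
#' @export
ffiHalfwidthReduction <- function(control, disinhibited) {
  hw <- function(x) {
    if (is(x, "PSPRecord")) x <- pspMetrics(x)
    if (inherits(x, "no_event") || is.na(x$halfwidth))
      stop("EPSP not detected in one of the conditions")
    x$halfwidth
  }
  hC <- hw(control); hD <- hw(disinhibited)
  list(reductionPct = 100 * (hD - hC) / hD,
       reductionPctControlDenom = 100 * (hD - hC) / hC,
       halfwidthControl = hC, halfwidthDisinhibited = hD)
}
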