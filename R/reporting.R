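# Study-level statistics and report assembly.

#' Proportion as a percentage at reporting precision
#'
#' @param numerator,denominator counts (denominator > 0)
#' @param digits decimals to report (1 for physiology tallies, 0 for
#'   morphology tallies)
#' @return list with `numerator`, `denominator`, `percent` (rounded) and
#'   `percentRaw`
#' @examples
#' proportionReport(214, 237)$percent        # 90.3
#' proportionReport(39, 42, digits = 0)$percent  # 93
#' @export
proportionReport <- function(numerator, denominator, digits = 1) {
  if (denominator <= 0) stop("denominator must be > 0")
  if (numerator > denominator) stop("numerator exceeds denominator")
  pct <- 100 * numerator / denominator
  list(numerator = numerator, denominator = denominator,
       percent = round(pct, digits), percentRaw = pct)
}

#' Two-group comparison
#'
#' Wilcoxon rank-sum (Mann-Whitney) or two-tailed Welch t-test between two
#' independent samples, with descriptive mean +/- SD per group. The
#' rank-sum test is exact for small untied samples and uses the normal
#' approximation with tie correction otherwise (stats::wilcox.test
#' semantics). Identical pooled values yield p = 1.
#'
#' @param a,b numeric samples (n >= 2 each)
#' @param test "wilcoxon_rank_sum" or "t_two_tailed"
#' @return list with per-group descriptives, `statistic`, `p`, `test`
#' @export
groupCompare <- function(a, b, test = c("wilcoxon_rank_sum", "t_two_tailed")) {
  test <- match.arg(test)
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  desc <- function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x))
  if (test == "wilcoxon_rank_sum") {
    if (stats::sd(c(a, b)) == 0) {
      res <- list(statistic = length(a) * length(b) / 2, p = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      res <- list(statistic = unname(wt$statistic), p = wt$p.value)
    }
  } else {
    tt <- stats::t.test(a, b)
    res <- list(statistic = unname(tt$statistic), p = tt$p.value)
  }
  c(list(groupA = desc(a), groupB = desc(b), test = test), res)
}

#' Assemble the end-to-end report bundle
#'
#' Merges the per-neuron tables (intrinsic profiles, morphometric profiles,
#' coordinates) by neuron id and recomputes the study-level summaries from
#' the merged table: firing-class proportions, shape-class proportions,
#' laminar statistics, plus any stereology estimates and PSP condition
#' tables passed through. Every summary number is recomputable from the
#' merged table.
#'
#' @param profiles data.frame of intrinsic profiles with an `id` column
#' @param morphometrics optional data.frame of morphometric profiles with
#'   an `id` column
#' @param stereo optional output of [estimateFraction()]
#' @param planeFits optional output of [tonotopyReport()]
#' @param pspTables optional list of [compareConditions()] results
#' @return list with `perNeuron` (merged table) and `summaries`
#' @export
buildReport <- function(profiles, morphometrics = NULL, stereo = NULL,
                        planeFits = NULL, pspTables = NULL) {
  if (is.null(profiles) && is.null(morphometrics))
    stop("need at least one input table")
  checkIds <- function(tab, what) {
    if (!"id" %in% names(tab)) stop(what, " table needs an 'id' column")
    dup <- unique(tab$id[duplicated(tab$id)])
    if (length(dup))
      stop("duplicate ids in ", what, " table: ", paste(dup, collapse = ", "))
    tab
  }
  merged <- NULL
  if (!is.null(profiles)) merged <- checkIds(profiles, "profiles")
  if (!is.null(morphometrics)) {
    morphometrics <- checkIds(morphometrics, "morphometrics")
    merged <- if (is.null(merged)) morphometrics else
      merge(merged, morphometrics, by = "id", all = TRUE)
  }
  summaries <- list()
  if (!is.null(profiles) && "firingClass" %in% names(profiles)) {
    cls <- profiles$firingClass[!is.na(profiles$firingClass)]
    tab <- table(cls)
    summaries$firingClasses <- data.frame(
      class = names(tab), n = as.integer(tab),
      percent = vapply(as.integer(tab), function(k)
        proportionReport(k, length(cls))$percent, numeric(1)))
    summaries$sfa <- c(mean = mean(profiles$sfa, na.rm = TRUE),
                       sd = stats::sd(profiles$sfa, na.rm = TRUE))
  }
  if (!is.null(morphometrics)) {
    shp <- morphometrics$shapeClass[!is.na(morphometrics$shapeClass)]
    if (length(shp)) {
      nSt <- sum(shp == "stellate")
      summaries$shapeClasses <- data.frame(
        class = c("stellate", "disc_shaped"),
        n = c(nSt, length(shp) - nSt),
        percent = c(proportionReport(nSt, length(shp), 0)$percent,
                    proportionReport(length(shp) - nSt, length(shp),
                                     0)$percent))
    }
    if ("laminarSpread" %in% names(morphometrics)) {
      sp <- morphometrics$laminarSpread[!is.na(morphometrics$laminarSpread)]
      summaries$laminarSpreadOver100 <-
        proportionReport(sum(sp > 100), length(sp), 0)
    }
    if ("withinLamina" %in% names(morphometrics)) {
      wl <- morphometrics$withinLamina[!is.na(morphometrics$withinLamina)]
      summaries$withinLamina <-
        proportionReport(sum(wl), length(wl), 0)
    }
  } else {
    summaries$notice <- "morphometrics absent: morphology section omitted"
  }
  if (!is.null(stereo)) summaries$stereo <- stereo
  if (!is.null(planeFits)) summaries$planeFits <- planeFits
  if (!is.null(pspTables)) summaries$psp <- pspTables
  list(perNeuron = merged, summaries = summaries)
}
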