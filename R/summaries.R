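#' Cohort composition counts
#'
#' Per line x sex x genotype cell counts with totals and one-decimal
#' percentages, the standard cohort-description table for a knockout F1
#' panel.
#'
#' @param cohort A [BWCohort-class].
#' @return A list of class `"cohortCounts"` with elements `cells` (data.frame
#'   `line, sex, genotype, n` over the full grid), `total`, `byGenotype` and
#'   `bySex` (data.frames with `n` and `percent`), and `byLine`.
#' @export
#' @examples
#' co <- simulateCohort(TrajectorySimParam(micePerCell = 2L, seed = 1L))
#' summarizeCounts(co)$total
summarizeCounts <- function(cohort) {
  n <- ncol(cohort)
  lines <- sort(unique(mouseLine(cohort)))
  if (n == 0L) {
    cells <- data.frame(line = character(0), sex = character(0),
                        genotype = integer(0), n = integer(0))
  } else {
    tab <- table(line = mouseLine(cohort), sex = mouseSex(cohort),
                 genotype = mouseGenotype(cohort))
    cells <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(cells)[names(cells) == "Freq"] <- "n"
    cells$genotype <- as.integer(cells$genotype)
    cells <- cells[order(cells$line, cells$sex, cells$genotype), ]
    rownames(cells) <- NULL
  }
  pct <- function(x) round(100 * x / max(n, 1L), 1)
  nG <- c(`0` = sum(mouseGenotype(cohort) == 0L),
          `1` = sum(mouseGenotype(cohort) == 1L))
  nS <- c(F = sum(mouseSex(cohort) == "F"), M = sum(mouseSex(cohort) == "M"))
  structure(list(
    cells = cells,
    total = n,
    byGenotype = data.frame(genotype = c(0L, 1L), n = as.integer(nG),
                            percent = pct(as.integer(nG))),
    bySex = data.frame(sex = c("F", "M"), n = as.integer(nS),
                       percent = pct(as.integer(nS))),
    byLine = if (n == 0L) data.frame(line = character(0), n = integer(0))
             else data.frame(line = lines,
                             n = as.integer(table(mouseLine(cohort))[lines]))
  ), class = "cohortCounts")
}

#' @export
print.cohortCounts <- function(x, ...) {
  cat("Cohort of", x$total, "mice,", nrow(x$byLine), "lines\n")
  cat(sprintf("  mutant:  %d (%.1f%%)   wild-type: %d (%.1f%%)\n",
              x$byGenotype$n[2], x$byGenotype$percent[2],
              x$byGenotype$n[1], x$byGenotype$percent[1]))
  cat(sprintf("  female:  %d (%.1f%%)   male:      %d (%.1f%%)\n",
              x$bySex$n[1], x$bySex$percent[1],
              x$bySex$n[2], x$bySex$percent[2]))
  invisible(x)
}

#' Percent body-weight gain from a baseline week
#'
#' The trait `%dBW to-from` is `100 * (BW_to - BW_from) / BW_from`, the
#' percent gain from the baseline week (default week 6). Mice missing either
#' weight get `NA` and are reported with a warning rather than silently
#' dropped.
#'
#' @param cohort A [BWCohort-class].
#' @param toWeek Target week (must be in the schedule).
#' @param fromWeek Baseline week, default 6.
#' @return data.frame `mouse_id, from_week, to_week, value` (percent).
#' @export
#' @examples
#' co <- simulateCohort(TrajectorySimParam(micePerCell = 1L, seed = 1L))
#' head(percentGain(co, 48))
percentGain <- function(cohort, toWeek, fromWeek = 6) {
  weeks <- schedule(cohort)
  for (w in c(fromWeek, toWeek))
    if (!w %in% weeks)
      ccwStop("ccweight_invalid_data", "week %s is not in the schedule", w)
  bw <- weightMatrix(cohort)
  from <- bw[paste0("wk", fromWeek), ]
  to <- bw[paste0("wk", toWeek), ]
  value <- 100 * (to - from) / from
  inc <- is.na(value)
  if (any(inc))
    warning(sprintf("incomplete record(s), %%gain undefined: %s",
                    paste(mouseIds(cohort)[inc], collapse = ", ")),
            call. = FALSE)
  data.frame(mouse_id = mouseIds(cohort),
             from_week = rep(fromWeek, ncol(cohort)),
             to_week = rep(toWeek, ncol(cohort)), value = unname(value),
             stringsAsFactors = FALSE)
}

.stratumSex <- function(stratum) {
  stratum <- match.arg(stratum, c("overall", "F", "M"))
  if (stratum == "overall") c("F", "M") else stratum
}

#' Per-week group trajectory of one line
#'
#' Mean and SEM of body weight per scheduled week for the wild-type and
#' mutant arms of one line (the curves behind per-line trajectory figures).
#' Means are over present weights only; weeks where an arm is empty are
#' omitted with a warning.
#'
#' @param cohort A [BWCohort-class].
#' @param line Line label.
#' @param stratum `"overall"`, `"F"` or `"M"`.
#' @return data.frame `week, genotype, n, mean, sem` (SEM = SD/sqrt(n);
#'   `NA` for n = 1).
#' @export
groupTrajectory <- function(cohort, line, stratum = "overall") {
  sx <- .stratumSex(stratum)
  sub <- subsetCohort(cohort, line = line, sex = sx)
  out <- list()
  for (gt in c(0L, 1L)) {
    arm <- subsetCohort(sub, genotype = gt)
    bw <- weightMatrix(arm)
    nW <- rowSums(!is.na(bw))
    empty <- nW == 0L
    if (any(empty))
      warning(sprintf("line %s genotype %d: no data at week(s) %s; omitted",
                      line, gt,
                      paste(schedule(cohort)[empty], collapse = ", ")),
              call. = FALSE)
    keep <- !empty
    out[[as.character(gt)]] <- data.frame(
      week = schedule(cohort)[keep], genotype = rep(gt, sum(keep)),
      n = nW[keep],
      mean = rowMeans(bw[keep, , drop = FALSE], na.rm = TRUE),
      sem = apply(bw[keep, , drop = FALSE], 1,
                  function(r) stats::sd(r, na.rm = TRUE)) /
        sqrt(nW[keep]),
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Welch comparison of the two genotype arms at one timepoint
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on the body weights
#' of wild-type versus mutant mice of one line at one scheduled week, with
#' the significance star convention used on trajectory figures:
#' `"*"` for 0.01 <= p < 0.05 and `"**"` for p < 0.01.
#'
#' @param cohort A [BWCohort-class].
#' @param line Line label.
#' @param week Scheduled week.
#' @param stratum `"overall"`, `"F"` or `"M"`.
#' @return A one-row data.frame of class `"groupComparison"`: `line, week,
#'   stratum, n0, n1, mean0, mean1, sd0, sd1, t, p, star`.
#' @export
timepointTest <- function(cohort, line, week, stratum = "overall") {
  weeks <- schedule(cohort)
  if (!week %in% weeks)
    ccwStop("ccweight_invalid_data", "week %s is not in the schedule", week)
  sx <- .stratumSex(stratum)
  sub <- subsetCohort(cohort, line = line, sex = sx)
  bw <- weightMatrix(sub)[paste0("wk", week), ]
  g0 <- bw[mouseGenotype(sub) == 0L]; g0 <- g0[!is.na(g0)]
  g1 <- bw[mouseGenotype(sub) == 1L]; g1 <- g1[!is.na(g1)]
  if (length(g0) < 2L || length(g1) < 2L)
    ccwStop("ccweight_insufficient_data",
            "line %s week %s: <2 mice in an arm (n0=%d, n1=%d)",
            line, week, length(g0), length(g1))
  if (stats::sd(g0) == 0 && stats::sd(g1) == 0) {
    # degenerate: Welch statistic undefined; by convention equal constants
    # compare as no difference, distinct constants as certain difference
    if (mean(g0) == mean(g1)) { tv <- 0; pv <- 1 }
    else { tv <- sign(mean(g0) - mean(g1)) * Inf; pv <- 0 }
  } else {
    tt <- stats::t.test(g0, g1, var.equal = FALSE)
    tv <- unname(tt$statistic); pv <- tt$p.value
  }
  star <- if (pv < 0.01) "**" else if (pv < 0.05) "*" else ""
  structure(data.frame(
    line = line, week = week, stratum = stratum,
    n0 = length(g0), n1 = length(g1),
    mean0 = mean(g0), mean1 = mean(g1),
    sd0 = stats::sd(g0), sd1 = stats::sd(g1),
    t = tv, p = pv, star = star, stringsAsFactors = FALSE),
    class = c("groupComparison", "data.frame"))
}
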