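## Broad-sense heritability from one-way ANOVA variance components.
##
## For a trait measured on k inbred lines, the fixed-effects one-way
## decomposition about the grand mean gives MS_between and MS_within;
## with effective per-line size n0, the between-line (genetic) variance is
## Vg = (MS_between - MS_within) / n0 (truncated at 0), the environmental
## variance Ve = MS_within, and broad-sense heritability
## H2 = Vg / (Vg + Ve).

#' One-way fixed-effects ANOVA decomposition
#'
#' Textbook sums of squares about the grand mean for a trait grouped by
#' line. `SS_between + SS_within` equals the total sum of squares.
#'
#' @param groups Named list of numeric vectors, one per line (k >= 2, every
#'   group non-empty, N > k).
#' @return A list of class `"anovaResult"`: `k, N, dfBetween, dfWithin,
#'   ssBetween, ssWithin, msBetween, msWithin, groupSizes`.
#' @export
#' @examples
#' oneWayAnova(list(a = c(1, 1), b = c(2, 2)))
oneWayAnova <- function(groups) {
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  sizes <- lengths(groups)
  k <- length(groups)
  if (k < 2L)
    ccwStop("ccweight_invalid_data", "at least 2 groups required (got %d)", k)
  if (any(sizes < 1L))
    ccwStop("ccweight_invalid_data", "every group must be non-empty")
  N <- sum(sizes)
  if (N <= k)
    ccwStop("ccweight_invalid_data",
            "need N > k for within-group df (N=%d, k=%d)", N, k)
  all <- unlist(groups, use.names = FALSE)
  gm <- mean(all)
  means <- vapply(groups, mean, numeric(1))
  ssB <- sum(sizes * (means - gm)^2)
  ssW <- sum(vapply(seq_len(k),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  structure(list(
    k = k, N = N, dfBetween = k - 1L, dfWithin = N - k,
    ssBetween = ssB, ssWithin = ssW,
    msBetween = ssB / (k - 1L), msWithin = ssW / (N - k),
    groupSizes = as.integer(sizes)), class = "anovaResult")
}

#' @export
print.anovaResult <- function(x, ...) {
  cat(sprintf("One-way ANOVA: k=%d groups, N=%d\n", x$k, x$N))
  cat(sprintf("  between: df=%d  SS=%.4f  MS=%.4f\n",
              x$dfBetween, x$ssBetween, x$msBetween))
  cat(sprintf("  within:  df=%d  SS=%.4f  MS=%.4f\n",
              x$dfWithin, x$ssWithin, x$msWithin))
  invisible(x)
}

#' Effective per-group size for unbalanced designs
#'
#' The standard unbalanced-design surrogate
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)`, equal to the common group size when
#' the design is balanced.
#'
#' @param groupSizes Integer vector of per-group sizes (k >= 2, each >= 1).
#' @return Effective size `n0` (numeric scalar).
#' @export
#' @examples
#' effectiveN(c(3, 5, 7))  # 4.7333...
effectiveN <- function(groupSizes) {
  k <- length(groupSizes)
  if (k < 2L || any(groupSizes < 1L))
    ccwStop("ccweight_invalid_data",
            "need k >= 2 groups with sizes >= 1")
  N <- sum(groupSizes)
  (N - sum(groupSizes^2) / N) / (k - 1)
}

#' Variance components and broad-sense heritability
#'
#' Converts one-way ANOVA mean squares into variance components:
#' `Vg = max(0, (MS_between - MS_within) / nEff)`, `Ve = MS_within`,
#' `H2 = Vg / (Vg + Ve)` (0 by convention when both components vanish).
#' `nEff` may be the balanced group size, [effectiveN()], or an explicit
#' override so that published ANOVA summaries can be converted as printed.
#'
#' @param msBetween,msWithin Mean squares (>= 0).
#' @param nEff Effective per-group size (> 0).
#' @return A list of class `"varianceComponents"`: `vg, ve, nEff, h2`.
#' @export
#' @examples
#' varianceComponents(582.107, 170.343, 8)
varianceComponents <- function(msBetween, msWithin, nEff) {
  if (!is.finite(nEff) || nEff <= 0)
    ccwStop("ccweight_invalid_data", "nEff must be > 0")
  if (msBetween < 0 || msWithin < 0)
    ccwStop("ccweight_invalid_data", "mean squares must be >= 0")
  vg <- max(0, (msBetween - msWithin) / nEff)
  ve <- msWithin
  h2 <- if (vg + ve == 0) 0 else vg / (vg + ve)
  structure(list(vg = vg, ve = ve, nEff = nEff, h2 = h2),
            class = "varianceComponents")
}

#' @export
print.varianceComponents <- function(x, ...) {
  cat(sprintf("Vg = %.5f  Ve = %.5f  (nEff = %.4g)  H2 = %.6f\n",
              x$vg, x$ve, x$nEff, x$h2))
  invisible(x)
}

#' Heritability table over sex x genotype strata and %gain traits
#'
#' For each sex x genotype stratum and each percent-gain trait, groups the
#' trait by line, runs [oneWayAnova()], and converts the mean squares with
#' [effectiveN()] and [varianceComponents()]. Lines with no complete record
#' for a trait are excluded with a message; strata with fewer than 2 usable
#' lines are returned as not estimable.
#'
#' @param cohort A [BWCohort-class].
#' @param toWeeks Target weeks of the percent-gain traits (default
#'   `c(16, 32, 40, 48)`).
#' @param fromWeek Baseline week (default 6).
#' @return data.frame, one row per stratum x trait: `sex, genotype, trait,
#'   toWeek, fromWeek, nLines, dfBetween, dfWithin, nEff, msBetween,
#'   msWithin, vg, ve, h2, estimable`.
#' @export
heritabilityTable <- function(cohort, toWeeks = c(16, 32, 40, 48),
                              fromWeek = 6) {
  rows <- list()
  for (sx in c("F", "M")) for (gt in c(0L, 1L)) {
    sub <- subsetCohort(cohort, sex = sx, genotype = gt)
    for (tw in toWeeks) {
      trait <- sprintf("pctBW_%d_%d", tw, fromWeek)
      vals <- withCallingHandlers(
        percentGain(sub, tw, fromWeek)$value,
        warning = function(w) invokeRestart("muffleWarning"))
      byLine <- split(vals, mouseLine(sub))
      byLine <- lapply(byLine, function(v) v[!is.na(v)])
      drop <- names(byLine)[lengths(byLine) == 0L]
      if (length(drop))
        message(sprintf("stratum %s/%d trait %s: excluding line(s) %s ",
                        sx, gt, trait, paste(drop, collapse = ", ")),
                "(no complete record)")
      byLine <- byLine[lengths(byLine) > 0L]
      row <- data.frame(sex = sx, genotype = gt, trait = trait,
                        toWeek = tw, fromWeek = fromWeek,
                        nLines = length(byLine), dfBetween = NA_integer_,
                        dfWithin = NA_integer_, nEff = NA_real_,
                        msBetween = NA_real_, msWithin = NA_real_,
                        vg = NA_real_, ve = NA_real_, h2 = NA_real_,
                        estimable = FALSE, stringsAsFactors = FALSE)
      if (length(byLine) >= 2L && sum(lengths(byLine)) > length(byLine)) {
        av <- oneWayAnova(byLine)
        n0 <- effectiveN(lengths(byLine))
        vc <- varianceComponents(av$msBetween, av$msWithin, n0)
        row$dfBetween <- av$dfBetween; row$dfWithin <- av$dfWithin
        row$nEff <- n0
        row$msBetween <- av$msBetween; row$msWithin <- av$msWithin
        row$vg <- vc$vg; row$ve <- vc$ve; row$h2 <- vc$h2
        row$estimable <- TRUE
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
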