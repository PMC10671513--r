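## Chained linear-regression body-weight forecaster.
##
## Given weights observed up to a "last observed" week, each later week is
## predicted in schedule order by an OLS model on [sex, genotype, all
## earlier weeks], where weeks beyond the last observed one enter as their
## chained predictions. Training uses teacher forcing by default (observed
## predecessors); evaluation is k-fold cross-validated pooled R-squared
## over all out-of-fold (mouse, target-week) cells.

#' Minimum-norm ordinary least squares
#'
#' Fits `y ~ 1 + X` by SVD-based least squares; on rank-deficient designs
#' (common in the chain, where later weights are nearly collinear with
#' earlier ones) it returns the minimum-norm solution.
#'
#' @param X Numeric predictor matrix (no intercept column).
#' @param y Numeric response.
#' @return Named coefficient vector (`(Intercept)` first).
#' @export
#' @examples
#' olsFit(matrix(1:5, ncol = 1, dimnames = list(NULL, "x")), 3 * (1:5) + 1)
olsFit <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    ccwStop("ccweight_invalid_data", "olsFit needs at least 2 rows")
  if (nrow(X) != length(y))
    ccwStop("ccweight_invalid_data", "X and y differ in length")
  Xd <- cbind(`(Intercept)` = 1, X)
  s <- svd(Xd)
  tol <- max(dim(Xd)) * .Machine$double.eps * s$d[1]
  pos <- s$d > tol
  beta <- s$v[, pos, drop = FALSE] %*%
    ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos])
  stats::setNames(as.vector(beta), colnames(Xd))
}

## predictor week set for a target week: all schedule weeks before it
.chainPredictors <- function(sched, target) sched[sched < target]

## design matrix for one target week from a weights matrix (weeks x mice)
.chainDesign <- function(sexNum, genotype, bw, sched, target) {
  pred <- .chainPredictors(sched, target)
  cbind(sex = sexNum, genotype = genotype,
        t(bw[paste0("wk", pred), , drop = FALSE]))
}

#' Fit a chained linear-regression forecaster
#'
#' One OLS model per schedule week after `lastObservedWeek`; the model for
#' target week `w` regresses `w` on sex, genotype and every schedule week
#' before `w`. With `trainOnChained = FALSE` (default, teacher forcing) the
#' models are trained on observed predecessor weights; with `TRUE`, training
#' predictors beyond `lastObservedWeek` are the chain's own in-sample
#' predictions.
#'
#' @param cohort A [BWCohort-class] of training records (complete cases are
#'   used; incomplete records are dropped with a message).
#' @param lastObservedWeek Schedule week after which weights are predicted;
#'   must not be the final week.
#' @param trainOnChained Logical flag, see above.
#' @return A list of class `"chainModel"`: `lastObservedWeek, schedule,
#'   targetWeeks, coefs` (named list of coefficient vectors).
#' @export
fitChain <- function(cohort, lastObservedWeek, trainOnChained = FALSE) {
  sched <- schedule(cohort)
  if (!lastObservedWeek %in% sched)
    ccwStop("ccweight_invalid_data",
            "lastObservedWeek %s is not in the schedule", lastObservedWeek)
  if (lastObservedWeek == max(sched))
    ccwStop("ccweight_invalid_data",
            "lastObservedWeek must precede the final schedule week")
  dropped <- sum(!isComplete(cohort))
  if (dropped > 0)
    message(sprintf("fitChain: dropping %d incomplete record(s)", dropped))
  cohort <- completeCases(cohort)
  targets <- sched[sched > lastObservedWeek]
  widest <- 2L + length(.chainPredictors(sched, max(targets)))
  if (ncol(cohort) < widest + 2L)
    ccwStop("ccweight_invalid_data",
            "too few records (%d) for target week %d (%d predictors + 2)",
            ncol(cohort), max(targets), widest)
  bw <- weightMatrix(cohort)
  sexNum <- as.numeric(mouseSex(cohort) == "M")
  geno <- mouseGenotype(cohort)
  trainBw <- bw  # teacher forcing: observed predecessors
  coefs <- list()
  for (tw in targets) {
    X <- .chainDesign(sexNum, geno, trainBw, sched, tw)
    coefs[[paste0("wk", tw)]] <- olsFit(X, bw[paste0("wk", tw), ])
    if (trainOnChained) {
      Xd <- cbind(`(Intercept)` = 1, X)
      trainBw[paste0("wk", tw), ] <-
        as.vector(Xd %*% coefs[[paste0("wk", tw)]])
    }
  }
  structure(list(lastObservedWeek = lastObservedWeek, schedule = sched,
                 targetWeeks = targets, coefs = coefs,
                 trainOnChained = trainOnChained),
            class = "chainModel")
}

#' @export
print.chainModel <- function(x, ...) {
  cat(sprintf("Chained OLS forecaster: last observed week %d -> %d target(s) (%s)\n",
              x$lastObservedWeek, length(x$targetWeeks),
              paste(x$targetWeeks, collapse = ", ")))
  invisible(x)
}

#' Predict later weights with a chained model
#'
#' Targets are predicted in schedule order; each target's predictor vector
#' uses the observed weights up to the model's last observed week and the
#' chain's own predictions for intermediate target weeks.
#'
#' @param model A `"chainModel"` from [fitChain()].
#' @param sex `"F"` or `"M"` (or 0/1 numeric with M = 1).
#' @param genotype 0 or 1.
#' @param observed Named numeric vector of observed weights; names are weeks
#'   (e.g. `c("6" = 20, "8" = 22)`); all weeks up to the last observed week
#'   must be present.
#' @return Named numeric vector of predictions for every target week.
#' @export
predictChain <- function(model, sex, genotype, observed) {
  stopifnot(inherits(model, "chainModel"))
  sched <- model$schedule
  obsWeeks <- sched[sched <= model$lastObservedWeek]
  have <- names(observed)
  miss <- setdiff(as.character(obsWeeks), have)
  if (length(miss))
    ccwStop("ccweight_invalid_data",
            "missing observed predecessor week(s): %s",
            paste(miss, collapse = ", "))
  sexNum <- if (is.character(sex)) as.numeric(sex == "M") else as.numeric(sex)
  known <- stats::setNames(as.numeric(observed[as.character(obsWeeks)]),
                           as.character(obsWeeks))
  out <- numeric(0)
  for (tw in model$targetWeeks) {
    pred <- .chainPredictors(sched, tw)
    v <- c(1, sexNum, as.numeric(genotype), known[as.character(pred)])
    yhat <- sum(v * model$coefs[[paste0("wk", tw)]])
    known[as.character(tw)] <- yhat
    out[as.character(tw)] <- yhat
  }
  out
}

## pooled R^2 = 1 - SSE/SST over all cells, SST about the pooled actual mean
pooledR2 <- function(actual, predicted) {
  sse <- sum((actual - predicted)^2)
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0)
    ccwStop("ccweight_invalid_data",
            "pooled R2 undefined: actual values are constant")
  1 - sse / sst
}

#' Cross-validated evaluation of the chained forecaster
#'
#' K-fold cross-validation over the complete-case mice of one line (or the
#' whole cohort): each fold's held-out mice are forecast from
#' `lastObservedWeek` with a chain fit on the remaining mice, and all
#' out-of-fold (mouse, target-week) cells are pooled into a single
#' R-squared about the pooled mean of the actual values. Pooled R-squared
#' may be negative when the chain predicts worse than that mean.
#'
#' @param cohort A [BWCohort-class].
#' @param line Line label, or `NULL` to pool the whole cohort.
#' @param lastObservedWeek Week after which weights are forecast.
#' @param folds Number of CV folds (default 5).
#' @param seed Root seed for the fold shuffle.
#' @param trainOnChained Passed to [fitChain()].
#' @return A list of class `"chainEval"`: `line, lastObservedWeek, pooledR2,
#'   n, folds, perWeek` (data.frame of per-target-week R-squared
#'   diagnostics).
#' @export
evaluateChain <- function(cohort, line = NULL, lastObservedWeek,
                          folds = 5L, seed = 1L, trainOnChained = FALSE) {
  sub <- if (is.null(line)) cohort else subsetCohort(cohort, line = line)
  sub <- completeCases(sub)
  n <- ncol(sub)
  if (n < folds)
    ccwStop("ccweight_not_evaluable",
            "line %s: %d complete mice < %d folds",
            if (is.null(line)) "<all>" else line, n, folds)
  set.seed(childSeed(seed, sprintf("chain:%s:%d",
                                   if (is.null(line)) "all" else line,
                                   lastObservedWeek)))
  fid <- rep_len(seq_len(folds), n)[sample.int(n)]
  sched <- schedule(sub)
  targets <- sched[sched > lastObservedWeek]
  obsWeeks <- sched[sched <= lastObservedWeek]
  bw <- weightMatrix(sub)
  actual <- predicted <- matrix(NA_real_, nrow = length(targets), ncol = n,
                                dimnames = list(paste0("wk", targets),
                                                mouseIds(sub)))
  for (f in seq_len(folds)) {
    te <- which(fid == f)
    model <- fitChain(sub[, -te], lastObservedWeek,
                      trainOnChained = trainOnChained)
    for (i in te) {
      obs <- stats::setNames(bw[paste0("wk", obsWeeks), i],
                             as.character(obsWeeks))
      predicted[, i] <- predictChain(model, mouseSex(sub)[i],
                                     mouseGenotype(sub)[i], obs)
      actual[, i] <- bw[paste0("wk", targets), i]
    }
  }
  perWeek <- data.frame(
    week = targets,
    r2 = vapply(seq_along(targets), function(j)
      tryCatch(pooledR2(actual[j, ], predicted[j, ]),
               ccweight_invalid_data = function(e) NA_real_), numeric(1)))
  structure(list(line = if (is.null(line)) NA_character_ else line,
                 lastObservedWeek = lastObservedWeek,
                 pooledR2 = pooledR2(as.vector(actual),
                                     as.vector(predicted)),
                 n = n, folds = folds, perWeek = perWeek),
            class = "chainEval")
}

#' @export
print.chainEval <- function(x, ...) {
  cat(sprintf(
    "Chain evaluation: line %s, last observed week %d, n=%d, %d folds\n",
    x$line, x$lastObservedWeek, x$n, x$folds))
  cat(sprintf("  pooled out-of-fold R2 = %.4f\n", x$pooledR2))
  invisible(x)
}

#' Forecast-quality table per line and last-observed week
#'
#' Runs [evaluateChain()] for each line and each last-observed week,
#' skipping combinations that are not evaluable with a message.
#'
#' @inheritParams evaluateChain
#' @param lines Lines to evaluate (default: all).
#' @param lastWeeks Last-observed weeks (default: weeks 6-24 of the
#'   schedule).
#' @return Long data.frame: `line, lastObservedWeek, pooledR2, n`.
#' @export
forecastTable <- function(cohort, lines = sort(unique(mouseLine(cohort))),
                          lastWeeks = schedule(cohort)[
                            schedule(cohort) <= 24],
                          folds = 5L, seed = 1L) {
  rows <- list()
  for (ln in lines) for (lw in lastWeeks) {
    ev <- tryCatch(
      evaluateChain(cohort, ln, lw, folds = folds, seed = seed),
      ccweight_error = function(e) {
        message(sprintf("line %s from week %d: %s (skipped)",
                        ln, lw, conditionMessage(e)))
        NULL
      })
    if (!is.null(ev))
      rows[[length(rows) + 1L]] <- data.frame(
        line = ln, lastObservedWeek = lw, pooledR2 = ev$pooledR2, n = ev$n,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
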