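## Per-line genotype classification benchmark.
##
## Six classifiers predict genotype (0/1) from sex plus the 14 recorded
## weights; each line is scored by the mean ROC-AUC over repeated
## stratified cross-validation (4 folds x 3 repeats by default). The CV
## harness, fold scoring and AUC are implemented here; the estimators are
## library-backed (rpart, randomForest, e1071, class, stats::glm).

.MODEL_NAMES <- c("DT", "NaBa", "KNN", "RF", "SVC", "LR")

#' Build the per-line feature matrix
#'
#' Complete-case mice of one line; columns are sex (F=0, M=1) followed by
#' the scheduled weights in order, labels are genotype 0/1.
#'
#' @param cohort A [BWCohort-class].
#' @param line Line label.
#' @return A list of class `"featureMatrix"`: `x` (n x (1 + weeks) numeric
#'   matrix), `y` (integer 0/1), `mouseIds`, `line`. Signals a classed error
#'   (`ccweight_not_benchmarkable`) when fewer than 4 complete mice remain
#'   or either class has fewer than 2.
#' @export
buildFeatures <- function(cohort, line) {
  sub <- subsetCohort(cohort, line = line)
  dropped <- mouseIds(sub)[!isComplete(sub)]
  if (length(dropped))
    message(sprintf("line %s: excluding %d incomplete record(s): %s",
                    line, length(dropped), paste(dropped, collapse = ", ")))
  sub <- completeCases(sub)
  x <- cbind(sex = as.numeric(mouseSex(sub) == "M"), t(weightMatrix(sub)))
  y <- mouseGenotype(sub)
  if (nrow(x) < 4L || min(table(factor(y, levels = c(0, 1)))) < 2L)
    ccwStop("ccweight_not_benchmarkable",
            "line %s is not benchmarkable: %d complete mice (%d/%d per class)",
            line, nrow(x), sum(y == 0L), sum(y == 1L))
  structure(list(x = x, y = y, mouseIds = mouseIds(sub), line = line),
            class = "featureMatrix")
}

#' ROC-AUC as Mann-Whitney concordance
#'
#' Over all (positive, negative) pairs, the fraction where the positive's
#' score exceeds the negative's, counting ties as 1/2 (mid-rank
#' implementation). Equals the area under the ROC curve.
#'
#' @param scores Numeric scores, higher = more class-1.
#' @param labels 0/1 labels (numeric, logical or two-level factor).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' rocAuc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))  # 0.75
rocAuc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (length(scores) != length(labels))
    ccwStop("ccweight_invalid_data", "scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels))
    ccwStop("ccweight_invalid_data", "scores/labels must not contain NA")
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    ccwStop("ccweight_single_class",
            "AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

## stratified fold assignment: within each class, shuffle and deal
## round-robin; returns integer fold id per observation
.stratifiedFolds <- function(y, folds, seed) {
  set.seed(seed)
  fid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fid
}

## held-out class-1 scores for one model on one fold
.modelScore <- function(model, xtr, ytr, xte) {
  ytrF <- factor(ytr, levels = c(0, 1))
  dtr <- data.frame(xtr, check.names = FALSE)
  dte <- data.frame(xte, check.names = FALSE)
  switch(model,
    DT = {
      fit <- rpart::rpart(y ~ ., data = cbind(dtr, y = ytrF),
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 10, cp = 0, minsplit = 2, xval = 0))
      unname(predict(fit, dte, type = "prob")[, "1"])
    },
    NaBa = {
      fit <- e1071::naiveBayes(x = dtr, y = ytrF)
      # guard degenerate zero within-class SDs (e.g. single-sex folds)
      fit$tables <- lapply(fit$tables, function(tb) {
        if (is.matrix(tb) && ncol(tb) == 2L) tb[, 2][tb[, 2] == 0] <- 1e-9
        tb
      })
      unname(predict(fit, dte, type = "raw")[, "1"])
    },
    KNN = {
      k <- min(5L, nrow(xtr))
      pr <- class::knn(train = xtr, test = xte, cl = ytrF, k = k,
                       prob = TRUE)
      pwin <- attr(pr, "prob")
      ifelse(pr == "1", pwin, 1 - pwin)
    },
    RF = {
      fit <- randomForest::randomForest(x = xtr, y = ytrF, ntree = 100)
      unname(predict(fit, xte, type = "prob")[, "1"])
    },
    SVC = {
      fit <- suppressWarnings(
        e1071::svm(x = xtr, y = ytrF, kernel = "radial"))
      pr <- predict(fit, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision values are oriented toward the class named first in the
      # "a/b" column label; flip so higher = class 1
      if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
    },
    LR = {
      fit <- suppressWarnings(
        stats::glm(y ~ ., family = stats::binomial(),
                   data = cbind(dtr, y = ytrF)))
      unname(suppressWarnings(predict(fit, dte, type = "response")))
    },
    ccwStop("ccweight_invalid_config", "unknown model: %s", model))
}

#' Benchmark one line with repeated stratified cross-validation
#'
#' Scores each classifier by the mean held-out ROC-AUC over
#' `folds x repeats` fold-scores. Folds are stratified by genotype; the
#' held-out scores are class-1 probabilities (decision values for SVC).
#' Deterministic for a fixed seed (one root seed generates the repeat
#' shuffles and per-fit streams). If a fold ends up single-class the repeat
#' is reshuffled once, then an error is raised.
#'
#' @param features A `"featureMatrix"` from [buildFeatures()].
#' @param models Subset of `c("DT", "NaBa", "KNN", "RF", "SVC", "LR")`:
#'   decision tree (max depth 10), Gaussian naive Bayes, 5-nearest
#'   neighbours, random forest (100 trees), support-vector classifier
#'   (radial kernel, default settings), logistic regression.
#' @param folds,repeats CV geometry (defaults 4 and 3).
#' @param seed Root seed.
#' @param standardize Standardize feature columns (default `FALSE`).
#' @return data.frame, one row per model: `line, model, meanAuc, nMice,
#'   folds, repeats`.
#' @export
benchmarkLine <- function(features, models = .MODEL_NAMES,
                          folds = 4L, repeats = 3L, seed = 1L,
                          standardize = FALSE) {
  stopifnot(inherits(features, "featureMatrix"))
  models <- match.arg(models, .MODEL_NAMES, several.ok = TRUE)
  # canonical mouse order so results are invariant to row order
  ord <- order(features$mouseIds)
  x <- features$x[ord, , drop = FALSE]; y <- features$y[ord]
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0
  }
  aucs <- matrix(NA_real_, nrow = folds * repeats, ncol = length(models),
                 dimnames = list(NULL, models))
  for (r in seq_len(repeats)) {
    fid <- .stratifiedFolds(y, folds,
                            childSeed(seed, paste0("repeat:", r)))
    bad <- vapply(seq_len(folds), function(f)
      length(unique(y[fid == f])) < 2L, logical(1))
    if (any(bad)) {
      fid <- .stratifiedFolds(y, folds,
                              childSeed(seed, paste0("reshuffle:", r)))
      bad <- vapply(seq_len(folds), function(f)
        length(unique(y[fid == f])) < 2L, logical(1))
      if (any(bad))
        ccwStop("ccweight_fold_degenerate",
                "line %s: fold lost a class even after reshuffling ",
                features$line)
    }
    for (f in seq_len(folds)) {
      te <- fid == f
      for (m in models) {
        set.seed(childSeed(seed, sprintf("fit:%s:%d:%d", m, r, f)))
        sc <- .modelScore(m, x[!te, , drop = FALSE], y[!te],
                          x[te, , drop = FALSE])
        aucs[(r - 1L) * folds + f, m] <- rocAuc(sc, y[te])
      }
    }
  }
  data.frame(line = features$line, model = models,
             meanAuc = unname(colMeans(aucs[, models, drop = FALSE])),
             nMice = length(y), folds = folds, repeats = repeats,
             stringsAsFactors = FALSE)
}

#' Benchmark every line of a cohort
#'
#' Runs [buildFeatures()] and [benchmarkLine()] per line, skipping lines
#' that are not benchmarkable with a message.
#'
#' @inheritParams benchmarkLine
#' @param cohort A [BWCohort-class].
#' @param lines Lines to benchmark (default: all in the cohort).
#' @return Long data.frame of per line x model results.
#' @export
benchmarkCohort <- function(cohort, lines = sort(unique(mouseLine(cohort))),
                            models = .MODEL_NAMES, folds = 4L, repeats = 3L,
                            seed = 1L, standardize = FALSE) {
  out <- list()
  for (ln in lines) {
    res <- tryCatch(
      benchmarkLine(buildFeatures(cohort, ln), models = models,
                    folds = folds, repeats = repeats,
                    seed = childSeed(seed, paste0("line:", ln)),
                    standardize = standardize),
      ccweight_not_benchmarkable = function(e) {
        message(conditionMessage(e), " (skipped)")
        NULL
      })
    if (!is.null(res)) out[[ln]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
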