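## Pearson correlation structure of body weight across timepoints,
## per line x sex x genotype stratum, with diverging heatmap export.

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return Pearson r in `[-1, 1]`. A constant input signals a classed error
#'   (`ccweight_undefined_correlation`); matrix callers render such cells as
#'   missing.
#' @export
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    ccwStop("ccweight_invalid_data", "x and y differ in length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    ccwStop("ccweight_invalid_data",
            "need >= 3 paired observations (got %d)", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ccwStop("ccweight_undefined_correlation",
            "correlation undefined for a constant vector")
  stats::cor(x, y, method = "pearson")
}

#' Week-by-week Pearson correlation matrix for one stratum
#'
#' Correlates body weight between every pair of scheduled weeks over the
#' mice of one line x sex x genotype stratum. Missing weights are handled
#' pairwise-complete, with the per-cell n recorded; cells with fewer than 3
#' pairs or a constant week are `NA`.
#'
#' @param cohort A [BWCohort-class].
#' @param line Line label.
#' @param sex `"F"` or `"M"`.
#' @param genotype 0 or 1.
#' @return A list of class `"bwCorrelation"`: `r` (weeks x weeks matrix),
#'   `n` (pairwise-complete counts), `weeks`, `line`, `sex`, `genotype`.
#'   Signals `ccweight_not_estimable` when the stratum has fewer than 3
#'   mice.
#' @export
correlationMatrix <- function(cohort, line, sex, genotype) {
  sub <- subsetCohort(cohort, line = line, sex = sex, genotype = genotype)
  if (ncol(sub) < 3L)
    ccwStop("ccweight_not_estimable",
            "stratum %s/%s/%d has %d mice (< 3)", line, sex, genotype,
            ncol(sub))
  m <- t(weightMatrix(sub))  # mice x weeks
  present <- !is.na(m)
  nMat <- crossprod(present)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[nMat < 3L] <- NA_real_
  dimnames(nMat) <- dimnames(r)
  structure(list(r = r, n = nMat, weeks = schedule(sub),
                 line = line, sex = sex, genotype = genotype),
            class = "bwCorrelation")
}

#' @export
print.bwCorrelation <- function(x, ...) {
  cat(sprintf("Pearson BW correlation, line %s %s genotype %d (%d weeks)\n",
              x$line, x$sex, x$genotype, length(x$weeks)))
  print(round(x$r, 2))
  invisible(x)
}

#' Export a correlation heatmap
#'
#' Renders the matrix as an unclustered heatmap with a diverging palette
#' anchored at -1, 0 and +1 and writes it to a PNG file.
#'
#' @param corr A `"bwCorrelation"` (or a plain correlation matrix).
#' @param path Output file path (`.png`).
#' @return `path`, invisibly.
#' @export
exportCorrelationHeatmap <- function(corr, path) {
  r <- if (inherits(corr, "bwCorrelation")) corr$r else as.matrix(corr)
  main <- if (inherits(corr, "bwCorrelation"))
    sprintf("line %s, %s, genotype %d", corr$line, corr$sex, corr$genotype)
  else ""
  pal <- grDevices::colorRampPalette(
    c("#2166AC", "#F7F7F7", "#B2182B"))(100)
  pheatmap::pheatmap(r, cluster_rows = FALSE, cluster_cols = FALSE,
                     breaks = seq(-1, 1, length.out = 101), color = pal,
                     na_col = "#CCCCCC", main = main,
                     filename = path, silent = TRUE)
  invisible(path)
}
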