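## Synthetic cohort generation.
##
## Trajectory mode: per-animal logistic growth with line, genotype-by-line,
## sex and individual effects on the asymptote, a female plateau rule and an
## optional male decline rule, plus per-observation measurement noise.
## Trait mode: the direct generative counterpart of the one-way ANOVA
## variance decomposition, for heritability parameter-recovery tests.

## logistic mean curve evaluated at the schedule
.logisticCurve <- function(weeks, asymptote, rate, midpoint) {
  asymptote / (1 + exp(-rate * (weeks - midpoint)))
}

## apply the plateau / decline rules to a raw mean curve, visit by visit
.applyDynamicsRules <- function(raw, weeks, female, declining, param) {
  m <- numeric(length(raw))
  m[1] <- raw[1]
  for (j in seq_along(raw)[-1]) {
    delta <- raw[j] - raw[j - 1]
    if (female && weeks[j] > param@femalePlateauWeek)
      delta <- delta * param@plateauFactor
    if (declining && weeks[j] > param@maleDeclineWeek)
      delta <- -param@declinePerVisit
    m[j] <- m[j - 1] + delta
  }
  m
}

#' Simulate a longitudinal body-weight cohort
#'
#' Generates one [BWCohort-class] under the model described in
#' [TrajectorySimParam-class]: each animal's asymptote is
#' `baselineAsymptote + b_line + genotype * g_line + male * sexEffect + u_i`
#' with `b_line ~ N(0, sigmaLine^2)`, `g_line ~ N(genotypeMain, sigmaGxL^2)`
#' drawn once per line (so lines can gain or lose weight under the
#' mutation), and `u_i ~ N(0, sigmaIndividual^2)` per animal. The mean
#' trajectory is logistic in the week of age, modified visit-by-visit by the
#' female plateau and male decline rules; i.i.d.
#' `N(0, sigmaMeasurement^2)` noise is added per observation and weights are
#' floored at 1 g.
#'
#' Randomness uses one root seed split into per-line and per-mouse
#' substreams by [childSeed()], so adding a line does not reshuffle the
#' draws of existing mice.
#'
#' @param param A [TrajectorySimParam-class].
#' @return A [BWCohort-class]; deterministic for a fixed seed.
#' @export
#' @examples
#' co <- simulateCohort(TrajectorySimParam(micePerCell = 2L, seed = 7L))
#' co
setMethod("simulateCohort", "TrajectorySimParam", function(param) {
  methods::validObject(param)
  weeks <- param@schedule
  cells <- expand.grid(sex = c("F", "M"), genotype = c(0L, 1L),
                       stringsAsFactors = FALSE)
  ids <- character(0); lineV <- character(0)
  sexV <- character(0); genoV <- integer(0)
  cols <- list()
  for (ln in param@lineNames) {
    withr_seed <- childSeed(param@seed, paste0("line:", ln))
    set.seed(withr_seed)
    bLine <- stats::rnorm(1, 0, param@sigmaLine)
    gLine <- stats::rnorm(1, param@genotypeMain, param@sigmaGxL)
    declining <- ln %in% param@declineLine
    for (ci in seq_len(nrow(cells))) {
      sx <- cells$sex[ci]; gt <- cells$genotype[ci]
      for (j in seq_len(param@micePerCell)) {
        id <- sprintf("%s_%s_g%d_%02d", ln, sx, gt, j)
        set.seed(childSeed(param@seed, paste0("mouse:", id)))
        u <- stats::rnorm(1, 0, param@sigmaIndividual)
        asym <- param@baselineAsymptote + bLine + gt * gLine +
          (sx == "M") * param@sexEffect + u
        raw <- .logisticCurve(weeks, asym, param@baselineRate,
                              param@baselineMidpoint)
        m <- .applyDynamicsRules(raw, weeks, female = (sx == "F"),
                                 declining = declining && sx == "M", param)
        w <- m + stats::rnorm(length(weeks), 0, param@sigmaMeasurement)
        w <- pmax(w, 1)  # biological floor
        ids <- c(ids, id); lineV <- c(lineV, ln)
        sexV <- c(sexV, sx); genoV <- c(genoV, gt)
        cols[[id]] <- w
      }
    }
  }
  wm <- do.call(cbind, cols)
  BWCohort(wm, line = lineV, sex = sexV, genotype = genoV,
           mouseIds = ids, schedule = weeks)
})

#' Simulate grouped trait values for heritability recovery
#'
#' Draws `y_il = mu + b_l + e_il` with `b_l ~ N(0, Vg)` and
#' `e_il ~ N(0, Ve)`, the generative model whose broad-sense heritability is
#' `Vg / (Vg + Ve)`.
#'
#' @param param A [TraitSimParam-class].
#' @return A named list, one numeric vector of trait values per line;
#'   deterministic for a fixed seed.
#' @export
#' @examples
#' simulateTraitData(TraitSimParam(kGroups = 3, groupSizes = 4, seed = 1L))
setMethod("simulateTraitData", "TraitSimParam", function(param) {
  methods::validObject(param)
  k <- length(param@groupSizes)
  set.seed(param@seed)
  b <- stats::rnorm(k, 0, sqrt(param@Vg))
  groups <- vector("list", k)
  names(groups) <- sprintf("L%03d", seq_len(k))
  for (l in seq_len(k)) {
    groups[[l]] <- param@mu + b[l] +
      stats::rnorm(param@groupSizes[l], 0, sqrt(param@Ve))
  }
  groups
})
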