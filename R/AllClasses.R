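#' BWCohort: a longitudinal body-weight cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay `"bw"`
#' holds body weight in grams with one row per scheduled week of age and one
#' column per mouse. Per-mouse metadata (`line`, `sex`, `genotype`) lives in
#' `colData`; the measurement schedule is stored in `metadata(x)$schedule`
#' and mirrored by the assay rownames (`wk6`, `wk8`, ...).
#'
#' Missing weights (e.g. terminated animals) are `NA` and flag the record as
#' incomplete; all present weights must be strictly positive.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @export
setClass("BWCohort", contains = "SummarizedExperiment")

.validBWCohort <- function(object) {
  msg <- character()
  if (!"bw" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'bw' is required")
  sched <- S4Vectors::metadata(object)$schedule
  if (is.null(sched)) {
    msg <- c(msg, "metadata(x)$schedule is required")
  } else {
    if (any(diff(sched) <= 0))
      msg <- c(msg, "schedule must be strictly increasing")
    if (length(sched) != nrow(object))
      msg <- c(msg, "length(schedule) must equal nrow(x)")
  }
  cd <- SummarizedExperiment::colData(object)
  for (f in c("line", "sex", "genotype"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", f))
  if (ncol(object) > 0 && "sex" %in% colnames(cd) &&
      !all(cd$sex %in% c("F", "M")))
    msg <- c(msg, "sex must be 'F' or 'M'")
  if (ncol(object) > 0 && "genotype" %in% colnames(cd) &&
      !all(cd$genotype %in% c(0L, 1L)))
    msg <- c(msg, "genotype must be 0 (wild-type) or 1 (mutant)")
  ids <- colnames(object)
  if (ncol(object) > 0 && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "mouse ids (colnames) must be present and unique")
  if ("bw" %in% SummarizedExperiment::assayNames(object)) {
    bw <- SummarizedExperiment::assay(object, "bw")
    if (any(bw[!is.na(bw)] <= 0))
      msg <- c(msg, "all present weights must be > 0 grams")
  }
  if (length(msg)) msg else TRUE
}
setValidity("BWCohort", .validBWCohort)

#' Construct a BWCohort
#'
#' @param weights Numeric matrix of weights in grams, `length(schedule)` rows
#'   (weeks) by one column per mouse; `NA` marks a missing measurement.
#' @param line Character vector of CC line labels, one per mouse.
#' @param sex Character vector, `"F"` or `"M"`, one per mouse.
#' @param genotype Integer vector, `0` (wild-type) or `1` (mutant).
#' @param mouseIds Unique mouse identifiers; defaults to `colnames(weights)`.
#' @param schedule Integer weeks of age; defaults to [defaultSchedule()].
#' @return A [BWCohort-class] object.
#' @export
#' @examples
#' w <- matrix(20 + 1:28, nrow = 14,
#'             dimnames = list(NULL, c("m1", "m2")))
#' BWCohort(w, line = c("IL72", "IL72"), sex = c("F", "M"),
#'          genotype = c(0L, 1L))
BWCohort <- function(weights, line, sex, genotype,
                     mouseIds = colnames(weights),
                     schedule = defaultSchedule()) {
  weights <- as.matrix(weights)
  schedule <- checkScheduleWeeks(schedule)
  if (nrow(weights) != length(schedule))
    ccwStop("ccweight_invalid_config",
            "weights must have one row per schedule week (%d), got %d",
            length(schedule), nrow(weights))
  n <- ncol(weights)
  if (is.null(mouseIds)) mouseIds <- paste0("mouse", seq_len(n))
  dup <- mouseIds[duplicated(mouseIds)]
  if (length(dup))
    ccwStop("ccweight_invalid_data", "duplicate mouse_id: %s",
            paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(sex), c("F", "M"))
  if (length(bad))
    ccwStop("ccweight_invalid_data", "invalid sex code: %s",
            paste(bad, collapse = ", "))
  badg <- setdiff(unique(genotype), c(0, 1))
  if (length(badg))
    ccwStop("ccweight_invalid_data", "invalid genotype code: %s",
            paste(badg, collapse = ", "))
  dimnames(weights) <- list(paste0("wk", schedule), mouseIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bw = weights),
    colData = S4Vectors::DataFrame(
      line = as.character(line), sex = as.character(sex),
      genotype = as.integer(genotype), row.names = mouseIds),
    metadata = list(schedule = schedule))
  methods::new("BWCohort", se)
}

#' Parameters for the trajectory-mode cohort simulator
#'
#' Defaults emulate the design of a 10-line CC F1 knockout panel: roughly
#' 40 mice per line split over sex x genotype cells, a logistic mean growth
#' curve giving week-6 weights near 21 g and week-48 weights of roughly
#' 32-50 g across lines, a female plateau after week 40, and one line whose
#' males lose weight after week 32.
#'
#' @slot lineNames character; CC line labels.
#' @slot micePerCell integer; mice per line x sex x genotype cell.
#' @slot schedule integer; weeks of age at measurement.
#' @slot baselineAsymptote numeric; logistic asymptote (g).
#' @slot baselineRate numeric; logistic growth rate (1/week).
#' @slot baselineMidpoint numeric; logistic midpoint (week).
#' @slot sigmaLine numeric; SD of the line random effect on the asymptote (g).
#' @slot sigmaGxL numeric; SD of the line-specific genotype effect (g).
#' @slot genotypeMain numeric; mean mutant shift on the asymptote (g).
#' @slot sexEffect numeric; fixed male shift on the asymptote (g).
#' @slot femalePlateauWeek numeric; female mean increments after this week
#'   are multiplied by `plateauFactor` (use `Inf` to disable).
#' @slot plateauFactor numeric in `[0, 1]`.
#' @slot maleDeclineWeek numeric; after this week, males of `declineLine`
#'   lose `declinePerVisit` grams per visit (use `Inf` to disable).
#' @slot declineLine character; the designated declining line (may be empty).
#' @slot declinePerVisit numeric; grams lost per visit after the decline week.
#' @slot sigmaIndividual numeric; SD of the per-animal random effect (g).
#' @slot sigmaMeasurement numeric; SD of the per-observation noise (g).
#' @slot seed integer; root seed for the documented splitting scheme.
#' @export
setClass("TrajectorySimParam",
  representation(
    lineNames = "character", micePerCell = "integer", schedule = "integer",
    baselineAsymptote = "numeric", baselineRate = "numeric",
    baselineMidpoint = "numeric", sigmaLine = "numeric", sigmaGxL = "numeric",
    genotypeMain = "numeric", sexEffect = "numeric",
    femalePlateauWeek = "numeric", plateauFactor = "numeric",
    maleDeclineWeek = "numeric", declineLine = "character",
    declinePerVisit = "numeric", sigmaIndividual = "numeric",
    sigmaMeasurement = "numeric", seed = "integer"))

.validTrajectorySimParam <- function(object) {
  msg <- character()
  chkSd <- function(slot) {
    v <- methods::slot(object, slot)
    if (length(v) != 1L || is.na(v) || v < 0)
      msg <<- c(msg, sprintf("%s must be a single non-negative number", slot))
  }
  for (s in c("sigmaLine", "sigmaGxL", "sigmaIndividual", "sigmaMeasurement",
              "declinePerVisit")) chkSd(s)
  if (length(object@lineNames) < 1L || anyDuplicated(object@lineNames))
    msg <- c(msg, "lineNames must be non-empty and unique")
  if (length(object@micePerCell) != 1L || is.na(object@micePerCell) ||
      object@micePerCell < 1L)
    msg <- c(msg, "micePerCell must be >= 1")
  if (any(diff(object@schedule) <= 0) || length(object@schedule) < 2L)
    msg <- c(msg, "schedule must be strictly increasing")
  if (object@baselineAsymptote <= 0)
    msg <- c(msg, "baselineAsymptote must be > 0")
  if (object@baselineRate < 0)
    msg <- c(msg, "baselineRate must be >= 0")
  if (object@plateauFactor < 0 || object@plateauFactor > 1)
    msg <- c(msg, "plateauFactor must be in [0, 1]")
  if (length(object@declineLine) > 0L &&
      !all(object@declineLine %in% object@lineNames))
    msg <- c(msg, "declineLine must be one of lineNames")
  if (length(msg)) msg else TRUE
}
setValidity("TrajectorySimParam", .validTrajectorySimParam)

#' @rdname TrajectorySimParam-class
#' @param lineNames,micePerCell,schedule,baselineAsymptote,baselineRate,baselineMidpoint,sigmaLine,sigmaGxL,genotypeMain,sexEffect,femalePlateauWeek,plateauFactor,maleDeclineWeek,declineLine,declinePerVisit,sigmaIndividual,sigmaMeasurement,seed
#'   see the slot documentation.
#' @return A `TrajectorySimParam` object.
#' @export
#' @examples
#' TrajectorySimParam(micePerCell = 2L, seed = 1L)
TrajectorySimParam <- function(
    lineNames = c("IL72", "IL188", "IL2513", "IL2750", "IL3348",
                  "IL5000", "IL5008", "IL6009", "IL6012", "IL6018"),
    micePerCell = 10L,
    schedule = defaultSchedule(),
    baselineAsymptote = 42, baselineRate = 0.13, baselineMidpoint = 6,
    sigmaLine = 3, sigmaGxL = 2.5, genotypeMain = 1.5, sexEffect = 3,
    femalePlateauWeek = 40, plateauFactor = 0.15,
    maleDeclineWeek = 32, declineLine = "IL6018", declinePerVisit = 0.8,
    sigmaIndividual = 1.5, sigmaMeasurement = 0.5,
    seed = 1L) {
  declineLine <- intersect(declineLine, lineNames)
  methods::new("TrajectorySimParam",
    lineNames = as.character(lineNames),
    micePerCell = as.integer(micePerCell),
    schedule = as.integer(schedule),
    baselineAsymptote = baselineAsymptote, baselineRate = baselineRate,
    baselineMidpoint = baselineMidpoint,
    sigmaLine = sigmaLine, sigmaGxL = sigmaGxL,
    genotypeMain = genotypeMain, sexEffect = sexEffect,
    femalePlateauWeek = femalePlateauWeek, plateauFactor = plateauFactor,
    maleDeclineWeek = maleDeclineWeek, declineLine = declineLine,
    declinePerVisit = declinePerVisit,
    sigmaIndividual = sigmaIndividual, sigmaMeasurement = sigmaMeasurement,
    seed = as.integer(seed))
}

#' Parameters for the direct trait-mode simulator
#'
#' Generates grouped trait values `y_il = mu + b_l + e_il` with
#' `Var(b_l) = Vg` between lines and `Var(e_il) = Ve` within lines, the
#' generative counterpart of the broad-sense heritability decomposition
#' `H2 = Vg / (Vg + Ve)`.
#'
#' @slot groupSizes integer; per-line sample sizes (each >= 2).
#' @slot mu numeric; trait mean.
#' @slot Vg numeric; between-line variance (>= 0).
#' @slot Ve numeric; within-line variance (> 0).
#' @slot seed integer.
#' @export
setClass("TraitSimParam",
  representation(groupSizes = "integer", mu = "numeric",
                 Vg = "numeric", Ve = "numeric", seed = "integer"))

.validTraitSimParam <- function(object) {
  msg <- character()
  if (length(object@groupSizes) < 2L)
    msg <- c(msg, "at least 2 groups are required")
  if (any(object@groupSizes < 2L))
    msg <- c(msg, "every groupSizes entry must be >= 2")
  if (object@Vg < 0) msg <- c(msg, "Vg must be >= 0")
  if (object@Ve <= 0) msg <- c(msg, "Ve must be > 0")
  if (length(msg)) msg else TRUE
}
setValidity("TraitSimParam", .validTraitSimParam)

#' @rdname TraitSimParam-class
#' @param kGroups Number of lines; used when `groupSizes` is a scalar.
#' @param groupSizes Per-line sizes; a scalar is recycled to `kGroups`.
#' @param mu,Vg,Ve,seed see the slot documentation.
#' @return A `TraitSimParam` object.
#' @export
#' @examples
#' TraitSimParam(kGroups = 10, groupSizes = 8, Vg = 1, Ve = 1, seed = 3L)
TraitSimParam <- function(kGroups = 10L, groupSizes = 10L,
                          mu = 0, Vg = 1, Ve = 1, seed = 1L) {
  if (length(groupSizes) == 1L)
    groupSizes <- rep(as.integer(groupSizes), kGroups)
  methods::new("TraitSimParam", groupSizes = as.integer(groupSizes),
               mu = mu, Vg = Vg, Ve = Ve, seed = as.integer(seed))
}
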