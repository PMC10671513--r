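#' Accessors for BWCohort
#'
#' @param x A [BWCohort-class].
#' @return `schedule` returns the integer weeks of age; `weightMatrix` the
#'   weeks x mice weight matrix in grams; `mouseIds`, `mouseLine`,
#'   `mouseSex`, `mouseGenotype` per-mouse vectors; `isComplete` a logical
#'   per mouse (no missing weight); `completeCases` the subset cohort of
#'   complete records.
#' @name BWCohort-accessors
#' @aliases schedule weightMatrix mouseIds mouseLine mouseSex mouseGenotype
#'   isComplete completeCases
#' @examples
#' co <- simulateCohort(TrajectorySimParam(micePerCell = 1L, seed = 1L))
#' schedule(co)
#' dim(weightMatrix(co))
NULL

#' @rdname BWCohort-accessors
#' @export
setMethod("schedule", "BWCohort", function(x)
  S4Vectors::metadata(x)$schedule)

#' @rdname BWCohort-accessors
#' @export
setMethod("weightMatrix", "BWCohort", function(x)
  SummarizedExperiment::assay(x, "bw"))

#' @rdname BWCohort-accessors
#' @export
setMethod("mouseIds", "BWCohort", function(x) colnames(x))

#' @rdname BWCohort-accessors
#' @export
setMethod("mouseLine", "BWCohort", function(x)
  SummarizedExperiment::colData(x)$line)

#' @rdname BWCohort-accessors
#' @export
setMethod("mouseSex", "BWCohort", function(x)
  SummarizedExperiment::colData(x)$sex)

#' @rdname BWCohort-accessors
#' @export
setMethod("mouseGenotype", "BWCohort", function(x)
  SummarizedExperiment::colData(x)$genotype)

#' @rdname BWCohort-accessors
#' @export
setMethod("isComplete", "BWCohort", function(x)
  colSums(is.na(weightMatrix(x))) == 0L)

#' @rdname BWCohort-accessors
#' @export
setMethod("completeCases", "BWCohort", function(x) x[, isComplete(x)])

setMethod("show", "BWCohort", function(object) {
  sched <- schedule(object)
  cat("BWCohort:", ncol(object), "mice x", length(sched), "timepoints",
      sprintf("(weeks %d-%d)\n", min(sched), max(sched)))
  if (ncol(object) > 0) {
    cat("  lines:   ", paste(sort(unique(mouseLine(object))), collapse = ", "),
        "\n")
    cat("  sex:     ", sum(mouseSex(object) == "F"), "F /",
        sum(mouseSex(object) == "M"), "M\n")
    cat("  genotype:", sum(mouseGenotype(object) == 0L), "wild-type /",
        sum(mouseGenotype(object) == 1L), "mutant\n")
    inc <- sum(!isComplete(object))
    if (inc > 0) cat("  incomplete records:", inc, "\n")
  }
  invisible(object)
})

## internal: subset by line/sex/genotype (NULL = no restriction)
subsetCohort <- function(x, line = NULL, sex = NULL, genotype = NULL) {
  keep <- rep(TRUE, ncol(x))
  if (!is.null(line)) {
    if (!all(line %in% mouseLine(x)))
      ccwStop("ccweight_invalid_data", "line not present in cohort: %s",
              paste(setdiff(line, mouseLine(x)), collapse = ", "))
    keep <- keep & mouseLine(x) %in% line
  }
  if (!is.null(sex)) keep <- keep & mouseSex(x) %in% sex
  if (!is.null(genotype)) keep <- keep & mouseGenotype(x) %in% genotype
  x[, keep]
}
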