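#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @export
setGeneric("mouseIds", function(x) standardGeneric("mouseIds"))

#' @export
setGeneric("mouseLine", function(x) standardGeneric("mouseLine"))

#' @export
setGeneric("mouseSex", function(x) standardGeneric("mouseSex"))

#' @export
setGeneric("mouseGenotype", function(x) standardGeneric("mouseGenotype"))

#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @export
setGeneric("completeCases", function(x) standardGeneric("completeCases"))

#' @export
setGeneric("simulateCohort", function(param) standardGeneric("simulateCohort"))

#' @export
setGeneric("simulateTraitData",
           function(param) standardGeneric("simulateTraitData"))
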