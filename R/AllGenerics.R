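#' @rdname TimeCourseExperiment
#' @param x a `TimeCourseExperiment`.
#' @export
setGeneric("caseMatrix", function(x) standardGeneric("caseMatrix"))

#' @rdname TimeCourseExperiment
#' @export
setGeneric("controlMatrix", function(x) standardGeneric("controlMatrix"))

#' @rdname TimeCourseExperiment
#' @export
setGeneric("timeLabels", function(x) standardGeneric("timeLabels"))

#' @rdname TimeCourseExperiment
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' Module genes
#' @param x a `GeneModule`, `DNBScoreSeries` or `DominantGroup`.
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' Composite-index trajectory
#' @param x a `DNBScoreSeries`, `DominantGroup` or `BootstrapResult`.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Detected pre-transition index
#' @param x a `DNBScoreSeries` or `DominantGroup`.
#' @export
setGeneric("transitionIndex", function(x) standardGeneric("transitionIndex"))

#' Network accessors
#' @param x a `GeneNetwork`.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
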