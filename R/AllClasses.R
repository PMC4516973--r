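#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TimeCourseExperiment: case/control time-course expression data
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a fixed
#' `colData` contract: every sample carries a `group` (`"case"` or
#' `"control"`), an integer `time` index into the ordered time-point labels,
#' the corresponding `timeLabel`, and an integer `replicate` index. The
#' ordered labels themselves live in `metadata(x)$timePoints`.
#'
#' All DNB statistics are estimated from the case samples; the control
#' samples provide the stationary reference (differential-expression
#' filtering, optional SD normalisation).
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [TimeCourseExperiment()] for construction,
#'   [caseMatrix()], [controlMatrix()], [timeLabels()].
#' @export
setClass("TimeCourseExperiment", contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    need <- c("group", "time", "replicate")
    if (!all(need %in% colnames(cd)))
        return(sprintf("colData must contain columns: %s",
                       paste(need, collapse = ", ")))
    if (!all(cd$group %in% c("case", "control")))
        return("group must be 'case' or 'control'")
    tp <- S4Vectors::metadata(object)$timePoints
    if (is.null(tp) || !length(tp))
        return("metadata(x)$timePoints must hold the ordered time labels")
    if (!all(cd$time %in% seq_along(tp)))
        return("sample time indices must lie in 1..length(timePoints)")
    key <- paste(cd$group, cd$time, cd$replicate)
    if (anyDuplicated(key))
        return("each (group, time, replicate) triple must be unique")
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        return("gene identifiers (rownames) must be present and unique")
    a <- SummarizedExperiment::assay(object)
    if (anyNA(a))
        return("expression values must not contain NA after preprocessing")
    TRUE
})

#' Parameters of the near-bifurcation simulator
#'
#' Describes a case/control time course of `nGenes` genes over
#' `length(timePoints)` points with `replicates` case (and control) arrays per
#' point. A planted block of `nDNB` genes follows per-time-point schedules for
#' its SD multiplier (`sigmaSchedule`), intra-block Pearson correlation
#' (`rhoInSchedule`) and block-to-background correlation (`rhoOutSchedule`);
#' all three peak (in signal strength) at `tStar`, the planted pre-transition
#' point. The remaining genes are an uncorrelated stationary background with
#' SD `sigmaBackground`. The block-background coupling is planted against a
#' bounded neighbour subset of `nOutCoupled` background genes, because a
#' uniform coupling to an entire *uncorrelated* background cannot stay
#' positive semi-definite beyond a handful of genes (Schur bound
#' `nDNB * nOutCoupled * rhoOut^2 < 1 + (nDNB - 1) * rhoIn`). Case-group DNB genes additionally carry a constant
#' mean offset `meanShift` (expression units) so that they are differentially
#' expressed, as the response genes of a real perturbation are.
#'
#' @seealso [SimulationParams()] for validated construction with the default
#'   schedules, [simulateDNBDataset()].
#' @export
setClass("SimulationParams",
    representation(
        nGenes = "integer", nDNB = "integer",
        timePoints = "character", replicates = "integer",
        tStar = "integer",
        sigmaBackground = "numeric",
        sigmaSchedule = "numeric",
        rhoInSchedule = "numeric",
        rhoOutSchedule = "numeric",
        nOutCoupled = "integer",
        meanShift = "numeric",
        seed = "integer"))

setValidity("SimulationParams", function(object) {
    T <- length(object@timePoints)
    if (T < 1) return("at least one time point is required")
    if (length(object@sigmaSchedule) != T ||
        length(object@rhoInSchedule) != T ||
        length(object@rhoOutSchedule) != T)
        return("all schedules must have one entry per time point")
    if (object@tStar < 1L || object@tStar > T)
        return("tStar must index a time point")
    if (object@nDNB >= object@nGenes)
        return("nDNB must be smaller than nGenes")
    if (object@nDNB < 0L) return("nDNB must be >= 0")
    if (object@replicates < 2L)
        return("at least 2 replicates per time point are required")
    if (object@sigmaBackground <= 0) return("sigmaBackground must be > 0")
    if (any(object@sigmaSchedule <= 0)) return("sigmaSchedule must be > 0")
    if (any(object@rhoInSchedule < 0) || any(object@rhoInSchedule >= 1))
        return("rhoInSchedule must lie in [0, 1)")
    if (any(abs(object@rhoOutSchedule) >= 1))
        return("rhoOutSchedule must lie in (-1, 1)")
    if (object@nDNB > 1L &&
        any(object@rhoInSchedule <= -1 / (object@nDNB - 1)))
        return("rhoInSchedule violates the compound-symmetry PSD bound")
    if (object@nOutCoupled < 0L ||
        object@nOutCoupled > object@nGenes - object@nDNB)
        return("nOutCoupled must lie in [0, nGenes - nDNB]")
    if (object@nDNB > 0L && object@nOutCoupled > 0L) {
        bound <- 1 + (object@nDNB - 1) * object@rhoInSchedule -
            object@rhoOutSchedule^2 * object@nDNB * object@nOutCoupled
        if (any(bound <= 0))
            return(sprintf(
                "rhoOutSchedule makes the covariance non-PSD at time point %d (reduce |rhoOut| or nOutCoupled)",
                which(bound <= 0)[1L]))
    }
    ts <- object@tStar
    if (which.max(object@sigmaSchedule) != ts)
        return("sigmaSchedule must attain its maximum at tStar")
    if (which.max(object@rhoInSchedule) != ts)
        return("rhoInSchedule must attain its maximum at tStar")
    if (which.min(abs(object@rhoOutSchedule)) != ts)
        return("rhoOutSchedule must attain its minimum magnitude at tStar")
    TRUE
})

#' Planted ground truth of a simulated dataset
#'
#' @slot dnbGenes character, identifiers of the planted DNB genes.
#' @slot tStar integer, the planted pre-transition time index.
#' @export
setClass("PlantedTruth",
    representation(dnbGenes = "character", tStar = "integer"))

#' A candidate or dominant gene module
#'
#' @slot genes character, the member gene identifiers (at least 2).
#' @slot clusterId integer, id of the originating cluster (NA if not from
#'   clustering).
#' @slot timeIndex integer, time point at which the module was selected
#'   (NA if not time-specific).
#' @export
setClass("GeneModule",
    representation(genes = "character", clusterId = "integer",
                   timeIndex = "integer"))

setValidity("GeneModule", function(object) {
    if (length(object@genes) < 2L) return("a module needs at least 2 genes")
    if (anyDuplicated(object@genes)) return("module genes must be unique")
    TRUE
})

#' Per-time-point DNB statistics of one module
#'
#' `sdIn` is the mean per-gene sample SD of the module genes (expression
#' units); `pccIn` the mean absolute Pearson correlation over within-module
#' gene pairs; `pccOut` the mean absolute Pearson correlation over
#' module-by-outside pairs; `ci` the composite index
#' `sdIn * pccIn / max(pccOut, 1e-3)`. `nZeroVar` counts zero-variance genes
#' whose correlations were set to 0.
#'
#' @export
setClass("ModuleStats",
    representation(sdIn = "numeric", pccIn = "numeric", pccOut = "numeric",
                   ci = "numeric", nSamples = "integer",
                   nZeroVar = "integer"))

setValidity("ModuleStats", function(object) {
    if (object@sdIn < 0) return("sdIn must be >= 0")
    if (object@pccIn < -1e-12 || object@pccIn > 1 + 1e-12)
        return("pccIn must lie in [0, 1]")
    if (object@pccOut < -1e-12 || object@pccOut > 1 + 1e-12)
        return("pccOut must lie in [0, 1]")
    if (object@ci < 0) return("ci must be >= 0")
    TRUE
})

#' Composite-index trajectory of one module
#'
#' @slot module the scored [GeneModule-class].
#' @slot stats data.frame with one row per time point: `time`, `timeLabel`,
#'   `sdIn`, `pccIn`, `pccOut`, `ci`, `nSamples`.
#' @slot window integer, window half-width used for estimation.
#' @slot transitionIndex integer, detected pre-transition time index
#'   (NA if none detected / detection not yet run).
#' @export
setClass("DNBScoreSeries",
    representation(module = "GeneModule", stats = "data.frame",
                   window = "integer", transitionIndex = "integer"))

setValidity("DNBScoreSeries", function(object) {
    need <- c("time", "timeLabel", "sdIn", "pccIn", "pccOut", "ci",
              "nSamples")
    if (!all(need %in% colnames(object@stats)))
        return(sprintf("stats must contain columns: %s",
                       paste(need, collapse = ", ")))
    ti <- object@transitionIndex
    if (!is.na(ti) && (ti < 1L || ti > nrow(object@stats)))
        return("transitionIndex out of range")
    TRUE
})

#' Result of dominant-group selection
#'
#' `found = FALSE` encodes the explicit "no DNB found" outcome (no candidate
#' module of the minimum size anywhere in the time course); `module` and
#' `series` are only meaningful when `found` is TRUE. `searchLog` records,
#' per time point, how many candidate modules were scored and the best
#' composite index among them.
#'
#' @export
setClass("DominantGroup",
    representation(found = "logical", module = "GeneModule",
                   series = "DNBScoreSeries", searchLog = "data.frame"))

#' Bootstrap null of size-matched random gene groups
#'
#' @slot nullSeries list of [DNBScoreSeries-class], one per random group.
#' @slot observed the observed module's score series, recomputed with the
#'   same settings as the null groups.
#' @slot exceedance fraction of null groups whose maximum score reaches or
#'   exceeds the observed maximum.
#' @slot seed integer seed used to draw the groups.
#' @export
setClass("BootstrapResult",
    representation(nullSeries = "list", observed = "DNBScoreSeries",
                   exceedance = "numeric", seed = "integer"))

setValidity("BootstrapResult", function(object) {
    if (object@exceedance < 0 || object@exceedance > 1)
        return("exceedance must lie in [0, 1]")
    TRUE
})

#' An undirected simple gene-interaction network
#'
#' @slot nodes character, all gene identifiers (superset of edge endpoints).
#' @slot edges 2-column character matrix of unordered gene pairs.
#' @export
setClass("GeneNetwork",
    representation(nodes = "character", edges = "matrix"))

setValidity("GeneNetwork", function(object) {
    e <- object@edges
    if (ncol(e) != 2L) return("edges must be a 2-column matrix")
    if (nrow(e)) {
        if (any(e[, 1L] == e[, 2L])) return("self-loops are not allowed")
        key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
        if (anyDuplicated(key)) return("duplicate edges are not allowed")
        if (!all(as.vector(e) %in% object@nodes))
            return("all edge endpoints must be nodes")
    }
    TRUE
})
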