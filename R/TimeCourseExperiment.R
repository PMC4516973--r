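#' Construct a TimeCourseExperiment from case and control matrices
#'
#' @param case numeric matrix, genes x case samples. Column names of the form
#'   `t<time>_r<replicate>` (e.g. `t3_r1`) are parsed automatically;
#'   otherwise supply `caseTime`/`caseRep`.
#' @param control numeric matrix over the same genes (same rownames, same
#'   order) for the control group. Column-name convention as for `case`.
#' @param timePoints character, ordered time-point labels; the number of
#'   time points T is `length(timePoints)`.
#' @param caseTime,caseRep,controlTime,controlRep optional integer vectors
#'   assigning each column to a time index in `1..T` and a replicate index;
#'   required when the column names do not follow the `t<k>_r<j>` scheme.
#' @return a [TimeCourseExperiment-class].
#' @examples
#' g <- paste0("G", 1:4)
#' m <- matrix(rnorm(4 * 6), 4, dimnames = list(g, paste0(
#'   "t", rep(1:3, each = 2), "_r", rep(1:2, 3))))
#' tce <- TimeCourseExperiment(m, m, timePoints = c("0h", "1h", "2h"))
#' caseMatrix(tce)
#' @export
TimeCourseExperiment <- function(case, control, timePoints,
                                 caseTime = NULL, caseRep = NULL,
                                 controlTime = NULL, controlRep = NULL) {
    if (!identical(rownames(case), rownames(control)))
        stop("case and control must share identical, identically ordered gene ids")
    cs <- .sampleAssignment(case, caseTime, caseRep, "case")
    ct <- .sampleAssignment(control, controlTime, controlRep, "control")
    expr <- cbind(case, control)
    colnames(expr) <- make.unique(c(
        paste0("case_t", cs$time, "_r", cs$rep),
        paste0("ctrl_t", ct$time, "_r", ct$rep)))
    cd <- S4Vectors::DataFrame(
        group = rep(c("case", "control"), c(ncol(case), ncol(control))),
        time = c(cs$time, ct$time),
        timeLabel = timePoints[c(cs$time, ct$time)],
        replicate = c(cs$rep, ct$rep),
        row.names = colnames(expr))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = expr), colData = cd)
    S4Vectors::metadata(se)$timePoints <- timePoints
    new("TimeCourseExperiment", se)
}

.sampleAssignment <- function(mat, time, rep, what) {
    if (is.null(time)) {
        cn <- colnames(mat)
        if (is.null(cn) || !all(grepl("^t[0-9]+_r[0-9]+$", cn)))
            stop(what, " columns need t<k>_r<j> names or explicit time/rep vectors")
        time <- as.integer(sub("^t([0-9]+)_r[0-9]+$", "\\1", cn))
        rep <- as.integer(sub("^t[0-9]+_r([0-9]+)$", "\\1", cn))
    }
    if (is.null(rep)) rep <- stats::ave(time, time, FUN = seq_along)
    stopifnot(length(time) == ncol(mat), length(rep) == ncol(mat))
    list(time = as.integer(time), rep = as.integer(rep))
}

#' @rdname TimeCourseExperiment
#' @export
setMethod("caseMatrix", "TimeCourseExperiment", function(x) {
    SummarizedExperiment::assay(x)[, x$group == "case", drop = FALSE]
})

#' @rdname TimeCourseExperiment
#' @export
setMethod("controlMatrix", "TimeCourseExperiment", function(x) {
    SummarizedExperiment::assay(x)[, x$group == "control", drop = FALSE]
})

#' @rdname TimeCourseExperiment
#' @export
setMethod("timeLabels", "TimeCourseExperiment", function(x)
    S4Vectors::metadata(x)$timePoints)

#' @rdname TimeCourseExperiment
#' @export
setMethod("nTimePoints", "TimeCourseExperiment", function(x)
    length(S4Vectors::metadata(x)$timePoints))

setMethod("show", "TimeCourseExperiment", function(object) {
    cat(sprintf(
        "TimeCourseExperiment: %d genes, %d time points (%d case / %d control samples)\n",
        nrow(object), nTimePoints(object),
        sum(object$group == "case"), sum(object$group == "control")))
    callNextMethod()
})
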