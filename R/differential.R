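#' Welch differential-expression pre-filter
#'
#' The DNB score is insensitive for genes that do not respond to the
#' perturbation at all, so genes are pre-filtered by a per-gene two-sample
#' Welch test of case versus control expression. By default all case
#' samples are pooled against all control samples; `perTime = TRUE` instead
#' tests each time point's case replicates against the full control pool
#' and keeps a gene if any time point is significant after Bonferroni
#' correction across time points.
#'
#' @param dataset a [TimeCourseExperiment-class] with at least 2 control
#'   samples.
#' @param alpha significance level in (0, 1).
#' @param perTime test per time point instead of pooling across time.
#' @return character vector of retained gene ids (a subset of
#'   `rownames(dataset)`, in dataset order).
#' @export
differentialFilter <- function(dataset, alpha = 0.05, perTime = FALSE) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
        alpha >= 1)
        stop("alpha must lie strictly between 0 and 1", call. = FALSE)
    ctrl <- controlMatrix(dataset)
    if (ncol(ctrl) < 2L)
        stop("at least 2 control samples are required", call. = FALSE)
    if (!perTime) {
        p <- .welchRows(caseMatrix(dataset), ctrl)
        return(rownames(dataset)[p < alpha])
    }
    T <- nTimePoints(dataset)
    caseTime <- dataset$time[dataset$group == "case"]
    cs <- caseMatrix(dataset)
    pmin <- rep(1, nrow(dataset))
    for (t in seq_len(T)) {
        sub <- cs[, caseTime == t, drop = FALSE]
        if (ncol(sub) < 2L) next
        pmin <- pmin(pmin, .welchRows(sub, ctrl))
    }
    rownames(dataset)[pmin * T < alpha]
}

## vectorised per-row Welch t-test p-values
.welchRows <- function(x, y) {
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- matrixStats::rowVars(x); vy <- matrixStats::rowVars(y)
    se2 <- vx / nx + vy / ny
    tt <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    # degenerate rows: both groups constant
    p[se2 == 0] <- ifelse(mx[se2 == 0] == my[se2 == 0], 1, 0)
    p
}
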