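#' Case-sample window around a time point
#'
#' Collects the case replicates of all time points within `w` of `t`
#' (truncated at the ends of the course). With `w = 0` only the replicates
#' of `t` itself are used; widening the window trades temporal resolution
#' for estimation stability, which matters for series with one array per
#' point.
#'
#' @param dataset a [TimeCourseExperiment-class].
#' @param t 1-based time index.
#' @param w window half-width (number of neighbouring time points on each
#'   side).
#' @return genes x samples matrix; `ncol()` is the effective sample count.
#' @export
windowSamples <- function(dataset, t, w = 1L) {
    T <- nTimePoints(dataset)
    stopifnot(t >= 1L, t <= T, w >= 0L)
    keep <- dataset$group == "case" &
        dataset$time >= max(1L, t - w) & dataset$time <= min(T, t + w)
    m <- SummarizedExperiment::assay(dataset)[, keep, drop = FALSE]
    if (ncol(m) < 3L)
        stop("only ", ncol(m), " case sample(s) fall in the window at time ",
             t, "; increase the window half-width w or provide more ",
             "replicates (>= 3 samples are needed)", call. = FALSE)
    m
}

#' Per-gene sample standard deviation
#'
#' @param samples genes x samples matrix with at least 3 columns.
#' @return named numeric vector of sample SDs (denominator n - 1).
#' @export
geneSD <- function(samples) {
    stopifnot(ncol(samples) >= 3L)
    stats::setNames(matrixStats::rowSds(samples), rownames(samples))
}

#' Pearson correlation matrix over genes
#'
#' Symmetric with unit diagonal. Genes with zero variance in the window
#' cannot carry correlation information; their rows/columns are set to 0
#' (diagonal kept at 1) and their count is attached as attribute
#' `nZeroVar`.
#'
#' @param samples genes x samples matrix with at least 3 columns.
#' @return gene x gene correlation matrix.
#' @export
pccMatrix <- function(samples) {
    stopifnot(ncol(samples) >= 3L)
    R <- suppressWarnings(stats::cor(t(samples)))
    zv <- matrixStats::rowSds(samples) == 0
    if (any(zv)) {
        R[zv, ] <- 0
        R[, zv] <- 0
    }
    diag(R) <- 1
    structure(R, nZeroVar = sum(zv))
}

#' Composite DNB index of a module at one window
#'
#' Evaluates the three DNB conditions on a sample window and combines them:
#' `sdIn` (fluctuation) is the mean per-gene sample SD over module genes;
#' `pccIn` (internal correlation) the mean absolute Pearson correlation over
#' all within-module pairs; `pccOut` (external correlation) the mean
#' absolute Pearson correlation over all module-by-outside pairs; and the
#' composite index is
#' \deqn{I = \mathrm{SD}_{in} \cdot \mathrm{PCC}_{in} /
#'       \max(\mathrm{PCC}_{out}, \epsilon)}
#' with \eqn{\epsilon = 10^{-3}} guarding the division. A rising `I` means
#' the module fluctuates more, coheres more, and decouples from the rest —
#' the joint signature of an approaching critical transition. Zero-variance
#' genes contribute correlation 0 (their count is reported in `nZeroVar`).
#'
#' @param module a [GeneModule-class] or character vector of >= 2 gene ids.
#' @param samples genes x samples window matrix covering the universe.
#' @param universe character, the gene universe to compute `pccOut` against;
#'   defaults to all rows of `samples`. Must leave at least one
#'   outside gene.
#' @return a [ModuleStats-class].
#' @examples
#' m <- matrix(rnorm(6 * 8), 6, dimnames = list(paste0("G", 1:6), NULL))
#' compositeIndex(paste0("G", 1:3), m)
#' @export
compositeIndex <- function(module, samples, universe = rownames(samples)) {
    genes <- if (is(module, "GeneModule")) module@genes else module
    if (length(genes) < 2L)
        stop("a module of at least 2 genes is required (pccIn is undefined ",
             "for fewer)", call. = FALSE)
    if (!all(genes %in% universe))
        stop("module genes must be contained in the universe", call. = FALSE)
    outside <- setdiff(universe, genes)
    if (!length(outside))
        stop("the universe must contain at least one non-module gene",
             call. = FALSE)
    stopifnot(all(universe %in% rownames(samples)), ncol(samples) >= 3L)

    m <- length(genes)
    modMat <- samples[genes, , drop = FALSE]
    uniMat <- samples[universe, , drop = FALSE]
    sds <- matrixStats::rowSds(uniMat)
    zv <- sds == 0
    A <- abs(suppressWarnings(stats::cor(t(modMat), t(uniMat))))
    A[is.na(A)] <- 0

    inBlock <- A[, match(genes, universe), drop = FALSE]
    pccIn <- (sum(inBlock) - sum(diag(inBlock))) / (m * (m - 1L))
    outBlock <- A[, match(outside, universe), drop = FALSE]
    pccOut <- mean(outBlock)
    sdIn <- mean(sds[match(genes, universe)])
    new("ModuleStats", sdIn = sdIn, pccIn = pccIn, pccOut = pccOut,
        ci = sdIn * pccIn / max(pccOut, 1e-3),
        nSamples = ncol(samples), nZeroVar = sum(zv))
}

setMethod("show", "ModuleStats", function(object) {
    cat(sprintf(
        "ModuleStats: sdIn=%.4g  pccIn=%.4g  pccOut=%.4g  ci=%.4g (n=%d)\n",
        object@sdIn, object@pccIn, object@pccOut, object@ci,
        object@nSamples))
    if (object@nZeroVar > 0L)
        cat(sprintf("  %d zero-variance gene(s) contributed correlation 0\n",
                    object@nZeroVar))
})
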