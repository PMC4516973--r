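#' Composite-index trajectory of a module over the time course
#'
#' Evaluates [compositeIndex()] at every time point on the sliding window
#' of case samples ([windowSamples()]).
#'
#' @param module a [GeneModule-class] or character vector of gene ids.
#' @param dataset a [TimeCourseExperiment-class].
#' @param w window half-width passed to [windowSamples()].
#' @param universe gene universe for the external-correlation term;
#'   defaults to all genes of the dataset.
#' @return a [DNBScoreSeries-class] (transition index not yet set; see
#'   [detectTransition()]).
#' @export
scoreSeries <- function(module, dataset, w = 1L,
                        universe = rownames(dataset)) {
    mod <- if (is(module, "GeneModule")) module else
        new("GeneModule", genes = module, clusterId = NA_integer_,
            timeIndex = NA_integer_)
    if (!all(mod@genes %in% rownames(dataset)))
        stop("module genes must be present in the dataset", call. = FALSE)
    T <- nTimePoints(dataset)
    rows <- lapply(seq_len(T), function(t) {
        win <- windowSamples(dataset, t, w)
        st <- compositeIndex(mod, win, universe)
        data.frame(time = t, timeLabel = timeLabels(dataset)[t],
                   sdIn = st@sdIn, pccIn = st@pccIn, pccOut = st@pccOut,
                   ci = st@ci, nSamples = st@nSamples)
    })
    new("DNBScoreSeries", module = mod, stats = do.call(rbind, rows),
        window = as.integer(w), transitionIndex = NA_integer_)
}

#' Detect the pre-transition point in a score trajectory
#'
#' Flags the series maximum as the pre-transition point when it stands out
#' from the rest of the trajectory: the maximum must exceed the mean of the
#' remaining scores by at least `k` of their standard deviations. Ties in
#' the maximum resolve to the earliest time point (an earlier warning is
#' preferred).
#'
#' @param series a [DNBScoreSeries-class] with at least 4 time points.
#' @param k threshold multiplier (default 2).
#' @return the input series with `transitionIndex` set to the detected
#'   1-based index, or `NA` if no point stands out.
#' @export
detectTransition <- function(series, k = 2) {
    stopifnot(is(series, "DNBScoreSeries"))
    sc <- series@stats$ci
    if (length(sc) < 4L)
        stop("at least 4 time points are required", call. = FALSE)
    i <- which.max(sc)
    rest <- sc[-i]
    fired <- sc[i] > mean(rest) + k * stats::sd(rest)
    series@transitionIndex <- if (isTRUE(fired)) as.integer(i) else
        NA_integer_
    series
}

#' Identify the dominant DNB group of a time course
#'
#' At every time point, genes passing the differential-expression filter are
#' clustered on the window's absolute Pearson correlation
#' ([clusterCandidates()]) and every candidate module of at least `minSize`
#' genes is scored with the composite index against the filtered universe.
#' The dominant group is the module attaining the global maximum composite
#' index over all (module, time) pairs, ties resolved toward the earliest
#' time point. Its full trajectory is then computed and transition detection
#' applied.
#'
#' When a [GeneNetwork-class] is supplied, candidate modules are first
#' intersected with the network's nodes and must be connected within the
#' union of network edges and strong correlation edges (`|PCC| >= 0.8` in
#' the window); disconnected candidates are split into their connected
#' components.
#'
#' @param dataset a [TimeCourseExperiment-class].
#' @param w window half-width.
#' @param cut clustering tree-cut dissimilarity.
#' @param alpha significance level of the Welch differential-expression
#'   pre-filter ([differentialFilter()]); `NULL` skips the filter (use when
#'   the dataset is already filtered).
#' @param minSize smallest module considered for dominance (default 5, to
#'   avoid spurious high-scoring pairs).
#' @param network optional [GeneNetwork-class] constraining candidates.
#' @param k transition-detection threshold multiplier.
#' @return a [DominantGroup-class]; `found` is `FALSE` when no candidate of
#'   the minimum size exists anywhere ("no DNB found").
#' @examples
#' sim <- simulateDNBDataset(SimulationParams(nGenes = 120, nDNB = 12,
#'                                            replicates = 5, seed = 3))
#' res <- selectDominantGroup(sim$dataset, alpha = 0.05)
#' if (res@found) moduleGenes(res)
#' @export
selectDominantGroup <- function(dataset, w = 1L, cut = 0.5, alpha = 0.05,
                                minSize = 5L, network = NULL, k = 2) {
    genes <- if (is.null(alpha)) rownames(dataset) else
        differentialFilter(dataset, alpha)
    emptyMod <- new("GeneModule", genes = c(".none.1", ".none.2"),
                    clusterId = NA_integer_, timeIndex = NA_integer_)
    emptySeries <- new("DNBScoreSeries", module = emptyMod,
                       stats = data.frame(time = integer(), timeLabel =
                           character(), sdIn = numeric(), pccIn = numeric(),
                           pccOut = numeric(), ci = numeric(),
                           nSamples = integer()),
                       window = as.integer(w),
                       transitionIndex = NA_integer_)
    noDNB <- function(log) new("DominantGroup", found = FALSE,
                               module = emptyMod, series = emptySeries,
                               searchLog = log)
    if (length(genes) < minSize + 1L)
        return(noDNB(data.frame(time = integer(), nModules = integer(),
                                bestCI = numeric())))

    T <- nTimePoints(dataset)
    best <- NULL; bestCI <- -Inf
    log <- vector("list", T)
    for (t in seq_len(T)) {
        win <- windowSamples(dataset, t, w)[genes, , drop = FALSE]
        corr <- pccMatrix(win)
        mods <- clusterCandidates(corr, cut = cut, minSize = 2L,
                                  timeIndex = t)
        if (!is.null(network))
            mods <- .applyNetworkConstraint(mods, network, corr, t)
        mods <- Filter(function(m) length(m@genes) >= minSize, mods)
        cis <- vapply(mods, function(m)
            compositeIndex(m, win, universe = genes)@ci, numeric(1))
        log[[t]] <- data.frame(time = t, nModules = length(mods),
                               bestCI = if (length(cis)) max(cis) else NA_real_)
        if (length(cis) && max(cis) > bestCI) {   # strict ">": earliest wins
            bestCI <- max(cis)
            best <- mods[[which.max(cis)]]
        }
    }
    log <- do.call(rbind, log)
    if (is.null(best)) return(noDNB(log))
    series <- detectTransition(
        scoreSeries(best, dataset, w = w, universe = genes), k = k)
    new("DominantGroup", found = TRUE, module = best, series = series,
        searchLog = log)
}

## split candidates into components of the (network + strong correlation)
## union graph restricted to network nodes
.applyNetworkConstraint <- function(mods, network, corr, timeIndex,
                                    corThreshold = 0.8) {
    out <- list()
    for (m in mods) {
        genes <- intersect(m@genes, network@nodes)
        if (length(genes) < 2L) next
        A <- abs(corr[genes, genes, drop = FALSE]) >= corThreshold
        diag(A) <- FALSE
        g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
        e <- network@edges
        keep <- e[, 1L] %in% genes & e[, 2L] %in% genes
        if (any(keep))
            g <- igraph::add_edges(g, t(matrix(match(e[keep, , drop = FALSE],
                                                     genes), ncol = 2)))
        comp <- igraph::components(g)
        for (cid in seq_len(comp$no)) {
            cg <- genes[comp$membership == cid]
            if (length(cg) >= 2L)
                out[[length(out) + 1L]] <- new("GeneModule", genes = cg,
                    clusterId = m@clusterId, timeIndex = as.integer(timeIndex))
        }
    }
    out
}

#' @rdname scores
#' @export
setMethod("scores", "DNBScoreSeries", function(x) x@stats)

#' @rdname moduleGenes
#' @export
setMethod("moduleGenes", "DNBScoreSeries", function(x) x@module@genes)

#' @rdname transitionIndex
#' @export
setMethod("transitionIndex", "DNBScoreSeries", function(x)
    x@transitionIndex)

#' @rdname scores
#' @export
setMethod("scores", "DominantGroup", function(x) x@series@stats)

#' @rdname moduleGenes
#' @export
setMethod("moduleGenes", "DominantGroup", function(x) x@module@genes)

#' @rdname transitionIndex
#' @export
setMethod("transitionIndex", "DominantGroup", function(x)
    x@series@transitionIndex)

setMethod("show", "DNBScoreSeries", function(object) {
    s <- object@stats
    cat(sprintf(
        "DNBScoreSeries: %d-gene module over %d time points (w=%d)\n",
        length(object@module@genes), nrow(s), object@window))
    if (nrow(s)) {
        i <- which.max(s$ci)
        cat(sprintf("  peak ci %.4g at time %d (%s); transition: %s\n",
                    s$ci[i], s$time[i], s$timeLabel[i],
                    ifelse(is.na(object@transitionIndex), "none detected",
                           sprintf("time %d (%s)", object@transitionIndex,
                                   s$timeLabel[object@transitionIndex]))))
    }
})

setMethod("show", "DominantGroup", function(object) {
    if (!object@found) {
        cat("DominantGroup: no DNB found\n")
    } else {
        cat(sprintf("DominantGroup: %d genes selected at time %s\n",
                    length(object@module@genes),
                    ifelse(is.na(object@module@timeIndex), "-",
                           object@module@timeIndex)))
        show(object@series)
    }
})
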