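#' Bootstrap null of size-matched random gene groups
#'
#' Draws `nGroups` gene sets of the same size as the observed module,
#' uniformly without replacement from the universe excluding the module,
#' and scores each exactly as the observed module (same window half-width
#' and scoring universe). To make the comparison apples-to-apples, the
#' observed module is re-scored with the same settings. The `exceedance`
#' is the fraction of null groups whose maximum score reaches or exceeds
#' the observed maximum — an empirical tail probability for the claim that
#' the observed trajectory stands out.
#'
#' @param dataset a [TimeCourseExperiment-class].
#' @param observed the observed module's [DNBScoreSeries-class] (as from
#'   [scoreSeries()] or [selectDominantGroup()]).
#' @param nGroups number of random groups (>= 1).
#' @param seed integer seed driving the draws.
#' @param universe gene pool to draw from and to score against; defaults to
#'   all measured genes. Supply the differential-expression-filtered set to
#'   restrict the null to responsive genes.
#' @return a [BootstrapResult-class].
#' @export
bootstrapNull <- function(dataset, observed, nGroups = 10L, seed = 1L,
                          universe = rownames(dataset)) {
    stopifnot(is(observed, "DNBScoreSeries"), nGroups >= 1L)
    m <- length(observed@module@genes)
    pool <- setdiff(universe, observed@module@genes)
    if (length(pool) < m)
        stop("universe too small: ", length(pool), " non-module genes for ",
             "groups of size ", m, call. = FALSE)
    w <- observed@window
    obs <- scoreSeries(observed@module, dataset, w = w, universe = universe)
    set.seed(seed)
    nullSeries <- lapply(seq_len(nGroups), function(i)
        scoreSeries(sample(pool, m), dataset, w = w, universe = universe))
    nullMax <- vapply(nullSeries, function(s) max(s@stats$ci), numeric(1))
    new("BootstrapResult", nullSeries = nullSeries, observed = obs,
        exceedance = mean(nullMax >= max(obs@stats$ci)),
        seed = as.integer(seed))
}

#' Per-time-point null envelope of a bootstrap result
#'
#' @param result a [BootstrapResult-class].
#' @param probs envelope quantiles.
#' @return data.frame with the observed trajectory and the null quantiles
#'   per time point (for plotting).
#' @export
nullEnvelope <- function(result, probs = c(0.05, 0.5, 0.95)) {
    nm <- vapply(result@nullSeries, function(s) s@stats$ci,
                 numeric(nrow(result@observed@stats)))
    q <- t(apply(as.matrix(nm), 1L, stats::quantile, probs = probs))
    colnames(q) <- paste0("null_q", format(100 * probs, trim = TRUE))
    cbind(result@observed@stats[, c("time", "timeLabel", "ci")], q)
}

setMethod("show", "BootstrapResult", function(object) {
    cat(sprintf(
        "BootstrapResult: %d null groups (size %d), exceedance = %.3f\n",
        length(object@nullSeries), length(object@observed@module@genes),
        object@exceedance))
})

#' @rdname scores
#' @export
setMethod("scores", "BootstrapResult", function(x) x@observed@stats)

#' Score a fixed gene list on another dataset
#'
#' Cross-dataset validation: a module identified on one dataset is scored,
#' unchanged, on an independent time course. Gene symbols are matched
#' case-insensitively; the number retained is reported via `message()` and
#' must reach `minSize`, and at least one measured gene must remain outside
#' the module.
#'
#' @param genes character, the fixed gene list.
#' @param dataset a [TimeCourseExperiment-class].
#' @param w window half-width.
#' @param minSize minimum number of matched genes required.
#' @param k transition-detection threshold multiplier.
#' @return a [DNBScoreSeries-class] with transition detection applied.
#' @export
crossScore <- function(genes, dataset, w = 1L, minSize = 5L, k = 2) {
    matched <- rownames(dataset)[toupper(rownames(dataset)) %in%
                                 toupper(genes)]
    message(length(matched), " of ", length(genes),
            " genes matched in the dataset")
    if (length(matched) < minSize)
        stop("only ", length(matched), " gene(s) of the fixed list are ",
             "measured in the dataset (minimum ", minSize, ")",
             call. = FALSE)
    if (length(matched) >= nrow(dataset))
        stop("the fixed list covers every measured gene; external ",
             "correlation is undefined", call. = FALSE)
    detectTransition(scoreSeries(matched, dataset, w = w), k = k)
}
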