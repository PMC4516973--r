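#' Candidate modules by correlation clustering
#'
#' Average-linkage hierarchical clustering of genes under the dissimilarity
#' `d = 1 - |PCC|`, cut at height `cut`; clusters below `minSize` members
#' (singletons by default) are discarded. The resulting modules are disjoint
#' by construction.
#'
#' @param corr gene x gene correlation matrix (as from [pccMatrix()]).
#' @param cut tree-cut dissimilarity in (0, 1]; genes whose average absolute
#'   correlation exceeds `1 - cut` end up together.
#' @param minSize smallest module size to keep (>= 2).
#' @param timeIndex optional time index recorded as module provenance.
#' @return list of [GeneModule-class], ordered by decreasing size.
#' @export
clusterCandidates <- function(corr, cut = 0.5, minSize = 2L,
                              timeIndex = NA_integer_) {
    if (!is.numeric(cut) || cut <= 0 || cut > 1)
        stop("cut must lie in (0, 1]", call. = FALSE)
    stopifnot(nrow(corr) == ncol(corr), minSize >= 2L)
    genes <- rownames(corr)
    if (length(genes) < 2L) return(list())
    d <- stats::as.dist(1 - abs(corr))
    cl <- stats::cutree(stats::hclust(d, method = "average"), h = cut)
    sizes <- table(cl)
    keep <- as.integer(names(sizes)[sizes >= minSize])
    mods <- lapply(keep, function(id)
        new("GeneModule", genes = genes[cl == id], clusterId = id,
            timeIndex = as.integer(timeIndex)))
    mods[order(vapply(mods, function(m) length(m@genes), 1L),
               decreasing = TRUE)]
}

#' @rdname moduleGenes
#' @export
setMethod("moduleGenes", "GeneModule", function(x) x@genes)

setMethod("show", "GeneModule", function(object) {
    cat(sprintf("GeneModule: %d genes (cluster %s, time %s)\n",
                length(object@genes),
                ifelse(is.na(object@clusterId), "-", object@clusterId),
                ifelse(is.na(object@timeIndex), "-", object@timeIndex)))
    cat("  ", paste(utils::head(object@genes, 8), collapse = ", "),
        if (length(object@genes) > 8) ", ..." else "", "\n", sep = "")
})
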