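#' Export a module's correlation network at one window
#'
#' Nodes are the module genes; edges connect pairs whose absolute Pearson
#' correlation in the window reaches `threshold`. GraphML output carries
#' the signed correlation as edge attribute `pcc` and the per-gene SD as
#' node attribute `sd`; SIF output carries the edge list only (the format
#' has no attribute slots).
#'
#' @param module a [GeneModule-class] or character vector of gene ids.
#' @param samples genes x samples window matrix covering the module.
#' @param threshold absolute-correlation edge threshold in (0, 1].
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @return the path, invisibly.
#' @export
exportModuleNetwork <- function(module, samples, threshold, path,
                                format = c("sif", "graphml")) {
    format <- match.arg(format)
    if (threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]", call. = FALSE)
    genes <- if (is(module, "GeneModule")) module@genes else module
    stopifnot(all(genes %in% rownames(samples)))
    sub <- samples[genes, , drop = FALSE]
    R <- pccMatrix(sub)
    A <- abs(R) >= threshold
    diag(A) <- FALSE
    idx <- which(A & upper.tri(A), arr.ind = TRUE)
    if (format == "sif") {
        net <- GeneNetwork(cbind(genes[idx[, 1L]], genes[idx[, 2L]]),
                           nodes = genes)
        writeSIF(net, path)
    } else {
        g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
        g <- igraph::set_vertex_attr(g, "name", value = genes)
        g <- igraph::set_vertex_attr(g, "sd", value = geneSD(sub))
        if (nrow(idx)) {
            g <- igraph::add_edges(g, as.vector(t(idx)))
            g <- igraph::set_edge_attr(g, "pcc",
                                       value = R[idx])
        }
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' Export per-time-point module networks
#'
#' Writes one network file per time point (Cytoscape-ready snapshots of
#' the module's dynamical rewiring), named
#' `module_network_t<index>.<ext>`.
#'
#' @param module a [GeneModule-class] or character vector of gene ids.
#' @param dataset a [TimeCourseExperiment-class].
#' @param dir output directory (created if needed).
#' @param w window half-width.
#' @param threshold absolute-correlation edge threshold.
#' @param format `"sif"` or `"graphml"`.
#' @param times time indices to export (default: all).
#' @return character vector of written paths, invisibly.
#' @export
exportModuleNetworks <- function(module, dataset, dir, w = 1L,
                                 threshold = 0.8,
                                 format = c("sif", "graphml"),
                                 times = seq_len(nTimePoints(dataset))) {
    format <- match.arg(format)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (format == "sif") "sif" else "graphml"
    paths <- vapply(times, function(t) {
        p <- file.path(dir, sprintf("module_network_t%02d.%s", t, ext))
        exportModuleNetwork(module, windowSamples(dataset, t, w),
                            threshold, p, format)
        p
    }, character(1))
    invisible(paths)
}
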