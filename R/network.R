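#' Construct a GeneNetwork from an edge table
#'
#' @param edges 2-column character matrix or data.frame of gene pairs.
#' @param nodes optional full node set (defaults to the edge endpoints).
#' @return a [GeneNetwork-class]; duplicate edges (in either orientation)
#'   are collapsed and self-loops dropped with a message.
#' @export
GeneNetwork <- function(edges, nodes = NULL) {
    e <- if (is.null(edges) || NROW(edges) == 0L)
        matrix(character(0), 0L, 2L)
    else as.matrix(edges)[, 1:2, drop = FALSE]
    mode(e) <- "character"
    loops <- e[, 1L] == e[, 2L]
    if (any(loops)) {
        message(sum(loops), " self-loop(s) dropped")
        e <- e[!loops, , drop = FALSE]
    }
    if (nrow(e)) {
        o <- e[, 1L] > e[, 2L]
        e[o, ] <- e[o, 2:1]
        e <- e[!duplicated(paste(e[, 1L], e[, 2L])), , drop = FALSE]
    }
    if (is.null(nodes)) nodes <- sort(unique(as.vector(e)))
    colnames(e) <- c("geneA", "geneB")
    new("GeneNetwork", nodes = as.character(nodes), edges = e)
}

#' Read a gene-interaction network
#'
#' Supports the SIF dialect (`geneA <tab-or-space> relation <...> geneB`,
#' possibly with several targets per line) and plain 2-column TSV edge
#' lists. The graph is simplified: duplicate edges are merged and
#' self-loops dropped (with a message reporting the count).
#'
#' @param path edge-list file.
#' @param format `"sif"` or `"tsv"`.
#' @return a [GeneNetwork-class].
#' @export
readNetwork <- function(path, format = c("sif", "tsv")) {
    format <- match.arg(format)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    edges <- if (format == "sif") {
        do.call(rbind, lapply(toks, function(f) {
            if (length(f) < 3L)
                stop("malformed SIF line: '", paste(f, collapse = " "),
                     "'", call. = FALSE)
            cbind(f[1L], f[3:length(f)])
        }))
    } else {
        do.call(rbind, lapply(toks, function(f) {
            if (length(f) < 2L)
                stop("malformed edge line", call. = FALSE)
            cbind(f[1L], f[2L])
        }))
    }
    GeneNetwork(edges)
}

#' Write a network as SIF
#'
#' @param network a [GeneNetwork-class].
#' @param path output file.
#' @param relation SIF relation tag (default `"pp"`).
#' @export
writeSIF <- function(network, path, relation = "pp") {
    e <- network@edges
    writeLines(if (nrow(e)) paste(e[, 1L], relation, e[, 2L], sep = "\t")
               else character(0), path)
    invisible(path)
}

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "GeneNetwork", function(x) x@nodes)

#' @rdname networkNodes
#' @export
setMethod("networkEdges", "GeneNetwork", function(x) x@edges)

setMethod("show", "GeneNetwork", function(object) {
    cat(sprintf("GeneNetwork: %d nodes, %d edges\n",
                length(object@nodes), nrow(object@edges)))
})
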