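#' Random toy network on a gene set
#'
#' Erdos-Renyi-style simple undirected graph with exactly
#' `floor(density * choose(n, 2))` edges, drawn uniformly among all pairs.
#'
#' @param geneIds character vector of at least 2 genes.
#' @param edgeDensity fraction of all possible pairs to realise, in (0, 1].
#' @param seed integer seed.
#' @return a [GeneNetwork-class] whose node set is `geneIds`.
#' @export
makeToyNetwork <- function(geneIds, edgeDensity, seed = 1L) {
    if (length(geneIds) < 2L)
        stop("at least 2 genes are required", call. = FALSE)
    if (edgeDensity < 0 || edgeDensity > 1)
        stop("edgeDensity must lie in [0, 1]", call. = FALSE)
    pairs <- t(utils::combn(geneIds, 2L))
    nEdges <- floor(edgeDensity * nrow(pairs))
    set.seed(seed)
    keep <- sample.int(nrow(pairs), nEdges)
    GeneNetwork(pairs[keep, , drop = FALSE], nodes = geneIds)
}

#' Gene-set fixture with one planted-enriched set
#'
#' Builds `nSets` gene sets over `universe`, exactly one of which (the
#' first, named `"planted_enriched"`) draws at least 80% of its members
#' from the planted DNB genes; the decoy sets are drawn from the
#' non-planted universe.
#'
#' @param universe character, the full gene universe.
#' @param planted a [PlantedTruth-class] or character vector of planted
#'   genes (subset of `universe`).
#' @param nSets number of sets (>= 1).
#' @param seed integer seed.
#' @param setSize size of each decoy set (default: planted size).
#' @return named list of character vectors (GMT-style collection).
#' @export
makeGmtFixture <- function(universe, planted, nSets, seed = 1L,
                           setSize = NULL) {
    genes <- if (is(planted, "PlantedTruth")) planted@dnbGenes else planted
    if (nSets < 1L) stop("nSets must be >= 1", call. = FALSE)
    if (!all(genes %in% universe))
        stop("planted genes must be contained in the universe",
             call. = FALSE)
    np <- length(genes)
    if (is.null(setSize)) setSize <- np
    rest <- setdiff(universe, genes)
    set.seed(seed)
    nIn <- ceiling(0.8 * np)
    enriched <- c(sample(genes, nIn),
                  if (np > nIn) sample(rest, np - nIn))
    sets <- list(planted_enriched = enriched)
    for (i in seq_len(nSets - 1L))
        sets[[sprintf("decoy_%02d", i)]] <-
            sample(rest, min(setSize, length(rest)))
    sets
}

#' Write a gene-set collection as GMT
#'
#' One set per line: name, description, then the tab-separated genes.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description per-set description column (recycled).
#' @export
writeGMT <- function(sets, path, description = "na") {
    stopifnot(length(sets) >= 1L, !is.null(names(sets)))
    writeLines(mapply(function(nm, g, d)
        paste(c(nm, d, g), collapse = "\t"),
        names(sets), sets, rep_len(description, length(sets))), path)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' Write a TimeCourseExperiment as TSV files
#'
#' Writes `case.tsv` and `control.tsv` (genes x samples, first column
#' `gene`, sample ids of the form `t<time>_r<replicate>`) plus
#' `time_points.txt` (one ordered label per line) into `dir`.
#'
#' @param dataset a [TimeCourseExperiment-class].
#' @param dir output directory (created if needed).
#' @export
writeDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dump <- function(m, cd, file) {
        colnames(m) <- paste0("t", cd$time, "_r", cd$replicate)
        df <- data.frame(gene = rownames(m), m, check.names = FALSE)
        utils::write.table(df, file.path(dir, file), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    cd <- SummarizedExperiment::colData(dataset)
    dump(caseMatrix(dataset), cd[cd$group == "case", ], "case.tsv")
    dump(controlMatrix(dataset), cd[cd$group == "control", ],
         "control.tsv")
    writeLines(timeLabels(dataset), file.path(dir, "time_points.txt"))
    invisible(dir)
}

#' Read a TSV dataset written by [writeDataset()]
#'
#' @param dir directory holding `case.tsv`, `control.tsv`,
#'   `time_points.txt`.
#' @return a [TimeCourseExperiment-class].
#' @export
readDataset <- function(dir) {
    slurp <- function(file) {
        df <- utils::read.delim(file.path(dir, file), check.names = FALSE,
                                row.names = 1L)
        as.matrix(df)
    }
    TimeCourseExperiment(slurp("case.tsv"), slurp("control.tsv"),
        timePoints = readLines(file.path(dir, "time_points.txt")))
}
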