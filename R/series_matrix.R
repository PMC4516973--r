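#' Read a GEO series-matrix expression table
#'
#' Parses the series-matrix dialect: `!`-prefixed metadata lines, with the
#' probe x sample expression block delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end`. Quoted fields
#' are unquoted; sample titles (from the `!Sample_title` line, if present)
#' and all metadata lines are preserved for design construction.
#'
#' @param path path to a series-matrix text file (uncompressed).
#' @return list with `exprs` (numeric probe x sample matrix), `sampleTitles`
#'   (character, or `NULL` when absent) and `metadata` (the raw `!` lines).
#' @export
readSeriesMatrix <- function(path) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    b <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    e <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
        stop("not a series-matrix file: missing or empty ",
             "!series_matrix_table_begin/!series_matrix_table_end block",
             call. = FALSE)
    meta <- grep("^!", lines, value = TRUE)
    meta <- setdiff(meta, lines[c(b, e)])

    block <- lines[(b + 1L):(e - 1L)]
    fields <- strsplit(block, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != nf[1L]))
        stop("ragged series-matrix table: line ",
             b + which(nf != nf[1L])[1L], " has ",
             nf[nf != nf[1L]][1L], " fields, expected ", nf[1L],
             call. = FALSE)
    unq <- function(x) gsub('^"|"$', "", x)
    header <- unq(fields[[1L]])
    body <- fields[-1L]
    exprs <- matrix(NA_real_, length(body), nf[1L] - 1L,
                    dimnames = list(vapply(body, function(f) unq(f[1L]),
                                           character(1)),
                                    header[-1L]))
    for (i in seq_along(body))
        exprs[i, ] <- suppressWarnings(as.numeric(body[[i]][-1L]))

    titleLine <- grep("^!Sample_title\\b", meta, value = TRUE)
    titles <- if (length(titleLine))
        unq(strsplit(titleLine[1L], "\t", fixed = TRUE)[[1L]][-1L])
    list(exprs = exprs, sampleTitles = titles, metadata = meta)
}

#' Read a probe-to-gene annotation table
#'
#' Accepts a plain 2-column TSV (probe, symbol) or the tab-table section of
#' a GEO SOFT platform file (delimited by `!platform_table_begin/_end`), in
#' which case the probe id column (`ID`) and a gene-symbol column are
#' located by name.
#'
#' @param path annotation file.
#' @param symbolColumn column name holding the gene symbol in a SOFT table;
#'   any of the common spellings is found automatically when `NULL`.
#' @return data.frame with columns `probe` and `symbol`.
#' @export
readProbeMap <- function(path, symbolColumn = NULL) {
    lines <- readLines(path)
    b <- grep("^!platform_table_begin", lines, ignore.case = TRUE)
    e <- grep("^!platform_table_end", lines, ignore.case = TRUE)
    if (length(b) == 1L && length(e) == 1L)
        lines <- lines[(b + 1L):(e - 1L)]
    tab <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                             quote = "\"", check.names = FALSE,
                             colClasses = "character")
    if (ncol(tab) == 2L && is.null(symbolColumn))
        return(stats::setNames(tab, c("probe", "symbol")))
    if (is.null(symbolColumn)) {
        cand <- c("Gene Symbol", "GENE_SYMBOL", "Symbol", "gene_symbol",
                  "GeneSymbol", "SYMBOL")
        symbolColumn <- cand[cand %in% colnames(tab)][1L]
        if (is.na(symbolColumn))
            stop("could not locate a gene-symbol column; pass symbolColumn",
                 call. = FALSE)
    }
    data.frame(probe = tab[[1L]], symbol = tab[[symbolColumn]])
}

#' Collapse probe rows to gene rows
#'
#' Probes mapping to the same gene symbol are averaged (arithmetic mean);
#' probes without a gene symbol in the map are dropped. Symbols are matched
#' case-insensitively and upper-cased in the output.
#'
#' @param probeMatrix probe x sample numeric matrix.
#' @param probeMap data.frame whose first two columns are (probe, symbol);
#'   empty or `NA` symbols mark unannotated probes.
#' @return gene x sample matrix, rows ordered by symbol.
#' @examples
#' m <- matrix(c(1, 3, 3, 5), 2, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' collapseProbes(m, data.frame(probe = c("p1", "p2"),
#'                              symbol = c("g", "g")))
#' @export
collapseProbes <- function(probeMatrix, probeMap) {
    map <- data.frame(probe = as.character(probeMap[[1L]]),
                      symbol = toupper(trimws(as.character(probeMap[[2L]]))))
    map <- map[!is.na(map$symbol) & map$symbol != "" &
               map$symbol != "NA", , drop = FALSE]
    map <- map[map$probe %in% rownames(probeMatrix), , drop = FALSE]
    if (!nrow(map))
        stop("no probe of the matrix is covered by the annotation map",
             call. = FALSE)
    sub <- probeMatrix[map$probe, , drop = FALSE]
    sums <- rowsum(sub, group = map$symbol)
    counts <- as.vector(table(map$symbol)[rownames(sums)])
    sums / counts
}

#' Impute missing values and bring expression onto log2 scale
#'
#' Probes (rows) with more than `maxMissing` missing values are dropped;
#' remaining `NA`s are imputed with the per-row median. When the matrix
#' maximum exceeds 50 the values are taken to be on a linear scale and are
#' log2-transformed (`log2(x + 1)`); the decision is reported via
#' `message()` and recorded in the `"log2Transformed"` attribute.
#'
#' @param mat numeric matrix.
#' @param maxMissing maximum tolerated fraction of missing values per row.
#' @return cleaned matrix with attribute `log2Transformed`.
#' @export
normalizeExpression <- function(mat, maxMissing = 0.2) {
    frac <- rowMeans(is.na(mat))
    if (any(frac > maxMissing)) {
        message(sum(frac > maxMissing), " row(s) dropped (> ",
                round(100 * maxMissing), "% missing)")
        mat <- mat[frac <= maxMissing, , drop = FALSE]
    }
    if (anyNA(mat)) {
        med <- matrixStats::rowMedians(mat, na.rm = TRUE)
        idx <- which(is.na(mat), arr.ind = TRUE)
        mat[idx] <- med[idx[, 1L]]
    }
    doLog <- max(mat) > 50
    if (doLog) {
        message("matrix maximum ", format(max(mat)),
                " > 50: applying log2(x + 1)")
        mat <- log2(pmax(mat, 0) + 1)
    }
    structure(mat, log2Transformed = doLog)
}
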