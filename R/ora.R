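#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a module against a
#' measured-gene universe: the p-value is the upper-tail hypergeometric
#' probability `P(X >= overlap)` of drawing at least the observed overlap
#' when `|module|` genes are sampled from the universe without replacement.
#' Sets are intersected with the universe before testing;
#' Benjamini-Hochberg adjustment is applied across all tested sets. Raw
#' p-values are always reported alongside the adjusted ones.
#'
#' @param module character, the gene module (must intersect the universe).
#' @param sets named list of character vectors (e.g. from [readGMT()]).
#' @param universe character, the measured gene universe.
#' @return data.frame with one row per set — `setName`, `overlap`,
#'   `setSize`, `moduleSize`, `universeSize`, `pValue`, `pAdjusted` —
#'   sorted by `pValue`, ties by `setName`.
#' @examples
#' ora <- hypergeometricORA(c("a", "b"), list(s1 = c("a", "b", "c")),
#'                          universe = letters[1:10])
#' ora$pValue
#' @export
hypergeometricORA <- function(module, sets, universe) {
    if (!length(universe)) stop("empty universe", call. = FALSE)
    module <- intersect(module, universe)
    if (!length(module))
        stop("the module shares no gene with the universe", call. = FALSE)
    stopifnot(length(sets) >= 1L, !is.null(names(sets)))
    N <- length(universe); m <- length(module)
    rows <- lapply(names(sets), function(nm) {
        s <- intersect(sets[[nm]], universe)
        ov <- length(intersect(s, module))
        p <- stats::phyper(ov - 1L, length(s), N - length(s), m,
                           lower.tail = FALSE)
        data.frame(setName = nm, overlap = ov, setSize = length(s),
                   moduleSize = m, universeSize = N, pValue = p)
    })
    out <- do.call(rbind, rows)
    out$pAdjusted <- stats::p.adjust(out$pValue, method = "BH")
    out <- out[order(out$pValue, out$setName), , drop = FALSE]
    rownames(out) <- NULL
    out
}
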