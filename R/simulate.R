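#' Piecewise-linear schedule peaking at the pre-transition point
#'
#' Rises linearly from `base` at the first time point to `peak` at `tStar`,
#' then decays linearly back to `base` over `decay` further points and stays
#' at `base` afterwards. This rise-then-fall shape is the qualitative
#' behaviour expected of the DNB moments around a critical transition: the
#' signal grows as the system loses resilience and vanishes again once the
#' new regime is reached.
#'
#' @param T number of time points.
#' @param tStar 1-based peak index.
#' @param base,peak schedule values away from / at the peak.
#' @param decay number of points over which the schedule returns to `base`.
#' @return numeric vector of length `T`.
#' @export
rampSchedule <- function(T, tStar, base, peak, decay = 3L) {
    stopifnot(T >= 1L, tStar >= 1L, tStar <= T, decay >= 1L)
    out <- rep(base, T)
    if (tStar > 1L)
        out[1:tStar] <- base + (peak - base) * (0:(tStar - 1L)) / (tStar - 1L)
    out[tStar] <- peak
    down <- seq(tStar + 1L, min(T, tStar + decay))
    if (tStar < T)
        out[down] <- peak + (base - peak) * (down - tStar) / decay
    out
}

#' Construct simulation parameters with near-bifurcation defaults
#'
#' The defaults describe a 17-point case/control time course (the sampling
#' grid of an HRG-stimulation experiment, 10 min to 72 h) with 1000 genes, a
#' 30-gene planted DNB block and 5 replicate arrays per point. Approaching
#' the pre-transition point `tStar` (default 7, i.e. 1.5 h), the block's SD
#' multiplier ramps 1 to 3, its intra-block correlation 0.1 to 0.8, and its
#' correlation with the background decays 0.1 to 0; all three return to
#' baseline within three further points.
#'
#' @param nGenes,nDNB total and planted-block gene counts.
#' @param timePoints ordered time labels (length T).
#' @param replicates case (and control) arrays per time point.
#' @param tStar 1-based index of the planted pre-transition point.
#' @param sigmaBackground background per-gene SD (expression units).
#' @param sigmaSchedule,rhoInSchedule,rhoOutSchedule per-time-point DNB
#'   SD multiplier, intra-block correlation and block-background
#'   correlation; defaults are [rampSchedule()] ramps peaking at `tStar`.
#' @param nOutCoupled number of background genes carrying the
#'   `rhoOutSchedule` coupling to the DNB block (see
#'   [SimulationParams-class] for the positive-semi-definiteness bound that
#'   forces this to be a bounded subset).
#' @param meanShift constant case-group mean offset of DNB genes
#'   (expression units); makes the planted block differentially expressed.
#' @param seed integer driving all randomness of [simulateDNBDataset()].
#' @return a validated [SimulationParams-class].
#' @examples
#' p <- SimulationParams(nGenes = 100, nDNB = 10, replicates = 5, seed = 1)
#' p
#' @export
SimulationParams <- function(nGenes = 1000L, nDNB = 30L,
                             timePoints = c("10min", "15min", "20min",
                               "30min", "45min", "1h", "1.5h", "2h", "3h",
                               "4h", "6h", "8h", "12h", "24h", "36h",
                               "48h", "72h"),
                             replicates = 5L, tStar = 7L,
                             sigmaBackground = 1,
                             sigmaSchedule = rampSchedule(
                                 length(timePoints), tStar, 1, 3),
                             rhoInSchedule = rampSchedule(
                                 length(timePoints), tStar, 0.1, 0.8),
                             rhoOutSchedule = rampSchedule(
                                 length(timePoints), tStar, 0.1, 0),
                             nOutCoupled = min(10L, nGenes - nDNB),
                             meanShift = 1, seed = 1L) {
    new("SimulationParams",
        nGenes = as.integer(nGenes), nDNB = as.integer(nDNB),
        timePoints = as.character(timePoints),
        replicates = as.integer(replicates), tStar = as.integer(tStar),
        sigmaBackground = sigmaBackground,
        sigmaSchedule = sigmaSchedule,
        rhoInSchedule = rhoInSchedule,
        rhoOutSchedule = rhoOutSchedule,
        nOutCoupled = as.integer(nOutCoupled),
        meanShift = meanShift, seed = as.integer(seed))
}

setMethod("show", "SimulationParams", function(object) {
    cat(sprintf(
        "SimulationParams: %d genes (%d DNB), T=%d, s=%d, tStar=%d, seed=%d\n",
        object@nGenes, object@nDNB, length(object@timePoints),
        object@replicates, object@tStar, object@seed))
})

## per-time-point covariance of the case group (block compound symmetry)
.caseCovariance <- function(p, k) {
    n <- p@nGenes; b <- p@nDNB; sg <- p@sigmaBackground
    sdD <- sg * p@sigmaSchedule[k]
    S <- diag(rep(sg^2, n))
    if (b > 0L) {
        S[1:b, 1:b] <- sdD^2 * p@rhoInSchedule[k]
        diag(S)[1:b] <- sdD^2
        nOut <- min(p@nOutCoupled, n - b)
        if (nOut > 0L) {
            cross <- p@rhoOutSchedule[k] * sdD * sg
            out <- (b + 1L):(b + nOut)
            S[1:b, out] <- cross
            S[out, 1:b] <- cross
        }
    }
    S
}

#' Simulate a case/control time course with a planted DNB block
#'
#' For each time point `k`, the case replicates are independent draws from a
#' multivariate normal whose covariance has block-compound-symmetry
#' structure: the planted block has variance
#' `(sigmaBackground * sigmaSchedule[k])^2` and pairwise correlation
#' `rhoInSchedule[k]`, each block gene correlates at `rhoOutSchedule[k]`
#' with the `nOutCoupled` coupled background genes, and the background is
#' otherwise uncorrelated with variance `sigmaBackground^2`. Control replicates are drawn from the stationary
#' background model (all genes uncorrelated, unit schedules) at every time
#' point. The same parameters and seed reproduce the dataset bit for bit.
#'
#' @param params a [SimulationParams-class].
#' @return list with `dataset` (a [TimeCourseExperiment-class]) and `truth`
#'   (a [PlantedTruth-class] naming the planted genes and `tStar`).
#' @examples
#' sim <- simulateDNBDataset(SimulationParams(nGenes = 50, nDNB = 5,
#'                                            replicates = 5, seed = 7))
#' sim$truth@dnbGenes
#' @export
simulateDNBDataset <- function(params) {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    p <- params
    n <- p@nGenes; b <- p@nDNB; s <- p@replicates
    T <- length(p@timePoints)
    genes <- sprintf("G%04d", seq_len(n))
    dnb <- if (b > 0L) genes[1:b] else character(0)
    mu <- rep(0, n)
    if (b > 0L) mu[1:b] <- p@meanShift

    set.seed(p@seed)
    caseCols <- vector("list", T)
    for (k in seq_len(T)) {
        if (b > 0L && (p@rhoInSchedule[k] != 0 || p@rhoOutSchedule[k] != 0)) {
            S <- .caseCovariance(p, k)
            U <- tryCatch(chol(S), error = function(e) stop(
                "covariance at time point ", k, " ('", p@timePoints[k],
                "') is not positive semi-definite: ", conditionMessage(e),
                call. = FALSE))
            Z <- matrix(stats::rnorm(s * n), s, n)
            X <- Z %*% U
        } else {
            sds <- rep(p@sigmaBackground, n)
            if (b > 0L) sds[1:b] <- p@sigmaBackground * p@sigmaSchedule[k]
            X <- matrix(stats::rnorm(s * n), s, n) * rep(sds, each = s)
        }
        caseCols[[k]] <- t(X + rep(mu, each = s))
    }
    case <- do.call(cbind, caseCols)
    control <- matrix(stats::rnorm(n * T * s, sd = p@sigmaBackground),
                      n, T * s)
    rownames(case) <- rownames(control) <- genes
    tt <- rep(seq_len(T), each = s)
    rr <- rep(seq_len(s), T)
    colnames(case) <- colnames(control) <- paste0("t", tt, "_r", rr)

    dataset <- TimeCourseExperiment(case, control, timePoints = p@timePoints)
    list(dataset = dataset,
         truth = new("PlantedTruth", dnbGenes = dnb, tStar = p@tStar))
}

#' Expected composite-index trajectory of the planted module
#'
#' Computes, from the true covariance schedules alone, the expected value of
#' each composite-index ingredient for the planted block at a given
#' per-window sample size `n`: the expected sample SD
#' `sigma_k * c4(n)` (exact chi-distribution factor), and the expected mean
#' absolute sample correlation via the folded-normal approximation to the
#' sampling distribution of a Pearson correlation,
#' `r ~ N(rho, (1 - rho^2)^2 / (n - 1))`. Note that at small `|rho|` the
#' expected *absolute* correlation does not vanish — it converges to
#' `sqrt(2 / (pi (n-1)))` — which is why the plug-in `|rho|` is not the
#' large-replicate limit of the estimator.
#'
#' @param params a [SimulationParams-class].
#' @param n per-window sample count the estimators will see (e.g.
#'   `replicates` for window half-width 0).
#' @return data.frame with one row per time point: `sdIn`, `pccIn`,
#'   `pccOut`, `ci`.
#' @export
populationScoreSeries <- function(params, n = params@replicates) {
    stopifnot(n >= 3L)
    p <- params
    c4 <- sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
    sdIn <- p@sigmaBackground * p@sigmaSchedule * c4
    pccIn <- .expectedAbsCor(p@rhoInSchedule, n)
    # cross pairs: nOutCoupled background genes carry rhoOut, the rest 0
    m <- p@nGenes - p@nDNB
    wOut <- min(p@nOutCoupled, m) / m
    pccOut <- wOut * .expectedAbsCor(p@rhoOutSchedule, n) +
        (1 - wOut) * .expectedAbsCor(0, n)
    data.frame(time = seq_along(p@timePoints), timeLabel = p@timePoints,
               sdIn = sdIn, pccIn = pccIn, pccOut = pccOut,
               ci = sdIn * pccIn / pmax(pccOut, 1e-3))
}

## E|r| under r ~ N(rho, (1-rho^2)^2/(n-1))  (folded normal mean)
.expectedAbsCor <- function(rho, n) {
    s <- (1 - rho^2) / sqrt(n - 1)
    s * sqrt(2 / pi) * exp(-rho^2 / (2 * s^2)) +
        rho * (1 - 2 * stats::pnorm(-rho / s))
}
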