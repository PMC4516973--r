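test_that("the simulator is deterministic under its seed", {
    a <- simulateDNBDataset(smallParams(seed = 11))
    b <- simulateDNBDataset(smallParams(seed = 11))
    c <- simulateDNBDataset(smallParams(seed = 12))
    expect_identical(SummarizedExperiment::assay(a$dataset),
                     SummarizedExperiment::assay(b$dataset))
    expect_identical(a$truth@dnbGenes, b$truth@dnbGenes)
    expect_false(identical(SummarizedExperiment::assay(a$dataset),
                           SummarizedExperiment::assay(c$dataset)))
})

test_that("an empty DNB block yields pure iid background", {
    sim <- simulateDNBDataset(smallParams(seed = 5, nDNB = 0L))
    expect_length(sim$truth@dnbGenes, 0)
    cs <- caseMatrix(sim$dataset)
    # all genes stationary at sigma_background across the whole course
    sds <- apply(cs, 1, sd)
    expect_true(all(sds > 0.5 & sds < 1.6))
    expect_equal(mean(sds), 1, tolerance = 0.05)
})

test_that("planted moments are recovered empirically at large s", {
    p <- SimulationParams(nGenes = 150L, nDNB = 20L, replicates = 200L,
                          seed = 21)
    sim <- simulateDNBDataset(p)
    win <- windowSamples(sim$dataset, p@tStar, w = 0L)
    dnb <- sim$truth@dnbGenes
    R <- cor(t(win[dnb, ]))
    expect_equal(mean(R[upper.tri(R)]), 0.8, tolerance = 0.05)
    # SD multiplier 3 at t*
    expect_equal(mean(geneSD(win)[dnb]), 3, tolerance = 0.15)
    # control stationarity: per-time mean SD varies < 10%
    ctrl <- controlMatrix(sim$dataset)
    ctime <- sim$dataset$time[sim$dataset$group == "control"]
    msd <- sapply(seq_len(nTimePoints(sim$dataset)), function(t)
        mean(apply(ctrl[, ctime == t, drop = FALSE], 1, sd)))
    expect_lt((max(msd) - min(msd)) / mean(msd), 0.1)
})

test_that("infeasible correlation schedules are rejected, naming the time point", {
    expect_error(
        SimulationParams(nGenes = 100L, nDNB = 30L, nOutCoupled = 70L,
                         rhoOutSchedule = rampSchedule(17, 7, 0.5, 0)),
        "time point")
    expect_error(SimulationParams(nDNB = 2000L), "nDNB")
    expect_error(SimulationParams(replicates = 1L), "replicates")
})

test_that("default schedules peak (in signal) at tStar", {
    p <- SimulationParams()
    expect_equal(which.max(p@sigmaSchedule), p@tStar)
    expect_equal(which.max(p@rhoInSchedule), p@tStar)
    expect_equal(which.min(abs(p@rhoOutSchedule)), p@tStar)
    expect_length(p@sigmaSchedule, 17)
    # ramps return to baseline within 3 points of the peak
    expect_equal(p@sigmaSchedule[p@tStar + 3L], p@sigmaSchedule[1])
    expect_equal(rampSchedule(10, 4, 1, 3),
                 c(1, 5/3, 7/3, 3, 7/3, 5/3, 1, 1, 1, 1),
                 tolerance = 1e-12)
})

test_that("sampled trajectories track the closed-form expectation within MC dispersion", {
    # mean-|PCC| estimators carry a shared-factor sampling component that
    # does not average out over pairs; at s = 200 its dispersion at the
    # small-correlation baseline points is ~20% relative (see vignette)
    p <- SimulationParams(replicates = 200L, seed = 77)
    sim <- simulateDNBDataset(p)
    s <- scores(scoreSeries(sim$truth@dnbGenes, sim$dataset, w = 0L))
    pop <- populationScoreSeries(p, n = 200L)
    expect_equal(which.max(pop$ci), p@tStar)
    expect_lte(abs(which.max(s$ci) - p@tStar), 1)
    rel <- abs(s$ci - pop$ci) / pop$ci
    expect_lt(max(rel), 0.35)
    expect_lt(rel[p@tStar], 0.10)          # strong-signal point is tight
    # SD and external-correlation components are tight everywhere
    expect_lt(max(abs(s$sdIn - pop$sdIn) / pop$sdIn), 0.10)
    expect_lt(max(abs(s$pccOut - pop$pccOut) / pop$pccOut), 0.10)
})

test_that("DNB genes out-fluctuate and out-correlate the background at tStar", {
    sdWins <- corWins <- logical(100)
    for (i in 1:100) {
        p <- SimulationParams(nGenes = 60L, nDNB = 10L, replicates = 50L,
                              seed = 7000 + i)
        sim <- simulateDNBDataset(p)
        win <- windowSamples(sim$dataset, p@tStar, w = 0L)
        dnb <- sim$truth@dnbGenes
        sds <- geneSD(win)
        sdWins[i] <- mean(sds[dnb]) > mean(sds[setdiff(names(sds), dnb)])
        Rstar <- abs(cor(t(win[dnb, ])))
        win0 <- windowSamples(sim$dataset, 1L, w = 0L)
        R0 <- abs(cor(t(win0[dnb, ])))
        corWins[i] <- mean(Rstar[upper.tri(Rstar)]) >
            mean(R0[upper.tri(R0)])
    }
    expect_gte(mean(sdWins), 0.99)
    expect_gte(mean(corWins), 0.99)
})
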