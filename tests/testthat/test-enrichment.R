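test_that("hypergeometric p-values match closed forms", {
    universe <- paste0("G", 1:20)
    module <- universe[1:5]
    # full overlap of a size-5 set: p = 1 / choose(20, 5)
    ora <- hypergeometricORA(module, list(hit = module), universe)
    expect_equal(ora$pValue, 1 / choose(20, 5), tolerance = 1e-12)
    expect_equal(ora$overlap, 5)
    # set == universe: overlap is forced, p = 1
    expect_equal(hypergeometricORA(module, list(all = universe),
                                   universe)$pValue, 1.0)
    # zero overlap: p close to 1, never above
    p0 <- hypergeometricORA(module, list(miss = universe[16:18]),
                            universe)$pValue
    expect_lte(p0, 1)
    expect_gt(p0, 0.3)
    expect_error(hypergeometricORA(character(0), list(a = "x"), universe),
                 "no gene")
    expect_error(hypergeometricORA(module, list(a = "x"), character(0)),
                 "universe")
})

test_that("upper-tail p-values agree with exhaustive enumeration", {
    # tiny instance: universe 8, set 3, module 4 — enumerate all draws
    universe <- letters[1:8]; set <- letters[1:3]
    draws <- combn(8, 4)
    for (ov in 0:3) {
        pEnum <- mean(apply(draws, 2, function(d)
            sum(d <= 3) >= ov))
        pPkg <- phyper(ov - 1, 3, 5, 4, lower.tail = FALSE)
        ora <- hypergeometricORA(universe[c(seq_len(ov),
                                            seq.int(4, length.out = 4 - ov))],
                                 list(s = set), universe)
        expect_equal(ora$pValue, pEnum, tolerance = 1e-12)
        expect_equal(pPkg, pEnum, tolerance = 1e-12)
    }
})

test_that("the planted-enriched set ranks first on the GMT fixture", {
    for (i in 1:10) {
        sim <- simulateDNBDataset(smallParams(seed = 1200 + i))
        sets <- makeGmtFixture(rownames(sim$dataset), sim$truth,
                               nSets = 8L, seed = i)
        expect_gte(length(intersect(sets$planted_enriched,
                                    sim$truth@dnbGenes)),
                   ceiling(0.8 * length(sim$truth@dnbGenes)))
        ora <- hypergeometricORA(sim$truth@dnbGenes, sets,
                                 rownames(sim$dataset))
        expect_equal(ora$setName[1], "planted_enriched")
        # BH keeps the p-value order
        expect_equal(order(ora$pValue), order(ora$pAdjusted))
        expect_true(all(ora$pAdjusted >= ora$pValue - 1e-15))
    }
    expect_error(makeGmtFixture(paste0("G", 1:10), paste0("G", 1:3), 0L),
                 "nSets")
})

test_that("GMT files round-trip through write and read", {
    sets <- list(one = c("A", "B", "C"), two = c("D", "E"))
    f <- withr::local_tempfile(fileext = ".gmt")
    writeGMT(sets, f)
    expect_equal(readGMT(f), sets)
})

test_that("toy networks have the exact requested edge count", {
    g <- paste0("G", 1:20)
    expect_equal(nrow(networkEdges(makeToyNetwork(g, 0.1, seed = 4))), 19)
    expect_equal(nrow(networkEdges(makeToyNetwork(g[1:2], 1.0))), 1)
    expect_equal(nrow(networkEdges(makeToyNetwork(g[1:10], 0))), 0)
    expect_error(makeToyNetwork("G1", 0.5), "2 genes")
    a <- makeToyNetwork(g, 0.3, seed = 9)
    b <- makeToyNetwork(g, 0.3, seed = 9)
    expect_identical(networkEdges(a), networkEdges(b))
})

test_that("module network export honours the threshold and round-trips", {
    set.seed(5)
    n <- 10
    m <- matrix(rnorm(4 * n), 4, dimnames = list(paste0("g", 1:4), NULL))
    m["g2", ] <- m["g1", ] # perfect correlation
    d <- withr::local_tempdir()
    # threshold 1 on independent noisy genes: edgeless graph
    p0 <- file.path(d, "empty.sif")
    exportModuleNetwork(paste0("g", 3:4), m, threshold = 1, path = p0)
    expect_length(readLines(p0), 0)
    expect_equal(nrow(networkEdges(readNetwork(p0, "sif"))), 0)
    # near-1 threshold: only the duplicated pair survives
    p1 <- file.path(d, "net.sif")
    exportModuleNetwork(paste0("g", 1:4), m, threshold = 0.9999, path = p1)
    net <- readNetwork(p1, "sif")
    expect_equal(nrow(networkEdges(net)), 1)
    expect_setequal(as.vector(networkEdges(net)), c("g1", "g2"))
    # graphml carries weights and node SDs
    p2 <- file.path(d, "net.graphml")
    exportModuleNetwork(c("g1", "g2"), m, threshold = 0.5, path = p2,
                        format = "graphml")
    g <- igraph::read_graph(p2, format = "graphml")
    expect_equal(igraph::ecount(g), 1)
    expect_equal(igraph::edge_attr(g, "pcc"), 1.0, tolerance = 1e-12)
    expect_equal(sort(igraph::vertex_attr(g, "name")), c("g1", "g2"))
    expect_error(exportModuleNetwork(c("g1", "g2"), m, threshold = 0,
                                     path = p1), "threshold")
    # SIF export of a full correlation graph re-reads identically
    sim <- simulateDNBDataset(smallParams(seed = 2, nGenes = 30L,
                                          nDNB = 6L))
    win <- windowSamples(sim$dataset, 7, w = 1L)
    p3 <- file.path(d, "mod.sif")
    exportModuleNetwork(sim$truth@dnbGenes, win, threshold = 0.5,
                        path = p3)
    back <- readNetwork(p3, "sif")
    R <- pccMatrix(win[sim$truth@dnbGenes, ])
    want <- sum(abs(R[upper.tri(R)]) >= 0.5)
    expect_equal(nrow(networkEdges(back)), want)
})
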