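test_that("gene SDs match closed forms and the textbook oracle", {
    m <- rbind(flat = rep(2, 5), ramp = c(1, 2, 3, 4, 5))
    expect_equal(unname(geneSD(m)), c(0, sd(1:5)))
    expect_equal(unname(geneSD(rbind(g = c(1, 2, 3)))["g"]), 1.0)
    set.seed(7)
    r <- matrix(rnorm(24), 4, 6, dimnames = list(paste0("g", 1:4), NULL))
    expect_equal(unname(geneSD(r)),
                 vapply(1:4, function(i) bruteSD(r[i, ]), 1),
                 tolerance = 1e-12)
    expect_error(geneSD(matrix(1:4, 2)), "ncol")
})

test_that("correlation matrices match the textbook formula and handle degeneracy", {
    set.seed(8)
    m <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("g", 1:5), NULL))
    m["g2", ] <- m["g1", ]          # duplicated gene
    m["g3", ] <- -m["g1", ]         # negated gene
    R <- pccMatrix(m)
    expect_equal(R["g1", "g2"], 1.0)
    expect_equal(R["g1", "g3"], -1.0)
    expect_equal(unname(diag(R)), rep(1, 5))
    for (i in 1:5) for (j in 1:5) if (i != j)
        expect_equal(R[i, j], bruteCor(m[i, ], m[j, ]), tolerance = 1e-12)
    m["g4", ] <- 3                  # zero variance
    Rz <- pccMatrix(m)
    expect_equal(unname(Rz["g4", c(1:3, 5)]), rep(0, 4))
    expect_equal(Rz["g4", "g4"], 1)
    expect_equal(attr(Rz, "nZeroVar"), 1L)
})

test_that("sample windows have the documented extent and guard rails", {
    sim <- simulateDNBDataset(smallParams(seed = 3, nGenes = 20L,
                                          nDNB = 3L))
    expect_equal(ncol(windowSamples(sim$dataset, 5, w = 0L)), 5)
    expect_equal(ncol(windowSamples(sim$dataset, 5, w = 1L)), 15)
    expect_equal(ncol(windowSamples(sim$dataset, 1, w = 2L)), 15)  # truncated
    expect_equal(ncol(windowSamples(sim$dataset, 17, w = 3L)), 20)
    one <- SimulationParams(nGenes = 20L, nDNB = 3L, replicates = 2L,
                            seed = 1)
    d1 <- simulateDNBDataset(one)$dataset
    expect_equal(ncol(windowSamples(d1, 9, w = 1L)), 6)
    expect_error(windowSamples(d1, 1, w = 0L), "window half-width")
})

test_that("correlated blocks cluster into the planted modules", {
    set.seed(10)
    n <- 12; base1 <- rnorm(n); base2 <- rnorm(n)
    m <- rbind(
        t(sapply(1:4, function(i) base1 + rnorm(n, sd = 0.1))),
        t(sapply(1:4, function(i) base2 + rnorm(n, sd = 0.1))))
    rownames(m) <- paste0("g", 1:8)
    mods <- clusterCandidates(pccMatrix(m), cut = 0.5)
    expect_length(mods, 2)
    got <- lapply(mods, moduleGenes)
    expect_setequal(got[[which(sapply(got, function(g) "g1" %in% g))]],
                    paste0("g", 1:4))
    # independent genes at a tight cut: all singletons, no modules
    set.seed(11)
    ind <- matrix(rnorm(8 * 50), 8, dimnames = list(paste0("g", 1:8), NULL))
    expect_length(clusterCandidates(pccMatrix(ind), cut = 0.05), 0)
    # 2-gene universe with strong correlation: one 2-gene module
    two <- rbind(a = base1, b = base1 + rnorm(n, sd = 0.3))
    expect_length(clusterCandidates(pccMatrix(two), cut = 0.5), 1)
    expect_error(clusterCandidates(pccMatrix(two), cut = 0), "cut")
    expect_error(clusterCandidates(pccMatrix(two), cut = 1.5), "cut")
})

test_that("composite index matches the brute-force pairwise oracle", {
    set.seed(123)
    for (rep in 1:50) {
        n <- sample(4:8, 1); ns <- sample(4:10, 1)
        m <- matrix(rnorm(n * ns), n,
                    dimnames = list(paste0("g", seq_len(n)), NULL))
        k <- sample(2:(n - 1), 1)
        mod <- sample(rownames(m), k)
        got <- compositeIndex(mod, m)
        want <- bruteCompositeIndex(mod, m)
        expect_equal(got@sdIn, want$sdIn, tolerance = 1e-10)
        expect_equal(got@pccIn, want$pccIn, tolerance = 1e-10)
        expect_equal(got@pccOut, want$pccOut, tolerance = 1e-10)
        expect_equal(got@ci, want$ci, tolerance = 1e-10)
    }
})

test_that("composite index is scale-equivariant and order-invariant", {
    set.seed(30)
    m <- matrix(rnorm(10 * 8), 10, dimnames = list(paste0("g", 1:10), NULL))
    mod <- c("g2", "g5", "g7")
    a <- compositeIndex(mod, m)
    b <- compositeIndex(mod, 2 * m)
    expect_equal(b@sdIn, 2 * a@sdIn)
    expect_equal(b@ci, 2 * a@ci)
    expect_equal(b@pccIn, a@pccIn)
    expect_equal(b@pccOut, a@pccOut)
    perm <- compositeIndex(rev(mod), m[sample(10), sample(8)])
    expect_equal(perm@ci, a@ci, tolerance = 1e-12)
    # constant module: ci = 0
    mc <- m; mc[mod, ] <- 1
    expect_equal(compositeIndex(mod, mc)@ci, 0)
    expect_error(compositeIndex("g1", m), "2 genes")
    expect_error(compositeIndex(rownames(m), m), "non-module")
})

test_that("transition detection follows the standout rule", {
    mkSeries <- function(ci) new("DNBScoreSeries",
        module = new("GeneModule", genes = c("a", "b"),
                     clusterId = NA_integer_, timeIndex = NA_integer_),
        stats = data.frame(time = seq_along(ci),
                           timeLabel = as.character(seq_along(ci)),
                           sdIn = 1, pccIn = 1, pccOut = 1, ci = ci,
                           nSamples = 5L),
        window = 1L, transitionIndex = NA_integer_)
    expect_true(is.na(transitionIndex(detectTransition(mkSeries(rep(1, 8))))))
    expect_equal(transitionIndex(detectTransition(mkSeries(c(0, 0, 0, 10, 0)))), 4L)
    # direct evaluation of the rule on a mixed series (1-based index 7)
    s <- c(1, 1, 1, 1, 1, 5, 9, 2, 1)
    expect_equal(transitionIndex(detectTransition(mkSeries(s), k = 2)), 7L)
    rest <- s[-7]
    expect_gt(s[7], mean(rest) + 2 * sd(rest))   # the rule, spelled out
    # a stricter k suppresses the same detection
    expect_true(is.na(transitionIndex(detectTransition(mkSeries(s), k = 6))))
    expect_error(detectTransition(mkSeries(c(1, 2, 3))), "4 time points")
})
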