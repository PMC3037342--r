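test_that("Pearson correlation matches hand-computed and dual-route values", {
    expect_equal(pearsonCorr(c(1, 2, 3), c(3, 5, 7)), 1)
    expect_equal(pearsonCorr(c(1, 2, 3), c(6, 4, 2)), -1)
    expect_equal(pearsonCorr(c(1, 2, 3), c(1, 3, 2)), 0.5)
    expect_equal(pearsonCorr(c(2, 2, 2), c(1, 3, 2)), 0)  # zero variance
    expect_error(pearsonCorr(1:3, 1:4), "dimension mismatch")

    ## population-moment formula agrees with stats::cor (sample moments)
    set.seed(11)
    for (rep in 1:20) {
        x <- rnorm(sample(3:20, 1))
        y <- rnorm(length(x))
        expect_equal(pearsonCorr(x, y), cor(x, y), tolerance = 1e-12)
    }
})

test_that("correlation is invariant under positive affine transforms", {
    set.seed(12)
    for (rep in 1:10) {
        x <- rnorm(8); y <- rnorm(8)
        a1 <- runif(1, 0.1, 5); a2 <- runif(1, 0.1, 5)
        expect_equal(pearsonCorr(a1 * x + rnorm(1), a2 * y + rnorm(1)),
            pearsonCorr(x, y), tolerance = 1e-9)
        expect_equal(pearsonCorr(-x, y), -pearsonCorr(x, y), tolerance = 1e-12)
    }
})

test_that("average correlation of shifting-and-scaling patterns is exactly 1", {
    m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(3, 5, 7, 9))
    colnames(m) <- paste0("c", 1:4)
    b <- Bicluster(1:3, 1:4, parentDim = m)
    expect_equal(avgCorrelation(b, m), 1, tolerance = 1e-12)
    expect_equal(corrSD(b, m), 0, tolerance = 1e-12)
})

test_that("average correlation and its SD aggregate the pairwise coefficients", {
    ## pairwise coefficients {1, 0.5, 0.5} -> mean 2/3, population SD sqrt(1/18)
    m <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(1, 3, 2))
    colnames(m) <- paste0("c", 1:3)
    b <- Bicluster(1:3, 1:3, parentDim = m)
    expect_equal(avgCorrelation(b, m), 2 / 3, tolerance = 1e-12)
    expect_equal(corrSD(b, m), sqrt(1 / 18), tolerance = 1e-12)

    ## a 2-gene bicluster has a single coefficient: mean is it, SD is 0
    b2 <- Bicluster(c(1, 3), 1:3, parentDim = m)
    expect_equal(avgCorrelation(b2, m), 0.5, tolerance = 1e-12)
    expect_equal(corrSD(b2, m), 0)
})

test_that("fitness composes correlation, homogeneity and volume penalties", {
    m <- outer(1:10, 1:5) + 2
    rownames(m) <- paste0("g", 1:10); colnames(m) <- paste0("c", 1:5)
    b <- Bicluster(1:10, 1:5, parentDim = m)
    expect_equal(biclusterFitness(b, m, M1 = 1, M2 = 1), 0.3, tolerance = 1e-12)
    expect_equal(biclusterFitness(b, m, M1 = 0, M2 = 0), 0, tolerance = 1e-12)

    ## direct arithmetic of the composite on given components
    expect_equal(corrbic:::.fitnessFromScores(0.5, 0.2, 5, 4, 1, 1), 1.15)

    ## degenerate biclusters carry worst fitness instead of erroring
    expect_identical(biclusterFitness(Bicluster(1L, 1:5, parentDim = m), m), Inf)
    expect_identical(biclusterFitness(Bicluster(1:10, 2L, parentDim = m), m), Inf)
    expect_identical(biclusterFitness(Bicluster(integer(), integer(),
        parentDim = m), m), Inf)
})

test_that("fitness decreases with correlation and with size", {
    f <- corrbic:::.fitnessFromScores
    expect_gt(f(0.6, 0.1, 5, 5, 1, 1), f(0.9, 0.1, 5, 5, 1, 1))
    expect_gt(f(0.9, 0.1, 5, 5, 1, 1), f(0.9, 0.1, 8, 5, 1, 1))
    expect_gt(f(0.9, 0.1, 5, 5, 1, 1), f(0.9, 0.1, 5, 8, 1, 1))
})

test_that("mean squared residue is zero for constant and shifting patterns", {
    const <- matrix(3.7, 4, 5,
        dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
    b <- Bicluster(1:4, 1:5, parentDim = const)
    expect_equal(biclusterMSR(b, const), 0)

    p <- c(1, 4, 2, 6, 3)
    shift <- rbind(p, p + 2, p - 1.5, p + 10)
    dimnames(shift) <- dimnames(const)
    expect_equal(biclusterMSR(b, shift), 0, tolerance = 1e-12)

    m <- rbind(g1 = c(1, 2), g2 = c(3, 5)); colnames(m) <- c("c1", "c2")
    expect_equal(biclusterMSR(Bicluster(1:2, 1:2, parentDim = m), m), 0.0625)
})

test_that("gene variance measures squared deviation from gene means", {
    m <- rbind(g1 = c(1, 3), g2 = c(2, 6)); colnames(m) <- c("c1", "c2")
    expect_equal(geneVariance(Bicluster(1:2, 1:2, parentDim = m), m), 2.5)

    const <- matrix(5, 3, 4,
        dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
    expect_equal(geneVariance(Bicluster(1:3, 1:4, parentDim = const), const), 0)

    ## scaling one gene by c multiplies its contribution by c^2
    p <- c(1, 5, 2, 4)
    m2 <- rbind(g1 = p, g2 = 3 * p); colnames(m2) <- paste0("c", 1:4)
    g1only <- geneVariance(Bicluster(1L, 1:4, parentDim = m2), m2)
    g2only <- geneVariance(Bicluster(2L, 1:4, parentDim = m2), m2)
    expect_equal(g2only, 9 * g1only, tolerance = 1e-12)
})

test_that("correlation accepts scaling patterns that MSR penalizes", {
    set.seed(21)
    profile <- rnorm(6)
    alphas <- c(0.2, 1, 5, 25)   # widely spread scaling factors
    m <- outer(alphas, profile)  # pure scaling, no shift
    rownames(m) <- paste0("g", 1:4); colnames(m) <- paste0("c", 1:6)
    b <- Bicluster(1:4, 1:6, parentDim = m)
    expect_equal(avgCorrelation(b, m), 1, tolerance = 1e-9)
    expect_equal(corrSD(b, m), 0, tolerance = 1e-9)
    expect_gt(biclusterMSR(b, m), 0.1)
    expect_gt(geneVariance(b, m), 1)
})

test_that("measures agree with brute-force double-loop oracles", {
    set.seed(31)
    for (rep in 1:50) {
        nG <- sample(2:6, 1); nC <- sample(2:6, 1)
        N <- nG + sample(0:3, 1); L <- nC + sample(0:3, 1)
        mat <- randomExpressionMatrix(N, L)
        g <- sort(sample(N, nG)); co <- sort(sample(L, nC))
        b <- Bicluster(g, co, parentDim = mat)
        sub <- mat[g, co, drop = FALSE]
        expect_equal(avgCorrelation(b, mat), naiveAvgCorr(sub), tolerance = 1e-9)
        expect_equal(corrSD(b, mat), naiveCorrSd(sub), tolerance = 1e-9)
        expect_equal(biclusterMSR(b, mat), naiveMSR(sub), tolerance = 1e-9)
        expect_equal(geneVariance(b, mat), naiveGeneVariance(sub), tolerance = 1e-9)
    }
})

test_that("scoreBicluster bundles all measures consistently", {
    set.seed(41)
    mat <- randomExpressionMatrix(8, 6)
    b <- Bicluster(c(1, 3, 5), c(2, 4, 6), parentDim = mat)
    sc <- scoreBicluster(b, mat, M1 = 1, M2 = 2)
    expect_equal(sc@avgCorr, avgCorrelation(b, mat))
    expect_equal(sc@corrSd, corrSD(b, mat))
    expect_equal(sc@fitness, biclusterFitness(b, mat, 1, 2))
    expect_equal(sc@msr, biclusterMSR(b, mat))
    expect_equal(sc@geneVariance, geneVariance(b, mat))
    expect_identical(sc@volume, 9L)
})
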