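test_that("the diversification rule flips every 1 + kh position", {
    expect_identical(diversifyBits(rep(0L, 10), 2),
        c(1L,0L,1L,0L,1L,0L,1L,0L,1L,0L))
    expect_identical(diversifyBits(rep(0L, 10), 3),
        c(1L,0L,0L,1L,0L,0L,1L,0L,0L,1L))
    seed <- sample(c(0L, 1L), 12, replace = TRUE)
    expect_identical(diversifyBits(seed, 1), 1L - seed)
    expect_error(diversifyBits(rep(0L, 10), 0), "1 <= h")
    expect_error(diversifyBits(rep(0L, 10), 2.5), "1 <= h")
})

test_that("population generation is deterministic, sized and duplicate-free", {
    mat <- randomExpressionMatrix(12, 8)
    p1 <- generatePopulation(mat, size = 30, seed = 5)
    p2 <- generatePopulation(mat, size = 30, seed = 5)
    expect_length(p1, 30)
    expect_identical(p1, p2)
    keys <- vapply(p1, function(b) paste(encodeBicluster(b), collapse = ""), "")
    expect_identical(anyDuplicated(keys), 0L)
    expect_length(generatePopulation(mat, size = 1, seed = 1), 1)
})

test_that("uniform crossover follows the mask positionwise", {
    a <- c(0L, 0L, 0L, 0L); b <- c(1L, 1L, 1L, 1L)
    expect_identical(crossoverBits(a, b, mask = rep(1L, 4)), a)
    expect_identical(crossoverBits(a, b, mask = rep(0L, 4)), b)
    expect_identical(crossoverBits(a, b, mask = c(1L, 0L, 1L, 0L)),
        c(0L, 1L, 0L, 1L))
    expect_error(crossoverBits(a, c(1L, 1L)), "dimension mismatch")
    set.seed(3)
    child <- crossoverBits(a, b)
    expect_true(all(child %in% c(0L, 1L)))
})

test_that("combining a reference set yields S(S-1)/2 children", {
    mat <- randomExpressionMatrix(10, 6)
    set.seed(9)
    refset <- generatePopulation(mat, size = 10, seed = 9)
    expect_length(combineAll(refset), 45)
    expect_length(combineAll(refset[1:2]), 1)
    set.seed(1); n1 <- length(combineAll(refset))
    set.seed(99); n2 <- length(combineAll(refset))
    expect_identical(n1, n2)  # count independent of rng state
    expect_error(combineAll(refset[1]), "at least 2")
})

test_that("selectBest returns the k lowest-fitness distinct candidates", {
    set.seed(13)
    mat <- randomExpressionMatrix(12, 8)
    cands <- generatePopulation(mat, size = 15, seed = 13)
    fits <- vapply(cands, biclusterFitness, 0, mat = mat)
    sel <- selectBest(cands, mat, k = 4)
    selFits <- vapply(sel, biclusterFitness, 0, mat = mat)
    expect_equal(selFits, sort(fits)[1:4])

    ## duplicates collapse before selection
    dup <- c(cands[1], cands[1], cands[2])
    expect_length(selectBest(dup, mat, k = 2), 2)
    expect_error(selectBest(dup, mat, k = 3), "shortage")

    expect_length(selectBest(cands, mat, k = length(cands)), length(cands))
})

test_that("scattered selection greedily maximizes the min Hamming distance", {
    dec <- function(s) decodeBicluster(as.integer(strsplit(s, "")[[1]]), 2, 2)
    anchors <- list(dec("0000"))
    pool <- list(dec("1111"), dec("0001"), dec("1110"))
    one <- selectScattered(pool, anchors, k = 1)
    expect_identical(encodeBicluster(one[[1]]), rep(1L, 4))
    two <- selectScattered(pool, anchors, k = 2)
    expect_identical(encodeBicluster(two[[1]]), rep(1L, 4))
    expect_identical(encodeBicluster(two[[2]]), c(0L, 0L, 0L, 1L))
    expect_error(selectScattered(pool, anchors, k = 4), "shortage")
})

test_that("a single search restart is deterministic per seed", {
    sim <- makeSyntheticMatrix(20, 10, list(ImplantSpec(5, 4)), seed = 2)
    param <- ScatterSearchParam(numBiclusters = 1, numIterations = 2,
        refSetSize = 6, populationSize = 30)
    b1 <- scatterSearchOnce(sim$matrix, param, seed = 8)
    b2 <- scatterSearchOnce(sim$matrix, param, seed = 8)
    expect_identical(b1, b2)
    expect_s4_class(b1, "Bicluster")
})

test_that("with zero iterations the best of the initial reference set is returned", {
    sim <- makeSyntheticMatrix(20, 10, list(ImplantSpec(5, 4)), seed = 2)
    param0 <- ScatterSearchParam(numBiclusters = 1, numIterations = 0,
        refSetSize = 6, populationSize = 30)
    b <- scatterSearchOnce(sim$matrix, param0, seed = 4, details = TRUE)
    expect_s4_class(b$bicluster, "Bicluster")
    expect_length(b$trace$innerBest, 0)
    ## it must be the fitness-best of a freshly built reference set: its
    ## fitness cannot beat an identical run that also evolves the set
    bFull <- scatterSearchOnce(sim$matrix,
        ScatterSearchParam(numBiclusters = 1, numIterations = 3,
            refSetSize = 6, populationSize = 30), seed = 4, details = TRUE)
    expect_lte(bFull$score@fitness, b$score@fitness)
})

test_that("search invariants hold: monotone best fitness, stability, disjointness", {
    sim <- makeSyntheticMatrix(25, 12, list(ImplantSpec(6, 5)), seed = 3)
    for (s in 1:3) {
        res <- scatterSearchOnce(sim$matrix,
            ScatterSearchParam(numBiclusters = 1, numIterations = 4,
                refSetSize = 6, populationSize = 40),
            seed = s, details = TRUE)
        tr <- res$trace
        for (it in seq_along(tr$innerBest)) {
            v <- tr$innerBest[[it]]
            if (length(v) > 1)
                expect_true(all(diff(v) <= 1e-12))
        }
        expect_true(all(tr$stable))
        expect_true(all(tr$disjoint))
    }
})

test_that("the full run reports numBiclusters results with coherent statistics", {
    sim <- makeSyntheticMatrix(20, 10, list(ImplantSpec(5, 4)), seed = 6)
    param <- ScatterSearchParam(numBiclusters = 3, numIterations = 2,
        refSetSize = 4, populationSize = 25)
    res <- scatterSearch(sim$matrix, param, seed = 10)
    expect_s4_class(res, "BiclusterSet")
    expect_length(res, 3)
    df <- as.data.frame(res)
    expect_identical(nrow(df), 3L)
    expect_identical(df$volume, df$nGenes * df$nConditions)
    expect_named(df, c("id", "nGenes", "nConditions", "volume", "avgCorr",
        "corrSd", "fitness", "msr", "geneVariance"))
    b1 <- res[[1]]
    expect_equal(df$fitness[1],
        biclusterFitness(b1, sim$matrix, param@M1, param@M2))

    res2 <- scatterSearch(sim$matrix, param, seed = 10)
    expect_identical(as.data.frame(res2), df)
})

test_that("parameter validation rejects impossible configurations", {
    expect_error(ScatterSearchParam(refSetSize = 7), "even")
    expect_error(ScatterSearchParam(refSetSize = 10, populationSize = 10),
        "exceed")
    expect_error(ScatterSearchParam(M1 = -1), "non-negative")
})
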