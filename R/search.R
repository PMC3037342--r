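## ---------------------------------------------------------------------------
## Scatter Search engine. Internally candidates are plain lists
## (bits, g, c, key, fit, rho, sd) for speed; the exported surface converts
## to and from Bicluster objects.
## ---------------------------------------------------------------------------

#' Diversification generation rule
#'
#' Given a seed bit string of length n and a stride h, complements the bits
#' at positions 1, 1 + h, 1 + 2h, ... (1-based, while within the string)
#' and copies all other bits. With h = 1 this is the bitwise complement.
#' The initial population is built by applying the rule for every stride of
#' the population schedule (1 <= h < n/5), then re-seeding from the last
#' generated solution until enough distinct solutions exist; the rule
#' itself accepts any stride `1 <= h < n`.
#'
#' @param seed integer 0/1 vector.
#' @param h stride, an integer with `1 <= h < length(seed)`.
#' @return the diversified 0/1 vector, same length as `seed`.
#' @examples
#' diversifyBits(rep(0L, 10), h = 2)  # 1 0 1 0 1 0 1 0 1 0
#' diversifyBits(rep(0L, 10), h = 3)  # 1 0 0 1 0 0 1 0 0 1
#' @export
diversifyBits <- function(seed, h) {
    n <- length(seed)
    if (h < 1 || h >= n || h != round(h))
        stop(sprintf("stride h must satisfy 1 <= h < n = %d", n))
    .diversifyCore(as.integer(seed), as.integer(h))
}

.diversifyCore <- function(seed, h) {
    out <- seed
    pos <- seq.int(1L, length(seed), by = h)
    out[pos] <- 1L - out[pos]
    out
}

## Generate `size` distinct bit strings of length n (keys not in `exclude`),
## cycling the diversification rule over strides 1..hMax and re-seeding from
## the last generated solution; a sterile full pass draws a fresh random seed.
.genBits <- function(n, size, hMax, exclude = character()) {
    seen <- new.env(parent = emptyenv(), hash = TRUE)
    for (k in exclude) assign(k, TRUE, envir = seen)
    out <- vector("list", size)
    cnt <- 0L
    seed <- sample(c(0L, 1L), n, replace = TRUE)
    repeat {
        added <- 0L
        last <- seed
        for (h in seq_len(hMax)) {
            x <- .diversifyCore(seed, h)
            last <- x
            k <- paste(x, collapse = "")
            if (is.null(seen[[k]])) {
                assign(k, TRUE, envir = seen)
                cnt <- cnt + 1L
                out[[cnt]] <- x
                added <- added + 1L
                if (cnt == size)
                    return(out)
            }
        }
        seed <- if (added > 0L) last else sample(c(0L, 1L), n, replace = TRUE)
    }
}

#' Generate the diverse initial population
#'
#' Builds `size` pairwise-distinct biclusters of `mat` with the
#' diversification generation rule (see [diversifyBits()]) started from a
#' random seed string. Deterministic for a given `seed`.
#'
#' @param mat expression matrix (genes x conditions).
#' @param size number of solutions.
#' @param param a [ScatterSearchParam-class] (only `hMaxDivisor` is used).
#' @param seed optional integer seed for reproducibility.
#' @return list of [Bicluster-class] objects, all distinct.
#' @export
generatePopulation <- function(mat, size = 200L,
                               param = ScatterSearchParam(), seed = NULL) {
    mat <- .checkMatrix(mat)
    if (!is.null(seed)) set.seed(seed)
    N <- nrow(mat); L <- ncol(mat)
    n <- N + L
    hMax <- max(1L, as.integer(ceiling(n / param@hMaxDivisor)) - 1L)
    lapply(.genBits(n, as.integer(size), hMax), decodeBicluster, N = N, L = L)
}

#' Uniform crossover of two binary encodings
#'
#' The child takes the bit of `a` where the mask is 1 and the bit of `b`
#' where it is 0. When `mask` is omitted it is drawn uniformly (each
#' position 1 with probability 1/2) from the current RNG stream.
#'
#' @param a,b equal-length integer 0/1 vectors (the parents).
#' @param mask optional 0/1 vector of the same length.
#' @return the child 0/1 vector.
#' @examples
#' crossoverBits(c(0L,0L,0L,0L), c(1L,1L,1L,1L), mask = c(1L,0L,1L,0L))
#' # 0 1 0 1
#' @export
crossoverBits <- function(a, b, mask = NULL) {
    if (length(a) != length(b))
        stop("dimension mismatch: parents differ in length")
    if (is.null(mask))
        mask <- sample(c(0L, 1L), length(a), replace = TRUE)
    if (length(mask) != length(a))
        stop("dimension mismatch: mask length differs from parents")
    ifelse(mask == 1L, a, b)
}

#' Combine all reference-set pairs
#'
#' Applies uniform crossover to every unordered pair of the given
#' biclusters, yielding exactly `S * (S - 1) / 2` children (S = number of
#' inputs). Children may be degenerate (empty gene or condition sets);
#' they are representable and receive worst fitness downstream.
#'
#' @param biclusters list of [Bicluster-class] objects sharing one parent
#'   matrix shape.
#' @return list of child [Bicluster-class] objects.
#' @export
combineAll <- function(biclusters) {
    S <- length(biclusters)
    if (S < 2L)
        stop("need at least 2 biclusters to combine")
    d <- biclusters[[1L]]@parentDim
    bits <- lapply(biclusters, encodeBicluster)
    children <- vector("list", S * (S - 1L) %/% 2L)
    k <- 0L
    for (i in seq_len(S - 1L)) {
        for (j in (i + 1L):S) {
            k <- k + 1L
            children[[k]] <- decodeBicluster(
                crossoverBits(bits[[i]], bits[[j]]), d[1L], d[2L])
        }
    }
    children
}

#' Quality and diversity selection
#'
#' `selectBest` returns the `k` distinct biclusters with the lowest fitness
#' (ties broken by first appearance in the input). `selectScattered`
#' greedily picks from `pool` the bicluster maximizing its minimum Hamming
#' distance to `anchors` plus the already-picked ones — the diversity rule
#' used for the reference set's second half.
#'
#' @param candidates,pool,anchors lists of [Bicluster-class] objects
#'   sharing a parent matrix shape.
#' @param mat the parent expression matrix (for fitness evaluation).
#' @param k how many to select.
#' @param M1,M2 fitness penalty weights.
#' @return list of `k` selected [Bicluster-class] objects.
#' @export
selectBest <- function(candidates, mat, k, M1 = 1, M2 = 1) {
    keys <- vapply(candidates, function(b) paste(encodeBicluster(b), collapse = ""), "")
    candidates <- candidates[!duplicated(keys)]
    if (k > length(candidates))
        stop("shortage: fewer distinct candidates than requested")
    fit <- vapply(candidates, biclusterFitness, 0, mat = mat, M1 = M1, M2 = M2)
    candidates[order(fit)[seq_len(k)]]
}

#' @rdname selectBest
#' @export
selectScattered <- function(pool, anchors, k) {
    if (k > length(pool))
        stop("shortage: pool smaller than requested selection")
    if (k == 0L)
        return(pool[0])
    poolBits <- lapply(pool, encodeBicluster)
    anchorBits <- lapply(anchors, encodeBicluster)
    idx <- .selectScatteredIdx(poolBits, anchorBits, k)
    pool[idx]
}

## greedy max-min Hamming selection on lists of bit vectors; ties go to the
## earliest pool member (which.max)
.selectScatteredIdx <- function(poolBits, anchorBits, k) {
    np <- length(poolBits)
    minD <- rep.int(Inf, np)
    for (a in anchorBits) {
        d <- vapply(poolBits, function(x) sum(x != a), 0)
        minD <- pmin(minD, d)
    }
    picked <- integer(0)
    avail <- rep.int(TRUE, np)
    for (step in seq_len(k)) {
        cand <- which(avail)
        sel <- cand[which.max(minD[cand])]
        picked <- c(picked, sel)
        avail[sel] <- FALSE
        d <- vapply(poolBits, function(x) sum(x != poolBits[[sel]]), 0)
        minD <- pmin(minD, d)
    }
    picked
}

## ---- internal candidate handling ------------------------------------------

## decode + improve + score a bit string in one pass, reusing the gene
## correlation matrix between pruning and fitness
.newCand <- function(bits, N, L, vals, M1, M2, mode, improve = TRUE) {
    g <- which(bits[seq_len(N)] == 1L)
    co <- which(bits[N + seq_len(L)] == 1L)
    rho <- NA_real_; sdv <- NA_real_
    if (length(g) >= 2L && length(co) >= 2L) {
        C <- .geneCorrMatrix(vals, g, co)
        if (improve) {
            kept <- .improveKeep(C, mode)
            if (length(kept) < length(g)) {
                bits[g[-kept]] <- 0L
                g <- g[kept]
                C <- C[kept, kept, drop = FALSE]
            }
        }
        if (length(g) >= 2L) {
            s <- .corrSummary(C)
            rho <- s$avgCorr; sdv <- s$corrSd
        }
    }
    fit <- if (length(g) >= 2L && length(co) >= 2L)
        .fitnessFromScores(rho, sdv, length(g), length(co), M1, M2)
    else Inf
    list(bits = bits, g = g, c = co, key = paste(bits, collapse = ""),
        fit = fit, rho = rho, sd = sdv)
}

.candKeys <- function(cands) vapply(cands, `[[`, "", "key")
.candFits <- function(cands) vapply(cands, `[[`, 0, "fit")
.dedupeCands <- function(cands) cands[!duplicated(.candKeys(cands))]
.bestIdx <- function(cands, k) order(.candFits(cands))[seq_len(k)]

.candToBicluster <- function(cand, N, L) {
    new("Bicluster", geneIndices = as.integer(cand$g),
        conditionIndices = as.integer(cand$c),
        parentDim = as.integer(c(N, L)))
}

## `size` distinct diversification strings, improved and scored; the
## improvement step can collapse distinct strings onto one solution, so the
## returned population may be slightly smaller after de-duplication
.makePopulation <- function(vals, size, hMax, M1, M2, mode,
                            exclude = character()) {
    N <- nrow(vals); L <- ncol(vals)
    bitsList <- .genBits(N + L, size, hMax, exclude = exclude)
    cands <- lapply(bitsList, .newCand, N = N, L = L, vals = vals,
        M1 = M1, M2 = M2, mode = mode)
    cands <- .dedupeCands(cands)
    cands[!(.candKeys(cands) %in% exclude)]
}

## one complete Scatter Search run; assumes the RNG is positioned
.ssEngine <- function(vals, param, details = FALSE) {
    N <- nrow(vals); L <- ncol(vals)
    n <- N + L
    S <- param@refSetSize
    half <- S %/% 2L
    M1 <- param@M1; M2 <- param@M2
    mode <- param@improveMode
    hMax <- max(1L, as.integer(ceiling(n / param@hMaxDivisor)) - 1L)

    pop <- .makePopulation(vals, param@populationSize, hMax, M1, M2, mode)
    while (length(pop) < S)
        pop <- c(pop, .makePopulation(vals, param@populationSize, hMax,
            M1, M2, mode, exclude = .candKeys(pop)))

    ## build reference set: S/2 by quality, S/2 by max-min Hamming diversity
    bi <- .bestIdx(pop, half)
    R1 <- pop[bi]
    rest <- pop[-bi]
    si <- .selectScatteredIdx(lapply(rest, `[[`, "bits"),
        lapply(R1, `[[`, "bits"), half)
    refset <- c(R1, rest[si])
    pop <- rest[-si]

    trace <- if (details)
        list(innerBest = vector("list", param@numIterations),
             stable = logical(param@numIterations),
             disjoint = logical(param@numIterations))
    else NULL

    iter <- 0L
    while (iter < param@numIterations) {
        iter <- iter + 1L
        ## update to stability: combine all pairs, improve offspring, keep
        ## the S best of the union (incumbents win ties, so the loop
        ## terminates once no strict improvement remains)
        stable <- FALSE
        guard <- 0L
        innerBest <- numeric(0)
        while (!stable) {
            guard <- guard + 1L
            if (guard > 1000L) {
                warning("inner loop failed to stabilize after 1000 updates")
                break
            }
            prevKeys <- sort(.candKeys(refset))
            children <- vector("list", S * (S - 1L) %/% 2L)
            k <- 0L
            for (i in seq_len(S - 1L)) {
                for (j in (i + 1L):S) {
                    k <- k + 1L
                    mask <- sample(c(0L, 1L), n, replace = TRUE)
                    bits <- ifelse(mask == 1L, refset[[i]]$bits, refset[[j]]$bits)
                    children[[k]] <- .newCand(bits, N, L, vals, M1, M2, mode)
                }
            }
            union <- .dedupeCands(c(refset, children))
            refset <- union[.bestIdx(union, S)]
            innerBest <- c(innerBest, refset[[1L]]$fit)
            stable <- identical(sort(.candKeys(refset)), prevKeys)
        }

        ## rebuild: keep the quality half, refresh the diversity half from
        ## the (remaining or regenerated) population
        R1 <- refset[.bestIdx(refset, half)]
        while (length(pop) < half)
            pop <- c(pop, .makePopulation(vals, param@populationSize, hMax,
                M1, M2, mode, exclude = c(.candKeys(R1), .candKeys(pop))))
        si <- .selectScatteredIdx(lapply(pop, `[[`, "bits"),
            lapply(R1, `[[`, "bits"), half)
        refset <- c(R1, pop[si])
        pop <- pop[-si]

        if (details) {
            trace$innerBest[[iter]] <- innerBest
            trace$stable[iter] <- stable
            trace$disjoint[iter] <-
                !any(.candKeys(pop) %in% .candKeys(refset))
        }
    }

    best <- refset[[.bestIdx(refset, 1L)]]
    list(best = best, trace = trace)
}

#' Run one Scatter Search and return its best bicluster
#'
#' A single restart of the search: generate and improve the initial
#' population, build the reference set (S/2 best by fitness, S/2 most
#' scattered by Hamming distance), then repeat `numIterations` times
#' \{combine all reference-set pairs, improve the offspring, keep the S
#' best of the union until the set stabilizes; rebuild the diversity half
#' from the population\}. Returns the best member of the final reference
#' set. With `numIterations = 0` the best member of the initially built
#' reference set is returned.
#'
#' @param mat expression matrix (genes x conditions).
#' @param param a [ScatterSearchParam-class].
#' @param seed optional integer; runs with equal seeds are identical.
#' @param details if `TRUE`, return a list with the bicluster, its
#'   [BiclusterScore-class], and a per-iteration trace (best fitness after
#'   each inner update, whether stability was reached, and whether the
#'   population stayed disjoint from the reference set).
#' @return a [Bicluster-class], or a list when `details = TRUE`.
#' @export
scatterSearchOnce <- function(mat, param = ScatterSearchParam(), seed = NULL,
                              details = FALSE) {
    mat <- .checkMatrix(mat)
    validObject(param)
    if (!is.null(seed)) set.seed(seed)
    res <- .ssEngine(mat, param, details = details)
    b <- .candToBicluster(res$best, nrow(mat), ncol(mat))
    if (!details)
        return(b)
    list(bicluster = b,
        score = scoreBicluster(b, mat, M1 = param@M1, M2 = param@M2),
        trace = res$trace)
}

#' Scatter Search biclustering
#'
#' The full algorithm: `numBiclusters` independent Scatter Search restarts
#' (each from a fresh diversification-generated population and its own RNG
#' substream), each contributing the best bicluster of its final reference
#' set. Results are returned with the standard per-bicluster statistics:
#' number of genes and conditions, volume, average correlation rho(B), its
#' standard deviation, fitness, mean squared residue and gene variance.
#'
#' @inheritParams scatterSearchOnce
#' @param verbose print per-restart progress (best fitness) to the console.
#' @return a [BiclusterSet-class].
#' @examples
#' sim <- makeSyntheticMatrix(30, 12,
#'     implants = list(ImplantSpec(6, 5)), seed = 1)
#' res <- scatterSearch(sim$matrix,
#'     ScatterSearchParam(numBiclusters = 2, numIterations = 2,
#'         populationSize = 40), seed = 1)
#' as.data.frame(res)
#' @export
scatterSearch <- function(mat, param = ScatterSearchParam(), seed = NULL,
                          verbose = FALSE) {
    mat <- .checkMatrix(mat)
    validObject(param)
    if (!is.null(seed)) set.seed(seed)
    numBi <- param@numBiclusters
    restartSeeds <- sample.int(.Machine$integer.max, numBi)
    biclusters <- vector("list", numBi)
    for (i in seq_len(numBi)) {
        set.seed(restartSeeds[i])
        res <- .ssEngine(mat, param)
        biclusters[[i]] <- .candToBicluster(res$best, nrow(mat), ncol(mat))
        if (verbose)
            message(sprintf("bicluster %d/%d: fitness %.4f", i, numBi,
                res$best$fit))
    }
    scores <- lapply(biclusters, scoreBicluster, mat = mat,
        M1 = param@M1, M2 = param@M2)
    summary <- data.frame(
        id = paste0("bi", seq_len(numBi)),
        nGenes = vapply(biclusters, nGenes, 0L),
        nConditions = vapply(biclusters, nConditions, 0L),
        volume = vapply(biclusters, volume, 0L),
        avgCorr = vapply(scores, slot, 0, "avgCorr"),
        corrSd = vapply(scores, slot, 0, "corrSd"),
        fitness = vapply(scores, slot, 0, "fitness"),
        msr = vapply(scores, slot, 0, "msr"),
        geneVariance = vapply(scores, slot, 0, "geneVariance"),
        stringsAsFactors = FALSE)
    new("BiclusterSet", biclusters = biclusters, summary = summary,
        param = param)
}
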