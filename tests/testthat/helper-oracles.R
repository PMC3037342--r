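## Independent brute-force oracles: scalar loops straight from the measure
## definitions, kept free of any package internals.

naivePearson <- function(x, y) {
    n <- length(x)
    dx <- x - mean(x)
    dy <- y - mean(y)
    sx <- sqrt(sum(dx^2) / n)
    sy <- sqrt(sum(dy^2) / n)
    if (sx == 0 || sy == 0)
        return(0)
    sum(dx * dy) / (n * sx * sy)
}

naivePairwise <- function(sub) {
    nG <- nrow(sub)
    vals <- c()
    for (i in seq_len(nG - 1)) {
        for (j in (i + 1):nG) {
            vals <- c(vals, naivePearson(sub[i, ], sub[j, ]))
        }
    }
    vals
}

naiveAvgCorr <- function(sub) mean(naivePairwise(sub))

naiveCorrSd <- function(sub) {
    v <- naivePairwise(sub)
    sqrt(mean((v - mean(v))^2))
}

naiveMSR <- function(sub) {
    aIJ <- mean(sub)
    total <- 0
    for (i in seq_len(nrow(sub))) {
        for (j in seq_len(ncol(sub))) {
            r <- sub[i, j] - mean(sub[i, ]) - mean(sub[, j]) + aIJ
            total <- total + r^2
        }
    }
    total / (nrow(sub) * ncol(sub))
}

naiveGeneVariance <- function(sub) {
    total <- 0
    for (i in seq_len(nrow(sub))) {
        for (j in seq_len(ncol(sub))) {
            total <- total + (sub[i, j] - mean(sub[i, ]))^2
        }
    }
    total / (nrow(sub) * ncol(sub))
}

## gene-by-condition matrix whose first `nPattern` rows are positive affine
## transforms of one base profile, remaining rows independent noise
affinePatternMatrix <- function(nPattern, nC, nNoise = 0, alphas = NULL,
                                betas = NULL, profile = NULL) {
    if (is.null(profile)) profile <- rnorm(nC)
    if (is.null(alphas)) alphas <- runif(nPattern, 0.5, 2)
    if (is.null(betas)) betas <- runif(nPattern, -2, 2)
    top <- outer(alphas, profile) + betas
    mat <- if (nNoise > 0) rbind(top, matrix(rnorm(nNoise * nC), nNoise, nC))
        else top
    rownames(mat) <- paste0("g", seq_len(nrow(mat)))
    colnames(mat) <- paste0("c", seq_len(ncol(mat)))
    mat
}

randomExpressionMatrix <- function(n, l) {
    matrix(rnorm(n * l), n, l,
        dimnames = list(paste0("g", seq_len(n)), paste0("c", seq_len(l))))
}
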