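# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct matrix algebra, explicit loops, closed
# forms.

# Direct evaluation of the 2SLS matrix expression
# [X'Z(Z'Z)^-1 Z'X]^-1 X'Z(Z'Z)^-1 Z'Y on centered data.
oracle_tsls <- function(x, y, z) {
    z <- as.matrix(z)
    xc <- x - mean(x)
    yc <- y - mean(y)
    zc <- sweep(z, 2L, colMeans(z))
    a <- t(xc) %*% zc %*% solve(t(zc) %*% zc) %*% t(zc) %*% xc
    b <- t(xc) %*% zc %*% solve(t(zc) %*% zc) %*% t(zc) %*% yc
    as.numeric(b / a)
}

oracle_wald <- function(x, y, z) {
    cov(z, y) / cov(z, x)
}

# Greedy clumping replayed with explicit loops over a correlation matrix.
oracle_clump <- function(pvals, cors, r2) {
    ord <- order(pvals, seq_along(pvals))
    kept <- integer()
    for (j in ord) {
        if (all(cors[j, kept]^2 < r2)) kept <- c(kept, j)
    }
    sort(kept)
}

# Jackknife IV: leave-one-out first-stage least squares on a fixed variant
# set, prediction for the left-out row, then 2SLS with that instrument.
oracle_jive <- function(g, x, y) {
    n <- length(x)
    inst <- numeric(n)
    for (i in seq_len(n)) {
        d <- cbind(1, g[-i, , drop = FALSE])
        cf <- solve(t(d) %*% d, t(d) %*% x[-i])
        inst[i] <- c(1, g[i, ]) %*% cf
    }
    oracle_tsls(x, y, inst)
}

oracle_meta <- function(b, s) {
    w <- 1 / s^2
    c(sum(w * b) / sum(w), sqrt(1 / sum(w)))
}

# Simulation shorthand used by several files.
std_config <- function(n, h2 = 0.2, beta0 = 0, sigmaUV = 0.8, seed = 1,
                       nVariants = 300L, nCausal = 5L, maf = 0.3) {
    simulationConfig(nIndividuals = n, nVariants = nVariants,
                     nCausal = nCausal, maf = maf, h2 = h2, beta0 = beta0,
                     sigmaU2 = 5, sigmaV2 = 5, sigmaUV = sigmaUV,
                     seed = seed)
}
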