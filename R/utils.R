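# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Residualize columns of m on [1, covariates]; with covariates = NULL this is
# plain centering. Returns a matrix of the same shape.
residualize <- function(m, covariates = NULL) {
    m <- as.matrix(m)
    if (is.null(covariates)) {
        return(sweep(m, 2L, colMeans(m)))
    }
    design <- cbind(1, as.matrix(covariates))
    qr_d <- qr(design)
    m - qr.fitted(qr_d, m)
}

# Coerce a cohort or matrix argument to the individuals x variants matrix.
asDosageMatrix <- function(genotypes) {
    if (is(genotypes, "MRCohort")) return(dosages(genotypes))
    g <- as.matrix(genotypes)
    if (is.null(colnames(g)))
        colnames(g) <- paste0("variant_", seq_len(ncol(g)))
    g
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

Z975 <- qnorm(0.975)

# Assemble an IVEstimate from a point estimate and its variance.
makeIVEstimate <- function(beta, var, method, n, k = NA_integer_,
                           nInstruments = 1L, nDegenerate = 0L) {
    se <- sqrt(var)
    z <- beta / se
    new("IVEstimate", betaHat = beta, se = se,
        ciLow = beta - Z975 * se, ciHigh = beta + Z975 * se,
        pvalue = 2 * pnorm(-abs(z)), method = method, n = as.integer(n),
        k = as.integer(k), nInstruments = as.integer(nInstruments),
        nDegenerate = as.integer(nDegenerate))
}
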