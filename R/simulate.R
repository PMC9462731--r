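#' Construct a simulation configuration
#'
#' Convenience constructor for [SimulationConfig-class] with the default
#' scenario of the package's Monte-Carlo studies: 300 independent variants at
#' minor allele frequency 0.3, of which the first five act on the exposure,
#' error variances of 5 with covariance 0.8, and the causal variants
#' calibrated to explain \code{h2} of the exposure variance.
#'
#' @param nIndividuals cohort size N.
#' @param nVariants total number of variants simulated.
#' @param nCausal number of causal variants (the first columns).
#' @param maf minor allele frequency in (0, 0.5].
#' @param h2 fraction of exposure variance explained by the causal variants.
#' @param beta0 causal effect of exposure on outcome.
#' @param sigmaU2,sigmaV2 error variances of outcome and exposure equations.
#' @param sigmaUV error covariance; nonzero values confound X and Y.
#' @param seed integer seed.
#' @return a validated [SimulationConfig-class].
#' @examples
#' simulationConfig(nIndividuals = 1000, h2 = 0.2, beta0 = 0.05, seed = 7)
#' @export
simulationConfig <- function(nIndividuals, nVariants = 300L, nCausal = 5L,
                             maf = 0.3, h2 = 0.2, beta0 = 0,
                             sigmaU2 = 5, sigmaV2 = 5, sigmaUV = 0.8,
                             seed = 1L) {
    new("SimulationConfig",
        nIndividuals = as.integer(nIndividuals),
        nVariants = as.integer(nVariants), nCausal = as.integer(nCausal),
        maf = maf, h2 = h2, beta0 = beta0, sigmaU2 = sigmaU2,
        sigmaV2 = sigmaV2, sigmaUV = sigmaUV, seed = as.integer(seed))
}

#' Construct an MR cohort from matrices and vectors
#'
#' @param genotypes individuals-by-variants dosage matrix; row names are
#'   individual identifiers, column names variant identifiers (generated when
#'   absent).
#' @param exposure,outcome numeric phenotype vectors of length nrow(genotypes).
#' @param covariates optional numeric matrix of covariates.
#' @param population optional character vector of population labels.
#' @param truePi optional length-nVariants vector of generative effects.
#' @param trueBeta0 optional generative causal effect.
#' @param seed optional integer seed the cohort was generated under.
#' @return an [MRCohort-class].
#' @examples
#' g <- matrix(rbinom(60, 2, 0.3), 20, 3)
#' MRCohort(g, exposure = rnorm(20), outcome = rnorm(20))
#' @export
MRCohort <- function(genotypes, exposure, outcome, covariates = NULL,
                     population = NULL, truePi = NULL, trueBeta0 = NULL,
                     seed = NULL) {
    g <- as.matrix(genotypes)
    if (is.null(colnames(g)))
        colnames(g) <- paste0("variant_", seq_len(ncol(g)))
    if (is.null(rownames(g)))
        rownames(g) <- paste0("ind_", seq_len(nrow(g)))
    stopIfNot(length(exposure) == nrow(g) && length(outcome) == nrow(g),
              "exposure and outcome must match the number of individuals")
    cd <- S4Vectors::DataFrame(exposure = as.numeric(exposure),
                               outcome = as.numeric(outcome),
                               row.names = rownames(g))
    if (!is.null(covariates)) {
        cv <- as.matrix(covariates)
        stopIfNot(nrow(cv) == nrow(g), "covariates must match individuals")
        if (is.null(colnames(cv)))
            colnames(cv) <- paste0("c", seq_len(ncol(cv)))
        for (j in seq_len(ncol(cv)))
            cd[[paste0("covariate_", colnames(cv)[j])]] <- cv[, j]
    }
    if (!is.null(population)) {
        stopIfNot(length(population) == nrow(g),
                  "population labels must match individuals")
        cd$population <- as.character(population)
    }
    rd <- S4Vectors::DataFrame(row.names = colnames(g))
    if (!is.null(truePi)) {
        stopIfNot(length(truePi) == ncol(g),
                  "truePi must have one entry per variant")
        rd$true_pi <- as.numeric(truePi)
    }
    md <- list()
    if (!is.null(trueBeta0)) md$true_beta0 <- trueBeta0
    if (!is.null(seed)) md$seed <- as.integer(seed)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = t(g)), colData = cd, rowData = rd,
        metadata = md)
    new("MRCohort", se)
}

#' Calibrate the per-variant effect size to a target heritability
#'
#' Returns the common effect \eqn{\pi \ge 0} such that \code{nCausal}
#' independent Binomial(2, maf) variants, each with effect \eqn{\pi}, explain
#' exactly the fraction \code{h2} of the exposure variance against a residual
#' variance \code{sigmaV2}:
#' \deqn{n_c \pi^2 \, 2\,maf(1-maf) = \frac{h^2}{1-h^2}\,\sigma_V^2.}
#'
#' @param h2 target variance-explained fraction in [0, 1).
#' @param nCausal number of causal variants (>= 1 when h2 > 0).
#' @param maf allele frequency in (0, 0.5].
#' @param sigmaV2 residual exposure variance (> 0).
#' @return scalar per-variant effect.
#' @examples
#' calibrateEffectSize(0.2, 5, 0.3, 5)   # ~0.7715
#' @export
calibrateEffectSize <- function(h2, nCausal, maf, sigmaV2) {
    stopIfNot(h2 >= 0 && h2 < 1, "h2 must lie in [0, 1)")
    stopIfNot(sigmaV2 > 0, "sigmaV2 must be positive")
    if (h2 == 0) return(0)
    stopIfNot(nCausal >= 1, "nCausal must be >= 1 when h2 > 0")
    stopIfNot(maf > 0 && maf <= 0.5,
              "maf must lie in (0, 0.5] when h2 > 0")
    sqrt(h2 * sigmaV2 / ((1 - h2) * nCausal * 2 * maf * (1 - maf)))
}

#' Simulate a dosage matrix of independent biallelic variants
#'
#' Entries are independent Binomial(2, maf) draws (Hardy-Weinberg dosages).
#' The same seed always yields the same matrix.
#'
#' @param nIndividuals,nVariants positive counts.
#' @param maf allele frequency in [0, 0.5].
#' @param seed integer seed.
#' @return integer matrix (individuals x variants) with dimnames.
#' @examples
#' g <- simulateGenotypes(100, 10, 0.3, seed = 1)
#' colMeans(g)  # ~ 2 * 0.3
#' @export
simulateGenotypes <- function(nIndividuals, nVariants, maf, seed) {
    stopIfNot(nIndividuals >= 1 && nVariants >= 1, "counts must be positive")
    stopIfNot(maf >= 0 && maf <= 0.5, "maf must lie in [0, 0.5]")
    g <- withSeed(seed, matrix(rbinom(nIndividuals * nVariants, 2L, maf),
                               nrow = nIndividuals, ncol = nVariants))
    dimnames(g) <- list(paste0("ind_", seq_len(nIndividuals)),
                        paste0("variant_", seq_len(nVariants)))
    g
}

# Draw n iid bivariate-normal (U, V) rows with the configured covariance.
drawErrors <- function(n, sigmaU2, sigmaV2, sigmaUV) {
    u <- rnorm(n, 0, sqrt(sigmaU2))
    # V | U is normal with mean (sigmaUV/sigmaU2) U and the Schur-complement
    # variance; exact for any admissible covariance.
    condVar <- sigmaV2 - sigmaUV^2 / sigmaU2
    v <- sigmaUV / sigmaU2 * u + rnorm(n, 0, sqrt(max(condVar, 0)))
    cbind(u = u, v = v)
}

#' Simulate a full synthetic cohort
#'
#' Generates genotypes, exposure and outcome under the linear structural
#' model: dosages are independent Binomial(2, maf); the exposure is
#' \eqn{X = Z\Pi + V} with \eqn{\Pi} equal to the calibrated effect on the
#' first \code{nCausal} variants and zero elsewhere; the outcome is
#' \eqn{Y = \beta_0 X + U}; \eqn{(U, V)} are iid bivariate normal with the
#' configured covariance. The result is bit-for-bit regenerable from the
#' configuration's seed.
#'
#' @param config a [SimulationConfig-class].
#' @return an [MRCohort-class] carrying the ground truth (\code{truePi},
#'   \code{trueBeta0}) used to generate it.
#' @examples
#' cohort <- simulateDataset(simulationConfig(200, seed = 3, beta0 = 0.05))
#' cor(exposure(cohort), outcome(cohort))
#' @export
simulateDataset <- function(config) {
    dat <- simulateCore(config)
    cohort <- MRCohort(dat$g, exposure = dat$x, outcome = dat$y,
                       truePi = dat$piVec, trueBeta0 = config@beta0,
                       seed = config@seed)
    S4Vectors::metadata(cohort)$config <- config
    cohort
}

# Shared generator: raw matrices/vectors without container overhead. Used by
# simulateDataset() and by the scenario driver; both therefore produce
# bit-identical draws for a given configuration.
simulateCore <- function(config) {
    validObject(config)
    n <- config@nIndividuals
    p <- config@nVariants
    pi_eff <- calibrateEffectSize(config@h2, config@nCausal, config@maf,
                                  config@sigmaV2)
    piVec <- c(rep(pi_eff, config@nCausal),
               rep(0, p - config@nCausal))
    dat <- withSeed(config@seed, {
        g <- matrix(rbinom(n * p, 2L, config@maf), nrow = n, ncol = p)
        err <- drawErrors(n, config@sigmaU2, config@sigmaV2, config@sigmaUV)
        list(g = g, err = err)
    })
    gx <- if (config@nCausal > 0)
        dat$g[, seq_len(config@nCausal), drop = FALSE] %*%
            rep(pi_eff, config@nCausal)
    else rep(0, n)
    x <- as.numeric(gx) + dat$err[, "v"]
    y <- config@beta0 * x + dat$err[, "u"]
    dimnames(dat$g) <- list(paste0("ind_", seq_len(n)),
                            paste0("variant_", seq_len(p)))
    list(g = dat$g, x = x, y = y, piVec = piVec)
}

#' Simulate two populations sharing one causal effect
#'
#' Generates two independent cohorts that may differ in allele frequency,
#' heritability, genetic architecture and error covariance, but share the
#' causal effect \code{sharedBeta0} (which overrides each configuration's
#' \code{beta0}). Stratum labels ("A", "B") and concatenation order are
#' stable.
#'
#' @param configA,configB [SimulationConfig-class] objects for the strata.
#' @param sharedBeta0 common causal effect.
#' @return named list of two [MRCohort-class] objects with population labels
#'   set, in the fixed order A then B.
#' @examples
#' a <- simulationConfig(300, h2 = 0.2, seed = 1)
#' b <- simulationConfig(300, h2 = 0.05, maf = 0.2, seed = 2)
#' str(simulateTwoPopulations(a, b, sharedBeta0 = 1), max.level = 1)
#' @export
simulateTwoPopulations <- function(configA, configB, sharedBeta0) {
    cohorts <- list(A = configA, B = configB)
    out <- vector("list", 2L)
    names(out) <- names(cohorts)
    for (i in seq_along(cohorts)) {
        cfg <- cohorts[[i]]
        cfg@beta0 <- sharedBeta0
        validObject(cfg)
        cohort <- simulateDataset(cfg)
        SummarizedExperiment::colData(cohort)$population <- names(out)[i]
        colnames(cohort) <- paste0(names(out)[i], "_", seq_len(ncol(cohort)))
        out[[i]] <- cohort
    }
    out
}
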