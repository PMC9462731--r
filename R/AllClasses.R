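#' @import methods
#' @importFrom stats coef cor pnorm predict qnorm rbinom rnorm sd var
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Simulation configuration for a synthetic MR cohort
#'
#' Holds every parameter of the generative model used throughout the package:
#' independent biallelic variants with dosages drawn as Binomial(2, maf), an
#' exposure built from a sparse linear genetic model
#' \eqn{X = Z \Pi + V}, and an outcome \eqn{Y = \beta_0 X + U} with
#' \eqn{(U, V)} bivariate normal so that \code{sigmaUV != 0} induces
#' confounding between exposure and outcome.
#'
#' @slot nIndividuals integer, cohort size N.
#' @slot nVariants integer, total number of simulated variants.
#' @slot nCausal integer, number of variants (the first columns) with a
#'   nonzero effect on the exposure.
#' @slot maf allele frequency in (0, 0.5] (0 allowed only when \code{h2 = 0}).
#' @slot h2 fraction of exposure variance explained by the causal variants,
#'   in [0, 1).
#' @slot beta0 causal effect of the exposure on the outcome.
#' @slot sigmaU2,sigmaV2 variances of the outcome- and exposure-side errors.
#' @slot sigmaUV covariance of (U, V); nonzero values confound X and Y.
#' @slot seed integer RNG seed; a dataset is bit-for-bit regenerable from it.
#'
#' @seealso [simulationConfig()], [simulateDataset()]
#' @export
setClass("SimulationConfig",
    representation(
        nIndividuals = "integer",
        nVariants    = "integer",
        nCausal      = "integer",
        maf          = "numeric",
        h2           = "numeric",
        beta0        = "numeric",
        sigmaU2      = "numeric",
        sigmaV2      = "numeric",
        sigmaUV      = "numeric",
        seed         = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
    if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
    if (object@nCausal < 0L || object@nCausal > object@nVariants)
        msg <- c(msg, "nCausal must lie in [0, nVariants]")
    if (object@maf < 0 || object@maf > 0.5)
        msg <- c(msg, "maf must lie in [0, 0.5]")
    if (object@h2 < 0 || object@h2 >= 1)
        msg <- c(msg, "h2 must lie in [0, 1)")
    if (object@h2 > 0 && object@nCausal < 1L)
        msg <- c(msg, "nCausal must be >= 1 when h2 > 0")
    if (object@h2 > 0 && object@maf == 0)
        msg <- c(msg, "maf must be positive when h2 > 0")
    if (object@sigmaU2 <= 0 || object@sigmaV2 <= 0)
        msg <- c(msg, "error variances must be positive")
    if (abs(object@sigmaUV) > sqrt(object@sigmaU2 * object@sigmaV2) + 1e-12)
        msg <- c(msg, "|sigmaUV| must not exceed sqrt(sigmaU2 * sigmaV2)")
    if (length(msg)) msg else TRUE
})

#' Synthetic MR cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a genotype dosage
#' assay (variants in rows, individuals in columns, entries in \{0, 1, 2\}),
#' phenotypes in \code{colData} (\code{exposure}, \code{outcome}, optional
#' covariate columns and an optional \code{population} label), the true
#' per-variant effects in \code{rowData(x)$true_pi} (when simulated), and the
#' generative parameters in \code{metadata}.
#'
#' Use [dosages()] to obtain the individuals-by-variants matrix that the
#' statistical functions consume.
#'
#' @seealso [MRCohort()], [simulateDataset()], [readCohort()]
#' @export
setClass("MRCohort", contains = "SummarizedExperiment")

setValidity("MRCohort", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "an assay named 'dosage' is required")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("exposure", "outcome"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (length(msg)) msg else TRUE
})

#' Random K-fold partition of observation indices
#'
#' Disjoint folds covering 1..n with sizes differing by at most one; when k
#' does not divide n the first \code{n mod k} folds receive one extra element.
#'
#' @slot n total sample size.
#' @slot k number of folds.
#' @slot folds list of K disjoint integer index vectors.
#' @slot seed integer seed the partition was drawn under.
#'
#' @seealso [makeFolds()]
#' @export
setClass("FoldPartition",
    representation(n = "integer", k = "integer", folds = "list",
                   seed = "integer")
)

setValidity("FoldPartition", function(object) {
    idx <- sort(unlist(object@folds, use.names = FALSE))
    msg <- character()
    if (length(object@folds) != object@k)
        msg <- c(msg, "number of folds must equal k")
    if (!identical(idx, seq_len(object@n)))
        msg <- c(msg, "folds must be disjoint and cover 1..n exactly")
    sizes <- lengths(object@folds)
    if (length(sizes) && diff(range(sizes)) > 1L)
        msg <- c(msg, "fold sizes must differ by at most 1")
    if (length(msg)) msg else TRUE
})

#' Marginal association scan of an exposure on variant dosages
#'
#' Per-variant simple linear regression of the exposure on the dosage
#' (both residualized on covariates when supplied), restricted to a given
#' index set. Zero-variance variants are flagged and reported with p = 1.
#'
#' @slot variantIds character variant identifiers.
#' @slot beta,se,pvalue per-variant slope, standard error and two-sided
#'   p-value from the t distribution.
#' @slot nUsed number of individuals in the scan.
#' @slot indices the index set the scan was restricted to.
#' @slot flagged logical, TRUE for variants with undefined slopes.
#'
#' @seealso [marginalScan()], [greedyClump()], [selectByPvalue()]
#' @export
setClass("AssociationScan",
    representation(variantIds = "character", beta = "numeric",
                   se = "numeric", pvalue = "numeric", nUsed = "integer",
                   indices = "integer", flagged = "logical")
)

setValidity("AssociationScan", function(object) {
    p <- length(object@variantIds)
    msg <- character()
    if (length(object@beta) != p || length(object@se) != p ||
        length(object@pvalue) != p || length(object@flagged) != p)
        msg <- c(msg, "beta, se, pvalue, flagged must match variantIds")
    pv <- object@pvalue[!is.na(object@pvalue)]
    if (any(pv < 0 | pv > 1)) msg <- c(msg, "pvalues must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Trained per-fold exposure predictor
#'
#' An affine function of the selected dosage columns only: intercept plus
#' the weighted sum of the selected dosages. A predictor with an
#' empty selection (or one whose penalty removed every coefficient) is
#' intercept-only and flagged \code{degenerate}.
#'
#' @slot selectedIds variant identifiers entering the predictor.
#' @slot weights per-selected-variant coefficients (named).
#' @slot intercept scalar intercept.
#' @slot trainingIndices rows used for training (a fold complement in the
#'   cross-fitting pipeline).
#' @slot method one of "lasso", "allele-score", "ols", "fixed".
#' @slot trainingR2 squared correlation of prediction and exposure on the
#'   training set (0 when degenerate).
#' @slot lambda penalty at which a lasso predictor was extracted (NA
#'   otherwise).
#' @slot degenerate logical flag.
#'
#' @seealso [fitPredictor()], [predictExposure()]
#' @export
setClass("FittedPredictor",
    representation(selectedIds = "character", weights = "numeric",
                   intercept = "numeric", trainingIndices = "integer",
                   method = "character", trainingR2 = "numeric",
                   lambda = "numeric", degenerate = "logical")
)

setValidity("FittedPredictor", function(object) {
    if (length(object@weights) != length(object@selectedIds))
        return("weights must match selectedIds")
    TRUE
})

#' Cross-fitted instrument
#'
#' The length-N vector of out-of-fold exposure predictions: on fold k it
#' equals the prediction of a model trained on the fold's complement, so no
#' individual's exposure (or outcome) enters the model that predicts it.
#'
#' @slot values numeric length-N instrument vector.
#' @slot foldOf integer length-N map from individual to fold.
#' @slot predictors list of K [FittedPredictor-class] objects.
#' @slot heldoutR2 per-fold squared correlation of the instrument with the
#'   observed exposure on the held-out fold (0 and flagged when degenerate).
#' @slot degenerate logical length-K flags.
#' @slot partition the [FoldPartition-class] used.
#'
#' @seealso [buildCFI()], [cfmr1()], [cfmr2()]
#' @export
setClass("CrossFittedInstrument",
    representation(values = "numeric", foldOf = "integer",
                   predictors = "list", heldoutR2 = "numeric",
                   degenerate = "logical", partition = "FoldPartition")
)

setValidity("CrossFittedInstrument", function(object) {
    msg <- character()
    n <- object@partition@n
    k <- object@partition@k
    if (length(object@values) != n) msg <- c(msg, "values must have length n")
    if (length(object@foldOf) != n) msg <- c(msg, "foldOf must have length n")
    if (length(object@predictors) != k || length(object@heldoutR2) != k ||
        length(object@degenerate) != k)
        msg <- c(msg, "per-fold slots must have length k")
    if (length(msg)) msg else TRUE
})

#' Instrumental-variable estimate
#'
#' Point estimate of the causal effect of the exposure on the outcome, with
#' a normal-approximation standard error, 95% Wald confidence interval and
#' two-sided p-value.
#'
#' @slot betaHat estimated causal effect (outcome units per exposure unit).
#' @slot se standard error.
#' @slot ciLow,ciHigh 95% Wald confidence bounds.
#' @slot pvalue two-sided normal p-value.
#' @slot method one of "2SLS", "CFMR1", "CFMR2", "1SMR".
#' @slot n sample size used.
#' @slot k folds used (NA when not applicable).
#' @slot nInstruments number of instrument columns.
#' @slot nDegenerate number of degenerate folds encountered.
#'
#' @seealso [tsls()], [cfmr1()], [cfmr2()], [oneSampleMR()]
#' @export
setClass("IVEstimate",
    representation(betaHat = "numeric", se = "numeric", ciLow = "numeric",
                   ciHigh = "numeric", pvalue = "numeric",
                   method = "character", n = "integer", k = "integer",
                   nInstruments = "integer", nDegenerate = "integer")
)

setValidity("IVEstimate", function(object) {
    msg <- character()
    if (is.finite(object@se) && object@se <= 0)
        msg <- c(msg, "se must be positive")
    if (is.finite(object@ciLow) &&
        !(object@ciLow <= object@betaHat && object@betaHat <= object@ciHigh))
        msg <- c(msg, "confidence bounds must bracket betaHat")
    if (length(msg)) msg else TRUE
})

#' Per-stratum causal estimate
#'
#' @slot label population identifier.
#' @slot estimate the stratum [IVEstimate-class].
#' @slot n stratum size.
#'
#' @seealso [crossPopulationCFMR()]
#' @export
setClass("StratumEstimate",
    representation(label = "character", estimate = "IVEstimate",
                   n = "integer")
)

#' Fixed-effect pooled causal estimate across strata
#'
#' Inverse-variance weighted combination of per-stratum estimates, with
#' Cochran's Q as a heterogeneity diagnostic.
#'
#' @slot betaHat pooled effect.
#' @slot se pooled standard error (never larger than any stratum SE).
#' @slot ciLow,ciHigh 95% Wald bounds.
#' @slot pvalue two-sided normal p-value.
#' @slot heterogeneityQ Cochran's Q across strata.
#' @slot perStratum list of [StratumEstimate-class] objects.
#'
#' @seealso [inverseVarianceMeta()], [crossPopulationCFMR()]
#' @export
setClass("MetaEstimate",
    representation(betaHat = "numeric", se = "numeric", ciLow = "numeric",
                   ciHigh = "numeric", pvalue = "numeric",
                   heterogeneityQ = "numeric", perStratum = "list")
)

setValidity("MetaEstimate", function(object) {
    ses <- vapply(object@perStratum,
                  function(s) s@estimate@se, numeric(1))
    if (length(ses) && object@se > min(ses) + 1e-12)
        return("pooled se must not exceed the smallest stratum se")
    TRUE
})
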