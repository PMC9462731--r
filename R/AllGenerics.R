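#' @name cfmr-accessors
#' @title Accessors for cfmr classes
#'
#' @description Slot accessors. \code{dosages()} returns the
#' individuals-by-variants dosage matrix of a cohort; \code{exposure()} and
#' \code{outcome()} its phenotype vectors; \code{covariates()} the covariate
#' matrix (or NULL); \code{populationLabels()} the population label vector
#' (or NULL); \code{truePi()} and \code{trueBeta0()} the simulation ground
#' truth; \code{cfiValues()}, \code{heldoutR2()}, \code{foldOf()},
#' \code{foldPredictors()} the components of a cross-fitted instrument;
#' \code{betaHat()}, \code{stdError()}, \code{pValue()},
#' \code{confInt()}, \code{methodLabel()}, \code{nInstruments()} and
#' \code{degenerateFolds()} the components of an estimate; \code{folds()} the
#' index lists of a partition.
#'
#' @param x an object of the documented class.
#' @return The slot value; see Description.
#' @examples
#' cfg <- simulationConfig(nIndividuals = 50, nVariants = 10, nCausal = 2,
#'                         seed = 1)
#' cohort <- simulateDataset(cfg)
#' dim(dosages(cohort))
#' trueBeta0(cohort)
NULL

#' @rdname cfmr-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname cfmr-accessors
#' @export
setGeneric("exposure", function(x) standardGeneric("exposure"))
#' @rdname cfmr-accessors
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))
#' @rdname cfmr-accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname cfmr-accessors
#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))
#' @rdname cfmr-accessors
#' @export
setGeneric("truePi", function(x) standardGeneric("truePi"))
#' @rdname cfmr-accessors
#' @export
setGeneric("trueBeta0", function(x) standardGeneric("trueBeta0"))
#' @rdname cfmr-accessors
#' @export
setGeneric("folds", function(x) standardGeneric("folds"))
#' @rdname cfmr-accessors
#' @export
setGeneric("cfiValues", function(x) standardGeneric("cfiValues"))
#' @rdname cfmr-accessors
#' @export
setGeneric("heldoutR2", function(x) standardGeneric("heldoutR2"))
#' @rdname cfmr-accessors
#' @export
setGeneric("foldOf", function(x) standardGeneric("foldOf"))
#' @rdname cfmr-accessors
#' @export
setGeneric("foldPredictors", function(x) standardGeneric("foldPredictors"))
#' @rdname cfmr-accessors
#' @export
setGeneric("degenerateFolds", function(x) standardGeneric("degenerateFolds"))
#' @rdname cfmr-accessors
#' @export
setGeneric("betaHat", function(x) standardGeneric("betaHat"))
#' @rdname cfmr-accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))
#' @rdname cfmr-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname cfmr-accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
#' @rdname cfmr-accessors
#' @export
setGeneric("methodLabel", function(x) standardGeneric("methodLabel"))
#' @rdname cfmr-accessors
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' Predict the exposure with a fitted per-fold predictor
#'
#' Evaluates the affine map \code{intercept + dosages[idx, selected] \%*\%
#' weights} on an arbitrary index set. A degenerate (intercept-only)
#' predictor returns a constant vector.
#'
#' @param object a [FittedPredictor-class].
#' @param genotypes individuals-by-variants dosage matrix with column names,
#'   or an [MRCohort-class].
#' @param indices integer rows to predict on (default: all rows).
#' @return numeric vector of predicted exposures.
#' @export
setGeneric("predictExposure",
    function(object, genotypes, indices = NULL)
        standardGeneric("predictExposure"))
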