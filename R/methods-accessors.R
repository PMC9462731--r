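#' @rdname cfmr-accessors
#' @export
setMethod("dosages", "MRCohort", function(x) {
    t(SummarizedExperiment::assay(x, "dosage"))
})

#' @rdname cfmr-accessors
#' @export
setMethod("exposure", "MRCohort", function(x) {
    as.numeric(SummarizedExperiment::colData(x)$exposure)
})

#' @rdname cfmr-accessors
#' @export
setMethod("outcome", "MRCohort", function(x) {
    as.numeric(SummarizedExperiment::colData(x)$outcome)
})

#' @rdname cfmr-accessors
#' @export
setMethod("covariates", "MRCohort", function(x) {
    cd <- SummarizedExperiment::colData(x)
    cols <- grep("^covariate_", colnames(cd), value = TRUE)
    if (!length(cols)) return(NULL)
    as.matrix(as.data.frame(cd[, cols, drop = FALSE]))
})

#' @rdname cfmr-accessors
#' @export
setMethod("populationLabels", "MRCohort", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"population" %in% colnames(cd)) return(NULL)
    as.character(cd$population)
})

#' @rdname cfmr-accessors
#' @export
setMethod("truePi", "MRCohort", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"true_pi" %in% colnames(rd)) return(NULL)
    stats::setNames(as.numeric(rd$true_pi), rownames(x))
})

#' @rdname cfmr-accessors
#' @export
setMethod("trueBeta0", "MRCohort", function(x) {
    S4Vectors::metadata(x)$true_beta0
})

#' @rdname cfmr-accessors
#' @export
setMethod("folds", "FoldPartition", function(x) x@folds)

#' @rdname cfmr-accessors
#' @export
setMethod("cfiValues", "CrossFittedInstrument", function(x) x@values)

#' @rdname cfmr-accessors
#' @export
setMethod("heldoutR2", "CrossFittedInstrument", function(x) x@heldoutR2)

#' @rdname cfmr-accessors
#' @export
setMethod("foldOf", "CrossFittedInstrument", function(x) x@foldOf)

#' @rdname cfmr-accessors
#' @export
setMethod("foldPredictors", "CrossFittedInstrument", function(x) x@predictors)

#' @rdname cfmr-accessors
#' @export
setMethod("degenerateFolds", "CrossFittedInstrument",
          function(x) which(x@degenerate))

#' @rdname cfmr-accessors
#' @export
setMethod("degenerateFolds", "IVEstimate", function(x) x@nDegenerate)

#' @rdname cfmr-accessors
#' @export
setMethod("betaHat", "IVEstimate", function(x) x@betaHat)

#' @rdname cfmr-accessors
#' @export
setMethod("stdError", "IVEstimate", function(x) x@se)

#' @rdname cfmr-accessors
#' @export
setMethod("pValue", "IVEstimate", function(x) x@pvalue)

#' @rdname cfmr-accessors
#' @export
setMethod("confInt", "IVEstimate",
          function(x) c(lower = x@ciLow, upper = x@ciHigh))

#' @rdname cfmr-accessors
#' @export
setMethod("methodLabel", "IVEstimate", function(x) x@method)

#' @rdname cfmr-accessors
#' @export
setMethod("nInstruments", "IVEstimate", function(x) x@nInstruments)

#' @rdname cfmr-accessors
#' @export
setMethod("betaHat", "MetaEstimate", function(x) x@betaHat)

#' @rdname cfmr-accessors
#' @export
setMethod("stdError", "MetaEstimate", function(x) x@se)

#' @rdname cfmr-accessors
#' @export
setMethod("pValue", "MetaEstimate", function(x) x@pvalue)

#' @rdname cfmr-accessors
#' @export
setMethod("confInt", "MetaEstimate",
          function(x) c(lower = x@ciLow, upper = x@ciHigh))

#' Coerce an association scan to a data.frame
#'
#' @param x an [AssociationScan-class].
#' @param row.names,optional ignored; present for generic consistency.
#' @param ... ignored.
#' @return data.frame with columns variant, beta, se, pvalue, flagged.
#' @export
as.data.frame.AssociationScan <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    data.frame(variant = x@variantIds, beta = x@beta, se = x@se,
               pvalue = x@pvalue, flagged = x@flagged,
               stringsAsFactors = FALSE)
}

#' Coerce an IV estimate to a one-row data.frame
#'
#' @param x an [IVEstimate-class].
#' @param row.names,optional ignored.
#' @param ... ignored.
#' @return one-row data.frame mirroring the estimate-table export columns.
#' @export
as.data.frame.IVEstimate <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
    data.frame(method = x@method, estimate = x@betaHat, se = x@se,
               pvalue = x@pvalue, ci_low = x@ciLow, ci_high = x@ciHigh,
               n = x@n, k = x@k, n_instruments = x@nInstruments,
               degenerate_folds = x@nDegenerate, stringsAsFactors = FALSE)
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:",
        sprintf("N=%d, variants=%d (causal=%d), maf=%g, h2=%g",
                object@nIndividuals, object@nVariants, object@nCausal,
                object@maf, object@h2), "\n")
    cat(sprintf("  beta0=%g, Sigma=[[%g, %g], [%g, %g]], seed=%d\n",
                object@beta0, object@sigmaU2, object@sigmaUV,
                object@sigmaUV, object@sigmaV2, object@seed))
})

setMethod("show", "FoldPartition", function(object) {
    cat(sprintf("FoldPartition: n=%d, k=%d, fold sizes %s, seed=%d\n",
                object@n, object@k,
                paste(range(lengths(object@folds)), collapse = "-"),
                object@seed))
})

setMethod("show", "AssociationScan", function(object) {
    cat(sprintf("AssociationScan: %d variants on %d individuals; min p = %g\n",
                length(object@variantIds), object@nUsed,
                suppressWarnings(min(object@pvalue, na.rm = TRUE))))
})

setMethod("show", "FittedPredictor", function(object) {
    cat(sprintf("FittedPredictor (%s): %d variants, training R2 = %.4f%s\n",
                object@method, length(object@selectedIds), object@trainingR2,
                if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "CrossFittedInstrument", function(object) {
    cat(sprintf(
        "CrossFittedInstrument: n=%d, k=%d, held-out R2 %.4f (mean), %d degenerate fold(s)\n",
        object@partition@n, object@partition@k, mean(object@heldoutR2),
        sum(object@degenerate)))
})

setMethod("show", "IVEstimate", function(object) {
    cat(sprintf("%s estimate: %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
                object@method, object@betaHat, object@se, object@ciLow,
                object@ciHigh, object@pvalue))
    cat(sprintf("  n=%d, instruments=%d%s%s\n", object@n,
                object@nInstruments,
                if (!is.na(object@k)) sprintf(", folds=%d", object@k) else "",
                if (object@nDegenerate > 0)
                    sprintf(", degenerate folds=%d", object@nDegenerate)
                else ""))
})

setMethod("show", "MetaEstimate", function(object) {
    cat(sprintf(
        "Pooled estimate: %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
        object@betaHat, object@se, object@ciLow, object@ciHigh,
        object@pvalue))
    cat(sprintf("  %d strata, Cochran's Q = %.3f\n",
                length(object@perStratum), object@heterogeneityQ))
})
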