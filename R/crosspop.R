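#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools estimates with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\hat\beta = \sum w_i b_i / \sum w_i}, \eqn{se = 1/\sqrt{\sum w_i}},
#' and Cochran's \eqn{Q = \sum w_i (b_i - \hat\beta)^2} as a heterogeneity
#' diagnostic. The pooled SE never exceeds the smallest input SE, and the
#' result is invariant to input order.
#'
#' @param estimates list of [IVEstimate-class] or [StratumEstimate-class]
#'   objects, or a numeric vector of point estimates.
#' @param se standard errors (required when \code{estimates} is numeric; all
#'   must be positive).
#' @param labels optional stratum labels.
#' @return a [MetaEstimate-class].
#' @examples
#' m <- inverseVarianceMeta(c(1.0, 1.4), se = c(0.2, 0.4))
#' betaHat(m); stdError(m)
#' @export
inverseVarianceMeta <- function(estimates, se = NULL, labels = NULL) {
    if (is.list(estimates)) {
        strata <- lapply(seq_along(estimates), function(i) {
            e <- estimates[[i]]
            if (is(e, "StratumEstimate")) return(e)
            lab <- if (!is.null(labels)) labels[i] else as.character(i)
            new("StratumEstimate", label = lab, estimate = e, n = e@n)
        })
        b <- vapply(strata, function(s) s@estimate@betaHat, numeric(1))
        s <- vapply(strata, function(s) s@estimate@se, numeric(1))
    } else {
        stopIfNot(!is.null(se), "se is required for numeric estimates")
        b <- as.numeric(estimates)
        s <- as.numeric(se)
        if (is.null(labels)) labels <- as.character(seq_along(b))
        strata <- lapply(seq_along(b), function(i) {
            new("StratumEstimate", label = labels[i],
                estimate = makeIVEstimate(b[i], s[i]^2, method = "input",
                                          n = NA_integer_),
                n = NA_integer_)
        })
    }
    if (any(!is.finite(s)) || any(s <= 0))
        stop("all standard errors must be positive and finite",
             call. = FALSE)
    w <- 1 / s^2
    beta <- sum(w * b) / sum(w)
    pooledVar <- 1 / sum(w)
    q <- sum(w * (b - beta)^2)
    seP <- sqrt(pooledVar)
    new("MetaEstimate", betaHat = beta, se = seP,
        ciLow = beta - Z975 * seP, ciHigh = beta + Z975 * seP,
        pvalue = 2 * pnorm(-abs(beta / seP)), heterogeneityQ = q,
        perStratum = strata)
}

#' Cross-population cross-fitted MR
#'
#' Runs the full cross-fitted pipeline independently within each population
#' stratum — its own fold partition, per-fold scans and predictors, and a
#' CFMR2 estimate — then pools the stratum estimates by fixed-effect
#' inverse-variance meta-analysis. Building the instrument within stratum
#' respects the heterogeneous genetic architecture of the exposure across
#' populations, which typically yields a more precise pooled estimate than
#' running one instrument on the naively pooled data.
#'
#' @param cohorts a named list of [MRCohort-class] objects (one per
#'   stratum), or a single cohort whose \code{population} labels define the
#'   strata.
#' @param k folds per stratum.
#' @param selection a [selectionSpec()].
#' @param predictor a [predictorSpec()].
#' @param seed integer seed; stratum s uses \code{seed + s} for its
#'   partition.
#' @param sizeFloor minimum usable stratum size; smaller strata are excluded
#'   with a warning.
#' @param robust use sandwich variances in the per-stratum 2SLS.
#' @return a [MetaEstimate-class] whose \code{perStratum} slot holds the
#'   per-population estimates.
#' @export
crossPopulationCFMR <- function(cohorts, k = 10L,
                                selection = selectionSpec(),
                                predictor = predictorSpec(), seed = 1L,
                                sizeFloor = 100L, robust = FALSE) {
    if (is(cohorts, "MRCohort")) {
        labs <- populationLabels(cohorts)
        stopIfNot(!is.null(labs),
                  "a single cohort requires population labels")
        cohorts <- lapply(split(seq_along(labs), labs),
                          function(idx) cohorts[, idx])
    }
    stopIfNot(length(cohorts) >= 1L, "at least one stratum is required")
    if (is.null(names(cohorts)))
        names(cohorts) <- paste0("stratum_", seq_along(cohorts))
    strata <- list()
    for (s in seq_along(cohorts)) {
        cohort <- cohorts[[s]]
        n_s <- ncol(cohort)
        if (n_s < sizeFloor) {
            warning(sprintf("stratum '%s' (n=%d) below size floor %d; excluded",
                            names(cohorts)[s], n_s, sizeFloor))
            next
        }
        est <- tryCatch({
            part <- makeFolds(n_s, k, seed = seed + s)
            cfi <- buildCFI(cohort, partition = part, selection = selection,
                            predictor = predictor)
            cfmr2(exposure(cohort), outcome(cohort), cfi,
                  covariates = covariates(cohort), robust = robust)
        }, error = function(e) e)
        if (inherits(est, "error")) {
            warning(sprintf("stratum '%s' failed: %s", names(cohorts)[s],
                            conditionMessage(est)))
            next
        }
        strata[[length(strata) + 1L]] <-
            new("StratumEstimate", label = names(cohorts)[s],
                estimate = est, n = as.integer(n_s))
    }
    if (!length(strata))
        stop("every stratum was degenerate or below the size floor",
             call. = FALSE)
    inverseVarianceMeta(strata)
}

#' Export a meta-estimate as TSV
#'
#' One row per stratum plus a pooled row.
#'
#' @param meta a [MetaEstimate-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMetaEstimate <- function(meta, path) {
    rows <- lapply(meta@perStratum, function(s) {
        cbind(stratum = s@label, as.data.frame.IVEstimate(s@estimate))
    })
    pooled <- data.frame(stratum = "pooled", method = "meta",
                         estimate = meta@betaHat, se = meta@se,
                         pvalue = meta@pvalue, ci_low = meta@ciLow,
                         ci_high = meta@ciHigh, n = NA_integer_,
                         k = NA_integer_, n_instruments = NA_integer_,
                         degenerate_folds = NA_integer_)
    data.table::fwrite(rbind(do.call(rbind, rows), pooled), path, sep = "\t")
    invisible(path)
}
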