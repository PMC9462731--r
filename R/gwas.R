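#' Marginal association scan of the exposure on each variant
#'
#' For every variant, fits the simple linear regression of the exposure on
#' the dosage restricted to \code{indices}; when covariates are supplied,
#' exposure and dosages are first residualized on them (Frisch-Waugh), and
#' the t-test degrees of freedom become \code{n - 2 - q}. Variants with zero
#' dosage variance in the index set have an undefined slope and are reported
#' with \code{p = 1} and \code{flagged = TRUE}.
#'
#' The outcome vector is never an input here: instrument construction sees
#' genotypes and exposure only.
#'
#' @param genotypes individuals-by-variants dosage matrix or [MRCohort-class].
#' @param exposure numeric exposure vector (ignored if \code{genotypes} is a
#'   cohort, whose own exposure is used).
#' @param indices integer index set to scan on (default: all individuals).
#' @param covariates optional covariate matrix (full cohort rows; subset
#'   internally).
#' @return an [AssociationScan-class].
#' @examples
#' g <- simulateGenotypes(500, 20, 0.3, seed = 1)
#' x <- 2 * g[, 3] + rnorm(500)
#' scan <- marginalScan(g, x)
#' as.data.frame(scan)[3, ]
#' @export
marginalScan <- function(genotypes, exposure = NULL, indices = NULL,
                         covariates = NULL) {
    if (is(genotypes, "MRCohort")) {
        if (is.null(exposure)) exposure <- exposure(genotypes)
        if (is.null(covariates)) covariates <- covariates(genotypes)
        genotypes <- dosages(genotypes)
    }
    g <- asDosageMatrix(genotypes)
    stopIfNot(length(exposure) == nrow(g),
              "exposure length must match genotype rows")
    if (is.null(indices)) indices <- seq_len(nrow(g))
    stopIfNot(length(indices) > 0, "index set must be non-empty")
    gs <- g[indices, , drop = FALSE]
    xs <- exposure[indices]
    q <- 0L
    if (!is.null(covariates)) {
        cv <- as.matrix(covariates)[indices, , drop = FALSE]
        q <- ncol(cv)
        gs <- residualize(gs, cv)
        xs <- as.numeric(residualize(matrix(xs), cv))
    }
    n <- length(indices)
    gc_mean <- colMeans(gs)
    sxx <- colSums(gs^2) - n * gc_mean^2
    xc <- xs - mean(xs)
    sxy <- as.numeric(crossprod(gs, xc))
    ok <- sxx > 0
    beta <- se <- pval <- rep(NA_real_, ncol(gs))
    df <- n - 2L - q
    beta[ok] <- sxy[ok] / sxx[ok]
    syy <- sum(xc^2)
    sse <- pmax(syy - beta[ok]^2 * sxx[ok], 0)
    se[ok] <- sqrt(sse / df / sxx[ok])
    tt <- beta[ok] / se[ok]
    pval[ok] <- 2 * stats::pt(-abs(tt), df = df)
    pval[!ok] <- 1
    new("AssociationScan", variantIds = colnames(g), beta = beta, se = se,
        pvalue = pval, nUsed = as.integer(n),
        indices = as.integer(indices), flagged = !ok)
}

#' Select variants below a p-value threshold
#'
#' Strict comparison, stable (scan) order.
#'
#' @param scan an [AssociationScan-class].
#' @param threshold p-value cutoff in (0, 1].
#' @return character vector of variant identifiers with \code{p < threshold}.
#' @export
selectByPvalue <- function(scan, threshold) {
    stopIfNot(threshold > 0 && threshold <= 1,
              "threshold must lie in (0, 1]")
    keep <- !is.na(scan@pvalue) & scan@pvalue < threshold & !scan@flagged
    scan@variantIds[keep]
}

#' Greedy linkage-disequilibrium clumping
#'
#' Thins a scan to approximately uncorrelated variants: candidates are
#' processed in ascending p-value order (ties broken by variant index) and a
#' variant is retained iff its squared sample dosage correlation with every
#' already-retained variant (within \code{windowBp} when positions are
#' supplied) is below \code{r2Threshold}. Correlations are computed over the
#' scan's own index set. On pairwise-independent variants the whole input is
#' retained. Applying the rule to its own output changes nothing.
#'
#' @param scan an [AssociationScan-class].
#' @param genotypes the dosage matrix or [MRCohort-class] the scan was run on.
#' @param r2Threshold squared-correlation cutoff in (0, 1].
#' @param windowBp optional window half-width in base pairs; variants farther
#'   apart than this are never compared. Requires \code{positions}.
#' @param positions optional numeric genomic coordinates, one per variant.
#' @param candidates optional subset of variant identifiers to clump
#'   (default: all unflagged variants in the scan).
#' @return character vector of retained variant identifiers in processing
#'   (ascending p-value) order.
#' @examples
#' g <- simulateGenotypes(200, 5, 0.3, seed = 2)
#' scan <- marginalScan(g, rnorm(200) + g[, 1])
#' greedyClump(scan, g, r2Threshold = 0.1)
#' @export
greedyClump <- function(scan, genotypes, r2Threshold, windowBp = NULL,
                        positions = NULL, candidates = NULL) {
    stopIfNot(r2Threshold > 0 && r2Threshold <= 1,
              "r2Threshold must lie in (0, 1]")
    if (!is.null(windowBp) && is.null(positions))
        stop("positions are required when windowBp is finite", call. = FALSE)
    g <- asDosageMatrix(genotypes)
    ids <- scan@variantIds
    if (!is.null(positions))
        stopIfNot(length(positions) == length(ids),
                  "positions must have one entry per scanned variant")
    use <- if (is.null(candidates)) ids[!scan@flagged]
           else intersect(candidates, ids[!scan@flagged])
    if (!length(use)) return(character())
    ord <- match(use, ids)
    ord <- ord[order(scan@pvalue[ord], ord)]   # ascending p, ties by index
    gs <- g[scan@indices, ids[ord], drop = FALSE]
    gs <- sweep(gs, 2L, colMeans(gs))
    norms <- sqrt(colSums(gs^2))
    pos <- if (is.null(positions)) NULL else positions[ord]
    retained <- integer()
    for (j in seq_along(ord)) {
        comp <- retained
        if (!is.null(windowBp) && length(comp))
            comp <- comp[abs(pos[comp] - pos[j]) <= windowBp]
        if (length(comp)) {
            r <- as.numeric(crossprod(gs[, comp, drop = FALSE], gs[, j])) /
                (norms[comp] * norms[j])
            if (any(r^2 >= r2Threshold)) next
        }
        retained <- c(retained, j)
    }
    ids[ord][retained]
}

#' Selection settings for instrument construction
#'
#' @param pThreshold p-value cutoff for variant inclusion (strict); 1 keeps
#'   every variant.
#' @param clumpR2 squared-correlation cutoff for greedy clumping; NULL
#'   disables clumping.
#' @param windowBp clumping window half-width in base pairs; NULL means an
#'   infinite window (all pairs compared).
#' @param positions optional per-variant genomic coordinates (required for a
#'   finite window).
#' @param fixed optional character vector of variant identifiers: bypasses
#'   the scan entirely and forces this selection in every fold.
#' @return a list of class \code{cfmr_selection}.
#' @export
selectionSpec <- function(pThreshold = 1e-6, clumpR2 = 0.1, windowBp = NULL,
                          positions = NULL, fixed = NULL) {
    stopIfNot(pThreshold > 0 && pThreshold <= 1,
              "pThreshold must lie in (0, 1]")
    if (!is.null(windowBp) && is.null(positions))
        stop("positions are required when windowBp is finite", call. = FALSE)
    structure(list(pThreshold = pThreshold, clumpR2 = clumpR2,
                   windowBp = windowBp, positions = positions, fixed = fixed),
              class = "cfmr_selection")
}

#' Predictor settings for instrument construction
#'
#' @param method "lasso" (L1-penalized regression, penalty by cross-validated
#'   prediction error at the CV minimum), "allele-score" (marginal-scan slopes
#'   as fixed weights, no refit), "ols" (unpenalized least squares on the
#'   selected variants), or "fixed" (user-supplied weights; a constant
#'   function family, useful for oracle checks).
#' @param cvFolds inner cross-validation folds for the lasso penalty.
#' @param nlambda length of the lasso penalty path.
#' @param seed integer seed for the inner CV fold assignment.
#' @param lambdaOverride optional fixed penalty bypassing CV; \code{Inf}
#'   forces an intercept-only (fully shrunk) predictor.
#' @param weights,intercept coefficients for \code{method = "fixed"}; weights
#'   must be named by variant identifier.
#' @return a list of class \code{cfmr_predictor}.
#' @export
predictorSpec <- function(method = c("lasso", "allele-score", "ols", "fixed"),
                          cvFolds = 10L, nlambda = 100L, seed = 1L,
                          lambdaOverride = NULL, weights = NULL,
                          intercept = 0) {
    method <- match.arg(method)
    if (method == "fixed")
        stopIfNot(!is.null(weights) && !is.null(names(weights)),
                  "method 'fixed' requires named weights")
    structure(list(method = method, cvFolds = as.integer(cvFolds),
                   nlambda = as.integer(nlambda), seed = as.integer(seed),
                   lambdaOverride = lambdaOverride, weights = weights,
                   intercept = intercept),
              class = "cfmr_predictor")
}

#' Train an exposure predictor on a training index set
#'
#' Fits the exposure on the selected dosage columns over
#' \code{trainIndices}. The "lasso" method uses [glmnet::cv.glmnet()] with
#' the penalty at the cross-validation minimum; because glmnet requires at
#' least two columns, a single selected variant is fitted by unpenalized
#' simple regression instead. The "allele-score" method uses the
#' training-set marginal slopes as fixed weights with a centering intercept
#' and no refit. An empty selection — or a penalty that removes every
#' coefficient — yields an intercept-only predictor flagged degenerate (its
#' intercept is the training-set exposure mean).
#'
#' @param genotypes dosage matrix or [MRCohort-class].
#' @param exposure numeric exposure vector.
#' @param trainIndices integer training rows (non-empty).
#' @param selected character vector of selected variant identifiers.
#' @param spec a [predictorSpec()].
#' @return a [FittedPredictor-class].
#' @examples
#' g <- simulateGenotypes(400, 10, 0.3, seed = 1)
#' x <- 0.8 * g[, 1] + rnorm(400)
#' fitPredictor(g, x, seq_len(300), colnames(g)[1:4],
#'              predictorSpec("ols"))
#' @export
fitPredictor <- function(genotypes, exposure = NULL,
                         trainIndices, selected,
                         spec = predictorSpec()) {
    if (is(genotypes, "MRCohort")) {
        if (is.null(exposure)) exposure <- exposure(genotypes)
        genotypes <- dosages(genotypes)
    }
    g <- asDosageMatrix(genotypes)
    stopIfNot(length(trainIndices) > 0, "trainIndices must be non-empty")
    y <- exposure[trainIndices]
    selected <- intersect(selected, colnames(g))

    interceptOnly <- function() {
        new("FittedPredictor", selectedIds = character(),
            weights = numeric(), intercept = mean(y),
            trainingIndices = as.integer(trainIndices),
            method = spec$method, trainingR2 = 0, lambda = NA_real_,
            degenerate = TRUE)
    }
    if (!length(selected)) return(interceptOnly())
    if (!is.null(spec$lambdaOverride) && is.infinite(spec$lambdaOverride))
        return(interceptOnly())

    xs <- g[trainIndices, selected, drop = FALSE]
    lambda <- NA_real_
    if (spec$method == "fixed") {
        w <- spec$weights[selected]
        intercept <- spec$intercept
    } else if (spec$method == "allele-score") {
        sc <- marginalScan(g[, selected, drop = FALSE], exposure,
                           indices = trainIndices)
        w <- stats::setNames(sc@beta, selected)
        w[is.na(w)] <- 0
        intercept <- mean(y) - sum(w * colMeans(xs))
    } else if (spec$method == "ols" || length(selected) == 1L) {
        fit <- stats::lm.fit(cbind(1, xs), y)
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        intercept <- cf[1L]
        w <- stats::setNames(cf[-1L], selected)
        if (spec$method == "lasso") lambda <- 0
    } else {
        if (!is.null(spec$lambdaOverride)) {
            fit <- glmnet::glmnet(xs, y, lambda = spec$lambdaOverride)
            lambda <- spec$lambdaOverride
        } else {
            fit <- withSeed(spec$seed,
                glmnet::cv.glmnet(xs, y, nfolds = spec$cvFolds,
                                  nlambda = spec$nlambda))
            lambda <- fit$lambda.min
        }
        cf <- as.numeric(coef(fit, s = lambda))
        intercept <- cf[1L]
        w <- stats::setNames(cf[-1L], selected)
    }
    keep <- w != 0
    if (!any(keep)) return(interceptOnly())
    w <- w[keep]
    pred <- intercept +
        as.numeric(g[trainIndices, names(w), drop = FALSE] %*% w)
    r2 <- if (stats::sd(pred) > 0) cor(pred, y)^2 else 0
    new("FittedPredictor", selectedIds = names(w), weights = as.numeric(w) |>
            stats::setNames(names(w)), intercept = as.numeric(intercept),
        trainingIndices = as.integer(trainIndices), method = spec$method,
        trainingR2 = r2, lambda = lambda, degenerate = FALSE)
}

#' @rdname predictExposure
#' @export
setMethod("predictExposure", "FittedPredictor",
    function(object, genotypes, indices = NULL) {
        g <- asDosageMatrix(genotypes)
        if (is.null(indices)) indices <- seq_len(nrow(g))
        if (object@degenerate || !length(object@selectedIds))
            return(rep(object@intercept, length(indices)))
        object@intercept +
            as.numeric(g[indices, object@selectedIds, drop = FALSE] %*%
                       object@weights)
    })

#' Export a scan as a TSV file
#'
#' Writes columns variant, beta, se, pvalue, flagged.
#'
#' @param scan an [AssociationScan-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeScan <- function(scan, path) {
    data.table::fwrite(as.data.frame(scan), path, sep = "\t")
    invisible(path)
}
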