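#' Two-stage least squares
#'
#' Computes the instrumental-variable estimate
#' \deqn{\hat\beta = [X^t Z (Z^t Z)^{-1} Z^t X]^{-1}
#'       X^t Z (Z^t Z)^{-1} Z^t Y,}
#' after residualizing exposure, outcome and instruments on the intercept
#' (and covariates, when supplied; Frisch-Waugh, equivalent to carrying the
#' covariates through both stages). With a single instrument column this
#' reduces to the Wald ratio cov(Z, Y)/cov(Z, X), and with Z = X to the OLS
#' slope.
#'
#' The default standard error is the homoskedastic second-stage formula:
#' residuals \eqn{e = Y - X\hat\beta} on the residualized frame,
#' \eqn{\hat\sigma^2 = e^t e / (n - q - 2)} with q covariates, and
#' \eqn{Var(\hat\beta) = \hat\sigma^2 [X^t Z (Z^t Z)^{-1} Z^t X]^{-1}}.
#' \code{robust = TRUE} gives the heteroskedasticity-consistent sandwich
#' variant. Confidence interval and p-value use the normal approximation.
#'
#' @param exposure,outcome numeric vectors.
#' @param instrument numeric vector or matrix of instruments (>= 1 column
#'   with nonzero variance).
#' @param covariates optional covariate matrix.
#' @param robust use the sandwich variance instead of the homoskedastic one.
#' @param method label stored on the estimate (internal use).
#' @param k,nDegenerate bookkeeping stored on the estimate (internal use).
#' @return an [IVEstimate-class].
#' @examples
#' z <- rnorm(200); x <- z + rnorm(200); y <- 3 * x + rnorm(200)
#' tsls(x, y, z)
#' @export
tsls <- function(exposure, outcome, instrument, covariates = NULL,
                 robust = FALSE, method = "2SLS", k = NA_integer_,
                 nDegenerate = 0L) {
    z <- as.matrix(instrument)
    n <- length(exposure)
    stopIfNot(length(outcome) == n && nrow(z) == n,
              "exposure, outcome and instrument rows must align")
    if (is.null(colnames(z)))
        colnames(z) <- paste0("iv", seq_len(ncol(z)))
    zvar <- apply(z, 2L, stats::var)
    if (any(zvar == 0))
        stop(sprintf("degenerate instrument: zero variance in column(s) %s",
                     paste(colnames(z)[zvar == 0], collapse = ", ")),
             call. = FALSE)
    q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
    xr <- as.numeric(residualize(matrix(exposure), covariates))
    yr <- as.numeric(residualize(matrix(outcome), covariates))
    zr <- residualize(z, covariates)
    qr_z <- qr(zr)
    if (qr_z$rank < ncol(zr)) {
        bad <- colnames(zr)[qr_z$pivot[seq(qr_z$rank + 1L, ncol(zr))]]
        stop(sprintf("instrument cross-product is singular; offending column(s): %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
    }
    xp <- qr.fitted(qr_z, xr)        # projection of X onto span(Z)
    a <- sum(xp * xr)                # X'Z(Z'Z)^-1 Z'X
    if (a <= 0)
        stop("instrument is orthogonal to the exposure; estimate undefined",
             call. = FALSE)
    beta <- sum(xp * yr) / a
    e <- yr - xr * beta
    v <- if (robust) sum(e^2 * xp^2) / a^2
         else sum(e^2) / (n - q - 2L) / a
    makeIVEstimate(beta, v, method = method, n = n, k = k,
                   nInstruments = ncol(z), nDegenerate = nDegenerate)
}

#' Fold-averaged cross-fitted MR estimate (CFMR1)
#'
#' Runs one single-instrument two-stage least squares per fold, using the
#' fold's out-of-fold exposure prediction as the instrument and only the
#' fold's own rows, then averages the per-fold estimates with equal weights
#' over the non-degenerate folds. The variance is the sum of per-fold
#' variances divided by the squared number of folds used — an approximation
#' that treats folds as independent (their training complements overlap).
#' CFMR2 is generally preferred in finite samples.
#'
#' @param exposure,outcome numeric vectors for the full cohort.
#' @param cfi a [CrossFittedInstrument-class].
#' @param covariates optional covariate matrix (full cohort rows).
#' @param robust use sandwich per-fold variances.
#' @return an [IVEstimate-class] with method "CFMR1".
#' @export
cfmr1 <- function(exposure, outcome, cfi, covariates = NULL,
                  robust = FALSE) {
    usable <- which(!cfi@degenerate)
    usable <- usable[vapply(usable, function(i) {
        isTRUE(stats::sd(cfi@values[cfi@partition@folds[[i]]]) > 0)
    }, logical(1))]
    if (!length(usable))
        stop("all folds degenerate: CFMR1 undefined", call. = FALSE)
    nd <- cfi@partition@k - length(usable)
    if (nd > 0)
        warning(sprintf("%d degenerate fold(s) excluded from CFMR1", nd))
    est <- vapply(usable, function(i) {
        idx <- cfi@partition@folds[[i]]
        cv <- if (is.null(covariates)) NULL
              else as.matrix(covariates)[idx, , drop = FALSE]
        fit <- tsls(exposure[idx], outcome[idx], cfi@values[idx],
                    covariates = cv, robust = robust)
        c(fit@betaHat, fit@se^2)
    }, numeric(2))
    kUsed <- length(usable)
    beta <- mean(est[1L, ])
    v <- sum(est[2L, ]) / kUsed^2
    makeIVEstimate(beta, v, method = "CFMR1", n = length(exposure),
                   k = cfi@partition@k, nInstruments = 1L,
                   nDegenerate = nd)
}

#' Pooled cross-fitted MR estimate (CFMR2)
#'
#' A single two-stage least squares of the outcome on the exposure over the
#' entire cohort, using the concatenated out-of-fold exposure predictions as
#' the one-column instrument. This is the recommended cross-fitted
#' estimator: because each component of the instrument was built without the
#' corresponding individual's data, the first- and second-stage errors are
#' uncorrelated and the finite-sample bias, if any, points toward the null.
#' With K = n and leave-one-out least-squares predictors it coincides with
#' the jackknife IV estimator.
#'
#' @param exposure,outcome numeric vectors.
#' @param cfi a [CrossFittedInstrument-class].
#' @param covariates optional covariate matrix.
#' @param robust use the sandwich variance.
#' @return an [IVEstimate-class] with method "CFMR2".
#' @export
cfmr2 <- function(exposure, outcome, cfi, covariates = NULL,
                  robust = FALSE) {
    if (stats::sd(cfi@values) == 0)
        stop("degenerate instrument: cross-fitted values have zero variance",
             call. = FALSE)
    tsls(exposure, outcome, cfi@values, covariates = covariates,
         robust = robust, method = "CFMR2", k = cfi@partition@k,
         nDegenerate = sum(cfi@degenerate))
}

#' Naive one-sample MR baseline
#'
#' Trains a single exposure predictor on the full cohort (scan, clumping,
#' p-value selection, predictor fit) and uses its in-sample prediction as
#' the instrument. Because selection and estimation share every observation,
#' the first- and second-stage errors are correlated and the estimate is
#' pulled toward the confounded association (weak-instrument bias plus
#' winner's curse). Provided as the biased baseline the cross-fitted
#' estimators are contrasted against.
#'
#' @param genotypes dosage matrix or [MRCohort-class].
#' @param exposure,outcome numeric vectors (taken from the cohort when
#'   omitted).
#' @param selection a [selectionSpec()].
#' @param predictor a [predictorSpec()].
#' @param covariates optional covariate matrix.
#' @param robust use the sandwich variance.
#' @return an [IVEstimate-class] with method "1SMR".
#' @export
oneSampleMR <- function(genotypes, exposure = NULL, outcome = NULL,
                        selection = selectionSpec(),
                        predictor = predictorSpec(), covariates = NULL,
                        robust = FALSE) {
    if (is(genotypes, "MRCohort")) {
        if (is.null(exposure)) exposure <- exposure(genotypes)
        if (is.null(outcome)) outcome <- outcome(genotypes)
        if (is.null(covariates)) covariates <- covariates(genotypes)
        genotypes <- dosages(genotypes)
    }
    g <- asDosageMatrix(genotypes)
    all_idx <- seq_len(nrow(g))
    if (!is.null(selection$fixed)) {
        sel <- selection$fixed
    } else {
        scan <- marginalScan(g, exposure, covariates = covariates)
        sel <- selectByPvalue(scan, selection$pThreshold)
        if (!is.null(selection$clumpR2) && selection$clumpR2 < 1 &&
            length(sel) > 1L)
            sel <- greedyClump(scan, g, selection$clumpR2,
                               windowBp = selection$windowBp,
                               positions = selection$positions,
                               candidates = sel)
    }
    fp <- fitPredictor(g, exposure, all_idx, sel, predictor)
    if (fp@degenerate)
        stop("degenerate predictor: no variant enters the one-sample instrument",
             call. = FALSE)
    inst <- predictExposure(fp, g)
    fit <- tsls(exposure, outcome, inst, covariates = covariates,
                robust = robust, method = "1SMR")
    fit
}

#' Leading endogeneity-bias term of naive two-stage least squares
#'
#' The Nagar approximation to the bias that instrument overfitting induces
#' when the same sample selects and applies the instruments: proportional to
#' \code{nInstruments / n * sigmaUV}, the number of instruments per
#' observation times the covariance of the first- and second-stage errors.
#' Cross-fitting removes this term by making the instrument independent of
#' the second-stage error.
#'
#' @param nInstruments number of instruments.
#' @param n sample size (> 0).
#' @param sigmaUV error covariance.
#' @return scalar bias term.
#' @examples
#' nagarBiasTerm(300, 1000, 4.9)  # 1.47
#' @export
nagarBiasTerm <- function(nInstruments, n, sigmaUV) {
    stopIfNot(n > 0, "n must be positive")
    nInstruments / n * sigmaUV
}

#' Export estimates as a TSV table
#'
#' One row per estimate with the columns method, estimate, se, pvalue,
#' ci_low, ci_high, n, k, n_instruments, degenerate_folds.
#'
#' @param estimates an [IVEstimate-class] or list of them.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEstimates <- function(estimates, path) {
    if (is(estimates, "IVEstimate")) estimates <- list(estimates)
    tab <- do.call(rbind, lapply(estimates, as.data.frame.IVEstimate))
    data.table::fwrite(tab, path, sep = "\t")
    invisible(path)
}
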