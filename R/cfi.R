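#' Draw a random K-fold partition
#'
#' Uniformly random disjoint folds covering 1..n. When k does not divide n,
#' the first \code{n mod k} folds receive one extra element, so fold sizes
#' differ by at most one. Deterministic under a fixed seed.
#'
#' @param n total sample size.
#' @param k number of folds, between 2 and n. The default of 10 follows the
#'   recommendation for cross-fitted MR; k = n gives the jackknife
#'   (leave-one-out) limit.
#' @param seed integer seed.
#' @return a [FoldPartition-class].
#' @examples
#' lengths(folds(makeFolds(10, 3, seed = 1)))  # 4 3 3
#' @export
makeFolds <- function(n, k = 10L, seed = 1L) {
    n <- as.integer(n); k <- as.integer(k)
    if (k < 2L || k > n)
        stop("k must lie between 2 and n", call. = FALSE)
    sizes <- rep(n %/% k, k)
    r <- n %% k
    if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
    perm <- withSeed(seed, sample.int(n))
    stops <- cumsum(sizes)
    starts <- c(1L, stops[-k] + 1L)
    fl <- lapply(seq_len(k), function(i) sort(perm[starts[i]:stops[i]]))
    new("FoldPartition", n = n, k = k, folds = fl, seed = as.integer(seed))
}

#' Build a cross-fitted instrument
#'
#' For each fold k: run the marginal exposure scan on the fold's complement,
#' select variants below the p-value threshold, thin them by greedy clumping,
#' train the exposure predictor on the complement, and predict the exposure
#' on the held-out fold. The concatenated out-of-fold predictions form the
#' instrument. No step ever reads the outcome, and no row of fold k enters
#' the model that predicts fold k.
#'
#' Thresholding is applied before clumping among the survivors; this yields
#' the same retained set as clumping the full scan first, because a variant
#' below the threshold has a larger p-value than every variant above it and
#' therefore can never shadow one during the ascending-p greedy pass.
#'
#' @param genotypes dosage matrix or [MRCohort-class].
#' @param exposure exposure vector (taken from the cohort when omitted).
#' @param partition a [FoldPartition-class] matching the data.
#' @param selection a [selectionSpec()].
#' @param predictor a [predictorSpec()].
#' @param covariates optional covariate matrix used in the per-fold scans.
#' @param strict when TRUE (default), fail if every fold is degenerate (the
#'   instrument carries no identification); when FALSE, return the flagged
#'   object for inspection.
#' @return a [CrossFittedInstrument-class].
#' @examples
#' cohort <- simulateDataset(simulationConfig(400, nVariants = 20,
#'                           h2 = 0.3, seed = 2))
#' part <- makeFolds(400, 4, seed = 9)
#' cfi <- buildCFI(cohort, partition = part,
#'                 selection = selectionSpec(pThreshold = 1e-3))
#' heldoutR2(cfi)
#' @export
buildCFI <- function(genotypes, exposure = NULL, partition,
                     selection = selectionSpec(),
                     predictor = predictorSpec(), covariates = NULL,
                     strict = TRUE) {
    if (is(genotypes, "MRCohort")) {
        if (is.null(exposure)) exposure <- exposure(genotypes)
        if (is.null(covariates)) covariates <- covariates(genotypes)
        genotypes <- dosages(genotypes)
    }
    g <- asDosageMatrix(genotypes)
    stopIfNot(partition@n == nrow(g),
              "partition size must match the number of individuals")
    stopIfNot(length(exposure) == nrow(g),
              "exposure length must match genotype rows")
    n <- nrow(g)
    k <- partition@k
    values <- numeric(n)
    foldOf <- integer(n)
    preds <- vector("list", k)
    r2 <- numeric(k)
    degen <- logical(k)
    all_idx <- seq_len(n)
    for (i in seq_len(k)) {
        fold <- partition@folds[[i]]
        train <- all_idx[-fold]
        if (!is.null(selection$fixed)) {
            sel <- selection$fixed
        } else {
            scan <- marginalScan(g, exposure, indices = train,
                                 covariates = covariates)
            sel <- selectByPvalue(scan, selection$pThreshold)
            if (!is.null(selection$clumpR2) && selection$clumpR2 < 1 &&
                length(sel) > 1L)
                sel <- greedyClump(scan, g, selection$clumpR2,
                                   windowBp = selection$windowBp,
                                   positions = selection$positions,
                                   candidates = sel)
        }
        fp <- fitPredictor(g, exposure, train, sel, predictor)
        preds[[i]] <- fp
        vals_k <- predictExposure(fp, g, fold)
        values[fold] <- vals_k
        foldOf[fold] <- i
        degen[i] <- fp@degenerate
        # single-observation folds (K = n) have no within-fold variance
        r2[i] <- if (!fp@degenerate && length(vals_k) > 1L &&
                     isTRUE(stats::sd(vals_k) > 0))
            cor(vals_k, exposure[fold])^2 else 0
    }
    if (strict && all(degen))
        stop("instrument construction failed: all folds degenerate",
             call. = FALSE)
    new("CrossFittedInstrument", values = values, foldOf = foldOf,
        predictors = preds, heldoutR2 = r2, degenerate = degen,
        partition = partition)
}

#' Held-out diagnostics for a cross-fitted instrument
#'
#' Reports the overall held-out variance explained (squared correlation of
#' the instrument with the observed exposure, as a percentage) and, for each
#' candidate confounder, the slope and p-value of a simple regression of the
#' confounder on the instrument. An instrument associated with measured
#' confounders violates the exclusion assumptions and should not be used.
#'
#' @param cfi a [CrossFittedInstrument-class].
#' @param exposure the observed exposure vector.
#' @param candidateConfounders optional numeric matrix, one column per
#'   candidate confounder.
#' @return a list with elements \code{variance_explained_pct} (scalar; NA and
#'   \code{flagged = TRUE} for a zero-variance instrument) and
#'   \code{confounders} (data.frame with slope, se, pvalue per candidate, or
#'   NULL).
#' @export
cfiDiagnostics <- function(cfi, exposure, candidateConfounders = NULL) {
    v <- cfi@values
    stopIfNot(length(exposure) == length(v),
              "exposure length must match the instrument")
    flagged <- stats::sd(v) == 0
    ve <- if (flagged) NA_real_ else 100 * cor(v, exposure)^2
    conf <- NULL
    if (!is.null(candidateConfounders)) {
        cc <- as.matrix(candidateConfounders)
        stopIfNot(nrow(cc) == length(v),
                  "confounder rows must match the instrument")
        if (is.null(colnames(cc)))
            colnames(cc) <- paste0("confounder_", seq_len(ncol(cc)))
        if (flagged) {
            conf <- data.frame(confounder = colnames(cc), slope = NA_real_,
                               se = NA_real_, pvalue = NA_real_)
        } else {
            # simple regression of each confounder on the CFI
            n <- length(v)
            vc <- v - mean(v)
            svv <- sum(vc^2)
            slope <- as.numeric(crossprod(sweep(cc, 2L, colMeans(cc)), vc)) /
                svv
            fitted <- outer(vc, slope)
            resid <- sweep(cc, 2L, colMeans(cc)) - fitted
            sse <- colSums(resid^2)
            se <- sqrt(sse / (n - 2) / svv)
            tt <- slope / se
            conf <- data.frame(confounder = colnames(cc), slope = slope,
                               se = se,
                               pvalue = 2 * stats::pt(-abs(tt), df = n - 2))
        }
    }
    list(variance_explained_pct = ve, flagged = flagged, confounders = conf)
}

#' Export a cross-fitted instrument as TSV
#'
#' Writes one row per individual: identifier, fold and instrument value.
#'
#' @param cfi a [CrossFittedInstrument-class].
#' @param path output file path.
#' @param ids optional individual identifiers (default \code{ind_<i>}).
#' @return the path, invisibly.
#' @export
writeCFI <- function(cfi, path, ids = NULL) {
    n <- cfi@partition@n
    if (is.null(ids)) ids <- paste0("ind_", seq_len(n))
    data.table::fwrite(
        data.frame(individual = ids, fold = cfi@foldOf, cfi = cfi@values),
        path, sep = "\t")
    invisible(path)
}
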