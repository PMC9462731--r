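test_that("marginal scan equals textbook simple regression", {
    set.seed(41)
    g <- simulateGenotypes(20, 1, 0.4, seed = 41)
    x <- rnorm(20) + 0.5 * g[, 1]
    scan <- marginalScan(g, x)
    expect_equal(scan@beta[1], cov(g[, 1], x) / var(g[, 1]),
                 tolerance = 1e-10)
    fit <- summary(lm(x ~ g[, 1]))$coefficients
    expect_equal(scan@beta[1], fit[2, 1], tolerance = 1e-10)
    expect_equal(scan@se[1], fit[2, 2], tolerance = 1e-10)
    expect_equal(scan@pvalue[1], fit[2, 4], tolerance = 1e-10)

    # exact linear relation: slope 2, p ~ 0
    g2 <- simulateGenotypes(100, 3, 0.3, seed = 42)
    scan2 <- marginalScan(g2, 2 * g2[, 2])
    expect_equal(scan2@beta[2], 2, tolerance = 1e-10)
    expect_lt(scan2@pvalue[2], 1e-100)
})

test_that("scan equals simple regression on every variant (oracle sweep)", {
    set.seed(43)
    g <- simulateGenotypes(80, 25, 0.3, seed = 43)
    x <- rnorm(80) + g[, 1] * 0.3
    scan <- marginalScan(g, x)
    for (j in seq_len(25)) {
        fit <- summary(lm(x ~ g[, j]))$coefficients
        expect_equal(scan@beta[j], fit[2, 1], tolerance = 1e-10)
        expect_equal(scan@se[j], fit[2, 2], tolerance = 1e-10)
    }
})

test_that("null p-values are uniform and zero-variance variants are flagged", {
    n <- 5000
    g <- simulateGenotypes(n, 1000, 0.3, seed = 44)
    x <- local({ set.seed(45); rnorm(n) })
    scan <- marginalScan(g, x)
    frac <- mean(scan@pvalue < 0.05)
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

    gz <- cbind(g[, 1:3], constant = 0L)
    colnames(gz) <- paste0("v", 1:4)
    scanz <- marginalScan(gz, x)
    expect_true(scanz@flagged[4])
    expect_identical(scanz@pvalue[4], 1)
    expect_false(any(scanz@flagged[1:3]))
})

test_that("scan with covariates residualizes both sides", {
    set.seed(46)
    n <- 300
    g <- simulateGenotypes(n, 5, 0.3, seed = 46)
    cv <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
    x <- 0.4 * g[, 1] + 0.9 * cv[, 1] + rnorm(n)
    scan <- marginalScan(g, x, covariates = cv)
    fit <- summary(lm(x ~ g[, 1] + cv))$coefficients
    expect_equal(scan@beta[1], fit[2, 1], tolerance = 1e-8)
    expect_equal(scan@se[1], fit[2, 2], tolerance = 1e-8)
})

test_that("p-value selection is strict with stable order", {
    scan <- new("AssociationScan", variantIds = c("a", "b", "c"),
                beta = c(1, 1, 1), se = c(1, 1, 1),
                pvalue = c(1e-7, 1e-5, 0.2), nUsed = 10L,
                indices = 1:10, flagged = rep(FALSE, 3))
    expect_identical(selectByPvalue(scan, 1e-6), "a")
    expect_identical(selectByPvalue(scan, 1), c("a", "b", "c"))
    scan@pvalue <- rep(0.5, 3)
    expect_identical(selectByPvalue(scan, 1e-6), character())
})

test_that("greedy clumping retains independents, drops duplicates, matches oracle", {
    # independent variants: everything retained
    g <- simulateGenotypes(500, 6, 0.3, seed = 47)
    x <- local({ set.seed(48); rnorm(500) + g[, 1] })
    scan <- marginalScan(g, x)
    kept <- greedyClump(scan, g, r2Threshold = 0.5)
    expect_setequal(kept, colnames(g))

    # identical dosage columns: only the smaller p survives
    g2 <- cbind(g[, 1], g[, 1], g[, 3])
    colnames(g2) <- c("dup1", "dup2", "other")
    scan2 <- marginalScan(g2, x)
    # dup1 and dup2 tie; index order breaks the tie
    kept2 <- greedyClump(scan2, g2, r2Threshold = 0.1)
    expect_true("dup1" %in% kept2 && !"dup2" %in% kept2)

    # 5-variant correlated toy vs brute-force greedy replay
    set.seed(49)
    base <- rnorm(200)
    gc5 <- cbind(v1 = base + rnorm(200, 0, 0.3),
                 v2 = base + rnorm(200, 0, 0.3),
                 v3 = rnorm(200),
                 v4 = base + rnorm(200, 0, 1.5),
                 v5 = rnorm(200))
    xq <- gc5[, 1] + rnorm(200)
    scan5 <- marginalScan(gc5, xq)
    for (r2 in c(0.05, 0.2, 0.5, 0.9)) {
        kept5 <- greedyClump(scan5, gc5, r2Threshold = r2)
        want <- oracle_clump(scan5@pvalue, cor(gc5), r2)
        expect_setequal(kept5, colnames(gc5)[want])
    }
})

test_that("clumping is idempotent and honors genomic windows", {
    g <- simulateGenotypes(300, 8, 0.3, seed = 50)
    base <- g[, 1]
    g[, 2] <- base   # perfect LD pair
    x <- local({ set.seed(51); base + rnorm(300) })
    scan <- marginalScan(g, x)
    kept <- greedyClump(scan, g, r2Threshold = 0.1)
    scan_kept <- marginalScan(g[, kept, drop = FALSE], x)
    expect_identical(greedyClump(scan_kept, g[, kept, drop = FALSE],
                                 r2Threshold = 0.1), kept)
    # with distant positions the LD pair is never compared, so both survive
    pos <- c(1e6, 9e6, seq(2e7, by = 1e6, length.out = 6))
    keptw <- greedyClump(scan, g, r2Threshold = 0.1, windowBp = 5e5,
                         positions = pos)
    expect_true(all(c("variant_1", "variant_2") %in% keptw))
    expect_error(greedyClump(scan, g, r2Threshold = 0.1, windowBp = 5e5),
                 "positions")
})

test_that("predictor training: shrinkage limit, consistency, optimism", {
    # full shrinkage: intercept-only at the training mean, flagged
    g <- simulateGenotypes(500, 10, 0.3, seed = 52)
    x <- local({ set.seed(53); 0.7 * g[, 1] + rnorm(500) })
    fp <- fitPredictor(g, x, 1:400, colnames(g)[1:5],
                       predictorSpec("lasso", lambdaOverride = Inf))
    expect_true(fp@degenerate)
    expect_equal(fp@intercept, mean(x[1:400]), tolerance = 1e-12)
    expect_identical(predictExposure(fp, g, 401:500),
                     rep(fp@intercept, 100))

    # one strong causal variant: lasso weight within 10% of the generative
    # effect and close to an OLS refit oracle
    cfg <- simulationConfig(20000, nVariants = 20, nCausal = 1, maf = 0.3,
                            h2 = 0.3, beta0 = 0, sigmaU2 = 5, sigmaV2 = 5,
                            sigmaUV = 0, seed = 54)
    d <- simulateDataset(cfg)
    gd <- dosages(d); xd <- exposure(d)
    pi_true <- unname(truePi(d)[1])
    fp2 <- fitPredictor(gd, xd, seq_len(20000), colnames(gd),
                        predictorSpec("lasso", cvFolds = 5, seed = 2))
    expect_true("variant_1" %in% fp2@selectedIds)
    w1 <- fp2@weights["variant_1"]
    expect_lt(abs(w1 - pi_true) / pi_true, 0.10)
    ols <- unname(coef(lm(xd ~ gd[, 1]))[2])
    expect_lt(abs(w1 - ols) / abs(ols), 0.10)

    # optimism: training R2 >= held-out R2 on average
    set.seed(55)
    gap <- replicate(30, {
        cfgr <- simulationConfig(600, nVariants = 30, nCausal = 3,
                                 maf = 0.3, h2 = 0.1, beta0 = 0,
                                 sigmaUV = 0, seed = sample.int(1e6, 1))
        dr <- simulateDataset(cfgr)
        gr <- dosages(dr); xr <- exposure(dr)
        train <- 1:400; test <- 401:600
        fpr <- fitPredictor(gr, xr, train, colnames(gr)[1:10],
                            predictorSpec("lasso", cvFolds = 5, seed = 1))
        if (fpr@degenerate) return(NA_real_)
        pred <- predictExposure(fpr, gr, test)
        fpr@trainingR2 - cor(pred, xr[test])^2
    })
    expect_gt(mean(gap, na.rm = TRUE), 0)
})

test_that("allele-score and single-variant predictors behave as documented", {
    g <- simulateGenotypes(800, 6, 0.3, seed = 56)
    x <- local({ set.seed(57); 0.5 * g[, 1] - 0.3 * g[, 2] + rnorm(800) })
    sel <- colnames(g)[1:3]
    fp <- fitPredictor(g, x, 1:600, sel, predictorSpec("allele-score"))
    sc <- marginalScan(g[, sel], x, indices = 1:600)
    expect_equal(unname(fp@weights[sel]), unname(sc@beta), tolerance = 1e-10)
    # centering intercept: mean prediction equals mean training exposure
    expect_equal(mean(predictExposure(fp, g, 1:600)), mean(x[1:600]),
                 tolerance = 1e-10)

    # single selected variant: unpenalized simple-regression fallback
    fp1 <- fitPredictor(g, x, 1:600, "variant_1", predictorSpec("lasso"))
    fit <- coef(lm(x[1:600] ~ g[1:600, 1]))
    expect_equal(unname(fp1@weights), unname(fit[2]), tolerance = 1e-10)
    expect_equal(fp1@intercept, unname(fit[1]), tolerance = 1e-10)

    # empty selection: degenerate intercept-only
    fp0 <- fitPredictor(g, x, 1:600, character(), predictorSpec("lasso"))
    expect_true(fp0@degenerate)
})

test_that("instrument construction never reads the outcome", {
    # scans, selection and predictors are functions of genotypes + exposure;
    # flipping the outcome must leave every piece identical
    d <- simulateDataset(std_config(400, h2 = 0.3, beta0 = 0.5, seed = 58,
                                    nVariants = 30))
    g <- dosages(d); x <- exposure(d)
    part <- makeFolds(400, 4, seed = 59)
    spec <- selectionSpec(pThreshold = 1e-3)
    cfi1 <- buildCFI(g, x, part, spec)
    cfi2 <- buildCFI(g, x, part, spec)   # outcome is not even an argument
    expect_identical(cfiValues(cfi1), cfiValues(cfi2))
    args <- names(formals(marginalScan))
    expect_false("outcome" %in% args)
    expect_false("outcome" %in% names(formals(fitPredictor)))
    expect_false("outcome" %in% names(formals(buildCFI)))
})
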