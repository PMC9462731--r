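test_that("2SLS matches the direct matrix expression on random instances", {
    set.seed(81)
    for (i in 1:100) {
        n <- sample(30:200, 1)
        p <- sample(1:5, 1)
        z <- matrix(rnorm(n * p), n, p)
        x <- z %*% runif(p, -1, 1) + rnorm(n)
        y <- 0.7 * x + rnorm(n)
        fit <- tsls(as.numeric(x), as.numeric(y), z)
        expect_equal(betaHat(fit), oracle_tsls(x, y, z), tolerance = 1e-10)
    }
})

test_that("2SLS collapses to the Wald ratio and the OLS slope", {
    set.seed(82)
    n <- 500
    z <- rnorm(n)
    x <- z + rnorm(n)
    y <- 3 * x + rnorm(n)
    fit <- tsls(x, y, z)
    expect_equal(betaHat(fit), oracle_wald(x, y, z), tolerance = 1e-10)
    expect_identical(nInstruments(fit), 1L)
    # Z = X with no confounding: OLS
    fit2 <- tsls(x, y, x)
    expect_equal(betaHat(fit2), unname(coef(lm(y ~ x))[2]),
                 tolerance = 1e-10)
    expect_equal(betaHat(fit2), 3, tolerance = 0.2)
})

test_that("2SLS standard errors, CI and p-values are internally consistent", {
    set.seed(83)
    n <- 400
    z <- matrix(rnorm(n * 2), n, 2)
    x <- as.numeric(z %*% c(1, 0.5)) + rnorm(n)
    y <- 0.3 * x + rnorm(n)
    fit <- tsls(x, y, z)
    ci <- confInt(fit)
    expect_lt(abs(unname(ci["lower"]) -
                  (betaHat(fit) - 1.959964 * stdError(fit))), 1e-9)
    expect_lt(abs(unname(ci["upper"]) -
                  (betaHat(fit) + 1.959964 * stdError(fit))), 1e-9)
    expect_equal(pValue(fit),
                 2 * pnorm(-abs(betaHat(fit) / stdError(fit))),
                 tolerance = 1e-12)
    # robust variant runs and stays the same order of magnitude
    fitr <- tsls(x, y, z, robust = TRUE)
    expect_equal(betaHat(fitr), betaHat(fit), tolerance = 1e-12)
    expect_lt(abs(log(stdError(fitr) / stdError(fit))), log(2))
})

test_that("2SLS errors on degenerate and collinear instruments", {
    set.seed(84)
    x <- rnorm(50); y <- rnorm(50)
    expect_error(tsls(x, y, rep(1, 50)), "zero variance")
    z <- rnorm(50)
    expect_error(tsls(x, y, cbind(a = z, b = z)), "singular")
})

test_that("scale equivariance and instrument-scale invariance hold", {
    set.seed(85)
    n <- 300
    z <- rnorm(n); x <- z + rnorm(n); y <- 0.4 * x + rnorm(n)
    f0 <- tsls(x, y, z)
    fy <- tsls(x, 5 * y, z)
    expect_equal(betaHat(fy), 5 * betaHat(f0), tolerance = 1e-10)
    expect_equal(stdError(fy), 5 * stdError(f0), tolerance = 1e-10)
    fx <- tsls(5 * x, y, z)
    expect_equal(betaHat(fx), betaHat(f0) / 5, tolerance = 1e-10)
    expect_equal(stdError(fx), stdError(f0) / 5, tolerance = 1e-10)
    fz <- tsls(x, y, -17 * z)
    expect_equal(betaHat(fz), betaHat(f0), tolerance = 1e-10)
    expect_equal(stdError(fz), stdError(f0), tolerance = 1e-10)
})

test_that("covariate adjustment equals explicit two-stage regression", {
    set.seed(86)
    n <- 400
    cv <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
    z <- rnorm(n)
    x <- z + 0.5 * cv[, 1] + rnorm(n)
    y <- 0.6 * x - 0.8 * cv[, 2] + rnorm(n)
    fit <- tsls(x, y, z, covariates = cv)
    # oracle: residualize everything on [1, C], then plain IV
    r <- function(m) resid(lm(m ~ cv))
    expect_equal(betaHat(fit), oracle_tsls(r(x), r(y), matrix(r(z))),
                 tolerance = 1e-10)
})

test_that("CFMR1 averages per-fold Wald ratios", {
    d <- simulateDataset(std_config(200, h2 = 0.3, beta0 = 0.2, seed = 87,
                                    nVariants = 10))
    g <- dosages(d); x <- exposure(d); y <- outcome(d)
    part <- makeFolds(200, 2, seed = 88)
    cfi <- buildCFI(g, x, part, selection = selectionSpec(pThreshold = 1e-2))
    fit <- cfmr1(x, y, cfi)
    wald <- vapply(folds(part), function(idx) {
        oracle_wald(x[idx], y[idx], cfiValues(cfi)[idx])
    }, numeric(1))
    expect_equal(betaHat(fit), mean(wald), tolerance = 1e-10)
    expect_identical(methodLabel(fit), "CFMR1")

    # identical per-fold estimates: the mean is that constant
    cfi2 <- cfi
    cfi2@values <- x   # per-fold 2SLS of X on X gives the fold OLS slope
    fold_b <- vapply(folds(part), function(idx)
        oracle_wald(x[idx], y[idx], x[idx]), numeric(1))
    fit2 <- cfmr1(x, y, cfi2)
    expect_equal(betaHat(fit2), mean(fold_b), tolerance = 1e-10)
})

test_that("CFMR2 equals 2SLS on a globally fixed affine instrument", {
    d <- simulateDataset(std_config(300, h2 = 0.2, beta0 = 0.1, seed = 89,
                                    nVariants = 15))
    g <- dosages(d); x <- exposure(d); y <- outcome(d)
    part <- makeFolds(300, 3, seed = 90)
    w <- c(variant_1 = 0.5, variant_2 = -0.2)
    cfi <- buildCFI(g, x, part,
                    selection = selectionSpec(fixed = names(w)),
                    predictor = predictorSpec("fixed", weights = w,
                                              intercept = 1.3))
    fit <- cfmr2(x, y, cfi)
    inst <- 1.3 + as.numeric(g[, names(w)] %*% w)
    ref <- tsls(x, y, inst)
    expect_equal(betaHat(fit), betaHat(ref), tolerance = 1e-12)
    expect_equal(stdError(fit), stdError(ref), tolerance = 1e-12)
    expect_identical(methodLabel(fit), "CFMR2")
})

test_that("CFMR2 with K = n and leave-one-out least squares is jackknife IV", {
    cfg <- simulationConfig(200, nVariants = 2, nCausal = 2, maf = 0.3,
                            h2 = 0.2, beta0 = 0.3, sigmaU2 = 5,
                            sigmaV2 = 5, sigmaUV = 2, seed = 91)
    d <- simulateDataset(cfg)
    g <- dosages(d); x <- exposure(d); y <- outcome(d)
    part <- makeFolds(200, 200, seed = 92)
    cfi <- buildCFI(g, x, part,
                    selection = selectionSpec(fixed = colnames(g)),
                    predictor = predictorSpec("ols"))
    fit <- cfmr2(x, y, cfi)
    expect_equal(betaHat(fit), oracle_jive(g, x, y), tolerance = 1e-8)
})

test_that("CFMR1 and CFMR2 agree in distribution at moderate sample size", {
    reps <- 40
    est <- vapply(seq_len(reps), function(r) {
        d <- simulateDataset(std_config(2500, h2 = 0.2, beta0 = 0.05,
                                        seed = 9000 + r))
        x <- exposure(d); y <- outcome(d)
        cfi <- buildCFI(dosages(d), x, makeFolds(2500, 10, seed = 9000 + r),
                        selection = selectionSpec(),
                        predictor = predictorSpec(cvFolds = 5))
        c(betaHat(suppressWarnings(cfmr1(x, y, cfi))),
          betaHat(cfmr2(x, y, cfi)))
    }, numeric(2))
    diff <- est[1, ] - est[2, ]
    expect_lt(abs(mean(diff)), 2 * sd(diff) / sqrt(reps))
})

test_that("one-sample MR is deterministic and unbiased without confounding", {
    d <- simulateDataset(std_config(2000, h2 = 0.2, beta0 = 0.3,
                                    sigmaUV = 0, seed = 93))
    fit1 <- oneSampleMR(d, predictor = predictorSpec(seed = 5))
    fit2 <- oneSampleMR(d, predictor = predictorSpec(seed = 5))
    expect_identical(betaHat(fit1), betaHat(fit2))
    expect_identical(methodLabel(fit1), "1SMR")
    # no confounding, strong signal: roughly centered on beta0
    expect_lt(abs(betaHat(fit1) - 0.3), 4 * stdError(fit1))
    # degenerate predictor errors out
    d0 <- simulateDataset(std_config(500, h2 = 0, seed = 94))
    expect_error(oneSampleMR(d0), "degenerate|no variant")
})

test_that("the endogeneity-bias term is Y/N * sigmaUV", {
    expect_equal(nagarBiasTerm(300, 1000, 4.9), 300 / 1000 * 4.9,
                 tolerance = 1e-12)
    expect_equal(nagarBiasTerm(300, 1000, 4.9), 1.47, tolerance = 1e-12)
    expect_equal(nagarBiasTerm(300, 1000, 0.8), 0.24, tolerance = 1e-12)
    expect_identical(nagarBiasTerm(300, 1000, 0), 0)
    expect_error(nagarBiasTerm(10, 0, 1), "positive")
})
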