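#' Define a Monte-Carlo scenario grid
#'
#' A grid is a list of simulation configurations (cells), a replicate count
#' per cell, the estimators to run, the nominal test sizes and a base seed.
#' Replicate r of every cell uses seed \code{baseSeed + r}, so any replicate
#' is independently regenerable and cells with equal generative parameters
#' share matched seeds (method and effect-size contrasts are
#' within-replicate).
#'
#' @param configs list of [SimulationConfig-class] cells.
#' @param replicates replicates per cell (>= 1).
#' @param methods subset of c("CFMR1", "CFMR2", "1SMR").
#' @param alphaLevels nominal test sizes, all in (0, 1).
#' @param baseSeed integer base seed.
#' @return a list of class \code{cfmr_grid}.
#' @export
scenarioGrid <- function(configs, replicates = 200L,
                         methods = c("CFMR2"), alphaLevels = 0.05,
                         baseSeed = 1L) {
    stopIfNot(replicates >= 1, "replicates must be >= 1")
    stopIfNot(all(alphaLevels > 0 & alphaLevels < 1),
              "alpha levels must lie in (0, 1)")
    stopIfNot(all(methods %in% c("CFMR1", "CFMR2", "1SMR")),
              "methods must be among CFMR1, CFMR2, 1SMR")
    if (is(configs, "SimulationConfig")) configs <- list(configs)
    structure(list(configs = configs, replicates = as.integer(replicates),
                   methods = methods, alphaLevels = alphaLevels,
                   baseSeed = as.integer(baseSeed)),
              class = "cfmr_grid")
}

runCell <- function(config, grid, partitionK, selection, predictor) {
    rows <- vector("list", grid$replicates * length(grid$methods))
    ri <- 0L
    for (r in seq_len(grid$replicates)) {
        cfg <- config
        cfg@seed <- grid$baseSeed + r
        dat <- simulateCore(cfg)
        x <- dat$x; y <- dat$y; g <- dat$g
        cfi <- NULL
        if (any(c("CFMR1", "CFMR2") %in% grid$methods)) {
            cfi <- tryCatch(
                buildCFI(g, x,
                         partition = makeFolds(cfg@nIndividuals, partitionK,
                                               seed = cfg@seed),
                         selection = selection, predictor = predictor),
                error = function(e) e)
        }
        for (m in grid$methods) {
            ri <- ri + 1L
            est <- tryCatch(suppressWarnings(switch(m,
                CFMR1 = if (inherits(cfi, "error")) stop(cfi) else
                    cfmr1(x, y, cfi),
                CFMR2 = if (inherits(cfi, "error")) stop(cfi) else
                    cfmr2(x, y, cfi),
                `1SMR` = oneSampleMR(g, x, y, selection = selection,
                                     predictor = predictor))),
                error = function(e) e)
            rows[[ri]] <- if (inherits(est, "error")) {
                data.frame(method = m, replicate = r, seed = cfg@seed,
                           estimate = NA_real_, se = NA_real_,
                           pvalue = NA_real_, failed = TRUE)
            } else {
                data.frame(method = m, replicate = r, seed = cfg@seed,
                           estimate = est@betaHat, se = est@se,
                           pvalue = est@pvalue, failed = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

#' Run a Monte-Carlo scenario grid
#'
#' For each cell and replicate: simulate a cohort, build the cross-fitted
#' instrument with \code{partitionK} folds, run the requested estimators and
#' record estimate, standard error and p-value. Failed replicates
#' (degenerate instruments, typical at very low heritability) are recorded,
#' not dropped: they count as non-rejections in the rejection rates and
#' their rate is reported per cell. Cells are independent; results do not
#' depend on execution order.
#'
#' @param grid a [scenarioGrid()].
#' @param partitionK folds for the cross-fitted instrument.
#' @param selection a [selectionSpec()]; the default applies the standard
#'   instrument-building protocol (clump at r2 = 0.1, keep p < 1e-6).
#' @param predictor a [predictorSpec()].
#' @param verbose print per-cell progress.
#' @return a list of class \code{cfmr_simsummary} with elements
#'   \code{summary} (one row per cell x method: mean estimate, empirical SD,
#'   mean reported SE, rejection rate per alpha, failure count) and
#'   \code{draws} (one row per replicate x method with the raw results).
#' @export
runScenarioGrid <- function(grid, partitionK = 10L,
                            selection = selectionSpec(),
                            predictor = predictorSpec(),
                            verbose = FALSE) {
    stopIfNot(inherits(grid, "cfmr_grid"), "grid must be a scenarioGrid()")
    draws <- vector("list", length(grid$configs))
    for (ci in seq_along(grid$configs)) {
        cfg <- grid$configs[[ci]]
        if (verbose)
            message(sprintf("cell %d/%d: N=%d h2=%g beta0=%g", ci,
                            length(grid$configs), cfg@nIndividuals, cfg@h2,
                            cfg@beta0))
        d <- runCell(cfg, grid, partitionK, selection, predictor)
        d$cell <- ci
        d$n <- cfg@nIndividuals
        d$h2 <- cfg@h2
        d$beta0 <- cfg@beta0
        d$sigma_uv <- cfg@sigmaUV
        draws[[ci]] <- d
    }
    draws <- do.call(rbind, draws)
    summarize <- function(d) {
        ok <- !d$failed
        out <- data.frame(cell = d$cell[1L], method = d$method[1L],
                          n = d$n[1L], h2 = d$h2[1L], beta0 = d$beta0[1L],
                          sigma_uv = d$sigma_uv[1L],
                          replicates = nrow(d), failed = sum(!ok),
                          mean_estimate = mean(d$estimate[ok]),
                          empirical_sd = stats::sd(d$estimate[ok]),
                          mean_se = mean(d$se[ok]))
        for (a in grid$alphaLevels) {
            rej <- !is.na(d$pvalue) & d$pvalue < a   # failures don't reject
            out[[sprintf("reject_%g", a)]] <- mean(rej)
        }
        out
    }
    pieces <- split(draws, list(draws$cell, draws$method), drop = TRUE)
    summary <- do.call(rbind, lapply(pieces, summarize))
    summary <- summary[order(summary$cell, summary$method), ]
    rownames(summary) <- NULL
    structure(list(summary = summary, draws = draws, grid = grid,
                   partitionK = as.integer(partitionK)),
              class = "cfmr_simsummary")
}

#' @export
print.cfmr_simsummary <- function(x, ...) {
    cat("Monte-Carlo scenario summary (", nrow(x$summary), " cells x methods, ",
        x$grid$replicates, " replicates each)\n", sep = "")
    print(x$summary, digits = 4)
    invisible(x)
}

#' Closed-form power of two-sample MR
#'
#' Asymptotic normal power of the two-sample-MR comparator with instruments
#' explaining a fraction \code{h2} of the exposure variance:
#' \eqn{SE_\infty = \sqrt{\sigma_U^2 / (n \, h^2 \, Var(X))}} and
#' \deqn{power = \Phi(-z_{1-\alpha/2} + |\beta_0|/SE_\infty) +
#'       \Phi(-z_{1-\alpha/2} - |\beta_0|/SE_\infty).}
#' At \code{h2 = 0} the instrument carries no information and the power
#' equals \code{alpha}; at \code{beta0 = 0} it equals \code{alpha} exactly.
#'
#' @param beta0 causal effect.
#' @param n sample size.
#' @param h2 instrument variance-explained fraction.
#' @param varX total exposure variance.
#' @param sigmaU2 outcome error variance.
#' @param alpha nominal size in (0, 1).
#' @return power in [0, 1].
#' @examples
#' theoreticalPower2SMR(0.08, 10000, 0.2, 6.25, 5, 0.05)  # ~0.979
#' @export
theoreticalPower2SMR <- function(beta0, n, h2, varX, sigmaU2,
                                 alpha = 0.05) {
    stopIfNot(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
    stopIfNot(n > 0 && varX > 0 && sigmaU2 > 0,
              "n, varX and sigmaU2 must be positive")
    if (h2 == 0) return(alpha)
    seInf <- sqrt(sigmaU2 / (n * h2 * varX))
    z <- qnorm(1 - alpha / 2)
    ncp <- abs(beta0) / seInf
    pnorm(-z + ncp) + pnorm(-z - ncp)
}

#' Bias comparison between naive and cross-fitted estimators
#'
#' From a scenario run containing both the one-sample baseline and a
#' cross-fitted method on matched seeds, tabulates per cell and method the
#' mean estimate, the bias (mean minus the generative effect) and its
#' Monte-Carlo standard error, plus the within-replicate (paired) contrast
#' of each method against "1SMR".
#'
#' @param result a \code{cfmr_simsummary} from [runScenarioGrid()].
#' @return data.frame with one row per cell x method.
#' @export
summarizeBiasComparison <- function(result) {
    stopIfNot(inherits(result, "cfmr_simsummary"),
              "result must come from runScenarioGrid()")
    d <- result$draws
    stopIfNot("1SMR" %in% d$method && any(d$method != "1SMR"),
              "the run must contain 1SMR and at least one CFMR method")
    cells <- split(d, d$cell)
    rows <- lapply(cells, function(dc) {
        base <- dc[dc$method == "1SMR", ]
        counts <- table(dc$method)
        if (length(unique(counts)) != 1L)
            stop("unmatched cells: methods have unequal replicate counts",
                 call. = FALSE)
        do.call(rbind, lapply(split(dc, dc$method), function(dm) {
            ok <- !dm$failed
            bias <- dm$estimate - dm$beta0
            paired <- dm$estimate - base$estimate[match(dm$replicate,
                                                        base$replicate)]
            data.frame(cell = dm$cell[1L], method = dm$method[1L],
                       n = dm$n[1L], h2 = dm$h2[1L], beta0 = dm$beta0[1L],
                       mean_estimate = mean(dm$estimate[ok]),
                       bias = mean(bias[ok]),
                       bias_mc_se = stats::sd(bias[ok]) / sqrt(sum(ok)),
                       contrast_vs_1smr = mean(paired, na.rm = TRUE),
                       failed = sum(!ok))
        }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a scenario summary as TSV
#'
#' @param result a \code{cfmr_simsummary}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSimulationSummary <- function(result, path) {
    data.table::fwrite(result$summary, path, sep = "\t")
    invisible(path)
}
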