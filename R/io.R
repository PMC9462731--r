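#' Write a cohort to TSV files
#'
#' Writes \code{<prefix>_genotypes.tsv} (first column \code{individual},
#' then one integer dosage column per variant), \code{<prefix>_phenotypes.tsv}
#' (individual, exposure, outcome, optional covariate columns, optional
#' population label) and, when the cohort carries generative parameters,
#' \code{<prefix>_config.yaml}. Joins on re-import are by the individual
#' identifier, never by row order.
#'
#' @param cohort an [MRCohort-class].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir, prefix = "cohort") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    g <- dosages(cohort)
    gpath <- file.path(dir, paste0(prefix, "_genotypes.tsv"))
    ppath <- file.path(dir, paste0(prefix, "_phenotypes.tsv"))
    gt <- data.table::data.table(individual = rownames(g))
    for (j in seq_len(ncol(g))) gt[[colnames(g)[j]]] <- as.integer(g[, j])
    data.table::fwrite(gt, gpath, sep = "\t")
    ph <- data.frame(individual = rownames(g),
                     exposure = exposure(cohort),
                     outcome = outcome(cohort))
    cv <- covariates(cohort)
    if (!is.null(cv)) for (j in seq_len(ncol(cv)))
        ph[[paste0("covariate_", colnames(cv)[j])]] <- cv[, j]
    pop <- populationLabels(cohort)
    if (!is.null(pop)) ph$population <- pop
    data.table::fwrite(ph, ppath, sep = "\t")
    paths <- c(genotypes = gpath, phenotypes = ppath)
    md <- S4Vectors::metadata(cohort)
    if (!is.null(md$config)) {
        cpath <- file.path(dir, paste0(prefix, "_config.yaml"))
        writeRunConfig(configAsList(md$config), cpath)
        paths <- c(paths, config = cpath)
    }
    invisible(paths)
}

configAsList <- function(config) {
    list(n_individuals = config@nIndividuals,
         n_variants = config@nVariants, n_causal = config@nCausal,
         maf = config@maf, h2 = config@h2, beta0 = config@beta0,
         sigma_u2 = config@sigmaU2, sigma_v2 = config@sigmaV2,
         sigma_uv = config@sigmaUV, seed = config@seed)
}

configFromList <- function(x) {
    simulationConfig(nIndividuals = x$n_individuals,
                     nVariants = x$n_variants, nCausal = x$n_causal,
                     maf = x$maf, h2 = x$h2, beta0 = x$beta0,
                     sigmaU2 = x$sigma_u2, sigmaV2 = x$sigma_v2,
                     sigmaUV = x$sigma_uv, seed = x$seed)
}

#' Read a cohort from TSV files
#'
#' Reads the genotype and phenotype tables written by [writeCohort()] (or
#' compatible files) and joins them by the individual identifier. Rows
#' present in only one file, or duplicated identifiers, raise an error
#' naming the file.
#'
#' @param genotypes path to the genotype TSV.
#' @param phenotypes path to the phenotype TSV.
#' @return an [MRCohort-class].
#' @export
readCohort <- function(genotypes, phenotypes) {
    gt <- data.table::fread(genotypes, sep = "\t", data.table = FALSE)
    ph <- data.table::fread(phenotypes, sep = "\t", data.table = FALSE)
    if (colnames(gt)[1L] != "individual")
        stop(sprintf("%s: first column must be 'individual'", genotypes),
             call. = FALSE)
    for (col in c("individual", "exposure", "outcome"))
        if (!col %in% colnames(ph))
            stop(sprintf("%s: column '%s' is required", phenotypes, col),
                 call. = FALSE)
    if (anyDuplicated(gt$individual))
        stop(sprintf("%s: duplicated individual identifiers", genotypes),
             call. = FALSE)
    if (anyDuplicated(ph$individual))
        stop(sprintf("%s: duplicated individual identifiers", phenotypes),
             call. = FALSE)
    m <- match(gt$individual, ph$individual)
    if (anyNA(m))
        stop(sprintf("%s: individual(s) missing from the phenotype table: %s",
                     phenotypes,
                     paste(utils::head(gt$individual[is.na(m)], 3L),
                           collapse = ", ")), call. = FALSE)
    ph <- ph[m, , drop = FALSE]
    g <- as.matrix(gt[, -1L, drop = FALSE])
    rownames(g) <- gt$individual
    covCols <- grep("^covariate_", colnames(ph), value = TRUE)
    cv <- if (length(covCols)) {
        m2 <- as.matrix(ph[, covCols, drop = FALSE])
        colnames(m2) <- sub("^covariate_", "", covCols)
        m2
    } else NULL
    MRCohort(g, exposure = ph$exposure, outcome = ph$outcome,
             covariates = cv,
             population = if ("population" %in% colnames(ph))
                 ph$population else NULL)
}

#' Import a dosage matrix from a VCF file
#'
#' Extracts GT-based dosages (count of alternate alleles) from a VCF.
#' Multiallelic records are rejected with an error; missing genotypes become
#' NA. Requires the optional vcfR package.
#'
#' @param path VCF file path.
#' @return integer matrix, individuals x variants, with variant identifiers
#'   as column names.
#' @export
readDosageVCF <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("VCF import requires the 'vcfR' package", call. = FALSE)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    if (any(grepl(",", alt)))
        stop("multiallelic records are not supported", call. = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, c(1, 2), function(x) {
        if (is.na(x)) return(NA_integer_)
        alleles <- strsplit(x, "[/|]")[[1]]
        if (any(alleles == ".")) return(NA_integer_)
        sum(alleles != "0")
    })
    ids <- vcfR::getID(v)
    if (anyNA(ids))
        ids <- ifelse(is.na(ids),
                      paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v)), ids)
    rownames(dose) <- ids
    t(dose)
}

#' Write a resolved run configuration as YAML
#'
#' Every pipeline run records its fully resolved settings (plus the package
#' version) next to its outputs, so any artifact can be regenerated.
#'
#' @param config named list of settings.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    config$package_version <- as.character(utils::packageVersion("cfmr"))
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
    yaml::read_yaml(path)
}
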