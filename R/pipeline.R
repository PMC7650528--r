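#' Run the full deconvolution pipeline from a structured configuration
#'
#' Orchestrates the four stages end to end: marker selection and expression
#' reference construction from clustered single-cell data; the
#' imputable-gene scan on a matched expression/methylation compendium;
#' gamma-mixture fitting and methylation-reference imputation; weighted
#' robust deconvolution of the bulk profiles; and, when a phenotype is
#' supplied, cell-type-specific differential methylation. All outputs are
#' TSV files in `outDir`, plus a YAML log echoing the configuration and
#' recording package version and seed, so a run is a deterministic function
#' of (inputs, config, seed).
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Inputs may be given in-memory (`counts`, `labels`, `matchedExpr`,
#'   `matchedMeth`, `genes`, `cpgs`, `bulk`, `pheno`, `covars`) or as file
#'   paths with the `File` suffix (`countsFile`, `labelsFile`, ...; TSV, or
#'   MatrixMarket for counts via `countsFormat = "mtx"`; BED + gene TSV via
#'   `annotationFiles = c(genes, cpgs)`). Optional `params` sub-list:
#'   `fdr` (0.05), `mssMin`, `statistic` ("median"), `mode` ("promoter" or
#'   "enhancer"), `rangeDnamMin` (0.1), `rangeExprMin` (1), `pMax` (0.05),
#'   `pThreshold` (0.2), `wMin` (0.4), `huberK` (1.345), `intercept` (TRUE),
#'   `celldmcFdr` (0.05), `seed` (1).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (`markers`, `exprRef`, `imputable`, `mixtureModel`, `dnamRef`,
#'   `fractionEstimate`, `dmct`).
#' @export
runPipeline <- function(config, outDir = "pipeline-out") {
    if (is.character(config)) config <- yaml::read_yaml(config)
    p <- utils::modifyList(list(fdr = 0.05, mssMin = NULL,
                                statistic = "median", mode = "promoter",
                                rangeDnamMin = 0.1, rangeExprMin = 1,
                                pMax = 0.05, pThreshold = 0.2, wMin = 0.4,
                                huberK = 1.345, intercept = TRUE,
                                celldmcFdr = 0.05, seed = 1L),
                           if (is.null(config$params)) list() else config$params)
    stopifnot(p$fdr > 0, p$fdr < 1, p$pThreshold > 0, p$pThreshold < 1,
              p$wMin >= 0, p$wMin <= 1, p$huberK > 0)
    getIn <- function(name, reader, ...) {
        if (!is.null(config[[name]])) return(config[[name]])
        f <- config[[paste0(name, "File")]]
        if (is.null(f)) return(NULL)
        reader(f, ...)
    }
    counts <- getIn("counts", readExpression,
                    format = if (is.null(config$countsFormat)) "tsv"
                             else config$countsFormat)
    labels <- getIn("labels", function(f)
        data.table::fread(f, data.table = FALSE))
    matchedExpr <- getIn("matchedExpr", readExpression)
    matchedMeth <- getIn("matchedMeth", readMethylation)
    genes <- config$genes
    cpgs <- config$cpgs
    if (is.null(genes) && !is.null(config$annotationFiles)) {
        ann <- readAnnotation(config$annotationFiles[1],
                              config$annotationFiles[2])
        genes <- ann$genes; cpgs <- ann$cpgs
    }
    bulk <- getIn("bulk", readMethylation)
    pheno <- getIn("pheno", function(f) {
        d <- data.table::fread(f, data.table = FALSE)
        stats::setNames(d[[2L]], d[[1L]])
    })
    covars <- config$covars
    # validate the requested stages before any compute
    need <- c(counts = is.null(counts), labels = is.null(labels),
              matchedExpr = is.null(matchedExpr),
              matchedMeth = is.null(matchedMeth), genes = is.null(genes),
              cpgs = is.null(cpgs))
    if (any(need))
        stop("missing required input(s): ",
             paste(names(need)[need], collapse = ", "))
    if (!is.null(pheno) && is.null(bulk))
        stop("differential-methylation stage requested (phenotype given) ",
             "but no bulk methylation data supplied")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    expr <- stage("scref", normalizeCounts(counts))
    lab <- labels$cellType[match(colnames(expr), labels$cell)]
    markers <- stage("scref",
        selectMarkers(expr, lab, fdr = p$fdr, mssMin = p$mssMin))
    exprRef <- stage("scref",
        buildReference(expr, lab, markers, statistic = p$statistic))
    data.table::fwrite(markers, file.path(outDir, "markers.tsv"), sep = "\t")
    writeReference(exprRef, file.path(outDir, "expr_ref.tsv"))

    pm <- stage("imputable",
        collapseToPromoter(matchedMeth, cpgs, genes))
    scan <- stage("imputable",
        scanImputable(matchedExpr, pm$values, rangeDnamMin = p$rangeDnamMin,
                      rangeExprMin = p$rangeExprMin, pMax = p$pMax))
    data.table::fwrite(scan, file.path(outDir, "imputable.tsv"), sep = "\t")

    mixModel <- stage("imputer",
        fitExpressionMixture(matchedExpr, seed = .subSeed(p$seed, 1L)))
    coreGenes <- scan$gene[scan$core]
    gm <- stage("imputer",
        imputeMarkers(intersect(markers$gene, coreGenes), matchedExpr,
                      pm$values, mixModel, pThreshold = p$pThreshold))
    dnamRef <- stage("imputer",
        buildDnamReference(exprRef, gm, wMin = p$wMin,
                           provenance = "pipeline"))
    writeReference(dnamRef, file.path(outDir, "dnam_ref.tsv"))
    jsonlite::write_json(
        list(gamma = list(shape = mixModel@shape, scale = mixModel@scale,
                          pi = mixModel@pi),
             genes = gm),
        file.path(outDir, "imputation_model.json"), auto_unbox = TRUE,
        digits = NA)

    fracs <- NULL; dmct <- NULL
    if (!is.null(bulk)) {
        bulkGene <- stage("deconv",
            collapseToPromoter(bulk, cpgs, genes))
        fracs <- stage("deconv",
            estimateFractions(bulkGene$values, dnamRef, huberK = p$huberK,
                              intercept = p$intercept))
        data.table::fwrite(
            data.frame(sample = rownames(fractions(fracs)),
                       fractions(fracs), check.names = FALSE),
            file.path(outDir, "fractions.tsv"), sep = "\t")
        if (!is.null(pheno)) {
            ph <- pheno[colnames(bulk)]
            if (anyNA(ph)) stop("phenotype missing for some bulk samples")
            dmct <- stage("celldmc",
                fitCellDMC(bulk, fractions(fracs)[colnames(bulk), ], ph,
                           covars = covars, fdr = p$celldmcFdr))
            data.table::fwrite(dmctTable(dmct),
                               file.path(outDir, "dmct.tsv"), sep = "\t")
        }
    }
    yaml::write_yaml(
        list(package = as.character(utils::packageVersion("scMethylDeconv")),
             rversion = paste(R.version$major, R.version$minor, sep = "."),
             seed = p$seed, params = p[order(names(p))]),
        file.path(outDir, "run_log.yaml"))
    invisible(list(markers = markers, exprRef = exprRef, imputable = scan,
                   mixtureModel = mixModel, dnamRef = dnamRef,
                   fractionEstimate = fracs, dmct = dmct))
}
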