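# Session-cached fixtures so expensive simulations are built once per run.
.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, expr, envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

fixtureSc <- function() cached("sc", simSingleCellCounts(seed = 101L))

fixtureMatched <- function() cached("matched", simMatchedOmics(seed = 202L))

# full synthetic tissue and the pipeline stages run on it
fixtureTissue <- function() cached("tissue", {
    tt <- simTissueTruth(seed = 303L)
    expr <- normalizeCounts(tt$sc$counts)
    mk <- suppressMessages(selectMarkers(expr, tt$sc$labels$cellType))
    exprRef <- buildReference(expr, tt$sc$labels$cellType, mk)
    pm <- collapseToPromoter(tt$matched$methCpg, tt$matched$cpgs,
                             tt$matched$genes)
    scan <- scanImputable(tt$matched$expr, pm$values)
    gm <- fitExpressionMixture(tt$matched$expr, seed = 1L)
    mods <- imputeMarkers(intersect(mk$gene, scan$gene[scan$core]),
                          tt$matched$expr, pm$values, gm)
    dnamRef <- buildDnamReference(exprRef, mods, provenance = "synthetic")
    list(truth = tt, expr = expr, markers = mk, exprRef = exprRef,
         pmeth = pm, scan = scan, mixModel = gm, geneModels = mods,
         dnamRef = dnamRef)
})

# small well-conditioned methylation reference for deconvolution unit tests
fixtureSmallRef <- function() cached("smallRef", {
    set.seed(42)
    M <- matrix(runif(80, 0.05, 0.95), 20, 4,
                dimnames = list(sprintf("f%02d", 1:20), paste0("CT", 1:4)))
    MethylationReference(M, weights = runif(20, 0.3, 1))
})
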