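# Seeded generators for every input class the pipeline consumes, with the
# ground truth recorded alongside. Every generator is a pure function of its
# parameter tuple plus seed (the caller's RNG state is restored on exit).

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(seed)
    force(expr)
}

# decreasing logistic link from log-scale expression to promoter beta
.methLink <- function(x, mid = 4, steep = 1.5) stats::plogis(-steep * (x - mid))

#' Simulate clustered single-cell RNA-seq counts with planted markers
#'
#' Negative-binomial counts with independent dropout. Each planted marker is
#' expressed only in its own cell type (structural zeros elsewhere), so a
#' maximally specific marker (specificity score K-1) is recoverable by
#' construction. Cell numbers per type default to the scale of a typical
#' tissue atlas (150-700 cells per type).
#'
#' @param K number of cell types.
#' @param nGenes total genes.
#' @param markersPerType planted markers per cell type.
#' @param cellsPerType integer vector of length K, or a `c(min, max)` range
#'   to draw from uniformly.
#' @param markerMu,backgroundMu negative-binomial means for marker genes (in
#'   their own type) and background genes.
#' @param nbDispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param dropoutRate independent zeroing probability per entry.
#' @param seed integer seed.
#' @return list with `counts` (genes x cells), `labels` (data.frame
#'   `cell, cellType`) and `truth` (planted marker map and parameters).
#' @export
simSingleCellCounts <- function(K = 4L, nGenes = 2000L, markersPerType = 50L,
                                cellsPerType = c(150L, 700L), markerMu = 8,
                                backgroundMu = 2, nbDispersion = 0.4,
                                dropoutRate = 0.1, seed = 1L) {
    stopifnot(markersPerType * K <= nGenes)
    .withSeed(seed, {
        types <- paste0("CT", seq_len(K))
        nCells <- if (length(cellsPerType) == K) as.integer(cellsPerType)
                  else sample(seq(cellsPerType[1], cellsPerType[2]), K,
                              replace = TRUE)
        labels <- rep(types, nCells)
        nc <- length(labels)
        genes <- sprintf("g%04d", seq_len(nGenes))
        markerIdx <- seq_len(markersPerType * K)
        markerMap <- stats::setNames(rep(types, each = markersPerType),
                                     genes[markerIdx])
        # per-gene background means (log-normal spread)
        mu <- backgroundMu * stats::rlnorm(nGenes, 0, 0.5)
        muMat <- matrix(rep(mu, nc), nGenes, nc)
        for (k in seq_len(K)) {
            gi <- markerIdx[(k - 1L) * markersPerType + seq_len(markersPerType)]
            muMat[gi, ] <- 0                       # structural zeros
            muMat[gi, labels == types[k]] <- markerMu
        }
        size <- if (nbDispersion > 0) 1 / nbDispersion else Inf
        counts <- matrix(0L, nGenes, nc)
        pos <- muMat > 0
        counts[pos] <- if (is.finite(size))
            stats::rnbinom(sum(pos), mu = muMat[pos], size = size)
        else stats::rpois(sum(pos), muMat[pos])
        if (dropoutRate > 0)
            counts[pos][stats::runif(sum(pos)) < dropoutRate] <- 0L
        cells <- sprintf("c%05d", seq_len(nc))
        dimnames(counts) <- list(genes, cells)
        # no cell may end with zero total count
        empty <- colSums(counts) == 0
        if (any(empty)) counts[1L, empty] <- 1L
        list(counts = counts,
             labels = data.frame(cell = cells, cellType = labels,
                                 stringsAsFactors = FALSE),
             truth = list(seed = seed, markerMap = markerMap,
                          params = list(K = K, nGenes = nGenes,
                                        markersPerType = markersPerType,
                                        cellsPerType = nCells,
                                        markerMu = markerMu,
                                        backgroundMu = backgroundMu,
                                        nbDispersion = nbDispersion,
                                        dropoutRate = dropoutRate)))
    })
}

#' Simulate a matched expression / promoter-methylation compendium
#'
#' Expression values are drawn i.i.d. from the two-state gamma mixture. For
#' a planted fraction of genes (or an explicitly supplied gene set) the
#' promoter beta follows a decreasing logistic function of expression plus
#' truncated Gaussian noise; all other genes have betas independent of
#' expression. Synthetic TSS/first-exon/CpG annotations consistent with the
#' promoter collapse rule are generated alongside (one promoter CpG per
#' gene, strand alternating).
#'
#' @param nGenes,nSamples compendium dimensions (defaults mirror an
#'   array-based purified-sample compendium: 3000 x 34).
#' @param fracAnticorr fraction of genes with a planted expression-
#'   methylation link.
#' @param linkedGenes optional character vector overriding the random choice
#'   of linked genes (must be a subset of the generated gene ids
#'   `g0001...`).
#' @param shapeU,scaleU,shapeE,scaleE,piE gamma-mixture generating
#'   parameters (unexpressed mean 1, expressed mean 10 by default).
#' @param linkMid,linkSteep logistic link midpoint and steepness.
#' @param linkMidSd per-gene spread of the link midpoint (truncated at
#'   `linkMid` +/- 2.5), emulating the gene-to-gene heterogeneity of the
#'   unexpressed-state methylation level seen in real compendia.
#' @param noiseSd truncated-Gaussian beta noise.
#' @param seed integer seed.
#' @return list with `expr`, `pmeth` (gene-level), `methCpg` (CpG-level),
#'   `genes`, `cpgs` annotations, and `truth`.
#' @export
simMatchedOmics <- function(nGenes = 3000L, nSamples = 34L,
                            fracAnticorr = 0.1, linkedGenes = NULL,
                            shapeU = 2, scaleU = 0.5, shapeE = 20,
                            scaleE = 0.5, piE = 0.3, linkMid = 4,
                            linkMidSd = 1.2, linkSteep = 1.5, noiseSd = 0.05,
                            seed = 1L) {
    .withSeed(seed, {
        genes <- sprintf("g%04d", seq_len(nGenes))
        samples <- sprintf("s%03d", seq_len(nSamples))
        nv <- nGenes * nSamples
        state <- stats::rbinom(nv, 1L, piE)
        x <- numeric(nv)
        x[state == 0L] <- stats::rgamma(sum(state == 0L), shape = shapeU,
                                        scale = scaleU)
        x[state == 1L] <- stats::rgamma(sum(state == 1L), shape = shapeE,
                                        scale = scaleE)
        expr <- matrix(x, nGenes, nSamples, dimnames = list(genes, samples))
        if (is.null(linkedGenes)) {
            linkedGenes <- sample(genes, round(fracAnticorr * nGenes))
        } else {
            stopifnot(all(linkedGenes %in% genes))
        }
        linked <- genes %in% linkedGenes
        mids <- stats::setNames(pmin(pmax(stats::rnorm(nGenes, linkMid,
                                                       linkMidSd),
                                          linkMid - 2.5), linkMid + 2.5),
                                genes)
        pmeth <- matrix(0, nGenes, nSamples, dimnames = list(genes, samples))
        pmeth[linked, ] <- .methLink(expr[linked, , drop = FALSE],
                                     mids[linked], linkSteep)
        # null genes: per-gene baseline, independent of expression
        base <- stats::runif(sum(!linked), 0.2, 0.8)
        pmeth[!linked, ] <- matrix(rep(base, nSamples), ncol = nSamples)
        if (noiseSd > 0)
            pmeth <- pmeth + stats::rnorm(nv, 0, noiseSd)
        pmeth <- .clip01(pmeth)
        # annotations: genes spaced 10 kb apart on one chromosome, strand
        # alternating; one promoter CpG 100 bp upstream of each TSS
        tss <- 10000L * seq_len(nGenes) + 5000L
        strand <- rep(c("+", "-"), length.out = nGenes)
        geneAnn <- data.frame(gene_id = genes, chrom = "chr1", tss = tss,
                              strand = strand,
                              exon1_start = ifelse(strand == "+", tss,
                                                   tss - 500L),
                              exon1_end = ifelse(strand == "+", tss + 500L,
                                                 tss),
                              stringsAsFactors = FALSE)
        cpgPos <- ifelse(strand == "+", tss - 100L, tss + 100L)
        cpgAnn <- data.frame(cpg_id = sprintf("cg%04d", seq_len(nGenes)),
                             chrom = "chr1", position = cpgPos,
                             stringsAsFactors = FALSE)
        methCpg <- pmeth
        rownames(methCpg) <- cpgAnn$cpg_id
        list(expr = expr, pmeth = pmeth, methCpg = methCpg, genes = geneAnn,
             cpgs = cpgAnn,
             truth = list(seed = seed, anticorrGenes = sort(linkedGenes),
                          linkMids = mids,
                          params = list(shapeU = shapeU, scaleU = scaleU,
                                        shapeE = shapeE, scaleE = scaleE,
                                        piE = piE, linkMid = linkMid,
                                        linkMidSd = linkMidSd,
                                        linkSteep = linkSteep,
                                        noiseSd = noiseSd)))
    })
}

#' Simulate bulk methylation with planted cell-type-specific effects
#'
#' Bulk betas follow `y_c = sum_k f_k m_ck + delta_c f_k0 z + noise`,
#' clipped to [0,1], with Dirichlet fractions, a balanced binary phenotype,
#' and `nDmcts` CpGs carrying an effect of magnitude `deltaBeta` (random
#' sign) in one target cell type.
#'
#' @param nSamples,K,nCpgs dimensions.
#' @param dirichletAlpha Dirichlet concentration (length K or scalar).
#' @param nDmcts planted differentially methylated CpGs.
#' @param deltaBeta planted effect magnitude.
#' @param targetCellType index of the affected cell type (default 1).
#' @param noiseSd Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `meth` (CpGs x samples), `fractions` (samples x K, on
#'   the simplex), `pheno` (0/1), and `truth` (planted CpGs, signs,
#'   baselines).
#' @export
simCellDMCData <- function(nSamples = 500L, K = 4L, dirichletAlpha = 1,
                           nCpgs = 2000L, nDmcts = 100L, deltaBeta = 0.1,
                           targetCellType = 1L, noiseSd = 0.02, seed = 1L) {
    stopifnot(nDmcts <= nCpgs)
    .withSeed(seed, {
        types <- paste0("CT", seq_len(K))
        if (length(dirichletAlpha) == 1L)
            dirichletAlpha <- rep(dirichletAlpha, K)
        F <- .rdirichlet(nSamples, stats::setNames(dirichletAlpha, types))
        rownames(F) <- sprintf("s%04d", seq_len(nSamples))
        z <- rep(c(0, 1), length.out = nSamples)
        cpgs <- sprintf("cg%05d", seq_len(nCpgs))
        M <- matrix(stats::runif(nCpgs * K, 0.1, 0.9), nCpgs, K,
                    dimnames = list(cpgs, types))
        dmctIdx <- seq_len(nDmcts)
        signs <- sample(c(-1, 1), nDmcts, replace = TRUE)
        # keep room for the effect inside [0,1]
        M[dmctIdx, targetCellType] <- stats::runif(nDmcts, 0.3, 0.7)
        delta <- numeric(nCpgs)
        delta[dmctIdx] <- signs * deltaBeta
        Y <- M %*% t(F) +
            outer(delta, F[, targetCellType] * z)
        if (noiseSd > 0)
            Y <- Y + matrix(stats::rnorm(length(Y), 0, noiseSd), nrow(Y))
        Y <- .clip01(Y)
        colnames(Y) <- rownames(F)
        list(meth = Y, fractions = F,
             pheno = stats::setNames(z, rownames(F)),
             truth = list(seed = seed, dmctCpgs = cpgs[dmctIdx],
                          signs = stats::setNames(signs, cpgs[dmctIdx]),
                          targetCellType = types[targetCellType],
                          baseline = M,
                          params = list(deltaBeta = deltaBeta,
                                        noiseSd = noiseSd)))
    })
}

#' Simulate a complete synthetic tissue for end-to-end evaluation
#'
#' Couples the single-cell generator with a matched compendium sharing the
#' same gene universe: every planted marker (plus a background fraction of
#' other genes) carries the logistic expression-methylation link, so the
#' whole pipeline (marker selection, imputable-gene scan, mixture model,
#' imputation, deconvolution) can be run against recorded truth. The true
#' per-cell-type methylation profile of a marker gene is the logistic link
#' evaluated at its expected log-scale reference expression.
#'
#' @param seed integer seed.
#' @param K,nGenes,markersPerType,cellsPerType passed to
#'   [simSingleCellCounts()].
#' @param nSamples matched-compendium sample count.
#' @param noiseSd matched-compendium beta noise.
#' @return list with `sc` (single-cell simulation), `matched` (compendium),
#'   and `trueDnam` (marker genes x K true beta matrix).
#' @export
simTissueTruth <- function(seed = 1L, K = 4L, nGenes = 2000L,
                           markersPerType = 50L, cellsPerType = c(150L, 700L),
                           nSamples = 34L, noiseSd = 0.05) {
    sc <- simSingleCellCounts(K = K, nGenes = nGenes,
                              markersPerType = markersPerType,
                              cellsPerType = cellsPerType, seed = seed)
    markerGenes <- names(sc$truth$markerMap)
    extra <- .withSeed(.subSeed(seed, 7L),
        sample(setdiff(rownames(sc$counts), markerGenes),
               round(0.05 * nGenes)))
    matched <- simMatchedOmics(nGenes = nGenes, nSamples = nSamples,
                               linkedGenes = c(markerGenes, extra),
                               noiseSd = noiseSd,
                               seed = .subSeed(seed, 11L))
    # truth on the compendium expression scale: a marker's promoter beta is
    # the link evaluated at the expressed-state mean in its own type and at
    # the unexpressed-state mean elsewhere
    pp <- matched$truth$params
    mids <- matched$truth$linkMids[markerGenes]
    meanE <- pp$shapeE * pp$scaleE
    meanU <- pp$shapeU * pp$scaleU
    types <- paste0("CT", seq_len(K))
    trueDnam <- matrix(rep(.methLink(meanU, mids, pp$linkSteep), K),
                       length(markerGenes), K,
                       dimnames = list(markerGenes, types))
    for (g in markerGenes)
        trueDnam[g, sc$truth$markerMap[g]] <- .methLink(meanE, mids[g],
                                                        pp$linkSteep)
    list(sc = sc, matched = matched, trueDnam = trueDnam)
}
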