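#' Collapse CpG-level methylation to gene promoters
#'
#' Assigns each gene the mean beta of CpGs in its strand-aware upstream
#' promoter window (`[tss - window, tss - 1]` on +, `[tss + 1, tss + window]`
#' on -, both ends inclusive; the TSS itself is excluded), or, when that
#' window contains no CpG, the mean beta of first-exon CpGs. Genes with no
#' CpG in either region are dropped.
#'
#' @param meth CpG x sample beta matrix.
#' @param cpgs CpG annotation data.frame (`cpg_id, chrom, position`, 1-based).
#' @param genes gene annotation data.frame (`gene_id, chrom, tss, strand,
#'   exon1_start, exon1_end`, 1-based inclusive).
#' @param window upstream window size in bp (default 200).
#' @return list with `values` (gene x sample beta matrix) and `provenance`
#'   (named character, "tss200" or "exon1" per retained gene).
#' @export
collapseToPromoter <- function(meth, cpgs, genes, window = 200L) {
    cpgs <- cpgs[cpgs$cpg_id %in% rownames(meth), , drop = FALSE]
    cpgGR <- GenomicRanges::GRanges(cpgs$chrom,
                                    IRanges::IRanges(cpgs$position, width = 1L))
    plus <- genes$strand == "+"
    upStart <- ifelse(plus, genes$tss - window, genes$tss + 1L)
    upEnd <- ifelse(plus, genes$tss - 1L, genes$tss + window)
    upGR <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(pmax(upStart, 1L), upEnd))
    exGR <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$exon1_start,
                                                    genes$exon1_end))
    hitsUp <- GenomicRanges::findOverlaps(upGR, cpgGR)
    hitsEx <- GenomicRanges::findOverlaps(exGR, cpgGR)
    upList <- split(S4Vectors::subjectHits(hitsUp),
                    factor(S4Vectors::queryHits(hitsUp),
                           levels = seq_len(nrow(genes))))
    exList <- split(S4Vectors::subjectHits(hitsEx),
                    factor(S4Vectors::queryHits(hitsEx),
                           levels = seq_len(nrow(genes))))
    vals <- matrix(NA_real_, nrow(genes), ncol(meth),
                   dimnames = list(genes$gene_id, colnames(meth)))
    prov <- rep(NA_character_, nrow(genes))
    sub <- meth[cpgs$cpg_id, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
        ii <- upList[[i]]
        if (length(ii)) {
            prov[i] <- "tss200"
        } else {
            ii <- exList[[i]]
            if (length(ii)) prov[i] <- "exon1"
        }
        if (length(ii))
            vals[i, ] <- colMeans(sub[ii, , drop = FALSE], na.rm = TRUE)
    }
    keep <- !is.na(prov)
    if (any(!keep))
        message(sum(!keep), " gene(s) without promoter or first-exon CpGs ",
                "dropped")
    list(values = vals[keep, , drop = FALSE],
         provenance = stats::setNames(prov[keep], genes$gene_id[keep]))
}

#' Genome-wide scan for genes with methylation predictable from expression
#'
#' Across the samples shared by the two matrices, genes passing both
#' variability filters (methylation range > `rangeDnamMin`, expression range
#' > `rangeExprMin`; range = max - min after removing missing values) are
#' tested for Pearson correlation between promoter methylation and
#' expression (two-sided p from the t transform, n - 2 df). The "core"
#' imputable set is the significantly *anti*-correlated genes.
#'
#' @param expr gene x sample log-scale expression matrix.
#' @param pmeth gene x sample promoter beta matrix (e.g. from
#'   [collapseToPromoter()]).
#' @param rangeDnamMin,rangeExprMin variability filters (defaults 0.1 and 1).
#' @param pMax significance threshold on the nominal p value (default 0.05);
#'   set `useFdr = TRUE` to threshold the BH FDR instead.
#' @param useFdr logical, see above.
#' @return data.frame, one row per gene passing both filters, with columns
#'   `gene, pcc, p, fdr, dnamRange, exprRange, direction, significant, core`.
#'   Attribute `"nShared"` holds the size of the shared gene universe before
#'   the variability filters.
#' @export
scanImputable <- function(expr, pmeth, rangeDnamMin = 0.1,
                          rangeExprMin = 1.0, pMax = 0.05, useFdr = FALSE) {
    sharedS <- intersect(colnames(expr), colnames(pmeth))
    if (length(sharedS) < 3L) stop("need >= 3 shared samples")
    sharedG <- intersect(rownames(expr), rownames(pmeth))
    e <- expr[sharedG, sharedS, drop = FALSE]
    m <- pmeth[sharedG, sharedS, drop = FALSE]
    rng <- function(x) apply(x, 1L, function(v) diff(range(v, na.rm = TRUE)))
    dr <- rng(m); er <- rng(e)
    keep <- dr > rangeDnamMin & er > rangeExprMin
    e <- e[keep, , drop = FALSE]; m <- m[keep, , drop = FALSE]
    if (!nrow(e)) {
        out <- data.frame(gene = character(), pcc = numeric(), p = numeric(),
                          fdr = numeric(), dnamRange = numeric(),
                          exprRange = numeric(), direction = character(),
                          significant = logical(), core = logical())
        attr(out, "nShared") <- length(sharedG)
        return(out)
    }
    cs <- .rowPearson(e, m)
    if (any(!is.finite(cs$r)))
        stop("constant gene vector survived the range filters")  # defensive
    fdrv <- stats::p.adjust(cs$p, method = "BH")
    sig <- if (useFdr) fdrv < pMax else cs$p < pMax
    out <- data.frame(gene = rownames(e), pcc = cs$r, p = cs$p, fdr = fdrv,
                      dnamRange = dr[keep], exprRange = er[keep],
                      direction = ifelse(cs$r < 0, "anti", "positive"),
                      significant = sig, core = sig & cs$r < 0,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "nShared") <- length(sharedG)
    out
}

#' Significance of the overlap between two gene sets
#'
#' One-tailed hypergeometric (enrichment) p value plus a seeded Monte-Carlo
#' empirical p from random draws of `|setA|` genes out of the universe.
#'
#' @param setA,setB character vectors of gene ids (subsets of the universe).
#' @param universeSize size of the common gene universe.
#' @param nMC number of Monte-Carlo draws (default 1e5). Uses the current
#'   RNG state; set a seed upstream for reproducibility.
#' @return list with `nOverlap`, `fisherP` (hypergeometric tail) and `mcP`.
#' @export
overlapSignificance <- function(setA, setB, universeSize, nMC = 1e5L) {
    setA <- unique(setA); setB <- unique(setB)
    nA <- length(setA); nB <- length(setB)
    nOv <- length(intersect(setA, setB))
    if (nA == 0L || nB == 0L) {
        warning("empty input set; overlap p value set to 1")
        return(list(nOverlap = nOv, fisherP = 1, mcP = 1))
    }
    stopifnot(nA <= universeSize, nB <= universeSize)
    fisherP <- stats::phyper(nOv - 1L, nB, universeSize - nB, nA,
                             lower.tail = FALSE)
    # Monte-Carlo: resample setA's size from the universe, count hits in setB
    hits <- 0L
    done <- 0L
    while (done < nMC) {
        chunk <- min(nMC - done, 10000L)
        ov <- vapply(seq_len(chunk), function(i)
            sum(sample.int(universeSize, nA) <= nB), integer(1L))
        hits <- hits + sum(ov >= nOv)
        done <- done + chunk
    }
    list(nOverlap = nOv, fisherP = fisherP, mcP = (hits + 1) / (nMC + 1))
}

#' Link distal (enhancer) CpGs to genes by expression--methylation regression
#'
#' Candidate pairs are CpGs within `window` bp of a gene's TSS but outside
#' the `exclude` bp proximal zone on either side. For each candidate pair a
#' simple linear regression of beta on expression is fitted across the
#' shared samples; pairs with BH FDR below `fdr` and R-squared above `r2Min`
#' are kept, and each CpG is assigned to the single gene with the largest
#' absolute t statistic (ties: smaller p, then lexicographic gene id).
#'
#' @param meth CpG x sample beta matrix.
#' @param cpgs,genes annotation data.frames as in [collapseToPromoter()].
#' @param expr gene x sample log-scale expression matrix.
#' @param window,exclude distance rule in bp (defaults 500 kb / 5 kb).
#' @param rangeDnamMin,rangeExprMin variability filters (defaults 0.5 and 1).
#' @param r2Min minimum R-squared (default 0.8).
#' @param fdr BH FDR threshold over all tested pairs (default 0.05).
#' @return data.frame `cpg, gene, slope, intercept, t, r2, p, fdr`, one row
#'   per retained CpG.
#' @export
linkEnhancerCpGs <- function(meth, cpgs, genes, expr, window = 5e5,
                             exclude = 5e3, rangeDnamMin = 0.5,
                             rangeExprMin = 1.0, r2Min = 0.8, fdr = 0.05) {
    sharedS <- intersect(colnames(meth), colnames(expr))
    if (length(sharedS) < 6L) stop("need >= 6 shared samples")
    meth <- meth[, sharedS, drop = FALSE]
    expr <- expr[, sharedS, drop = FALSE]
    rng <- function(x) apply(x, 1L, function(v) diff(range(v, na.rm = TRUE)))
    cpgs <- cpgs[cpgs$cpg_id %in% rownames(meth), , drop = FALSE]
    cpgs <- cpgs[rng(meth[cpgs$cpg_id, , drop = FALSE]) > rangeDnamMin, ,
                 drop = FALSE]
    genes <- genes[genes$gene_id %in% rownames(expr), , drop = FALSE]
    genes <- genes[rng(expr[genes$gene_id, , drop = FALSE]) > rangeExprMin, ,
                   drop = FALSE]
    if (!nrow(cpgs) || !nrow(genes)) {
        warning("no candidate CpG-gene pairs")
        return(data.frame(cpg = character(), gene = character(),
                          slope = numeric(), intercept = numeric(),
                          t = numeric(), r2 = numeric(), p = numeric(),
                          fdr = numeric()))
    }
    cpgGR <- GenomicRanges::GRanges(cpgs$chrom,
                                    IRanges::IRanges(cpgs$position, width = 1L))
    winGR <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(pmax(genes$tss - window, 1),
                                                     genes$tss + window))
    hits <- GenomicRanges::findOverlaps(winGR, cpgGR)
    gi <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
    dist <- abs(cpgs$position[ci] - genes$tss[gi])
    keep <- dist > exclude
    gi <- gi[keep]; ci <- ci[keep]
    if (!length(gi)) {
        warning("no candidate CpG-gene pairs after the proximal exclusion")
        return(data.frame(cpg = character(), gene = character(),
                          slope = numeric(), intercept = numeric(),
                          t = numeric(), r2 = numeric(), p = numeric(),
                          fdr = numeric()))
    }
    n <- length(sharedS)
    y <- meth[cpgs$cpg_id[ci], , drop = FALSE]
    x <- expr[genes$gene_id[gi], , drop = FALSE]
    cs <- .rowPearson(x, y)
    sdy <- apply(y, 1L, stats::sd); sdx <- apply(x, 1L, stats::sd)
    slope <- cs$r * sdy / sdx
    intercept <- rowMeans(y) - slope * rowMeans(x)
    tstat <- cs$r * sqrt((n - 2) / pmax(1 - cs$r^2, .Machine$double.eps))
    pairs <- data.frame(cpg = cpgs$cpg_id[ci], gene = genes$gene_id[gi],
                        slope = slope, intercept = intercept, t = tstat,
                        r2 = cs$r^2, p = cs$p,
                        fdr = stats::p.adjust(cs$p, method = "BH"),
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$fdr < fdr & pairs$r2 > r2Min, , drop = FALSE]
    if (!nrow(pairs)) {
        warning("no significant CpG-gene pairs")
        return(pairs)
    }
    # unique gene per CpG: max |t|, ties by smaller p then gene id
    pairs <- pairs[order(pairs$cpg, -abs(pairs$t), pairs$p, pairs$gene), ,
                   drop = FALSE]
    nDup <- sum(duplicated(pairs$cpg))
    if (nDup) message(nDup, " multi-gene CpG assignment(s) resolved by ",
                      "max |t| (ties: smaller p, then gene id)")
    pairs <- pairs[!duplicated(pairs$cpg), , drop = FALSE]
    rownames(pairs) <- NULL
    pairs
}
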