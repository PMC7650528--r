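#' Library-size normalisation of single-cell counts
#'
#' Each cell is scaled by the ratio of the maximum total count across cells
#' to its own total count, then transformed as log2(x + 1).
#'
#' @param counts genes x cells non-negative count matrix.
#' @return log2-scale matrix of the same dimensions.
#' @export
normalizeCounts <- function(counts) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    tot <- colSums(counts)
    if (any(tot == 0))
        stop("cells with zero total count: ",
             paste(colnames(counts)[tot == 0], collapse = ", "))
    sf <- max(tot) / tot
    log2(sweep(counts, 2L, sf, `*`) + 1)
}

# per-cell-type summary matrices (genes x K)
.groupStat <- function(expr, labels, fun) {
    types <- sort(unique(labels))
    out <- vapply(types,
                  function(k) apply(expr[, labels == k, drop = FALSE], 1L, fun),
                  numeric(nrow(expr)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(expr))
    dimnames(out) <- list(rownames(expr), types)
    out
}

#' Select cell-type marker genes from clustered single-cell data
#'
#' Runs K one-vs-rest Wilcoxon rank-sum scans (BH adjustment within each
#' scan). In the default `"mss"` mode a gene is a marker for a cell type when
#' (i) FDR is below `fdr`, (ii) its median expression is highest and non-zero
#' in that cell type, and (iii) its marker specificity score (MSS, the number
#' of other cell types with zero median expression, at most K-1) reaches the
#' per-cell-type minimum `mssMin`. Ties for the highest median are broken by
#' higher mean, then lexicographic cell-type name.
#'
#' The `"rank-cap"` mode is the preset used for closely related cell types
#' (e.g. blood subsets): FDR < `fdr`, log2 fold change > `log2fcMin`, highest
#' mean expression in the own type, then the top `topN` genes per cell type
#' ranked by decreasing log2 fold change.
#'
#' @param expr genes x cells log-scale matrix.
#' @param labels character vector of cell-type labels, one per column.
#' @param fdr BH FDR threshold within each one-vs-rest scan.
#' @param mssMin minimum MSS; scalar or named per-cell-type vector
#'   (default K-1 for every type).
#' @param mode "mss" or "rank-cap".
#' @param log2fcMin,topN rank-cap mode parameters.
#' @return data.frame with columns `gene, cellType, p, fdr, mss, log2fc`.
#' @export
selectMarkers <- function(expr, labels, fdr = 0.05, mssMin = NULL,
                          mode = c("mss", "rank-cap"),
                          log2fcMin = 0.5, topN = 20L) {
    mode <- match.arg(mode)
    expr <- as.matrix(expr)
    labels <- as.character(labels)
    stopifnot(length(labels) == ncol(expr))
    types <- sort(unique(labels))
    K <- length(types)
    if (K < 2L) stop("need at least two cell types")
    if (any(table(labels) < 2L)) stop("every cell type needs >= 2 cells")
    if (is.null(mssMin)) mssMin <- K - 1L
    if (length(mssMin) == 1L) mssMin <- stats::setNames(rep(mssMin, K), types)
    medMat <- .groupStat(expr, labels, stats::median)
    meanMat <- .groupStat(expr, labels, mean)
    pMat <- vapply(types, function(k) .rowWilcoxon(expr, labels == k),
                   numeric(nrow(expr)))
    fdrMat <- apply(pMat, 2L, stats::p.adjust, method = "BH")
    dimnames(pMat) <- dimnames(fdrMat) <- list(rownames(expr), types)
    # pooled-rest log2FC: own-type mean minus mean over all other cells
    fcMat <- vapply(types, function(k) {
        rowMeans(expr[, labels == k, drop = FALSE]) -
            rowMeans(expr[, labels != k, drop = FALSE])
    }, numeric(nrow(expr)))
    dimnames(fcMat) <- list(rownames(expr), types)

    # best type per gene: highest median, ties by higher mean, then name
    bestIdx <- apply(cbind(medMat, meanMat), 1L, function(v) {
        md <- v[seq_len(K)]; mn <- v[K + seq_len(K)]
        order(-md, -mn, types)[1L]
    })
    bestType <- types[bestIdx]
    nTiedMedians <- rowSums(medMat == medMat[cbind(seq_len(nrow(medMat)),
                                                   bestIdx)])
    if (any(nTiedMedians > 1L & medMat[cbind(seq_along(bestIdx), bestIdx)] > 0))
        message(sum(nTiedMedians > 1L &
                    medMat[cbind(seq_along(bestIdx), bestIdx)] > 0),
                " gene(s) with tied highest medians; ties broken by mean, ",
                "then cell-type name")

    idx <- cbind(seq_len(nrow(expr)), bestIdx)
    out <- data.frame(gene = rownames(expr), cellType = bestType,
                      p = pMat[idx], fdr = fdrMat[idx],
                      mss = rowSums(medMat == 0) - (medMat[idx] == 0),
                      log2fc = fcMat[idx], stringsAsFactors = FALSE)

    if (mode == "mss") {
        keep <- out$fdr < fdr &
            medMat[idx] > 0 &
            out$mss >= mssMin[out$cellType]
    } else {
        keep <- out$fdr < fdr &
            out$log2fc > log2fcMin &
            meanMat[idx] == apply(meanMat, 1L, max)
    }
    out <- out[keep & !is.na(keep), , drop = FALSE]
    if (mode == "rank-cap") {
        out <- do.call(rbind, lapply(split(out, out$cellType), function(d) {
            d[order(-d$log2fc), , drop = FALSE][seq_len(min(topN, nrow(d))), ,
                                                drop = FALSE]
        }))
    }
    missing <- setdiff(types, out$cellType)
    if (length(missing))
        warning("no markers found for cell type(s): ",
                paste(missing, collapse = ", "))
    rownames(out) <- NULL
    out[order(out$cellType, out$p, out$gene), , drop = FALSE]
}

#' Build an expression reference matrix from selected markers
#'
#' @param expr genes x cells log-scale matrix.
#' @param labels cell-type labels per column.
#' @param markers marker data.frame from [selectMarkers()] (or any data.frame
#'   with `gene` and `cellType` columns).
#' @param statistic per-cluster summary, "median" (default) or "mean".
#' @return an [ExpressionReference-class].
#' @export
buildReference <- function(expr, labels, markers,
                           statistic = c("median", "mean")) {
    statistic <- match.arg(statistic)
    expr <- as.matrix(expr)
    absent <- setdiff(markers$gene, rownames(expr))
    if (length(absent))
        stop("marker gene(s) absent from expression matrix: ",
             paste(utils::head(absent, 5), collapse = ", "))
    sub <- expr[markers$gene, , drop = FALSE]
    fun <- if (statistic == "median") stats::median else mean
    vals <- .groupStat(sub, as.character(labels), fun)
    ExpressionReference(vals, statistic = statistic,
                        markerMap = stats::setNames(markers$cellType,
                                                    markers$gene))
}

#' Build a reference from purified bulk expression profiles
#'
#' One-vs-rest Wilcoxon differential expression on purified bulk samples,
#' keeping genes with BH FDR below `fdr`, pooled log2 fold change above
#' `minLog2fc`, and a gap of at least `secondGap` between the own-type mean
#' and the second-highest cell-type mean. Reference values are per-cell-type
#' means of the log-scale expression.
#'
#' @param expr genes x samples log-scale matrix of purified bulk profiles.
#' @param labels cell-type label per sample (>= 2 samples per type).
#' @param fdr BH FDR threshold.
#' @param minLog2fc minimum pooled log2 fold change.
#' @param secondGap minimum gap to the second-highest expressing cell type.
#' @return an [ExpressionReference-class] (statistic "mean").
#' @export
buildBulkReference <- function(expr, labels, fdr = 0.05, minLog2fc = 2.0,
                               secondGap = 0.2) {
    expr <- as.matrix(expr)
    labels <- as.character(labels)
    types <- sort(unique(labels))
    if (any(table(labels) < 2L)) stop("every cell type needs >= 2 samples")
    meanMat <- .groupStat(expr, labels, mean)
    pMat <- vapply(types, function(k) .rowWilcoxon(expr, labels == k),
                   numeric(nrow(expr)))
    fdrMat <- apply(pMat, 2L, stats::p.adjust, method = "BH")
    fcMat <- vapply(types, function(k) {
        rowMeans(expr[, labels == k, drop = FALSE]) -
            rowMeans(expr[, labels != k, drop = FALSE])
    }, numeric(nrow(expr)))
    dimnames(pMat) <- dimnames(fdrMat) <- dimnames(fcMat) <-
        list(rownames(expr), types)
    ord <- t(apply(meanMat, 1L, sort, decreasing = TRUE))
    gap <- ord[, 1L] - ord[, 2L]
    bestIdx <- max.col(meanMat, ties.method = "first")
    idx <- cbind(seq_len(nrow(expr)), bestIdx)
    keep <- fdrMat[idx] < fdr & fcMat[idx] > minLog2fc & gap >= secondGap
    keep[is.na(keep)] <- FALSE
    markers <- data.frame(gene = rownames(expr)[keep],
                          cellType = types[bestIdx][keep],
                          p = pMat[idx][keep], fdr = fdrMat[idx][keep],
                          mss = NA_integer_, log2fc = fcMat[idx][keep],
                          stringsAsFactors = FALSE)
    missing <- setdiff(types, markers$cellType)
    if (length(missing))
        warning("no genes survive filters for cell type(s): ",
                paste(missing, collapse = ", "))
    ExpressionReference(meanMat[markers$gene, , drop = FALSE],
                        statistic = "mean",
                        markerMap = stats::setNames(markers$cellType,
                                                    markers$gene))
}

#' Annotate pre-computed single-cell clusters against a bulk reference
#'
#' Each cell is classified by its maximum estimated fraction (robust
#' regression against the bulk reference). Clusters where more than
#' `dominance` of cells share one predicted type are annotated to that
#' dominant type; clusters without a dominant type are dropped, cells
#' disagreeing with their cluster's dominant type are dropped, and clusters
#' with the same dominant type are merged.
#'
#' @param scExpr genes x cells log-scale matrix.
#' @param clusterLabels cluster id per cell (clustering is upstream input).
#' @param bulkRef an [ExpressionReference-class] built from purified bulk
#'   profiles.
#' @param dominance dominant-type fraction threshold (default 0.8).
#' @return list with `labels` (data.frame `cell, cellType` for retained
#'   cells) and `report` (per-cluster data.frame).
#' @export
annotateClusters <- function(scExpr, clusterLabels, bulkRef, dominance = 0.8) {
    scExpr <- as.matrix(scExpr)
    refv <- refValues(bulkRef)
    shared <- intersect(rownames(refv), rownames(scExpr))
    if (length(shared) < 0.5 * nrow(refv))
        stop("insufficient overlap: only ", length(shared), " of ",
             nrow(refv), " reference genes present in the expression matrix")
    M <- refv[shared, , drop = FALSE]
    fr <- estimateFractions(scExpr[shared, , drop = FALSE],
                            ExpressionReference(M), weights = "uniform")
    pred <- classifyCells(fr, warnTies = FALSE)
    cl <- as.character(clusterLabels)
    report <- do.call(rbind, lapply(split(seq_along(cl), cl), function(ii) {
        tab <- table(pred[ii])
        domFrac <- max(tab) / length(ii)
        data.frame(cluster = cl[ii[1L]], nCells = length(ii),
                   dominantType = names(tab)[which.max(tab)],
                   dominantFraction = domFrac,
                   retained = domFrac > dominance,
                   stringsAsFactors = FALSE)
    }))
    rownames(report) <- NULL
    keepClusters <- report$cluster[report$retained]
    dom <- stats::setNames(report$dominantType, report$cluster)
    cellKeep <- cl %in% keepClusters & pred == dom[cl]
    cells <- colnames(scExpr)
    if (is.null(cells)) cells <- as.character(seq_along(cl))
    list(labels = data.frame(cell = cells[cellKeep],
                             cellType = unname(dom[cl[cellKeep]]),
                             stringsAsFactors = FALSE),
         report = report)
}
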