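#' Read an expression (or generic feature x sample) matrix
#'
#' Reads either a dense TSV (first column = feature ids, header = sample ids)
#' or a MatrixMarket triplet file accompanied by row/column name files
#' (`<path>.rownames` / `<path>.colnames`, one id per line). Zero entries
#' omitted from the triplet file are filled in. Duplicate feature ids are
#' resolved deterministically by keeping the row with the greatest variance
#' (message emitted).
#'
#' @param path file path.
#' @param format "tsv" or "mtx".
#' @param rowNames,colNames optional name-file paths for `format = "mtx"`
#'   (default `<path>.rownames` / `<path>.colnames`).
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
readExpression <- function(path, format = c("tsv", "mtx"),
                           rowNames = NULL, colNames = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "tsv") {
        dt <- data.table::fread(path, sep = "\t", header = TRUE,
                                data.table = FALSE)
        if (ncol(dt) < 2L)
            stop("malformed header in ", path,
                 ": expected id column plus >= 1 sample column (line 1)")
        ids <- as.character(dt[[1L]])
        m <- as.matrix(dt[, -1L, drop = FALSE])
        if (!is.numeric(m))
            stop("non-numeric values in ", path)
        rownames(m) <- ids
    } else {
        if (is.null(rowNames)) rowNames <- paste0(path, ".rownames")
        if (is.null(colNames)) colNames <- paste0(path, ".colnames")
        if (!file.exists(rowNames) || !file.exists(colNames))
            stop("triplet matrix requires name files: ", rowNames, ", ", colNames)
        sp <- Matrix::readMM(path)
        rn <- readLines(rowNames)
        cn <- readLines(colNames)
        if (length(rn) != nrow(sp) || length(cn) != ncol(sp))
            stop("dimension mismatch between triplet file (", nrow(sp), "x",
                 ncol(sp), ") and name files (", length(rn), "/", length(cn), ")")
        m <- as.matrix(sp)
        dimnames(m) <- list(rn, cn)
    }
    if (any(!is.finite(m))) stop("non-finite values in ", path)
    .collapseDuplicates(m)
}

# keep the max-variance row among duplicated ids (deterministic; first wins
# on exact variance ties)
.collapseDuplicates <- function(m) {
    if (!anyDuplicated(rownames(m))) return(m)
    v <- apply(m, 1L, stats::var)
    ord <- order(rownames(m), -v)
    m2 <- m[ord, , drop = FALSE]
    keep <- !duplicated(rownames(m2))
    message("collapsed ", sum(!keep), " duplicated feature id(s), ",
            "keeping max-variance rows")
    m2 <- m2[keep, , drop = FALSE]
    m2[match(unique(rownames(m)), rownames(m2)), , drop = FALSE]
}

#' Read a bulk methylation beta matrix
#'
#' TSV with CpG/gene ids in the first column; values must be in [0,1] or NA.
#'
#' @inheritParams readExpression
#' @param allowMissing logical; keep NA betas (impute explicitly with
#'   [imputeMissingBeta()] if desired).
#' @return numeric matrix of beta values.
#' @export
readMethylation <- function(path, allowMissing = TRUE) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    if (ncol(dt) < 2L) stop("malformed header in ", path)
    m <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(m) <- as.character(dt[[1L]])
    if (!allowMissing && anyNA(m)) stop("missing beta values in ", path)
    rng <- range(m, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
        stop("beta values outside [0,1] in ", path)
    .collapseDuplicates(m)
}

#' Read gene and CpG annotation
#'
#' The gene table is a TSV with columns `gene_id, chrom, tss, strand,
#' exon1_start, exon1_end` (1-based inclusive coordinates, strand + or -).
#' CpG positions come from a BED file (0-based half-open); they are converted
#' to the package's 1-based convention (`position = start + 1`).
#'
#' @param genePath gene table TSV path.
#' @param cpgPath CpG BED path (chrom, start, end, cpg_id).
#' @return list with `genes` (data.frame) and `cpgs` (data.frame with
#'   `cpg_id, chrom, position`).
#' @export
readAnnotation <- function(genePath, cpgPath) {
    genes <- data.table::fread(genePath, sep = "\t", header = TRUE,
                               data.table = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand", "exon1_start", "exon1_end")
    if (!all(need %in% colnames(genes)))
        stop("gene annotation must have columns: ", paste(need, collapse = ", "))
    if (!all(genes$strand %in% c("+", "-")))
        stop("unknown strand symbol(s): ",
             paste(setdiff(unique(genes$strand), c("+", "-")), collapse = ", "))
    for (cc in c("tss", "exon1_start", "exon1_end"))
        if (any(genes[[cc]] != round(genes[[cc]])))
            stop("non-integer coordinate in column ", cc)
    if (any(genes$exon1_end < genes$exon1_start))
        stop("empty first-exon interval(s)")
    bed <- data.table::fread(cpgPath, header = FALSE, data.table = FALSE)
    if (ncol(bed) < 4L) stop("BED file must have chrom,start,end,name")
    colnames(bed)[1:4] <- c("chrom", "start", "end", "cpg_id")
    if (any(bed$start != round(bed$start)) || any(bed$end != round(bed$end)))
        stop("non-integer BED coordinate")
    if (any(bed$start >= bed$end))
        stop("malformed BED interval with start >= end")
    if (anyDuplicated(bed$cpg_id)) stop("duplicated cpg ids in BED")
    cpgs <- data.frame(cpg_id = as.character(bed$cpg_id),
                       chrom = as.character(bed$chrom),
                       position = as.integer(bed$start + 1L),
                       stringsAsFactors = FALSE)
    list(genes = genes, cpgs = cpgs)
}

#' Write / read a reference matrix as TSV
#'
#' One row per feature, one column per cell type; a methylation reference
#' gains a final `weight` column. Values are written at 10 significant
#' digits so the round trip reproduces them in decimal text.
#'
#' @param ref an [ExpressionReference-class] or [MethylationReference-class].
#' @param path output path.
#' @return `writeReference` returns `path` invisibly; `readReference` the
#'   reconstructed object.
#' @export
writeReference <- function(ref, path) {
    v <- refValues(ref)
    if (nrow(v) == 0L) stop("refusing to write an empty reference")
    df <- data.frame(feature = rownames(v),
                     signif(v, 10), check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (is(ref, "MethylationReference"))
        df$weight <- signif(unname(refWeights(ref)), 10)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' @rdname writeReference
#' @param level feature level for a methylation reference read-back.
#' @export
readReference <- function(path, level = "gene-promoter") {
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    hasW <- "weight" %in% colnames(df)
    ids <- as.character(df[[1L]])
    keep <- setdiff(colnames(df)[-1L], "weight")
    v <- as.matrix(df[, keep, drop = FALSE])
    rownames(v) <- ids
    if (hasW)
        MethylationReference(v, weights = df$weight, level = level)
    else
        ExpressionReference(v)
}

#' Nearest-neighbour imputation of missing beta values
#'
#' Explicit, user-invoked utility: each missing entry is replaced by the mean
#' beta of the `k` samples most correlated with the affected sample
#' (complete-pair Pearson across CpGs). Missing values are never imputed
#' silently by any reader.
#'
#' @param meth CpG x sample beta matrix, NAs allowed.
#' @param k number of neighbouring samples (default 5).
#' @return matrix without NAs.
#' @export
imputeMissingBeta <- function(meth, k = 5L) {
    if (!anyNA(meth)) return(meth)
    cc <- suppressWarnings(stats::cor(meth, use = "pairwise.complete.obs"))
    diag(cc) <- -Inf
    cc[is.na(cc)] <- -Inf
    for (j in seq_len(ncol(meth))) {
        miss <- which(is.na(meth[, j]))
        if (!length(miss)) next
        nb <- order(cc[, j], decreasing = TRUE)[seq_len(min(k, ncol(meth) - 1L))]
        fill <- rowMeans(meth[miss, nb, drop = FALSE], na.rm = TRUE)
        # fall back to the CpG's overall mean when all neighbours are missing
        bad <- !is.finite(fill)
        if (any(bad))
            fill[bad] <- rowMeans(meth[miss[bad], , drop = FALSE], na.rm = TRUE)
        meth[miss, j] <- fill
    }
    meth
}
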