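#' Constructors for reference objects
#'
#' @param values numeric matrix with feature rownames and cell-type colnames.
#' @param statistic summary statistic used per cluster ("median" or "mean").
#' @param markerMap named character vector, marker gene -> cell type.
#'
#' @return An [ExpressionReference-class] object.
#' @export
ExpressionReference <- function(values, statistic = "median",
                                markerMap = character()) {
    new("ExpressionReference", values = as.matrix(values),
        statistic = statistic, markerMap = markerMap)
}

#' @rdname ExpressionReference
#' @param weights per-feature quality weights in [0,1].
#' @param provenance free-text provenance tag.
#' @param level "gene-promoter" or "cpg".
#' @return For `MethylationReference`, a [MethylationReference-class] object.
#' @export
MethylationReference <- function(values, weights = rep(1, nrow(values)),
                                 provenance = "unspecified",
                                 level = "gene-promoter") {
    new("MethylationReference", values = as.matrix(values),
        weights = as.numeric(weights), provenance = provenance, level = level)
}

#' Accessors for reference, fraction and DMCT objects
#'
#' `refValues` returns the core feature x cell-type matrix, `cellTypes` the
#' cell-type (column) names, `refWeights` the per-feature quality weights of
#' a methylation reference, and `markerMap` the marker -> cell-type map of an
#' expression reference.
#'
#' @param object a reference object.
#' @return matrix / character / numeric as described.
#' @name refValues
NULL

#' @rdname refValues
#' @export
setMethod("refValues", "ExpressionReference", function(object) object@values)
#' @rdname refValues
#' @export
setMethod("refValues", "MethylationReference", function(object) object@values)
#' @rdname refValues
#' @export
setMethod("cellTypes", "ExpressionReference",
    function(object) colnames(object@values))
#' @rdname refValues
#' @export
setMethod("cellTypes", "MethylationReference",
    function(object) colnames(object@values))
#' @rdname refValues
#' @export
setMethod("refWeights", "MethylationReference", function(object) {
    w <- object@weights
    names(w) <- rownames(object@values)
    w
})
#' @rdname refValues
#' @export
setMethod("markerMap", "ExpressionReference", function(object) object@markerMap)

#' Fraction estimate accessors
#'
#' `fractions` returns the constrained samples x cell-types proportion matrix
#' (rows on the simplex); `rawCoefficients` the unconstrained robust
#' regression coefficients.
#'
#' @param object a [FractionEstimate-class].
#' @return numeric matrix.
#' @name fractions
NULL

#' @rdname fractions
#' @export
setMethod("fractions", "FractionEstimate", function(object) object@fractions)
#' @rdname fractions
#' @export
setMethod("rawCoefficients", "FractionEstimate", function(object) object@raw)

#' DMCT result accessors
#'
#' `dmctTable` flattens a [DMCTResult-class] into a long data.frame with one
#' row per CpG x cell type; `dmctCalls` returns the CpG x cell-type matrix of
#' -1/0/+1 calls.
#'
#' @param object a [DMCTResult-class].
#' @param significantOnly logical; keep only rows with a non-zero call.
#' @param ... unused.
#' @return data.frame / integer matrix.
#' @name dmctTable
NULL

#' @rdname dmctTable
#' @export
setMethod("dmctTable", "DMCTResult", function(object, significantOnly = FALSE, ...) {
    ct <- colnames(object@coef)
    out <- data.frame(
        cpg = rep(rownames(object@coef), times = length(ct)),
        cellType = rep(ct, each = nrow(object@coef)),
        mu = as.vector(object@mu),
        estimate = as.vector(object@coef),
        t = as.vector(object@tstat),
        p = as.vector(object@pval),
        fdr = as.vector(object@fdr),
        call = as.vector(object@call),
        stringsAsFactors = FALSE)
    if (significantOnly) out <- out[!is.na(out$call) & out$call != 0L, ]
    rownames(out) <- NULL
    out
})

#' @rdname dmctTable
#' @export
setMethod("dmctCalls", "DMCTResult", function(object) object@call)

setMethod("show", "ExpressionReference", function(object) {
    v <- object@values
    cat("ExpressionReference:", nrow(v), "marker genes x", ncol(v),
        "cell types (", object@statistic, ")\n")
    cat("  cell types:", paste(colnames(v), collapse = ", "), "\n")
    if (length(object@markerMap))
        cat("  markers per type:",
            paste(sprintf("%s=%d", names(table(object@markerMap)),
                          table(object@markerMap)), collapse = ", "), "\n")
})

setMethod("show", "MethylationReference", function(object) {
    v <- object@values
    cat("MethylationReference (", object@level, ", ", object@provenance,
        "): ", nrow(v), " features x ", ncol(v), " cell types\n", sep = "")
    cat("  cell types:", paste(colnames(v), collapse = ", "), "\n")
    cat(sprintf("  weights: median %.2f, %d features with weight > 0.5\n",
                stats::median(object@weights), sum(object@weights > 0.5)))
})

setMethod("show", "GammaMixtureModel", function(object) {
    cat("GammaMixtureModel (2 states)\n")
    m <- object@shape * object@scale
    cat(sprintf("  unexpressed: shape %.3f scale %.3f mean %.3f pi %.3f\n",
                object@shape[1], object@scale[1], m[1], object@pi[1]))
    cat(sprintf("  expressed:   shape %.3f scale %.3f mean %.3f pi %.3f\n",
                object@shape[2], object@scale[2], m[2], object@pi[2]))
    cat(sprintf("  EM: %d iterations, logLik %.2f, converged: %s\n",
                length(object@logLik), utils::tail(object@logLik, 1),
                object@converged))
})

setMethod("show", "FractionEstimate", function(object) {
    f <- object@fractions
    cat("FractionEstimate:", nrow(f), "samples x", ncol(f), "cell types\n")
    cat("  mean fractions:",
        paste(sprintf("%s=%.3f", colnames(f), colMeans(f)), collapse = ", "),
        "\n")
})

setMethod("show", "DMCTResult", function(object) {
    n <- colSums(object@call != 0L, na.rm = TRUE)
    cat("DMCTResult:", nrow(object@coef), "CpGs x", ncol(object@coef),
        "cell types (FDR <", object@fdrThreshold, ")\n")
    cat("  DMCT calls:",
        paste(sprintf("%s=%d", colnames(object@coef), n), collapse = ", "),
        "\n")
})
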