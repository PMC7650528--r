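#' @import methods
NULL

#' Expression reference matrix
#'
#' Marker genes x cell types matrix of representative (median or mean)
#' log-scale expression values, together with the marker-to-cell-type
#' assignment produced during marker selection.
#'
#' @slot values numeric matrix, marker genes (rows) x cell types (columns),
#'   log2 scale, non-negative.
#' @slot statistic character, the per-cluster summary used ("median" or
#'   "mean").
#' @slot markerMap named character vector mapping each marker gene to the
#'   cell type it defines.
#'
#' @export
setClass("ExpressionReference",
    representation(values = "matrix", statistic = "character",
                   markerMap = "character"))

setValidity("ExpressionReference", function(object) {
    v <- object@values
    msg <- NULL
    if (nrow(v) > 0 && (is.null(rownames(v)) || is.null(colnames(v))))
        msg <- c(msg, "values must have gene rownames and cell-type colnames")
    else if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicated marker gene ids")
    if (any(!is.finite(v)))
        msg <- c(msg, "non-finite expression values")
    else if (any(v < 0))
        msg <- c(msg, "log-scale reference values must be >= 0")
    if (!object@statistic %in% c("median", "mean"))
        msg <- c(msg, "statistic must be 'median' or 'mean'")
    if (length(object@markerMap) &&
        !all(names(object@markerMap) %in% rownames(v)))
        msg <- c(msg, "markerMap names must be reference rows")
    if (is.null(msg)) TRUE else msg
})

#' DNA methylation reference matrix
#'
#' Features (gene promoters or CpGs) x cell types matrix of imputed beta
#' values, with a per-feature quality weight in [0,1]. Features with weight
#' zero are excluded from deconvolution.
#'
#' @slot values numeric matrix of beta values in [0,1], features x cell types.
#' @slot weights numeric vector in [0,1], one quality weight per feature.
#' @slot provenance character, which matched compendium the imputation model
#'   was trained on (free text; "merged" after [mergeReferences()]).
#' @slot level character, feature level: "gene-promoter" or "cpg".
#'
#' @export
setClass("MethylationReference",
    representation(values = "matrix", weights = "numeric",
                   provenance = "character", level = "character"))

setValidity("MethylationReference", function(object) {
    v <- object@values
    msg <- NULL
    if (nrow(v) > 0 && (is.null(rownames(v)) || is.null(colnames(v))))
        msg <- c(msg, "values must have feature rownames and cell-type colnames")
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
        msg <- c(msg, "beta values must be finite and in [0,1]")
    if (length(object@weights) != nrow(v))
        msg <- c(msg, "one weight per feature required")
    else if (any(!is.finite(object@weights)) || any(object@weights < 0) ||
             any(object@weights > 1))
        msg <- c(msg, "weights must be finite and in [0,1]")
    if (!object@level %in% c("gene-promoter", "cpg"))
        msg <- c(msg, "level must be 'gene-promoter' or 'cpg'")
    if (is.null(msg)) TRUE else msg
})

#' Two-state gamma mixture model of expression values
#'
#' Parameters of the mixture of two gamma distributions fitted to all
#' (positive) expression values of a matched compendium, representing the
#' unexpressed and expressed states. Components are ordered so that the
#' unexpressed state has the smaller mean.
#'
#' @slot shape numeric(2), gamma shape for (unexpressed, expressed).
#' @slot scale numeric(2), gamma scale for (unexpressed, expressed).
#' @slot pi numeric(2), mixing weights, sum to 1.
#' @slot logLik numeric, the log-likelihood trace over EM iterations
#'   (non-decreasing).
#' @slot converged logical.
#'
#' @export
setClass("GammaMixtureModel",
    representation(shape = "numeric", scale = "numeric", pi = "numeric",
                   logLik = "numeric", converged = "logical"))

setValidity("GammaMixtureModel", function(object) {
    msg <- NULL
    if (length(object@shape) != 2L || any(object@shape <= 0))
        msg <- c(msg, "two positive shape parameters required")
    if (length(object@scale) != 2L || any(object@scale <= 0))
        msg <- c(msg, "two positive scale parameters required")
    if (length(object@pi) != 2L || any(object@pi <= 0) ||
        abs(sum(object@pi) - 1) > 1e-8)
        msg <- c(msg, "mixing weights must be in (0,1) and sum to 1")
    if (length(object@logLik) > 1L &&
        any(diff(object@logLik) < -1e-6 * abs(object@logLik[-1])))
        msg <- c(msg, "log-likelihood trace must be non-decreasing")
    if (is.null(msg)) TRUE else msg
})

#' Per-sample cell-type fraction estimates
#'
#' Constrained (non-negative, sum-to-one) cell-type proportions per sample,
#' together with the raw unconstrained robust-regression coefficients.
#'
#' @slot fractions numeric matrix, samples x cell types, rows on the simplex.
#' @slot raw numeric matrix, samples x cell types, unconstrained coefficients.
#' @slot converged logical vector per sample.
#'
#' @export
setClass("FractionEstimate",
    representation(fractions = "matrix", raw = "matrix",
                   converged = "logical"))

setValidity("FractionEstimate", function(object) {
    f <- object@fractions
    msg <- NULL
    if (!identical(dim(f), dim(object@raw)))
        msg <- c(msg, "fractions and raw coefficients must share dimensions")
    if (any(f < -1e-12))
        msg <- c(msg, "fractions must be non-negative")
    if (nrow(f) && any(abs(rowSums(f) - 1) > 1e-6))
        msg <- c(msg, "fractions must sum to 1 per sample")
    if (length(object@converged) != nrow(f))
        msg <- c(msg, "one convergence flag per sample required")
    if (is.null(msg)) TRUE else msg
})

#' Differentially methylated cell type (DMCT) results
#'
#' Per-CpG x cell-type estimates from the fraction-by-phenotype interaction
#' model: baseline methylation per cell type, interaction effect, t statistic,
#' p value, within-cell-type BH FDR, and a -1/0/+1 call.
#'
#' @slot mu numeric matrix, CpGs x cell types, baseline methylation estimates.
#' @slot coef numeric matrix, interaction (phenotype effect) estimates.
#' @slot tstat,pval,fdr numeric matrices, CpGs x cell types.
#' @slot call integer matrix in {-1, 0, 1}; non-zero iff fdr below the
#'   threshold used at fitting, sign following the interaction estimate.
#' @slot fdrThreshold numeric, threshold used for the calls.
#' @slot testable logical vector per cell type; FALSE when the design was
#'   rank-deficient for that cell type.
#'
#' @export
setClass("DMCTResult",
    representation(mu = "matrix", coef = "matrix", tstat = "matrix",
                   pval = "matrix", fdr = "matrix", call = "matrix",
                   fdrThreshold = "numeric", testable = "logical"))

setValidity("DMCTResult", function(object) {
    msg <- NULL
    dims <- list(object@mu, object@coef, object@tstat, object@pval,
                 object@fdr, object@call)
    if (length(unique(vapply(dims, function(m) paste(dim(m), collapse = "x"),
                             ""))) != 1L)
        msg <- c(msg, "all result matrices must share dimensions")
    ok <- object@call[!is.na(object@call)]
    if (!all(ok %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "calls must be -1, 0 or +1")
    if (length(object@testable) != ncol(object@coef))
        msg <- c(msg, "one testable flag per cell type required")
    if (is.null(msg)) TRUE else msg
})
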