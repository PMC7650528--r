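#' Detect cell-type-specific differential methylation (DMCTs)
#'
#' Fits, separately for each CpG c, the interaction model
#' `y_c = sum_k mu_ck f_k + sum_k beta_ck f_k * z + (covariates) + e`
#' by least squares, where f_k are the estimated cell-type fractions and z
#' the phenotype. Because the fractions lie on the simplex they span the
#' intercept, so no separate intercept is included (one is added with a
#' warning if non-simplex fractions are supplied). t statistics and p values
#' for the interaction terms use the homoscedastic per-CpG residual
#' variance; p values are BH-adjusted within each cell type, and a CpG is
#' called a DMCT in cell type k (call -1/+1 by the sign of the interaction
#' estimate) when its FDR is below `fdr`.
#'
#' A cell type whose fraction is (near) constant zero across samples makes
#' the design rank-deficient; its columns are dropped and it is reported as
#' not testable.
#'
#' @param meth CpG x sample beta matrix.
#' @param frac a [FractionEstimate-class] or samples x cell-types fraction
#'   matrix.
#' @param pheno numeric phenotype per sample (binary encoded 0/1 or
#'   continuous), aligned with the columns of `meth`.
#' @param covars optional samples x covariates numeric matrix (main effects
#'   only).
#' @param fdr BH FDR threshold for DMCT calls (default 0.05).
#' @return a [DMCTResult-class].
#' @export
fitCellDMC <- function(meth, frac, pheno, covars = NULL, fdr = 0.05) {
    F <- if (is(frac, "FractionEstimate")) fractions(frac) else as.matrix(frac)
    meth <- as.matrix(meth)
    n <- ncol(meth)
    stopifnot(nrow(F) == n, length(pheno) == n)
    if (anyNA(pheno) || anyNA(F)) stop("missing values in phenotype/fractions")
    if (stats::sd(pheno) == 0) stop("phenotype is constant")
    K <- ncol(F)
    ctypes <- colnames(F)
    if (is.null(ctypes)) ctypes <- paste0("CT", seq_len(K))
    nCov <- if (is.null(covars)) 0L else ncol(covars)
    if (n < 2 * K + nCov + 2L)
        stop("need at least ", 2 * K + nCov + 2L, " samples")
    X <- cbind(F, F * pheno)
    colnames(X) <- c(ctypes, paste0(ctypes, ":z"))
    simplex <- all(abs(rowSums(F) - 1) < 1e-6) && all(F >= -1e-12)
    if (!simplex) {
        warning("fractions are not on the simplex; adding an intercept")
        X <- cbind(`(Intercept)` = 1, X)
    }
    if (!is.null(covars)) {
        covars <- as.matrix(covars)
        colnames(covars) <- paste0("cov", seq_len(ncol(covars)))
        X <- cbind(X, covars)
    }
    # drop columns that make the design rank-deficient; a cell type is
    # testable only if both its main and interaction columns survive
    qrX <- qr(X)
    keepCols <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X)), keepCols)
    testable <- stats::setNames(rep(TRUE, K), ctypes)
    if (length(dropped)) {
        badNames <- colnames(X)[dropped]
        badCT <- unique(sub(":z$", "", badNames))
        testable[ctypes %in% badCT] <- FALSE
        if (!any(testable))
            warning("design rank-deficient for every cell type; ",
                    "no testable interactions")
        else
            warning("cell type(s) not testable (rank-deficient design): ",
                    paste(intersect(badCT, ctypes), collapse = ", "))
        X <- X[, keepCols, drop = FALSE]
    }
    p <- ncol(X)
    df <- n - p
    if (df < 1L) stop("no residual degrees of freedom")
    fit <- stats::lm.fit(X, t(meth))
    B <- as.matrix(fit$coefficients)           # p x nCpG
    res <- as.matrix(fit$residuals)            # n x nCpG
    sigma2 <- colSums(res^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    se2diag <- diag(XtXinv)
    mkMat <- function(cols) {
        out <- matrix(NA_real_, nrow(meth), K,
                      dimnames = list(rownames(meth), ctypes))
        present <- intersect(cols, rownames(B))
        for (nm in present) {
            ct <- sub(":z$", "", nm)
            out[, ct] <- B[nm, ]
        }
        out
    }
    mu <- mkMat(ctypes)
    coefI <- mkMat(paste0(ctypes, ":z"))
    tstat <- matrix(NA_real_, nrow(meth), K,
                    dimnames = list(rownames(meth), ctypes))
    for (k in seq_len(K)) {
        nm <- paste0(ctypes[k], ":z")
        if (!testable[k] || !(nm %in% rownames(B))) next
        j <- match(nm, colnames(X))
        tstat[, k] <- coefI[, k] / sqrt(sigma2 * se2diag[j])
    }
    pval <- 2 * stats::pt(-abs(tstat), df = df)
    fdrMat <- apply(pval, 2L, function(pp) {
        out <- rep(NA_real_, length(pp))
        ok <- !is.na(pp)
        out[ok] <- stats::p.adjust(pp[ok], method = "BH")
        out
    })
    if (!is.matrix(fdrMat)) fdrMat <- matrix(fdrMat, nrow = 1L)
    dimnames(fdrMat) <- dimnames(pval)
    call <- matrix(0L, nrow(meth), K, dimnames = dimnames(pval))
    sigIdx <- which(fdrMat < fdr & !is.na(fdrMat))
    call[sigIdx] <- as.integer(sign(coefI[sigIdx]))
    call[is.na(fdrMat)] <- NA_integer_
    new("DMCTResult", mu = mu, coef = coefI, tstat = tstat, pval = pval,
        fdr = fdrMat, call = call, fdrThreshold = fdr,
        testable = unname(testable))
}

#' Per-cell-type DMCT lists and pairwise overlap significance
#'
#' @param result a [DMCTResult-class].
#' @param fdr call threshold; defaults to the threshold used at fitting.
#' @return list with `hyper` / `hypo` (per-cell-type CpG id lists) and
#'   `overlap` (pairwise data.frame with overlap counts and one-tailed
#'   hypergeometric p values over the tested CpG universe).
#' @export
callDMCTs <- function(result, fdr = NULL) {
    if (is.null(fdr)) fdr <- result@fdrThreshold
    sig <- result@fdr < fdr & !is.na(result@fdr)
    calls <- sign(result@coef) * sig
    ctypes <- colnames(result@coef)
    cpgIds <- rownames(result@coef)
    hyper <- lapply(ctypes, function(k) cpgIds[which(calls[, k] > 0)])
    hypo <- lapply(ctypes, function(k) cpgIds[which(calls[, k] < 0)])
    names(hyper) <- names(hypo) <- ctypes
    universe <- nrow(result@coef)
    combos <- utils::combn(ctypes, 2L)
    overlap <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
        a <- c(hyper[[combos[1, i]]], hypo[[combos[1, i]]])
        b <- c(hyper[[combos[2, i]]], hypo[[combos[2, i]]])
        ov <- length(intersect(a, b))
        p <- if (length(a) && length(b))
            stats::phyper(ov - 1L, length(b), universe - length(b),
                          length(a), lower.tail = FALSE) else 1
        data.frame(cellTypeA = combos[1, i], cellTypeB = combos[2, i],
                   nA = length(a), nB = length(b), nOverlap = ov,
                   hypergeomP = p, stringsAsFactors = FALSE)
    }))
    list(hyper = hyper, hypo = hypo, overlap = overlap)
}

#' Adjust methylation values for cell-type composition
#'
#' Residuals of a CpG's beta values regressed on the cell-type fractions
#' alone (no intercept; the simplex spans it), re-centred at the CpG's mean
#' for plotting against the fraction of the cell type of interest.
#'
#' @param methRow numeric vector of beta values across samples.
#' @param frac a [FractionEstimate-class] or samples x cell-types matrix.
#' @return numeric vector of adjusted values.
#' @export
adjustBeta <- function(methRow, frac) {
    F <- if (is(frac, "FractionEstimate")) fractions(frac) else as.matrix(frac)
    stopifnot(length(methRow) == nrow(F))
    fit <- stats::lm.fit(F, methRow)
    fit$residuals + mean(methRow)
}
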