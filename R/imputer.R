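# Weighted maximum-likelihood gamma fit: solves
#   log(a) - digamma(a) = log(weighted mean) - weighted mean log
# by Newton iteration from the standard closed-form starting value.
.wGammaMLE <- function(x, w) {
    W <- sum(w)
    mw <- sum(w * x) / W
    mlw <- sum(w * log(x)) / W
    cc <- log(mw) - mlw
    if (cc <= 1e-12) return(c(shape = 1e6, scale = mw / 1e6))  # ~degenerate
    a <- (3 - cc + sqrt((cc - 3)^2 + 24 * cc)) / (12 * cc)
    for (i in 1:50) {
        step <- (log(a) - digamma(a) - cc) / (1 / a - trigamma(a))
        aNew <- a - step
        if (aNew <= 0) aNew <- a / 2
        if (abs(aNew - a) < 1e-12 * a) { a <- aNew; break }
        a <- aNew
    }
    c(shape = a, scale = mw / a)
}

.gammaMixLogLik <- function(x, shape, scale, pi) {
    l1 <- stats::dgamma(x, shape = shape[1], scale = scale[1], log = TRUE) +
        log(pi[1])
    l2 <- stats::dgamma(x, shape = shape[2], scale = scale[2], log = TRUE) +
        log(pi[2])
    m <- pmax(l1, l2)
    ll <- m + log(exp(l1 - m) + exp(l2 - m))
    list(total = sum(ll), resp2 = exp(l2 - ll))
}

.emGammaMix <- function(x, shape, scale, pi, maxIter, tol) {
    trace <- numeric(0)
    llOld <- -Inf
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        e <- .gammaMixLogLik(x, shape, scale, pi)
        trace <- c(trace, e$total)
        if (is.finite(llOld) && abs(e$total - llOld) < tol * (1 + abs(e$total))) {
            converged <- TRUE
            break
        }
        llOld <- e$total
        r2 <- pmin(pmax(e$resp2, 1e-12), 1 - 1e-12)
        r1 <- 1 - r2
        f1 <- .wGammaMLE(x, r1); f2 <- .wGammaMLE(x, r2)
        shape <- c(f1["shape"], f2["shape"])
        scale <- c(f1["scale"], f2["scale"])
        pi <- c(mean(r1), mean(r2))
    }
    list(shape = unname(shape), scale = unname(scale), pi = unname(pi),
         trace = trace, converged = converged)
}

#' Fit a two-state gamma mixture to all expression values
#'
#' EM fit of a mixture of two gamma distributions to the strictly positive
#' expression values of a matched compendium, modelling the unexpressed and
#' expressed states. Gamma densities are undefined at zero, so zeros (which
#' on a log2(x+1) scale correspond to raw zeros) are excluded from fitting;
#' [posteriorExpressed()] classifies them as unexpressed by definition.
#' Initialisation: split at the overall median with method-of-moments per
#' half, plus `nRestarts` seeded random-quantile splits; the fit with the
#' best log-likelihood is kept. Components are returned ordered so the
#' unexpressed state has the smaller mean.
#'
#' @param expr numeric matrix or vector of expression values (>= 0).
#' @param maxIter,tol EM stopping rule (relative log-likelihood change).
#' @param nRestarts number of additional random initialisations (default 5).
#' @param seed integer seed for the random restarts (restores the caller's
#'   RNG state afterwards).
#' @return a [GammaMixtureModel-class].
#' @export
fitExpressionMixture <- function(expr, maxIter = 1000L, tol = 1e-8,
                                 nRestarts = 5L, seed = 1L) {
    x <- as.numeric(expr)
    if (any(x < 0)) stop("expression values must be non-negative")
    x <- x[x > 0]
    if (length(x) < 100L)
        stop("fewer than 100 positive values: mixture unidentifiable")
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(seed)
    momInit <- function(q) {
        cut <- stats::quantile(x, q)
        lo <- x[x <= cut]; hi <- x[x > cut]
        if (length(lo) < 10L || length(hi) < 10L) return(NULL)
        mom <- function(v) {
            m <- mean(v); vv <- stats::var(v)
            if (!is.finite(vv) || vv <= 0) vv <- m^2 / 4
            c(shape = m^2 / vv, scale = vv / m)
        }
        p1 <- mom(lo); p2 <- mom(hi)
        list(shape = c(p1["shape"], p2["shape"]),
             scale = c(p1["scale"], p2["scale"]),
             pi = c(length(lo), length(hi)) / length(x))
    }
    qs <- c(0.5, stats::runif(nRestarts, 0.2, 0.8))
    best <- NULL
    for (q in qs) {
        ini <- momInit(q)
        if (is.null(ini)) next
        fit <- .emGammaMix(x, ini$shape, ini$scale, ini$pi, maxIter, tol)
        if (is.null(best) ||
            utils::tail(fit$trace, 1) > utils::tail(best$trace, 1))
            best <- fit
    }
    if (is.null(best)) stop("EM initialisation failed")
    if (!best$converged)
        warning("EM reached maxIter without meeting the tolerance")
    ord <- order(best$shape * best$scale)  # unexpressed = smaller mean
    new("GammaMixtureModel", shape = best$shape[ord], scale = best$scale[ord],
        pi = best$pi[ord], logLik = cummax(best$trace),
        converged = best$converged)
}

#' Posterior probability that a gene is expressed
#'
#' Bayes posterior for the expressed state of the two-state gamma mixture,
#' `p(E=1|x) = pi_E g_E(x) / (pi_U g_U(x) + pi_E g_E(x))`, computed in log
#' space so it is finite for any positive x. Zero expression is classified
#' as unexpressed (posterior 0) by definition.
#'
#' @param model a [GammaMixtureModel-class].
#' @param x numeric vector of expression values (>= 0).
#' @return numeric vector of posteriors in [0,1].
#' @export
posteriorExpressed <- function(model, x) {
    stopifnot(is(model, "GammaMixtureModel"))
    if (any(x < 0)) stop("expression values must be non-negative")
    out <- numeric(length(x))
    pos <- x > 0
    if (any(pos)) {
        xp <- x[pos]
        lU <- stats::dgamma(xp, shape = model@shape[1],
                            scale = model@scale[1], log = TRUE) +
            log(model@pi[1])
        lE <- stats::dgamma(xp, shape = model@shape[2],
                            scale = model@scale[2], log = TRUE) +
            log(model@pi[2])
        out[pos] <- stats::plogis(lE - lU)
    }
    out
}

#' Impute the unexpressed-state promoter methylation of one gene
#'
#' Samples with posterior probability of expression strictly below
#' `pThreshold` are declared non-expressing, and the imputed value is the
#' median promoter beta over those samples. When no sample qualifies, a
#' logistic regression of beta on expression is fitted (quasi-binomial IRLS
#' on the continuous proportions) and extrapolated to zero expression; the
#' imputed value is clipped to [0,1]. A failed logistic fit marks the gene
#' non-imputable (`mode = "none"`, quality weight zero downstream).
#'
#' @param exprRow,pmethRow expression and promoter-beta values of the gene
#'   across the matched samples (aligned; >= 3 samples).
#' @param model a [GammaMixtureModel-class] fitted on the full matrix.
#' @param pThreshold posterior threshold (default 0.2; strict `<`).
#' @return list with `mode` ("median", "logistic" or "none"), `value`,
#'   `nNonExpressing`, and for logistic mode `intercept` and `slope`.
#' @export
imputeGene <- function(exprRow, pmethRow, model, pThreshold = 0.2) {
    ok <- is.finite(exprRow) & is.finite(pmethRow)
    exprRow <- exprRow[ok]; pmethRow <- pmethRow[ok]
    if (length(exprRow) < 3L) stop("need >= 3 shared samples")
    post <- posteriorExpressed(model, exprRow)
    non <- post < pThreshold
    if (any(non)) {
        return(list(mode = "median",
                    value = .clip01(stats::median(pmethRow[non])),
                    nNonExpressing = sum(non)))
    }
    fit <- tryCatch(
        suppressWarnings(stats::glm(y ~ x,
            family = stats::quasibinomial(),
            data = data.frame(y = .clip01(pmethRow, 1e-6), x = exprRow))),
        error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(stats::coef(fit)))
        return(list(mode = "none", value = NA_real_, nNonExpressing = 0L))
    co <- stats::coef(fit)
    list(mode = "logistic", value = .clip01(stats::plogis(co[[1]])),
         nNonExpressing = 0L, intercept = co[[1]], slope = co[[2]])
}

#' Impute the unexpressed-state methylation for a set of marker genes
#'
#' Convenience wrapper applying [imputeGene()] to every requested gene
#' present in both matched matrices.
#'
#' @param geneIds genes to impute (e.g. marker genes intersected with the
#'   core imputable set).
#' @param expr,pmeth matched gene x sample expression / promoter-beta
#'   matrices.
#' @param model a [GammaMixtureModel-class].
#' @param pThreshold posterior threshold, see [imputeGene()].
#' @return named list of per-gene imputation models.
#' @export
imputeMarkers <- function(geneIds, expr, pmeth, model, pThreshold = 0.2) {
    sharedS <- intersect(colnames(expr), colnames(pmeth))
    geneIds <- intersect(geneIds, intersect(rownames(expr), rownames(pmeth)))
    out <- lapply(geneIds, function(g)
        imputeGene(expr[g, sharedS], pmeth[g, sharedS], model,
                   pThreshold = pThreshold))
    names(out) <- geneIds
    out
}

#' Build a DNA methylation reference from an expression reference
#'
#' For each marker gene with a successful imputation model, the reference
#' entry is zero in cell types where the gene is expressed and the gene's
#' imputed unexpressed-state beta elsewhere. The quality weight w_g is the
#' mean imputed beta over the unexpressed cell types (near 1 = highly
#' informative marker). Genes expressed in every cell type are uninformative
#' and dropped; genes with weight below `wMin` are filtered out.
#'
#' @param exprRef an [ExpressionReference-class].
#' @param geneModels named list from [imputeMarkers()].
#' @param expressedRule "nonzero" (gene expressed in a cell type iff its
#'   reference value there is > 0; exact zero medians are guaranteed for
#'   maximally specific markers) or "posterior" (posterior of the reference
#'   value >= 0.5 under `model`).
#' @param model required for `expressedRule = "posterior"`.
#' @param wMin minimum quality weight retained (default 0.4).
#' @param provenance provenance tag for the result.
#' @return a [MethylationReference-class] at gene-promoter level.
#' @export
buildDnamReference <- function(exprRef, geneModels,
                               expressedRule = c("nonzero", "posterior"),
                               model = NULL, wMin = 0.4,
                               provenance = "unspecified") {
    expressedRule <- match.arg(expressedRule)
    ev <- refValues(exprRef)
    genes <- intersect(rownames(ev), names(geneModels))
    genes <- genes[vapply(genes, function(g) geneModels[[g]]$mode != "none",
                          logical(1L))]
    if (!length(genes)) stop("no imputable marker genes")
    if (expressedRule == "posterior" && is.null(model))
        stop("expressedRule='posterior' requires the mixture model")
    rows <- list(); wts <- numeric(0)
    dropped <- 0L
    for (g in genes) {
        iv <- geneModels[[g]]$value
        expressed <- if (expressedRule == "nonzero") ev[g, ] > 0
                     else posteriorExpressed(model, ev[g, ]) >= 0.5
        if (all(expressed)) { dropped <- dropped + 1L; next }
        row <- ifelse(expressed, 0, iv)
        w <- mean(row[!expressed])
        rows[[g]] <- row
        wts <- c(wts, w)
    }
    if (dropped)
        message(dropped, " marker(s) expressed in all cell types dropped")
    if (!length(rows)) stop("no informative marker genes")
    vals <- do.call(rbind, rows)
    colnames(vals) <- colnames(ev)
    keep <- wts >= wMin
    if (!any(keep))
        stop("no markers with quality weight >= ", wMin)
    MethylationReference(vals[keep, , drop = FALSE], weights = wts[keep],
                         provenance = provenance, level = "gene-promoter")
}

#' Merge two DNA methylation references
#'
#' References must share the same cell types (columns are order-normalised
#' by name). Genes present in both are averaged elementwise (values and
#' weights); genes exclusive to one reference are copied unchanged.
#'
#' @param refA,refB [MethylationReference-class] objects.
#' @return merged [MethylationReference-class] with provenance "merged".
#' @export
mergeReferences <- function(refA, refB) {
    a <- refValues(refA); b <- refValues(refB)
    if (!setequal(colnames(a), colnames(b)))
        stop("cell-type mismatch: ",
             paste(c(setdiff(colnames(a), colnames(b)),
                     setdiff(colnames(b), colnames(a))), collapse = ", "))
    if (refA@level != refB@level) stop("feature-level mismatch")
    b <- b[, colnames(a), drop = FALSE]
    wA <- refWeights(refA); wB <- refWeights(refB)
    shared <- intersect(rownames(a), rownames(b))
    onlyA <- setdiff(rownames(a), shared)
    onlyB <- setdiff(rownames(b), shared)
    vals <- rbind((a[shared, , drop = FALSE] + b[shared, , drop = FALSE]) / 2,
                  a[onlyA, , drop = FALSE], b[onlyB, , drop = FALSE])
    w <- c((wA[shared] + wB[shared]) / 2, wA[onlyA], wB[onlyB])
    MethylationReference(vals, weights = unname(w), provenance = "merged",
                         level = refA@level)
}

#' Fit per-CpG logistic models for enhancer-linked CpGs
#'
#' For every linked CpG-gene pair, the linked gene's expression is z-score
#' normalised across the matched samples and a logistic regression of the
#' CpG's beta on the z-scored expression is fitted (quasi-binomial IRLS).
#'
#' @param pairs data.frame from [linkEnhancerCpGs()].
#' @param expr,meth matched gene x sample expression and CpG x sample beta
#'   matrices.
#' @return data.frame `cpg, gene, intercept, slope` (non-converging fits are
#'   dropped with a message).
#' @export
fitEnhancerLogistic <- function(pairs, expr, meth) {
    sharedS <- intersect(colnames(expr), colnames(meth))
    if (length(sharedS) < 6L) stop("need >= 6 shared samples")
    fits <- lapply(seq_len(nrow(pairs)), function(i) {
        g <- pairs$gene[i]; c0 <- pairs$cpg[i]
        x <- expr[g, sharedS]
        if (stats::sd(x) == 0) return(NULL)
        z <- (x - mean(x)) / stats::sd(x)
        fit <- tryCatch(suppressWarnings(stats::glm(y ~ z,
            family = stats::quasibinomial(),
            data = data.frame(y = .clip01(meth[c0, sharedS], 1e-6), z = z))),
            error = function(e) NULL)
        if (is.null(fit) || !fit$converged) return(NULL)
        co <- stats::coef(fit)
        data.frame(cpg = c0, gene = g, intercept = co[[1]], slope = co[[2]],
                   stringsAsFactors = FALSE)
    })
    drop <- sum(vapply(fits, is.null, logical(1L)))
    if (drop) message(drop, " enhancer CpG fit(s) dropped")
    out <- do.call(rbind, fits)
    if (is.null(out)) stop("no enhancer logistic fit succeeded")
    rownames(out) <- NULL
    out
}

#' Impute a CpG-level methylation reference via enhancer logistic models
#'
#' Each gene's reference expression profile is z-score normalised across
#' cell types and fed through the linked CpG's logistic curve, giving an
#' imputed beta per CpG and cell type. Constant reference rows cannot be
#' z-scored and their CpGs are dropped with a warning. The quality weight of
#' a CpG is the mean imputed beta over cell types with below-average
#' expression of the linked gene (the analogue of the promoter-level
#' unexpressed-state weight).
#'
#' @param exprRef an [ExpressionReference-class].
#' @param enhModels data.frame from [fitEnhancerLogistic()].
#' @param provenance provenance tag.
#' @return a [MethylationReference-class] at CpG level.
#' @export
imputeEnhancer <- function(exprRef, enhModels, provenance = "unspecified") {
    ev <- refValues(exprRef)
    enhModels <- enhModels[enhModels$gene %in% rownames(ev), , drop = FALSE]
    if (!nrow(enhModels)) stop("no enhancer models match the reference genes")
    rows <- list(); wts <- numeric(0)
    for (i in seq_len(nrow(enhModels))) {
        g <- enhModels$gene[i]
        e <- ev[g, ]
        if (stats::sd(e) == 0) {
            warning("constant reference row for ", g, "; CpG dropped")
            next
        }
        z <- (e - mean(e)) / stats::sd(e)
        beta <- .clip01(stats::plogis(enhModels$intercept[i] +
                                      enhModels$slope[i] * z))
        rows[[enhModels$cpg[i]]] <- beta
        wts <- c(wts, mean(beta[z < 0]))
    }
    if (!length(rows)) stop("no CpG could be imputed")
    vals <- do.call(rbind, rows)
    colnames(vals) <- colnames(ev)
    MethylationReference(vals, weights = wts, provenance = provenance,
                         level = "cpg")
}
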