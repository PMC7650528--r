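#' Estimate cell-type fractions by weighted robust regression
#'
#' Regresses each bulk profile on the reference columns using Huber's robust
#' M-estimator, minimising `|| W^(1/2) (y - M f) ||` where W is the diagonal
#' matrix of per-feature quality weights: both the profile and the reference
#' rows are multiplied by sqrt(w) before the robust fit. Non-negativity and
#' sum-to-one constraints are imposed a posteriori by zeroing negative
#' coefficients and rescaling the rest, so the raw coefficients are invariant
#' to shifts (intercept mode) and positive scaling of the profile.
#'
#' @param bulk numeric vector (one profile over the reference features) or
#'   features x samples matrix. For CpG-level bulk data against a
#'   gene-promoter reference, collapse first with [collapseToPromoter()].
#' @param ref a [MethylationReference-class] or [ExpressionReference-class].
#' @param weights "reference" (use the reference quality weights; uniform
#'   for an expression reference) or "uniform".
#' @param huberK Huber tuning constant (default 1.345, 95% Gaussian
#'   efficiency).
#' @param intercept include an intercept column (default TRUE; required for
#'   shift invariance). Set FALSE for the strict objective.
#' @param maxit,acc IRLS iteration cap and coefficient tolerance.
#' @return a [FractionEstimate-class].
#' @export
estimateFractions <- function(bulk, ref, weights = c("reference", "uniform"),
                              huberK = 1.345, intercept = TRUE,
                              maxit = 50L, acc = 1e-8) {
    weights <- match.arg(weights)
    M <- refValues(ref)
    if (is.null(dim(bulk)))
        bulk <- matrix(bulk, ncol = 1L,
                       dimnames = list(names(bulk), "sample1"))
    w <- if (weights == "reference" && is(ref, "MethylationReference"))
        refWeights(ref) else stats::setNames(rep(1, nrow(M)), rownames(M))
    w <- w[w > 0]
    shared <- intersect(names(w), rownames(bulk))
    K <- ncol(M)
    if (length(shared) < K + 2L)
        stop("only ", length(shared), " usable features shared with the ",
             "reference; need at least ", K + 2L)
    M <- M[shared, , drop = FALSE]
    Y <- bulk[shared, , drop = FALSE]
    qrM <- qr(M)
    if (qrM$rank < K)
        stop("rank-deficient reference; collinear column(s): ",
             paste(colnames(M)[-qrM$pivot[seq_len(qrM$rank)]], collapse = ", "))
    sw <- sqrt(w[shared])
    X <- M * sw
    if (intercept) X <- cbind(`(Intercept)` = sw, X)
    psi <- function(u, deriv = 0) MASS::psi.huber(u, k = huberK, deriv = deriv)
    raw <- matrix(NA_real_, ncol(Y), K,
                  dimnames = list(colnames(Y), colnames(M)))
    frac <- raw
    conv <- logical(ncol(Y))
    for (j in seq_len(ncol(Y))) {
        fit <- MASS::rlm(X, Y[, j] * sw, psi = psi, maxit = maxit, acc = acc)
        co <- stats::coef(fit)
        if (intercept) co <- co[-1L]
        raw[j, ] <- co
        conv[j] <- fit$converged
        pos <- pmax(co, 0)
        if (sum(pos) <= 0)
            stop("no cell type detected for sample ", colnames(Y)[j],
                 ": all raw coefficients non-positive")
        frac[j, ] <- pos / sum(pos)
    }
    new("FractionEstimate", fractions = frac, raw = raw, converged = conv)
}

#' Classify samples by maximum estimated fraction
#'
#' @param f a [FractionEstimate-class].
#' @param warnTies warn when the maximum is tied (ties broken by
#'   lexicographically smallest cell-type name).
#' @return character vector of cell-type labels, one per sample.
#' @export
classifyCells <- function(f, warnTies = TRUE) {
    fr <- fractions(f)
    types <- colnames(fr)
    ord <- order(types)
    lab <- vapply(seq_len(nrow(fr)), function(i) {
        v <- fr[i, ord]
        types[ord][which.max(v)]
    }, character(1L))
    nTies <- sum(apply(fr, 1L, function(v) sum(v == max(v)) > 1L))
    if (nTies && warnTies)
        warning(nTies, " sample(s) with tied maximum fractions; ties broken ",
                "by cell-type name")
    stats::setNames(lab, rownames(fr))
    }

#' Simulate bulk profiles as in-silico mixtures with known weights
#'
#' Mixture weights per simulated sample are drawn from a Dirichlet
#' distribution: `alpha = "uniform"` gives the flat Dirichlet(1,...,1);
#' a numeric vector is used as the concentration directly; a
#' `list(means=, var=)` matches the per-cell-type mean fractions and the
#' average variance observed in real data. In `"profile-mix"` mode each
#' mixture is the convex combination of the per-type mean profiles; in
#' `"cell-mix"` mode `cellsPerMix` single-cell profiles are drawn
#' multinomially by the weights and averaged.
#'
#' @param profiles features x samples(cells) matrix of pure profiles.
#' @param labels cell-type label per column of `profiles`.
#' @param n number of mixtures.
#' @param mode "profile-mix" or "cell-mix".
#' @param alpha Dirichlet specification, see above.
#' @param cellsPerMix cells per simulated bulk sample (cell-mix mode).
#' @param seed integer seed (caller RNG state is restored).
#' @return list with `mixtures` (features x n), `truth` (n x K true weight
#'   matrix), and `seed`.
#' @export
makeMixtures <- function(profiles, labels, n = 100L,
                         mode = c("profile-mix", "cell-mix"),
                         alpha = "uniform", cellsPerMix = 1000L, seed = 1L) {
    mode <- match.arg(mode)
    labels <- as.character(labels)
    types <- sort(unique(labels))
    K <- length(types)
    if (is.character(alpha) && identical(alpha, "uniform")) {
        a <- rep(1, K)
    } else if (is.list(alpha)) {
        a <- .matchedDirichletAlpha(alpha$means[types], alpha$var)
    } else {
        stopifnot(length(alpha) == K)
        a <- as.numeric(alpha)
    }
    names(a) <- types
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(seed)
    W <- .rdirichlet(n, a)
    rownames(W) <- paste0("mix", seq_len(n))
    if (mode == "profile-mix") {
        P <- .groupStat(profiles, labels, mean)
        mix <- P[, types, drop = FALSE] %*% t(W)
    } else {
        mix <- matrix(0, nrow(profiles), n)
        idxByType <- split(seq_along(labels), labels)
        for (i in seq_len(n)) {
            cnt <- stats::rmultinom(1L, cellsPerMix, W[i, ])[, 1L]
            picks <- unlist(lapply(types, function(k) {
                if (cnt[k] == 0L) return(integer(0))
                sample(idxByType[[k]], cnt[k], replace = TRUE)
            }))
            mix[, i] <- rowMeans(profiles[, picks, drop = FALSE])
        }
        rownames(mix) <- rownames(profiles)
    }
    colnames(mix) <- rownames(W)
    list(mixtures = mix, truth = W, seed = seed)
}

#' Compare estimated to true mixture fractions
#'
#' @param estimates a [FractionEstimate-class] or samples x cell-types
#'   matrix.
#' @param truth samples x cell-types matrix of true weights (matching
#'   sample ids).
#' @return data.frame with per-cell-type `pcc`, `r2` (squared Pearson
#'   correlation) and `rmse`.
#' @export
evaluateFractions <- function(estimates, truth) {
    est <- if (is(estimates, "FractionEstimate")) fractions(estimates)
           else as.matrix(estimates)
    stopifnot(all(rownames(truth) %in% rownames(est)))
    est <- est[rownames(truth), colnames(truth), drop = FALSE]
    out <- do.call(rbind, lapply(colnames(truth), function(k) {
        r <- stats::cor(est[, k], truth[, k])
        data.frame(cellType = k, pcc = r, r2 = r^2,
                   rmse = sqrt(mean((est[, k] - truth[, k])^2)),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
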