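# independent gamma pdf for the posterior oracle (no stats::dgamma)
gammaPdf <- function(x, shape, scale) {
    x^(shape - 1) * exp(-x / scale) / (gamma(shape) * scale^shape)
}

test_that("EM recovers gamma-mixture parameters from simulated draws", {
    withr::with_seed(5, {
        n <- 50000
        state <- rbinom(n, 1, 0.3)
        x <- ifelse(state == 1, rgamma(n, 20, scale = 0.5),
                    rgamma(n, 2, scale = 0.5))
    })
    fit <- fitExpressionMixture(x, seed = 1)
    expect_lt(abs(fit@pi[2] - 0.3), 0.02)
    expect_lt(abs(fit@shape[1] * fit@scale[1] - 1) / 1, 0.05)
    expect_lt(abs(fit@shape[2] * fit@scale[2] - 10) / 10, 0.05)
    # ordering contract and monotone log-likelihood
    expect_lt(fit@shape[1] * fit@scale[1], fit@shape[2] * fit@scale[2])
    expect_true(all(diff(fit@logLik) >= 0))
    expect_error(fitExpressionMixture(rep(2, 50)), "100 positive")
})

test_that("posterior probabilities equal an independent density-ratio oracle", {
    model <- new("GammaMixtureModel", shape = c(2, 20), scale = c(0.5, 0.5),
                 pi = c(0.7, 0.3), logLik = 0, converged = TRUE)
    xs <- c(0.01, 0.1, 0.5, 1, 2, 4, 6, 10, 20, 50)
    oracle <- vapply(xs, function(x) {
        num <- 0.3 * gammaPdf(x, 20, 0.5)
        num / (num + 0.7 * gammaPdf(x, 2, 0.5))
    }, numeric(1))
    expect_equal(posteriorExpressed(model, xs), oracle, tolerance = 1e-12)
    # near-degenerate mixing with identical components: posterior equals
    # the prior weight for every x
    m1 <- new("GammaMixtureModel", shape = c(3, 3), scale = c(1, 1),
              pi = c(1e-6, 1 - 1e-6), logLik = 0, converged = TRUE)
    expect_true(all(posteriorExpressed(m1, c(0.5, 3, 8)) > 1 - 1e-5))
    mSym <- new("GammaMixtureModel", shape = c(3, 3), scale = c(1, 1),
                pi = c(0.5, 0.5), logLik = 0, converged = TRUE)
    expect_equal(posteriorExpressed(mSym, c(0.3, 2, 9)), rep(0.5, 3))
    # log-space evaluation stays finite over the whole dynamic range
    big <- posteriorExpressed(model, c(0, 10^seq(-6, 6)))
    expect_true(all(is.finite(big) & big >= 0 & big <= 1))
    expect_equal(posteriorExpressed(model, 0), 0)  # zero = unexpressed
})

test_that("gene imputation takes the non-expressing median or the logistic fallback", {
    model <- new("GammaMixtureModel", shape = c(2, 20), scale = c(0.5, 0.5),
                 pi = c(0.7, 0.3), logLik = 0, converged = TRUE)
    exprRow <- c(0.5, 0.8, 1.0, 1.2, 0.9, 10, 11)
    pmethRow <- c(0.8, 0.9, 0.7, 0.95, 0.85, 0.05, 0.02)
    got <- imputeGene(exprRow, pmethRow, model)
    expect_equal(got$mode, "median")
    expect_equal(got$value, 0.85)
    expect_equal(got$nNonExpressing, 5L)

    # all samples expressed: logistic extrapolation to zero expression;
    # data generated exactly on a logistic curve, so the IRLS fit recovers
    # the curve and the imputed value is its intercept probability
    xs <- seq(6, 12, length.out = 20)
    ys <- plogis(2.2 - 0.45 * xs)
    gotL <- imputeGene(xs, ys, model)
    expect_equal(gotL$mode, "logistic")
    expect_equal(gotL$intercept, 2.2, tolerance = 1e-4)
    expect_equal(gotL$value, plogis(2.2), tolerance = 1e-4)
    expect_equal(round(gotL$value, 3), 0.900)

    # boundary contract: posterior exactly at the threshold counts as
    # expressed (strict <)
    post <- posteriorExpressed(model, exprRow)
    atThr <- imputeGene(exprRow, pmethRow, model, pThreshold = min(post))
    expect_equal(atThr$mode, "logistic")
    above <- imputeGene(exprRow, pmethRow, model,
                        pThreshold = min(post) + 1e-12)
    expect_equal(above$mode, "median")
})

test_that("imputed values are robust to relaxing the posterior threshold", {
    tt <- fixtureTissue()
    genes <- names(tt$geneModels)
    v02 <- vapply(genes, function(g) tt$geneModels[[g]]$value, numeric(1))
    m03 <- imputeMarkers(genes, tt$truth$matched$expr, tt$pmeth$values,
                         tt$mixModel, pThreshold = 0.3)
    v03 <- vapply(genes, function(g) m03[[g]]$value, numeric(1))
    expect_lt(mean(abs(v02 - v03)), 0.05)
})

test_that("methylation reference rows, weights and exclusions follow the rules", {
    ev <- rbind(mA = c(3, 0, 0, 0), mB = c(0, 2, 0, 0), all = c(1, 2, 3, 4),
                zeroVal = c(0, 0, 5, 0))
    colnames(ev) <- paste0("CT", 1:4)
    exprRef <- ExpressionReference(ev)
    models <- list(mA = list(mode = "median", value = 0.9),
                   mB = list(mode = "median", value = 0.6),
                   all = list(mode = "median", value = 0.8),
                   zeroVal = list(mode = "median", value = 0))
    ref <- suppressMessages(buildDnamReference(exprRef, models, wMin = 0))
    expect_equal(unname(refValues(ref)["mA", ]), c(0, 0.9, 0.9, 0.9))
    expect_equal(unname(refWeights(ref)["mA"]), 0.9)
    expect_false("all" %in% rownames(refValues(ref)))  # expressed everywhere
    expect_equal(unname(refWeights(ref)["zeroVal"]), 0)
    refW <- suppressMessages(buildDnamReference(exprRef, models, wMin = 0.4))
    expect_false("zeroVal" %in% rownames(refValues(refW)))
    # brute-force weight recomputation on the synthetic tissue reference
    tt <- fixtureTissue()
    v <- refValues(tt$dnamRef); w <- refWeights(tt$dnamRef)
    ev2 <- refValues(tt$exprRef)[rownames(v), colnames(v)]
    brute <- vapply(rownames(v), function(g)
        mean(v[g, ev2[g, ] == 0]), numeric(1))
    expect_equal(unname(w), unname(brute))
    expect_true(all(v >= 0 & v <= 1) && all(w >= 0 & w <= 1))
})

test_that("merging references averages shared genes and unions the rest", {
    mk <- function(genes, val, w) MethylationReference(
        matrix(val, length(genes), 3,
               dimnames = list(genes, paste0("CT", 1:3))),
        weights = rep(w, length(genes)))
    a <- mk(c("g1", "g2", "g3"), 0.8, 0.8)
    b <- mk(c("g2", "g3", "g4"), 0.6, 0.6)
    m <- mergeReferences(a, b)
    expect_setequal(rownames(refValues(m)), c("g1", "g2", "g3", "g4"))
    expect_equal(unname(refValues(m)["g2", 1]), 0.7)     # exact midpoint
    expect_equal(unname(refValues(m)["g1", 1]), 0.8)     # exclusive copied
    expect_equal(unname(refWeights(m)["g2"]), 0.7)
    expect_equal(m@provenance, "merged")
    # idempotence
    same <- mergeReferences(a, a)
    expect_equal(refValues(same)[rownames(refValues(a)), ], refValues(a))
    # column mismatch errors
    bBad <- MethylationReference(matrix(0.5, 2, 3,
        dimnames = list(c("g1", "g2"), paste0("XX", 1:3))))
    expect_error(mergeReferences(a, bBad), "mismatch")
})

test_that("enhancer logistic imputation reproduces planted curves", {
    set.seed(95)
    n <- 12; nCpg <- 10
    samples <- paste0("s", 1:n)
    expr <- matrix(rnorm(nCpg * n, 5, 2), nCpg, n,
                   dimnames = list(paste0("g", 1:nCpg), samples))
    z <- t(scale(t(expr)))
    trueInt <- runif(nCpg, -1, 1); trueSlope <- runif(nCpg, -3, -1)
    meth <- plogis(trueInt + trueSlope * z) +
        matrix(rnorm(nCpg * n, 0, 0.01), nCpg)
    meth <- scMethylDeconv:::.clip01(meth)
    rownames(meth) <- paste0("cg", 1:nCpg)
    pairs <- data.frame(cpg = rownames(meth), gene = rownames(expr))
    fits <- fitEnhancerLogistic(pairs, expr, meth)
    expect_equal(nrow(fits), nCpg)
    expect_true(all(fits$slope < 0))             # monotone decreasing
    expect_equal(fits$intercept, trueInt, tolerance = 0.15)
    # z = 0 input gives the intercept probability
    refv <- matrix(c(4, 5, 6, 5), 1, 4,
                   dimnames = list("g1", paste0("CT", 1:4)))
    ref1 <- ExpressionReference(refv)
    imp <- imputeEnhancer(ref1, fits[fits$gene == "g1", , drop = FALSE])
    zRef <- (refv[1, ] - mean(refv[1, ])) / sd(refv[1, ])
    expect_equal(unname(refValues(imp)["cg1", ]),
                 unname(plogis(fits$intercept[1] + fits$slope[1] * zRef)))
    expect_true(all(refValues(imp) >= 0 & refValues(imp) <= 1))
    # imputed values track the generating curve at the reference z-scores
    refBig <- ExpressionReference(
        matrix(runif(nCpg * 4, 2, 9), nCpg, 4,
               dimnames = list(rownames(expr), paste0("CT", 1:4))))
    impBig <- imputeEnhancer(refBig, fits)
    zB <- t(scale(t(refValues(refBig))))
    for (i in seq_len(nCpg)) {
        want <- plogis(trueInt[i] + trueSlope[i] * zB[i, ])
        expect_lt(max(abs(refValues(impBig)[paste0("cg", i), ] - want)), 0.1)
    }
    # constant reference rows cannot be z-scored
    refConst <- ExpressionReference(matrix(3, 1, 4,
        dimnames = list("g1", paste0("CT", 1:4))))
    expect_warning(
        expect_error(imputeEnhancer(refConst,
                                    fits[fits$gene == "g1", , drop = FALSE]),
                     "no CpG"),
        "constant")
})
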