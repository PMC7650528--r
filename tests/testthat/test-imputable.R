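test_that("promoter collapse is strand-aware and falls back to first exon", {
    samples <- paste0("s", 1:3)
    meth <- rbind(cgUp = c(0.7, 0.7, 0.7),
                  cgE1 = c(0.2, 0.2, 0.2), cgE2 = c(0.4, 0.4, 0.4),
                  cgMinus = c(0.6, 0.5, 0.4))
    colnames(meth) <- samples
    cpgs <- data.frame(cpg_id = rownames(meth), chrom = "chr1",
                       position = c(900, 5100, 5300, 2150))
    genes <- data.frame(gene_id = c("gPlus", "gExon", "gMinus", "gNone"),
                        chrom = "chr1",
                        tss = c(1000, 5000, 2000, 9000),
                        strand = c("+", "+", "-", "+"),
                        exon1_start = c(1000, 5000, 1500, 9000),
                        exon1_end = c(1100, 5400, 2000, 9100))
    # gPlus: cgUp at tss-100 inside [800, 999]; cgE1/cgE2 in its exon? no
    got <- suppressMessages(collapseToPromoter(meth, cpgs, genes))
    expect_equal(unname(got$provenance),
                 c("tss200", "exon1", "tss200"))
    expect_equal(got$values["gPlus", ], meth["cgUp", ])
    expect_equal(unname(got$values["gExon", ]), rep(0.3, 3))  # mean(0.2, 0.4)
    # minus-strand gene: upstream is [tss+1, tss+200]; cgMinus at tss+150
    expect_equal(got$values["gMinus", ], meth["cgMinus", ])
    expect_false("gNone" %in% rownames(got$values))
    expect_true(all(got$values >= 0 & got$values <= 1))
})

test_that("promoter collapse matches a coordinate-arithmetic oracle", {
    set.seed(71)
    nG <- 20; nC <- 200
    genes <- data.frame(gene_id = paste0("g", 1:nG), chrom = "chr1",
                        tss = sort(sample(10000:1e6, nG)),
                        strand = sample(c("+", "-"), nG, TRUE))
    genes$exon1_start <- ifelse(genes$strand == "+", genes$tss,
                                genes$tss - 300)
    genes$exon1_end <- genes$exon1_start + 300
    cpgs <- data.frame(cpg_id = paste0("cg", 1:nC), chrom = "chr1",
                       position = sample(10000:1e6, nC))
    meth <- matrix(runif(nC * 4), nC, 4,
                   dimnames = list(cpgs$cpg_id, paste0("s", 1:4)))
    got <- suppressMessages(collapseToPromoter(meth, cpgs, genes))
    # independent oracle: plain coordinate arithmetic per gene
    for (i in seq_len(nG)) {
        g <- genes[i, ]
        up <- if (g$strand == "+") {
            cpgs$position >= g$tss - 200 & cpgs$position <= g$tss - 1
        } else {
            cpgs$position >= g$tss + 1 & cpgs$position <= g$tss + 200
        }
        ex <- cpgs$position >= g$exon1_start & cpgs$position <= g$exon1_end
        use <- if (any(up)) up else ex
        if (!any(use)) {
            expect_false(g$gene_id %in% rownames(got$values))
        } else {
            expect_equal(got$values[g$gene_id, ],
                         colMeans(meth[use, , drop = FALSE]),
                         info = g$gene_id)
        }
    }
})

test_that("imputable scan filters, correlates and flags the anti-correlated core", {
    e <- matrix(c(1, 2, 3, 4,
                  1, 2, 3, 4,
                  5, 5.01, 5.02, 5.03), 3, 4, byrow = TRUE,
                dimnames = list(c("gA", "gFlat", "gLowRange"),
                                paste0("s", 1:4)))
    m <- matrix(c(0.9, 0.6, 0.3, 0.0,
                  0.5, 0.51, 0.52, 0.515,
                  0.1, 0.9, 0.2, 0.8), 3, 4, byrow = TRUE,
                dimnames = dimnames(e))
    got <- scanImputable(e, m)
    expect_false("gLowRange" %in% got$gene)      # expression range 0.03
    expect_false("gFlat" %in% got$gene)          # methylation range 0.02
    expect_equal(got$pcc[got$gene == "gA"], -1)
    expect_true(got$core[got$gene == "gA"])
    expect_equal(attr(got, "nShared"), 3L)
})

test_that("planted anti-correlated genes are recovered and the null is calibrated", {
    mo <- fixtureMatched()
    scan <- scanImputable(mo$expr, mo$pmeth)
    planted <- mo$truth$anticorrGenes
    hit <- intersect(scan$gene[scan$core], planted)
    expect_gte(length(hit) / length(planted), 0.90)
    nullRows <- scan[!scan$gene %in% planted, ]
    fpr <- mean(nullRows$significant)
    se <- sqrt(0.05 * 0.95 / nrow(nullRows))
    expect_lt(abs(fpr - 0.05), 4 * se + 0.01)
})

test_that("range filters commute", {
    mo <- fixtureMatched()
    a <- scanImputable(mo$expr, mo$pmeth)
    b <- scanImputable(mo$expr[rev(rownames(mo$expr)), ], mo$pmeth)
    b <- b[match(a$gene, b$gene), ]
    expect_equal(a$pcc, b$pcc)
    expect_equal(a$core, b$core)
})

test_that("overlap significance matches the closed-form hypergeometric tail", {
    u <- paste0("g", 1:20)
    withr::with_seed(1, {
        disjoint <- overlapSignificance(u[1:10], u[11:20], 20, nMC = 1000)
    })
    expect_equal(disjoint$nOverlap, 0L)
    expect_equal(disjoint$fisherP, 1)
    withr::with_seed(2, {
        same <- overlapSignificance(u[1:5], u[1:5], 20, nMC = 1000)
    })
    expect_equal(same$nOverlap, 5L)
    expect_equal(same$fisherP,
                 phyper(4, 5, 15, 5, lower.tail = FALSE))
    expect_equal(same$fisherP, 1 / choose(20, 5))
    expect_warning(res <- overlapSignificance(character(0), u[1:5], 20,
                                              nMC = 10),
                   "empty")
    expect_equal(res$fisherP, 1)
})

test_that("Monte-Carlo overlap p converges to the hypergeometric value", {
    u <- paste0("g", 1:60)
    withr::with_seed(3, {
        got <- overlapSignificance(u[1:20], u[15:34], 60, nMC = 20000)
    })
    p <- got$fisherP
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(got$mcP - p), 3 * se + 2 / 20000)
})

test_that("enhancer linking applies the distance rule and max-|t| assignment", {
    set.seed(81)
    n <- 12
    samples <- paste0("s", 1:n)
    x1 <- rnorm(n, 5, 2); x2 <- rnorm(n, 5, 2)
    expr <- rbind(gStrong = x1, gWeak = x2, gFar = rnorm(n, 5, 2))
    colnames(expr) <- samples
    yLinked <- scMethylDeconv:::.clip01(0.5 - 0.2 * scale(x1)[, 1] +
                                        rnorm(n, 0, 0.01))
    meth <- rbind(cgLinked = yLinked,
                  cgNear = runif(n),
                  cgNull = runif(n))
    colnames(meth) <- samples
    genes <- data.frame(gene_id = rownames(expr), chrom = "chr1",
                        tss = c(100000, 150000, 5e6), strand = "+",
                        exon1_start = c(100000, 150000, 5e6),
                        exon1_end = c(100100, 150100, 5e6 + 100))
    cpgs <- data.frame(cpg_id = rownames(meth), chrom = "chr1",
                       position = c(200000, 103000, 300000))
    pairs <- suppressWarnings(suppressMessages(
        linkEnhancerCpGs(meth, cpgs, genes, expr, rangeDnamMin = 0.1,
                         r2Min = 0.5)))
    # cgNear is 3 kb from gStrong's TSS -> excluded by the proximal rule
    expect_false("cgNear" %in% pairs$cpg)
    expect_true("cgLinked" %in% pairs$cpg)
    # cgLinked is within 500 kb of both gStrong and gWeak; assignment by |t|
    expect_equal(pairs$gene[pairs$cpg == "cgLinked"], "gStrong")
    # r2 equals the brute-force 1 - SSE/SST of the simple regression
    row <- pairs[pairs$cpg == "cgLinked", ]
    fit <- lm(yLinked ~ x1)
    expect_equal(row$r2, 1 - sum(residuals(fit)^2) /
                     sum((yLinked - mean(yLinked))^2), tolerance = 1e-10)
    expect_equal(row$slope, unname(coef(fit)[2]), tolerance = 1e-10)
})

test_that("planted enhancer pairs are recovered in a 12-sample design", {
    set.seed(91)
    n <- 12; nPairs <- 15
    samples <- paste0("s", 1:n)
    expr <- matrix(rnorm(nPairs * n, 5, 2), nPairs, n,
                   dimnames = list(paste0("g", 1:nPairs), samples))
    meth <- scMethylDeconv:::.clip01(
        0.5 - 0.22 * t(scale(t(expr))) + matrix(rnorm(nPairs * n, 0, 0.02),
                                                nPairs))
    rownames(meth) <- paste0("cg", 1:nPairs)
    genes <- data.frame(gene_id = rownames(expr), chrom = "chr1",
                        tss = 1e6 * seq_len(nPairs) + 5e8, strand = "+",
                        exon1_start = 1e6 * seq_len(nPairs) + 5e8,
                        exon1_end = 1e6 * seq_len(nPairs) + 5e8 + 100)
    cpgs <- data.frame(cpg_id = rownames(meth), chrom = "chr1",
                       position = genes$tss + 50000)
    pairs <- suppressMessages(
        linkEnhancerCpGs(meth, cpgs, genes, expr, rangeDnamMin = 0.1))
    # true R2 of every planted pair is > 0.9; all must be recovered
    expect_equal(sort(pairs$cpg), sort(rownames(meth)))
    expect_equal(pairs$gene, sub("cg", "g", pairs$cpg))
    expect_true(all(pairs$r2 > 0.8))
})
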