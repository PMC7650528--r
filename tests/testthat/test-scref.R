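test_that("count normalisation matches the hand-computed scaling rule", {
    counts <- matrix(c(50, 50, 5, 45), 2, 2,
                     dimnames = list(c("g1", "g2"), c("c1", "c2")))
    # totals 100 and 50: count 5 in the second cell -> log2(5 * 2 + 1)
    got <- normalizeCounts(counts)
    expect_equal(got["g1", "c2"], log2(11))
    expect_equal(got["g1", "c1"], log2(51))
    # equal totals -> plain log2(x + 1)
    eq <- matrix(c(3, 7, 9, 1), 2, 2, dimnames = dimnames(counts))
    expect_equal(normalizeCounts(eq), log2(eq + 1))
    expect_equal(normalizeCounts(matrix(c(0, 1), 2, 1))[1, 1], 0)
    z <- counts; z[, 2] <- 0
    expect_error(normalizeCounts(z), "zero total")
})

test_that("vectorised Wilcoxon scan agrees with stats::wilcox.test", {
    set.seed(21)
    x <- matrix(rpois(30 * 60, 2), 30, 60)
    grp <- rep(c(TRUE, FALSE), c(30, 30))
    p1 <- scMethylDeconv:::.rowWilcoxon(x, grp, exactBelow = 25L)
    p2 <- apply(x, 1, function(v)
        suppressWarnings(wilcox.test(v[grp], v[!grp])$p.value))
    expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("marker selection enforces the three-part rule with MSS semantics", {
    set.seed(31)
    K <- 4
    labels <- rep(paste0("CT", 1:K), each = 30)
    n <- length(labels)
    # perfect marker of CT1: 5 in every CT1 cell, 0 elsewhere
    perfect <- ifelse(labels == "CT1", 5, 0)
    # highest median in CT1 but non-zero median in CT2 (MSS = 2)
    leaky <- ifelse(labels == "CT1", 5, ifelse(labels == "CT2", 2, 0))
    noise <- matrix(rpois(10 * n, 3), 10, n)
    expr <- rbind(perfect = perfect, leaky = leaky, noise)
    rownames(expr) <- c("perfect", "leaky", paste0("bg", 1:10))
    colnames(expr) <- paste0("c", seq_len(n))

    mk3 <- suppressWarnings(selectMarkers(expr, labels, mssMin = 3))
    expect_true("perfect" %in% mk3$gene)
    expect_equal(mk3$cellType[mk3$gene == "perfect"], "CT1")
    expect_equal(mk3$mss[mk3$gene == "perfect"], 3)
    expect_false("leaky" %in% mk3$gene)
    mk2 <- suppressWarnings(selectMarkers(expr, labels, mssMin = 2))
    expect_true("leaky" %in% mk2$gene)
    expect_equal(mk2$mss[mk2$gene == "leaky"], 2)
})

test_that("MSS equals the brute-force count of zero-median other types", {
    sc <- fixtureSc()
    expr <- normalizeCounts(sc$counts)
    lab <- sc$labels$cellType
    mk <- suppressMessages(selectMarkers(expr, lab))
    types <- sort(unique(lab))
    med <- sapply(types, function(k)
        apply(expr[mk$gene, lab == k, drop = FALSE], 1, median))
    brute <- sapply(seq_len(nrow(mk)), function(i)
        sum(med[i, setdiff(types, mk$cellType[i])] == 0))
    expect_equal(mk$mss, brute)
})

test_that("planted markers are recovered with no cross-type misassignment", {
    sc <- fixtureSc()
    expr <- normalizeCounts(sc$counts)
    mk <- suppressMessages(selectMarkers(expr, sc$labels$cellType))
    planted <- sc$truth$markerMap
    recovered <- mk$gene[mk$gene %in% names(planted)]
    expect_gte(length(recovered) / length(planted), 0.95)
    sel <- mk[mk$gene %in% names(planted), ]
    expect_equal(sum(sel$cellType != planted[sel$gene]), 0L)
})

test_that("marker selection is invariant to monotone rescaling", {
    sc <- fixtureSc()
    expr <- normalizeCounts(sc$counts)[1:400, ]
    lab <- sc$labels$cellType
    a <- suppressMessages(suppressWarnings(selectMarkers(expr, lab)))
    b <- suppressMessages(suppressWarnings(selectMarkers(2.5 * expr, lab)))
    expect_equal(a$gene, b$gene)
    expect_equal(a$cellType, b$cellType)
    expect_equal(a$mss, b$mss)
})

test_that("reference construction matches brute-force group statistics", {
    set.seed(41)
    expr <- matrix(rpois(10 * 9, 4), 10, 9,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:9)))
    lab <- rep(c("A", "B", "C"), each = 3)
    mk <- data.frame(gene = rownames(expr), cellType = "A")
    refMed <- buildReference(expr, lab, mk, statistic = "median")
    refMean <- buildReference(expr, lab, mk, statistic = "mean")
    for (k in c("A", "B", "C")) {
        expect_equal(refValues(refMed)[, k],
                     apply(expr[, lab == k], 1, median))
        expect_equal(refValues(refMean)[, k], rowMeans(expr[, lab == k]))
    }
    expect_error(buildReference(expr, lab,
                                data.frame(gene = "nope", cellType = "A")),
                 "absent")
    # a perfect maximally specific marker has exactly one non-zero column
    tt <- fixtureTissue()
    rv <- refValues(tt$exprRef)
    full <- tt$markers$gene[tt$markers$mss == 3]
    expect_true(all(rowSums(rv[full, , drop = FALSE] > 0) == 1))
})

test_that("bulk reference selection applies fold-change and second-gap rules", {
    set.seed(51)
    lab <- rep(paste0("CT", 1:5), each = 4)
    mkGene <- function(means, sd = 0.05)
        unlist(lapply(means, function(m) rnorm(4, m, sd)))
    expr <- rbind(good = mkGene(c(10, 2, 2, 2, 2)),
                  tied = mkGene(c(10, 9.9, 2, 2, 2)),
                  flat = mkGene(c(3, 3, 3, 3, 3)))
    colnames(expr) <- paste0("s", seq_along(lab))
    ref <- suppressWarnings(buildBulkReference(expr, lab))
    expect_true("good" %in% names(markerMap(ref)))
    expect_equal(unname(markerMap(ref)["good"]), "CT1")
    expect_false("tied" %in% names(markerMap(ref)))   # gap 0.1 < 0.2
    expect_false("flat" %in% names(markerMap(ref)))
})

test_that("cluster annotation retains dominant clusters and drops mixed ones", {
    set.seed(61)
    K <- 3
    types <- paste0("CT", 1:K)
    nGenes <- 60
    P <- matrix(runif(nGenes * K, 0, 8), nGenes, K,
                dimnames = list(paste0("g", 1:nGenes), types))
    bulkRef <- ExpressionReference(P, statistic = "mean",
                                   markerMap = setNames(rep(types, 20),
                                                        rownames(P)))
    makeCells <- function(k, n) P[, k] %*% t(rep(1, n)) +
        matrix(rnorm(nGenes * n, 0, 0.3), nGenes)
    sc <- cbind(makeCells(1, 30), makeCells(2, 30),
                cbind(makeCells(1, 12), makeCells(3, 8)))  # mixed cluster
    sc[sc < 0] <- 0
    rownames(sc) <- rownames(P)
    colnames(sc) <- paste0("cell", seq_len(ncol(sc)))
    clusters <- rep(c("cl1", "cl2", "cl3"), c(30, 30, 20))
    ann <- annotateClusters(sc, clusters, bulkRef)
    rep1 <- ann$report
    expect_true(all(rep1$retained[rep1$cluster %in% c("cl1", "cl2")]))
    expect_false(rep1$retained[rep1$cluster == "cl3"])  # 60/40 split
    expect_equal(rep1$dominantType[rep1$cluster == "cl1"], "CT1")
    expect_true(all(ann$labels$cellType[grepl("^cell([1-9]|[12][0-9]|30)$",
                                              ann$labels$cell)] == "CT1"))
    # insufficient gene overlap errors
    sc2 <- sc[1:20, ]
    expect_error(annotateClusters(sc2, clusters, bulkRef), "overlap")
})
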