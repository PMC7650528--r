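# Internal numerical helpers shared across the pipeline.

# One-vs-rest Wilcoxon rank-sum p-values for every row of `x`, comparing the
# columns in `inGroup` against the rest. Normal approximation with tie
# correction and continuity correction; rows are independent so everything is
# vectorised over genes. When either group has fewer than `exactBelow`
# members, falls back to stats::wilcox.test row by row (which chooses the
# exact distribution when there are no ties). Two-sided.
.rowWilcoxon <- function(x, inGroup, exactBelow = 25L) {
    x <- as.matrix(x)
    n1 <- sum(inGroup)
    n2 <- ncol(x) - n1
    stopifnot(n1 >= 1L, n2 >= 1L)
    if (min(n1, n2) < exactBelow) {
        return(apply(x, 1L, function(v)
            suppressWarnings(stats::wilcox.test(v[inGroup], v[!inGroup])$p.value)))
    }
    N <- n1 + n2
    rk <- t(apply(x, 1L, rank))
    R1 <- rowSums(rk[, inGroup, drop = FALSE])
    U <- R1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    # tie correction: sum over tied groups of (t^3 - t), per row
    tieTerm <- apply(x, 1L, function(v) {
        tt <- table(v)
        sum(tt^3 - tt)
    })
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tieTerm / (N * (N - 1)))
    z <- U - mu
    z <- z - sign(z) * 0.5          # continuity correction
    z <- z / sqrt(pmax(sigma2, .Machine$double.eps))
    p <- 2 * stats::pnorm(-abs(z))
    p[sigma2 <= 0] <- 1             # constant row: no evidence
    pmin(p, 1)
}

# Row-wise Pearson correlation between matching rows of two matrices with the
# same dimensions, plus the two-sided p value from the t transform (n-2 df).
.rowPearson <- function(a, b) {
    stopifnot(identical(dim(a), dim(b)))
    n <- ncol(a)
    ac <- a - rowMeans(a)
    bc <- b - rowMeans(b)
    num <- rowSums(ac * bc)
    den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
    r <- ifelse(den > 0, num / den, NA_real_)
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1] <- 0
    list(r = r, p = p, n = n)
}

# Dirichlet draws: n x length(alpha) matrix, rows on the simplex.
.rdirichlet <- function(n, alpha) {
    K <- length(alpha)
    g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n), rate = 1),
                nrow = n)
    sw <- rowSums(g)
    # degenerate all-zero rows (tiny alpha): resample uniformly
    bad <- sw <= 0
    if (any(bad)) {
        g[bad, ] <- matrix(stats::rexp(sum(bad) * K), ncol = K)
        sw <- rowSums(g)
    }
    out <- g / sw
    colnames(out) <- names(alpha)
    out
}

# Dirichlet concentration matched to target means and a target mean variance:
# Var_k = m_k (1 - m_k) / (s0 + 1); s0 chosen so the average variance across
# cell types matches `targetVar`.
.matchedDirichletAlpha <- function(means, targetVar) {
    means <- means / sum(means)
    s0 <- mean(means * (1 - means)) / targetVar - 1
    if (s0 <= 0)
        stop("target variance too large for a Dirichlet with these means")
    means * s0
}

.clip01 <- function(x, eps = 0) pmin(pmax(x, eps), 1 - eps)

# deterministic sub-seed derivation (keeps values < 2^31)
.subSeed <- function(seed, k) (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
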