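# Independent from-definition oracles used across the suite. These share no
# code with the package implementation paths they check.

# Benjamini-Hochberg step-up from the definition: q_(i) = min over j >= i of
# m * p_(j) / j, capped at 1
bhOracle <- function(p) {
    m <- length(p)
    if (!m) return(numeric(0))
    ord <- order(p)
    ps <- p[ord]
    q <- numeric(m)
    for (i in seq_len(m))
        q[i] <- min(1, min(m * ps[i:m] / (i:m)))
    out <- numeric(m)
    out[ord] <- q
    out
}

# two-sided Fisher p by full enumeration over tables with the observed
# margins, using log-binomial coefficients (no dhyper)
fisherOracle <- function(tab) {
    a <- tab[1, 1]
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
    n <- sum(tab)
    if (r1 == 0 || r1 == n || c1 == 0 || c2 == 0) return(1)
    ks <- max(0, r1 - c2):min(r1, c1)
    logp <- lchoose(c1, ks) + lchoose(c2, r1 - ks) - lchoose(n, r1)
    probs <- exp(logp)
    pObs <- probs[ks == a]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# OLS genotype coefficient by the normal equations
olsOracle <- function(X, y) {
    XtX <- t(X) %*% X
    beta <- solve(XtX, t(X) %*% y)
    res <- y - X %*% beta
    df <- nrow(X) - ncol(X)
    sigma2 <- sum(res^2) / df
    covb <- sigma2 * solve(XtX)
    i <- match("genotype", colnames(X))
    list(beta = beta[i], se = sqrt(covb[i, i]),
         p = 2 * pt(-abs(beta[i] / sqrt(covb[i, i])), df))
}

# Ward's method from the definition: at each step merge the pair of clusters
# whose union minimizes the increase in total within-cluster sum of squares;
# records merge heights as sqrt(2 * deltaSSE) (the Euclidean-distance scale)
# and the partition after each merge.
wardOracle <- function(X) {
    clusters <- lapply(seq_len(nrow(X)), identity)
    heights <- numeric(0)
    partitions <- list()
    while (length(clusters) > 1) {
        best <- c(NA, NA); bestCost <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            A <- clusters[[i]]; B <- clusters[[j]]
            cA <- colMeans(X[A, , drop = FALSE])
            cB <- colMeans(X[B, , drop = FALSE])
            cost <- length(A) * length(B) / (length(A) + length(B)) *
                sum((cA - cB)^2)
            if (cost < bestCost) { bestCost <- cost; best <- c(i, j) }
        }
        merged <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters <- c(clusters[-best], list(merged))
        heights <- c(heights, sqrt(2 * bestCost))
        lab <- integer(nrow(X))
        for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
        partitions[[length(partitions) + 1]] <- lab
    }
    list(heights = heights, partitions = partitions)
}

# canonical form of a cluster labelling (invariant to label permutation)
canonicalPartition <- function(lab) as.integer(factor(lab, unique(lab)))

# inline rank inverse-normal transform (the definition)
intOracle <- function(v) qnorm((rank(v) - 0.5) / length(v))

# finite-n Monte-Carlo oracle for the expected genotype contrast after the
# rank inverse-normal transform: two-group mixture N(0,1) vs N(d,1) at the
# analysis sample sizes, transformed inline, group means differenced
intAttenuatedEffect <- function(d, n1, n0, reps = 2000) {
    mean(vapply(seq_len(reps), function(r) {
        y <- c(rnorm(n1, d), rnorm(n0))
        z <- intOracle(y)
        mean(z[seq_len(n1)]) - mean(z[-seq_len(n1)])
    }, numeric(1)))
}
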