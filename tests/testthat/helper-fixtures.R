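# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (enumeration, normal equations, quadratic-time
# agglomeration) and share no code with the package internals.

toyExpr <- function(n = 5, m = 8, seed = 42) {
    set.seed(seed)
    matrix(rnorm(n * m), n, m,
           dimnames = list(sprintf("g%02d", seq_len(n)),
                           sprintf("s%02d", seq_len(m))))
}

# OLS via explicit normal equations on a design with an intercept column.
olsOracle <- function(expr, target, regs) {
    X <- cbind(1, t(expr[regs, , drop = FALSE]))
    y <- expr[target, ]
    beta <- solve(crossprod(X), crossprod(X, y))
    list(intercept = beta[1L], coef = drop(beta[-1L]))
}

# Brute-force threshold-stopped UPGMA: cluster distances recomputed from
# scratch as means over all original cross pairs; lexicographic tie-break
# on the smallest member gene id.
bruteAverageLinkage <- function(D, threshold) {
    genes <- rownames(D)
    clusters <- as.list(genes)
    repeat {
        if (length(clusters) < 2L) break
        best <- NULL
        bestD <- Inf
        for (i in seq_len(length(clusters) - 1L))
            for (j in seq(i + 1L, length(clusters))) {
                d <- mean(D[clusters[[i]], clusters[[j]]])
                la <- min(min(clusters[[i]]), min(clusters[[j]]))
                lb <- max(min(clusters[[i]]), min(clusters[[j]]))
                better <- d < bestD ||
                    (d == bestD && (is.null(best) ||
                     la < best$la || (la == best$la && lb < best$lb)))
                if (better) {
                    bestD <- d
                    best <- list(i = i, j = j, la = la, lb = lb)
                }
            }
        if (bestD > threshold) break
        clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
        clusters[[best$j]] <- NULL
    }
    clusters <- clusters[order(vapply(clusters, min, character(1)))]
    out <- integer(length(genes))
    names(out) <- genes
    for (k in seq_along(clusters)) out[clusters[[k]]] <- k
    out
}

samePartition <- function(a, b) {
    a <- a[sort(names(a))]
    b <- b[sort(names(b))]
    identical(names(a), names(b)) &&
        identical(match(a, unique(a)), match(b, unique(b)))
}

# Brute-force AUPR: precision/recall at every distinct threshold, ties in
# one block, trapezoid anchored at recall 0.
bruteAupr <- function(ranked, truthKeys) {
    ranked <- ranked[order(-ranked$confidence), , drop = FALSE]
    keys <- paste(ranked$regulator, ranked$target)
    pr <- NULL
    for (t in unique(ranked$confidence)) {
        sel <- keys[ranked$confidence >= t]
        tp <- sum(sel %in% truthKeys)
        pr <- rbind(pr, c(recall = tp / length(truthKeys),
                          precision = tp / length(sel)))
    }
    r <- c(0, pr[, "recall"])
    p <- c(pr[1L, "precision"], pr[, "precision"])
    sum(diff(r) * (head(p, -1L) + tail(p, -1L)) / 2)
}

# Hypergeometric upper tail by direct combinatorial summation.
bruteHyperTail <- function(k, K, n, N) {
    if (k == 0) return(1)
    sum(vapply(k:min(K, n), function(i)
        choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# Textbook BH step-up adjustment.
bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
}

# Correlated pair generator with an exact target Pearson correlation.
exprWithCorrelation <- function(rho, m = 10, seed = 3) {
    set.seed(seed)
    u <- scale(rnorm(m))[, 1L]
    w <- rnorm(m)
    w <- scale(residuals(lm(w ~ u)))[, 1L]
    y <- rho * u + sqrt(1 - rho^2) * w
    x <- rbind(a = u, b = y)
    colnames(x) <- paste0("s", seq_len(m))
    x
}

# Small simulated instance for learner tests.
smallInstance <- function(nGenes = 40, q = 0.8, noise = 0.1, seed = 1) {
    truth <- generateModularNetwork(nGenes, regulatorFraction = 0.15,
                                    nModules = 3, q = q, seed = seed)
    list(truth = truth,
         expr = simulateKnockoutExpression(truth, noiseSd = noise,
                                           seed = seed))
}
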