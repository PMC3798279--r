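# Greedy selection, distances, clustering, the iterative learner, and
# consensus/stability.

test_that("greedy selection separates signal from noise and obeys the prior", {
    set.seed(9)
    a <- rnorm(20); b <- rnorm(20)
    x <- rbind(A = a, B = b, T = 2 * a + rnorm(20, sd = 0.05))
    colnames(x) <- paste0("s", 1:20)
    mods <- c(A = 1L, B = 1L, T = 1L)
    empty <- RegulatoryNetwork()
    p <- selectRegulatorsForGene(x, "T", c("A", "B"), empty, mods)
    expect_identical(regulatorIds(p), "A")
    # an overwhelming sparsity penalty empties every program
    hard <- MerlinParams(sparsity = -1e6)
    p0 <- selectRegulatorsForGene(x, "T", c("A", "B"), empty, mods, hard)
    expect_identical(regulatorIds(p0), character(0))
    # empty candidate set is a valid empty program
    pe <- selectRegulatorsForGene(x, "T", character(0), empty, mods)
    expect_identical(regulatorIds(pe), character(0))
})

test_that("the first greedy pick equals exhaustive single-regulator scoring", {
    x <- toyExpr(5, 15, seed = 21)
    cands <- c("g02", "g03", "g04")
    mods <- setNames(rep(1L, 5), rownames(x))
    empty <- RegulatoryNetwork()
    params <- MerlinParams(sparsity = -2, maxRegulators = 1)
    # oracle: score every single-regulator model through the public API
    base <- logPseudoLikelihood(x, fitConditionalGaussian(x, "g01"))
    deltas <- vapply(cands, function(r) {
        fit <- fitConditionalGaussian(x, "g01", r, ridge = params@ridge)
        logPseudoLikelihood(x, fit) - base +
            edgePriorLogOdds(edgeFeature(empty, mods, r, "g01"), params)
    }, numeric(1))
    p <- selectRegulatorsForGene(x, "g01", cands, empty, mods, params)
    if (max(deltas) > params@scoreTolerance)
        expect_identical(regulatorIds(p), names(which.max(deltas)))
    else
        expect_identical(regulatorIds(p), character(0))
})

test_that("regulatory similarity follows the sign-aware L1 Jaccard form", {
    w <- c(A = 1, B = -2, C = 0.5)
    expect_equal(regulatorySimilarity(w, w), 1)
    expect_equal(regulatorySimilarity(c(A = 1), c(B = 1)), 0)
    expect_equal(regulatorySimilarity(w, -w), 0)
    expect_equal(regulatorySimilarity(c(A = 1, B = 2),
                                      c(A = 0.5, B = -2)), 0.1)
    expect_equal(regulatorySimilarity(numeric(0), numeric(0)), 0)
})

test_that("gene distance averages expression and regulatory distance", {
    x <- toyExpr(2, 10, seed = 4)
    x["g02", ] <- x["g01", ]
    w <- c(A = 1)
    expect_equal(geneDistance(x, w, w, "g01", "g02"), 0)
    y <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
    colnames(y) <- paste0("s", 1:4)
    expect_equal(geneDistance(y, c(A = 1), c(B = 1), "a", "b"), 1)
    z <- exprWithCorrelation(0.8)
    expect_equal(geneDistance(z, c(A = 1), c(A = 0.6), "a", "b"), 0.25,
                 tolerance = 1e-12)
    # constant gene: correlation defined as 0
    cst <- rbind(a = rep(1, 5), b = 1:5)
    colnames(cst) <- paste0("s", 1:5)
    expect_equal(geneDistance(cst, numeric(0), numeric(0), "a", "b"),
                 (0.5 + 1) / 2)
})

test_that("threshold-stopped clustering matches a brute-force UPGMA oracle", {
    # degenerate extremes
    d1 <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    diag(d1) <- 0
    expect_equal(unname(hierarchicalCluster(d1, 0.5)), 1:4)
    d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    expect_equal(unname(hierarchicalCluster(d0, 0.5)), rep(1L, 4))
    # random 5-gene matrices against the oracle
    for (seed in 1:10) {
        set.seed(seed)
        n <- 5
        D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
        D[upper.tri(D)] <- runif(n * (n - 1) / 2)
        D <- D + t(D)
        got <- hierarchicalCluster(D, 0.45)
        want <- bruteAverageLinkage(D, 0.45)
        expect_true(samePartition(got, want))
    }
})

test_that("raising the stop threshold never increases the module count", {
    set.seed(33)
    n <- 12
    D <- matrix(0, n, n,
                dimnames = list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n)))
    D[upper.tri(D)] <- runif(n * (n - 1) / 2)
    D <- D + t(D)
    counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(h)
        length(unique(hierarchicalCluster(D, h))), integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("the learner converges with a non-decreasing score trajectory", {
    inst <- smallInstance(seed = 3)
    fit <- runMerlin(inst$expr, regulators(inst$truth))
    expect_s4_class(fit, "MerlinModel")
    expect_true(all(diff(scoreTrajectory(fit)) >= -1e-6))
    expect_true(fit@converged)
    # network and programs agree (validity guarantees it; spot-check one)
    e <- edges(network(fit))
    g <- e$target[[1L]]
    expect_setequal(regulatorIds(programs(fit)[[g]]),
                    e$regulator[e$target == g])
})

test_that("unassigned genes in the initial modules raise an error", {
    inst <- smallInstance(seed = 2)
    init <- setNames(rep(1L, 3), rownames(inst$expr)[1:3])
    expect_error(runMerlin(inst$expr, regulators(inst$truth),
                           initModules = init), "unassigned")
})

test_that("a zero module weight reduces the learner to per-gene regression", {
    inst <- smallInstance(seed = 6)
    params <- MerlinParams(moduleWeight = 0)
    full <- runMerlin(inst$expr, regulators(inst$truth), params = params)
    base <- linearRegressionNetwork(inst$expr, regulators(inst$truth),
                                    params)
    sortE <- function(net) {
        e <- edges(net)[c("regulator", "target", "weight")]
        e[order(e$regulator, e$target), ]
    }
    expect_equal(sortE(network(full)), sortE(network(base)),
                 ignore_attr = TRUE)
    for (g in names(programs(full)))
        expect_identical(coef(programs(full)[[g]]),
                         coef(programs(base)[[g]]))
    # and module assignments cannot matter at weight 0
    genes <- rownames(inst$expr)
    modA <- setNames(rep(1L, length(genes)), genes)
    set.seed(1)
    modB <- setNames(sample(rep_len(1:4, length(genes))), genes)
    pA <- selectRegulatorsForGene(inst$expr, genes[[1L]],
                                  regulators(inst$truth),
                                  RegulatoryNetwork(), modA, params)
    pB <- selectRegulatorsForGene(inst$expr, genes[[1L]],
                                  regulators(inst$truth),
                                  RegulatoryNetwork(), modB, params)
    expect_identical(coef(pA), coef(pB))
})

test_that("the learner beats a random-ranking baseline on simulated truth", {
    inst <- smallInstance(nGenes = 60, seed = 7)
    fit <- runMerlin(inst$expr, regulators(inst$truth))
    conf <- edgeConfusion(network(fit), network(inst$truth))
    prec <- conf$truePositives / conf$inferredTotal
    rec <- conf$truePositives / conf$trueTotal
    f <- 2 * prec * rec / (prec + rec)
    prevalence <- conf$trueTotal / conf$universeTotal
    # a random ranking's precision sits at prevalence, so its F-score at
    # equal edge count is bounded by ~prevalence
    expect_gt(f, prevalence)
})

test_that("consensus keeps edges by support with mean weights", {
    mk <- function(targets, w = 1) RegulatoryNetwork(
        rep("R", length(targets)), targets, weight = w)
    runs <- list(mk(c("a", "b")), mk(c("a", "b")), mk(c("a", "c"), w = 2),
                 mk("d"), mk("d"))
    cons <- consensusNetwork(runs, 3)
    e <- edges(cons)
    expect_identical(e$target, "a")
    expect_equal(e$confidence, 3 / 5)
    expect_equal(e$weight, (1 + 1 + 2) / 3)
    # intersection rule
    all5 <- consensusNetwork(rep(list(mk(c("a", "b"))), 5), 5)
    expect_setequal(edges(all5)$target, c("a", "b"))
    expect_equal(edges(all5)$confidence, c(1, 1))
    # single run passes through
    one <- consensusNetwork(list(mk(c("a", "b"))), 1)
    expect_setequal(edges(one)$target, c("a", "b"))
    expect_warning(empty <- consensusNetwork(runs, 6), "exceeds")
    expect_equal(numEdges(empty), 0L)
})

test_that("stability confidences are reproducible and certain for strong edges", {
    inst <- smallInstance(nGenes = 30, noise = 0, seed = 8)
    cands <- regulators(inst$truth)
    one <- stabilityConfidence(inst$expr, cands, nSubsets = 1,
                               subsetFraction = 1, seed = 4)
    direct <- runMerlin(inst$expr, cands)
    expect_setequal(paste(edges(one)$regulator, edges(one)$target),
                    paste(edges(network(direct))$regulator,
                          edges(network(direct))$target))
    expect_true(all(edges(one)$confidence == 1))
    a <- stabilityConfidence(inst$expr, cands, nSubsets = 3,
                             subsetFraction = 0.8, seed = 5)
    b <- stabilityConfidence(inst$expr, cands, nSubsets = 3,
                             subsetFraction = 0.8, seed = 5)
    expect_identical(edges(a), edges(b))
    expect_true(all(edges(a)$confidence >= 0 & edges(a)$confidence <= 1))
    expect_error(stabilityConfidence(inst$expr, cands, nSubsets = 2,
                                     subsetFraction = 1.2), "subsetFraction")
})

test_that("a noise-free dependence reaches full stability confidence", {
    set.seed(10)
    x <- rbind(A = rnorm(30), B = rnorm(30))
    x <- rbind(x, T = 2 * x["A", ],
               N1 = rnorm(30), N2 = rnorm(30))
    colnames(x) <- paste0("s", seq_len(30))
    net <- stabilityConfidence(x, c("A", "B"), nSubsets = 20,
                               subsetFraction = 0.6, seed = 2)
    e <- edges(net)
    key <- paste(e$regulator, e$target)
    expect_true("A T" %in% key)
    expect_equal(e$confidence[key == "A T"], 1)
})

test_that("random initial modules are seed-stable partitions", {
    inst <- smallInstance(nGenes = 20, seed = 12)
    m1 <- randomInitialModules(inst$expr, 0.6, seed = 3)
    m2 <- randomInitialModules(inst$expr, 0.6, seed = 3)
    expect_identical(m1, m2)
    expect_no_error(validateModuleAssignment(m1))
})
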