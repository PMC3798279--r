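# Edge-, regulator- and module-based metrics against enumeration oracles.

mkNet <- function(reg, tgt, conf = NA_real_, w = 1)
    RegulatoryNetwork(reg, tgt, weight = w, confidence = conf)

test_that("edge confusion counts over the common universe", {
    truth <- mkNet(c("R1", "R1", "R2"), c("a", "b", "a"))
    expect_error(edgeConfusion(RegulatoryNetwork(), truth), "non-empty")
    same <- edgeConfusion(truth, truth)
    expect_equal(same$truePositives, 3L)
    expect_equal(same$inferredTotal, same$trueTotal)
    disjoint <- mkNet(c("R1", "R2"), c("b", "b"))
    # overlap of edge sets is empty apart from shared universe counting
    conf <- edgeConfusion(disjoint, mkNet(c("R1", "R2"), c("a", "a")))
    expect_equal(conf$truePositives, 0L)
    # 3-regulator toy vs exhaustive enumeration
    inferred <- mkNet(c("R1", "R2", "R3", "R1"), c("a", "b", "c", "c"))
    truth2 <- mkNet(c("R1", "R2", "R3"), c("c", "b", "a"))
    got <- edgeConfusion(inferred, truth2)
    regU <- intersect(c("R1", "R2", "R3"), c("R1", "R2", "R3"))
    nodes <- c("R1", "R2", "R3", "a", "b", "c")
    uni <- 0; tp <- 0; ni <- 0; nt <- 0
    ik <- paste(inferred@edges$regulator, inferred@edges$target)
    tk <- paste(truth2@edges$regulator, truth2@edges$target)
    for (r in regU) for (g in nodes) {
        if (r == g) next
        uni <- uni + 1
        key <- paste(r, g)
        if (key %in% ik) ni <- ni + 1
        if (key %in% tk) nt <- nt + 1
        if (key %in% ik && key %in% tk) tp <- tp + 1
    }
    expect_equal(got$universeTotal, uni)
    expect_equal(got$truePositives, tp)
    expect_equal(got$inferredTotal, ni)
    expect_equal(got$trueTotal, nt)
})

test_that("fold enrichment is precision over background density", {
    expect_equal(foldEnrichment(list(truePositives = 30, inferredTotal = 100,
                                     trueTotal = 60, universeTotal = 600)),
                 3)
    truth <- mkNet(c("R1", "R1", "R2"), c("a", "b", "a"))
    same <- edgeConfusion(truth, truth)
    expect_equal(foldEnrichment(same),
                 same$universeTotal / same$trueTotal)
    # precision at background density is the null value 1
    expect_equal(foldEnrichment(list(truePositives = 6, inferredTotal = 60,
                                     trueTotal = 10, universeTotal = 100)),
                 1)
    expect_error(foldEnrichment(list(truePositives = 0, inferredTotal = 0,
                                     trueTotal = 10, universeTotal = 100)),
                 "zero")
})

test_that("AUPR handles perfect rankings, single blocks, and matches brute force", {
    truth <- mkNet(c("R", "R", "R"), c("a", "b", "c"))
    perfect <- data.frame(regulator = rep("R", 5),
                          target = c("a", "b", "c", "d", "e"),
                          confidence = c(5, 4, 3, 2, 1))
    expect_equal(aupr(precisionRecallCurve(perfect, truth)), 1)
    oneBlock <- transform(perfect, confidence = 1)
    expect_equal(aupr(precisionRecallCurve(oneBlock, truth)), 3 / 5)
    # 6-edge toy with a tie, against threshold enumeration
    toy <- data.frame(regulator = rep("R", 6),
                      target = letters[1:6],
                      confidence = c(0.9, 0.8, 0.8, 0.5, 0.4, 0.1))
    truth2 <- mkNet(rep("R", 3), c("a", "c", "e"))
    tkeys <- paste("R", c("a", "c", "e"))
    expect_equal(aupr(precisionRecallCurve(toy, truth2)),
                 bruteAupr(toy, tkeys), tolerance = 1e-12)
    expect_error(precisionRecallCurve(toy, RegulatoryNetwork()),
                 "positive")
    # random instances, ties included
    for (seed in 1:10) {
        set.seed(seed)
        k <- sample(5:20, 1)
        ranked <- data.frame(regulator = "R",
                             target = paste0("t", seq_len(k)),
                             confidence = round(runif(k), 1))
        truthK <- paste("R", paste0("t", sample(k, ceiling(k / 3))))
        tn <- mkNet("R", sub("R ", "", truthK))
        expect_equal(aupr(precisionRecallCurve(ranked, tn)),
                     bruteAupr(ranked, truthK), tolerance = 1e-12)
    }
})

test_that("hypergeometric tail matches combinatorial enumeration", {
    expect_equal(hypergeometricTail(0, 3, 4, 10), 1)
    expect_equal(hypergeometricTail(2, 2, 2, 4), 1 / 6)
    for (seed in 1:20) {
        set.seed(seed)
        N <- sample(5:30, 1)
        K <- sample(0:N, 1)
        n <- sample(0:N, 1)
        k <- sample(0:min(K, n), 1)
        expect_equal(hypergeometricTail(k, K, n, N),
                     bruteHyperTail(k, K, n, N), tolerance = 1e-12)
        if (k >= 1)
            expect_equal(hypergeometricTail(k, K, n, N) +
                         phyper(k - 1, K, N - K, n), 1, tolerance = 1e-12)
    }
    expect_error(hypergeometricTail(5, 2, 2, 4), "invalid")
})

test_that("BH adjustment matches the textbook step-up and ignores order", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(rep(0.2, 4)), rep(0.2, 4))
    p <- c(0.01, 0.02, 0.03, 0.5)
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
    set.seed(8)
    q <- runif(25)
    perm <- sample(25)
    expect_equal(bhAdjust(q)[perm], bhAdjust(q[perm]), tolerance = 1e-12)
    expect_equal(bhAdjust(q), bruteBH(q), tolerance = 1e-12)
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("regulator target overlap is total for self-comparison and matches hand BH", {
    set.seed(12)
    targets <- paste0("t", 1:30)
    truth <- RegulatoryNetwork(
        rep(c("R1", "R2"), each = 10),
        c(sample(targets, 10), sample(targets, 10)))
    self <- regulatorTargetOverlap(truth, truth)
    expect_equal(self$fraction, 1)
    # hand-computed toy over an explicit shared universe: a second
    # regulator S carries the remaining genes into both networks, so the
    # background is u1..u20 plus the regulators R and S (N = 22)
    uniT <- paste0("u", sprintf("%02d", 1:20))
    filler <- uniT[7:20]
    tr <- RegulatoryNetwork(c(rep("R", 10), rep("S", 14)),
                            c(uniT[1:10], filler))
    inf <- RegulatoryNetwork(c(rep("R", 8), rep("S", 14)),
                             c(uniT[c(1:6, 15, 16)], filler))
    got <- regulatorTargetOverlap(inf, tr)
    pR <- bruteHyperTail(6, 10, 8, 22)
    pS <- bruteHyperTail(14, 14, 14, 22)
    expect_equal(got$table$p[got$table$regulator == "R"], pR,
                 tolerance = 1e-12)
    expect_equal(got$table$q, bruteBH(got$table$p), tolerance = 1e-12)
    expect_equal(got$table$p[got$table$regulator == "S"], pS,
                 tolerance = 1e-12)
})

test_that("regulator-module associations flag concentrated targets only", {
    genes <- paste0("g", sprintf("%03d", 1:100))
    mods <- setNames(c(rep(1L, 10), rep(2L, 45), rep(3L, 45)), genes)
    net <- RegulatoryNetwork(rep("g100", 10), genes[1:10])
    got <- regulatorModuleMap(net, mods)
    expect_identical(got$associations$module[
        got$associations$regulator == "g100"], 1L)
    expect_lt(got$associations$q[[1L]], 1e-6)
    # regulator absent from the network yields nothing
    empty <- regulatorModuleMap(RegulatoryNetwork(), mods)
    expect_equal(nrow(empty$associations), 0L)
})

test_that("regulator-module F-score is the harmonic mean of set overlaps", {
    a <- data.frame(regulator = c("R1", "R2"), module = c(1L, 2L))
    sameMap <- regulatorModuleFscore(a, a)
    expect_equal(sameMap$precision, 1)
    expect_equal(sameMap$recall, 1)
    expect_equal(sameMap$fscore, 1)
    b <- data.frame(regulator = c("R3", "R4"), module = c(1L, 2L))
    expect_equal(regulatorModuleFscore(a, b)$fscore, 0)
    # P = 0.5, R = 0.25 -> F = 1/3
    trueMap <- data.frame(regulator = paste0("R", 1:4), module = rep(1L, 4))
    infMap <- data.frame(regulator = c("R1", "X"), module = c(1L, 1L))
    fs <- regulatorModuleFscore(trueMap, infMap)
    expect_equal(fs$precision, 0.5)
    expect_equal(fs$recall, 0.25)
    expect_equal(fs$fscore, 1 / 3)
    expect_error(regulatorModuleFscore(trueMap[0, ], infMap), "empty")
})

test_that("regulatory modularity matches a hand computation and its bounds", {
    # two modules of two genes, regulators shared strictly within modules
    mods <- c(a = 1L, b = 1L, c = 2L, d = 2L)
    net <- RegulatoryNetwork(c("Ra", "Ra", "Rb", "Rb"),
                             c("a", "b", "c", "d"))
    modsAll <- c(mods, Ra = 1L, Rb = 2L)
    got <- suppressMessages(regulatoryModularity(net, modsAll))
    # oracle: explicit pair loop over the stated s_ij
    regsOf <- function(g) net@edges$regulator[net@edges$target == g]
    sij <- function(i, j) {
        ni <- length(regsOf(i)); nj <- length(regsOf(j))
        if (ni + nj == 0) 0
        else 2 * length(intersect(regsOf(i), regsOf(j))) / (ni + nj)
    }
    genes <- names(modsAll)
    for (m in 1:2) {
        inM <- genes[modsAll == m]
        outM <- genes[modsAll != m]
        pairs <- combn(inM, 2)
        within <- mean(apply(pairs, 2, function(p) sij(p[1], p[2])))
        between <- mean(outer(inM, outM, Vectorize(sij)))
        expect_equal(unname(got[[as.character(m)]]), within - between)
    }
    expect_true(all(got > 0))  # sharing is exclusively within modules
    # identical regulator sets everywhere: within = between = 1 -> 0
    uni <- RegulatoryNetwork(rep("R", 4), c("a", "b", "c", "d"))
    modsU <- c(a = 1L, b = 1L, c = 2L, d = 2L)
    expect_equal(unname(regulatoryModularity(uni, modsU)), c(0, 0))
    # bounds on random networks and partitions
    set.seed(4)
    for (i in 1:25) {
        g <- paste0("n", 1:8)
        e <- expand.grid(regulator = g[1:3], target = g,
                         stringsAsFactors = FALSE)
        e <- e[e$regulator != e$target, ]
        e <- e[sample(nrow(e), 8), ]
        rn <- RegulatoryNetwork(e$regulator, e$target)
        rm <- setNames(sample(rep_len(1:3, 8)), g)
        rm <- setNames(match(rm, sort(unique(rm))), g)
        vals <- suppressMessages(regulatoryModularity(rn, rm))
        expect_true(all(vals >= -1 & vals <= 1))
    }
})

test_that("silhouette separates expression blocks and zeroes ties", {
    set.seed(5)
    block <- function(center) t(replicate(5, center + rnorm(12, sd = 0.1)))
    x <- rbind(block(sin(1:12)), block(cos(1:12)))
    rownames(x) <- paste0("g", 1:10)
    colnames(x) <- paste0("s", 1:12)
    mods <- setNames(rep(1:2, each = 5), rownames(x))
    sil <- silhouetteByModule(x, mods)
    expect_true(all(sil > 0.5))
    expect_error(silhouetteByModule(x, setNames(rep(1L, 10), rownames(x))),
                 "2 modules")
    # equidistant gene scores zero: two identical-profile clusters
    y <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
    colnames(y) <- paste0("s", 1:3)
    modsY <- c(a = 1L, b = 1L, c = 2L)
    expect_equal(unname(silhouetteByModule(y, modsY)), c(0, 0))
})

test_that("interaction z-score flags cliques and degenerate draws", {
    pool <- paste0("P", 1:20)
    clique <- combn(pool[1:5], 2)
    inter <- data.frame(a = clique[1, ], b = clique[2, ])
    z <- interactionEnrichmentZscore(pool[1:5], inter, pool, nRandom = 100,
                                     seed = 1)
    expect_gt(z$z, 1)
    # z equals the oracle recomputation with the same seed
    set.seed(1)
    nullCounts <- vapply(1:100, function(i) {
        s <- sample(pool, 5)
        sum(inter$a %in% s & inter$b %in% s)
    }, numeric(1))
    expect_equal(z$z, (10 - mean(nullCounts)) / sd(nullCounts))
    expect_equal(z$observed, 10)
    # drawing the whole pool every time has zero null sd
    expect_message(
        full <- interactionEnrichmentZscore(pool, inter, pool, nRandom = 5),
        "undefined")
    expect_true(is.na(full$z))
    expect_error(interactionEnrichmentZscore("X", inter, pool), "subset")
})

test_that("gene-set enrichment matches hand hypergeometrics", {
    genes <- paste0("g", sprintf("%02d", 1:20))
    mods <- setNames(rep(1:2, each = 10), genes)
    sets <- list(exact = genes[1:10], off = genes[11:15],
                 absent = paste0("x", 1:4))
    tab <- genesetEnrichment(mods, sets)
    exact <- tab[tab$module == 1 & tab$term == "exact", ]
    expect_equal(exact$p, bruteHyperTail(10, 10, 10, 20), tolerance = 1e-12)
    expect_equal(exact$p, min(tab$p))
    expect_true(exact$significant)
    expect_equal(exact$foldEnrichment, (10 / 10) / (10 / 20))
    # disjoint set never significant
    off2 <- tab[tab$module == 1 & tab$term == "off", ]
    expect_false(off2$significant)
    # absent set dropped from the background entirely
    expect_false("absent" %in% tab$term)
    expect_error(genesetEnrichment(mods, sets, background = character(0)),
                 "background")
})

test_that("module statistics count good-sized modules and coverage", {
    singles <- setNames(1:6, paste0("g", 1:6))
    expect_equal(moduleStats(singles),
                 list(goodModules = 0L, coverage = 0))
    one <- setNames(rep(1L, 8), paste0("g", 1:8))
    expect_equal(moduleStats(one), list(goodModules = 1L, coverage = 1))
    mixed <- setNames(rep(1:4, c(6, 5, 4, 3)), paste0("g", 1:18))
    got <- moduleStats(mixed)
    expect_equal(got$goodModules, 2L)
    expect_equal(got$coverage, 11 / 18)
})

test_that("evaluateNetwork bundles the metric suite", {
    inst <- smallInstance(nGenes = 40, seed = 9)
    fit <- runMerlin(inst$expr, regulators(inst$truth))
    rep <- evaluateNetwork(network(fit), network(inst$truth),
                           modules = modules(fit),
                           trueModules = modules(inst$truth),
                           expr = inst$expr,
                           rankedEdges = rankedEdges(fit))
    m <- metrics(rep)
    expect_true(m$foldEnrichment > 0)
    expect_true(m$aupr >= 0 && m$aupr <= 1)
    expect_true(m$regulatorOverlapFraction >= 0 &&
                m$regulatorOverlapFraction <= 1)
    expect_true(is.numeric(m$meanRegulatoryModularity))
    expect_output(show(rep), "EvaluationReport")
})
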