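#' @include AllClasses.R
NULL

.networkNodes <- function(net) unique(c(net@edges$regulator,
                                        net@edges$target))

# paste0 recycles zero-length inputs to ""; keep empty edge sets empty
.pairKeys <- function(reg, tgt) {
    if (length(reg) == 0L) character(0) else paste0(reg, "\r", tgt)
}

#' Edge confusion counts over the common universe
#'
#' Counts true-positive edges between an inferred and a true network over
#' the universe of possible edges restricted to regulators present in both
#' networks' regulator sets and nodes present in both networks, excluding
#' self-pairs.
#'
#' @param inferred,truth [RegulatoryNetwork-class] objects (both
#'   non-empty).
#' @return a list with elements \code{truePositives},
#'   \code{inferredTotal}, \code{trueTotal} and \code{universeTotal}.
#' @export
edgeConfusion <- function(inferred, truth) {
    if (numEdges(inferred) == 0L || numEdges(truth) == 0L)
        stop("both networks must be non-empty", call. = FALSE)
    regU <- intersect(regulators(inferred), regulators(truth))
    tgtU <- intersect(.networkNodes(inferred), .networkNodes(truth))
    universeTotal <- length(regU) * length(tgtU) -
        length(intersect(regU, tgtU))
    if (universeTotal <= 0L)
        stop("empty edge universe: the networks share no regulators/nodes",
             call. = FALSE)
    inU <- function(e) e$regulator %in% regU & e$target %in% tgtU
    ei <- inferred@edges[inU(inferred@edges), , drop = FALSE]
    et <- truth@edges[inU(truth@edges), , drop = FALSE]
    ki <- .pairKeys(ei$regulator, ei$target)
    kt <- .pairKeys(et$regulator, et$target)
    list(truePositives = length(intersect(ki, kt)),
         inferredTotal = nrow(ei), trueTotal = nrow(et),
         universeTotal = universeTotal)
}

#' Fold enrichment of true edges in an inferred network
#'
#' The precision of the inferred network divided by the density of true
#' edges in the common universe:
#' \eqn{(t / |inferred|) / (T / |universe|)}. Equals 1 in expectation for
#' a random network, and \eqn{|universe| / T} when the inferred network
#' reproduces the truth exactly.
#'
#' @param confusion output of [edgeConfusion()].
#' @return a single numeric fold enrichment.
#' @export
foldEnrichment <- function(confusion) {
    if (confusion$inferredTotal == 0L || confusion$trueTotal == 0L ||
        confusion$universeTotal == 0L)
        stop("fold enrichment undefined with zero counts", call. = FALSE)
    (confusion$truePositives / confusion$inferredTotal) /
        (confusion$trueTotal / confusion$universeTotal)
}

#' Precision-recall curve over ranked edges
#'
#' One precision-recall point per distinct confidence threshold, with
#' tied confidences entering as one block. Recall is against the full
#' true edge set.
#'
#' @param rankedEdges a \code{data.frame} with columns \code{regulator},
#'   \code{target} and \code{confidence}, or a [RegulatoryNetwork-class]
#'   with confidences.
#' @param truth a [RegulatoryNetwork-class] with at least one edge.
#' @return a \code{data.frame} with columns \code{threshold}, \code{n},
#'   \code{truePositives}, \code{precision}, \code{recall}, ordered by
#'   decreasing threshold.
#' @export
precisionRecallCurve <- function(rankedEdges, truth) {
    if (is(rankedEdges, "RegulatoryNetwork"))
        rankedEdges <- rankedEdges@edges
    if (numEdges(truth) == 0L)
        stop("truth has no positive edges", call. = FALSE)
    if (anyNA(rankedEdges$confidence))
        stop("all ranked edges need a confidence", call. = FALSE)
    pos <- .pairKeys(truth@edges$regulator, truth@edges$target)
    key <- .pairKeys(rankedEdges$regulator, rankedEdges$target)
    conf <- rankedEdges$confidence
    ord <- order(-conf)
    key <- key[ord]
    conf <- conf[ord]
    isPos <- key %in% pos
    ends <- cumsum(rle(conf)$lengths)
    thr <- conf[ends]
    n <- ends
    tp <- cumsum(isPos)[ends]
    data.frame(threshold = thr, n = n, truePositives = tp,
               precision = tp / n, recall = tp / length(pos))
}

#' Area under the precision-recall curve
#'
#' Trapezoidal area over recall, anchored at recall 0 with the precision
#' of the first block (so a single block containing everything integrates
#' to its prevalence).
#'
#' @param curve output of [precisionRecallCurve()], or the arguments of
#'   that function via \code{...}.
#' @param ... passed to [precisionRecallCurve()] when \code{curve} is a
#'   ranked edge table.
#' @return the AUPR in \eqn{[0, 1]}.
#' @export
aupr <- function(curve, ...) {
    if (!is.data.frame(curve) || !"recall" %in% names(curve))
        curve <- precisionRecallCurve(curve, ...)
    r <- c(0, curve$recall)
    p <- c(curve$precision[1L], curve$precision)
    sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}

#' Upper tail of the hypergeometric distribution
#'
#' \eqn{P(X \ge k)} for the overlap of a draw of size \eqn{n} with a set
#' of \eqn{K} successes in a universe of \eqn{N}.
#'
#' @param k observed overlap.
#' @param K number of successes in the universe.
#' @param n draw size.
#' @param N universe size.
#' @return the tail probability.
#' @examples
#' hypergeometricTail(2, 2, 2, 4)  # 1/6
#' @export
hypergeometricTail <- function(k, K, n, N) {
    if (any(c(k, K, n, N) < 0) || k > min(K, n) + 0 || K > N || n > N)
        stop("invalid hypergeometric counts", call. = FALSE)
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order and is invariant to it.
#'
#' @param pValues numeric vector of p-values in \eqn{[0, 1]}.
#' @return adjusted q-values.
#' @export
bhAdjust <- function(pValues) {
    if (any(!is.finite(pValues)) || any(pValues < 0) || any(pValues > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    stats::p.adjust(pValues, method = "BH")
}

#' Per-regulator overlap of true and inferred target sets
#'
#' For every regulator, tests whether its targets in the true network
#' significantly overlap its targets in the inferred network
#' (hypergeometric tail over the shared target universe), adjusts across
#' regulators with Benjamini-Hochberg, and reports the fraction of
#' regulators significant at the FDR threshold.
#'
#' @param inferred,truth [RegulatoryNetwork-class] objects.
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @return a list with \code{fraction} and a per-regulator \code{table}
#'   (regulator, overlap, trueTargets, inferredTargets, p, q,
#'   significant).
#' @export
regulatorTargetOverlap <- function(inferred, truth, fdrThreshold = 0.05) {
    tgtU <- intersect(.networkNodes(inferred), .networkNodes(truth))
    regs <- sort(union(regulators(inferred), regulators(truth)))
    rows <- list()
    for (r in regs) {
        Tt <- intersect(targetsOf(truth, r), tgtU)
        Ti <- intersect(targetsOf(inferred, r), tgtU)
        if (length(Tt) == 0L && length(Ti) == 0L) {
            message("regulator ", r,
                    " has no targets in the shared universe; excluded")
            next
        }
        rows[[r]] <- data.frame(
            regulator = r, overlap = length(intersect(Tt, Ti)),
            trueTargets = length(Tt), inferredTargets = length(Ti),
            p = hypergeometricTail(length(intersect(Tt, Ti)), length(Tt),
                                   length(Ti), length(tgtU)),
            stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab))
        stop("no regulators with targets in the shared universe",
             call. = FALSE)
    rownames(tab) <- NULL
    tab$q <- bhAdjust(tab$p)
    tab$significant <- tab$q < fdrThreshold
    list(fraction = mean(tab$significant), table = tab)
}

#' Regulator-module association map
#'
#' Tests, for each regulator and each module of at least
#' \code{minModuleSize} genes, whether the regulator's targets are
#' over-represented in the module (hypergeometric tail against the
#' all-genes background), with Benjamini-Hochberg adjustment across all
#' regulator-by-module tests. Associations are the pairs significant at
#' the FDR threshold.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param modules named integer module assignment (the background is its
#'   gene universe).
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @param minModuleSize smallest module tested (default 5).
#' @return a list with \code{associations} (regulator, module, p, q) and
#'   the full \code{tests} table.
#' @export
regulatorModuleMap <- function(network, modules, fdrThreshold = 0.05,
                               minModuleSize = 5L) {
    validateModuleAssignment(modules)
    background <- names(modules)
    N <- length(background)
    sizes <- table(modules)
    good <- as.integer(names(sizes)[sizes >= minModuleSize])
    rows <- list()
    for (r in regulators(network)) {
        tg <- intersect(targetsOf(network, r), background)
        if (length(tg) == 0L)
            next
        for (m in good) {
            inMod <- names(modules)[modules == m]
            k <- length(intersect(tg, inMod))
            rows[[paste0(r, ".", m)]] <- data.frame(
                regulator = r, module = m, overlap = k,
                targets = length(tg), moduleSize = length(inMod),
                p = hypergeometricTail(k, length(inMod), length(tg), N),
                stringsAsFactors = FALSE)
        }
    }
    tests <- do.call(rbind, rows)
    if (is.null(tests)) {
        tests <- data.frame(regulator = character(), module = integer(),
                            overlap = integer(), targets = integer(),
                            moduleSize = integer(), p = numeric(),
                            q = numeric())
        return(list(associations = tests, tests = tests))
    }
    rownames(tests) <- NULL
    tests$q <- bhAdjust(tests$p)
    list(associations = tests[tests$q < fdrThreshold, , drop = FALSE],
         tests = tests)
}

#' Precision, recall and F-score of regulator-module maps
#'
#' Set overlap of (regulator, module) association pairs between a map
#' derived from the true network and one derived from an inferred
#' network, plus the hypergeometric p-value of the overlap.
#'
#' @param trueMap,inferredMap association tables with columns
#'   \code{regulator} and \code{module} (as produced by
#'   [regulatorModuleMap()]), or the lists returned by that function.
#' @param universeSize number of regulator-by-module pairs tested; by
#'   default the cross of regulators and modules seen in either map.
#' @return a list with \code{precision}, \code{recall}, \code{fscore} and
#'   \code{overlapP}.
#' @export
regulatorModuleFscore <- function(trueMap, inferredMap,
                                  universeSize = NULL) {
    pick <- function(x) if (is.list(x) && !is.data.frame(x))
                            x$associations else x
    trueMap <- pick(trueMap)
    inferredMap <- pick(inferredMap)
    if (nrow(trueMap) == 0L)
        stop("the true regulator-module map is empty", call. = FALSE)
    kt <- .pairKeys(trueMap$regulator, trueMap$module)
    ki <- .pairKeys(inferredMap$regulator, inferredMap$module)
    tp <- length(intersect(kt, ki))
    precision <- if (length(ki)) tp / length(ki) else 0
    recall <- tp / length(kt)
    fscore <- if (precision + recall > 0)
                  2 * precision * recall / (precision + recall) else 0
    if (is.null(universeSize)) {
        regsU <- union(trueMap$regulator, inferredMap$regulator)
        modsU <- union(trueMap$module, inferredMap$module)
        universeSize <- max(length(regsU) * length(modsU), 1L)
    }
    universeSize <- max(universeSize, length(unique(kt)),
                        length(unique(ki)))
    overlapP <- hypergeometricTail(tp, length(unique(kt)),
                                   length(unique(ki)), universeSize)
    list(precision = precision, recall = recall, fscore = fscore,
         overlapP = overlapP)
}

#' Regulatory modularity of a network under a module assignment
#'
#' For every gene pair the regulator-sharing similarity is
#' \eqn{s_{ij} = 2 c_{ij} / (n_i + n_j)} (shared regulators over summed
#' regulator counts; 0 when both genes have none). A module's score is the
#' mean within-module similarity minus the mean similarity between its
#' genes and all other genes; both components lie in \eqn{[0, 1]} so the
#' score lies in \eqn{[-1, 1]}. Singleton modules have no within term and
#' score 0.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param modules named integer module assignment covering the network's
#'   genes.
#' @return named numeric vector of per-module scores.
#' @export
regulatoryModularity <- function(network, modules) {
    validateModuleAssignment(modules)
    genes <- names(modules)
    n <- length(genes)
    e <- network@edges
    regsOf <- split(e$regulator, factor(e$target, levels = genes))
    nreg <- lengths(regsOf)
    S <- matrix(0, n, n, dimnames = list(genes, genes))
    for (i in seq_len(n - 1L))
        for (j in seq(i + 1L, n)) {
            tot <- nreg[[i]] + nreg[[j]]
            s <- if (tot == 0L) 0 else
                2 * length(intersect(regsOf[[i]], regsOf[[j]])) / tot
            S[i, j] <- s
            S[j, i] <- s
        }
    mods <- sort(unique(modules))
    out <- numeric(length(mods))
    names(out) <- mods
    for (m in mods) {
        inM <- which(modules == m)
        outM <- which(modules != m)
        if (length(inM) < 2L) {
            message("module ", m, " is a singleton; modularity set to 0")
            out[[as.character(m)]] <- 0
            next
        }
        within <- mean(S[inM, inM][upper.tri(S[inM, inM])])
        between <- if (length(outM))
                       mean(S[inM, outM, drop = FALSE]) else 0
        out[[as.character(m)]] <- within - between
    }
    out
}

#' Mean regulatory modularity of a network
#'
#' Unweighted mean of the per-module [regulatoryModularity()] scores over
#' modules with at least \code{minModuleSize} genes (all non-singleton
#' modules by default).
#'
#' @inheritParams regulatoryModularity
#' @param minModuleSize smallest module included (default 2).
#' @return a single numeric score in \eqn{[-1, 1]}.
#' @export
meanRegulatoryModularity <- function(network, modules, minModuleSize = 2L) {
    per <- suppressMessages(regulatoryModularity(network, modules))
    sizes <- table(modules)
    keep <- names(sizes)[sizes >= minModuleSize]
    if (length(keep) == 0L)
        return(0)
    mean(per[keep])
}

#' Silhouette index per module on expression distance
#'
#' Standard silhouette with gene-gene distance \eqn{(1 - \rho)/2}
#' (Pearson), averaged per module. A gene alone in its module scores 0,
#' as does a gene equidistant to its own and nearest other module.
#'
#' @param expr numeric matrix, genes x samples.
#' @param modules named integer module assignment with at least 2 modules.
#' @return named numeric vector of per-module mean silhouettes.
#' @export
silhouetteByModule <- function(expr, modules) {
    .checkExpression(expr)
    validateModuleAssignment(modules)
    if (length(unique(modules)) < 2L)
        stop("silhouette needs at least 2 modules", call. = FALSE)
    genes <- names(modules)
    d <- .expressionDistance(expr[genes, , drop = FALSE])
    mods <- sort(unique(modules))
    sil <- numeric(length(genes))
    names(sil) <- genes
    for (g in genes) {
        own <- setdiff(genes[modules == modules[[g]]], g)
        if (length(own) == 0L) {
            sil[[g]] <- 0
            next
        }
        a <- mean(d[g, own])
        b <- min(vapply(mods[mods != modules[[g]]], function(m)
            mean(d[g, genes[modules == m]]), numeric(1)))
        sil[[g]] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    vapply(split(sil, modules[genes]), mean, numeric(1))
}

#' Interaction enrichment z-score of a regulator set
#'
#' Compares the number of (undirected) interactions among a regulator set
#' with the mean and standard deviation of the count among equal-sized
#' random sets drawn from the candidate pool. Sets with \eqn{z > 1} are
#' conventionally called significantly interaction-enriched.
#'
#' @param regulatorSet character vector, a subset of
#'   \code{candidatePool}.
#' @param interactionEdges 2-column \code{data.frame} of undirected
#'   interaction pairs.
#' @param candidatePool character vector of all candidate regulators.
#' @param nRandom number of random draws (default 100).
#' @param seed integer seed.
#' @return a list with \code{z} (\code{NA} when the null sd is 0),
#'   \code{observed}, \code{nullMean} and \code{nullSd}.
#' @export
interactionEnrichmentZscore <- function(regulatorSet, interactionEdges,
                                        candidatePool, nRandom = 100L,
                                        seed = 1L) {
    if (!all(regulatorSet %in% candidatePool))
        stop("regulatorSet must be a subset of candidatePool",
             call. = FALSE)
    if (nRandom < 2L)
        stop("nRandom must be >= 2", call. = FALSE)
    a <- as.character(interactionEdges[[1L]])
    b <- as.character(interactionEdges[[2L]])
    countIn <- function(set) sum(a %in% set & b %in% set)
    observed <- countIn(regulatorSet)
    set.seed(seed)
    nullCounts <- vapply(seq_len(nRandom), function(i)
        countIn(sample(candidatePool, length(regulatorSet))), numeric(1))
    mu <- mean(nullCounts)
    sdv <- stats::sd(nullCounts)
    if (sdv == 0) {
        message("null standard deviation is 0; z-score undefined")
        return(list(z = NA_real_, observed = observed, nullMean = mu,
                    nullSd = sdv))
    }
    list(z = (observed - mu) / sdv, observed = observed, nullMean = mu,
         nullSd = sdv)
}

#' Gene-set enrichment of modules
#'
#' Hypergeometric over-representation of each gene set in each module of
#' at least \code{minModuleSize} genes, Benjamini-Hochberg adjusted across
#' all module-by-set tests.
#'
#' @param modules named integer module assignment.
#' @param genesets named list of character vectors (e.g. from
#'   [readGMT()]).
#' @param background character vector of background genes; defaults to the
#'   genes of \code{modules}.
#' @param fdrThreshold FDR cutoff recorded in the \code{significant}
#'   column (default 0.05).
#' @param minModuleSize smallest module tested (default 5).
#' @return a \code{data.frame} with columns \code{module}, \code{term},
#'   \code{p}, \code{fdr}, \code{backgroundSize}, \code{termSize},
#'   \code{moduleSize}, \code{overlap}, \code{foldEnrichment},
#'   \code{genes}, \code{significant}, ordered by \code{p}.
#' @export
genesetEnrichment <- function(modules, genesets, background = NULL,
                              fdrThreshold = 0.05, minModuleSize = 5L) {
    validateModuleAssignment(modules)
    if (is.null(background))
        background <- names(modules)
    if (length(background) == 0L)
        stop("empty background", call. = FALSE)
    sizes <- table(modules)
    good <- as.integer(names(sizes)[sizes >= minModuleSize])
    N <- length(background)
    rows <- list()
    for (m in good) {
        inMod <- intersect(names(modules)[modules == m], background)
        for (term in names(genesets)) {
            set <- intersect(genesets[[term]], background)
            if (length(set) == 0L)
                next
            hit <- intersect(inMod, set)
            k <- length(hit)
            rows[[paste0(m, ".", term)]] <- data.frame(
                module = m, term = term,
                p = hypergeometricTail(k, length(set), length(inMod), N),
                backgroundSize = N, termSize = length(set),
                moduleSize = length(inMod), overlap = k,
                foldEnrichment = if (k == 0L) 0 else
                    (k / length(inMod)) / (length(set) / N),
                genes = paste(sort(hit), collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab))
        return(data.frame(module = integer(), term = character(),
                          p = numeric(), fdr = numeric(),
                          backgroundSize = integer(), termSize = integer(),
                          moduleSize = integer(), overlap = integer(),
                          foldEnrichment = numeric(), genes = character(),
                          significant = logical()))
    rownames(tab) <- NULL
    tab$fdr <- bhAdjust(tab$p)
    tab$significant <- tab$fdr < fdrThreshold
    tab[order(tab$p), ]
}

#' Good-sized module count and gene coverage
#'
#' @param modules named integer module assignment.
#' @param minSize minimum size of a good module (default 5).
#' @return a list with \code{goodModules} (count of modules with at least
#'   \code{minSize} genes) and \code{coverage} (fraction of genes inside
#'   them).
#' @examples
#' moduleStats(setNames(rep(1:4, c(6, 5, 4, 3)), paste0("g", 1:18)))
#' @export
moduleStats <- function(modules, minSize = 5L) {
    validateModuleAssignment(modules)
    if (length(modules) == 0L)
        return(list(goodModules = 0L, coverage = 0))
    sizes <- table(modules)
    good <- sizes[sizes >= minSize]
    list(goodModules = length(good),
         coverage = sum(good) / length(modules))
}

#' Evaluate an inferred network against a ground truth
#'
#' Bundles the edge-, regulator- and module-based metrics into one report:
#' edge confusion and fold enrichment, AUPR when the inferred edges carry
#' confidences, the per-regulator target-overlap fraction, the
#' regulator-module F-score when true modules are supplied, and the
#' module diagnostics (regulatory modularity, silhouette, good-module
#' statistics) when a module assignment is supplied.
#'
#' @param inferred the inferred [RegulatoryNetwork-class].
#' @param truth the true [RegulatoryNetwork-class].
#' @param modules optional inferred module assignment.
#' @param trueModules optional true module assignment (used for the
#'   regulator-module comparison).
#' @param expr optional expression matrix for silhouette computation.
#' @param rankedEdges optional ranked edge table for AUPR; defaults to the
#'   inferred network's own confidences when present.
#' @param fdrThreshold FDR cutoff used throughout (default 0.05).
#' @return an [EvaluationReport-class].
#' @export
evaluateNetwork <- function(inferred, truth, modules = NULL,
                            trueModules = NULL, expr = NULL,
                            rankedEdges = NULL, fdrThreshold = 0.05) {
    m <- list()
    conf <- edgeConfusion(inferred, truth)
    m$truePositives <- conf$truePositives
    m$inferredEdges <- conf$inferredTotal
    m$trueEdges <- conf$trueTotal
    m$universe <- conf$universeTotal
    m$foldEnrichment <- foldEnrichment(conf)
    if (is.null(rankedEdges) && !anyNA(inferred@edges$confidence) &&
        numEdges(inferred) > 0L)
        rankedEdges <- inferred@edges
    if (!is.null(rankedEdges))
        m$aupr <- aupr(precisionRecallCurve(rankedEdges, truth))
    ov <- suppressMessages(
        regulatorTargetOverlap(inferred, truth, fdrThreshold))
    m$regulatorOverlapFraction <- ov$fraction
    m$regulatorOverlap <- ov$table
    if (!is.null(trueModules)) {
        tm <- regulatorModuleMap(truth, trueModules, fdrThreshold)
        im <- regulatorModuleMap(inferred, trueModules, fdrThreshold)
        if (nrow(tm$associations)) {
            fs <- regulatorModuleFscore(tm, im)
            m$regulatorModulePrecision <- fs$precision
            m$regulatorModuleRecall <- fs$recall
            m$regulatorModuleFscore <- fs$fscore
            m$regulatorModuleOverlapP <- fs$overlapP
        }
    }
    if (!is.null(modules)) {
        m$meanRegulatoryModularity <-
            meanRegulatoryModularity(inferred, modules)
        stats <- moduleStats(modules)
        m$goodModules <- stats$goodModules
        m$moduleCoverage <- stats$coverage
        if (!is.null(expr) && length(unique(modules)) > 1L)
            m$meanSilhouette <- mean(silhouetteByModule(expr, modules))
    }
    EvaluationReport(m)
}
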