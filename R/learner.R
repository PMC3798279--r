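#' @include core-model.R
NULL

# Greedy Markov-blanket growth for one target gene. Candidates are scanned
# in lexicographic order and the first maximum wins, so ties break
# lexicographically by regulator id. logOdds is a named vector of
# edge-prior log-odds per candidate (frozen for the sweep). Returns the
# fitted program (with per-step score gains) and its training
# log pseudo-likelihood.
.greedySelect <- function(st, target, candidates, logOdds, params) {
    candidates <- sort(setdiff(candidates, target))
    sel <- character()
    gains <- numeric()
    cur <- .fitFromStats(st, target, sel, params@ridge, params@varianceFloor)
    while (length(sel) < params@maxRegulators && length(candidates)) {
        best <- NA_character_
        bestDelta <- -Inf
        bestFit <- NULL
        for (r in candidates) {
            fit <- .fitFromStats(st, target, c(sel, r), params@ridge,
                                 params@varianceFloor)
            delta <- fit$loglik - cur$loglik + logOdds[[r]]
            if (delta > bestDelta) {
                bestDelta <- delta
                best <- r
                bestFit <- fit
            }
        }
        if (bestDelta <= params@scoreTolerance)
            break
        sel <- c(sel, best)
        gains <- c(gains, bestDelta)
        cur <- bestFit
        candidates <- setdiff(candidates, best)
    }
    list(program = GeneRegulatoryProgram(target, sel, cur$a, cur$intercept,
                                         cur$s2, gains),
         loglik = cur$loglik)
}

#' Greedy regulator selection for one gene
#'
#' Grows the gene's regulator set (initially empty) by repeatedly adding
#' the candidate with the largest improvement in
#' \eqn{\Delta}log-pseudo-likelihood plus edge-prior log-odds, stopping
#' when the best improvement is at most \code{scoreTolerance} or the
#' regulator cap is reached. Ties break lexicographically by regulator id.
#' Edge-prior features are computed against \code{prevGraph} and frozen
#' for the whole sweep.
#'
#' @param expr numeric matrix, genes x samples, no missing values.
#' @param target the target gene id (excluded from its own candidates).
#' @param candidates character vector of candidate regulator ids.
#' @param prevGraph [RegulatoryNetwork-class] of the previous iteration
#'   (empty network for the first).
#' @param modules named integer module assignment over all genes.
#' @param params a [MerlinParams-class].
#' @return a [GeneRegulatoryProgram-class]; empty candidate set gives an
#'   empty (unconditional) program.
#' @export
selectRegulatorsForGene <- function(expr, target, candidates, prevGraph,
                                    modules, params = MerlinParams()) {
    .checkExpression(expr)
    validateModuleAssignment(modules)
    candidates <- sort(setdiff(candidates, target))
    if (!all(candidates %in% rownames(expr)))
        stop("candidates must be genes of the expression matrix",
             call. = FALSE)
    st <- .expressionStats(expr)
    lo <- vapply(candidates, function(r)
        edgePriorLogOdds(edgeFeature(prevGraph, modules, r, target), params),
        numeric(1))
    .greedySelect(st, target, candidates,
                  stats::setNames(lo, candidates), params)$program
}

# ---- regulatory similarity and gene distance ----------------------------

#' Sign- and magnitude-aware regulatory similarity
#'
#' A modification of the Jaccard coefficient on two regulator-coefficient
#' maps: the numerator sums \eqn{\min(|w_i|, |w_j|)} over regulators shared
#' with matching coefficient sign, and the denominator is
#' \eqn{\|w_i\|_1 + \|w_j\|_1} minus the numerator. Two empty maps give 0.
#'
#' @param wi,wj named numeric vectors of regression coefficients (names
#'   are regulator ids).
#' @return a number in \eqn{[0, 1]}.
#' @examples
#' regulatorySimilarity(c(A = 1, B = 2), c(A = 0.5, B = -2))  # 0.1
#' @export
regulatorySimilarity <- function(wi, wj) {
    shared <- intersect(names(wi), names(wj))
    same <- shared[sign(wi[shared]) == sign(wj[shared]) &
                   wi[shared] != 0]
    num <- sum(pmin(abs(wi[same]), abs(wj[same])))
    den <- sum(abs(wi)) + sum(abs(wj)) - num
    if (den <= 0)
        return(0)
    num / den
}

.safeCor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(0)
    stats::cor(x, y)
}

#' Combined expression and regulatory distance between two genes
#'
#' The unweighted mean of an expression distance \eqn{(1 - \rho)/2}
#' (\eqn{\rho} = Pearson correlation of the two genes' expression; defined
#' as 0 for a constant gene) and a regulatory distance
#' \eqn{1 - } [regulatorySimilarity()]. Lies in \eqn{[0, 1]}.
#'
#' @param expr numeric matrix, genes x samples.
#' @param wi,wj named coefficient vectors of the two genes' programs.
#' @param geneI,geneJ the two gene ids.
#' @return a number in \eqn{[0, 1]}.
#' @export
geneDistance <- function(expr, wi, wj, geneI, geneJ) {
    .checkExpression(expr)
    rho <- .safeCor(expr[geneI, ], expr[geneJ, ])
    ((1 - rho) / 2 + (1 - regulatorySimilarity(wi, wj))) / 2
}

#' All-pairs gene distance matrix
#'
#' @param expr numeric matrix, genes x samples.
#' @param programs named list of [GeneRegulatoryProgram-class] covering the
#'   genes of \code{expr}; \code{NULL} uses expression distance only
#'   (regulatory similarity 0 for distinct genes).
#' @return symmetric matrix in \eqn{[0, 1]} with zero diagonal.
#' @export
geneDistanceMatrix <- function(expr, programs = NULL) {
    .checkExpression(expr)
    genes <- rownames(expr)
    n <- length(genes)
    rho <- suppressWarnings(stats::cor(t(expr)))
    rho[!is.finite(rho)] <- 0
    expD <- (1 - rho) / 2
    simM <- matrix(0, n, n, dimnames = list(genes, genes))
    if (!is.null(programs)) {
        w <- lapply(programs[genes], function(p)
            stats::setNames(p@coefficients, p@regulatorIds))
        for (i in seq_len(n - 1L))
            for (j in seq(i + 1L, n)) {
                s <- regulatorySimilarity(w[[i]], w[[j]])
                simM[i, j] <- s
                simM[j, i] <- s
            }
    }
    D <- (expD + (1 - simM)) / 2
    diag(D) <- 0
    D
}

# ---- threshold-stopped average-linkage clustering -----------------------

#' Agglomerative module clustering with a stop threshold
#'
#' Average-linkage (UPGMA) agglomeration that merges the closest pair of
#' clusters while the smallest inter-cluster distance is at most
#' \code{threshold}, and halts as soon as it exceeds it, so the data --
#' not a preset k -- determine the number of modules. Ties are broken
#' lexicographically by the smallest gene id in each cluster, making the
#' result deterministic. Module ids are dense from 1, ordered by each
#' module's lexicographically smallest member.
#'
#' @param dist symmetric numeric matrix of distances in \eqn{[0, 1]} with
#'   gene dimnames and zero diagonal.
#' @param threshold stop height in (0, 1).
#' @return named integer vector gene -> module id.
#' @examples
#' d <- matrix(0.9, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' d["a", "b"] <- d["b", "a"] <- 0.1; diag(d) <- 0
#' hierarchicalCluster(d, 0.5)
#' @export
hierarchicalCluster <- function(dist, threshold) {
    if (!is.matrix(dist) || is.null(rownames(dist)))
        stop("dist must be a matrix with gene dimnames", call. = FALSE)
    if (max(abs(dist - t(dist))) > 1e-12 || any(diag(dist) != 0))
        stop("dist must be symmetric with zero diagonal", call. = FALSE)
    genes <- rownames(dist)
    n <- length(genes)
    D <- dist
    diag(D) <- Inf
    active <- rep(TRUE, n)
    size <- rep(1L, n)
    members <- as.list(genes)
    label <- genes
    while (sum(active) > 1L) {
        idx <- which(active)
        sub <- D[idx, idx, drop = FALSE]
        mn <- min(sub)
        if (mn > threshold)
            break
        hits <- which(sub == mn, arr.ind = TRUE)
        hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
        la <- label[idx[hits[, 1L]]]
        lb <- label[idx[hits[, 2L]]]
        pick <- order(pmin(la, lb), pmax(la, lb))[1L]
        i <- idx[hits[pick, 1L]]
        j <- idx[hits[pick, 2L]]
        if (label[j] < label[i]) { k <- i; i <- j; j <- k }
        merged <- (size[i] * D[i, ] + size[j] * D[j, ]) /
            (size[i] + size[j])
        D[i, ] <- merged
        D[, i] <- merged
        D[i, i] <- Inf
        D[j, ] <- Inf
        D[, j] <- Inf
        size[i] <- size[i] + size[j]
        members[[i]] <- c(members[[i]], members[[j]])
        active[j] <- FALSE
    }
    clusters <- members[active]
    clusters <- clusters[order(vapply(clusters, min, character(1)))]
    out <- integer(n)
    names(out) <- genes
    for (k in seq_along(clusters))
        out[clusters[[k]]] <- k
    out
}

# Expression-only distance (1 - Pearson)/2, with constant genes treated as
# uncorrelated.
.expressionDistance <- function(expr) {
    rho <- suppressWarnings(stats::cor(t(expr)))
    rho[!is.finite(rho)] <- 0
    d <- (1 - rho) / 2
    diag(d) <- 0
    d
}

# Partition equality up to module relabelling.
.samePartition <- function(a, b) {
    a <- a[sort(names(a))]
    b <- b[sort(names(b))]
    if (!identical(names(a), names(b)))
        return(FALSE)
    identical(match(a, unique(a)), match(b, unique(b)))
}

.edgeKey <- function(e) sort(paste0(e$regulator, "\r", e$target))

# ---- the iterative learner ----------------------------------------------

#' Random perturbed initial module assignment
#'
#' Builds an initial module assignment by average-linkage clustering of the
#' expression distance \eqn{(1 - \rho)/2} computed on a random subsample of
#' the samples. Different seeds give the different random initial
#' clusterings used for consensus over restarts.
#'
#' @param expr numeric matrix, genes x samples.
#' @param clusterThreshold stop height for the clustering.
#' @param seed integer seed.
#' @param sampleFraction fraction of samples used (default 0.9).
#' @return named integer vector gene -> module id.
#' @export
randomInitialModules <- function(expr, clusterThreshold = 0.6, seed = 1L,
                                 sampleFraction = 0.9) {
    .checkExpression(expr)
    set.seed(seed)
    keep <- sort(sample.int(ncol(expr),
                            max(2L, round(sampleFraction * ncol(expr)))))
    sub <- expr[, keep, drop = FALSE]
    hierarchicalCluster(.expressionDistance(sub), clusterThreshold)
}

#' Infer a modular regulatory network
#'
#' The main learner. Starting from an initial module assignment (by
#' default, clustering of the expression distance alone), it alternates
#' (a) greedy regulator selection for every gene -- in lexicographic gene
#' order -- under the logistic module prior with features frozen against
#' the previous iteration's graph, and (b) re-clustering of genes using the
#' combined expression/regulatory distance. It stops when network and
#' modules are unchanged, when the score improvement falls below
#' \code{scoreTolerance * nGenes}, or after \code{maxIterations}. An
#' iteration whose score drops below the last accepted score is rejected
#' and the previous model returned, so the recorded score trajectory is
#' non-decreasing.
#'
#' @param expr numeric matrix, genes x samples, preprocessed (no missing
#'   values).
#' @param candidates character vector of candidate regulator gene ids.
#' @param initModules optional named integer module assignment covering all
#'   genes; an error is raised if genes are unassigned.
#' @param params a [MerlinParams-class].
#' @return a [MerlinModel-class].
#' @examples
#' truth <- generateModularNetwork(30, nModules = 3, seed = 1)
#' expr <- simulateKnockoutExpression(truth, seed = 1)
#' fit <- runMerlin(expr, regulators(truth),
#'                  params = MerlinParams(maxIterations = 3L))
#' fit
#' @export
runMerlin <- function(expr, candidates, initModules = NULL,
                      params = MerlinParams()) {
    .checkExpression(expr)
    genes <- rownames(expr)
    candidates <- sort(unique(candidates))
    if (!all(candidates %in% genes))
        stop("candidates must be genes of the expression matrix",
             call. = FALSE)
    if (is.null(initModules)) {
        initModules <- hierarchicalCluster(.expressionDistance(expr),
                                           params@clusterThreshold)
    } else {
        validateModuleAssignment(initModules)
        un <- setdiff(genes, names(initModules))
        if (length(un))
            stop("genes unassigned in initModules: ",
                 paste(utils::head(un, 5L), collapse = ", "), call. = FALSE)
        initModules <- initModules[genes]
        names(initModules) <- genes
    }
    st <- .expressionStats(expr)
    order <- sort(genes)
    modulesCur <- initModules
    prevGraph <- RegulatoryNetwork()
    accNetwork <- prevGraph
    accPrograms <- list()
    accModules <- modulesCur
    traj <- numeric()
    converged <- FALSE
    nIter <- 0L
    runTol <- params@scoreTolerance * length(genes)

    for (iter in seq_len(params@maxIterations)) {
        f <- .featureMatrix(prevGraph, modulesCur, candidates)
        lo <- params@sparsity + params@moduleWeight * f
        self <- outer(candidates, genes, "==")
        basePrior <- sum(.logOneMinusSigmoid(lo[!self]))
        progs <- vector("list", length(genes))
        names(progs) <- order
        llSum <- 0
        edgeLogOdds <- 0
        rows <- vector("list", length(genes))
        for (gi in seq_along(order)) {
            g <- order[[gi]]
            res <- .greedySelect(st, g, candidates,
                                 stats::setNames(lo[, g], candidates),
                                 params)
            p <- res$program
            progs[[g]] <- p
            llSum <- llSum + res$loglik
            if (length(p@regulatorIds)) {
                edgeLogOdds <- edgeLogOdds + sum(lo[p@regulatorIds, g])
                rows[[gi]] <- data.frame(regulator = p@regulatorIds,
                                         target = g,
                                         weight = p@coefficients,
                                         confidence = NA_real_,
                                         stringsAsFactors = FALSE)
            }
        }
        score <- llSum + basePrior + edgeLogOdds
        newNetwork <- RegulatoryNetwork(do.call(
            rbind, c(rows[!vapply(rows, is.null, logical(1))],
                     list(data.frame(regulator = character(),
                                     target = character(),
                                     weight = numeric(),
                                     confidence = numeric())))))
        if (length(traj) && score < utils::tail(traj, 1L) - 1e-9) {
            converged <- TRUE
            break
        }
        traj <- c(traj, score)
        nIter <- iter
        accNetwork <- newNetwork
        accPrograms <- progs
        newModules <- hierarchicalCluster(geneDistanceMatrix(expr, progs),
                                          params@clusterThreshold)
        accModules <- newModules
        stable <- identical(.edgeKey(newNetwork@edges),
                            .edgeKey(prevGraph@edges)) &&
            .samePartition(newModules, modulesCur)
        plateau <- length(traj) > 1L &&
            (traj[length(traj)] - traj[length(traj) - 1L]) < runTol
        if (stable || plateau) {
            converged <- TRUE
            break
        }
        modulesCur <- newModules
        prevGraph <- newNetwork
    }
    new("MerlinModel", network = accNetwork, programs = accPrograms,
        modules = accModules, scoreTrajectory = traj, params = params,
        converged = converged, iterations = nIter)
}

#' Per-gene greedy regression baseline
#'
#' The special case of the learner with the module prior switched off: a
#' single greedy regulator-selection sweep per gene under the bare
#' sparsity prior, with no module feedback. [runMerlin()] with
#' \code{moduleWeight = 0} produces exactly this network.
#'
#' @inheritParams runMerlin
#' @return a [MerlinModel-class] with one accepted iteration.
#' @export
linearRegressionNetwork <- function(expr, candidates,
                                    params = MerlinParams()) {
    .checkExpression(expr)
    genes <- rownames(expr)
    candidates <- sort(unique(candidates))
    if (!all(candidates %in% genes))
        stop("candidates must be genes of the expression matrix",
             call. = FALSE)
    st <- .expressionStats(expr)
    lo <- stats::setNames(rep(params@sparsity, length(candidates)),
                          candidates)
    order <- sort(genes)
    progs <- list()
    llSum <- 0
    rows <- list()
    for (g in order) {
        res <- .greedySelect(st, g, candidates, lo, params)
        p <- res$program
        progs[[g]] <- p
        llSum <- llSum + res$loglik
        if (length(p@regulatorIds))
            rows[[g]] <- data.frame(regulator = p@regulatorIds, target = g,
                                    weight = p@coefficients,
                                    confidence = NA_real_,
                                    stringsAsFactors = FALSE)
    }
    nPairs <- sum(outer(candidates, genes, "!="))
    nEdges <- sum(vapply(progs, function(p) length(p@regulatorIds),
                         integer(1)))
    score <- llSum + nPairs * .logOneMinusSigmoid(params@sparsity) +
        nEdges * params@sparsity
    net <- RegulatoryNetwork(do.call(
        rbind, c(rows, list(data.frame(regulator = character(),
                                       target = character(),
                                       weight = numeric(),
                                       confidence = numeric())))))
    mods <- hierarchicalCluster(geneDistanceMatrix(expr, progs),
                                params@clusterThreshold)
    new("MerlinModel", network = net, programs = progs, modules = mods,
        scoreTrajectory = score, params = params, converged = TRUE,
        iterations = 1L)
}

#' Ranked edge table of a fitted model
#'
#' Edges of the inferred network ranked by the total-score improvement
#' recorded when the greedy selection added them (larger = more
#' confident), as needed for precision-recall analysis of a single run.
#' Stability selection ([stabilityConfidence()]) provides the
#' subset-support alternative.
#'
#' @param model a [MerlinModel-class].
#' @return a \code{data.frame} with columns \code{regulator},
#'   \code{target} and \code{confidence}, ordered by decreasing
#'   confidence.
#' @export
rankedEdges <- function(model) {
    rows <- lapply(programs(model), function(p) {
        if (!length(p@regulatorIds))
            return(NULL)
        gains <- if (length(p@scoreGains)) p@scoreGains
                 else abs(p@coefficients)
        data.frame(regulator = p@regulatorIds, target = p@targetId,
                   confidence = gains, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(data.frame(
        regulator = character(), target = character(),
        confidence = numeric()))))
    rownames(out) <- NULL
    out[order(-out$confidence), , drop = FALSE]
}

# ---- consensus and stability --------------------------------------------

#' Consensus network over runs
#'
#' Keeps the edges present in at least \code{minSupport} of the input
#' networks (e.g. 3 of 5, or all 5, random initializations / folds).
#' Retained edges get confidence = support fraction and weight = mean
#' weight over the supporting runs.
#'
#' @param runs list of [RegulatoryNetwork-class] objects.
#' @param minSupport minimum number of runs an edge must appear in.
#' @return a [RegulatoryNetwork-class].
#' @export
consensusNetwork <- function(runs, minSupport) {
    if (length(runs) < 1L)
        stop("need at least one run", call. = FALSE)
    if (minSupport > length(runs)) {
        warning("minSupport exceeds the number of runs; empty network")
        return(RegulatoryNetwork())
    }
    all <- do.call(rbind, lapply(runs, function(x) x@edges))
    if (is.null(all) || nrow(all) == 0L)
        return(RegulatoryNetwork())
    key <- paste0(all$regulator, "\r", all$target)
    support <- table(key)
    keep <- names(support)[support >= minSupport]
    if (length(keep) == 0L)
        return(RegulatoryNetwork())
    keep <- sort(keep)
    sel <- all[key %in% keep, , drop = FALSE]
    selKey <- paste0(sel$regulator, "\r", sel$target)
    weight <- vapply(keep, function(k)
        mean(sel$weight[selKey == k], na.rm = TRUE), numeric(1))
    parts <- strsplit(keep, "\r", fixed = TRUE)
    RegulatoryNetwork(regulator = vapply(parts, `[`, character(1), 1L),
                      target = vapply(parts, `[`, character(1), 2L),
                      weight = unname(weight),
                      confidence = as.numeric(support[keep]) / length(runs))
}

#' Edge confidence from random data subsets
#'
#' Re-runs the learner on random subsets of the samples and scores each
#' edge by the fraction of subsets in which it was inferred, giving the
#' continuously varying confidence required for precision-recall analysis.
#'
#' @param expr numeric matrix, genes x samples.
#' @param candidates candidate regulator ids.
#' @param params a [MerlinParams-class].
#' @param nSubsets number of random subsets (the reference protocol uses
#'   100).
#' @param subsetFraction fraction of samples per subset, in (0, 1].
#' @param seed integer seed making the subsets reproducible.
#' @return a [RegulatoryNetwork-class] with confidences in \eqn{[0, 1]}.
#' @export
stabilityConfidence <- function(expr, candidates, params = MerlinParams(),
                                nSubsets = 100L, subsetFraction = 0.5,
                                seed = params@seed) {
    .checkExpression(expr)
    if (nSubsets < 1L)
        stop("nSubsets must be >= 1", call. = FALSE)
    if (subsetFraction <= 0 || subsetFraction > 1)
        stop("subsetFraction must lie in (0, 1]", call. = FALSE)
    set.seed(seed)
    subSeeds <- sample.int(.Machine$integer.max - 1L, nSubsets)
    nets <- vector("list", nSubsets)
    for (s in seq_len(nSubsets)) {
        set.seed(subSeeds[[s]])
        keep <- sort(sample.int(ncol(expr),
                                max(2L, round(subsetFraction * ncol(expr)))))
        fit <- runMerlin(expr[, keep, drop = FALSE], candidates,
                         params = params)
        nets[[s]] <- network(fit)
    }
    consensusNetwork(nets, minSupport = 1L)
}
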