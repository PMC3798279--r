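#' @include AllClasses.R
NULL

#' Generate a modular ground-truth regulatory network
#'
#' Genes are partitioned uniformly at random into modules; a fixed
#' fraction of genes per module is designated as regulators (allocated
#' proportionally to module size). Every gene then draws an in-degree of
#' \code{1 + Poisson(meanInDegree - 1)} and, for each incoming edge, the
#' source regulator comes from the gene's own module with probability
#' \code{q} and from another module otherwise -- so \code{q} directly
#' controls the regulatory modularity of the truth. Interaction strengths
#' are signed, drawn uniformly from \eqn{\pm[0.5, 1.5]}; basal levels are
#' standard normal.
#'
#' When the preferred pool is exhausted (small modules, high in-degree,
#' or a target that is its own module's sole regulator) the edge falls
#' back to the other pool; a module that contains genes but no regulator
#' at all is an error when \code{q = 1}.
#'
#' @param nGenes number of genes.
#' @param regulatorFraction fraction of genes that are candidate
#'   regulators, in (0, 1). The default 0.11 gives 11 regulators at 100
#'   genes (the NET100 design).
#' @param nModules number of modules; default targets roughly 30 genes
#'   (3-4 regulators) per module.
#' @param meanInDegree mean number of regulators per target gene
#'   (default 1.75, desk-scale benchmark connectivity).
#' @param q within-module edge probability in \eqn{[0, 1]}.
#' @param seed integer seed; identical seeds give identical truths.
#' @return a [GroundTruth-class].
#' @examples
#' truth <- generateModularNetwork(100, seed = 1)
#' length(regulators(truth))  # 11
#' @export
generateModularNetwork <- function(nGenes, regulatorFraction = 0.11,
                                   nModules = max(2L, round(nGenes / 30)),
                                   meanInDegree = 1.75, q = 0.8,
                                   seed = 1L) {
    if (regulatorFraction <= 0 || regulatorFraction >= 1)
        stop("regulatorFraction must lie in (0, 1)", call. = FALSE)
    if (nModules > nGenes)
        stop("nModules cannot exceed nGenes", call. = FALSE)
    if (q < 0 || q > 1)
        stop("q must lie in [0, 1]", call. = FALSE)
    if (meanInDegree < 1)
        stop("meanInDegree must be >= 1", call. = FALSE)
    set.seed(seed)
    genes <- sprintf("G%0*d", nchar(as.character(nGenes)), seq_len(nGenes))
    mod <- sample(rep_len(seq_len(nModules), nGenes))
    names(mod) <- genes

    nReg <- max(1L, round(regulatorFraction * nGenes))
    sizes <- tabulate(mod, nModules)
    alloc <- floor(nReg * sizes / nGenes)
    shortfall <- nReg - sum(alloc)
    if (shortfall > 0) {
        frac <- nReg * sizes / nGenes - alloc
        extra <- order(-frac, seq_len(nModules))[seq_len(shortfall)]
        alloc[extra] <- alloc[extra] + 1L
    }
    if (q == 1 && any(alloc == 0L & sizes > 0L))
        stop("q = 1 requires every module to contain a regulator; ",
             "module(s) without one: ",
             paste(which(alloc == 0L & sizes > 0L), collapse = ", "),
             call. = FALSE)
    regs <- character()
    for (m in seq_len(nModules)) {
        inMod <- genes[mod == m]
        if (alloc[m] > 0L)
            regs <- c(regs, sort(sample(inMod, alloc[m])))
    }
    regs <- sort(regs)

    rows <- vector("list", nGenes)
    for (gi in seq_len(nGenes)) {
        g <- genes[[gi]]
        own <- setdiff(regs[mod[regs] == mod[[g]]], g)
        other <- setdiff(regs, c(own, g))
        k <- min(1L + stats::rpois(1L, meanInDegree - 1),
                 length(own) + length(other))
        src <- character(k)
        for (e in seq_len(k)) {
            within <- stats::runif(1L) < q
            pool <- if (within) own else other
            if (length(pool) == 0L)
                pool <- if (within) other else own
            pick <- pool[[sample.int(length(pool), 1L)]]
            src[[e]] <- pick
            own <- setdiff(own, pick)
            other <- setdiff(other, pick)
        }
        strength <- sample(c(-1, 1), k, replace = TRUE) *
            stats::runif(k, 0.5, 1.5)
        rows[[gi]] <- data.frame(regulator = src, target = g,
                                 weight = strength,
                                 confidence = NA_real_,
                                 stringsAsFactors = FALSE)
    }
    net <- RegulatoryNetwork(do.call(rbind, rows))
    basal <- stats::rnorm(nGenes)
    names(basal) <- genes
    new("GroundTruth", network = net, modules = mod, regulators = regs,
        basal = basal, q = q)
}

#' Simulate steady-state knockout expression
#'
#' Emulates the classic benchmark design of knocking out every gene, one
#' at a time, and recording the steady state of the system: one expression
#' sample per gene. Dynamics are a linear-Gaussian stand-in for the full
#' nonlinear SDE engine: the interaction matrix is rescaled to spectral
#' radius 0.8 and each sample solves the clamped linear steady state
#' \eqn{x = b + Wx} with the knocked-out gene fixed at
#' \code{knockoutValue} and removed from its own update; Gaussian noise of
#' sd \code{noiseSd} perturbs the basal levels per sample.
#'
#' @param truth a [GroundTruth-class].
#' @param noiseSd standard deviation of the basal noise (default 0.1).
#' @param knockoutValue clamped value of the knocked-out gene (default -3,
#'   a strong depletion on log scale).
#' @param seed integer seed; identical seeds give identical matrices.
#' @return numeric matrix, genes x samples, sample \code{KO_<gene>} having
#'   that gene clamped.
#' @export
simulateKnockoutExpression <- function(truth, noiseSd = 0.1,
                                       knockoutValue = -3, seed = 1L) {
    if (noiseSd < 0)
        stop("noiseSd must be >= 0", call. = FALSE)
    genes <- names(truth@modules)
    n <- length(genes)
    W <- matrix(0, n, n, dimnames = list(genes, genes))
    e <- truth@network@edges
    if (nrow(e))
        W[cbind(match(e$target, genes), match(e$regulator, genes))] <-
            e$weight
    sr <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (sr > 0)
        W <- W * (0.8 / sr)
    if (max(Mod(eigen(W, only.values = TRUE)$values)) >= 1)
        stop("non-contractive system after rescaling", call. = FALSE)
    set.seed(seed)
    X <- matrix(0, n, n, dimnames = list(genes, paste0("KO_", genes)))
    for (g in seq_len(n)) {
        b <- truth@basal + if (noiseSd > 0) stats::rnorm(n, 0, noiseSd)
                           else 0
        idx <- setdiff(seq_len(n), g)
        A <- diag(n - 1L) - W[idx, idx]
        rhs <- b[idx] + W[idx, g] * knockoutValue
        sol <- tryCatch(solve(A, rhs), error = function(err)
            stop("non-contractive system after rescaling: ",
                 conditionMessage(err), call. = FALSE))
        X[idx, g] <- sol
        X[g, g] <- knockoutValue
    }
    X
}
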