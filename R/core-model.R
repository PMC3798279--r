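#' @include AllClasses.R
NULL

# Expression matrices are plain numeric matrices, genes x samples, with
# rownames = gene ids and colnames = sample ids (the standard assay
# orientation).

.checkExpression <- function(expr, requireComplete = TRUE) {
    if (!is.matrix(expr) || !is.numeric(expr))
        stop("expression must be a numeric matrix (genes x samples)",
             call. = FALSE)
    if (is.null(rownames(expr)) || is.null(colnames(expr)))
        stop("expression matrix must have gene rownames and sample colnames",
             call. = FALSE)
    if (anyDuplicated(rownames(expr)))
        stop("duplicate gene ids in expression matrix", call. = FALSE)
    if (requireComplete && anyNA(expr))
        stop("expression matrix contains missing values; impute first",
             call. = FALSE)
    invisible(expr)
}

# Sufficient statistics reused by every conditional-Gaussian fit: per-gene
# means and the maximum-likelihood (divide by m) covariance.
.expressionStats <- function(expr) {
    m <- ncol(expr)
    mu <- rowMeans(expr)
    xc <- expr - mu
    list(mu = mu, S = tcrossprod(xc) / m, m = m, genes = rownames(expr))
}

# Conditional Gaussian of gene ti given genes ri from joint-Gaussian
# sufficient statistics. Returns coefficients a = (S_RR + ridge I)^-1 S_RT,
# intercept mu_T - a' mu_R, the floored conditional variance, and the
# training log pseudo-likelihood in closed form (residual sum of squares
# equals m * unfloored conditional variance on the training data).
.fitFromStats <- function(st, ti, ri, ridge, floor) {
    if (length(ri) == 0L) {
        a <- numeric()
        intercept <- st$mu[[ti]]
        s2ml <- st$S[ti, ti]
    } else {
        Srr <- st$S[ri, ri, drop = FALSE]
        if (ridge > 0)
            diag(Srr) <- diag(Srr) + ridge
        Srt <- st$S[ri, ti]
        a <- tryCatch(drop(solve(Srr, Srt)), error = function(e)
            stop("singular regulator covariance (use ridge > 0): ",
                 conditionMessage(e), call. = FALSE))
        intercept <- st$mu[[ti]] - sum(a * st$mu[ri])
        # residual variance of the fitted coefficients; equals the
        # Schur complement S_TT - S_TR S_RR^-1 S_RT when ridge = 0
        s2ml <- st$S[ti, ti] - 2 * sum(Srt * a) +
            drop(crossprod(a, st$S[ri, ri, drop = FALSE] %*% a))
    }
    s2ml <- max(s2ml, 0)
    s2 <- max(s2ml, floor)
    ll <- -st$m / 2 * log(2 * pi * s2) - st$m * s2ml / (2 * s2)
    list(a = a, intercept = intercept, s2 = s2, loglik = ll)
}

#' Fit the conditional Gaussian of a target gene given regulators
#'
#' Estimates the joint \eqn{(k+1)}-dimensional Gaussian of the target and
#' its \eqn{k} regulators by maximum likelihood (covariance divided by the
#' sample count) and converts it to the conditional distribution of the
#' target: coefficients \eqn{a = \Sigma_{RR}^{-1}\Sigma_{RT}}, intercept
#' \eqn{\mu_T - a^\top\mu_R}, and conditional variance
#' \eqn{\Sigma_{TT} - \Sigma_{TR}\Sigma_{RR}^{-1}\Sigma_{RT}} floored at
#' \code{varianceFloor}. A ridge is added to the diagonal of
#' \eqn{\Sigma_{RR}} before inversion. On full-rank data with
#' \code{ridge = 0} the coefficients equal ordinary least squares.
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param target target gene id.
#' @param regulators ordered character vector of regulator gene ids (may be
#'   empty, giving the unconditional Gaussian).
#' @param ridge non-negative ridge on the regulator covariance diagonal.
#' @param varianceFloor positive floor on the conditional variance.
#' @return a [GeneRegulatoryProgram-class].
#' @examples
#' x <- rbind(A = c(1, 2, 3, 4, 5), B = c(2, 4, 6, 8, 10) + 1)
#' colnames(x) <- paste0("s", 1:5)
#' coef(fitConditionalGaussian(x, "B", "A", ridge = 0))
#' @export
fitConditionalGaussian <- function(expr, target, regulators = character(),
                                   ridge = 1e-6, varianceFloor = 1e-8) {
    .checkExpression(expr)
    if (ncol(expr) < 2L)
        stop("need at least 2 samples", call. = FALSE)
    missing <- setdiff(c(target, regulators), rownames(expr))
    if (length(missing))
        stop("gene(s) not found in expression matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)
    if (target %in% regulators)
        stop("target cannot be its own regulator", call. = FALSE)
    use <- unique(c(target, regulators))
    st <- .expressionStats(expr[use, , drop = FALSE])
    fit <- .fitFromStats(st, target, regulators, ridge, varianceFloor)
    GeneRegulatoryProgram(targetId = target, regulatorIds = regulators,
                          coefficients = fit$a, intercept = fit$intercept,
                          conditionalVariance = fit$s2)
}

#' Log pseudo-likelihood of a gene's program
#'
#' Sum over samples of the log Gaussian density of the target given its
#' regulators: \eqn{\sum_d \log N(x_T^d \mid a^\top x_R^d + b, \sigma^2)}.
#' The product of these per-gene terms over all genes is the
#' pseudo-likelihood of the (possibly cyclic) dependency network.
#'
#' @param expr numeric matrix, genes x samples.
#' @param program a [GeneRegulatoryProgram-class] fitted on a compatible
#'   gene set.
#' @param varianceFloor the floor that must have been applied at fit time;
#'   programs with smaller conditional variance are rejected.
#' @return a single numeric log-likelihood.
#' @export
logPseudoLikelihood <- function(expr, program, varianceFloor = 1e-8) {
    .checkExpression(expr)
    if (program@conditionalVariance < varianceFloor)
        stop("conditional variance below floor; refit the program",
             call. = FALSE)
    pred <- predictExpression(program,
                              expr[program@regulatorIds, , drop = FALSE])
    obs <- expr[program@targetId, ]
    sum(stats::dnorm(obs, mean = pred,
                     sd = sqrt(program@conditionalVariance), log = TRUE))
}

#' Predict a target gene's expression from its program
#'
#' Linear prediction \code{intercept + coefficients' values}. Accepts
#' either a vector with one value per regulator (returning a scalar) or a
#' regulators x samples matrix (returning one prediction per sample).
#'
#' @param program a [GeneRegulatoryProgram-class].
#' @param regulatorValues numeric vector aligned to
#'   \code{regulatorIds(program)}, or a matrix with those rows.
#' @return numeric predictions.
#' @examples
#' p <- merlin:::GeneRegulatoryProgram("G", c("A", "B"), c(1, -2), 0.5, 1)
#' predictExpression(p, c(1, 1))
#' @export
predictExpression <- function(program, regulatorValues) {
    k <- length(program@regulatorIds)
    if (is.matrix(regulatorValues)) {
        if (nrow(regulatorValues) != k)
            stop("regulatorValues rows must match the program's regulators",
                 call. = FALSE)
        return(program@intercept +
               drop(crossprod(regulatorValues, program@coefficients)))
    }
    if (length(regulatorValues) != k)
        stop("regulatorValues length must match the program's regulators",
             call. = FALSE)
    program@intercept + sum(program@coefficients * regulatorValues)
}

# ---- module feature and logistic graph prior ----------------------------

#' Module feature of a candidate edge
#'
#' The fraction of a regulator's predicted targets -- in the graph from the
#' previous learning iteration -- that lie in the candidate target gene's
#' module. A regulator with no predicted targets yields 0 (the 0/0
#' convention), so it receives only the sparsity term of the prior.
#'
#' @param prevGraph the [RegulatoryNetwork-class] of the previous
#'   iteration.
#' @param modules named integer module assignment covering all genes.
#' @param regulator,target gene ids of the candidate edge.
#' @return a number in \eqn{[0, 1]}.
#' @export
edgeFeature <- function(prevGraph, modules, regulator, target) {
    validateModuleAssignment(modules)
    tg <- targetsOf(prevGraph, regulator)
    if (length(tg) == 0L)
        return(0)
    mean(modules[tg] == modules[[target]])
}

# All-pairs feature matrix (regulators x genes) against a previous graph;
# the vectorized form of edgeFeature used by the learner.
.featureMatrix <- function(prevGraph, modules, regulatorIds) {
    genes <- names(modules)
    k <- length(unique(modules))
    f <- matrix(0, length(regulatorIds), length(genes),
                dimnames = list(regulatorIds, genes))
    e <- prevGraph@edges
    if (nrow(e) == 0L)
        return(f)
    for (r in intersect(regulatorIds, unique(e$regulator))) {
        tg <- e$target[e$regulator == r]
        cnt <- tabulate(modules[tg], nbins = k)
        f[r, ] <- cnt[modules[genes]] / length(tg)
    }
    f
}

#' Log-odds of an edge under the logistic structure prior
#'
#' The prior probability that an edge is present is the logistic transform
#' of \code{sparsity + moduleWeight * feature}. This function returns the
#' log-odds itself, which is exactly the change in the graph-prior log
#' score caused by adding the edge (the present-term replaces the
#' absent-term). With \code{moduleWeight = 0} every edge gets the bare
#' sparsity offset and the method reduces to per-gene regression.
#'
#' @param feature numeric feature value(s) in \eqn{[0, 1]} (see
#'   [edgeFeature()]).
#' @param params a [MerlinParams-class] (only \code{sparsity} and
#'   \code{moduleWeight} are used).
#' @return numeric log-odds, vectorized over \code{feature}.
#' @examples
#' p <- MerlinParams(sparsity = -5, moduleWeight = 4)
#' plogis(edgePriorLogOdds(0.5, p))  # edge-present probability
#' @export
edgePriorLogOdds <- function(feature, params) {
    params@sparsity + params@moduleWeight * feature
}

# Numerically stable log P(present) and log P(absent) for log-odds x.
.logSigmoid <- function(x) -log1p(exp(-x))
.logOneMinusSigmoid <- function(x) -log1p(exp(x))

#' Log score of the graph under the structure prior
#'
#' Sum over all candidate (regulator, target) pairs -- excluding
#' self-pairs -- of the log prior probability that the pair's edge is
#' present (for edges in \code{graph}) or absent (otherwise). Edge features
#' are computed against \code{prevGraph}, the graph frozen at the start of
#' the current learning iteration. The score decomposes as a per-target
#' sum, and adding one edge changes it by exactly that edge's
#' [edgePriorLogOdds()].
#'
#' @param graph the [RegulatoryNetwork-class] being scored.
#' @param prevGraph the frozen previous-iteration graph defining features.
#' @param modules named integer module assignment over all genes.
#' @param regulatorIds character vector of candidate regulators.
#' @param params a [MerlinParams-class].
#' @return a single numeric log score.
#' @export
graphPriorLogScore <- function(graph, prevGraph, modules, regulatorIds,
                               params) {
    validateModuleAssignment(modules)
    genes <- names(modules)
    f <- .featureMatrix(prevGraph, modules, regulatorIds)
    lo <- params@sparsity + params@moduleWeight * f
    present <- matrix(FALSE, length(regulatorIds), length(genes),
                      dimnames = dimnames(f))
    e <- graph@edges
    if (nrow(e)) {
        if (!all(e$regulator %in% regulatorIds))
            stop("graph contains edges from non-candidate regulators",
                 call. = FALSE)
        present[cbind(match(e$regulator, regulatorIds),
                      match(e$target, genes))] <- TRUE
    }
    self <- outer(regulatorIds, genes, "==")
    sum(.logSigmoid(lo[present & !self])) +
        sum(.logOneMinusSigmoid(lo[!present & !self]))
}

#' Total model score: pseudo-likelihood plus graph prior
#'
#' The score maximized by the learner: the sum over genes of the log
#' pseudo-likelihood of each gene's program, plus the log graph prior. The
#' module prior itself is uniform and contributes nothing. The score is
#' additive over genes.
#'
#' @param expr numeric matrix, genes x samples.
#' @param graph the scored [RegulatoryNetwork-class].
#' @param programs named list of [GeneRegulatoryProgram-class], one per
#'   gene of \code{expr}, consistent with \code{graph}.
#' @param prevGraph frozen previous-iteration graph for features.
#' @param modules named integer module assignment.
#' @param regulatorIds candidate regulators.
#' @param params a [MerlinParams-class].
#' @return a single numeric score.
#' @export
totalScore <- function(expr, graph, programs, prevGraph, modules,
                       regulatorIds, params) {
    .checkExpression(expr)
    e <- graph@edges
    for (p in programs) {
        inGraph <- sort(e$regulator[e$target == p@targetId])
        if (!identical(inGraph, sort(p@regulatorIds)))
            stop("graph and programs are inconsistent for gene ",
                 p@targetId, call. = FALSE)
    }
    ll <- sum(vapply(programs, function(p)
        logPseudoLikelihood(expr, p, params@varianceFloor), numeric(1)))
    ll + graphPriorLogScore(graph, prevGraph, modules, regulatorIds, params)
}
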