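#' @import methods
NULL

.EDGE_COLUMNS <- c("regulator", "target", "weight", "confidence")

#' Directed weighted regulatory network
#'
#' A set of directed edges from regulators to target genes. Edges carry the
#' regression coefficient of the regulator in the target's conditional
#' Gaussian as \code{weight}, and optionally a \code{confidence} in
#' \eqn{[0, 1]} (e.g. the support fraction from stability selection or a
#' consensus over random restarts). Cycles are permitted -- the model is a
#' dependency network, not a DAG -- but self-edges are not.
#'
#' @slot edges a \code{data.frame} with character columns \code{regulator}
#'   and \code{target} and numeric columns \code{weight} and
#'   \code{confidence} (\code{NA} when no confidence has been assigned).
#'
#' @seealso [RegulatoryNetwork()] for the constructor, [edges()],
#'   [regulators()], [targetsOf()], [numEdges()].
#' @export
setClass("RegulatoryNetwork", slots = c(edges = "data.frame"))

setValidity("RegulatoryNetwork", function(object) {
    e <- object@edges
    if (!all(.EDGE_COLUMNS %in% names(e)))
        return(sprintf("edges must have columns %s",
                       paste(.EDGE_COLUMNS, collapse = ", ")))
    if (nrow(e) == 0L)
        return(TRUE)
    if (!is.character(e$regulator) || !is.character(e$target))
        return("regulator and target must be character")
    if (!is.numeric(e$weight) || !is.numeric(e$confidence))
        return("weight and confidence must be numeric")
    if (any(e$regulator == e$target))
        return("self-edges are not allowed")
    if (anyDuplicated(paste0(e$regulator, "\r", e$target)))
        return("duplicate (regulator, target) pairs")
    conf <- e$confidence[!is.na(e$confidence)]
    if (length(conf) && (any(conf < 0) || any(conf > 1)))
        return("confidence must lie in [0, 1]")
    TRUE
})

#' Construct a RegulatoryNetwork
#'
#' @param regulator character vector of regulator gene ids, or a
#'   \code{data.frame} with columns \code{regulator}, \code{target} and
#'   optionally \code{weight} and \code{confidence}.
#' @param target character vector of target gene ids.
#' @param weight numeric edge weights (regression coefficients); recycled
#'   \code{NA} by default.
#' @param confidence numeric confidences in \eqn{[0, 1]} or \code{NA}.
#' @return a [RegulatoryNetwork-class] object.
#' @examples
#' net <- RegulatoryNetwork(c("R1", "R1"), c("G1", "G2"), weight = c(1, -2))
#' numEdges(net)
#' @export
RegulatoryNetwork <- function(regulator = character(), target = character(),
                              weight = NA_real_, confidence = NA_real_) {
    if (is.data.frame(regulator)) {
        df <- regulator
        if (is.null(df$weight)) df$weight <- NA_real_
        if (is.null(df$confidence)) df$confidence <- NA_real_
        e <- data.frame(regulator = as.character(df$regulator),
                        target = as.character(df$target),
                        weight = as.numeric(df$weight),
                        confidence = as.numeric(df$confidence),
                        stringsAsFactors = FALSE)
    } else {
        n <- length(regulator)
        e <- data.frame(regulator = as.character(regulator),
                        target = as.character(target),
                        weight = rep_len(as.numeric(weight), n),
                        confidence = rep_len(as.numeric(confidence), n),
                        stringsAsFactors = FALSE)
    }
    rownames(e) <- NULL
    new("RegulatoryNetwork", edges = e)
}

#' Per-gene regulatory program
#'
#' The conditional Gaussian of one target gene given its selected
#' regulators (its estimated Markov blanket): the target is modelled as
#' Normal(intercept + coefficients' x_R, conditionalVariance). Derived from
#' the maximum-likelihood joint Gaussian of the target and its regulators.
#'
#' @slot targetId the target gene id.
#' @slot regulatorIds regulator gene ids, in selection order.
#' @slot coefficients regression coefficients aligned to
#'   \code{regulatorIds}.
#' @slot intercept the conditional mean offset; equals the target's sample
#'   mean when no regulators are selected.
#' @slot conditionalVariance residual variance of the conditional Gaussian,
#'   floored at a small positive value at fit time.
#' @slot scoreGains per-regulator improvement in the total score at the
#'   greedy step that added it (empty when the program was fit directly).
#' @export
setClass("GeneRegulatoryProgram",
         slots = c(targetId = "character",
                   regulatorIds = "character",
                   coefficients = "numeric",
                   intercept = "numeric",
                   conditionalVariance = "numeric",
                   scoreGains = "numeric"))

setValidity("GeneRegulatoryProgram", function(object) {
    if (length(object@targetId) != 1L)
        return("targetId must be a single gene id")
    if (length(object@coefficients) != length(object@regulatorIds))
        return("coefficients must align with regulatorIds")
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
        return("intercept must be a single finite value")
    if (length(object@conditionalVariance) != 1L ||
        !is.finite(object@conditionalVariance) ||
        object@conditionalVariance <= 0)
        return("conditionalVariance must be a single positive value")
    if (object@targetId %in% object@regulatorIds)
        return("a gene cannot regulate itself")
    if (anyDuplicated(object@regulatorIds))
        return("duplicate regulator ids")
    if (length(object@scoreGains) &&
        length(object@scoreGains) != length(object@regulatorIds))
        return("scoreGains must be empty or align with regulatorIds")
    TRUE
})

GeneRegulatoryProgram <- function(targetId, regulatorIds = character(),
                                  coefficients = numeric(),
                                  intercept = 0, conditionalVariance = 1,
                                  scoreGains = numeric()) {
    new("GeneRegulatoryProgram", targetId = targetId,
        regulatorIds = as.character(regulatorIds),
        coefficients = as.numeric(coefficients),
        intercept = as.numeric(intercept),
        conditionalVariance = as.numeric(conditionalVariance),
        scoreGains = as.numeric(scoreGains))
}

#' Hyperparameters of the learner
#'
#' The three user-facing parameters of the method plus numerical controls.
#'
#' @slot sparsity log-odds offset of the logistic edge prior; more negative
#'   values give sparser networks. Default -5.
#' @slot moduleWeight non-negative coefficient on the module feature in the
#'   edge prior; 0 switches the module prior off and reduces the method to
#'   independent per-gene greedy regression. Default 4.
#' @slot clusterThreshold stop height in (0, 1) for the average-linkage
#'   module clustering. Default 0.6.
#' @slot maxIterations cap on structure/module alternations. Default 30.
#' @slot scoreTolerance per-move score improvement required to accept a
#'   regulator; run-level convergence uses \code{scoreTolerance * nGenes}.
#'   Default 1e-4.
#' @slot maxRegulators cap on regulators per gene (\code{Inf} = unbounded).
#'   Default 10.
#' @slot ridge ridge added to the regulator covariance diagonal before
#'   inversion. Default 1e-6.
#' @slot varianceFloor floor on conditional variances. Default 1e-8.
#' @slot seed integer seed controlling any randomized initialization.
#' @export
setClass("MerlinParams",
         slots = c(sparsity = "numeric", moduleWeight = "numeric",
                   clusterThreshold = "numeric", maxIterations = "integer",
                   scoreTolerance = "numeric", maxRegulators = "numeric",
                   ridge = "numeric", varianceFloor = "numeric",
                   seed = "integer"))

setValidity("MerlinParams", function(object) {
    if (!is.finite(object@sparsity))
        return("sparsity must be finite")
    if (object@moduleWeight < 0)
        return("moduleWeight must be >= 0")
    if (object@clusterThreshold <= 0 || object@clusterThreshold >= 1)
        return("clusterThreshold must lie in (0, 1)")
    if (object@maxIterations < 1L)
        return("maxIterations must be >= 1")
    if (object@scoreTolerance <= 0)
        return("scoreTolerance must be > 0")
    if (object@maxRegulators < 1)
        return("maxRegulators must be >= 1 (use Inf for unbounded)")
    if (object@ridge < 0)
        return("ridge must be >= 0")
    if (object@varianceFloor <= 0)
        return("varianceFloor must be > 0")
    TRUE
})

#' @rdname MerlinParams-class
#' @param sparsity,moduleWeight,clusterThreshold,maxIterations,scoreTolerance
#'   see the class slots.
#' @param maxRegulators,ridge,varianceFloor,seed see the class slots.
#' @return a \code{MerlinParams} object.
#' @examples
#' MerlinParams(sparsity = -5, moduleWeight = 4)
#' @export
MerlinParams <- function(sparsity = -5, moduleWeight = 4,
                         clusterThreshold = 0.6, maxIterations = 30L,
                         scoreTolerance = 1e-4, maxRegulators = 10,
                         ridge = 1e-6, varianceFloor = 1e-8, seed = 1L) {
    new("MerlinParams", sparsity = as.numeric(sparsity),
        moduleWeight = as.numeric(moduleWeight),
        clusterThreshold = as.numeric(clusterThreshold),
        maxIterations = as.integer(maxIterations),
        scoreTolerance = as.numeric(scoreTolerance),
        maxRegulators = as.numeric(maxRegulators),
        ridge = as.numeric(ridge),
        varianceFloor = as.numeric(varianceFloor),
        seed = as.integer(seed))
}

#' Fitted model: network, programs and modules
#'
#' The triple returned at convergence of [runMerlin()]: the inferred
#' regulatory network G, the per-gene conditional-Gaussian programs, and
#' the final module assignment M, together with the per-iteration score
#' trajectory and the hyperparameters that produced them.
#'
#' @slot network the inferred [RegulatoryNetwork-class].
#' @slot programs named list of [GeneRegulatoryProgram-class], one per gene.
#' @slot modules named integer vector gene -> module id (dense from 1).
#' @slot scoreTrajectory accepted total score per iteration
#'   (non-decreasing).
#' @slot params the [MerlinParams-class] used.
#' @slot converged whether the run stopped before \code{maxIterations}.
#' @slot iterations number of accepted iterations.
#' @export
setClass("MerlinModel",
         slots = c(network = "RegulatoryNetwork", programs = "list",
                   modules = "integer", scoreTrajectory = "numeric",
                   params = "MerlinParams", converged = "logical",
                   iterations = "integer"))

setValidity("MerlinModel", function(object) {
    msg <- .checkModules(object@modules)
    if (!isTRUE(msg)) return(msg)
    if (!all(names(object@programs) %in% names(object@modules)))
        return("programs must be named by genes in modules")
    for (p in object@programs) {
        e <- object@network@edges
        inNet <- sort(e$regulator[e$target == p@targetId])
        if (!identical(inNet, sort(p@regulatorIds)))
            return(sprintf("network/program mismatch for gene %s",
                           p@targetId))
    }
    if (length(object@scoreTrajectory) > 1L &&
        any(diff(object@scoreTrajectory) < -1e-6))
        return("scoreTrajectory must be non-decreasing within tolerance")
    TRUE
})

#' Simulated ground truth
#'
#' A modular truth network with signed interaction strengths, the module
#' partition it was generated from, its regulator set, per-gene basal
#' levels, and the within-module edge probability q used to wire it.
#'
#' @slot network the true [RegulatoryNetwork-class]; weights are signed
#'   interaction strengths.
#' @slot modules named integer vector gene -> module id.
#' @slot regulators character vector of regulator gene ids.
#' @slot basal named numeric vector of basal expression levels.
#' @slot q within-module edge probability in \eqn{[0, 1]}.
#' @export
setClass("GroundTruth",
         slots = c(network = "RegulatoryNetwork", modules = "integer",
                   regulators = "character", basal = "numeric",
                   q = "numeric"))

setValidity("GroundTruth", function(object) {
    msg <- .checkModules(object@modules)
    if (!isTRUE(msg)) return(msg)
    if (object@q < 0 || object@q > 1)
        return("q must lie in [0, 1]")
    if (!all(object@regulators %in% names(object@modules)))
        return("regulators must be genes of the truth")
    if (!all(object@network@edges$regulator %in% object@regulators))
        return("edge sources must be regulators")
    TRUE
})

#' Bundle of evaluation metrics
#'
#' @slot metrics named list of metric values as produced by
#'   [evaluateNetwork()].
#' @export
setClass("EvaluationReport", slots = c(metrics = "list"))

EvaluationReport <- function(metrics) new("EvaluationReport",
                                          metrics = metrics)

# ---- module-assignment checker (named integer vector convention) --------

.checkModules <- function(modules) {
    if (length(modules) == 0L)
        return(TRUE)
    if (is.null(names(modules)) || any(!nzchar(names(modules))))
        return("module assignment must be named by gene ids")
    if (anyDuplicated(names(modules)))
        return("duplicate gene ids in module assignment")
    if (anyNA(modules))
        return("every gene must be assigned to a module")
    ids <- sort(unique(as.integer(modules)))
    if (!identical(ids, seq_along(ids)))
        return("module ids must be dense integers starting at 1")
    TRUE
}

#' Validate a module assignment
#'
#' Module assignments are represented throughout the package as named
#' integer vectors mapping gene id to module id, with module ids dense
#' from 1. This checks that convention and returns the assignment
#' invisibly, erroring otherwise.
#'
#' @param modules named integer vector gene -> module id.
#' @return \code{modules}, invisibly.
#' @examples
#' validateModuleAssignment(c(G1 = 1L, G2 = 1L, G3 = 2L))
#' @export
validateModuleAssignment <- function(modules) {
    msg <- .checkModules(modules)
    if (!isTRUE(msg))
        stop(msg, call. = FALSE)
    invisible(modules)
}
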