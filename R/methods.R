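#' @include AllClasses.R AllGenerics.R
NULL

# ---- RegulatoryNetwork --------------------------------------------------

#' Accessors for RegulatoryNetwork
#'
#' \code{edges} returns the edge table, \code{numEdges} the edge count,
#' \code{regulators} the distinct regulator ids, and \code{targetsOf} the
#' targets of one regulator.
#'
#' @param x a [RegulatoryNetwork-class].
#' @param ... unused.
#' @param regulator a regulator gene id.
#' @return \code{edges}: a \code{data.frame}; \code{numEdges}: integer;
#'   \code{regulators}, \code{targetsOf}: character vectors.
#' @aliases edges numEdges targetsOf regulators
#' @name RegulatoryNetwork-accessors
NULL

#' @rdname RegulatoryNetwork-accessors
#' @export
setMethod("edges", "RegulatoryNetwork", function(x, ...) x@edges)

#' @rdname RegulatoryNetwork-accessors
#' @export
setMethod("numEdges", "RegulatoryNetwork", function(x) nrow(x@edges))

#' @rdname RegulatoryNetwork-accessors
#' @export
setMethod("regulators", "RegulatoryNetwork",
          function(x) sort(unique(x@edges$regulator)))

#' @rdname RegulatoryNetwork-accessors
#' @export
setMethod("targetsOf", "RegulatoryNetwork", function(x, regulator) {
    x@edges$target[x@edges$regulator == regulator]
})

setMethod("show", "RegulatoryNetwork", function(object) {
    e <- object@edges
    cat(sprintf("RegulatoryNetwork with %d edge%s (%d regulators, %d targets)\n",
                nrow(e), if (nrow(e) == 1L) "" else "s",
                length(unique(e$regulator)), length(unique(e$target))))
    if (nrow(e)) {
        print(utils::head(e, 5L))
        if (nrow(e) > 5L) cat(sprintf("... and %d more\n", nrow(e) - 5L))
    }
    invisible(NULL)
})

# ---- GeneRegulatoryProgram ----------------------------------------------

#' Accessors for GeneRegulatoryProgram
#'
#' @param x,object a [GeneRegulatoryProgram-class].
#' @param ... unused.
#' @return \code{targetId}, \code{regulatorIds}: character; \code{coef}:
#'   named numeric coefficients; \code{intercept},
#'   \code{conditionalVariance}: numeric scalars; \code{scoreGains}:
#'   numeric per-regulator score improvements.
#' @aliases targetId regulatorIds intercept conditionalVariance scoreGains
#' @name GeneRegulatoryProgram-accessors
NULL

#' @rdname GeneRegulatoryProgram-accessors
#' @export
setMethod("targetId", "GeneRegulatoryProgram", function(x) x@targetId)

#' @rdname GeneRegulatoryProgram-accessors
#' @export
setMethod("regulatorIds", "GeneRegulatoryProgram", function(x) x@regulatorIds)

#' @rdname GeneRegulatoryProgram-accessors
#' @export
setMethod("coef", "GeneRegulatoryProgram", function(object, ...) {
    stats::setNames(object@coefficients, object@regulatorIds)
})

#' @rdname GeneRegulatoryProgram-accessors
#' @export
setMethod("intercept", "GeneRegulatoryProgram", function(x) x@intercept)

#' @rdname GeneRegulatoryProgram-accessors
#' @export
setMethod("conditionalVariance", "GeneRegulatoryProgram",
          function(x) x@conditionalVariance)

#' @rdname GeneRegulatoryProgram-accessors
#' @export
setMethod("scoreGains", "GeneRegulatoryProgram", function(x) {
    if (length(x@scoreGains))
        stats::setNames(x@scoreGains, x@regulatorIds)
    else x@scoreGains
})

setMethod("show", "GeneRegulatoryProgram", function(object) {
    cat(sprintf("GeneRegulatoryProgram for %s: %d regulator%s, sigma^2 = %.4g\n",
                object@targetId, length(object@regulatorIds),
                if (length(object@regulatorIds) == 1L) "" else "s",
                object@conditionalVariance))
    if (length(object@regulatorIds))
        print(stats::setNames(object@coefficients, object@regulatorIds))
    invisible(NULL)
})

# ---- MerlinParams -------------------------------------------------------

setMethod("show", "MerlinParams", function(object) {
    cat("MerlinParams\n")
    cat(sprintf("  sparsity: %g  moduleWeight: %g  clusterThreshold: %g\n",
                object@sparsity, object@moduleWeight,
                object@clusterThreshold))
    cat(sprintf("  maxIterations: %d  scoreTolerance: %g  maxRegulators: %g\n",
                object@maxIterations, object@scoreTolerance,
                object@maxRegulators))
    cat(sprintf("  ridge: %g  varianceFloor: %g  seed: %d\n",
                object@ridge, object@varianceFloor, object@seed))
    invisible(NULL)
})

# ---- MerlinModel --------------------------------------------------------

#' Accessors for MerlinModel and GroundTruth
#'
#' @param x a [MerlinModel-class] or [GroundTruth-class].
#' @return \code{network}: a [RegulatoryNetwork-class]; \code{programs}: a
#'   named list of programs; \code{modules}: named integer vector;
#'   \code{scoreTrajectory}: numeric; \code{hyperParams}: the
#'   [MerlinParams-class]; \code{basalLevels}: named numeric vector.
#' @aliases network programs modules scoreTrajectory hyperParams basalLevels
#' @name MerlinModel-accessors
NULL

#' @rdname MerlinModel-accessors
#' @export
setMethod("network", "MerlinModel", function(x) x@network)

#' @rdname MerlinModel-accessors
#' @export
setMethod("programs", "MerlinModel", function(x) x@programs)

#' @rdname MerlinModel-accessors
#' @export
setMethod("modules", "MerlinModel", function(x) x@modules)

#' @rdname MerlinModel-accessors
#' @export
setMethod("scoreTrajectory", "MerlinModel", function(x) x@scoreTrajectory)

#' @rdname MerlinModel-accessors
#' @export
setMethod("hyperParams", "MerlinModel", function(x) x@params)

setMethod("show", "MerlinModel", function(object) {
    cat(sprintf("MerlinModel: %d genes, %d edges, %d modules\n",
                length(object@modules), numEdges(object@network),
                length(unique(object@modules))))
    cat(sprintf("  %d iteration%s, converged: %s, final score: %.4f\n",
                object@iterations,
                if (object@iterations == 1L) "" else "s",
                object@converged,
                utils::tail(object@scoreTrajectory, 1L)))
    invisible(NULL)
})

# ---- GroundTruth --------------------------------------------------------

#' @rdname MerlinModel-accessors
#' @export
setMethod("network", "GroundTruth", function(x) x@network)

#' @rdname MerlinModel-accessors
#' @export
setMethod("modules", "GroundTruth", function(x) x@modules)

#' @rdname RegulatoryNetwork-accessors
#' @export
setMethod("regulators", "GroundTruth", function(x) x@regulators)

#' @rdname MerlinModel-accessors
#' @export
setMethod("basalLevels", "GroundTruth", function(x) x@basal)

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d genes, %d regulators, %d edges, %d modules, q = %g\n",
                length(object@modules), length(object@regulators),
                numEdges(object@network), length(unique(object@modules)),
                object@q))
    invisible(NULL)
})

# ---- EvaluationReport ---------------------------------------------------

#' @describeIn EvaluationReport-class metric list accessor.
#' @param x an \code{EvaluationReport}.
#' @export
setMethod("metrics", "EvaluationReport", function(x) x@metrics)

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport\n")
    m <- object@metrics
    for (nm in names(m)) {
        v <- m[[nm]]
        if (is.numeric(v) && length(v) == 1L)
            cat(sprintf("  %s: %.4g\n", nm, v))
    }
    invisible(NULL)
})
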