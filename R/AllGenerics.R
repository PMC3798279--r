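#' @include AllClasses.R
NULL

#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))

#' @export
setGeneric("targetsOf", function(x, regulator) standardGeneric("targetsOf"))

#' @export
setGeneric("network", function(x) standardGeneric("network"))

#' @export
setGeneric("programs", function(x) standardGeneric("programs"))

#' @export
setGeneric("modules", function(x) standardGeneric("modules"))

#' @export
setGeneric("scoreTrajectory", function(x) standardGeneric("scoreTrajectory"))

#' @export
setGeneric("hyperParams", function(x) standardGeneric("hyperParams"))

#' @export
setGeneric("targetId", function(x) standardGeneric("targetId"))

#' @export
setGeneric("regulatorIds", function(x) standardGeneric("regulatorIds"))

#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @export
setGeneric("conditionalVariance", function(x) standardGeneric("conditionalVariance"))

#' @export
setGeneric("scoreGains", function(x) standardGeneric("scoreGains"))

#' @export
setGeneric("basalLevels", function(x) standardGeneric("basalLevels"))

#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))
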