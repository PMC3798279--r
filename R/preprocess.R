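#' @include core-model.R
NULL

#' Impute missing expression values with the gene mean
#'
#' Replaces each missing entry of a gene with the mean of that gene's
#' observed values in the other samples.
#'
#' @param expr numeric matrix, genes x samples, possibly with \code{NA}s.
#' @return the matrix with no missing values; a gene with no observed
#'   value at all is an error naming the gene.
#' @export
imputeMissingWithGeneMean <- function(expr) {
    .checkExpression(expr, requireComplete = FALSE)
    for (i in seq_len(nrow(expr))) {
        miss <- is.na(expr[i, ])
        if (!any(miss))
            next
        if (all(miss))
            stop("gene ", rownames(expr)[i], " has no observed values",
                 call. = FALSE)
        expr[i, miss] <- mean(expr[i, !miss])
    }
    expr
}

#' Log-transform raw counts
#'
#' \code{log2(count + pseudocount)} per entry.
#'
#' @param expr numeric matrix of non-negative counts.
#' @param pseudocount added before the log (default 1, so a zero count
#'   maps to 0).
#' @return the transformed matrix.
#' @export
logTransformCounts <- function(expr, pseudocount = 1) {
    .checkExpression(expr, requireComplete = FALSE)
    if (any(expr < 0, na.rm = TRUE))
        stop("counts must be non-negative", call. = FALSE)
    log2(expr + pseudocount)
}

#' Centre expression per sample group
#'
#' Subtracts, per gene and per sample group (e.g. a time course), the
#' group mean, so each gene is zero-mean within every group.
#'
#' @param expr numeric matrix, genes x samples.
#' @param grouping named character or factor vector sample -> group id
#'   covering every sample.
#' @return the centred matrix.
#' @export
centerPerGroup <- function(expr, grouping) {
    .checkExpression(expr)
    un <- setdiff(colnames(expr), names(grouping))
    if (length(un))
        stop("samples not assigned to a group: ",
             paste(utils::head(un, 5L), collapse = ", "), call. = FALSE)
    g <- as.character(grouping[colnames(expr)])
    for (grp in unique(g)) {
        cols <- which(g == grp)
        expr[, cols] <- expr[, cols, drop = FALSE] -
            rowMeans(expr[, cols, drop = FALSE])
    }
    expr
}

#' Filter genes with little expression change
#'
#' Keeps genes whose centred expression reaches at least
#' \code{threshold} in absolute value in at least one sample (the
#' boundary is inclusive).
#'
#' @param expr numeric matrix of centred expression.
#' @param threshold minimum absolute change (default 1).
#' @return the filtered matrix.
#' @export
filterLowChange <- function(expr, threshold = 1) {
    .checkExpression(expr)
    keep <- apply(abs(expr), 1L, max) >= threshold
    expr[keep, , drop = FALSE]
}

#' Full preprocessing pipeline
#'
#' Imputation, optional log2 transform of counts, per-group centering and
#' low-change filtering, in that order.
#'
#' @param expr numeric matrix, genes x samples.
#' @param grouping optional sample -> group mapping; when missing, all
#'   samples form one group.
#' @param log2Counts whether the input is raw counts to be
#'   log2(x + pseudocount)-transformed.
#' @param pseudocount pseudocount for the log transform.
#' @param minChange low-change filter threshold; \code{NULL} disables the
#'   filter.
#' @return the preprocessed matrix.
#' @export
preprocessExpression <- function(expr, grouping = NULL, log2Counts = FALSE,
                                 pseudocount = 1, minChange = 1) {
    expr <- imputeMissingWithGeneMean(expr)
    if (log2Counts)
        expr <- logTransformCounts(expr, pseudocount)
    if (is.null(grouping))
        grouping <- stats::setNames(rep("all", ncol(expr)), colnames(expr))
    expr <- centerPerGroup(expr, grouping)
    if (!is.null(minChange))
        expr <- filterLowChange(expr, minChange)
    expr
}
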