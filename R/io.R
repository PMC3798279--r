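#' @include AllClasses.R
NULL

# All files are tab-separated UTF-8 with '.' decimal separators.
# Expression: header "Gene" + sample ids, one gene per row, empty cell =
# missing. Network: header (regulator, target, weight, confidence).
# Modules: header (gene, module). Regulator list: one id per line, '#'
# comments. GMT: set name, description, then members. Interactions:
# 2-column TSV.

#' Read and write expression matrices
#'
#' @param path file path of a tab-separated expression table whose header
#'   row holds sample ids and whose first column (named \code{Gene}) holds
#'   gene ids; empty cells are missing values.
#' @return \code{readExpression}: a numeric matrix, genes x samples.
#'   Malformed headers and duplicate gene ids raise errors naming the
#'   offending line.
#' @name expression-io
#' @export
readExpression <- function(path) {
    lines <- readLines(path)
    if (length(lines) < 1L)
        stop("empty expression file: ", path, call. = FALSE)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L)
        stop("line 1: expression header needs a gene column and at least ",
             "one sample", call. = FALSE)
    samples <- header[-1L]
    if (anyDuplicated(samples))
        stop("line 1: duplicate sample ids", call. = FALSE)
    n <- length(lines) - 1L
    genes <- character(n)
    vals <- matrix(NA_real_, n, length(samples))
    for (i in seq_len(n)) {
        parts <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 1L || !nzchar(parts[[1L]]))
            stop("line ", i + 1L, ": missing gene id", call. = FALSE)
        if (length(parts) > length(samples) + 1L)
            stop("line ", i + 1L, ": too many fields", call. = FALSE)
        genes[[i]] <- parts[[1L]]
        row <- parts[-1L]
        row <- c(row, rep("", length(samples) - length(row)))
        row[row == ""] <- NA
        num <- suppressWarnings(as.numeric(row))
        if (any(is.na(num) & !is.na(row)))
            stop("line ", i + 1L, ": non-numeric expression value",
                 call. = FALSE)
        vals[i, ] <- num
    }
    dup <- which(duplicated(genes))
    if (length(dup))
        stop("line ", dup[[1L]] + 1L, ": duplicate gene id ",
             genes[[dup[[1L]]]], call. = FALSE)
    dimnames(vals) <- list(genes, samples)
    vals
}

#' @rdname expression-io
#' @param expr numeric matrix, genes x samples.
#' @export
writeExpression <- function(expr, path) {
    .checkExpression(expr, requireComplete = FALSE)
    header <- paste(c("Gene", colnames(expr)), collapse = "\t")
    body <- vapply(seq_len(nrow(expr)), function(i) {
        v <- expr[i, ]
        s <- ifelse(is.na(v), "", formatC(v, format = "g", digits = 15))
        paste(c(rownames(expr)[i], s), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read and write regulatory networks
#'
#' Edge lists are tab-separated with header
#' \code{regulator\ttarget\tweight\tconfidence}; the weight and confidence
#' columns are optional on input (e.g. for gold-standard networks).
#'
#' @param path file path.
#' @return \code{readNetwork}: a [RegulatoryNetwork-class].
#' @name network-io
#' @export
readNetwork <- function(path) {
    lines <- readLines(path)
    if (length(lines) < 1L)
        stop("empty network file: ", path, call. = FALSE)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L || header[[1L]] != "regulator" ||
        header[[2L]] != "target")
        stop("line 1: network header must start with 'regulator\ttarget'",
             call. = FALSE)
    n <- length(lines) - 1L
    reg <- character(n); tgt <- character(n)
    wt <- rep(NA_real_, n); cf <- rep(NA_real_, n)
    wCol <- match("weight", header)
    cCol <- match("confidence", header)
    for (i in seq_len(n)) {
        parts <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 2L)
            stop("line ", i + 1L, ": need regulator and target",
                 call. = FALSE)
        reg[[i]] <- parts[[1L]]
        tgt[[i]] <- parts[[2L]]
        if (!is.na(wCol) && length(parts) >= wCol && nzchar(parts[[wCol]]))
            wt[[i]] <- as.numeric(parts[[wCol]])
        if (!is.na(cCol) && length(parts) >= cCol && nzchar(parts[[cCol]]))
            cf[[i]] <- as.numeric(parts[[cCol]])
    }
    dup <- which(duplicated(paste0(reg, "\r", tgt)))
    if (length(dup))
        stop("line ", dup[[1L]] + 1L, ": duplicate edge ", reg[[dup[[1L]]]],
             " -> ", tgt[[dup[[1L]]]], call. = FALSE)
    RegulatoryNetwork(regulator = reg, target = tgt, weight = wt,
                      confidence = cf)
}

#' @rdname network-io
#' @param network a [RegulatoryNetwork-class].
#' @export
writeNetwork <- function(network, path) {
    e <- network@edges
    fmt <- function(v) ifelse(is.na(v), "",
                              formatC(v, format = "g", digits = 15))
    writeLines(c("regulator\ttarget\tweight\tconfidence",
                 if (nrow(e)) paste(e$regulator, e$target, fmt(e$weight),
                                    fmt(e$confidence), sep = "\t")),
               path)
    invisible(path)
}

#' Read and write module assignments
#'
#' Tab-separated with header \code{gene\tmodule}.
#'
#' @param path file path.
#' @return \code{readModules}: named integer vector gene -> module id.
#' @name modules-io
#' @export
readModules <- function(path) {
    lines <- readLines(path)
    if (length(lines) < 1L || !identical(
            strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][1:2],
            c("gene", "module")))
        stop("line 1: module header must be 'gene\tmodule'", call. = FALSE)
    n <- length(lines) - 1L
    genes <- character(n)
    mods <- integer(n)
    for (i in seq_len(n)) {
        parts <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 2L)
            stop("line ", i + 1L, ": need gene and module", call. = FALSE)
        genes[[i]] <- parts[[1L]]
        mods[[i]] <- as.integer(parts[[2L]])
    }
    dup <- which(duplicated(genes))
    if (length(dup))
        stop("line ", dup[[1L]] + 1L, ": duplicate gene id ",
             genes[[dup[[1L]]]], call. = FALSE)
    names(mods) <- genes
    validateModuleAssignment(mods)
}

#' @rdname modules-io
#' @param modules named integer module assignment.
#' @export
writeModules <- function(modules, path) {
    validateModuleAssignment(modules)
    writeLines(c("gene\tmodule",
                 paste(names(modules), modules, sep = "\t")), path)
    invisible(path)
}

#' Read a regulator list
#'
#' One gene id per line; blank lines and \code{#} comments are ignored.
#'
#' @param path file path.
#' @return character vector of regulator ids.
#' @export
readRegulators <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (anyDuplicated(lines))
        stop("duplicate regulator ids in ", path, call. = FALSE)
    lines
}

#' Read GMT gene sets
#'
#' Standard GMT: tab-separated lines of set name, description, then the
#' member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (i in seq_along(lines)) {
        parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(parts) < 3L)
            stop("line ", i, ": GMT lines need a name, description and at ",
                 "least one member", call. = FALSE)
        sets[[parts[[1L]]]] <- unique(parts[-(1:2)])
    }
    sets
}

#' Read a 2-column interaction TSV
#'
#' Undirected interaction pairs (e.g. genetic or protein-protein
#' interactions), one per line, optionally with a header.
#'
#' @param path file path.
#' @param header whether the first line is a header (default TRUE).
#' @return a 2-column \code{data.frame} with columns \code{a} and
#'   \code{b}.
#' @export
readInteractions <- function(path, header = TRUE) {
    tab <- utils::read.delim(path, header = header,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("interaction files need 2 columns", call. = FALSE)
    data.frame(a = as.character(tab[[1L]]), b = as.character(tab[[2L]]),
               stringsAsFactors = FALSE)
}

#' Write an evaluation report
#'
#' Scalar metrics go to a tab-separated \code{metric\tvalue} table and,
#' optionally, a JSON file with the full report including tables.
#'
#' @param report an [EvaluationReport-class].
#' @param path output TSV path.
#' @param jsonPath optional JSON output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path, jsonPath = NULL) {
    m <- metrics(report)
    scalar <- m[vapply(m, function(v)
        is.numeric(v) && length(v) == 1L, logical(1))]
    writeLines(c("metric\tvalue",
                 paste(names(scalar),
                       vapply(scalar, function(v)
                           formatC(v, format = "g", digits = 15),
                           character(1)),
                       sep = "\t")), path)
    if (!is.null(jsonPath))
        jsonlite::write_json(m, jsonPath, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", force = TRUE)
    invisible(path)
}

# Minimal flat YAML (key: value) used for run-config echoes.
.writeConfigYaml <- function(config, path) {
    fmt <- function(v) {
        if (is.character(v)) v
        else if (is.logical(v)) tolower(as.character(v))
        else formatC(v, format = "g", digits = 15)
    }
    writeLines(vapply(names(config), function(k)
        paste0(k, ": ", fmt(config[[k]])), character(1)), path)
    invisible(path)
}
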