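#' Read word2vec text-format vectors
#'
#' The text interchange format: a header line \code{"<vocab_size>
#' <dimension>"}, then one line per token, space-separated, the token first
#' (underscores allowed, spaces not) followed by its components. Header
#' counts are validated against the body and duplicate tokens are rejected;
#' malformed lines are reported with their line number.
#'
#' @param path file to read.
#' @param frequencies optional path to a 2-column TSV \code{token<TAB>count}
#'   supplying corpus frequencies.
#' @param modelTag label for the space.
#' @param normalize L2-normalize on load (default TRUE).
#' @return an [EmbeddingSpace-class].
#' @export
readWordVectors <- function(path, frequencies = NULL, modelTag = "other",
                            normalize = TRUE) {
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines)) stop("empty vector file: ", path)
    hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
    if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
        stop("line 1: malformed header (expected '<vocab_size> <dimension>')")
    nTok <- as.integer(hdr[1L]); dim <- as.integer(hdr[2L])
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    if (length(body) != nTok)
        stop(sprintf("header announces %d tokens but body has %d lines",
                     nTok, length(body)))
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(parts) != dim + 1L)
    if (length(bad))
        stop(sprintf("line %d: expected %d fields, found %d",
                     bad[1L] + 1L, dim + 1L, lengths(parts)[bad[1L]]))
    tokens <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(tokens))
        stop("duplicate token(s): ",
             paste(unique(tokens[duplicated(tokens)]), collapse = ", "))
    vals <- suppressWarnings(
        vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim)))
    if (anyNA(vals))
        stop(sprintf("line %d: non-numeric vector component",
                     which(apply(is.na(rbind(vals)), 2, any))[1L] + 1L))
    m <- t(rbind(vals))
    rownames(m) <- tokens
    freq <- NULL
    if (!is.null(frequencies)) {
        ft <- readTsv(frequencies)
        if (!all(c("token", "count") %in% names(ft)))
            stop("frequency table needs columns 'token' and 'count'")
        freq <- stats::setNames(as.integer(ft$count), ft$token)
    }
    EmbeddingSpace(m, frequencies = freq, modelTag = modelTag,
                   normalize = normalize)
}

#' Write word2vec text-format vectors
#'
#' @param space an [EmbeddingSpace-class].
#' @param path output file.
#' @param digits significant digits for the components.
#' @return \code{path}, invisibly.
#' @export
writeWordVectors <- function(space, path, digits = 8L) {
    m <- embeddingMatrix(space)
    lines <- c(paste(nrow(m), ncol(m)),
               vapply(seq_len(nrow(m)), function(i)
                   paste(c(rownames(m)[i],
                           formatC(m[i, ], digits = digits, format = "g")),
                         collapse = " "), ""))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read a single-header-row TSV
#'
#' UTF-8, tab-delimited, one header row; ragged rows are rejected.
#'
#' @param path file to read.
#' @return data.frame (all columns character unless clearly numeric).
#' @export
readTsv <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty table: ", path)
    nf <- lengths(regmatches(lines, gregexpr("\t", lines))) + 1L
    if (any(nf != nf[1L]))
        stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                     path, which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L],
                     nf[1L]))
    utils::read.delim(text = paste(lines, collapse = "\n"),
                      stringsAsFactors = FALSE, quote = "",
                      check.names = FALSE)
}

#' Write a single-header-row TSV
#'
#' @param df data.frame to write.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a prior-knowledge disease-treatment pair table
#'
#' Columns: \code{x_token}, \code{z_token}, \code{x_cui}, \code{z_cuis}
#' (pipe-joined), optional \code{z_short_form} (0/1).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readPriorPairs <- function(path) {
    df <- readTsv(path)
    need <- c("x_token", "z_token", "x_cui", "z_cuis")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("prior-pair table lacks column(s): ",
             paste(miss, collapse = ", "))
    df
}

#' The annotated worked-example query
#'
#' The fully annotated record of one four-term analogy query,
#' \code{-epilepsy +valproate +antiepileptic_drug} run against a CBOW
#' space: its 12 top-ranked candidate n-grams with analogy scores, the
#' expert Tx/non-Tx label, the concepts (CUIs) each Tx candidate maps to,
#' and the evidence-based categories assigned to each concept. One candidate
#' (\code{low_propensity}) is non-Tx and so carries no concept. Shipped as a
#' plain-text fixture; the query's treatment terms map to Z1=C0080356
#' (valproate) and Z2=C0003299 (antiepileptic agents).
#'
#' @return list with \code{candidates} (data.frame \code{rank}, \code{y},
#'   \code{score}, \code{label}, \code{cuis}, \code{categories}), \code{x},
#'   \code{z1}, \code{z2}, \code{xCui}, \code{zCuis}.
#' @examples
#' ex <- epilepsyExample()
#' nerStats(ex$candidates, ex$zCuis)
#' @export
epilepsyExample <- function() {
    path <- system.file("extdata", "epilepsy_query_candidates.tsv",
                        package = "TxAnalogy", mustWork = TRUE)
    cand <- readTsv(path)
    cand$cuis <- as.character(cand$cuis)
    cand$categories <- as.character(cand$categories)
    list(candidates = cand, x = "epilepsy", z1 = "valproate",
         z2 = "antiepileptic_drug", xCui = "C0014544",
         zCuis = c("C0080356", "C0003299"))
}
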