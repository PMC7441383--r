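#' Build all four-term analogy queries from prior disease-treatment pairs
#'
#' Given prior-knowledge n-gram pairs (disease \code{x}, treatment \code{z}),
#' constructs every search query \code{-x +z1 +z2}: for each disease, one
#' query per unordered pair of its distinct treatment n-grams, taken in
#' input-file appearance order. A disease with fewer than two treatment
#' n-grams yields no query (the analogy needs two known treatments), which
#' is why the number of queries per disease is \eqn{k(k-1)/2} for a
#' treatment set of size k.
#'
#' @param pairs data.frame with columns \code{x_token} and \code{z_token}
#'   (extra columns such as CUIs are ignored here); duplicated rows are
#'   dropped.
#' @param ordered if \code{TRUE}, emit both orderings of each z-pair
#'   (\eqn{k(k-1)} queries per disease); default \code{FALSE}.
#' @return data.frame with columns \code{x}, \code{z1}, \code{z2}, one row
#'   per query.
#' @export
buildQueries <- function(pairs, ordered = FALSE) {
    stopifnot(is.data.frame(pairs),
              all(c("x_token", "z_token") %in% names(pairs)))
    pairs <- pairs[!duplicated(pairs[c("x_token", "z_token")]), , drop = FALSE]
    if (any(pairs$x_token == pairs$z_token))
        stop("a prior pair must relate two distinct n-grams")
    out <- list()
    for (x in unique(pairs$x_token)) {
        z <- pairs$z_token[pairs$x_token == x]
        if (length(z) < 2L) next
        idx <- utils::combn(length(z), 2L)
        q <- data.frame(x = x, z1 = z[idx[1L, ]], z2 = z[idx[2L, ]],
                        stringsAsFactors = FALSE)
        if (ordered)
            q <- rbind(q, data.frame(x = x, z1 = z[idx[2L, ]],
                                     z2 = z[idx[1L, ]]))
        out[[x]] <- q
    }
    if (!length(out))
        return(data.frame(x = character(), z1 = character(),
                          z2 = character(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[!duplicated(res), , drop = FALSE]
}

## printable-ASCII test: every byte in U+0020..U+007E
.isAscii <- function(tokens) {
    !vapply(tokens, function(t) grepl("[^ -~]", t, useBytes = TRUE),
            logical(1), USE.NAMES = FALSE)
}

#' Run analogy queries against an embedding space
#'
#' Executes each \code{-x +z1 +z2} query with [topCandidates()] and applies
#' the candidate hygiene rule: candidate n-grams containing characters
#' outside printable ASCII are discarded \emph{after} ranking (no
#' back-filling by default, so a query can return fewer than \code{k}
#' candidates). A query whose tokens are missing from the vocabulary is
#' reported as failed rather than aborting the batch.
#'
#' @param space an [EmbeddingSpace-class].
#' @param queries data.frame from [buildQueries()] (columns \code{x},
#'   \code{z1}, \code{z2}).
#' @param k candidates retained per query (default 12).
#' @param variant scoring variant, see [analogyScores()].
#' @param backfill if \code{TRUE}, discarded candidates are replaced by the
#'   next-ranked eligible ones so each query still returns \code{k}
#'   candidates when possible.
#' @return a list with components
#'   \describe{
#'     \item{candidates}{data.frame \code{model_tag, x, z1, z2, rank, y,
#'       score}, one row per retained candidate; scores printed elsewhere at
#'       6 decimals.}
#'     \item{discarded}{data.frame \code{x, z1, z2, token, reason}.}
#'     \item{failed}{data.frame \code{x, z1, z2, reason} for queries that
#'       could not run.}
#'   }
#' @export
runQueries <- function(space, queries, k = 12L,
                       variant = c("composite", "additive"),
                       backfill = FALSE) {
    variant <- match.arg(variant)
    stopifnot(is.data.frame(queries),
              all(c("x", "z1", "z2") %in% names(queries)))
    vocab <- vocabulary(space)
    cand <- list(); disc <- list(); fail <- list()
    for (i in seq_len(nrow(queries))) {
        q <- queries[i, ]
        miss <- setdiff(unique(c(q$x, q$z1, q$z2)), vocab)
        if (length(miss)) {
            fail[[length(fail) + 1L]] <- data.frame(
                x = q$x, z1 = q$z1, z2 = q$z2,
                reason = paste0("missing-token: ",
                                paste(miss, collapse = ", ")),
                stringsAsFactors = FALSE)
            next
        }
        kEff <- if (backfill) min(k + 64L, length(vocab)) else k
        top <- topCandidates(space, q$x, q$z1, q$z2, k = kEff,
                             variant = variant)
        ok <- .isAscii(top$token)
        if (any(!ok))
            disc[[length(disc) + 1L]] <- data.frame(
                x = q$x, z1 = q$z1, z2 = q$z2, token = top$token[!ok],
                reason = "non-ascii", stringsAsFactors = FALSE)
        top <- top[ok, , drop = FALSE]
        top <- top[seq_len(min(k, nrow(top))), , drop = FALSE]
        top$rank <- seq_len(nrow(top))
        if (nrow(top))
            cand[[length(cand) + 1L]] <- data.frame(
                model_tag = modelTag(space), x = q$x, z1 = q$z1, z2 = q$z2,
                rank = top$rank, y = top$token, score = top$score,
                stringsAsFactors = FALSE)
    }
    empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
    list(
        candidates = if (length(cand)) do.call(rbind, cand) else
            empty(model_tag = character(), x = character(), z1 = character(),
                  z2 = character(), rank = integer(), y = character(),
                  score = numeric()),
        discarded = if (length(disc)) do.call(rbind, disc) else
            empty(x = character(), z1 = character(), z2 = character(),
                  token = character(), reason = character()),
        failed = if (length(fail)) do.call(rbind, fail) else
            empty(x = character(), z1 = character(), z2 = character(),
                  reason = character())
    )
}
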