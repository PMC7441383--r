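#' Cosine similarity of two vectors
#'
#' The workhorse similarity of vector semantics:
#' \eqn{\cos(a,b) = a \cdot b / (\lVert a\rVert\,\lVert b\rVert)}.
#' Symmetric and invariant to positive rescaling of either argument.
#'
#' @param a,b numeric vectors of equal length; neither may be the zero
#'   vector (a zero vector has no direction).
#' @return a single number in \[-1, 1\].
#' @examples
#' cosineSim(c(1, 2, 3), c(4, 5, 6))
#' @export
cosineSim <- function(a, b) {
    stopifnot(is.numeric(a), is.numeric(b))
    if (length(a) != length(b))
        stop("vectors differ in length (", length(a), " vs ", length(b), ")")
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0)
        stop("cosine is undefined for a zero vector")
    s <- sum(a * b) / (na * nb)
    ## clamp rounding spill so downstream code can rely on [-1, 1]
    max(-1, min(1, s))
}

.unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("degenerate query: combined vector is zero")
    v / n
}

#' Four-term analogy scores over a whole vocabulary
#'
#' Scores every vocabulary token y as an answer to the search query
#' \code{-x +z1 +z2}: "find the term y similar to z1 and to z2 while
#' different from x", the 3CosAdd analogy objective. The query terms
#' themselves are never candidates.
#'
#' Two scoring variants are provided. The additive variant sums the three
#' cosines, \eqn{\cos(y,z_1)+\cos(y,z_2)-\cos(y,x)} (range \[-3, 3\]).
#' The composite variant (default) takes the cosine between y and the single
#' combined direction \eqn{u(u(z_1)+u(z_2)-u(x))} where \eqn{u} normalizes to
#' unit length, the form word2vec-style tools print (range \[-1, 1\]).
#' Both order candidates identically when all stored vectors are unit length
#' only in special cases; rankings can differ, hence the explicit choice.
#'
#' @param space an [EmbeddingSpace-class].
#' @param x,z1,z2 query tokens: the target (e.g. a disease) whose semantic
#'   context is subtracted, and two terms of the sought semantic field (e.g.
#'   treatments). All must be in the vocabulary, \code{z1 != z2} and
#'   \code{x} distinct from both.
#' @param variant \code{"composite"} (default) or \code{"additive"}.
#' @return data.frame with columns \code{token} and \code{score}, one row per
#'   vocabulary token excluding \code{x}, \code{z1}, \code{z2}, in storage
#'   order (unranked).
#' @seealso [topCandidates()] for the ranked, truncated form.
#' @export
analogyScores <- function(space, x, z1, z2,
                          variant = c("composite", "additive")) {
    variant <- match.arg(variant)
    stopifnot(is(space, "EmbeddingSpace"))
    if (z1 == z2) stop("z1 and z2 must differ")
    if (x %in% c(z1, z2)) stop("x must differ from z1 and z2")
    qv <- .lookupVectors(space, c(x, z1, z2))
    V <- space@vectors
    keep <- !(rownames(V) %in% c(x, z1, z2))
    V <- V[keep, , drop = FALSE]
    if (variant == "composite") {
        target <- .unit(qv[2L, ] + qv[3L, ] - qv[1L, ])
        score <- as.vector(V %*% target)
    } else {
        score <- as.vector(V %*% qv[2L, ] + V %*% qv[3L, ] - V %*% qv[1L, ])
    }
    data.frame(token = rownames(V), score = score, row.names = NULL,
               stringsAsFactors = FALSE)
}

## rank a (token, score) table: score descending, ties by ascending
## lexicographic *byte* order (radix sort is locale-independent)
.rankCandidates <- function(tab, k) {
    o <- order(-tab$score, tab$token, method = "radix")
    o <- o[seq_len(min(k, length(o)))]
    out <- tab[o, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("rank", "token", "score")]
}

#' Top-k analogy candidates for a search query
#'
#' Runs [analogyScores()] and keeps the \code{k} highest-scoring candidate
#' n-grams (all of them if the eligible vocabulary is smaller). Equal scores
#' are broken by ascending lexicographic byte order of the token, so results
#' are deterministic and locale-independent.
#'
#' @inheritParams analogyScores
#' @param k number of candidates to retain; the retention used throughout
#'   the disease-treatment search is 12.
#' @return data.frame with columns \code{rank} (1-based, contiguous),
#'   \code{token}, \code{score} (non-increasing).
#' @examples
#' m <- rbind(x = c(1, 0), z1 = c(0.6, 0.8), z2 = c(0.8, 0.6),
#'            a = c(0.7, 0.7), b = c(1, 0.1))
#' sp <- EmbeddingSpace(m)
#' topCandidates(sp, "x", "z1", "z2", k = 2)
#' @export
topCandidates <- function(space, x, z1, z2, k = 12L,
                          variant = c("composite", "additive")) {
    stopifnot(length(k) == 1L, k >= 1)
    .rankCandidates(analogyScores(space, x, z1, z2, variant), k)
}

#' Nearest neighbors by cosine
#'
#' The \code{k} vocabulary tokens with the highest cosine to \code{token}
#' (the token itself excluded), ties broken lexicographically. Used both to
#' probe a space ("which term is most similar to the target?") and to feed
#' the selection heuristic's membership test against the 20 top-ranked
#' cosine neighbors of a target disease.
#'
#' @param space an [EmbeddingSpace-class].
#' @param token query token, must be in the vocabulary.
#' @param k number of neighbors to return.
#' @return data.frame with columns \code{rank}, \code{token}, \code{score}.
#' @export
nearestByCosine <- function(space, token, k = 20L) {
    stopifnot(is(space, "EmbeddingSpace"), length(k) == 1L, k >= 1)
    qv <- .lookupVectors(space, token)
    V <- space@vectors
    keep <- rownames(V) != token
    tab <- data.frame(token = rownames(V)[keep],
                      score = as.vector(V[keep, , drop = FALSE] %*% qv[1L, ]),
                      stringsAsFactors = FALSE)
    .rankCandidates(tab, k)
}
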