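#' @import methods
NULL

#' EmbeddingSpace: a vocabulary of n-gram vectors with corpus frequencies
#'
#' An \code{EmbeddingSpace} stores one embedding vector per n-gram token
#' (multiword terms joined by underscores, case-sensitive) together with the
#' token's corpus frequency count and a tag naming the neural language model
#' that produced the vectors (CBOW, Skip-gram, or other). Vectors are
#' L2-normalized at construction time, the convention of word2vec-style
#' tooling, so the dot product of two stored vectors is their cosine.
#'
#' @slot vectors numeric matrix, one row per token (rownames are the tokens),
#'   one column per embedding dimension.
#' @slot frequencies named integer vector of non-negative corpus counts,
#'   aligned with \code{rownames(vectors)}.
#' @slot modelTag single character string, one of \code{"CBOW"},
#'   \code{"Skip-gram"} or any other model label.
#'
#' @seealso [EmbeddingSpace()] the constructor, [readWordVectors()],
#'   [analogyScores()], [nearestByCosine()]
#' @name EmbeddingSpace-class
#' @rdname EmbeddingSpace-class
#' @exportClass EmbeddingSpace
setClass("EmbeddingSpace",
    representation(
        vectors     = "matrix",
        frequencies = "integer",
        modelTag    = "character"
    )
)

setValidity("EmbeddingSpace", function(object) {
    v <- object@vectors
    msg <- character(0)
    if (!is.numeric(v))
        msg <- c(msg, "'vectors' must be a numeric matrix")
    tok <- rownames(v)
    if (is.null(tok) || any(!nzchar(tok)))
        msg <- c(msg, "every row of 'vectors' must be named by a non-empty token")
    else {
        if (anyDuplicated(tok))
            msg <- c(msg, sprintf("duplicate token(s): %s",
                paste(unique(tok[duplicated(tok)]), collapse = ", ")))
        if (any(grepl("[[:space:]]", tok)))
            msg <- c(msg, "tokens must not contain whitespace")
    }
    if (length(object@frequencies) != nrow(v))
        msg <- c(msg, "'frequencies' must have one entry per token")
    else {
        if (!identical(names(object@frequencies), tok))
            msg <- c(msg, "'frequencies' names must match the tokens")
        if (any(object@frequencies < 0L, na.rm = TRUE))
            msg <- c(msg, "'frequencies' must be non-negative")
    }
    if (length(object@modelTag) != 1L)
        msg <- c(msg, "'modelTag' must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct an EmbeddingSpace
#'
#' @param vectors numeric matrix with one row per token; rownames are the
#'   tokens. A zero row is rejected: a zero vector has no direction and every
#'   cosine against it is undefined.
#' @param frequencies optional numeric vector of corpus counts, either named
#'   by token or in row order; missing tokens default to 0.
#' @param modelTag label for the producing model, e.g. \code{"CBOW"} or
#'   \code{"Skip-gram"}.
#' @param normalize if \code{TRUE} (default, the word2vec convention) rows
#'   are rescaled to unit L2 norm; raw norms are not retained.
#' @return an [EmbeddingSpace-class] object.
#' @examples
#' m <- rbind(aspirin = c(1, 0), headache = c(0, 1))
#' sp <- EmbeddingSpace(m, frequencies = c(aspirin = 120, headache = 40))
#' vocabulary(sp)
#' @export
EmbeddingSpace <- function(vectors, frequencies = NULL, modelTag = "other",
                           normalize = TRUE) {
    vectors <- as.matrix(vectors)
    storage.mode(vectors) <- "double"
    nrm <- sqrt(rowSums(vectors^2))
    if (any(nrm == 0))
        stop("zero vector for token(s): ",
             paste(rownames(vectors)[nrm == 0], collapse = ", "))
    if (normalize)
        vectors <- vectors / nrm
    tok <- rownames(vectors)
    if (is.null(frequencies)) {
        frequencies <- stats::setNames(integer(nrow(vectors)), tok)
    } else {
        if (is.null(names(frequencies))) {
            stopifnot(length(frequencies) == nrow(vectors))
            names(frequencies) <- tok
        }
        frequencies <- stats::setNames(
            as.integer(round(frequencies[tok])), tok)
        frequencies[is.na(frequencies)] <- 0L
    }
    new("EmbeddingSpace", vectors = vectors, frequencies = frequencies,
        modelTag = as.character(modelTag)[1L])
}

#' @describeIn EmbeddingSpace-class tokens in the space, in storage order
#' @param object,x an \code{EmbeddingSpace}
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname EmbeddingSpace-class
#' @export
setMethod("vocabulary", "EmbeddingSpace", function(x) rownames(x@vectors))

#' @describeIn EmbeddingSpace-class number of embedding dimensions
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @rdname EmbeddingSpace-class
#' @export
setMethod("embeddingDim", "EmbeddingSpace", function(x) ncol(x@vectors))

#' @describeIn EmbeddingSpace-class named integer vector of corpus counts
#' @export
setGeneric("tokenFrequencies", function(x) standardGeneric("tokenFrequencies"))

#' @rdname EmbeddingSpace-class
#' @export
setMethod("tokenFrequencies", "EmbeddingSpace", function(x) x@frequencies)

#' @describeIn EmbeddingSpace-class the producing model's label
#' @export
setGeneric("modelTag", function(x) standardGeneric("modelTag"))

#' @rdname EmbeddingSpace-class
#' @export
setMethod("modelTag", "EmbeddingSpace", function(x) x@modelTag)

#' @describeIn EmbeddingSpace-class the (normalized) vector matrix
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname EmbeddingSpace-class
#' @export
setMethod("embeddingMatrix", "EmbeddingSpace", function(x) x@vectors)

setMethod("show", "EmbeddingSpace", function(object) {
    cat(sprintf("EmbeddingSpace (%s): %d tokens, %d dimensions\n",
        object@modelTag, nrow(object@vectors), ncol(object@vectors)))
    tok <- rownames(object@vectors)
    if (length(tok))
        cat("tokens:", paste(utils::head(tok, 6L), collapse = " "),
            if (length(tok) > 6L) "..." else "", "\n")
})

#' @rdname EmbeddingSpace-class
#' @export
setMethod("length", "EmbeddingSpace", function(x) nrow(x@vectors))

## internal: look up token rows, failing with the offending token names
.lookupVectors <- function(space, tokens) {
    miss <- setdiff(tokens, vocabulary(space))
    if (length(miss))
        stop("token(s) not in vocabulary: ", paste(miss, collapse = ", "),
             call. = FALSE)
    space@vectors[tokens, , drop = FALSE]
}
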