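#' Tokenize a tiny corpus for embedding training
#'
#' Minimal preprocessing that deliberately keeps almost everything: letter
#' case is preserved and punctuation marks are kept as standalone tokens,
#' because punctuation can change the meaning of a sentence. The single
#' exception is double-quotation marks (straight or typographic), which are
#' deleted. Hyphens and apostrophes stay inside their words, so tokens like
#' \code{New-Hampshire's} survive intact.
#'
#' @param lines character vector, one line of raw text per element.
#' @return a list of class \code{ToyCorpus} with elements \code{lines} (the
#'   input) and \code{tokens} (a list of per-line token vectors).
#' @examples
#' tokenizeCorpus("Oh happy dagger!")$tokens
#' @export
tokenizeCorpus <- function(lines) {
    lines <- as.character(lines)
    txt <- gsub("[\"“”]", "", lines)
    ## detach sentence punctuation into standalone tokens
    txt <- gsub("([.,!?;:()])", " \\1 ", txt)
    tokens <- lapply(strsplit(trimws(txt), "[[:space:]]+"),
                     function(x) x[nzchar(x)])
    structure(list(lines = lines, tokens = tokens), class = "ToyCorpus")
}

#' @export
print.ToyCorpus <- function(x, ...) {
    cat(sprintf("ToyCorpus: %d lines, %d tokens, %d distinct\n",
        length(x$lines), sum(lengths(x$tokens)),
        length(unique(unlist(x$tokens)))))
    invisible(x)
}

#' The five-line Romeo corpus
#'
#' A five-line common-English corpus (Shakespeare's Romeo plus two lines
#' about New Hampshire) that is small enough to train embeddings on in
#' seconds yet rich enough to carry a four-term analogy relating the
#' semantic fields \emph{person} and \emph{death}. Shipped as a plain-text
#' fixture; see the package vignette for the experiment built on it.
#'
#' @return character vector of 5 lines.
#' @export
romeoCorpus <- function() {
    readLines(system.file("extdata", "romeo_corpus.txt",
                          package = "TxAnalogy", mustWork = TRUE),
              encoding = "UTF-8")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train word2vec-style embeddings on a tiny corpus
#'
#' A plain-R implementation of the CBOW and Skip-gram neural language models
#' with negative sampling, intended for toy corpora of a few lines (its only
#' supported scale). CBOW predicts the center word from the average of the
#' context vectors inside a dynamic window; Skip-gram predicts each context
#' word from the center word. Negative examples are drawn from the unigram
#' distribution raised to the 3/4 power. The learning rate decays linearly
#' over the total number of training steps, with a floor at 1e-4 of the
#' starting rate. Input vectors are initialized uniformly in
#' \code{[-0.5, 0.5]/dimension} and output vectors at zero, the word2vec
#' convention. Identical configuration and seed give bit-identical vectors.
#'
#' @param corpus a \code{ToyCorpus} from [tokenizeCorpus()], or a character
#'   vector of raw lines (tokenized on the fly).
#' @param model \code{"cbow"} or \code{"skipgram"}.
#' @param dimension embedding dimension (default 25; small corpora support
#'   only small dimensions).
#' @param window maximum one-sided context window; each step samples an
#'   effective window uniformly from 1..window (word2vec's dynamic window).
#' @param epochs full passes over the corpus; tiny corpora need many
#'   (default 200).
#' @param negative number of negative samples per positive example.
#' @param learningRate starting learning rate (default 0.025, decayed
#'   linearly).
#' @param minCount tokens with corpus count below this are dropped from the
#'   vocabulary before training.
#' @param seed integer seed fixing all stochastic draws.
#' @return an [EmbeddingSpace-class] holding the (L2-normalized) input
#'   vectors, with token frequencies set to corpus counts and
#'   \code{modelTag} \code{"CBOW"} or \code{"Skip-gram"}. The epoch-averaged
#'   negative-sampling loss trace is attached as attribute \code{"loss"}.
#' @examples
#' sp <- trainEmbeddings(tokenizeCorpus(c("a b c", "a c b")),
#'                       dimension = 4, epochs = 20, seed = 1)
#' vocabulary(sp)
#' @export
trainEmbeddings <- function(corpus, model = c("cbow", "skipgram"),
                            dimension = 25L, window = 5L, epochs = 200L,
                            negative = 5L, learningRate = 0.025,
                            minCount = 1L, seed = 1L) {
    model <- match.arg(model)
    if (is.character(corpus)) corpus <- tokenizeCorpus(corpus)
    stopifnot(inherits(corpus, "ToyCorpus"), dimension >= 2, minCount >= 1)
    sents <- corpus$tokens[lengths(corpus$tokens) > 0L]
    if (!length(sents)) stop("corpus is empty")
    counts <- table(unlist(sents))
    counts <- counts[counts >= minCount]
    if (!length(counts))
        stop("vocabulary is empty after the min-count filter")
    vocab <- names(counts)
    V <- length(vocab)
    ids <- lapply(sents, function(s) match(s[s %in% vocab], vocab))
    ids <- ids[lengths(ids) > 0L]

    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))

    noise <- as.numeric(counts)^0.75
    noise <- noise / sum(noise)
    syn0 <- matrix(stats::runif(V * dimension, -0.5, 0.5) / dimension,
                   V, dimension)
    syn1 <- matrix(0, V, dimension)

    totalSteps <- epochs * sum(lengths(ids))
    step <- 0L
    lossTrace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
        epLoss <- 0; epN <- 0L
        for (s in ids) {
            L <- length(s)
            for (t in seq_len(L)) {
                step <- step + 1L
                alpha <- max(learningRate * 1e-4,
                             learningRate * (1 - (step - 1L) / totalSteps))
                b <- sample.int(window, 1L)
                ctx <- s[max(1L, t - b):min(L, t + b)]
                ctx <- ctx[-(t - max(1L, t - b) + 1L)]
                if (!length(ctx)) next
                w <- s[t]
                negs <- sample.int(V, negative, replace = TRUE, prob = noise)
                outs <- c(w, negs)
                labels <- c(1, numeric(negative))
                if (model == "cbow") {
                    h <- colMeans(syn0[ctx, , drop = FALSE])
                    e <- numeric(dimension)
                    for (j in seq_along(outs)) {
                        ## sequential updates: negatives may repeat an index
                        f <- .sigmoid(sum(syn1[outs[j], ] * h))
                        g <- (labels[j] - f) * alpha
                        e <- e + g * syn1[outs[j], ]
                        syn1[outs[j], ] <- syn1[outs[j], ] + g * h
                        epLoss <- epLoss -
                            log(max(if (labels[j] == 1) f else 1 - f, 1e-12))
                    }
                    syn0[ctx, ] <- sweep(syn0[ctx, , drop = FALSE], 2, e, "+")
                    epN <- epN + 1L
                } else {
                    for (cw in ctx) {
                        h <- syn0[cw, ]
                        e <- numeric(dimension)
                        for (j in seq_along(outs)) {
                            f <- .sigmoid(sum(syn1[outs[j], ] * h))
                            g <- (labels[j] - f) * alpha
                            e <- e + g * syn1[outs[j], ]
                            syn1[outs[j], ] <- syn1[outs[j], ] + g * h
                            epLoss <- epLoss -
                                log(max(if (labels[j] == 1) f else 1 - f, 1e-12))
                        }
                        syn0[cw, ] <- syn0[cw, ] + e
                        epN <- epN + 1L
                    }
                }
            }
        }
        lossTrace[ep] <- epLoss / max(epN, 1L)
    }
    rownames(syn0) <- vocab
    sp <- EmbeddingSpace(syn0, frequencies = as.integer(counts),
                         modelTag = if (model == "cbow") "CBOW" else "Skip-gram")
    attr(sp, "loss") <- lossTrace
    sp
}
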