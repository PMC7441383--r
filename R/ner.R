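#' Resolve per-pair treatment labels from several raters
#'
#' Collapses the binary treatment-field classifications (Tx / non-Tx) of
#' multiple raters into one label per candidate pair by majority vote. An
#' even split is unresolved unless an explicit adjudication entry exists for
#' that pair, in which case the adjudication wins (it also overrides a
#' majority).
#'
#' @param annotations data.frame with columns \code{pair_id}, \code{rater},
#'   \code{label} (values \code{"Tx"} / \code{"non-Tx"}).
#' @param adjudication optional data.frame with columns \code{pair_id},
#'   \code{label}.
#' @return named character vector: \code{pair_id} to resolved label.
#' @export
consensusTx <- function(annotations, adjudication = NULL) {
    stopifnot(all(c("pair_id", "rater", "label") %in% names(annotations)))
    adj <- if (!is.null(adjudication))
        stats::setNames(as.character(adjudication$label),
                        adjudication$pair_id) else character(0)
    ids <- unique(annotations$pair_id)
    out <- character(length(ids)); names(out) <- ids
    unresolved <- character(0)
    for (id in ids) {
        if (id %in% names(adj)) { out[id] <- adj[[id]]; next }
        tab <- table(annotations$label[annotations$pair_id == id])
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1L) unresolved <- c(unresolved, id)
        else out[id] <- top
    }
    if (length(unresolved))
        stop("unresolved even split for pair(s): ",
             paste(unresolved, collapse = ", "))
    out
}

## split a pipe-joined CUI/category field; "" and NA give character(0)
.splitPipe <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    strsplit(x, "|", fixed = TRUE)[[1L]]
}

#' Micro-averaged precision/recall/F for concept mappings
#'
#' Compares automatic token-to-concept (CUI) mappings against gold-standard
#' mappings by pooling all (token, CUI) decision pairs across tokens
#' (micro-averaging): TP are pairs asserted by both, FP automatic-only, FN
#' gold-only. \eqn{P = TP/(TP+FP)}, \eqn{R = TP/(TP+FN)},
#' \eqn{F = 2PR/(P+R)}.
#'
#' @param gold,auto data.frames with columns \code{token} and \code{cuis}
#'   (pipe-joined when a token maps to several concepts).
#' @return list with \code{precision}, \code{recall}, \code{f_measure} (all
#'   percentages rounded to 2 decimals) and the raw \code{tp}, \code{fp},
#'   \code{fn} counts.
#' @examples
#' gold <- data.frame(token = c("a", "b", "c"),
#'                    cuis = c("C1", "C2|C3", "C4"))
#' auto <- data.frame(token = c("a", "b", "c"),
#'                    cuis = c("C1", "C2", "C5"))
#' microPRF(gold, auto)
#' @export
microPRF <- function(gold, auto) {
    pairs <- function(df) {
        stopifnot(all(c("token", "cuis") %in% names(df)))
        unique(unlist(lapply(seq_len(nrow(df)), function(i)
            paste(df$token[i], .splitPipe(df$cuis[i]), sep = "\r"))))
    }
    g <- pairs(gold); a <- pairs(auto)
    extra <- setdiff(sub("\r.*", "", a), sub("\r.*", "", g))
    if (length(extra))
        stop("gold standard does not cover token(s): ",
             paste(extra, collapse = ", "))
    tp <- length(intersect(g, a))
    fp <- length(setdiff(a, g))
    fn <- length(setdiff(g, a))
    if (tp + fp == 0 || tp + fn == 0)
        stop("precision/recall undefined: no positive decisions")
    p <- 100 * tp / (tp + fp)
    r <- 100 * tp / (tp + fn)
    list(precision = round(p, 2), recall = round(r, 2),
         f_measure = round(fMeasure(p, r), 2), tp = tp, fp = fp, fn = fn)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall percentages (or proportions; any common scale).
#' @return F-measure on the same scale.
#' @export
fMeasure <- function(precision, recall) {
    2 * precision * recall / (precision + recall)
}

#' Per-query named-entity statistics n1, n2, n3
#'
#' For one search query \code{-x +z1 +z2} and its ranked candidates:
#' \describe{
#'   \item{n1}{number of distinct concepts (CUIs) the query's treatment
#'     terms z1 and z2 map to — 1 when both are surface variants of one
#'     concept.}
#'   \item{n2}{number of distinct candidate n-grams labeled as belonging to
#'     the treatment semantic field (Tx).}
#'   \item{n3}{number of distinct concepts mapped to by the Tx candidates,
#'     excluding the z concepts; each concept of a multi-concept candidate
#'     counts separately.}
#' }
#'
#' @param candidates data.frame with columns \code{y}, \code{label}
#'   (\code{"Tx"}/\code{"non-Tx"}) and \code{cuis} (pipe-joined CUIs;
#'   required for Tx rows).
#' @param zCuis character vector of CUIs mapped to z1 and z2 (union).
#' @return list with integer elements \code{n1}, \code{n2}, \code{n3}.
#' @export
nerStats <- function(candidates, zCuis) {
    stopifnot(all(c("y", "label", "cuis") %in% names(candidates)),
              length(zCuis) >= 1L)
    tx <- candidates[candidates$label == "Tx", , drop = FALSE]
    noMap <- vapply(tx$cuis, function(x) length(.splitPipe(x)) == 0L,
                    logical(1), USE.NAMES = FALSE)
    if (any(noMap))
        stop("Tx candidate(s) without concept mapping: ",
             paste(tx$y[noMap], collapse = ", "))
    txCuis <- unique(unlist(lapply(tx$cuis, .splitPipe)))
    list(n1 = length(unique(zCuis)),
         n2 = length(unique(tx$y)),
         n3 = length(setdiff(txCuis, zCuis)))
}

#' Flag NER winners within (disease, model) groups
#'
#' An NER winner is a query attaining the maximum observed n2 or the
#' maximum observed n3 within its (disease, model) group; the two maxima are
#' flagged separately and ties produce multiple winners.
#'
#' @param stats data.frame with columns \code{disease}, \code{model},
#'   \code{n2}, \code{n3} (plus any identifying columns, carried through).
#' @return the input with logical columns \code{max_n2} and \code{max_n3}
#'   appended.
#' @export
nerWinners <- function(stats) {
    stopifnot(all(c("disease", "model", "n2", "n3") %in% names(stats)))
    grp <- interaction(stats$disease, stats$model, drop = TRUE)
    stats$max_n2 <- stats$n2 == stats::ave(stats$n2, grp, FUN = max)
    stats$max_n3 <- stats$n3 == stats::ave(stats$n3, grp, FUN = max)
    stats
}
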