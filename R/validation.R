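#' The closed set of evidence-based category identifiers
#'
#' Seven categories refine what a disease-treatment concept correlation
#' means clinically. Stable identifiers are used in files and code; the
#' display names carry the full clinical wording. \code{"Tx_therapeutic"}
#' ("Tx with therapeutic effect") is the category that makes a concept count
#' toward the clinical statistic n4. \code{"general_medical_term"} is the
#' only category that requires no supporting evidence quote.
#'
#' @return named character vector mapping identifier to display name.
#' @export
evidenceCategories <- function() {
    c(Tx_therapeutic = "Tx with therapeutic effect",
      Tx_uncertain = "Tx with uncertain therapeutic effect",
      Tx_adverse = "Tx with unwanted or adverse effects (ie, nontherapeutic)",
      Tx_potential = "Potential Tx (under research and development)",
      Tx_ingredient = "Tx ingredient",
      general_medical_term = "General medical term",
      correlation = "Correlation")
}

.checkCategories <- function(cats) {
    bad <- setdiff(unlist(cats), names(evidenceCategories()))
    if (length(bad))
        stop("unknown evidence categor(ies): ", paste(bad, collapse = ", "))
}

#' Expand a multi-concept candidate row into per-concept evidence records
#'
#' Annotated candidate tables pipe-join both the CUIs and the evidence
#' categories of a candidate n-gram. When the two lists have equal length
#' they are aligned positionally (category i belongs to CUI i). Otherwise
#' every CUI receives every category: a single category annotated on a
#' three-concept candidate applies to all three, and two categories on a
#' one-concept candidate both attach to it. Unequal lengths where both
#' exceed one are ambiguous and raise a warning before falling back to the
#' everything-to-everyone rule.
#'
#' @param candidates data.frame with columns \code{y}, \code{label},
#'   \code{cuis}, \code{categories} (pipe-joined identifiers from
#'   [evidenceCategories()]).
#' @param xCui CUI of the target disease concept X.
#' @return data.frame of evidence records: \code{x_cui}, \code{y_cui},
#'   \code{categories} (pipe-joined), one row per (X, Y) concept pair.
#' @export
evidenceFromCandidates <- function(candidates, xCui) {
    stopifnot(all(c("y", "label", "cuis", "categories") %in%
                  names(candidates)))
    rows <- list()
    for (i in seq_len(nrow(candidates))) {
        if (candidates$label[i] != "Tx") next
        cuis <- .splitPipe(candidates$cuis[i])
        cats <- .splitPipe(candidates$categories[i])
        .checkCategories(cats)
        if (!length(cuis)) next
        if (length(cats) == length(cuis)) {
            rec <- data.frame(x_cui = xCui, y_cui = cuis, categories = cats,
                              stringsAsFactors = FALSE)
        } else {
            if (length(cats) > 1L && length(cuis) > 1L)
                warning(sprintf(
                    "candidate '%s': %d CUIs vs %d categories; assigning all categories to every CUI",
                    candidates$y[i], length(cuis), length(cats)))
            rec <- data.frame(x_cui = xCui, y_cui = cuis,
                              categories = paste(cats, collapse = "|"),
                              stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- rec
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(x_cui = character(), y_cui = character(),
                   categories = character(), stringsAsFactors = FALSE)
    ## merge duplicate concept pairs, pooling their categories
    key <- paste(out$x_cui, out$y_cui)
    if (anyDuplicated(key)) {
        out <- do.call(rbind, lapply(split(out, key), function(d)
            data.frame(x_cui = d$x_cui[1L], y_cui = d$y_cui[1L],
                       categories = paste(unique(unlist(
                           lapply(d$categories, .splitPipe))),
                           collapse = "|"),
                       stringsAsFactors = FALSE)))
        rownames(out) <- NULL
    }
    out
}

#' Clinical statistic n4 for one query
#'
#' The number of distinct candidate concepts \eqn{Y_{Tx}} of a query,
#' excluding the query's own treatment concepts Z1/Z2, whose evidence
#' includes the category "Tx with therapeutic effect". A concept carrying
#' several categories counts as long as one of them is therapeutic
#' (any-match semantics).
#'
#' @param candidates data.frame with columns \code{y}, \code{label},
#'   \code{cuis} — the query's ranked Tx-labeled candidates (non-Tx rows are
#'   ignored).
#' @param evidence data.frame of evidence records with columns \code{x_cui},
#'   \code{y_cui}, \code{categories} (pipe-joined identifiers); must cover
#'   every (X, Y_Tx) concept pair of the query.
#' @param zCuis CUIs of z1/z2, excluded from the count.
#' @param xCui CUI of the target disease (used to select this query's
#'   evidence records).
#' @return integer n4.
#' @seealso [nerStats()] for n1-n3; n4 can never exceed n3.
#' @export
queryN4 <- function(candidates, evidence, zCuis, xCui) {
    stopifnot(all(c("x_cui", "y_cui", "categories") %in% names(evidence)))
    tx <- candidates[candidates$label == "Tx", , drop = FALSE]
    yCuis <- setdiff(unique(unlist(lapply(tx$cuis, .splitPipe))), zCuis)
    ev <- evidence[evidence$x_cui == xCui, , drop = FALSE]
    missing <- setdiff(yCuis, ev$y_cui)
    if (length(missing))
        stop("no evidence record for concept pair(s): ",
             paste(paste0("(", xCui, ",", missing, ")"), collapse = ", "))
    hasTx <- vapply(yCuis, function(cui) {
        cats <- unlist(lapply(ev$categories[ev$y_cui == cui], .splitPipe))
        .checkCategories(cats)
        "Tx_therapeutic" %in% cats
    }, logical(1))
    sum(hasTx)
}

#' Flag clinical winners within (disease, model) groups
#'
#' A clinical winner is a query attaining the maximum observed n4 in its
#' (disease, model) group — the query that surfaced the most evidence-backed
#' beneficial treatments. Ties produce multiple winners. A clinical winner
#' need not be an NER winner: a query can map to many treatment concepts of
#' which few are therapeutic, and vice versa.
#'
#' @param n4Table data.frame with columns \code{disease}, \code{model},
#'   \code{n4}.
#' @return the input with a logical \code{clinical_winner} column appended.
#' @export
clinicalWinners <- function(n4Table) {
    stopifnot(all(c("disease", "model", "n4") %in% names(n4Table)))
    grp <- interaction(n4Table$disease, n4Table$model, drop = TRUE)
    n4Table$clinical_winner <-
        n4Table$n4 == stats::ave(n4Table$n4, grp, FUN = max)
    n4Table
}

#' Per-observer evidence views after an audit
#'
#' Independent observers audit the expert evidence records, expressing
#' agreement or disagreement per concept pair; on disagreement they supply
#' replacement categories. This function builds one evidence view per
#' observer in which disagreed pairs carry the observer's categories, while
#' the expert baseline is left untouched — so baseline and per-observer
#' statistics (n4, clinical winners) are all computable from one dataset.
#'
#' @param evidence baseline evidence records (\code{x_cui}, \code{y_cui},
#'   \code{categories}).
#' @param judgments data.frame with columns \code{observer}, \code{x_cui},
#'   \code{y_cui}, \code{verdict} (\code{"agree"}/\code{"disagree"}),
#'   \code{replacement_categories} (pipe-joined; only for disagreements).
#' @return named list: observer id to evidence data.frame.
#' @export
applyObserverOverrides <- function(evidence, judgments) {
    if (is.null(judgments) || !nrow(judgments))
        return(list())
    stopifnot(all(c("observer", "x_cui", "y_cui", "verdict") %in%
                  names(judgments)))
    evKey <- paste(evidence$x_cui, evidence$y_cui)
    out <- list()
    for (obs in unique(judgments$observer)) {
        j <- judgments[judgments$observer == obs, , drop = FALSE]
        jKey <- paste(j$x_cui, j$y_cui)
        unknown <- setdiff(jKey, evKey)
        if (length(unknown))
            stop("judgment for unknown concept pair(s): ",
                 paste(unknown, collapse = "; "))
        view <- evidence
        dis <- j[j$verdict == "disagree", , drop = FALSE]
        if (nrow(dis)) {
            repl <- dis$replacement_categories
            .checkCategories(lapply(repl, .splitPipe))
            view$categories[match(paste(dis$x_cui, dis$y_cui), evKey)] <- repl
        }
        out[[as.character(obs)]] <- view
    }
    out
}
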