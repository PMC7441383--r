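#' Detect an abbreviation/acronym inside an n-gram
#'
#' Rule-based fallback used when no curated short-form flag is available: a
#' token counts as containing a short form when any underscore- or
#' hyphen-delimited sub-token has two or more consecutive uppercase letters
#' (AED, LABAs, (CRT), ...). Since the delimiters are not letters, this is
#' equivalent to the whole token containing an uppercase run of length >= 2.
#' A documented approximation of the curated judgment, not a reconstruction
#' of it.
#'
#' @param token character vector of n-grams.
#' @return logical vector.
#' @examples
#' detectShortForm(c("AED", "valproate",
#'                   "cardiac_resynchronization_therapy_(CRT)"))
#' @export
detectShortForm <- function(token) {
    grepl("[A-Z]{2}", as.character(token))
}

#' Assemble the per-query inputs of the selection heuristic
#'
#' Derives, for each query \code{-x +z1 +z2}, the raw facts the Boolean
#' heuristic needs: whether z1/z2 contain short forms (from an explicit flag
#' table when supplied, else [detectShortForm()]), whether each z appears
#' among the \code{topN} cosine neighbors of the target x in the reference
#' space (Skip-gram by convention), and the corpus frequency of z2.
#'
#' @param queries data.frame with columns \code{x}, \code{z1}, \code{z2}.
#' @param space reference [EmbeddingSpace-class] for the neighbor test.
#' @param frequencies named numeric vector of corpus counts (defaults to the
#'   space's own); tokens without a count get 0.
#' @param shortFormFlags optional data.frame \code{token},
#'   \code{short_form} (0/1 or logical) overriding rule-based detection.
#' @param topN neighborhood size for the membership test (default 20).
#' @return the queries with logical columns \code{z1_short_form},
#'   \code{z2_short_form}, \code{z1_in_top}, \code{z2_in_top} and numeric
#'   \code{z2_frequency} appended.
#' @export
buildHeuristicInputs <- function(queries, space, frequencies = NULL,
                                 shortFormFlags = NULL, topN = 20L) {
    stopifnot(all(c("x", "z1", "z2") %in% names(queries)))
    if (is.null(frequencies)) frequencies <- tokenFrequencies(space)
    sf <- function(tok) {
        if (!is.null(shortFormFlags)) {
            i <- match(tok, shortFormFlags$token)
            known <- !is.na(i)
            out <- logical(length(tok))
            out[known] <- as.logical(shortFormFlags$short_form[i[known]])
            out[!known] <- detectShortForm(tok[!known])
            out
        } else detectShortForm(tok)
    }
    topSets <- lapply(unique(queries$x), function(x)
        nearestByCosine(space, x, k = topN)$token)
    names(topSets) <- unique(queries$x)
    inTop <- function(z, x) mapply(function(zi, xi) zi %in% topSets[[xi]],
                                   z, x, USE.NAMES = FALSE)
    queries$z1_short_form <- sf(queries$z1)
    queries$z2_short_form <- sf(queries$z2)
    queries$z1_in_top <- inTop(queries$z1, queries$x)
    queries$z2_in_top <- inTop(queries$z2, queries$x)
    f <- frequencies[queries$z2]
    queries$z2_frequency <- ifelse(is.na(f), 0, as.numeric(f))
    queries
}

#' Apply the Boolean clinical-winner heuristic
#'
#' Conjunction of three empirical conditions predicting which queries will
#' surface evidence-backed beneficial treatments:
#' \describe{
#'   \item{a}{neither z1 nor z2 contains a short form;}
#'   \item{b}{z1 or z2 (or both) does \emph{not} appear among the target's
#'     \code{topN} cosine neighbors — the query must reach beyond the
#'     obvious neighborhood;}
#'   \item{c}{z2's corpus frequency exceeds 100 (strictly).}
#' }
#' \code{selected = a AND b AND c}.
#'
#' @param inputs data.frame from [buildHeuristicInputs()] (columns
#'   \code{z1_short_form}, \code{z2_short_form}, \code{z1_in_top},
#'   \code{z2_in_top}, \code{z2_frequency}).
#' @param freqThreshold strict lower bound for condition c (default 100).
#' @return the input with logical columns \code{condition_a},
#'   \code{condition_b}, \code{condition_c}, \code{selected} appended.
#' @export
applyHeuristic <- function(inputs, freqThreshold = 100) {
    need <- c("z1_short_form", "z2_short_form", "z1_in_top", "z2_in_top",
              "z2_frequency")
    stopifnot(all(need %in% names(inputs)))
    inputs$condition_a <- !(inputs$z1_short_form | inputs$z2_short_form)
    inputs$condition_b <- !inputs$z1_in_top | !inputs$z2_in_top
    inputs$condition_c <- inputs$z2_frequency > freqThreshold
    inputs$selected <- inputs$condition_a & inputs$condition_b &
        inputs$condition_c
    inputs
}

#' Precision/recall of a query selector across n4 thresholds
#'
#' Sweeps thresholds t over the clinical statistic n4: a query is a true
#' positive at t when it is selected and \code{n4 > t}, a false positive
#' when selected with \code{n4 <= t}, a false negative when unselected with
#' \code{n4 > t}, and a true negative otherwise. Since the selector is fixed,
#' TP+FP equals the number of selected queries at every threshold.
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), both as percentages rounded
#' to 2 decimals; precision is NA (undefined, not zero) when nothing is
#' selected, and likewise recall when no query exceeds the threshold.
#'
#' @param selected named logical vector: query id to selector decision.
#' @param n4 named integer vector over the same query ids.
#' @param thresholds integer thresholds to sweep (default 0:7).
#' @return data.frame with columns \code{threshold}, \code{tp}, \code{fp},
#'   \code{fn}, \code{tn}, \code{precision}, \code{recall}.
#' @export
evaluateThresholds <- function(selected, n4, thresholds = 0:7) {
    if (!setequal(names(selected), names(n4)))
        stop("'selected' and 'n4' must cover the same queries")
    n4 <- n4[names(selected)]
    out <- lapply(thresholds, function(t) {
        pos <- n4 > t
        tp <- sum(selected & pos); fp <- sum(selected & !pos)
        fn <- sum(!selected & pos); tn <- sum(!selected & !pos)
        data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = if (tp + fp > 0)
                       round(100 * tp / (tp + fp), 2) else NA_real_,
                   recall = if (tp + fn > 0)
                       round(100 * tp / (tp + fn), 2) else NA_real_)
    })
    do.call(rbind, out)
}

#' A benchmark selector/n4 table with known threshold behavior
#'
#' Reconstructs, programmatically, a canonical set of 304 evaluated queries
#' (93 selected) whose n4 distribution yields the reference confusion counts
#' at thresholds 0..7: TP 91, 84, 73, 48, 28, 14, 9, 4 against FN 189, 151,
#' 111, 76, 52, 20, 5, 0. Useful as a worked example and as a fixture for
#' validating [evaluateThresholds()] end to end.
#'
#' @return list with named logical \code{selected} and named integer
#'   \code{n4}.
#' @export
heuristicBenchmark <- function() {
    ## per-n4 query counts implied by the reference TP/FN columns
    selN4 <- c(`0` = 2, `1` = 7, `2` = 11, `3` = 25, `4` = 20, `5` = 14,
               `6` = 5, `7` = 5, `8` = 4)
    unsN4 <- c(`0` = 22, `1` = 38, `2` = 40, `3` = 35, `4` = 24, `5` = 32,
               `6` = 15, `7` = 5, `8` = 0)
    n4 <- c(rep(as.integer(names(selN4)), selN4),
            rep(as.integer(names(unsN4)), unsN4))
    selected <- rep(c(TRUE, FALSE), c(sum(selN4), sum(unsN4)))
    ids <- sprintf("q%03d", seq_along(n4))
    list(selected = stats::setNames(selected, ids),
         n4 = stats::setNames(n4, ids))
}
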