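#' Run the full analogy-discovery pipeline on file inputs
#'
#' Executes the three stages end to end and the heuristic evaluation:
#' \enumerate{
#'   \item knowledge acquisition — build every \code{-x +z1 +z2} query from
#'     the prior pairs and run it against each supplied embedding space,
#'     keeping the top \code{k} candidates (non-ASCII candidates
#'     discarded);
#'   \item knowledge organization — resolve Tx labels by majority over the
#'     raters, compute Krippendorff's alpha, attach concept mappings and
#'     derive n1/n2/n3 with NER winners;
#'   \item knowledge validation — derive n4 from the evidence records and
#'     flag clinical winners;
#'   \item heuristic — assemble the Boolean-heuristic inputs against the
#'     reference space, apply it, and sweep precision/recall over the n4
#'     thresholds.
#' }
#' All result tables are written as TSVs plus a JSON run summary.
#'
#' @param vectorFiles named character vector of word2vec text files; names
#'   are the model tags (e.g. \code{c(CBOW = "...", `Skip-gram` = "...")}).
#'   The last space is the reference for the heuristic's neighbor test.
#' @param freqFile 2-column TSV \code{token<TAB>count}.
#' @param priorPairsFile prior-knowledge pair TSV, see [readPriorPairs()].
#' @param annotationsFile rater-label TSV (\code{pair_id}, \code{rater},
#'   \code{label}).
#' @param mappingsFile concept-mapping TSV (\code{token}, \code{cuis}).
#' @param evidenceFile evidence TSV (\code{x_cui}, \code{y_cui},
#'   \code{categories}, ...).
#' @param outDir directory for the output tables.
#' @param k candidates retained per query (default 12).
#' @param topNCosine neighborhood size of the heuristic's condition b
#'   (default 20).
#' @param freqThreshold strict frequency bound of condition c (default 100).
#' @param thresholds n4 thresholds to sweep (default 0:7).
#' @param variant analogy scoring variant, see [analogyScores()].
#' @return invisibly, a list with \code{candidates}, \code{stats} (per-query
#'   n1..n4 with winner flags), \code{alpha}, \code{heuristic} (per-query
#'   decisions), \code{thresholds} (the precision/recall sweep) and
#'   \code{summary}.
#' @export
runPipeline <- function(vectorFiles, freqFile, priorPairsFile,
                        annotationsFile, mappingsFile, evidenceFile,
                        outDir, k = 12L, topNCosine = 20L,
                        freqThreshold = 100, thresholds = 0:7,
                        variant = c("composite", "additive")) {
    variant <- match.arg(variant)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(names(vectorFiles)) || any(!nzchar(names(vectorFiles))))
        stop("'vectorFiles' must be named by model tag")
    spaces <- lapply(names(vectorFiles), function(tag)
        readWordVectors(vectorFiles[[tag]], frequencies = freqFile,
                        modelTag = tag))
    names(spaces) <- names(vectorFiles)
    prior <- readPriorPairs(priorPairsFile)
    ann <- readTsv(annotationsFile)
    mappings <- readTsv(mappingsFile)
    evidence <- readTsv(evidenceFile)

    ## Stage 1: queries against every space
    queries <- buildQueries(prior)
    runs <- lapply(spaces, runQueries, queries = queries, k = k,
                   variant = variant)
    candidates <- do.call(rbind, lapply(runs, `[[`, "candidates"))
    rownames(candidates) <- NULL

    ## Stage 2: labels, mappings, n1-n3
    alpha <- krippendorffAlpha(ann)
    labels <- consensusTx(ann)
    cuisOf <- stats::setNames(as.character(mappings$cuis), mappings$token)
    zCuisOf <- lapply(split(prior$z_cuis, prior$z_token), function(x)
        unique(unlist(lapply(x, .splitPipe))))
    xCuiOf <- stats::setNames(as.character(prior$x_cui), prior$x_token)
    key <- interaction(candidates$model_tag, candidates$x, candidates$z1,
                       candidates$z2, drop = TRUE)
    perQuery <- split(candidates, key)
    stats <- do.call(rbind, lapply(perQuery, function(cand) {
        q <- cand[1L, c("model_tag", "x", "z1", "z2")]
        cand$label <- unname(labels[cand$y])
        cand$cuis <- unname(cuisOf[cand$y])
        cand$cuis[is.na(cand$cuis)] <- ""
        zc <- unique(c(zCuisOf[[q$z1]], zCuisOf[[q$z2]]))
        ns <- nerStats(cand, zc)
        n4 <- queryN4(cand, evidence, zc, xCuiOf[[q$x]])
        data.frame(disease = q$x, model = q$model_tag, z1 = q$z1,
                   z2 = q$z2, n1 = ns$n1, n2 = ns$n2, n3 = ns$n3, n4 = n4,
                   stringsAsFactors = FALSE)
    }))
    rownames(stats) <- NULL
    stats <- nerWinners(stats)
    stats <- clinicalWinners(stats)

    ## Stage 4: heuristic against the reference (last) space
    refSpace <- spaces[[length(spaces)]]
    sfFlags <- if ("z_short_form" %in% names(prior))
        data.frame(token = prior$z_token,
                   short_form = prior$z_short_form) else NULL
    hq <- unique(stats[c("disease", "model", "z1", "z2", "n4")])
    names(hq)[1L] <- "x"
    hin <- buildHeuristicInputs(hq, refSpace, shortFormFlags = sfFlags,
                                topN = topNCosine)
    hin <- applyHeuristic(hin, freqThreshold = freqThreshold)
    qid <- paste(hin$model, hin$x, hin$z1, hin$z2, sep = "::")
    sweep <- evaluateThresholds(
        stats::setNames(hin$selected, qid),
        stats::setNames(hin$n4, qid), thresholds = thresholds)

    writeTsv(candidates, file.path(outDir, "query_results.tsv"))
    writeTsv(stats, file.path(outDir, "winners.tsv"))
    writeTsv(hin, file.path(outDir, "heuristic.tsv"))
    writeTsv(sweep, file.path(outDir, "threshold_eval.tsv"))
    summary <- list(
        models = names(spaces),
        n_prior_pairs = nrow(prior),
        n_queries = nrow(queries),
        n_queries_run = nrow(queries) * length(spaces),
        n_candidate_pairs = nrow(candidates),
        n_discarded = sum(vapply(runs, function(r) nrow(r$discarded), 0L)),
        n_failed = sum(vapply(runs, function(r) nrow(r$failed), 0L)),
        krippendorff_alpha = alpha,
        n_ner_winners_n2 = sum(stats$max_n2),
        n_ner_winners_n3 = sum(stats$max_n3),
        n_clinical_winners = sum(stats$clinical_winner),
        n_selected = sum(hin$selected))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(candidates = candidates, stats = stats, alpha = alpha,
                   heuristic = hin, thresholds = sweep, summary = summary))
}
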