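#' Configuration for the synthetic embedding benchmark
#'
#' Bundles and validates the knobs of the planted-structure generator. The
#' generator emulates the situation the analogy pipeline faces: a vocabulary
#' carrying semantic fields (one per disease, one treatment field per
#' disease, distractor fields), corpus frequency counts straddling the
#' heuristic's >100 boundary, short-form spellings among treatment n-grams,
#' imperfect raters, and evidence categories with a controlled share of
#' "Tx with therapeutic effect".
#'
#' @param nDiseases number of target diseases (default 10, the study scale).
#' @param treatmentsPerDisease planted treatment n-grams per disease.
#' @param nDistractors vocabulary tokens outside all disease/treatment
#'   fields, grouped into small unrelated fields.
#' @param dimension embedding dimension.
#' @param intraFieldCosine target expected cosine between a field member and
#'   its field centroid, in (0, 1); 0.95 is a strong planted signal, values
#'   near 0 approach pure noise.
#' @param raterAccuracy probability a simulated rater reproduces the true
#'   Tx/non-Tx label, in (0.5, 1].
#' @param pTherapeutic probability an evidence record carries the
#'   therapeutic category (default 190/427, the share observed in curated
#'   disease-treatment evidence).
#' @param pMultiCategory fraction of evidence records carrying a second
#'   category (default 19/408).
#' @param pMultiCui fraction of treatment tokens mapping to two concepts.
#' @param pSynonym fraction of treatment tokens that share a concept with
#'   another treatment in their field (surface variants of one concept).
#' @param pShortForm fraction of treatment tokens spelled as short forms.
#' @param mappingErrorRate corruption rate of the "automatic" concept
#'   mappings relative to gold.
#' @param seed integer; fixes every stochastic draw of the generators.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nDiseases = 10L, treatmentsPerDisease = 6L,
                      nDistractors = 60L, dimension = 50L,
                      intraFieldCosine = 0.9, raterAccuracy = 0.93,
                      pTherapeutic = 190 / 427, pMultiCategory = 19 / 408,
                      pMultiCui = 0.1, pSynonym = 0.1, pShortForm = 0.15,
                      mappingErrorRate = 0.05, seed = 1L) {
    cfg <- list(nDiseases = as.integer(nDiseases),
                treatmentsPerDisease = as.integer(treatmentsPerDisease),
                nDistractors = as.integer(nDistractors),
                dimension = as.integer(dimension),
                intraFieldCosine = intraFieldCosine,
                raterAccuracy = raterAccuracy,
                pTherapeutic = pTherapeutic,
                pMultiCategory = pMultiCategory,
                pMultiCui = pMultiCui, pSynonym = pSynonym,
                pShortForm = pShortForm,
                mappingErrorRate = mappingErrorRate,
                seed = as.integer(seed))
    with(cfg, {
        stopifnot(nDiseases >= 1, treatmentsPerDisease >= 2,
                  nDistractors >= 0, dimension >= 2,
                  raterAccuracy > 0.5, raterAccuracy <= 1,
                  pTherapeutic >= 0, pTherapeutic <= 1)
        if (intraFieldCosine <= 0 || intraFieldCosine >= 1)
            stop("intraFieldCosine must lie strictly in (0, 1)")
    })
    structure(cfg, class = "SimConfig")
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

.unitRows <- function(m) m / sqrt(rowSums(m^2))

#' Generate an embedding space with planted semantic fields
#'
#' Each field gets a random unit centroid; a member vector is the normalized
#' sum of the centroid and isotropic Gaussian noise whose scale is chosen so
#' the expected member-centroid cosine matches
#' \code{cfg$intraFieldCosine} (noise sd \eqn{\sigma =
#' \sqrt{(\rho^{-2}-1)/d}} per coordinate). Diseases are singleton fields;
#' each disease owns a treatment field; distractors fall into small
#' unrelated fields. Frequencies are drawn from a long-tailed log-normal
#' spanning the >100 boundary, and a configured fraction of treatment tokens
#' are spelled as short forms (uppercase codes).
#'
#' @param cfg a [simConfig()].
#' @param modelTag label for the resulting space (default \code{"CBOW"}).
#' @param seedOffset added to \code{cfg$seed}, letting one configuration
#'   yield several independent spaces (e.g. a CBOW-like and a
#'   Skip-gram-like space).
#' @return list with elements \code{space} (an [EmbeddingSpace-class]) and
#'   \code{truth}, the planted ground truth: \code{fields} (name to token
#'   set), \code{diseases}, \code{treatments} (disease to token set),
#'   \code{intended_analogies} (data.frame \code{x}, \code{z1}, \code{z2}
#'   and list-column \code{expected_y}), \code{short_forms},
#'   \code{frequencies}.
#' @export
generateSpace <- function(cfg, modelTag = "CBOW", seedOffset = 0L) {
    stopifnot(inherits(cfg, "SimConfig"))
    ## vocabulary, frequencies and planted analogies depend only on
    ## cfg$seed, so spaces drawn at different offsets (CBOW-like vs
    ## Skip-gram-like) share one vocabulary and differ only in geometry
    scaffold <- .withSeed(cfg$seed, {
        diseases <- sprintf("disease_%02d", seq_len(cfg$nDiseases))
        treatments <- lapply(seq_len(cfg$nDiseases), function(i) {
            toks <- sprintf("tx%02d_%02d", i,
                            seq_len(cfg$treatmentsPerDisease))
            nSf <- round(cfg$pShortForm * length(toks))
            if (nSf > 0) {
                sf <- sample(seq_along(toks), nSf)
                toks[sf] <- toupper(toks[sf])
            }
            toks
        })
        names(treatments) <- diseases
        nDistFields <- max(1L, ceiling(cfg$nDistractors / 5L))
        distractors <- if (cfg$nDistractors > 0)
            sprintf("dist_%03d", seq_len(cfg$nDistractors)) else character(0)
        fields <- c(
            stats::setNames(as.list(diseases), paste0("field_", diseases)),
            stats::setNames(treatments, paste0("field_tx_", diseases)),
            if (length(distractors))
                split(distractors,
                      rep(seq_len(nDistFields), length.out =
                          length(distractors))))
        vocab <- unlist(fields, use.names = FALSE)
        freq <- stats::setNames(
            pmax(1L, as.integer(round(stats::rlnorm(
                length(vocab), meanlog = log(60), sdlog = 1.5)))), vocab)
        analogies <- do.call(rbind, lapply(diseases, function(x) {
            z <- treatments[[x]]
            idx <- utils::combn(length(z), 2L)
            data.frame(x = x, z1 = z[idx[1L, ]], z2 = z[idx[2L, ]],
                       stringsAsFactors = FALSE)
        }))
        analogies$expected_y <- lapply(seq_len(nrow(analogies)), function(i)
            setdiff(treatments[[analogies$x[i]]],
                    c(analogies$z1[i], analogies$z2[i])))
        list(fields = fields, diseases = diseases, treatments = treatments,
             vocab = vocab, freq = freq, analogies = analogies)
    })
    .withSeed(cfg$seed + 7919L * (seedOffset + 1L), {
        d <- cfg$dimension
        rho <- cfg$intraFieldCosine
        sigma <- sqrt((1 / rho^2 - 1) / d)
        vecs <- matrix(0, length(scaffold$vocab), d,
                       dimnames = list(scaffold$vocab, NULL))
        for (f in scaffold$fields) {
            centroid <- .unit(stats::rnorm(d))
            noise <- matrix(stats::rnorm(length(f) * d, sd = sigma),
                            length(f), d)
            vecs[f, ] <- .unitRows(sweep(noise, 2, centroid, "+"))
        }
        list(space = EmbeddingSpace(vecs, frequencies = scaffold$freq,
                                    modelTag = modelTag),
             truth = list(fields = scaffold$fields,
                          diseases = scaffold$diseases,
                          treatments = scaffold$treatments,
                          intended_analogies = scaffold$analogies,
                          short_forms =
                              scaffold$vocab[detectShortForm(scaffold$vocab)],
                          frequencies = scaffold$freq))
    })
}

#' Generate rater annotations and concept mappings for a planted space
#'
#' Emulates the knowledge-organization inputs: three raters label every
#' token as Tx (member of any planted treatment field) or non-Tx, each
#' flipping the true label independently with probability
#' \code{1 - raterAccuracy}; gold concept mappings assign synthetic CUIs in
#' a \code{SYN######} namespace (never colliding with real UMLS
#' identifiers), with configured fractions of two-concept tokens and of
#' surface-variant tokens sharing a concept; an automatic mapping variant
#' corrupts gold at \code{mappingErrorRate} for mapping-evaluation tests.
#'
#' @param truth the \code{truth} component of [generateSpace()].
#' @param cfg the same [simConfig()].
#' @param nRaters number of simulated raters (default 3).
#' @return list with \code{annotations} (data.frame \code{pair_id},
#'   \code{rater}, \code{label}), \code{gold} and \code{auto} mapping
#'   data.frames (\code{token}, \code{cuis}, \code{provenance}), and
#'   \code{txTruth}, the true token-level labels.
#' @export
generateAnnotations <- function(truth, cfg, nRaters = 3L) {
    stopifnot(inherits(cfg, "SimConfig"))
    .withSeed(cfg$seed + 1000L, {
        vocab <- unlist(truth$fields, use.names = FALSE)
        txTokens <- unlist(truth$treatments, use.names = FALSE)
        isTx <- vocab %in% txTokens
        txTruth <- stats::setNames(ifelse(isTx, "Tx", "non-Tx"), vocab)
        ann <- do.call(rbind, lapply(seq_len(nRaters), function(r) {
            flip <- stats::runif(length(vocab)) > cfg$raterAccuracy
            lab <- ifelse(xor(isTx, flip), "Tx", "non-Tx")
            data.frame(pair_id = vocab, rater = paste0("rater", r),
                       label = lab, stringsAsFactors = FALSE)
        }))
        ## gold mappings: one CUI per token, with synonym and multi-CUI shares
        cui <- stats::setNames(sprintf("SYN%06d", seq_along(vocab)), vocab)
        for (f in truth$treatments) {
            if (length(f) < 2L) next
            syn <- f[stats::runif(length(f)) < cfg$pSynonym]
            for (s in syn)
                cui[s] <- cui[f[1L]]  # surface variant of the field's head
        }
        cuis <- as.list(cui)
        multi <- txTokens[stats::runif(length(txTokens)) < cfg$pMultiCui]
        for (tok in multi)
            cuis[[tok]] <- c(cuis[[tok]],
                             sprintf("SYN9%05d", match(tok, vocab)))
        gold <- data.frame(token = vocab,
                           cuis = vapply(cuis[vocab], paste, "",
                                         collapse = "|"),
                           provenance = "gold", stringsAsFactors = FALSE)
        corrupt <- stats::runif(length(vocab)) < cfg$mappingErrorRate
        autoCuis <- gold$cuis
        autoCuis[corrupt] <- sprintf("SYNERR%04d", which(corrupt))
        auto <- data.frame(token = vocab, cuis = autoCuis,
                           provenance = "automatic",
                           stringsAsFactors = FALSE)
        rownames(gold) <- rownames(auto) <- NULL
        list(annotations = ann, gold = gold, auto = auto, txTruth = txTruth)
    })
}

#' Generate evidence-category records for a planted space
#'
#' Every (disease concept, candidate concept) pair gets an evidence record:
#' with probability \code{pTherapeutic} its category set contains
#' "Tx with therapeutic effect", otherwise one of the six remaining
#' categories drawn with weights matching their curated prevalence
#' (38 : 52 : 5 : 22 : 26 : 94); a \code{pMultiCategory} fraction of
#' records carries a second category. Records for non-"general medical
#' term" categories get a synthetic quote and source reference.
#'
#' @param truth the \code{truth} component of [generateSpace()].
#' @param cfg the same [simConfig()].
#' @param mappings gold mapping data.frame from [generateAnnotations()].
#' @return data.frame of evidence records (\code{x_cui}, \code{y_cui},
#'   \code{categories}, \code{quote}, \code{source_ref}) covering every
#'   disease x non-disease concept pair, with attribute
#'   \code{"therapeutic_set"}: the tokens having at least one therapeutic
#'   record.
#' @export
generateEvidence <- function(truth, cfg, mappings) {
    stopifnot(inherits(cfg, "SimConfig"))
    .withSeed(cfg$seed + 2000L, {
        cuisOf <- stats::setNames(lapply(mappings$cuis, .splitPipe),
                                  mappings$token)
        vocab <- mappings$token
        allCats <- names(evidenceCategories())
        others <- setdiff(allCats, "Tx_therapeutic")
        wOther <- c(38, 52, 5, 22, 26, 94)
        wOther <- wOther / sum(wOther)
        ## flat (token, cui) expansion once, then one block per disease
        flatTok <- rep(names(cuisOf), lengths(cuisOf))
        flatCui <- unlist(cuisOf, use.names = FALSE)
        blocks <- lapply(truth$diseases, function(x) {
            keep <- flatTok != x
            data.frame(x = x, x_cui = cuisOf[[x]][1L], y = flatTok[keep],
                       y_cui = flatCui[keep], stringsAsFactors = FALSE)
        })
        ev <- do.call(rbind, blocks)
        n <- nrow(ev)
        ther <- stats::runif(n) < cfg$pTherapeutic
        cat1 <- ifelse(ther, "Tx_therapeutic",
                       sample(others, n, replace = TRUE, prob = wOther))
        addSecond <- stats::runif(n) < cfg$pMultiCategory
        cats <- cat1
        if (any(addSecond))
            cats[addSecond] <- vapply(which(addSecond), function(i)
                paste(c(cat1[i], sample(setdiff(allCats, cat1[i]), 1L)),
                      collapse = "|"), "")
        ev$categories <- cats
        onlyGmt <- cats == "general_medical_term"
        ev$quote <- ifelse(onlyGmt, "",
                           sprintf("synthetic evidence for %s in %s",
                                   ev$y, ev$x))
        ev$source_ref <- ifelse(onlyGmt, "",
                                sprintf("SYNSRC:%s_%s", ev$x, ev$y))
        ## one record per concept pair: keep the first draw
        keep <- !duplicated(ev[c("x_cui", "y_cui")])
        therTokens <- unique(ev$y[keep & ther])
        ev <- ev[keep, c("x_cui", "y_cui", "categories", "quote",
                         "source_ref")]
        rownames(ev) <- NULL
        attr(ev, "therapeutic_set") <- therTokens
        ev
    })
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates a planted space (plus a second, independently drawn space
#' tagged Skip-gram), annotations, mappings and evidence, and writes them in
#' the package's interchange formats: \code{vectors_cbow.txt},
#' \code{vectors_skipgram.txt} (word2vec text format), \code{freq.tsv},
#' \code{prior_pairs.tsv} (first three treatments per disease, with their
#' gold concepts and short-form flags), \code{annotations.tsv},
#' \code{mappings.tsv}, \code{evidence.tsv}, and \code{truth.json}.
#'
#' @param cfg a [simConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the list of generated in-memory objects.
#' @export
simulateBundle <- function(cfg, outDir) {
    stopifnot(inherits(cfg, "SimConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cb <- generateSpace(cfg, modelTag = "CBOW", seedOffset = 0L)
    sg <- generateSpace(cfg, modelTag = "Skip-gram", seedOffset = 1L)
    ann <- generateAnnotations(cb$truth, cfg)
    ev <- generateEvidence(cb$truth, cfg, ann$gold)
    cuisOf <- stats::setNames(ann$gold$cuis, ann$gold$token)
    prior <- do.call(rbind, lapply(cb$truth$diseases, function(x) {
        z <- utils::head(cb$truth$treatments[[x]], 3L)
        data.frame(x_token = x, z_token = z,
                   x_cui = .splitPipe(cuisOf[[x]])[1L],
                   z_cuis = unname(cuisOf[z]),
                   z_short_form = as.integer(detectShortForm(z)),
                   stringsAsFactors = FALSE)
    }))
    writeWordVectors(cb$space, file.path(outDir, "vectors_cbow.txt"))
    writeWordVectors(sg$space, file.path(outDir, "vectors_skipgram.txt"))
    writeTsv(data.frame(token = names(cb$truth$frequencies),
                        count = as.integer(cb$truth$frequencies)),
             file.path(outDir, "freq.tsv"))
    writeTsv(prior, file.path(outDir, "prior_pairs.tsv"))
    writeTsv(ann$annotations, file.path(outDir, "annotations.tsv"))
    writeTsv(ann$gold, file.path(outDir, "mappings.tsv"))
    writeTsv(ev, file.path(outDir, "evidence.tsv"))
    truthJson <- list(
        diseases = cb$truth$diseases,
        treatments = cb$truth$treatments,
        short_forms = cb$truth$short_forms,
        therapeutic_set = attr(ev, "therapeutic_set"))
    jsonlite::write_json(truthJson, file.path(outDir, "truth.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    invisible(list(cbow = cb, skipgram = sg, annotations = ann,
                   evidence = ev, prior_pairs = prior))
}
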