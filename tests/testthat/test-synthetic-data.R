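smallCfg <- function(...) {
    args <- list(nDiseases = 4L, treatmentsPerDisease = 4L,
                 nDistractors = 20L, dimension = 25L,
                 intraFieldCosine = 0.95, seed = 42L)
    do.call(simConfig, utils::modifyList(args, list(...)))
}

test_that("generators are pure functions of configuration and seed", {
    cfg <- smallCfg()
    a <- generateSpace(cfg); b <- generateSpace(cfg)
    expect_identical(embeddingMatrix(a$space), embeddingMatrix(b$space))
    expect_identical(a$truth$intended_analogies$x,
                     b$truth$intended_analogies$x)
    annA <- generateAnnotations(a$truth, cfg)
    annB <- generateAnnotations(b$truth, cfg)
    expect_identical(annA$annotations, annB$annotations)
    evA <- generateEvidence(a$truth, cfg, annA$gold)
    evB <- generateEvidence(b$truth, cfg, annB$gold)
    expect_identical(evA$categories, evB$categories)
    ## different seed, different space
    c2 <- generateSpace(smallCfg(seed = 43L))
    expect_false(identical(embeddingMatrix(a$space),
                           embeddingMatrix(c2$space)))
    expect_error(simConfig(intraFieldCosine = 1.2), "strictly in")
})

test_that("planted fields respect the intra-field cosine target", {
    cfg <- smallCfg(nDistractors = 0L)
    g <- generateSpace(cfg)
    V <- embeddingMatrix(g$space)
    ## average pairwise cosine within a treatment field should approach
    ## the squared member-centroid target (independent directions of noise)
    fld <- g$truth$treatments[[1]]
    S <- V[fld, ] %*% t(V[fld, ])
    within <- mean(S[upper.tri(S)])
    expect_gt(within, 0.8)
    ## across unrelated fields similarity is low
    other <- g$truth$treatments[[2]]
    expect_lt(mean(V[fld, ] %*% t(V[other, ])), 0.5)
})

test_that("strong planted signal yields >=90% top-1 analogy recovery", {
    cfg <- simConfig(nDiseases = 10L, treatmentsPerDisease = 6L,
                     nDistractors = 60L, dimension = 50L,
                     intraFieldCosine = 0.95, seed = 7L)
    g <- generateSpace(cfg)
    an <- g$truth$intended_analogies
    an <- an[seq_len(min(100L, nrow(an))), ]
    hits <- vapply(seq_len(nrow(an)), function(i) {
        top <- topCandidates(g$space, an$x[i], an$z1[i], an$z2[i], k = 1)
        top$token %in% an$expected_y[[i]]
    }, logical(1))
    expect_gte(mean(hits), 0.9)
})

test_that("near-zero signal collapses recovery to chance level", {
    cfg <- smallCfg(intraFieldCosine = 0.02, seed = 9L)
    g <- generateSpace(cfg)
    an <- g$truth$intended_analogies
    hits <- vapply(seq_len(nrow(an)), function(i) {
        top <- topCandidates(g$space, an$x[i], an$z1[i], an$z2[i], k = 1)
        top$token %in% an$expected_y[[i]]
    }, logical(1))
    ## chance: |expected_y| out of (vocab - 3) eligible candidates
    pChance <- length(an$expected_y[[1]]) / (length(g$space) - 3)
    bound <- qbinom(0.999, nrow(an), pChance) / nrow(an)
    expect_lte(mean(hits), max(bound, 0.15))
})

test_that("perfect raters give alpha 1; imperfect raters match a Monte-Carlo oracle", {
    g <- generateSpace(smallCfg())
    annPerfect <- generateAnnotations(g$truth, smallCfg(raterAccuracy = 1))
    m <- .longToWideTest(annPerfect$annotations)
    expect_equal(krippendorffAlpha(m), 1.0)
    ## accuracy 0.93: compare against a direct large-sample simulation of
    ## the flip process (independent of the generator)
    cfgBig <- simConfig(nDiseases = 4L, treatmentsPerDisease = 4L,
                        nDistractors = 500L, dimension = 8L,
                        intraFieldCosine = 0.9, raterAccuracy = 0.93,
                        seed = 5L)
    gBig <- generateSpace(cfgBig)
    ann <- generateAnnotations(gBig$truth, cfgBig)
    alphaGen <- krippendorffAlpha(.longToWideTest(ann$annotations))
    set.seed(99)
    nMC <- 10000L
    pTx <- mean(ann$txTruth == "Tx")
    truthMC <- runif(nMC) < pTx
    mc <- sapply(1:3, function(r)
        ifelse(xor(truthMC, runif(nMC) > 0.93), "Tx", "non-Tx"))
    alphaMC <- krippendorffAlpha(mc)
    expect_lt(abs(alphaGen - alphaMC), 0.07)
})

test_that("mapping corruption drives the micro-averaged metrics", {
    g <- generateSpace(smallCfg())
    clean <- generateAnnotations(g$truth, smallCfg(mappingErrorRate = 0))
    r <- microPRF(clean$gold, clean$auto)
    expect_equal(c(r$precision, r$recall, r$f_measure), c(100, 100, 100))
    noisy <- generateAnnotations(g$truth, smallCfg(mappingErrorRate = 0.3))
    rn <- microPRF(noisy$gold, noisy$auto)
    expect_lt(rn$precision, 100)
    expect_lt(rn$recall, 100)
})

test_that("the therapeutic share controls n4 exactly at the extremes", {
    cfg1 <- smallCfg(pTherapeutic = 1, pMultiCategory = 0)
    g <- generateSpace(cfg1)
    ann <- generateAnnotations(g$truth, cfg1)
    ev <- generateEvidence(g$truth, cfg1, ann$gold)
    cuisOf <- setNames(ann$gold$cuis, ann$gold$token)
    an <- g$truth$intended_analogies[1:5, ]
    for (i in seq_len(nrow(an))) {
        ys <- an$expected_y[[i]]
        cand <- data.frame(y = ys, label = "Tx", cuis = unname(cuisOf[ys]))
        zc <- unique(unlist(strsplit(cuisOf[c(an$z1[i], an$z2[i])], "|",
                                     fixed = TRUE)))
        xCui <- strsplit(cuisOf[[an$x[i]]], "|", fixed = TRUE)[[1]][1]
        st <- nerStats(cand, zc)
        expect_equal(queryN4(cand, ev, zc, xCui), st$n3)   # p = 1
    }
    cfg0 <- smallCfg(pTherapeutic = 0, pMultiCategory = 0)
    ev0 <- generateEvidence(g$truth, cfg0, ann$gold)
    ys <- an$expected_y[[1]]
    cand <- data.frame(y = ys, label = "Tx", cuis = unname(cuisOf[ys]))
    zc <- unique(unlist(strsplit(cuisOf[c(an$z1[1], an$z2[1])], "|",
                                 fixed = TRUE)))
    xCui <- strsplit(cuisOf[[an$x[1]]], "|", fixed = TRUE)[[1]][1]
    expect_equal(queryN4(cand, ev0, zc, xCui), 0L)
    expect_length(attr(ev0, "therapeutic_set"), 0L)
})

test_that("evidence category frequencies track the configured weights", {
    ## ~10k concept pairs
    cfg <- simConfig(nDiseases = 20L, treatmentsPerDisease = 2L,
                     nDistractors = 480L, dimension = 8L,
                     intraFieldCosine = 0.9, pMultiCategory = 0,
                     seed = 17L)
    g <- generateSpace(cfg)
    ann <- generateAnnotations(g$truth, cfg)
    ev <- generateEvidence(g$truth, cfg, ann$gold)
    expect_gte(nrow(ev), 10000L)
    ther <- grepl("Tx_therapeutic", ev$categories)
    expect_lt(abs(mean(ther) - 190 / 427), 0.02)
    ## conditional distribution of the other six categories
    w <- c(Tx_uncertain = 38, Tx_adverse = 52, Tx_potential = 5,
           Tx_ingredient = 22, general_medical_term = 26, correlation = 94)
    w <- w / sum(w)
    othTab <- table(ev$categories[!ther]) / sum(!ther)
    for (nm in names(w))
        expect_lt(abs(othTab[[nm]] - w[[nm]]), 0.02)
})
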