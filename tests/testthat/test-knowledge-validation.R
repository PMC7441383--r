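## small worked query: 3 Tx candidates, 4 concepts
valFixture <- function() {
    cand <- data.frame(
        y = c("drug_a", "combo_ab", "junk", "drug_c"),
        label = c("Tx", "Tx", "non-Tx", "Tx"),
        cuis = c("C1", "C1|C2", "", "C3"),
        categories = c("Tx_therapeutic", "Tx_therapeutic|Tx_adverse", "",
                       "general_medical_term"))
    ev <- evidenceFromCandidates(cand, xCui = "X1")
    list(cand = cand, ev = ev)
}

test_that("candidate rows expand into per-concept evidence records", {
    f <- valFixture()
    expect_setequal(f$ev$y_cui, c("C1", "C2", "C3"))
    ## positional alignment on the 2-CUI/2-category row, merged with the
    ## single-CUI row for C1
    expect_setequal(strsplit(f$ev$categories[f$ev$y_cui == "C1"],
                             "|", fixed = TRUE)[[1]], "Tx_therapeutic")
    expect_equal(f$ev$categories[f$ev$y_cui == "C2"], "Tx_adverse")
    ## single category on a multi-CUI row broadcasts without warning
    bc <- evidenceFromCandidates(data.frame(
        y = "triple", label = "Tx", cuis = "C7|C8|C9",
        categories = "Tx_therapeutic"), "X1")
    expect_equal(nrow(bc), 3L)
    expect_equal(unique(bc$categories), "Tx_therapeutic")
    ## ambiguous unequal multi/multi warns and broadcasts
    expect_warning(evidenceFromCandidates(data.frame(
        y = "odd", label = "Tx", cuis = "C7|C8|C9",
        categories = "Tx_therapeutic|Tx_adverse"), "X1"),
        "assigning all")
    expect_error(evidenceFromCandidates(data.frame(
        y = "bad", label = "Tx", cuis = "C1", categories = "not_a_cat"),
        "X1"), "unknown evidence")
})

test_that("n4 counts distinct therapeutic concepts with any-match semantics", {
    f <- valFixture()
    ## C1 therapeutic, C2 adverse-only, C3 general term -> n4 = 1
    expect_equal(queryN4(f$cand, f$ev, zCuis = "C99", xCui = "X1"), 1L)
    ## multi-category concept (therapeutic|adverse) still counts
    ev2 <- f$ev
    ev2$categories[ev2$y_cui == "C2"] <- "Tx_therapeutic|Tx_adverse"
    expect_equal(queryN4(f$cand, ev2, "C99", "X1"), 2L)
    ## z-concept exclusion
    expect_equal(queryN4(f$cand, f$ev, zCuis = "C1", xCui = "X1"), 0L)
    ## all general terms -> 0
    ev3 <- f$ev; ev3$categories <- "general_medical_term"
    expect_equal(queryN4(f$cand, ev3, "C99", "X1"), 0L)
    ## missing evidence is an error listing the pair
    expect_error(queryN4(f$cand, f$ev[f$ev$y_cui != "C3", ], "C99", "X1"),
                 "\\(X1,C3\\)")
})

test_that("n4 never exceeds n3 and adding therapeutic never decreases n4", {
    set.seed(31)
    for (rep in 1:10) {
        nc <- sample(3:8, 1)
        cand <- data.frame(
            y = sprintf("y%d", seq_len(nc)),
            label = sample(c("Tx", "non-Tx"), nc, TRUE, prob = c(.8, .2)),
            cuis = replicate(nc, paste(sample(sprintf("C%d", 1:6),
                sample(1:2, 1)), collapse = "|")),
            stringsAsFactors = FALSE)
        cand$cuis[cand$label == "non-Tx"] <- ""
        allCuis <- unique(unlist(strsplit(cand$cuis[cand$label == "Tx"],
                                          "|", fixed = TRUE)))
        if (!length(allCuis)) next
        ev <- data.frame(x_cui = "X", y_cui = allCuis,
                         categories = sample(names(evidenceCategories()),
                                             length(allCuis), TRUE))
        zc <- sample(sprintf("C%d", 1:6), 2)
        st <- nerStats(cand, zc)
        n4 <- queryN4(cand, ev, zc, "X")
        expect_lte(n4, st$n3)
        ## monotonicity: appending the therapeutic category anywhere
        ev2 <- ev
        i <- sample(nrow(ev), 1)
        ev2$categories[i] <- paste(unique(c("Tx_therapeutic",
            strsplit(ev2$categories[i], "|", fixed = TRUE)[[1]])),
            collapse = "|")
        expect_gte(queryN4(cand, ev2, zc, "X"), n4)
    }
})

test_that("clinical winners flag all n4 maxima per group, order-invariantly", {
    tab <- data.frame(
        disease = c("ep", "ep", "ep", "gl"),
        model = c("CBOW", "CBOW", "Skip-gram", "CBOW"),
        n4 = c(8, 8, 7, 3))
    w <- clinicalWinners(tab)
    expect_equal(w$clinical_winner, c(TRUE, TRUE, TRUE, TRUE))
    tab2 <- tab; tab2$n4 <- c(8, 5, 7, 3)
    expect_equal(clinicalWinners(tab2)$clinical_winner,
                 c(TRUE, FALSE, TRUE, TRUE))
    perm <- sample(nrow(tab2))
    expect_equal(clinicalWinners(tab2[perm, ])$clinical_winner,
                 clinicalWinners(tab2)$clinical_winner[perm])
})

test_that("Cohen kappa matches the hand-computed confusion matrix", {
    expect_equal(cohenKappa(c("a", "b", "a"), c("a", "b", "a")), 1.0)
    ## [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5 -> kappa = 0.4
    r1 <- rep(c("a", "a", "b", "b"), c(20, 5, 10, 15))
    r2 <- rep(c("a", "b", "a", "b"), c(20, 5, 10, 15))
    expect_equal(cohenKappa(r1, r2), 0.4, tolerance = 1e-12)
    ## high raw agreement can still give near-zero/negative kappa
    j1 <- rep(c("agree", "disagree"), c(58, 2))
    j2 <- rep(c("agree", "disagree", "agree"), c(57, 1, 2))
    expect_gt(mean(j1 == j2), 0.9)
    expect_lt(cohenKappa(j1, j2), 0.1)
    expect_error(cohenKappa(rep("a", 5), rep("a", 5)), "undefined")
    expect_error(cohenKappa(c("a"), c("a", "b")), "different numbers")
})

test_that("observer overrides build parallel evidence views", {
    f <- valFixture()
    base_n4 <- queryN4(f$cand, f$ev, "C99", "X1")
    ## O1 withdraws the therapeutic category from C1: n4 drops by one
    ## O2 adds therapeutic evidence for C3: n4 rises by one
    j <- data.frame(
        observer = c("O1", "O2"),
        x_cui = "X1", y_cui = c("C1", "C3"),
        verdict = "disagree",
        replacement_categories = c("Tx_uncertain", "Tx_therapeutic"))
    views <- applyObserverOverrides(f$ev, j)
    expect_named(views, c("O1", "O2"))
    expect_equal(queryN4(f$cand, views$O1, "C99", "X1"), base_n4 - 1L)
    expect_equal(queryN4(f$cand, views$O2, "C99", "X1"), base_n4 + 1L)
    ## the baseline is untouched and empty judgments change nothing
    expect_equal(queryN4(f$cand, f$ev, "C99", "X1"), base_n4)
    expect_equal(applyObserverOverrides(f$ev, NULL), list())
    expect_error(applyObserverOverrides(f$ev, data.frame(
        observer = "O1", x_cui = "X1", y_cui = "C42",
        verdict = "disagree", replacement_categories = "correlation")),
        "unknown concept pair")
})
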