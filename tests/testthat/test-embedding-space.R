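test_that("cosine matches a direct dot-product oracle and its edge cases", {
    expect_equal(cosineSim(c(0.3, -2, 5), c(0.3, -2, 5)), 1.0)
    expect_equal(cosineSim(c(1, 0), c(0, 1)), 0.0)
    ## oracle: 32 / (sqrt(14) * sqrt(77))
    expect_equal(cosineSim(c(1, 2, 3), c(4, 5, 6)),
                 32 / (sqrt(14) * sqrt(77)), tolerance = 1e-12)
    expect_error(cosineSim(c(0, 0), c(1, 1)), "zero vector")
    expect_error(cosineSim(c(1, 2), c(1, 2, 3)), "length")
})

test_that("cosine is symmetric and invariant to positive rescaling", {
    set.seed(42)
    for (i in 1:20) {
        a <- rnorm(5); b <- rnorm(5); lambda <- runif(1, 0.1, 10)
        expect_equal(cosineSim(a, b), cosineSim(b, a))
        expect_equal(cosineSim(lambda * a, b), cosineSim(a, b),
                     tolerance = 1e-12)
    }
})

test_that("EmbeddingSpace validates tokens and normalizes rows", {
    m <- rbind(a = c(3, 4), b = c(0, 2))
    sp <- EmbeddingSpace(m, frequencies = c(a = 7, b = 2))
    expect_s4_class(sp, "EmbeddingSpace")
    expect_equal(vocabulary(sp), c("a", "b"))
    expect_equal(embeddingDim(sp), 2L)
    expect_equal(unname(rowSums(embeddingMatrix(sp)^2)), c(1, 1))
    expect_equal(tokenFrequencies(sp), c(a = 7L, b = 2L))
    expect_equal(length(sp), 2L)
    expect_error(EmbeddingSpace(rbind(a = c(1, 0), a = c(0, 1))),
                 "duplicate")
    expect_error(EmbeddingSpace(rbind(`a b` = c(1, 0))), "whitespace")
    expect_error(EmbeddingSpace(rbind(a = c(0, 0))), "zero vector")
})

test_that("analogy scores reproduce the hand-computed two-candidate space", {
    sp <- handSpace()
    add <- analogyScores(sp, "x", "z1", "z2", variant = "additive")
    expect_setequal(add$token, c("c1", "c2"))
    expect_equal(add$score[add$token == "c1"], 2.0)
    expect_equal(add$score[add$token == "c2"], -1.0)
    comp <- analogyScores(sp, "x", "z1", "z2", variant = "composite")
    ## unit(-1, 2): c1 = 2/sqrt(5), c2 = -1/sqrt(5)
    expect_equal(comp$score[comp$token == "c1"], 2 / sqrt(5))
    expect_equal(comp$score[comp$token == "c2"], -1 / sqrt(5))
    expect_gt(comp$score[comp$token == "c1"],
              comp$score[comp$token == "c2"])
})

test_that("query terms are never candidates and bad queries fail loudly", {
    sp <- randomSpace(8, 4, seed = 1)
    v <- vocabulary(sp)
    sc <- analogyScores(sp, v[1], v[2], v[3])
    expect_false(any(v[1:3] %in% sc$token))
    expect_equal(nrow(sc), 5L)
    expect_error(analogyScores(sp, v[1], v[2], v[2]), "z1 and z2")
    expect_error(analogyScores(sp, v[1], v[1], v[2]), "x must differ")
    expect_error(analogyScores(sp, "ghost", v[2], v[3]),
                 "not in vocabulary: ghost")
})

test_that("topCandidates equals an exhaustive-scoring oracle on random spaces", {
    for (seed in 1:6) {
        n <- sample(5:10, 1)
        sp <- randomSpace(n, 3, seed = seed)
        v <- vocabulary(sp)
        for (variant in c("additive", "composite")) {
            for (k in c(1, 3, n + 5)) {
                got <- topCandidates(sp, v[1], v[2], v[3], k = k,
                                     variant = variant)
                want <- oracleTopK(sp, v[1], v[2], v[3], k, variant)
                expect_equal(got$token, want$token)
                expect_equal(got$score, unname(want$score),
                             tolerance = 1e-12)
                expect_equal(got$rank, seq_len(nrow(got)))
                expect_true(all(diff(got$score) <= 1e-12))
            }
        }
    }
})

test_that("a top-k list is a prefix of the full sorted list", {
    sp <- randomSpace(10, 4, seed = 9)
    v <- vocabulary(sp)
    full <- topCandidates(sp, v[1], v[2], v[3], k = 7)
    for (k in 1:6)
        expect_equal(topCandidates(sp, v[1], v[2], v[3], k = k)$token,
                     full$token[seq_len(k)])
})

test_that("additive and composite variants rank identically on stored (unit) vectors", {
    ## with unit stored vectors the composite score is the additive score
    ## divided by the norm of the combined vector, so order is preserved
    for (seed in 1:5) {
        sp <- randomSpace(sample(5:10, 1), 4, seed = 100 + seed)
        v <- vocabulary(sp)
        a <- topCandidates(sp, v[1], v[2], v[3], k = 10, variant = "additive")
        b <- topCandidates(sp, v[1], v[2], v[3], k = 10, variant = "composite")
        expect_equal(a$token, b$token)
    }
})

test_that("score ties break by ascending lexicographic byte order", {
    sp <- EmbeddingSpace(rbind(
        x = c(1, 0), z1 = c(0, 1), z2 = c(1, 1),
        zz_twin = c(0.5, 0.5), aa_twin = c(0.5, 0.5)))
    top <- topCandidates(sp, "x", "z1", "z2", k = 2)
    expect_equal(top$token, c("aa_twin", "zz_twin"))
    expect_equal(top$rank, c(1L, 2L))
    expect_equal(top$score[1], top$score[2])
})

test_that("nearestByCosine ranks a collinear token first with score 1", {
    m <- rbind(t = c(1, 2, 2), u = c(2, 4, 4), w = c(-1, 0, 1))
    sp <- EmbeddingSpace(m)
    nb <- nearestByCosine(sp, "t", k = 2)
    expect_equal(nb$token[1], "u")
    expect_equal(nb$score[1], 1.0, tolerance = 1e-12)
    expect_false("t" %in% nb$token)
    expect_error(nearestByCosine(sp, "ghost", 1), "ghost")
})

test_that("nearestByCosine order matches an exhaustive pairwise-cosine oracle", {
    ## 3 vectors at hand-set angles from the query
    deg <- function(a) c(cos(a * pi / 180), sin(a * pi / 180))
    sp <- EmbeddingSpace(rbind(q = deg(0), near = deg(20),
                               mid = deg(70), far = deg(160)))
    nb <- nearestByCosine(sp, "q", k = 3)
    expect_equal(nb$token, c("near", "mid", "far"))
    expect_equal(nb$score, cos(c(20, 70, 160) * pi / 180),
                 tolerance = 1e-12)
})
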