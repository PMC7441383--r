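# shared fixtures, built in code

## long annotation table -> items x raters label matrix
.longToWideTest <- function(ann) {
    tapply(ann$label, list(ann$pair_id, ann$rater), function(x) x[1])
}

## a hand-set 2-D space where the analogy answer is known by construction
handSpace <- function() {
    EmbeddingSpace(rbind(
        x  = c(1, 0),
        z1 = c(0, 1),
        z2 = c(0, 1),
        c1 = c(0, 1),
        c2 = c(1, 0)))
}

## random unit-vector space for property tests
randomSpace <- function(n, d, seed, tag = "other") {
    set.seed(seed)
    m <- matrix(rnorm(n * d), n, d)
    rownames(m) <- sprintf("tok%02d", seq_len(n))
    EmbeddingSpace(m, modelTag = tag)
}

## independent oracle: score every candidate with explicit cosineSim calls
## and sort with base order(); no shared code with analogyScores/topCandidates
oracleTopK <- function(space, x, z1, z2, k, variant = "additive") {
    V <- embeddingMatrix(space)
    cands <- setdiff(rownames(V), c(x, z1, z2))
    sc <- vapply(cands, function(y) {
        if (variant == "additive")
            cosineSim(V[y, ], V[z1, ]) + cosineSim(V[y, ], V[z2, ]) -
                cosineSim(V[y, ], V[x, ])
        else {
            u <- function(v) v / sqrt(sum(v^2))
            cosineSim(V[y, ], u(u(V[z1, ]) + u(V[z2, ]) - u(V[x, ])))
        }
    }, numeric(1))
    o <- order(-sc, cands, method = "radix")
    data.frame(token = cands[o], score = sc[o],
               stringsAsFactors = FALSE)[seq_len(min(k, length(cands))), ]
}
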