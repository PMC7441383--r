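Package: TxAnalogy
Title: Four-Term Word-Embedding Analogies for Disease-Treatment Discovery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Literature-based discovery of disease treatments with
    word-embedding analogy search. Provides cosine and four-term analogy
    (3CosAdd) retrieval over word2vec-format embedding spaces, a small
    CBOW/Skip-gram trainer with negative sampling for toy corpora,
    systematic generation of "-x +z1 +z2" search queries from prior
    disease-treatment pairs, named-entity and clinical-validation summary
    statistics (n1-n4, NER winners, clinical winners) with inter-rater
    agreement (Krippendorff alpha, Cohen kappa) and micro-averaged
    concept-mapping evaluation, evidence-category bookkeeping with observer
    overrides, a Boolean selection heuristic with threshold precision/recall
    evaluation, and a synthetic embedding-space generator with planted
    semantic fields for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
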