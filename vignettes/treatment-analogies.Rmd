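---
title: "Four-term embedding analogies for disease-treatment discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-term embedding analogies for disease-treatment discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TxAnalogy)
```

## The problem and the model

Clinicians' most common question — how to treat a disease — is buried in
free-text biomedical literature. One route to surfacing candidate
treatments automatically is analogical reasoning over word embeddings.
Beyond the familiar pairwise analogy (*man:woman::king:queen*), a
four-term analogy of a different shape can be posed directly as vector
arithmetic: given a target disease $x$ and two known treatments $z_1$ and
$z_2$ for it, the search query $-x + z_1 + z_2$ asks for a term $y$ that
is *similar to $z_1$ and $z_2$ while different from $x$* — in semantic-field
terms, another member of the *treatment* field (Tx) of that disease.

`TxAnalogy` implements this search and the bookkeeping that turns its raw
output into auditable disease-treatment statements:

1. **Knowledge acquisition.** From prior-knowledge pairs (disease $x$,
   treatment $z$), every unordered pair of a disease's treatments yields
   one query; each query is scored over the whole vocabulary and the top
   12 candidates are retained (candidates with non-ASCII bytes are
   dropped).
2. **Knowledge organization.** Human raters classify candidates as
   Tx/non-Tx (inter-rater agreement by Krippendorff's alpha); candidates
   are normalized to concept identifiers (CUIs), with mapping quality
   summarized by micro-averaged precision/recall/F. Per query:
   `n1` = distinct CUIs of $z_1,z_2$; `n2` = distinct Tx candidates;
   `n3` = distinct Tx CUIs excluding the z-CUIs. *NER winners* maximize
   n2 or n3 within a (disease, model) group.
3. **Knowledge validation.** Each concept pair carries evidence-based
   categories; `n4` counts distinct therapeutic-category CUIs (excluding
   z-CUIs). *Clinical winners* maximize n4. Two audit observers can
   override categories (Cohen's kappa measures their agreement); override
   views are parallel copies, never mutations of the expert baseline, so
   baseline and per-observer winners are all recomputable from one
   dataset.
4. **A selection heuristic.** A Boolean conjunction — no short forms in
   $z_1,z_2$; at least one of $z_1,z_2$ outside the target's 20 nearest
   cosine neighbors; $z_2$ corpus frequency strictly above 100 — with
   precision/recall evaluated across n4 thresholds 0..7.

## Scoring variants and numerical choices

Two 3CosAdd variants are implemented. The *additive* form scores
$\cos(y,z_1)+\cos(y,z_2)-\cos(y,x)$ (range $[-3,3]$); the *composite*
form (the default) scores $\cos\!\big(y,\; u(u(z_1)+u(z_2)-u(x))\big)$
where $u(\cdot)$ normalizes to unit length, matching the scale of
word2vec-style tools whose printed analogy scores live in $[-1,1]$.
Because stored vectors are L2-normalized at load time (raw norms are not
retained), the composite score equals the additive score divided by a
positive constant, so the two variants produce identical *rankings* on a
loaded space; the choice matters only for reported magnitudes. Scores are
conventionally reported at 6 decimals.

Other numerical rules, all deterministic:

* ties in any ranking are broken by ascending lexicographic *byte* order
  of the token (radix sort; locale-independent);
* query terms $x, z_1, z_2$ are never candidates;
* discarded non-ASCII candidates are not back-filled by default (a
  back-fill mode exists), so a query can return fewer than `k`
  candidates;
* zero vectors are rejected at construction: every stored token has a
  direction;
* pipe-joined multi-CUI/multi-category rows align positionally when the
  lengths match, otherwise every CUI receives every category (with a
  warning when both sides exceed one, the genuinely ambiguous case);
* a concept with several categories counts toward n4 if *any* of them is
  therapeutic;
* the heuristic's frequency condition is strict (`> 100`; a count of
  exactly 100 fails);
* precision is reported as undefined (`NA`), never 0, when nothing is
  selected.

Agreement statistics are implemented from first principles (no suitable
package dependency): Krippendorff's alpha in the nominal
coincidence-matrix form, which tolerates missing labels and carries the
standard $(n-1)/n$ finite-sample correction — consequently alpha is *not*
exactly invariant under duplicating all units, though the effect vanishes
at realistic sizes; Cohen's kappa with marginal-product expected
agreement, which legitimately yields near-zero or negative values at high
raw agreement under skewed marginals (the kappa paradox).

## The toy trainer

To make the five-line Romeo corpus experiment reproducible end to end,
the package ships a plain-R CBOW/Skip-gram trainer with negative sampling
(unigram$^{3/4}$ noise, dynamic window, linear learning-rate decay,
word2vec-style initialization). Tokenization deletes double quotes only,
keeps case, and splits sentence punctuation into standalone tokens.
Defaults — dimension 25, window 5, 200 epochs, 5 negatives, rate 0.025,
`minCount` 1 — were fixed once for the toy scale: a corpus of ~40 running
tokens needs many epochs and supports only small dimensions. The trainer
is deliberately scoped to toy corpora; corpus-scale training is out of
scope.

A caveat the tests make explicit: on this corpus the query
$-Romeo + die + died \rightarrow dagger$ and the neighbor probe
$Romeo \rightarrow you$ are *stochastic* targets. "Romeo" and "you" share
no context words in the five lines, so no distributional trainer
reproduces the neighbor result reliably across seeds; the acceptance test
honestly counts successes over 20 seeded runs rather than cherry-picking
a seed, and is expected to fail until a configuration with distributional
support for the result exists.

## The synthetic benchmark

`generateSpace()` plants semantic fields: each field (one per disease,
one treatment field per disease, small distractor fields) receives a
random unit centroid, and members are unit-normalized
$\text{centroid} + \mathcal{N}(0, \sigma^2 I_d)$ draws with
$\sigma=\sqrt{(\rho^{-2}-1)/d}$, so the expected member-centroid cosine
is the configured `intraFieldCosine` $\rho$. This isotropic-Gaussian
model is the simplest that makes the planted signal a single dial:
$\rho = 0.95$ gives $\ge 90\%$ top-1 analogy recovery, $\rho \to 0$
collapses to chance. Vocabulary, frequencies (log-normal, straddling the
heuristic's 100 boundary) and planted analogies depend only on the seed,
so a CBOW-like and a Skip-gram-like space share one vocabulary and differ
only in geometry.

`generateAnnotations()` flips true Tx labels per rater with probability
$1-$`raterAccuracy` (default 0.93, chosen to land alpha in the observed
high-agreement regime) and corrupts gold concept mappings at a configured
rate. `generateEvidence()` draws the therapeutic category per concept
pair with probability `pTherapeutic` (default $190/427$, the category's
share in the curated evidence distribution) and the remaining six
categories with weights $38{:}52{:}5{:}22{:}26{:}94$; a $19/408$
fraction carries a second category. Synthetic CUIs use a `SYN######`
namespace that cannot collide with real UMLS identifiers.

What the generator does *not* emulate: real text, polysemy, MetaMap's
structured error modes (only a flat corruption rate), hubness of learned
embedding spaces, and correlated rater errors. Green tests on planted
spaces therefore demonstrate the pipeline's correctness and calibration,
not performance on PubMed-scale corpora.

## Worked example

```{r example}
ex <- epilepsyExample()
ex$candidates[, c("rank", "y", "score", "label")]
nerStats(ex$candidates, ex$zCuis)
ev <- evidenceFromCandidates(ex$candidates, ex$xCui)
queryN4(ex$candidates, ev, ex$zCuis, ex$xCui)
```

The twelve annotated candidates of `-epilepsy +valproate
+antiepileptic_drug` give n2 = 11 (one candidate, `low_propensity`, is
non-Tx), n3 = 10 (twelve distinct CUIs minus the two z-concepts
C0080356 and C0003299), and n4 = 8 (the distinct therapeutic-category
concepts, counting multi-category concepts such as lithium on any-match).

```{r heuristic}
b <- heuristicBenchmark()
head(evaluateThresholds(b$selected, b$n4), 3)
```

## Problem sizes and limitations

The shipped tests and examples run at desk scale by design: planted
spaces of 100-600 tokens in 8-50 dimensions, 100-query recovery batches,
a 223-query combinatorial check against two random 16-dimensional spaces,
and 20 seeded toy-trainer runs. These sizes were chosen as the smallest
at which each property is informative. Known limitations: the short-form
detector (consecutive-uppercase rule) is an approximation of curated
judgment and is therefore overridden by explicit flags whenever they are
supplied; semantic fields overlap and have gaps in real vocabularies, so
candidate lists are neither mutually exclusive nor complete; and the
ordered-query and back-fill modes exist behind flags because the
unordered/no-back-fill convention is an inference from the published
counts, not a stated rule.
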