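---
title: "Methods: constitution-aware formula recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constitution-aware formula recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbrec)
```

## The problem

Edible herbal formulas — preparations composed entirely of substances
that are simultaneously food and medicine — are traditionally matched to
a person in two coupled steps: symptom cluster → syndrome pattern
(证), and questionnaire → constitution type (体质). `herbrec`
implements this chain as a deterministic scoring pipeline over a
structured knowledge base, with a retrieval layer that attaches
documentary evidence to every recommendation and a linear composite
score that keeps each ranking decision inspectable term by term.

## Pipeline and assumptions

The stages run strictly in order, and the `NA` sentinel short-circuits
at the first stage that finds nothing:

1. **Normalization.** Raw surface forms are NFC-normalized and resolved
   through exact curated mappings (colloquial → canonical, then
   merge-group collapse), duplicates merged keeping first occurrence,
   non-clinical items excluded. Unmapped terms are dropped with a
   recorded reason rather than passed through, because every later stage
   requires canonical terms with defined weights; a strict mode raises
   instead. There is deliberately no fuzzy matching in the core: the
   mappings model a curated dictionary, not free-text NLP, and an
   edit-distance suggester (`suggest_term()`) is exposed but never
   applied silently.

2. **Syndrome scoring.** `Score(S) = Σ w(xᵢ,S) / Σ w_max(xᵢ)`. The
   denominator is the score the list *could* achieve if every symptom
   hit its best syndrome, which makes the measure length-normalized: a
   symptom that cannot contribute to `S` strictly lowers `Score(S)`.
   The numerator treats unlisted (symptom, syndrome) pairs as weight 0.
   A symptom with no weight-table entry at all is a data error, not a
   zero — silently ignoring it would make scores depend on coverage
   gaps.

3. **Constitution inference.** Each of the nine subscales is scored on
   the standard 0–100 transform `(raw − n)/(4n)·100` with negative
   items reverse-coded. The probability vector is the direct
   normalization of the nine transformed scores — the simplest total,
   smooth map satisfying the probability contract; a softmax would add
   a temperature parameter with no principled default. The instrument's
   categorical decision rules (balanced requires its own score ≥ 60
   with all biased scores < 30) shape only the reported label, never
   the probability vector, so the multiplicative combination below
   always sees a full distribution.

4. **Candidate selection.** `Score*(S,C) = Score(S)·(ε + P(C|X))`. The
   smoothing constant ε keeps a strong syndrome signal alive when the
   questionnaire puts zero mass on a constitution. One threshold τ
   applies to `Score(S)` and a second (default 0) to `Score*`; we chose
   two thresholds because the two quantities live on different scales —
   `Score*` is bounded by `ε + 1`, and reusing τ there would silently
   couple the stages.

5. **Retrieval.** One chunk per formula (records are short; finer
   segmentation buys nothing at this corpus size), embedded by an
   order-free bag of canonical terms with smoothed IDF weights, cosine
   similarity, ties broken by chunk id. Because the representation is a
   bag, the whole pipeline is invariant to the order in which symptoms
   are reported — forward and reversed inputs provably retrieve and
   rank identically. That property is the design response to the
   fragility of sequence-sensitive embeddings under symptom reordering;
   order-sensitive neural embedders can still plug in behind the same
   contract, and the evaluation harness will flag their divergences.

6. **Composite ranking.** `R = a·Ind + b·Compat + c·Cov − d·Contra`,
   each term in [0, 1], so `−d ≤ R ≤ a+b+c` always. When several
   (S, C) pairs survive selection, a formula is scored by its best pair
   (max-aggregation): a formula is as good as its best-supported match,
   which also mirrors the matching-maximization principle used to order
   recommendations. Mean-aggregation is available for sensitivity
   analyses. `Contra` is the maximum matched severity — a single strong
   conflict should dominate any number of mild ones.

7. **Output.** The ranked list becomes a structured completion
   `SYNDROME=<id>;CONSTITUTION=<code>;TOPN=<ids>` or the exact string
   `NA`. Every emitted string passes the standardization protocol
   (punctuation outside the field separators stripped, whitespace
   variants collapsed, all ids validated against the database), so by
   construction the engine cannot emit an unknown formula id. The
   completion syntax itself — `=`/`;`/`,` separators — is this
   package's dialect choice; it was picked to be unambiguous under the
   punctuation-elimination rule.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| role weights | primary 2, secondary 1 | only the ordering is doctrinally fixed (primary > secondary); 2:1 is the smallest integer ratio expressing it |
| τ | 0.30 | syndrome retention threshold (dimensionless, on [0,1]); development-set quantities are corpus-specific, so the default sits low enough to pass clear single-syndrome clusters and high enough to reject diffuse ones |
| K | 3 | retained syndromes and (S,C) pairs; matches the three formulas a practitioner-facing platform typically displays |
| ε | 1e-3 | smoothing on P(C|X); low end of the sensible 1e-3–1e-2 band so the constitution signal stays dominant |
| (a,b,c,d) | (0.4, 0.3, 0.2, 0.1) | syndrome indication first (syndrome-first doctrine), then constitution, coverage, contraindication; configurable on the simplex |
| M | 3 | evidence chunks attached per recommendation |
| TOPN k | 3 | formula ids per completion |
| match rule | rank-1 | a case counts correct only if the gold formula is ranked first; `match_topk` relaxes this to the displayed top-k |

## The synthetic knowledge-base generator

No curated MFH corpus is publicly deposited, so the package ships a
deterministic generator whose defaults emulate the scale such a corpus
has in practice: 288 formulas, 426 substances, 484 symptoms, 20
syndromes, nine constitutions. It is a pure function of its config — the
same seed yields byte-identical databases — and uses one independent
PRNG stream per artifact so regenerating an evaluation set never
perturbs the database.

Structural choices, and what they imply for interpretation:

- Every symptom belongs to exactly one syndrome (primary or secondary
  role), so its maximum weight is attained at its home syndrome. Real
  vocabularies have cross-syndrome symptoms; the scoring equations
  support them (and the oracle tests exercise them with random tables),
  but generated evaluation sets will not show the attenuation that
  ambiguous symptoms cause.
- Every generated formula indicates one syndrome and owns one
  *distinctive* effect no other formula documents. Evaluation cases
  always include a distinctive effect, which makes zero-distractor sets
  solvable at rank 1 by construction — those sets verify the machinery,
  not clinical difficulty. Distractor symptoms (`n_distractors > 0`)
  are the dial that makes cases genuinely hard.
- Colloquial variants, merge groups, category labels, an exclusion
  list, and the curated colloquial pair 长痘痘 → 易生疥疮或痤疮 are
  generated so every normalization path is exercised end to end.
- With `include_paper_mirror = TRUE` (the default) two hand-curated
  scenarios are layered in: a six-symptom yang-deficiency cluster whose
  labels make *yangzheng herbal drink* optimal with *minzheng* and
  *yusheng herbal drink* as runners-up, and a shared spleen-dampness
  cluster that resolves to *Poria cocos appetizing drink* under
  yin-deficiency but *dried tangerine peel fat loss drink* under
  phlegm-dampness. These pin the end-to-end behavior to concrete,
  human-checkable outcomes.
- Defect injection (`defect_count`) plants exactly the requested number
  of single-violation defects (dangling substance or syndrome
  references, empty constitution labels, out-of-range severities,
  non-canonical effects) for validator testing.

Synthetic precision numbers consequently measure *pipeline
correctness*, not expected field performance: passing them shows the
equations, thresholds, tie-breaks and data plumbing do what they claim
under controlled conditions, nothing more.

```{r example}
db <- generate_fixture_database(fixture_config(seed = 1))
resp <- make_questionnaire_response(db$questionnaire, "yang-deficiency")
recommend(c("visible dark circles", "more afraid of cold than others",
            "frequent bloating", "heavy body", "difficult in movement",
            "dry skin"), resp, db)
```

## Numerical and degenerate-input conventions

- All ingested text is NFC-normalized; comparisons are exact after
  normalization. All string ordering is byte-order (radix), never
  locale collation, so tie-breaks and serialized files are identical
  across platforms.
- Tie-breaks are total everywhere: score descending, then id ascending
  (syndrome id, then constitution code, then formula id, then chunk
  id). Two runs of any operation with equal inputs are bit-identical.
- Thresholds are strict (`>`), so τ = 0 still rejects zero-score
  syndromes and the default `Score*` threshold 0 rejects nothing with
  positive score (ε > 0 guarantees positivity).
- Empty symptom sets are a signalled condition at the scoring layer and
  the `NA` sentinel at the pipeline layer; an all-zero questionnaire
  maps to the uniform distribution rather than an error.
- Knowledge-base serialization is canonical (key-sorted objects, sorted
  set-valued fields, fixed numeric formatting), so structural equality
  and byte equality coincide; `save ∘ load ∘ save` is the identity on
  bytes.

## Evaluation harness

`precision()` implements `TP/(TP+FP)` with `NA` outputs excluded from
the ratio and reported as a separate count — under the printed formula
an abstention is neither a correct nor an incorrect recommendation, and
folding it into FP would conflate caution with error.
`order_robustness()` evaluates each case forward and exactly reversed
and reports both precision reports plus a per-case agreement table.
`ablation_harness()` runs three modes: retrieval-only (nearest chunks
by cosine), ranking-only (composite score without evidence), and full.
The problem sizes used by the shipped acceptance script — a 288-formula
database, 200 evaluation cases, one training pair per formula — were
chosen as the smallest sizes at which every stage (vocabulary, ablation
modes, both worked scenarios, the 9:1 split) is exercised at the
generator's default scale.

## Known limitations

- The generator's single-syndrome symptoms and distinctive effects make
  synthetic evaluations easier than real case mixes; treat reported
  precisions as correctness checks (see above).
- Free-text narrative complaints are out of scope; input is a list of
  surface forms. So are facial/tongue-image diagnostics.
- The generative step is a plug-in contract: the default generator is
  the deterministic rule pipeline, and no language model, fine-tuning
  loop, or hosted API is included. The symbolic path is self-sufficient
  for ranked recommendation; the contract exists so a tuned generator
  can be evaluated with the same harness.
- The partial-affinity table behind the 0.5 compatibility grade ships
  empty; meaningful affinities between constitution types are a
  clinical modelling decision the package does not presume to make.
- TP/FP adjudication is gold-id matching only; it cannot credit a
  recommendation that is clinically reasonable but differs from the
  labeled formula.
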