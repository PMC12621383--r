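# herbrec

Constitution-aware recommendation of edible herbal formulas.

In the medicine-and-food-homology (MFH) tradition, multi-ingredient
preparations composed entirely of dual-use (food/medicine) substances are
matched to a person through *syndrome differentiation and treatment*
(辨证论治): reported symptoms are resolved to a canonical syndrome
pattern, the person's constitution (体质, one of nine types in Qi Wang's
classification) is determined by a standardized questionnaire, and a
formula is chosen that fits both — so two people with the same complaints
can correctly receive different formulas (*different treatments for the
same disease*, 同病异治).

`herbrec` implements that reasoning chain as a deterministic, fully
interpretable engine over a structured formula knowledge base, for
researchers building or evaluating recommendation systems in
traditional-medicine informatics. It is a symbolic pipeline by design:
every recommendation comes with the complete score breakdown that
produced it.

## The model

Reported symptoms are first normalized against a curated controlled
vocabulary (colloquial → canonical mapping, duplicate merging, category
labels, exclusion of non-clinical items). A normalized symptom set
*X = {xᵢ}* is scored against each syndrome *S* with a length-normalized
weighted ratio:

    Score(S) = Σᵢ w(xᵢ, S) / Σᵢ w_max(xᵢ)   ∈ [0, 1]

where *w(x, S)* is the practitioner-assigned weight of symptom *x* toward
*S* (primary > secondary, 0 when unlisted) and *w_max(x)* is the largest
weight *x* can contribute to any syndrome — so padding the complaint list
with irrelevant symptoms strictly lowers every score rather than
inflating any. Syndromes scoring above a threshold τ are retained (top
K); otherwise the engine answers with the exact sentinel `NA`.

The constitution questionnaire (nine 5-point subscales with
reverse-coded negative items, transformed score = (raw − n)/(4n) × 100)
yields a probability vector *P(C|X)* over the nine types. Syndrome and
constitution are combined multiplicatively with smoothing:

    Score*(S, C) = Score(S) · (ε + P(C|X)),   ε ∈ [1e-3, 1e-2]

Retained (S, C) pairs drive retrieval (order-free TF-IDF over one
document chunk per formula, cosine top-M evidence) and a transparent
four-term composite ranking of every formula *F*:

    R(F | S, C, X) = a·Ind(S,F) + b·Compat(C,F) + c·Cov(X,F) − d·Contra(F)

with Ind = Jaccard overlap between candidate syndromes and the formula's
documented indications, Compat ∈ {0, 0.5, 1} constitution compatibility,
Cov = fraction of reported symptoms covered by the formula's effects,
Contra = maximum matched contraindication severity, and non-negative
weights a + b + c + d = 1 (defaults 0.4/0.3/0.2/0.1). The top-ranked
formulas are emitted as a structured completion
`SYNDROME=…;CONSTITUTION=…;TOPN=…` (or `NA`), which also makes the
package a prompt-completion dataset builder for instruction tuning of
generative recommenders: the deterministic pipeline is the default
"generator", and a language model can plug in behind the same contract.

## Worked example

```r
library(herbrec)

db <- generate_fixture_database(fixture_config(seed = 1))
symptoms <- c("visible dark circles", "more afraid of cold than others",
              "frequent bloating", "heavy body", "difficult in movement",
              "dry skin")
resp <- make_questionnaire_response(db$questionnaire, "yang-deficiency")
recommend(symptoms, resp, db)
#> <herbrec_report>
#>   symptoms: visible dark circles, more afraid of cold than others, frequent bloating, heavy body, difficult in movement, dry skin
#>   constitution: yang-deficiency
#>   completion: SYNDROME=syn-yang-deficiency;CONSTITUTION=yang-deficiency;TOPN=formula-yangzheng,formula-minzheng,formula-yusheng
#>   1. yangzheng herbal drink (R = 0.9000)
#>   2. minzheng herbal drink (R = 0.8667)
#>   3. yusheng herbal drink (R = 0.8333)
```

The questionnaire identifies a yang-deficiency constitution; the symptom
cluster scores 1.0 on the yang-deficiency pattern; and the composite
score ranks the three curated drinks by how completely their documented
effects cover the complaints (6/6, 5/6, 4/6 → R = 0.9000, 0.8667,
0.8333, each with Ind = Compat = 1 and no contraindication). The same
engine, given one shared dyspepsia/bloating cluster, recommends
`Poria cocos appetizing drink` to a yin-deficiency user and
`dried tangerine peel fat loss drink` to a phlegm-dampness user — the
constitution term is what separates them.

A command-line interface over the same functions ships in
`inst/cli/herbrec` (subcommands `fixture`, `validate`, `make-dataset`,
`recommend`, `evaluate`, `show-config`).

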