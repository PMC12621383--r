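Package: herbrec
Title: Constitution-Aware Recommendation of Edible Herbal Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-base driven engine for recommending edible herbal
    formulas in the medicine-and-food-homology tradition. Implements
    controlled-vocabulary symptom normalization, length-normalized syndrome
    scoring, nine-constitution questionnaire inference, smoothed
    multiplicative syndrome-by-constitution candidate selection, TF-IDF
    retrieval over a chunked formula knowledge base, and a four-term
    interpretable composite ranking with contraindication penalties.
    Ships a deterministic synthetic knowledge-base generator, a
    prompt-completion dataset builder for instruction tuning, and a
    precision / order-robustness evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
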