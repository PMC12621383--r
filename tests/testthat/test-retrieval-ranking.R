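test_that("chunking yields one chunk per formula containing its record fields", {
  db <- small_db()
  chunks <- chunk_database(db)
  expect_equal(nrow(chunks), length(db$formulas))
  expect_equal(chunks$formula_id, sort(names(db$formulas), method = "radix"))
  for (i in seq_len(nrow(chunks))) {
    f <- db$formulas[[chunks$formula_id[i]]]
    for (e in f$effects) expect_true(grepl(e, chunks$text[i], fixed = TRUE))
    expect_true(grepl(f$name, chunks$text[i], fixed = TRUE))
  }
  empty <- chunk_database(formula_db(list(), list(), list(), db$vocabulary,
                                     db$weight_table, db$questionnaire))
  expect_equal(nrow(empty), 0)
})

test_that("the default embedder is deterministic and order-free", {
  db <- small_db()
  idx <- build_vector_index(chunk_database(db))
  t1 <- "symptom-021 ; symptom-022 ; symptom-023"
  t2 <- "symptom-023 ; symptom-021 ; symptom-022"
  expect_identical(embed_text(t1, idx), embed_text(t1, idx))
  expect_identical(embed_text(t1, idx), embed_text(t2, idx))
  v <- embed_text(t1, idx)
  expect_equal(sum(v * v) / (sqrt(sum(v^2)) * sqrt(sum(v^2))), 1)
  expect_error(embed_text("", idx), "non-empty")
})

test_that("retrieval matches a brute-force all-pairs cosine computation", {
  db <- small_db()
  idx <- build_vector_index(chunk_database(db))
  cos <- function(a, b) {
    d <- sqrt(sum(a^2)) * sqrt(sum(b^2))
    if (d == 0) 0 else sum(a * b) / d
  }
  set.seed(5)
  pool <- unique(db$weight_table$entries$symptom)
  for (rep in 1:5) {
    q <- paste(sample(pool, 4), collapse = " ; ")
    qv <- embed_text(q, idx)
    sims <- vapply(seq_len(nrow(idx$chunks)), function(i)
      cos(qv, idx$matrix[i, ]), numeric(1))
    ord <- order(-sims, idx$chunks$chunk_id, method = "radix")
    for (m in c(1, 5, 100)) {
      got <- retrieve_top_m(q, idx, m)
      want <- head(ord, m)
      expect_equal(got$chunk_id, idx$chunks$chunk_id[want])
      expect_equal(got$similarity, sims[want])
    }
  }
  # a query equal to one chunk's text retrieves that chunk first
  self <- retrieve_top_m(idx$chunks$text[7], idx, 1)
  expect_equal(self$chunk_id, idx$chunks$chunk_id[7])
  expect_equal(self$similarity, 1)
})

test_that("indication overlap is Jaccard (proportion match as alternative)", {
  f <- list(indicated_syndromes = c("s2", "s3", "s4"))
  expect_equal(indication_overlap(c("s2", "s3", "s4"), f), 1.0)
  expect_equal(indication_overlap(c("s9"), f), 0.0)
  expect_equal(indication_overlap(c("s1", "s2"), f), 0.25)
  expect_equal(indication_overlap(c("s1", "s2"), f, method = "proportion"), 0.5)
  expect_error(indication_overlap(character(0), f), "empty")
})

test_that("constitution compatibility grades full, partial, and no affinity", {
  f <- list(suitable_constitutions = c("yang-deficiency", "qi-deficiency"))
  expect_equal(constitution_compatibility("yang-deficiency", f), 1.0)
  expect_equal(constitution_compatibility("damp-heat", f), 0.0)
  aff <- list("blood-stasis" = "qi-deficiency")
  expect_equal(constitution_compatibility("blood-stasis", f, aff), 0.5)
})

test_that("symptom coverage is the covered fraction of reported symptoms", {
  f <- list(effects = c("a", "b", "c"))
  expect_equal(symptom_coverage(c("a", "b"), f), 1.0)
  expect_equal(symptom_coverage(c("x", "y"), f), 0.0)
  expect_equal(symptom_coverage(c("a", "b", "z"), f), 2 / 3)
  expect_error(symptom_coverage(character(0), f), "empty")
})

test_that("contraindication penalty is the maximum matched severity", {
  f0 <- list(contraindications = numeric(0))
  expect_equal(contraindication_penalty(c("a"), "balanced", f0), 0.0)
  f1 <- list(contraindications = c(a = 1.0))
  expect_equal(contraindication_penalty(c("a", "b"), "balanced", f1), 1.0)
  f2 <- list(contraindications = c(a = 0.3, b = 0.8, z = 0.95))
  expect_equal(contraindication_penalty(c("a", "b"), "balanced", f2), 0.8)
  # constitution-keyed conflicts match through the constitution code
  f3 <- list(contraindications = c("yin-deficiency" = 0.6))
  expect_equal(contraindication_penalty(c("a"), "yin-deficiency", f3), 0.6)
  expect_equal(contraindication_penalty(c("a"), "balanced", f3), 0.0)
})

test_that("the composite score is the exact four-term linear combination", {
  w <- composite_weights()
  expect_equal(composite_score(1, 1, 1, 0, w), 0.9)
  expect_equal(composite_score(0, 0, 0, 1, w), -0.1)
  expect_equal(composite_score(0.5, 0.5, 2 / 3, 0, w),
               0.4 * 0.5 + 0.3 * 0.5 + 0.2 * (2 / 3))
  expect_error(composite_weights(0.5, 0.5, 0.5, 0.5), "sum to 1")
})

test_that("formula ranking agrees with brute-force enumeration over pairs", {
  db <- small_db()
  terms <- db$formulas[["formula-003"]]$effects[1:3]
  tabcfg <- selection_config(tau = 0.1, top_k = 3)
  syn <- rank_syndromes(terms, db$weight_table, tabcfg)
  dist <- constitution_distribution(stats::setNames(
    c(10, 30, 25, 0, 0, 5, 0, 0, 0), constitution_types()))
  cand <- select_candidates(syn, dist, tabcfg)
  w <- composite_weights()
  got <- rank_formulas(db, terms, cand, w)
  expect_equal(got$formula_id, oracle_rank(db, terms, cand, w))
  # the returned breakdown reproduces the reported score exactly
  expect_equal(got$r_score,
               w$a * got$ind + w$b * got$compat + w$c * got$cov -
                 w$d * got$contra)
  expect_true(all(got$r_score <= w$a + w$b + w$c + 1e-12))
  expect_true(all(got$r_score >= -w$d - 1e-12))
})

test_that("a single-formula database ranks that formula first", {
  db <- small_db()
  one <- db
  one$formulas <- db$formulas["formula-001"]
  terms <- db$formulas[["formula-005"]]$effects[1:2]
  cand <- data.frame(syndrome = "syn-01", constitution = "balanced",
                     syndrome_score = 1, p = 1, combined = 1,
                     stringsAsFactors = FALSE)
  got <- rank_formulas(one, terms, cand)
  expect_equal(nrow(got), 1)
  expect_equal(got$formula_id, "formula-001")
})

test_that("raising a formula's contraindication penalty never improves its rank", {
  db <- small_db()
  terms <- db$formulas[["formula-004"]]$effects[1:3]
  cfg <- selection_config(tau = 0.1, top_k = 3)
  syn <- rank_syndromes(terms, db$weight_table, cfg)
  dist <- constitution_distribution(stats::setNames(
    c(rep(0, 3), 60, rep(0, 5)), constitution_types()))
  cand <- select_candidates(syn, dist, cfg)
  base <- rank_formulas(db, terms, cand)
  top_id <- base$formula_id[1]
  poisoned <- db
  poisoned$formulas[[top_id]]$contraindications <-
    stats::setNames(1.0, terms[1])
  after <- rank_formulas(poisoned, terms, cand)
  expect_gte(which(after$formula_id == top_id),
             which(base$formula_id == top_id))
})
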