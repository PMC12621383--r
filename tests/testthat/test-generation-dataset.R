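test_that("prompts follow the instruction template and parse back exactly", {
  expect_equal(build_prompt(c("dyspepsia", "obesity")),
               "If the patient presents with dyspepsia, obesity. Then recommend")
  expect_equal(build_prompt(character(0)),
               "If the patient presents with . Then recommend")
  set.seed(3)
  pool <- c("dyspepsia", "obesity", "dry skin", "heavy body",
            "易生疥疮或痤疮")
  for (i in 1:10) {
    terms <- sample(pool, sample(0:5, 1))
    expect_equal(parse_prompt(build_prompt(terms)), terms)
  }
  expect_error(parse_prompt("free text"), "template")
})

test_that("completions carry the ranked TOPN or the exact NA sentinel", {
  cand <- data.frame(syndrome = "syn-01", constitution = "qi-deficiency")
  ranked <- data.frame(formula_id = paste0("formula-00", 1:5))
  expect_equal(build_completion(cand, ranked, k = 3),
               "SYNDROME=syn-01;CONSTITUTION=qi-deficiency;TOPN=formula-001,formula-002,formula-003")
  expect_equal(build_completion(cand, ranked[1, , drop = FALSE], k = 3),
               "SYNDROME=syn-01;CONSTITUTION=qi-deficiency;TOPN=formula-001")
  expect_identical(build_completion(NULL, ranked, k = 3), "NA")
})

test_that("output standardization strips punctuation and validates references", {
  db <- small_db()
  good <- "SYNDROME=syn-01;CONSTITUTION=qi-deficiency;TOPN=formula-001,formula-002"
  # well-formed completions are fixed points
  expect_equal(standardize_output(good, db)$completion, good)
  # trailing punctuation and whitespace variants are repaired
  expect_equal(standardize_output(paste0(good, "。"), db)$completion, good)
  expect_equal(standardize_output(
    "SYNDROME = syn-01 ; CONSTITUTION = qi-deficiency ; TOPN = formula-001, formula-002.",
    db)$completion, good)
  expect_equal(standardize_output("NA", db)$completion, "NA")
  expect_equal(standardize_output("NA.", db)$completion, "NA")
  # unknown references are rejections with reasons, not errors
  r1 <- standardize_output(
    "SYNDROME=syn-01;CONSTITUTION=qi-deficiency;TOPN=formula-999", db)
  expect_false(r1$ok)
  expect_match(r1$reason, "unknown formula id")
  r2 <- standardize_output(
    "SYNDROME=syn-99;CONSTITUTION=qi-deficiency;TOPN=formula-001", db)
  expect_match(r2$reason, "unknown syndrome")
  r3 <- standardize_output("recommend whatever feels right", db)
  expect_false(r3$ok)
})

test_that("a malformed generator output degrades to NA through standardization", {
  db <- small_db()
  cfg <- herbrec_config(generator = function(prompt, report) "gibberish!!")
  rep <- recommend(fig4_symptoms(), NULL, db, cfg)
  expect_identical(rep$completion, "NA")
  expect_equal(rep$na_stage, "output_standardization")
})

test_that("the training dataset splits 9:1, disjoint and seed-stable", {
  db <- small_db()
  split <- build_training_dataset(db, seed = 4, ratio = 0.9,
                                  pairs_per_formula = 4)
  n <- nrow(split$train) + nrow(split$test)
  # duplicates among sampled subsets are dropped, so n is at most 4/formula
  expect_lte(n, 4 * length(db$formulas))
  expect_gte(n, 3 * length(db$formulas))
  expect_equal(nrow(split$train), round(0.9 * n))
  key <- function(d) paste(d$prompt, d$completion)
  expect_length(intersect(key(split$train), key(split$test)), 0)
  again <- build_training_dataset(db, seed = 4, ratio = 0.9,
                                  pairs_per_formula = 4)
  expect_identical(split, again)
  other <- build_training_dataset(db, seed = 5, ratio = 0.9,
                                  pairs_per_formula = 4)
  expect_false(identical(split$train$prompt, other$train$prompt))
  expect_error(build_training_dataset(db, ratio = 1.2), "ratio")
})

test_that("every completion in a built dataset references only known ids", {
  db <- small_db()
  split <- build_training_dataset(db, seed = 8, pairs_per_formula = 2)
  all_pairs <- rbind(split$train, split$test)
  for (cmp in all_pairs$completion) {
    std <- standardize_output(cmp, db)
    expect_true(std$ok)
    parsed <- parse_completion(cmp)
    if (!is.null(parsed)) {
      expect_true(all(parsed$topn %in% names(db$formulas)))
      expect_true(parsed$syndrome %in% names(db$syndromes))
      expect_true(parsed$constitution %in% constitution_types())
    }
  }
})

test_that("prompt-completion pairs round-trip through JSONL", {
  db <- small_db()
  split <- build_training_dataset(db, seed = 2, pairs_per_formula = 1)
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_pairs_jsonl(split$test, p)
  lines <- readLines(p, encoding = "UTF-8")
  expect_equal(length(lines), nrow(split$test))
  back <- jsonlite::fromJSON(lines[1])
  expect_equal(back$prompt, split$test$prompt[1])
  expect_equal(back$completion, split$test$completion[1])
})

test_that("recommendation reports expose every pipeline intermediate", {
  db <- small_db()
  resp <- make_questionnaire_response(db$questionnaire, "yang-deficiency")
  rep <- recommend(fig4_symptoms(), resp, db)
  expect_s3_class(rep, "herbrec_report")
  expect_equal(length(rep$normalized$terms), 6)
  expect_true(is.data.frame(rep$syndromes))
  expect_equal(sum(rep$distribution), 1, tolerance = 1e-9)
  expect_equal(rep$constitution_label, "yang-deficiency")
  expect_true(is.data.frame(rep$candidates))
  expect_true(all(c("ind", "compat", "cov", "contra") %in%
                    names(rep$ranking)))
  expect_equal(nrow(rep$evidence), 3)
  expect_null(rep$na_stage)
  # pure function of its inputs: bit-identical reports across runs
  rep2 <- recommend(fig4_symptoms(), resp, db)
  expect_identical(rep, rep2)
})
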