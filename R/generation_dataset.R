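PROMPT_PREFIX <- "If the patient presents with "
PROMPT_SUFFIX <- ". Then recommend"
NA_SENTINEL <- "NA"

#' Pipeline configuration
#'
#' Bundles every tunable of the recommendation pipeline with its
#' documented default. All stages read their parameters from here, so a
#' single config object fully determines a run.
#'
#' @param selection a [selection_config()] (syndrome threshold `tau`,
#'   top-K, smoothing `epsilon`, combined-score threshold).
#' @param weights a [composite_weights()] — the `(a, b, c, d)` simplex
#'   point of the composite ranking.
#' @param top_m number of retrieved evidence chunks.
#' @param topn_k number of formula ids reported in a completion.
#' @param partial_affinity named list for
#'   [constitution_compatibility()]'s 0.5-grade lookups.
#' @param ind_method `"jaccard"` or `"proportion"` indication overlap.
#' @param aggregate `"max"` or `"mean"` over candidate pairs.
#' @param embedder optional plug-in embedding function (see
#'   [build_vector_index()]); `NULL` selects the order-free TF-IDF
#'   default.
#' @param mode pipeline mode: `"full"` (retrieval evidence + composite
#'   ranking), `"ranking"` (composite ranking only), or `"retrieval"`
#'   (cosine retrieval only — the nearest chunks' formulas, no composite
#'   score).
#' @param generator optional generator plug-in: a function
#'   `(augmented_prompt, report) -> raw completion string`. The default
#'   (`NULL`) is the deterministic rule pipeline itself: it formats the
#'   composite ranking as a structured completion. A fine-tuned language
#'   model would plug in behind the same contract.
#' @return A `herbrec_config` object.
#' @export
herbrec_config <- function(selection = selection_config(),
                           weights = composite_weights(),
                           top_m = 3, topn_k = 3,
                           partial_affinity = list(),
                           ind_method = c("jaccard", "proportion"),
                           aggregate = c("max", "mean"),
                           embedder = NULL,
                           mode = c("full", "ranking", "retrieval"),
                           generator = NULL) {
  structure(
    list(selection = selection, weights = weights,
         top_m = top_m, topn_k = topn_k,
         partial_affinity = partial_affinity,
         ind_method = match.arg(ind_method),
         aggregate = match.arg(aggregate),
         embedder = embedder, mode = match.arg(mode),
         generator = generator),
    class = "herbrec_config"
  )
}

#' Build an instruction prompt from a symptom list
#'
#' Instantiates the instruction template
#' `"If the patient presents with <term, term, ...>. Then recommend"`
#' with the comma-joined terms in input order. [parse_prompt()] is its
#' exact inverse (terms must not contain the `", "` separator).
#'
#' @param x a `normalized_symptoms` object or character vector (may be
#'   empty).
#' @return The prompt string.
#' @export
build_prompt <- function(x) {
  terms <- if (inherits(x, "normalized_symptoms")) x$terms else as.character(x)
  paste0(PROMPT_PREFIX, paste(terms, collapse = ", "), PROMPT_SUFFIX)
}

#' Recover the symptom list from a prompt
#'
#' @param prompt a string produced by [build_prompt()].
#' @return Character vector of terms (possibly empty).
#' @export
parse_prompt <- function(prompt) {
  if (!startsWith(prompt, PROMPT_PREFIX) || !endsWith(prompt, PROMPT_SUFFIX))
    stop_herbrec("parse_prompt", "not a recognised prompt template")
  body <- substr(prompt, nchar(PROMPT_PREFIX) + 1L,
                 nchar(prompt) - nchar(PROMPT_SUFFIX))
  if (!nzchar(body)) return(character(0))
  strsplit(body, ", ", fixed = TRUE)[[1]]
}

#' Format a structured completion
#'
#' The completion dialect is a punctuation-minimal structured triple
#' `SYNDROME=<id>;CONSTITUTION=<code>;TOPN=<id>,<id>,...`, or the exact
#' sentinel `"NA"` when no candidate survived selection. TOPN carries the
#' first `k` formula ids in rank order — recommendations are prioritized,
#' with the best-matching formula first.
#'
#' @param candidates output of [select_candidates()] (`NULL` for the NA
#'   sentinel).
#' @param ranked output of [rank_formulas()] (ignored when `candidates`
#'   is `NULL`).
#' @param k maximum TOPN length.
#' @return The completion string.
#' @export
build_completion <- function(candidates, ranked, k = 3) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NA_SENTINEL)
  if (is.null(ranked) || nrow(ranked) == 0L) return(NA_SENTINEL)
  top <- utils::head(ranked$formula_id, k)
  paste0("SYNDROME=", candidates$syndrome[1],
         ";CONSTITUTION=", candidates$constitution[1],
         ";TOPN=", paste(top, collapse = ","))
}

#' Standardize and validate a raw completion
#'
#' Enforces the output protocol on a raw generator string: whitespace
#' variants are collapsed, fullwidth separators are mapped to their ASCII
#' forms, punctuation outside the field separators (`= ; ,`) is stripped,
#' and the field structure plus every referenced id is validated against
#' the database. A string that cannot be brought into the dialect is
#' rejected with a reason — rejections are data, not errors.
#'
#' @param raw the raw completion string.
#' @param db a `formula_db`.
#' @return A list: `ok` (logical), `completion` (canonical string when
#'   `ok`), `reason` (when not).
#' @export
standardize_output <- function(raw, db) {
  reject <- function(reason) list(ok = FALSE, completion = NA_character_,
                                  reason = reason)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    return(reject("not a string"))
  s <- nfc(raw)
  s <- chartr("；，＝", ";,=", s)  # fullwidth ; , =
  s <- gsub("\\s+", " ", s)
  # strip punctuation that is not a field separator or id character
  s <- gsub("[^\\p{L}\\p{N}=;,_\\- ]", "", s, perl = TRUE)
  s <- gsub(" ?([=;,]) ?", "\\1", trimws(s))
  s <- gsub("[;,]+$", "", s)
  if (identical(s, NA_SENTINEL)) return(list(ok = TRUE, completion = NA_SENTINEL,
                                             reason = NA_character_))
  fields <- strsplit(s, ";", fixed = TRUE)[[1]]
  if (length(fields) != 3L) return(reject("expected 3 fields or NA"))
  kv <- lapply(fields, function(f) strsplit(f, "=", fixed = TRUE)[[1]])
  keys <- vapply(kv, `[`, "", 1)
  if (!identical(keys, c("SYNDROME", "CONSTITUTION", "TOPN")))
    return(reject("unexpected field structure"))
  vals <- vapply(kv, function(p) if (length(p) == 2L) p[2] else "", "")
  if (any(!nzchar(vals))) return(reject("empty field value"))
  syn <- vals[1]; ct <- vals[2]
  topn <- strsplit(vals[3], ",", fixed = TRUE)[[1]]
  if (!(syn %in% names(db$syndromes)))
    return(reject(paste("unknown syndrome id:", syn)))
  if (!(ct %in% constitution_types()))
    return(reject(paste("unknown constitution code:", ct)))
  bad <- setdiff(topn, names(db$formulas))
  if (length(bad) > 0)
    return(reject(paste("unknown formula id:", paste(bad, collapse = ","))))
  list(ok = TRUE,
       completion = paste0("SYNDROME=", syn, ";CONSTITUTION=", ct,
                           ";TOPN=", paste(topn, collapse = ",")),
       reason = NA_character_)
}

# ---- end-to-end recommendation ------------------------------------------

na_report <- function(stage, report) {
  report$completion <- NA_SENTINEL
  report$na_stage <- stage
  class(report) <- "herbrec_report"
  report
}

#' Run the full recommendation pipeline
#'
#' Executes the complete symptom-to-formula chain: normalize the raw
#' symptom report against the controlled vocabulary, score and retain
#' syndromes, score the constitution questionnaire into a probability
#' distribution, select (syndrome, constitution) candidate pairs by the
#' smoothed multiplicative combination, retrieve supporting evidence
#' chunks, rank all formulas by the four-term composite score, format the
#' structured completion via the configured generator, and validate it
#' through the output standardization protocol. The report retains every
#' intermediate (normalization trace, syndrome scores, constitution
#' distribution, candidate pairs, evidence, per-formula score breakdowns)
#' so each recommendation is fully interpretable. Whenever a stage finds
#' nothing — empty or fully-unmapped input, no syndrome above threshold,
#' no qualifying candidate pair — the exact `"NA"` sentinel propagates to
#' the completion and the report names the stage that emitted it.
#'
#' @param symptoms character vector of raw symptom surface forms, in the
#'   user's stated order.
#' @param questionnaire named numeric vector of 1–5 item responses
#'   covering the full questionnaire; `NULL` falls back to a uniform
#'   constitution distribution.
#' @param db a `formula_db`.
#' @param config a [herbrec_config()].
#' @param index optional prebuilt `vector_index` (rebuilt when `NULL`).
#' @return A `herbrec_report`: list with `input`, `normalized`,
#'   `syndromes`, `constitution_scores`, `distribution`,
#'   `constitution_label`, `candidates`, `evidence`, `ranking`,
#'   `completion`, `na_stage`, `config`.
#' @export
recommend <- function(symptoms, questionnaire, db,
                      config = herbrec_config(), index = NULL) {
  stopifnot(inherits(db, "formula_db"), inherits(config, "herbrec_config"))
  report <- list(input = as.character(symptoms), config = config,
                 na_stage = NULL)
  norm <- normalize_symptom_list(symptoms, db$vocabulary)
  report$normalized <- norm
  if (length(norm$terms) == 0L) return(na_report("normalization", report))

  syn <- rank_syndromes(norm, db$weight_table, config$selection)
  report$syndromes <- syn
  if (is.null(syn)) return(na_report("syndrome_selection", report))

  if (is.null(questionnaire)) {
    scores <- stats::setNames(rep(0, 9), constitution_types())
    report$constitution_label <- NA_character_
  } else {
    scores <- score_questionnaire(questionnaire, db$questionnaire)
    report$constitution_label <- constitution_label(scores, db$questionnaire)
  }
  dist <- constitution_distribution(scores)
  report$constitution_scores <- scores
  report$distribution <- dist

  cand <- select_candidates(syn, dist, config$selection)
  report$candidates <- cand
  if (is.null(cand)) return(na_report("candidate_selection", report))

  if (is.null(index))
    index <- build_vector_index(chunk_database(db), embedder = config$embedder)

  if (config$mode == "retrieval") {
    qtext <- query_text(db, norm$terms, unique(cand$syndrome),
                        cand$constitution[1])
    hits <- retrieve_top_m(qtext, index, max(config$top_m, config$topn_k))
    report$evidence <- hits
    ranking <- data.frame(formula_id = unique(hits$formula_id),
                          stringsAsFactors = FALSE)
    report$ranking <- ranking
  } else {
    m_eff <- if (config$mode == "ranking") 1L else config$top_m
    ranking <- rank_formulas(db, norm, cand, config$weights, index = index,
                             m = m_eff,
                             partial_affinity = config$partial_affinity,
                             ind_method = config$ind_method,
                             aggregate = config$aggregate)
    report$evidence <- if (config$mode == "ranking") NULL
      else attr(ranking, "evidence")
    report$ranking <- ranking
  }

  prompt <- build_prompt(norm)
  evidence_text <- if (!is.null(report$evidence)) {
    index$chunks$text[match(report$evidence$chunk_id, index$chunks$chunk_id)]
  } else character(0)
  report$augmented_prompt <- list(prompt = prompt,
                                  evidence = evidence_text,
                                  constitution = report$constitution_label)

  raw <- if (is.null(config$generator)) {
    build_completion(cand, ranking, config$topn_k)
  } else {
    config$generator(report$augmented_prompt, report)
  }
  std <- standardize_output(raw, db)
  if (!std$ok) {
    report$rejection <- std$reason
    return(na_report("output_standardization", report))
  }
  report$completion <- std$completion
  class(report) <- "herbrec_report"
  report
}

#' @export
print.herbrec_report <- function(x, ...) {
  cat("<herbrec_report>\n")
  cat("  symptoms:", paste(x$normalized$terms, collapse = ", "), "\n")
  if (!is.null(x$constitution_label) && !is.na(x$constitution_label))
    cat("  constitution:", x$constitution_label, "\n")
  cat("  completion:", x$completion, "\n")
  if (!is.null(x$na_stage)) cat("  NA emitted at stage:", x$na_stage, "\n")
  if (!is.null(x$ranking) && !is.null(x$ranking$r_score)) {
    top <- utils::head(x$ranking, 3)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %d. %s (R = %.4f)\n", i, top$name[i], top$r_score[i]))
  }
  invisible(x)
}

# ---- training dataset ----------------------------------------------------

#' Build a prompt-completion training dataset
#'
#' Produces one supervised pair per (formula, sampled symptom subset):
#' for each formula, symptom subsets are drawn from its documented
#' effects (surface forms occasionally swapped for their colloquial
#' variants so the dataset exercises normalization), a questionnaire
#' response consistent with one of its labeled constitutions is
#' synthesized, and the deterministic pipeline produces the completion.
#' Pairs are then split into train/test by a seeded shuffle at the given
#' ratio; the split is disjoint by construction and reproducible under
#' the seed.
#'
#' @param db a `formula_db`.
#' @param seed integer seed for subset sampling and the split shuffle.
#' @param ratio train fraction in (0, 1); 0.9 gives the conventional 9:1
#'   split.
#' @param pairs_per_formula subsets sampled per formula.
#' @param config a [herbrec_config()].
#' @return A `dataset_split`: list with `train` and `test` (data frames
#'   `prompt`, `completion`, `formula_id`), `seed`, `ratio`.
#' @export
build_training_dataset <- function(db, seed = 1, ratio = 0.9,
                                   pairs_per_formula = 3,
                                   config = herbrec_config()) {
  if (!is_number(ratio) || ratio <= 0 || ratio >= 1)
    stop_herbrec("build_training_dataset", "ratio must be in (0, 1)")
  rng <- rng_stream(seed, "training-dataset")
  index <- build_vector_index(chunk_database(db), embedder = config$embedder)
  colloq_rev <- stats::setNames(names(db$vocabulary$colloquial_to_canonical),
                                unname(db$vocabulary$colloquial_to_canonical))
  rows <- list()
  for (id in sort_c(names(db$formulas))) {
    f <- db$formulas[[id]]
    if (length(f$effects) == 0L) next
    for (j in seq_len(pairs_per_formula)) {
      k <- max(1L, rng_int(rng, length(f$effects)))
      terms <- rng_sample(rng, f$effects, k)
      surface <- vapply(terms, function(t) {
        v <- colloq_rev[t]
        if (!is.na(v) && rng_unif(rng) < 0.3) unname(v) else t
      }, character(1))
      ct <- rng_sample(rng, f$suitable_constitutions, 1L)
      resp <- make_questionnaire_response(db$questionnaire, ct)
      rep <- recommend(surface, resp, db, config, index = index)
      rows[[length(rows) + 1L]] <- data.frame(
        prompt = build_prompt(surface), completion = rep$completion,
        formula_id = id, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  # identical sampled subsets occasionally recur; duplicate supervised
  # pairs add nothing and would blur the train/test separation
  pairs <- pairs[!duplicated(pairs[c("prompt", "completion")]), , drop = FALSE]
  rownames(pairs) <- NULL
  split_dataset(pairs, seed = seed, ratio = ratio)
}

#' Split prompt-completion pairs into train and test sets
#'
#' Seeded shuffle, then a prefix/suffix cut at the ratio (rounded to the
#' nearest pair). Train and test are disjoint by construction.
#'
#' @param pairs data frame of prompt-completion pairs.
#' @param seed integer seed.
#' @param ratio train fraction in (0, 1).
#' @return A `dataset_split` object.
#' @export
split_dataset <- function(pairs, seed = 1, ratio = 0.9) {
  if (!is_number(ratio) || ratio <= 0 || ratio >= 1)
    stop_herbrec("split_dataset", "ratio must be in (0, 1)")
  rng <- rng_stream(seed, "dataset-split")
  n <- nrow(pairs)
  ord <- rng_sample(rng, seq_len(n), n)
  n_train <- round(n * ratio)
  train <- pairs[ord[seq_len(n_train)], , drop = FALSE]
  test <- pairs[ord[setdiff(seq_len(n), seq_len(n_train))], , drop = FALSE]
  rownames(train) <- NULL
  rownames(test) <- NULL
  structure(list(train = train, test = test, seed = seed, ratio = ratio),
            class = "dataset_split")
}

#' Write prompt-completion pairs as JSONL
#'
#' One JSON object per line with fields `prompt` and `completion` — the
#' interchange format consumed by instruction-tuning toolchains.
#'
#' @param pairs data frame with `prompt` and `completion` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_jsonl <- function(pairs, path) {
  lines <- vapply(seq_len(nrow(pairs)), function(i) {
    as.character(jsonlite::toJSON(
      list(prompt = pairs$prompt[i], completion = pairs$completion[i]),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  invisible(path)
}
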