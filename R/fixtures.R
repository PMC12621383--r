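#' Fixture generator configuration
#'
#' Controls the deterministic synthetic knowledge-base generator. The
#' default sizes emulate the scale of the curated corpus the engine is
#' designed for — 288 formulas over 426 dual-use substances and 484
#' catalogued symptoms across the nine constitutions — at full size;
#' tests use smaller explicit configs.
#'
#' @param seed integer; the same config always produces a byte-identical
#'   fixture.
#' @param n_formulas,n_substances,n_symptoms,n_syndromes positive counts.
#'   `n_symptoms` must be at least `n_formulas + n_syndromes` so every
#'   formula can carry a distinctive effect and every syndrome a shared
#'   symptom pool.
#' @param defect_count number of validation defects to inject (0 for a
#'   valid database); at most `n_formulas`.
#' @param include_paper_mirror when `TRUE`, the database additionally
#'   contains the two hand-curated worked scenarios: the yang-deficiency
#'   cluster resolved by \dQuote{yangzheng herbal drink} (with
#'   \dQuote{minzheng} and \dQuote{yusheng herbal drink} as runners-up)
#'   and the shared spleen-dampness cluster that recommends
#'   \dQuote{Poria cocos appetizing drink} for a yin-deficiency user but
#'   \dQuote{dried tangerine peel fat loss drink} for a phlegm-dampness
#'   user.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1, n_formulas = 288, n_substances = 426,
                           n_symptoms = 484, n_syndromes = 20,
                           defect_count = 0, include_paper_mirror = TRUE) {
  stopifnot(is_count(n_formulas), is_count(n_substances),
            is_count(n_symptoms), is_count(n_syndromes),
            is.numeric(defect_count), defect_count >= 0)
  if (n_symptoms < n_formulas + n_syndromes)
    stop_herbrec("fixture_config",
                 "need n_symptoms >= n_formulas + n_syndromes")
  if (defect_count > n_formulas)
    stop_herbrec("fixture_config",
                 "defect_count exceeds representable defects (one per formula)")
  structure(list(seed = seed, n_formulas = n_formulas,
                 n_substances = n_substances, n_symptoms = n_symptoms,
                 n_syndromes = n_syndromes, defect_count = defect_count,
                 include_paper_mirror = include_paper_mirror),
            class = "fixture_config")
}

# the two hand-curated worked scenarios layered onto generated fixtures
mirror_spec <- function() {
  yang <- c("visible dark circles", "more afraid of cold than others",
            "frequent bloating", "heavy body", "difficult in movement",
            "dry skin")
  damp <- c("dyspepsia", "dampness stagnancy due to spleen deficiency",
            "abdominal bloating", "abdominal obesity", "scanty dark urine",
            "obesity")
  list(
    yang_symptoms = yang,
    damp_symptoms = damp,
    syndromes = list(
      list(syndrome_id = "syn-yang-deficiency",
           label = "yang deficiency pattern"),
      list(syndrome_id = "syn-spleen-dampness",
           label = "spleen deficiency with damp stagnation pattern")
    ),
    formulas = list(
      list(formula_id = "formula-yangzheng", name = "yangzheng herbal drink",
           effects = yang, indicated_syndromes = "syn-yang-deficiency",
           suitable_constitutions = "yang-deficiency"),
      list(formula_id = "formula-minzheng", name = "minzheng herbal drink",
           effects = yang[1:5], indicated_syndromes = "syn-yang-deficiency",
           suitable_constitutions = "yang-deficiency"),
      list(formula_id = "formula-yusheng", name = "yusheng herbal drink",
           effects = yang[1:4], indicated_syndromes = "syn-yang-deficiency",
           suitable_constitutions = "yang-deficiency"),
      list(formula_id = "formula-poria",
           name = "Poria cocos appetizing drink",
           effects = damp, indicated_syndromes = "syn-spleen-dampness",
           suitable_constitutions = "yin-deficiency"),
      list(formula_id = "formula-chenpi",
           name = "dried tangerine peel fat loss drink",
           effects = damp, indicated_syndromes = "syn-spleen-dampness",
           suitable_constitutions = "phlegm-dampness")
    )
  )
}

#' Generate a synthetic knowledge base
#'
#' Builds a fully valid knowledge base of the requested size as a pure
#' function of the config: substances with aliases, syndromes with
#' disjoint symptom pools (each symptom plays a primary or secondary role
#' for exactly one syndrome, so its maximum weight is attained there),
#' formulas indicated for one syndrome each — carrying a distinctive
#' effect of their own plus shared effects from their syndrome's pool,
#' 1–3 suitable constitutions, and occasional graded contraindications —
#' a controlled vocabulary with colloquial variants, merge groups,
#' categories and a non-clinical exclusion list (including the
#' curated pair mapping the colloquial \dQuote{长痘痘} to
#' \dQuote{易生疥疮或痤疮}), and a nine-subscale constitution
#' questionnaire. Optionally injects a requested number of validation
#' defects (one per formula, cycling five defect kinds), and optionally
#' layers in the paper-mirror worked scenarios.
#'
#' @param cfg a [fixture_config()].
#' @return A `formula_db` (valid iff `defect_count == 0`).
#' @export
generate_fixture_database <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  rng <- rng_stream(cfg$seed, "fixture-db")

  categories <- c("digestive", "respiratory", "dermal", "circulatory",
                  "general", "sleep")
  sym <- sprintf("symptom-%03d", seq_len(cfg$n_symptoms))
  hallmark <- sym[seq_len(cfg$n_formulas)]
  shared <- sym[-seq_len(cfg$n_formulas)]
  syn_ids <- sprintf("syn-%02d", seq_len(cfg$n_syndromes))
  syndromes <- lapply(seq_along(syn_ids), function(j)
    list(syndrome_id = syn_ids[j],
         label = paste("fixture pattern", sprintf("%02d", j))))

  # disjoint symptom pools: shared symptoms round-robin over syndromes,
  # hallmark i follows formula i's home syndrome
  shared_syndrome <- syn_ids[((seq_along(shared) - 1L) %% cfg$n_syndromes) + 1L]
  home <- syn_ids[((seq_len(cfg$n_formulas) - 1L) %% cfg$n_syndromes) + 1L]

  acne <- "易生疥疮或痤疮"  # canonical acne term
  pimples <- "长痘痘"                       # colloquial form
  canon <- c(sym, acne)

  # colloquial surface for ~40% of symptoms, merge variant for ~20%
  has_colloq <- rng_unif(rng, cfg$n_symptoms) < 0.4
  colloq <- stats::setNames(sym[has_colloq],
                            sprintf("colloquial-%03d", which(has_colloq)))
  colloq[pimples] <- acne
  has_variant <- rng_unif(rng, cfg$n_symptoms) < 0.2
  variants <- sprintf("symptom-%03d-variant", which(has_variant))
  merge_groups <- stats::setNames(
    c(sym[has_variant], sym[has_variant]),
    c(variants, sym[has_variant])
  )
  canon <- c(canon, variants)
  category_of <- stats::setNames(
    categories[(seq_along(canon) - 1L) %% length(categories) + 1L], canon)
  exclusion <- c("likes spicy food", "stays up late", "drinks coffee daily",
                 "picky eater", "rarely exercises")

  entries <- data.frame(
    symptom = c(shared, hallmark, acne),
    syndrome = c(shared_syndrome, home, syn_ids[1]),
    role = "primary",
    stringsAsFactors = FALSE
  )
  # demote ~40% of shared symptoms to secondary within their syndrome
  sec <- rng_unif(rng, length(shared)) < 0.4
  entries$role[seq_along(shared)][sec] <- "secondary"

  sub_ids <- sprintf("sub-%03d", seq_len(cfg$n_substances))
  substances <- lapply(seq_along(sub_ids), function(i) {
    nm <- paste("fixture substance", sprintf("%03d", i))
    names_i <- if (rng_unif(rng) < 0.3) c(nm, paste(nm, "alias")) else nm
    list(substance_id = sub_ids[i], names = names_i)
  })

  pool_of <- split(shared, shared_syndrome)
  formulas <- lapply(seq_len(cfg$n_formulas), function(i) {
    pool <- pool_of[[home[i]]]
    n_eff <- min(length(pool), 2L + rng_int(rng, 4L))
    effects <- c(hallmark[i], rng_sample(rng, pool, n_eff))
    n_ct <- rng_int(rng, 3L)
    cts <- rng_sample(rng, constitution_types(), n_ct)
    contra <- numeric(0)
    if (rng_unif(rng) < 0.3) {
      foreign <- setdiff(shared, pool)
      terms <- rng_sample(rng, foreign, min(2L, length(foreign)))
      if (rng_unif(rng) < 0.5) {
        other_ct <- setdiff(constitution_types(), cts)
        terms <- c(terms, rng_sample(rng, other_ct, 1L))
      }
      contra <- stats::setNames(round(rng_unif(rng, length(terms)) * 0.7 + 0.3, 2),
                                terms)
    }
    list(
      formula_id = sprintf("formula-%03d", i),
      name = paste("fixture formula", sprintf("%03d", i), "drink"),
      ingredients = rng_sample(rng, sub_ids, 1L + rng_int(rng, 4L)),
      effects = effects,
      indicated_syndromes = home[i],
      suitable_constitutions = cts,
      target_population = paste("adults with", home[i], "presentations"),
      contraindications = contra
    )
  })

  if (cfg$include_paper_mirror) {
    mir <- mirror_spec()
    mir_sym <- c(mir$yang_symptoms, mir$damp_symptoms)
    canon <- c(canon, mir_sym)
    category_of[mir_sym] <- "general"
    colloq["fat"] <- "obesity"
    entries <- rbind(entries, data.frame(
      symptom = mir_sym,
      syndrome = rep(c("syn-yang-deficiency", "syn-spleen-dampness"),
                     each = 6),
      role = "primary", stringsAsFactors = FALSE))
    syndromes <- c(syndromes, mir$syndromes)
    mir_formulas <- lapply(mir$formulas, function(f) {
      f$ingredients <- sub_ids[seq_len(min(3L, length(sub_ids)))]
      f$target_population <- paste("adults with",
                                   f$suitable_constitutions[1], "constitution")
      f$contraindications <- numeric(0)
      f
    })
    formulas <- c(formulas, mir_formulas)
  }

  vocab <- vocabulary_map(
    colloquial_to_canonical = colloq,
    merge_groups = merge_groups,
    category_of = category_of,
    exclusion_list = exclusion,
    canonical = canon
  )
  wt <- syndrome_weight_table(entries)
  q <- questionnaire_spec(scales = stats::setNames(lapply(
    constitution_types(), function(ct) {
      list(items = lapply(1:4, function(k)
        list(item_id = sprintf("q-%s-%d", ct, k),
             direction = if (k == 4L) "negative" else "positive")))
    }), constitution_types()))

  db <- formula_db(substances, formulas, syndromes, vocab, wt, q,
                   version = paste0("fixture-", cfg$seed))
  if (cfg$defect_count > 0) db <- inject_defects(db, cfg, rng)
  db
}

# one defect per formula, cycling five kinds; each yields exactly one
# validation violation
inject_defects <- function(db, cfg, rng) {
  targets <- rng_sample(rng, sprintf("formula-%03d", seq_len(cfg$n_formulas)),
                        cfg$defect_count)
  for (i in seq_along(targets)) {
    f <- db$formulas[[targets[i]]]
    kind <- (i - 1L) %% 5L + 1L
    if (kind == 1L) {
      f$ingredients <- c(f$ingredients, "sub-bogus")
    } else if (kind == 2L) {
      f$suitable_constitutions <- character(0)
    } else if (kind == 3L) {
      f$contraindications <- c(f$contraindications,
                               stats::setNames(1.5, f$effects[1]))
    } else if (kind == 4L) {
      f$indicated_syndromes <- c(f$indicated_syndromes, "syn-bogus")
    } else {
      f$effects <- c(f$effects, "uncatalogued-effect-term")
    }
    db$formulas[[targets[i]]] <- f
  }
  db
}

#' Synthesize a questionnaire response for a target constitution
#'
#' Builds a complete 1–5 response set whose transformed scores place the
#' target constitution at `intensity` x 100 and all others at 0:
#' positively-keyed items of the target subscale get the high response,
#' negatively-keyed ones the low response, and vice versa elsewhere.
#'
#' @param spec a [questionnaire_spec()].
#' @param constitution the target constitution code.
#' @param intensity target subscale intensity in (0, 1\]; 1 gives the
#'   scale maximum.
#' @return Named numeric response vector covering every item.
#' @export
make_questionnaire_response <- function(spec, constitution, intensity = 1) {
  stopifnot(constitution %in% names(spec$scales))
  hi <- 1 + round(4 * intensity)
  resp <- numeric(0)
  for (ct in names(spec$scales)) {
    for (it in spec$scales[[ct]]$items) {
      pos <- identical(it$direction, "positive")
      on_target <- identical(ct, constitution)
      resp[it$item_id] <- if (on_target == pos) hi else 6 - hi
    }
  }
  resp[] <- pmin(pmax(resp, 1), 5)
  resp
}

#' Generate a labeled evaluation set
#'
#' Draws `n_cases` labeled cases from a knowledge base: a gold formula is
#' sampled among formulas owning at least one distinctive effect (an
#' effect no other formula documents), the symptom list combines one
#' distinctive effect with further effects of the gold formula (surface
#' forms occasionally swapped for their colloquial variants) plus
#' `n_distractors` canonical symptoms from outside the formula's effects,
#' shuffled into the case's forward order; the questionnaire response is
#' consistent with one of the gold formula's labeled constitutions. With
#' zero distractors the gold formula is recoverable at rank 1 by
#' construction.
#'
#' @param db a valid `formula_db`.
#' @param n_cases number of cases, >= 1.
#' @param seed integer seed; the case list is a pure function of
#'   `(db, n_cases, seed, n_distractors)`.
#' @param n_distractors off-target symptoms per case.
#' @return List of cases: `case_id`, `symptoms` (surface forms, forward
#'   order), `questionnaire`, `gold`, `constitution`.
#' @export
generate_eval_set <- function(db, n_cases, seed = 1, n_distractors = 0) {
  stopifnot(inherits(db, "formula_db"), is_count(n_cases))
  if (length(db$formulas) == 0L)
    stop_herbrec("generate_eval_set", "database has no formulas")
  rng <- rng_stream(seed, "eval-set")
  effect_count <- table(unlist(lapply(db$formulas, `[[`, "effects")))
  distinctive <- lapply(db$formulas, function(f)
    f$effects[effect_count[f$effects] == 1L])
  eligible <- names(db$formulas)[lengths(distinctive) > 0]
  if (length(eligible) == 0L)
    stop_herbrec("generate_eval_set", "no formula has a distinctive effect")
  colloq_rev <- stats::setNames(names(db$vocabulary$colloquial_to_canonical),
                                unname(db$vocabulary$colloquial_to_canonical))
  all_sym <- unique(db$weight_table$entries$symptom)
  lapply(seq_len(n_cases), function(i) {
    gold <- rng_sample(rng, eligible, 1L)
    f <- db$formulas[[gold]]
    mark <- rng_sample(rng, distinctive[[gold]], 1L)
    rest <- setdiff(f$effects, mark)
    n_more <- min(length(rest), rng_int(rng, 3L))
    terms <- c(mark, if (n_more > 0) rng_sample(rng, rest, n_more))
    if (n_distractors > 0) {
      out_pool <- setdiff(all_sym, f$effects)
      terms <- c(terms, rng_sample(rng, out_pool,
                                   min(n_distractors, length(out_pool))))
    }
    surface <- vapply(terms, function(t) {
      v <- colloq_rev[t]
      if (!is.na(v) && rng_unif(rng) < 0.3) unname(v) else t
    }, character(1))
    surface <- rng_sample(rng, surface, length(surface))
    ct <- rng_sample(rng, f$suitable_constitutions, 1L)
    list(case_id = sprintf("case-%04d", i),
         symptoms = unname(surface),
         questionnaire = make_questionnaire_response(db$questionnaire, ct),
         gold = gold,
         constitution = ct)
  })
}

#' Write an evaluation set as JSONL
#'
#' @param cases list of cases from [generate_eval_set()].
#' @param path output path (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_eval_jsonl <- function(cases, path) {
  lines <- vapply(cases, function(cs) {
    as.character(jsonlite::toJSON(
      list(case_id = cs$case_id, symptoms = cs$symptoms,
           questionnaire = as.list(cs$questionnaire), gold = cs$gold,
           constitution = cs$constitution),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  invisible(path)
}

#' Read an evaluation set from JSONL
#'
#' @param path path written by [write_eval_jsonl()].
#' @return List of cases.
#' @export
read_eval_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    list(case_id = x$case_id,
         symptoms = as.character(unlist(x$symptoms)),
         questionnaire = unlist(x$questionnaire),
         gold = x$gold,
         constitution = x$constitution)
  })
}
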