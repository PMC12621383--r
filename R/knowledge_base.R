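#' Construct a formula knowledge base
#'
#' Builds the in-memory knowledge base holding everything the
#' recommendation pipeline consumes: the substance catalogue, the formula
#' records, the syndrome patterns, the controlled symptom vocabulary, the
#' practitioner syndrome-weight table, and the constitution questionnaire
#' specification. All text is NFC-normalized on ingest so downstream
#' comparisons are exact.
#'
#' @param substances list of substance records, each
#'   `list(substance_id, names)` with the canonical name first.
#' @param formulas list of formula records, each
#'   `list(formula_id, name, ingredients, effects, indicated_syndromes,
#'   suitable_constitutions, target_population, contraindications)`;
#'   `contraindications` is a named numeric vector mapping canonical term
#'   to a severity grade in \[0, 1\] (terms without a stated grade default
#'   to 1).
#' @param syndromes list of `list(syndrome_id, label)` records.
#' @param vocabulary a [vocabulary_map()].
#' @param weight_table a [syndrome_weight_table()].
#' @param questionnaire a [questionnaire_spec()].
#' @param version version string stamped into serialized files.
#'
#' @return An object of class `formula_db`. Lookup tables (`substances`,
#'   `formulas`, `syndromes`) are named lists keyed by id.
#' @seealso [validate_database()], [load_database()], [save_database()]
#' @export
formula_db <- function(substances, formulas, syndromes, vocabulary,
                       weight_table, questionnaire, version = "1") {
  key_by <- function(records, id_field) {
    out <- lapply(records, function(r) {
      r[[id_field]] <- nfc(r[[id_field]])
      r
    })
    names(out) <- vapply(out, function(r) r[[id_field]], character(1))
    # key-sorted so equal databases compare and serialize identically
    out[sort_c(names(out))]
  }
  substances <- key_by(lapply(substances, normalize_substance), "substance_id")
  formulas <- key_by(lapply(formulas, normalize_formula), "formula_id")
  syndromes <- key_by(lapply(syndromes, normalize_syndrome), "syndrome_id")
  structure(
    list(
      version = nfc(version),
      substances = substances,
      formulas = formulas,
      syndromes = syndromes,
      vocabulary = vocabulary,
      weight_table = weight_table,
      questionnaire = questionnaire
    ),
    class = "formula_db"
  )
}

normalize_substance <- function(r) {
  list(substance_id = nfc(r$substance_id), names = nfc(unlist(r$names)))
}

normalize_formula <- function(r) {
  contra <- r$contraindications %||% numeric(0)
  if (is.list(contra)) contra <- unlist(contra)
  if (length(contra) > 0 && is.null(names(contra))) {
    # bare terms: severity defaults to 1
    contra <- stats::setNames(rep(1, length(contra)), as.character(contra))
  }
  sev <- as.numeric(contra)
  names(sev) <- nfc(names(contra))
  if (length(sev) > 0) sev <- sev[sort_c(names(sev))]
  # set-valued fields are stored sorted; ingredient order is preserved
  # (it is part of the recipe)
  list(
    formula_id = nfc(r$formula_id),
    name = nfc(r$name),
    ingredients = nfc(unlist(r$ingredients) %||% character(0)),
    effects = sort_c(unique(nfc(unlist(r$effects) %||% character(0)))),
    indicated_syndromes = sort_c(unique(nfc(unlist(r$indicated_syndromes) %||% character(0)))),
    suitable_constitutions = sort_c(unique(nfc(unlist(r$suitable_constitutions) %||% character(0)))),
    target_population = nfc(r$target_population %||% ""),
    contraindications = sev
  )
}

normalize_syndrome <- function(r) {
  list(syndrome_id = nfc(r$syndrome_id), label = nfc(r$label))
}

#' @export
print.formula_db <- function(x, ...) {
  cat("<formula_db> version", x$version, "\n")
  cat(" ", length(x$formulas), "formulas,", length(x$substances),
      "substances,", length(x$syndromes), "syndromes,",
      length(x$vocabulary$canonical), "canonical terms\n")
  invisible(x)
}

#' Validate a knowledge base
#'
#' Checks every structural invariant of the knowledge base: id uniqueness,
#' referential integrity between formulas and the substance / syndrome /
#' vocabulary id spaces, non-empty constitution labels drawn from the nine
#' admissible codes, contraindication severity grades inside \[0, 1\],
#' vocabulary self-consistency (merge representatives map to themselves,
#' exclusions disjoint from the canon), weight-table well-formedness
#' (primary weight strictly above secondary, entries referencing known
#' symptoms and syndromes), and questionnaire coverage of all nine
#' constitutions.
#'
#' Violations are data, not exceptions: the caller decides whether to stop.
#'
#' @param db a `formula_db`.
#' @return A data frame with columns `record`, `rule`, `detail`; zero rows
#'   when every invariant holds.
#' @export
validate_database <- function(db) {
  v <- list()
  add <- function(record, rule, detail) {
    v[[length(v) + 1L]] <<- data.frame(record = record, rule = rule,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  }
  canon <- db$vocabulary$canonical
  syn_ids <- names(db$syndromes)
  sub_ids <- names(db$substances)

  dup <- function(ids) unique(ids[duplicated(ids)])
  for (id in dup(vapply(db$substances, `[[`, "", "substance_id")))
    add(id, "substance-id-unique", "duplicate substance_id")
  for (s in db$substances)
    if (length(s$names) == 0L || all(!nzchar(s$names)))
      add(s$substance_id, "substance-named", "substance has no name")
  for (id in dup(vapply(db$formulas, `[[`, "", "formula_id")))
    add(id, "formula-id-unique", "duplicate formula_id")
  for (id in dup(vapply(db$syndromes, `[[`, "", "syndrome_id")))
    add(id, "syndrome-id-unique", "duplicate syndrome_id")

  for (f in db$formulas) {
    miss <- setdiff(f$ingredients, sub_ids)
    if (length(miss) > 0)
      add(f$formula_id, "unknown-substance",
          paste("unknown substance id:", paste(miss, collapse = ", ")))
    if (length(f$suitable_constitutions) == 0L)
      add(f$formula_id, "empty-constitutions",
          "suitable_constitutions must be non-empty")
    bad_c <- setdiff(f$suitable_constitutions, constitution_types())
    if (length(bad_c) > 0)
      add(f$formula_id, "invalid-constitution",
          paste("not one of the nine types:", paste(bad_c, collapse = ", ")))
    miss_s <- setdiff(f$indicated_syndromes, syn_ids)
    if (length(miss_s) > 0)
      add(f$formula_id, "unknown-syndrome",
          paste("unknown syndrome id:", paste(miss_s, collapse = ", ")))
    miss_e <- setdiff(f$effects, canon)
    if (length(miss_e) > 0)
      add(f$formula_id, "effect-not-canonical",
          paste("effect outside vocabulary canon:",
                paste(miss_e, collapse = ", ")))
    sev <- f$contraindications
    if (length(sev) > 0) {
      if (any(is.na(sev)) || any(sev < 0) || any(sev > 1))
        add(f$formula_id, "severity-range",
            "contraindication severity outside [0, 1]")
      miss_k <- setdiff(names(sev), c(canon, constitution_types()))
      if (length(miss_k) > 0)
        add(f$formula_id, "contra-not-canonical",
            paste("contraindication term outside canon:",
                  paste(miss_k, collapse = ", ")))
    }
  }

  voc <- db$vocabulary
  reps <- unique(unname(voc$merge_groups))
  bad_rep <- reps[!(reps %in% names(voc$merge_groups) &
                      voc$merge_groups[reps] == reps)]
  for (r in bad_rep)
    add(r, "merge-representative", "representative must map to itself")
  overlap <- intersect(voc$exclusion_list, canon)
  for (t in overlap)
    add(t, "exclusion-overlap", "exclusion term is also canonical")
  bad_map <- setdiff(unname(voc$colloquial_to_canonical), canon)
  for (t in unique(bad_map))
    add(t, "mapping-target-canonical",
        "colloquial mapping target is not canonical")

  wt <- db$weight_table
  if (!(wt$role_weights[["primary"]] > wt$role_weights[["secondary"]] &&
          wt$role_weights[["secondary"]] > 0))
    add("role_weights", "role-weights",
        "need primary > secondary > 0")
  ent <- wt$entries
  if (nrow(ent) > 0) {
    bad_role <- unique(ent$role[!ent$role %in% c("primary", "secondary")])
    for (r in bad_role) add(r, "weight-role", "role must be primary/secondary")
    for (s in unique(setdiff(ent$symptom, canon)))
      add(s, "weight-symptom-canonical", "weight entry symptom not canonical")
    for (s in unique(setdiff(ent$syndrome, syn_ids)))
      add(s, "weight-syndrome-known", "weight entry syndrome unknown")
    key <- paste(ent$symptom, ent$syndrome, sep = "\r")
    for (k in unique(key[duplicated(key)]))
      add(sub("\r.*", "", k), "weight-entry-unique",
          "duplicate (symptom, syndrome) weight entry")
  }

  q <- db$questionnaire
  miss_q <- setdiff(constitution_types(), names(q$scales))
  for (ct in miss_q)
    add(ct, "questionnaire-coverage", "constitution lacks a subscale")
  for (ct in names(q$scales)) {
    sc <- q$scales[[ct]]
    if (length(sc$items) == 0L)
      add(ct, "questionnaire-items", "subscale has no items")
  }
  if (!is.null(q$cutoffs)) {
    cuts <- unlist(q$cutoffs)
    if (any(cuts < 0 | cuts > 100))
      add("cutoffs", "questionnaire-cutoffs", "cutoff outside [0, 100]")
  }

  if (length(v) == 0L)
    return(data.frame(record = character(0), rule = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

stop_on_violations <- function(db, stage) {
  viol <- validate_database(db)
  if (nrow(viol) > 0) {
    stop_herbrec(stage, "knowledge base failed validation: ",
                 paste0(viol$record, " [", viol$rule, "]", collapse = "; "))
  }
  db
}

# ---- serialization -------------------------------------------------------

# Canonical form: recursively key-sorted objects, scalars unboxed, arrays
# sorted by record id where order is not semantic. Equal databases
# serialize to identical bytes.
db_to_canonical_list <- function(db) {
  records_of <- function(tbl) lapply(unname(tbl[sort_c(names(tbl))]), identity)
  wt <- db$weight_table
  ent <- wt$entries
  if (nrow(ent) > 0) {
    ent <- ent[order_c(ent$symptom, ent$syndrome), , drop = FALSE]
  }
  entries <- lapply(seq_len(nrow(ent)), function(i) {
    list(symptom = ent$symptom[i], syndrome = ent$syndrome[i],
         role = ent$role[i])
  })
  contra_list <- function(sev) {
    if (length(sev) == 0L) return(stats::setNames(list(), character(0)))
    as.list(sev[sort_c(names(sev))])
  }
  formulas <- lapply(records_of(db$formulas), function(f) {
    list(
      formula_id = f$formula_id, name = f$name,
      ingredients = as.list(f$ingredients),
      effects = as.list(sort_c(f$effects)),
      indicated_syndromes = as.list(sort_c(f$indicated_syndromes)),
      suitable_constitutions = as.list(sort_c(f$suitable_constitutions)),
      target_population = f$target_population,
      contraindications = contra_list(f$contraindications)
    )
  })
  named_chr <- function(x) {
    if (length(x) == 0L) return(stats::setNames(list(), character(0)))
    as.list(x[sort_c(names(x))])
  }
  q <- db$questionnaire
  scales <- lapply(q$scales[sort_c(names(q$scales))], function(sc) {
    items <- sc$items[order_c(vapply(sc$items, `[[`, "", "item_id"))]
    list(items = lapply(items, function(it)
      list(item_id = it$item_id, direction = it$direction)))
  })
  list(
    version = db$version,
    substances = lapply(records_of(db$substances), function(s)
      list(substance_id = s$substance_id, names = as.list(s$names))),
    formulas = formulas,
    syndromes = lapply(records_of(db$syndromes), function(s)
      list(syndrome_id = s$syndrome_id, label = s$label)),
    vocabulary = list(
      canonical = as.list(sort_c(db$vocabulary$canonical)),
      colloquial_to_canonical = named_chr(db$vocabulary$colloquial_to_canonical),
      merge_groups = named_chr(db$vocabulary$merge_groups),
      category_of = named_chr(db$vocabulary$category_of),
      exclusion_list = as.list(sort_c(db$vocabulary$exclusion_list))
    ),
    weight_table = list(
      role_weights = list(primary = unname(wt$role_weights[["primary"]]),
                          secondary = unname(wt$role_weights[["secondary"]])),
      entries = entries
    ),
    questionnaire = list(
      scales = scales,
      cutoffs = list(balanced_min = q$cutoffs$balanced_min,
                     biased_max = q$cutoffs$biased_max)
    )
  )
}

#' Save a knowledge base to canonical JSON
#'
#' Serialization is canonical — key-sorted objects, NFC text, fixed
#' numeric formatting — so two structurally equal databases always produce
#' byte-identical files, and save/load/save is the identity on bytes.
#'
#' @param db a valid `formula_db`.
#' @param path output file path (UTF-8 JSON).
#' @return `path`, invisibly.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "formula_db"))
  stop_on_violations(db, "save_database")
  json <- jsonlite::toJSON(db_to_canonical_list(db), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(as.character(json), "\n")), con)
  invisible(path)
}

#' Load a knowledge base from JSON
#'
#' Reads the single-document JSON dialect written by [save_database()],
#' NFC-normalizes all text, rebuilds the lookup structures, and validates
#' every invariant. A file that parses but violates an invariant raises a
#' validation error naming the offending record and rule.
#'
#' @param path path to a knowledge-base JSON file.
#' @return A validated `formula_db`.
#' @export
load_database <- function(path) {
  if (!file.exists(path))
    stop_herbrec("load_database", "file not found: ", path)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e)
      stop_herbrec("load_database", "malformed JSON in ", path, ": ",
                   conditionMessage(e))
  )
  as_chr <- function(x) as.character(unlist(x) %||% character(0))
  named_from <- function(x) {
    if (length(x) == 0L) return(stats::setNames(character(0), character(0)))
    stats::setNames(nfc(as_chr(x)), nfc(names(x)))
  }
  voc <- vocabulary_map(
    colloquial_to_canonical = named_from(raw$vocabulary$colloquial_to_canonical),
    merge_groups = named_from(raw$vocabulary$merge_groups),
    category_of = named_from(raw$vocabulary$category_of),
    exclusion_list = nfc(as_chr(raw$vocabulary$exclusion_list)),
    canonical = nfc(as_chr(raw$vocabulary$canonical))
  )
  ent_raw <- raw$weight_table$entries
  entries <- data.frame(
    symptom = nfc(vapply(ent_raw, function(e) e$symptom, character(1))),
    syndrome = nfc(vapply(ent_raw, function(e) e$syndrome, character(1))),
    role = vapply(ent_raw, function(e) e$role, character(1)),
    stringsAsFactors = FALSE
  )
  wt <- syndrome_weight_table(
    entries = entries,
    role_weights = c(primary = as.numeric(raw$weight_table$role_weights$primary),
                     secondary = as.numeric(raw$weight_table$role_weights$secondary))
  )
  scales <- lapply(raw$questionnaire$scales, function(sc) {
    list(items = lapply(sc$items, function(it)
      list(item_id = nfc(it$item_id), direction = it$direction)))
  })
  q <- questionnaire_spec(
    scales = scales,
    cutoffs = list(
      balanced_min = as.numeric(raw$questionnaire$cutoffs$balanced_min %||% 60),
      biased_max = as.numeric(raw$questionnaire$cutoffs$biased_max %||% 30)
    )
  )
  formulas <- lapply(raw$formulas, function(f) {
    sev <- f$contraindications
    f$contraindications <- stats::setNames(as.numeric(unlist(sev)),
                                           names(sev))
    f
  })
  db <- formula_db(
    substances = raw$substances,
    formulas = formulas,
    syndromes = raw$syndromes,
    vocabulary = voc,
    weight_table = wt,
    questionnaire = q,
    version = raw$version %||% "1"
  )
  stop_on_violations(db, "load_database")
}
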