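#' Chunk a knowledge base into retrievable documents
#'
#' Produces one document chunk per formula (the corpora here are small and
#' each record is short, so finer segmentation buys nothing). The chunk
#' text concatenates the fields a practitioner would consult: name,
#' documented effects, indicated syndrome labels, suitable constitutions,
#' and target population, joined by a field separator that the default
#' tokenizer splits on. Ordering is deterministic by formula id.
#'
#' @param db a `formula_db`.
#' @return Data frame with columns `chunk_id`, `formula_id`, `text`.
#' @export
chunk_database <- function(db) {
  ids <- sort_c(names(db$formulas))
  texts <- vapply(ids, function(id) {
    f <- db$formulas[[id]]
    labels <- vapply(f$indicated_syndromes, function(s)
      db$syndromes[[s]]$label %||% s, character(1))
    paste(c(f$name, f$effects, labels, f$indicated_syndromes,
            f$suitable_constitutions, f$target_population),
          collapse = " ; ")
  }, character(1))
  data.frame(
    chunk_id = if (length(ids)) paste0("chunk_", ids) else character(0),
    formula_id = ids,
    text = unname(texts),
    stringsAsFactors = FALSE
  )
}

# bag of canonical-term tokens: chunk and query text are built by joining
# whole terms with " ; ", so tokenization is a split, not NLP
tokenize_terms <- function(text) {
  toks <- nfc(strsplit(text, ";", fixed = TRUE)[[1]])
  toks[nzchar(toks)]
}

#' Build a TF-IDF vector index over document chunks
#'
#' The default embedder is an order-free bag of canonical terms: each
#' chunk becomes a term-frequency vector over the corpus vocabulary,
#' weighted by smoothed inverse document frequency
#' `idf(t) = log((1 + N) / (1 + df(t))) + 1`. Because the representation
#' is a bag, permuting the terms of a query cannot change its vector —
#' this is what makes the whole retrieval stage order-robust by
#' construction. Neural embedders can replace it behind the same contract
#' (a function from text to a fixed-length numeric vector).
#'
#' @param chunks output of [chunk_database()].
#' @param embedder optional plug-in: function `(text, index) -> numeric
#'   vector`; `NULL` selects the built-in TF-IDF embedder.
#' @param embedder_id identifier recorded on the index.
#' @return A `vector_index`: chunks plus an embedding matrix (rows =
#'   chunks) and the embedding closure.
#' @export
build_vector_index <- function(chunks, embedder = NULL,
                               embedder_id = "tfidf-bag-v1") {
  stopifnot(is.data.frame(chunks))
  token_sets <- lapply(chunks$text, tokenize_terms)
  vocab <- sort_c(unique(unlist(token_sets)))
  n_doc <- nrow(chunks)
  df <- vapply(vocab, function(t)
    sum(vapply(token_sets, function(s) t %in% s, logical(1))), numeric(1))
  idf <- log((1 + n_doc) / (1 + df)) + 1
  idx <- structure(
    list(chunks = chunks, vocab = vocab, idf = idf,
         embedder = embedder, embedder_id = embedder_id),
    class = "vector_index"
  )
  vecs <- lapply(chunks$text, function(tx) embed_text(tx, idx))
  dims <- unique(lengths(vecs))
  if (length(dims) > 1L)
    stop_herbrec("build_vector_index", "embedder returned mixed dimensions")
  mat <- if (length(vecs) == 0L) {
    matrix(numeric(0), nrow = 0, ncol = length(vocab))
  } else {
    do.call(rbind, vecs)
  }
  rownames(mat) <- chunks$chunk_id
  idx$matrix <- mat
  idx
}

#' Embed a text as a fixed-length vector
#'
#' With the default embedder: tokenizes on the field separator, counts
#' term frequencies over the index vocabulary (unknown terms are
#' ignored), and applies the index's IDF weights.
#'
#' @param text a non-empty string.
#' @param index a `vector_index` (supplies vocabulary, IDF, and any
#'   plug-in embedder).
#' @return Numeric vector of the index's fixed dimension.
#' @export
embed_text <- function(text, index) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop_herbrec("embed_text", "text must be a non-empty string")
  if (!is.null(index$embedder)) return(index$embedder(text, index))
  toks <- tokenize_terms(text)
  tf <- table(factor(toks, levels = index$vocab))
  as.numeric(tf) * index$idf
}

cosine_sim <- function(v, m) {
  nv <- sqrt(sum(v^2))
  nm <- sqrt(rowSums(m^2))
  denom <- nv * nm
  s <- as.numeric(m %*% v)
  ifelse(denom > 0, s / denom, 0)
}

# query text for retrieval: symptoms + retained syndrome labels +
# constitution, joined in the same bag-of-terms dialect as the chunks
query_text <- function(db, terms, syndromes = character(0),
                       constitution = character(0)) {
  labels <- vapply(syndromes, function(s)
    db$syndromes[[s]]$label %||% s, character(1))
  paste(c(terms, labels, syndromes, constitution), collapse = " ; ")
}

#' Retrieve the top-M evidence chunks for a query
#'
#' Ranks all indexed chunks by cosine similarity to the query vector and
#' returns the best `m` (ties broken by chunk id ascending). Fewer than
#' `m` chunks come back only when the index itself is smaller.
#'
#' @param query query text (same dialect as chunk text) or a precomputed
#'   numeric query vector.
#' @param index a `vector_index`.
#' @param m number of evidence chunks, >= 1.
#' @return Data frame `chunk_id`, `formula_id`, `similarity`, best first.
#' @export
retrieve_top_m <- function(query, index, m = 3) {
  stopifnot(is_count(m))
  if (nrow(index$chunks) == 0L)
    stop_herbrec("retrieve_top_m", "empty index")
  v <- if (is.numeric(query)) query else embed_text(query, index)
  sims <- cosine_sim(v, index$matrix)
  ord <- order_c(-sims, index$chunks$chunk_id)
  take <- utils::head(ord, m)
  data.frame(chunk_id = index$chunks$chunk_id[take],
             formula_id = index$chunks$formula_id[take],
             similarity = sims[take],
             stringsAsFactors = FALSE)
}

# ---- composite score terms ----------------------------------------------

#' Indication overlap between candidate syndromes and a formula
#'
#' Jaccard similarity between the candidate syndrome set and the
#' formula's documented indications. A proportion-match alternative
#' (`|intersection| / |candidate set|`) is available for sensitivity
#' analyses.
#'
#' @param s_set non-empty character vector of candidate syndrome ids.
#' @param formula a formula record from a `formula_db`.
#' @param method `"jaccard"` (default) or `"proportion"`.
#' @return A number in \[0, 1\].
#' @export
indication_overlap <- function(s_set, formula, method = c("jaccard", "proportion")) {
  method <- match.arg(method)
  s_set <- unique(as.character(s_set))
  if (length(s_set) == 0L)
    stop_herbrec("indication_overlap", "candidate syndrome set is empty")
  ind <- unique(formula$indicated_syndromes)
  inter <- length(intersect(s_set, ind))
  if (method == "jaccard") {
    uni <- length(union(s_set, ind))
    if (uni == 0L) return(0)
    inter / uni
  } else {
    inter / length(s_set)
  }
}

#' Constitution compatibility of a formula
#'
#' 1 when the inferred constitution is among the formula's labeled
#' suitable constitutions; 0.5 when it is partially affine to one of them
#' per a configured affinity table; 0 otherwise.
#'
#' @param constitution a constitution code.
#' @param formula a formula record.
#' @param partial_affinity named list mapping a constitution code to the
#'   codes it is partially affine with (symmetric use is the caller's
#'   choice; lookup is by the inferred constitution).
#' @return 0, 0.5, or 1.
#' @export
constitution_compatibility <- function(constitution, formula,
                                       partial_affinity = list()) {
  if (constitution %in% formula$suitable_constitutions) return(1)
  affine <- partial_affinity[[constitution]] %||% character(0)
  if (length(intersect(affine, formula$suitable_constitutions)) > 0) return(0.5)
  0
}

#' Symptom coverage of a formula
#'
#' Fraction of the reported canonical symptoms addressed by the formula's
#' documented effects: `|X intersect effects| / |X|`.
#'
#' @param x a `normalized_symptoms` object or character vector of
#'   canonical terms; non-empty.
#' @param formula a formula record.
#' @return A number in \[0, 1\].
#' @export
symptom_coverage <- function(x, formula) {
  terms <- if (inherits(x, "normalized_symptoms")) x$terms else as.character(x)
  terms <- unique(terms)
  if (length(terms) == 0L)
    stop_herbrec("symptom_coverage", "empty symptom set")
  length(intersect(terms, formula$effects)) / length(terms)
}

#' Contraindication penalty
#'
#' Maximum severity grade over the formula's contraindication terms that
#' match either a reported canonical symptom or the inferred constitution
#' code; 0 when nothing matches. Max-aggregation makes a single strong
#' conflict dominate, which is the clinically conservative choice.
#'
#' @param x canonical symptom terms (or `normalized_symptoms`).
#' @param constitution inferred constitution code (may be `character(0)`).
#' @param formula a formula record.
#' @return A number in \[0, 1\].
#' @export
contraindication_penalty <- function(x, constitution, formula) {
  terms <- if (inherits(x, "normalized_symptoms")) x$terms else as.character(x)
  sev <- formula$contraindications
  if (length(sev) == 0L) return(0)
  hit <- names(sev) %in% c(terms, constitution)
  if (!any(hit)) return(0)
  max(sev[hit])
}

#' Composite ranking weights
#'
#' The non-negative weights `(a, b, c, d)` of the four-term composite
#' score, constrained to the simplex `a + b + c + d = 1`. Defaults
#' `(0.4, 0.3, 0.2, 0.1)` put syndrome indication first, in line with the
#' syndrome-differentiation doctrine, then constitution compatibility,
#' symptom coverage, and the contraindication penalty.
#'
#' @param a,b,c,d non-negative weights summing to 1 (tolerance 1e-9).
#' @return A `composite_weights` object.
#' @export
composite_weights <- function(a = 0.4, b = 0.3, c = 0.2, d = 0.1) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (abs(a + b + c + d - 1) > 1e-9)
    stop_herbrec("composite_weights", "weights must sum to 1, got ",
                 format(a + b + c + d, digits = 12))
  structure(list(a = a, b = b, c = c, d = d), class = "composite_weights")
}

#' Four-term composite formula score
#'
#' \deqn{R(F \mid S, C, X) = a\,\mathrm{Ind} + b\,\mathrm{Compat} +
#'   c\,\mathrm{Cov} - d\,\mathrm{Contra}}
#' Each term lies in \[0, 1\], so `R` is bounded by `[-d, a + b + c]`,
#' and `R` is monotone increasing in the three affinity terms and
#' monotone decreasing in the penalty.
#'
#' @param ind,compat,cov,contra the four term values, each in \[0, 1\].
#' @param w a [composite_weights()].
#' @return The exact linear combination.
#' @export
composite_score <- function(ind, compat, cov, contra, w = composite_weights()) {
  stopifnot(ind >= 0, ind <= 1, compat >= 0, compat <= 1,
            cov >= 0, cov <= 1, contra >= 0, contra <= 1)
  w$a * ind + w$b * compat + w$c * cov - w$d * contra
}

#' Rank all formulas by the composite score
#'
#' Scores every formula against every retained (syndrome, constitution)
#' candidate pair and keeps, per formula, the best pair (max-aggregation,
#' mirroring the matching-maximization principle: a formula is as good as
#' its best-supported match). Results are sorted by score descending,
#' ties broken by formula id ascending, and each row carries the full
#' term breakdown of its best pair plus the top-M evidence chunks
#' retrieved for the query.
#'
#' @param db a `formula_db`.
#' @param x canonical symptoms (or `normalized_symptoms`), non-empty.
#' @param candidates output of [select_candidates()] (non-NULL).
#' @param w a [composite_weights()].
#' @param index optional prebuilt `vector_index`; built on the fly when
#'   `NULL`.
#' @param m evidence chunks per recommendation.
#' @param partial_affinity passed to [constitution_compatibility()].
#' @param ind_method passed to [indication_overlap()].
#' @param aggregate `"max"` (default) or `"mean"` over candidate pairs.
#' @return Data frame: `formula_id`, `name`, `r_score`, `ind`, `compat`,
#'   `cov`, `contra`, `syndrome`, `constitution` (the best pair), and
#'   `evidence` (list column of chunk ids).
#' @export
rank_formulas <- function(db, x, candidates, w = composite_weights(),
                          index = NULL, m = 3,
                          partial_affinity = list(),
                          ind_method = "jaccard",
                          aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop_herbrec("rank_formulas", "no candidate (syndrome, constitution) pairs")
  terms <- if (inherits(x, "normalized_symptoms")) x$terms else as.character(x)
  if (is.null(index)) index <- build_vector_index(chunk_database(db))
  qtext <- query_text(db, terms, unique(candidates$syndrome),
                      unique(candidates$constitution)[1])
  evidence <- retrieve_top_m(qtext, index, m)

  ids <- sort_c(names(db$formulas))
  fl <- db$formulas[ids]
  uterms <- unique(terms)
  n_f <- length(fl)
  n_p <- nrow(candidates)
  cov <- vapply(fl, function(f) symptom_coverage(uterms, f), numeric(1))
  # term matrices, pairs in rows, formulas in columns
  ind_m <- matrix(0, n_p, n_f)
  compat_m <- matrix(0, n_p, n_f)
  contra_m <- matrix(0, n_p, n_f)
  for (i in seq_len(n_p)) {
    s <- candidates$syndrome[i]
    ct <- candidates$constitution[i]
    ind_m[i, ] <- vapply(fl, function(f)
      indication_overlap(s, f, method = ind_method), numeric(1))
    compat_m[i, ] <- vapply(fl, function(f)
      constitution_compatibility(ct, f, partial_affinity), numeric(1))
    contra_m[i, ] <- vapply(fl, function(f)
      contraindication_penalty(uterms, ct, f), numeric(1))
  }
  r_m <- w$a * ind_m + w$b * compat_m +
    w$c * matrix(cov, n_p, n_f, byrow = TRUE) - w$d * contra_m
  best <- apply(r_m, 2, which.max)
  r <- if (aggregate == "max") apply(r_m, 2, max) else colMeans(r_m)
  pick <- cbind(best, seq_len(n_f))
  out <- data.frame(
    formula_id = ids,
    name = vapply(fl, `[[`, "", "name"),
    r_score = r,
    ind = ind_m[pick], compat = compat_m[pick],
    cov = cov, contra = contra_m[pick],
    syndrome = candidates$syndrome[best],
    constitution = candidates$constitution[best],
    stringsAsFactors = FALSE
  )
  out <- out[order_c(-out$r_score, out$formula_id), , drop = FALSE]
  rownames(out) <- NULL
  out$evidence <- rep(list(evidence$chunk_id), nrow(out))
  attr(out, "evidence") <- evidence
  out
}
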