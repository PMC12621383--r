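#' Controlled symptom vocabulary
#'
#' Holds the curated mappings that turn raw symptom reports into canonical
#' clinical terms: a colloquial-to-canonical dictionary (e.g. the
#' colloquial \dQuote{长痘痘} maps to the canonical
#' \dQuote{易生疥疮或痤疮}), merge groups
#' collapsing variant canonical spellings onto one representative, a
#' free-form clinical category for each canonical term, and an exclusion
#' list of non-clinical surface forms that are filtered out.
#'
#' @param colloquial_to_canonical named character vector, surface form ->
#'   canonical term.
#' @param merge_groups named character vector, variant canonical term ->
#'   group representative; every representative must map to itself.
#' @param category_of named character vector, canonical term -> category
#'   label.
#' @param exclusion_list character vector of non-clinical surface forms,
#'   disjoint from the canon.
#' @param canonical character vector: the canonical term set (the canon).
#' @return An object of class `vocabulary_map`.
#' @export
vocabulary_map <- function(colloquial_to_canonical = character(0),
                           merge_groups = character(0),
                           category_of = character(0),
                           exclusion_list = character(0),
                           canonical = character(0)) {
  nv <- function(x) {
    # key-sorted so equal vocabularies compare and serialize identically
    out <- stats::setNames(nfc(unname(x)), nfc(names(x) %||% character(0)))
    out[sort_c(names(out))]
  }
  structure(
    list(
      colloquial_to_canonical = nv(colloquial_to_canonical),
      merge_groups = nv(merge_groups),
      category_of = nv(category_of),
      exclusion_list = sort_c(unique(nfc(exclusion_list))),
      canonical = sort_c(unique(nfc(canonical)))
    ),
    class = "vocabulary_map"
  )
}

#' Standardize one raw symptom term
#'
#' Applies the curated cleaning order: NFC-normalize and trim, map a
#' colloquial surface form to its canonical term, then collapse merge-group
#' variants onto the group representative. A term that is neither mappable
#' nor already canonical yields `NA_character_` (not-found); it is never
#' passed through, because downstream weight lookups require canonical
#' terms. The function is idempotent on its own outputs.
#'
#' @param raw a single raw surface form (non-empty after trimming).
#' @param vocab a [vocabulary_map()].
#' @return The canonical term, or `NA_character_` when unmapped.
#' @export
#' @examples
#' v <- vocabulary_map(
#'   colloquial_to_canonical = c("tummy ache" = "abdominal pain"),
#'   canonical = "abdominal pain"
#' )
#' standardize_term("tummy ache", v)
standardize_term <- function(raw, vocab) {
  stopifnot(inherits(vocab, "vocabulary_map"), length(raw) == 1L)
  term <- nfc(raw)
  if (is.na(term) || !nzchar(term))
    stop_herbrec("standardize_term", "empty term")
  mapped <- vocab$colloquial_to_canonical[term]
  if (!is.na(mapped)) term <- unname(mapped)
  rep <- vocab$merge_groups[term]
  if (!is.na(rep)) term <- unname(rep)
  if (term %in% vocab$canonical) term else NA_character_
}

#' Normalize a raw symptom list
#'
#' Runs the full cleaning pipeline over an ordered list of raw surface
#' forms: standardize each term, merge duplicates (keeping the first
#' occurrence, which preserves the user's stated priority order), and
#' filter out exclusion-listed and unmapped items. Every removal is
#' recorded with its reason (`excluded`, `unmapped`, or `duplicate`), so
#' `length(terms) + nrow(dropped)` always equals `length(raws)`.
#'
#' @param raws character vector of raw surface forms (may be empty).
#' @param vocab a [vocabulary_map()].
#' @param strict when `TRUE`, an unmapped term raises an error instead of
#'   being dropped.
#' @return A `normalized_symptoms` object: list with `terms` (canonical,
#'   duplicate-free, input order), `category` (parallel category labels)
#'   and `dropped` (data frame `surface`, `reason`).
#' @export
normalize_symptom_list <- function(raws, vocab, strict = FALSE) {
  stopifnot(inherits(vocab, "vocabulary_map"))
  raws <- nfc(raws)
  raws <- raws[nzchar(raws)]
  terms <- character(0)
  dropped_surface <- character(0)
  dropped_reason <- character(0)
  for (r in raws) {
    if (r %in% vocab$exclusion_list) {
      dropped_surface <- c(dropped_surface, r)
      dropped_reason <- c(dropped_reason, "excluded")
      next
    }
    term <- standardize_term(r, vocab)
    if (is.na(term)) {
      if (strict)
        stop_herbrec("normalize_symptom_list", "unmapped term: ", r)
      dropped_surface <- c(dropped_surface, r)
      dropped_reason <- c(dropped_reason, "unmapped")
    } else if (term %in% terms) {
      dropped_surface <- c(dropped_surface, r)
      dropped_reason <- c(dropped_reason, "duplicate")
    } else {
      terms <- c(terms, term)
    }
  }
  structure(
    list(
      terms = terms,
      category = unname(vocab$category_of[terms]),
      dropped = data.frame(surface = dropped_surface,
                           reason = dropped_reason,
                           stringsAsFactors = FALSE)
    ),
    class = "normalized_symptoms"
  )
}

#' @export
print.normalized_symptoms <- function(x, ...) {
  cat("<normalized_symptoms>", length(x$terms), "terms")
  if (nrow(x$dropped) > 0) cat(",", nrow(x$dropped), "dropped")
  cat("\n")
  if (length(x$terms) > 0) cat(" ", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Suggest canonical terms for an unmapped surface form
#'
#' Optional helper for interactive use: ranks canonical terms by edit
#' distance to the raw input. Suggestions are never applied silently by
#' the pipeline — the curated mappings are exact by design.
#'
#' @param raw a single surface form.
#' @param vocab a [vocabulary_map()].
#' @param n maximum number of suggestions.
#' @return Character vector of up to `n` canonical terms, nearest first.
#' @export
suggest_term <- function(raw, vocab, n = 3) {
  term <- nfc(raw)
  d <- utils::adist(term, vocab$canonical)[1, ]
  vocab$canonical[order(d, method = "radix")][seq_len(min(n, length(d)))]
}
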