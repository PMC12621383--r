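#' Practitioner syndrome-weight table
#'
#' The controlled vocabulary links each canonical symptom to one or more
#' syndrome patterns with a designated role: `primary` symptoms carry more
#' weight toward a syndrome than `secondary` ones. The numeric weights are
#' per-role and configurable, with the single constraint that the primary
#' weight is strictly greater than the secondary weight.
#'
#' @param entries data frame with columns `symptom` (canonical term),
#'   `syndrome` (syndrome id), `role` (`"primary"` or `"secondary"`).
#' @param role_weights named numeric vector with elements `primary` and
#'   `secondary`, `primary > secondary > 0`. Defaults to 2 and 1.
#' @return An object of class `syndrome_weight_table` with a precomputed
#'   per-symptom maximum weight `w_max`.
#' @export
syndrome_weight_table <- function(entries,
                                  role_weights = c(primary = 2, secondary = 1)) {
  stopifnot(is.data.frame(entries),
            all(c("symptom", "syndrome", "role") %in% names(entries)))
  entries$symptom <- nfc(entries$symptom)
  entries$syndrome <- nfc(entries$syndrome)
  entries$role <- as.character(entries$role)
  w <- unname(role_weights[entries$role])
  w_max <- if (nrow(entries) > 0) {
    tapply(w, entries$symptom, max)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(
    list(entries = entries, role_weights = role_weights,
         w_max = w_max),
    class = "syndrome_weight_table"
  )
}

# weight of each term toward syndrome S; unlisted (term, S) pairs weigh 0
weights_toward <- function(terms, syndrome, table) {
  ent <- table$entries
  sel <- ent$syndrome == syndrome & ent$symptom %in% terms
  w <- stats::setNames(rep(0, length(terms)), terms)
  if (any(sel)) {
    hit <- ent[sel, , drop = FALSE]
    w[hit$symptom] <- unname(table$role_weights[hit$role])
  }
  w
}

#' Length-normalized syndrome score
#'
#' Scores how strongly a normalized symptom set `X` points to syndrome
#' `S`:
#' \deqn{\mathrm{Score}(S) = \frac{\sum_{x_i \in X} w(x_i, S)}
#'   {\sum_{x_i \in X} w_{max}(x_i)} \in [0, 1]}
#' where `w(x, S)` is the practitioner-assigned weight of symptom `x`
#' toward `S` (0 when `x` is not listed for `S`) and `w_max(x)` is the
#' largest weight `x` can contribute toward any syndrome. Normalizing by
#' the attainable maximum rather than the list length avoids bias toward
#' longer symptom lists: a symptom that cannot contribute to `S` still
#' grows the denominator and so strictly lowers the score.
#'
#' @param x a `normalized_symptoms` object or a character vector of
#'   canonical terms; must be non-empty and duplicate-free (scoring is a
#'   set operation).
#' @param syndrome a syndrome id.
#' @param table a [syndrome_weight_table()].
#' @return A number in \[0, 1\]; exactly 1 iff every symptom attains its
#'   maximum weight on `syndrome`.
#' @export
syndrome_score <- function(x, syndrome, table) {
  terms <- if (inherits(x, "normalized_symptoms")) x$terms else as.character(x)
  terms <- unique(terms)
  if (length(terms) == 0L)
    stop_herbrec("syndrome_score", "empty symptom set has no score")
  wmax <- table$w_max[terms]
  if (any(is.na(wmax)))
    stop_herbrec("syndrome_score", "no weight-table entry (w_max undefined) for: ",
                 paste(terms[is.na(wmax)], collapse = ", "))
  sum(weights_toward(terms, syndrome, table)) / sum(wmax)
}

#' Selection configuration for candidate retention
#'
#' Thresholds and smoothing for the syndrome and syndrome-by-constitution
#' selection stages.
#'
#' @param tau retention threshold on the syndrome score, in \[0, 1\].
#'   Syndromes scoring at or below `tau` are dropped; when none survive
#'   the pipeline output is the NA sentinel.
#' @param top_k number of retained syndromes and of retained (syndrome,
#'   constitution) pairs.
#' @param epsilon smoothing constant added to the constitution
#'   probability before the multiplicative combination; keeps a strong
#'   syndrome signal alive when the questionnaire assigns a constitution
#'   probability of zero. Sensible range 1e-3 to 1e-2.
#' @param star_threshold retention threshold applied to the combined
#'   score; candidates must exceed it.
#' @return A `selection_config` list.
#' @export
selection_config <- function(tau = 0.3, top_k = 3, epsilon = 1e-3,
                             star_threshold = 0) {
  stopifnot(is_number(tau), tau >= 0, tau <= 1,
            is_count(top_k),
            is_number(epsilon), epsilon > 0,
            is_number(star_threshold), star_threshold >= 0)
  structure(list(tau = tau, top_k = top_k, epsilon = epsilon,
                 star_threshold = star_threshold),
            class = "selection_config")
}

#' Rank syndromes for a symptom set
#'
#' Scores every syndrome in the table against `X`, retains those scoring
#' strictly above the threshold `tau`, sorts by score descending (ties
#' broken by syndrome id ascending, byte order), and truncates to the top
#' `K`. When no syndrome qualifies — or `X` is empty — the result is the
#' NA sentinel, which propagates through the rest of the pipeline.
#'
#' @inheritParams syndrome_score
#' @param cfg a [selection_config()].
#' @return A data frame with columns `syndrome`, `score` (at most
#'   `cfg$top_k` rows), or `NULL` (the NA sentinel).
#' @export
rank_syndromes <- function(x, table, cfg = selection_config()) {
  terms <- if (inherits(x, "normalized_symptoms")) x$terms else as.character(x)
  if (length(terms) == 0L) return(NULL)
  syndromes <- sort_c(unique(table$entries$syndrome))
  scores <- vapply(syndromes, function(s) syndrome_score(terms, s, table),
                   numeric(1))
  keep <- scores > cfg$tau
  if (!any(keep)) return(NULL)
  out <- data.frame(syndrome = syndromes[keep], score = unname(scores[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order_c(-out$score, out$syndrome), , drop = FALSE]
  out <- utils::head(out, cfg$top_k)
  rownames(out) <- NULL
  out
}

# ---- questionnaire -------------------------------------------------------

#' Constitution questionnaire specification
#'
#' Per-constitution subscales of 5-point Likert items. Items are scored
#' 1–5; negatively-keyed items are reverse-coded (6 minus the response)
#' before summation. The raw subscale sum is mapped to a 0–100 transformed
#' score by `(raw - n) / (4 n) * 100` with `n` the item count — the
#' standard transform for this instrument family. Cutoffs drive only the
#' categorical label: a balanced classification requires the balanced
#' score at or above `balanced_min` while all eight biased scores stay
#' below `biased_max`.
#'
#' @param scales named list, one entry per constitution code, each
#'   `list(items = list(list(item_id, direction)))` with `direction`
#'   `"positive"` or `"negative"`.
#' @param cutoffs list with `balanced_min` (default 60) and `biased_max`
#'   (default 30), both on the transformed 0–100 scale.
#' @return A `questionnaire_spec` object.
#' @export
questionnaire_spec <- function(scales,
                               cutoffs = list(balanced_min = 60,
                                              biased_max = 30)) {
  stopifnot(is.list(scales), !is.null(names(scales)))
  structure(list(scales = scales, cutoffs = cutoffs),
            class = "questionnaire_spec")
}

#' Score a constitution questionnaire
#'
#' Computes the transformed 0–100 score of every constitution subscale
#' from a complete item response set.
#'
#' @param resp named numeric vector, item id -> response on the 1–5
#'   scale. Every item of every subscale must be answered.
#' @param spec a [questionnaire_spec()].
#' @return Named numeric vector of transformed scores in \[0, 100\], one
#'   per constitution, in [constitution_types()] order.
#' @export
score_questionnaire <- function(resp, spec) {
  stopifnot(inherits(spec, "questionnaire_spec"))
  out <- stats::setNames(numeric(0), character(0))
  for (ct in names(spec$scales)) {
    sc <- spec$scales[[ct]]
    ids <- vapply(sc$items, `[[`, "", "item_id")
    dirs <- vapply(sc$items, `[[`, "", "direction")
    miss <- ids[!(ids %in% names(resp))]
    if (length(miss) > 0)
      stop_herbrec("score_questionnaire", "missing item(s): ",
                   paste(miss, collapse = ", "))
    vals <- as.numeric(resp[ids])
    if (any(is.na(vals)) || any(vals < 1 | vals > 5) ||
          any(vals != floor(vals)))
      stop_herbrec("score_questionnaire",
                   "responses must be integers on the 1-5 scale (", ct, ")")
    vals[dirs == "negative"] <- 6 - vals[dirs == "negative"]
    n <- length(ids)
    out[ct] <- (sum(vals) - n) / (4 * n) * 100
  }
  present <- intersect(constitution_types(), names(out))
  out[c(present, setdiff(names(out), present))]
}

#' Constitution probability distribution
#'
#' Maps the transformed subscale scores to a probability distribution over
#' the nine constitutions by direct normalization (scores are already on a
#' common 0–100 scale, so their relative sizes are meaningful). An
#' all-zero score vector maps to the uniform distribution.
#'
#' @param scores named numeric vector of transformed scores in
#'   \[0, 100\], one per constitution.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
constitution_distribution <- function(scores) {
  stopifnot(!is.null(names(scores)),
            all(scores >= 0), all(scores <= 100))
  tot <- sum(scores)
  p <- if (tot == 0) rep(1 / length(scores), length(scores)) else scores / tot
  stats::setNames(as.numeric(p), names(scores))
}

#' Categorical constitution label
#'
#' Applies the instrument's decision rules to the transformed scores: the
#' balanced type is assigned only when its own score reaches
#' `balanced_min` and every biased score stays below `biased_max`
#' (mutual exclusivity); otherwise the highest-scoring biased type wins,
#' ties broken by code in byte order. The rules shape only this label —
#' the probability vector from [constitution_distribution()] stays a
#' smooth, total map.
#'
#' @inheritParams constitution_distribution
#' @param spec a [questionnaire_spec()] (source of the cutoffs).
#' @return A single constitution code.
#' @export
constitution_label <- function(scores, spec) {
  cuts <- spec$cutoffs
  biased <- scores[setdiff(names(scores), "balanced")]
  if ("balanced" %in% names(scores) &&
        scores[["balanced"]] >= cuts$balanced_min &&
        all(biased < cuts$biased_max)) {
    return("balanced")
  }
  nm <- names(biased)
  nm[order_c(-as.numeric(biased), nm)][1]
}

# ---- combination ---------------------------------------------------------

#' Smoothed multiplicative syndrome-constitution combination
#'
#' \deqn{\mathrm{Score}^*(S, C) = \mathrm{Score}(S)\,(\varepsilon + P(C \mid X))}
#' The small positive `epsilon` keeps the syndrome signal from being
#' silenced when the questionnaire assigns a constitution probability of
#' exactly zero.
#'
#' @param score syndrome score in \[0, 1\].
#' @param p constitution probability in \[0, 1\].
#' @param epsilon smoothing constant, > 0.
#' @return The exact product `score * (epsilon + p)`.
#' @export
combined_score <- function(score, p, epsilon = 1e-3) {
  stopifnot(is_number(score), score >= 0, score <= 1,
            is_number(p), p >= 0, p <= 1,
            is_number(epsilon), epsilon > 0)
  score * (epsilon + p)
}

#' Select (syndrome, constitution) candidate pairs
#'
#' Crosses every retained syndrome with every constitution, scores each
#' pair with [combined_score()], keeps pairs strictly above the combined
#' threshold, sorts descending (ties: syndrome id then constitution code,
#' ascending byte order), and truncates to the top `K`. The NA sentinel
#' propagates: no retained syndromes, or no qualifying pair, yields
#' `NULL`.
#'
#' @param syndromes output of [rank_syndromes()] (or `NULL`).
#' @param dist a constitution probability vector from
#'   [constitution_distribution()].
#' @param cfg a [selection_config()].
#' @return Data frame with columns `syndrome`, `constitution`,
#'   `syndrome_score`, `p`, `combined`, or `NULL` (NA sentinel).
#' @export
select_candidates <- function(syndromes, dist, cfg = selection_config()) {
  if (is.null(syndromes) || nrow(syndromes) == 0L) return(NULL)
  grid <- expand.grid(i = seq_len(nrow(syndromes)),
                      constitution = names(dist),
                      stringsAsFactors = FALSE)
  out <- data.frame(
    syndrome = syndromes$syndrome[grid$i],
    constitution = grid$constitution,
    syndrome_score = syndromes$score[grid$i],
    p = as.numeric(dist[grid$constitution]),
    stringsAsFactors = FALSE
  )
  out$combined <- vapply(seq_len(nrow(out)), function(i)
    combined_score(out$syndrome_score[i], out$p[i], cfg$epsilon), numeric(1))
  out <- out[out$combined > cfg$star_threshold, , drop = FALSE]
  if (nrow(out) == 0L) return(NULL)
  out <- out[order_c(-out$combined, out$syndrome, out$constitution), ,
             drop = FALSE]
  out <- utils::head(out, cfg$top_k)
  rownames(out) <- NULL
  out
}
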