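# Shared fixtures, built once per test run. Sizes are deliberately small:
# 20 generic formulas over 6 syndromes exercises every code path while
# keeping brute-force oracles instant.

.fixture_cache <- new.env(parent = emptyenv())

small_cfg <- function(seed = 1, n_formulas = 20, n_substances = 30,
                      n_symptoms = 40, n_syndromes = 6, ...) {
  fixture_config(seed = seed, n_formulas = n_formulas,
                 n_substances = n_substances, n_symptoms = n_symptoms,
                 n_syndromes = n_syndromes, ...)
}

small_db <- function(seed = 1, ...) {
  key <- paste0("db-", seed, "-", paste(c(...), collapse = "-"))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_fixture_database(small_cfg(seed, ...))
  .fixture_cache[[key]]
}

full_db <- function(seed = 1) {
  key <- paste0("full-", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_fixture_database(fixture_config(seed = seed))
  .fixture_cache[[key]]
}

# a tiny hand-built weight table for exact-value scoring tests:
# primary = 2, secondary = 1
hand_table <- function() {
  syndrome_weight_table(data.frame(
    symptom = c("x1", "x2", "x1", "x3", "x2"),
    syndrome = c("S", "S", "T", "T", "U"),
    role = c("primary", "secondary", "primary", "primary", "primary"),
    stringsAsFactors = FALSE
  ))
}

fig4_symptoms <- function() {
  c("visible dark circles", "more afraid of cold than others",
    "frequent bloating", "heavy body", "difficult in movement", "dry skin")
}

shared_cluster_symptoms <- function() {
  c("dyspepsia", "dampness stagnancy due to spleen deficiency",
    "abdominal bloating", "abdominal obesity", "scanty dark urine",
    "obesity")
}

# independent brute-force evaluation of the length-normalized syndrome
# score, straight from its definition
oracle_syndrome_score <- function(terms, syndrome, entries, role_w) {
  num <- 0
  den <- 0
  for (t in unique(terms)) {
    here <- entries[entries$symptom == t, , drop = FALSE]
    w_all <- role_w[here$role]
    den <- den + max(w_all)
    w_s <- here[here$syndrome == syndrome, , drop = FALSE]
    if (nrow(w_s) > 0) num <- num + role_w[[w_s$role[1]]]
  }
  num / den
}

# independent brute-force composite ranking: enumerate every formula x
# candidate pair with raw set arithmetic
oracle_rank <- function(db, terms, candidates, w, affinity = list()) {
  terms <- unique(terms)
  ids <- sort(names(db$formulas), method = "radix")
  score_of <- vapply(ids, function(id) {
    f <- db$formulas[[id]]
    best <- -Inf
    for (i in seq_len(nrow(candidates))) {
      s <- candidates$syndrome[i]
      ct <- candidates$constitution[i]
      ind <- length(intersect(s, f$indicated_syndromes)) /
        length(union(s, f$indicated_syndromes))
      compat <- if (ct %in% f$suitable_constitutions) 1 else {
        aff <- affinity[[ct]]
        if (!is.null(aff) && length(intersect(aff, f$suitable_constitutions)))
          0.5 else 0
      }
      cov <- length(intersect(terms, f$effects)) / length(terms)
      sev <- f$contraindications
      hit <- names(sev) %in% c(terms, ct)
      contra <- if (any(hit)) max(sev[hit]) else 0
      r <- w$a * ind + w$b * compat + w$c * cov - w$d * contra
      if (r > best) best <- r
    }
    best
  }, numeric(1))
  ids[order(-score_of, ids, method = "radix")]
}
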