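#' Parse a structured completion
#'
#' Inverse of [build_completion()] for canonical completions.
#'
#' @param completion a canonical completion string or `"NA"`.
#' @return `NULL` for the NA sentinel, else a list with `syndrome`,
#'   `constitution`, `topn`.
#' @export
parse_completion <- function(completion) {
  if (identical(completion, NA_SENTINEL)) return(NULL)
  fields <- strsplit(completion, ";", fixed = TRUE)[[1]]
  kv <- lapply(fields, function(f) strsplit(f, "=", fixed = TRUE)[[1]])
  keys <- vapply(kv, `[`, "", 1)
  if (!identical(keys, c("SYNDROME", "CONSTITUTION", "TOPN")))
    stop_herbrec("parse_completion", "not a canonical completion: ", completion)
  list(syndrome = kv[[1]][2], constitution = kv[[2]][2],
       topn = strsplit(kv[[3]][2], ",", fixed = TRUE)[[1]])
}

#' Precision of ranked recommendations
#'
#' Runs the pipeline over labeled cases and scores it with
#' `Precision = TP / (TP + FP)`: a case counts as a true positive when
#' the gold formula appears within the first `match_topk` recommended ids
#' (default 1: exact rank-1 match), as a false positive otherwise. Cases
#' whose output is the `"NA"` sentinel are neither TP nor FP — they are
#' excluded from the ratio and reported as a separate NA count — so
#' `tp + fp` always equals the number of scored cases. When every output
#' is NA the precision is undefined and reported as `NA_real_`.
#'
#' @param cases list of labeled cases (see [generate_eval_set()]).
#' @param db a `formula_db`.
#' @param config a [herbrec_config()].
#' @param match_topk rank window for a correct match.
#' @param reverse evaluate with each case's symptom list exactly
#'   reversed.
#' @param index optional prebuilt `vector_index`.
#' @return A `precision_report`: `tp`, `fp`, `na`, `precision`,
#'   `per_case` (data frame), `mode`.
#' @export
precision <- function(cases, db, config = herbrec_config(), match_topk = 1,
                      reverse = FALSE, index = NULL) {
  stopifnot(length(cases) >= 1, is_count(match_topk))
  if (is.null(index))
    index <- build_vector_index(chunk_database(db), embedder = config$embedder)
  rows <- lapply(cases, function(cs) {
    syms <- if (reverse) rev(cs$symptoms) else cs$symptoms
    rep <- recommend(syms, cs$questionnaire, db, config, index = index)
    parsed <- parse_completion(rep$completion)
    if (is.null(parsed)) {
      data.frame(case_id = cs$case_id, gold = cs$gold, top1 = NA_character_,
                 completion = rep$completion, outcome = "na",
                 stringsAsFactors = FALSE)
    } else {
      hit <- cs$gold %in% utils::head(parsed$topn, match_topk)
      data.frame(case_id = cs$case_id, gold = cs$gold,
                 top1 = parsed$topn[1], completion = rep$completion,
                 outcome = if (hit) "tp" else "fp",
                 stringsAsFactors = FALSE)
    }
  })
  per_case <- do.call(rbind, rows)
  tp <- sum(per_case$outcome == "tp")
  fp <- sum(per_case$outcome == "fp")
  na <- sum(per_case$outcome == "na")
  structure(
    list(tp = tp, fp = fp, na = na,
         precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         per_case = per_case,
         mode = paste0(config$mode, if (reverse) "/reverse" else "/forward")),
    class = "precision_report"
  )
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report>", x$mode, "\n")
  cat(sprintf("  TP %d  FP %d  NA %d  precision %s\n", x$tp, x$fp, x$na,
              if (is.na(x$precision)) "undefined"
              else sprintf("%.4f", x$precision)))
  invisible(x)
}

#' Forward/reverse order-robustness protocol
#'
#' Evaluates every case twice — symptoms in their stated forward order
#' and exactly reversed — and reports both precision reports plus the
#' per-case agreement table (whether the two completions are identical).
#' With the default order-free bag-of-terms embedder the two runs agree
#' on every case by construction; an order-sensitive plug-in embedder can
#' make them diverge, which the agreement table flags.
#'
#' @inheritParams precision
#' @return List with `forward`, `reverse` (precision reports),
#'   `agreement` (fraction of cases with identical completions), and
#'   `table` (per-case comparison).
#' @export
order_robustness <- function(cases, db, config = herbrec_config(),
                             match_topk = 1, index = NULL) {
  if (is.null(index))
    index <- build_vector_index(chunk_database(db), embedder = config$embedder)
  fwd <- precision(cases, db, config, match_topk, reverse = FALSE,
                   index = index)
  rev <- precision(cases, db, config, match_topk, reverse = TRUE,
                   index = index)
  tab <- data.frame(
    case_id = fwd$per_case$case_id,
    forward = fwd$per_case$completion,
    reverse = rev$per_case$completion,
    agree = fwd$per_case$completion == rev$per_case$completion,
    stringsAsFactors = FALSE
  )
  list(forward = fwd, reverse = rev,
       agreement = mean(tab$agree), table = tab)
}

#' Ablation harness over pipeline modes
#'
#' Runs the evaluation in the three pipeline modes — `retrieval` (nearest
#' chunks by cosine, no composite score), `ranking` (composite score, no
#' retrieval evidence), and `full` — and tabulates one precision report
#' per mode.
#'
#' @inheritParams precision
#' @return List with `reports` (named list of precision reports) and
#'   `summary` (data frame `mode`, `tp`, `fp`, `na`, `precision`).
#' @export
ablation_harness <- function(cases, db, config = herbrec_config(),
                             match_topk = 1) {
  index <- build_vector_index(chunk_database(db), embedder = config$embedder)
  modes <- c("retrieval", "ranking", "full")
  reports <- lapply(modes, function(md) {
    cf <- config
    cf$mode <- md
    precision(cases, db, cf, match_topk, index = index)
  })
  names(reports) <- modes
  summary <- data.frame(
    mode = modes,
    tp = vapply(reports, `[[`, numeric(1), "tp"),
    fp = vapply(reports, `[[`, numeric(1), "fp"),
    na = vapply(reports, `[[`, numeric(1), "na"),
    precision = vapply(reports, `[[`, numeric(1), "precision"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(reports = reports, summary = summary)
}
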