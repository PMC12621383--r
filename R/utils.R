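#' @keywords internal
"_PACKAGE"

#' The nine constitution types
#'
#' Canonical codes for the nine-type constitution classification used
#' throughout the package (balanced plus eight biased types). Every
#' constitution label stored in a knowledge base, emitted by the
#' questionnaire scorer, or carried in a recommendation must be one of
#' these codes.
#'
#' @return Character vector of the nine constitution codes, in their
#'   conventional presentation order.
#' @export
#' @examples
#' constitution_types()
constitution_types <- function() {
  c(
    "balanced", "qi-deficiency", "yang-deficiency", "yin-deficiency",
    "phlegm-dampness", "damp-heat", "blood-stasis", "qi-stagnation",
    "inherited-special"
  )
}

# NFC-normalize and trim a character vector; all ingested text goes
# through this so comparisons are exact post-normalization.
nfc <- function(x) {
  if (length(x) == 0L) return(character(0))
  stringi::stri_trans_nfc(trimws(as.character(x)))
}

# Locale-independent (byte-order) sort / order, so tie-breaks and
# canonical serialization never depend on the session locale.
sort_c <- function(x) {
  if (length(x) == 0L) return(x)
  x[order_c(x)]
}

order_c <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_herbrec <- function(stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  stop(errorCondition(msg, class = c("herbrec_error", "error"),
                      stage = stage))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# ---- seeded RNG streams --------------------------------------------------
# One independent stream per generated artifact, so regenerating one
# artifact never perturbs another. A stream is an environment holding its
# own .Random.seed; draws swap it in and out of the global state.

rng_stream <- function(seed, label = "") {
  chars <- utf8ToInt(label)
  h <- if (length(chars)) sum(chars * ((seq_along(chars) %% 97) + 1)) else 0
  s <- as.integer((as.numeric(seed) %% 65011 * 33029 + h) %% 2147483629)
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(s)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  expr
}

rng_unif <- function(rng, n = 1L) with_rng(rng, stats::runif(n))

# uniform integer in 1..max
rng_int <- function(rng, max) with_rng(rng, sample.int(max, 1L))

rng_sample <- function(rng, x, k) {
  with_rng(rng, x[sample.int(length(x), k)])
}
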