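test_that("syndrome score matches direct evaluation of the weighted ratio", {
  tab <- hand_table()
  # x1 primary (2), x2 secondary (1), x3 absent (0) for S; each w_max = 2
  expect_equal(syndrome_score(c("x1", "x2", "x3"), "S", tab), 0.5)
  # every term primary for its syndrome -> exactly 1
  expect_equal(syndrome_score(c("x1", "x3"), "T", tab), 1.0)
  # order-free and deduplicating
  expect_equal(syndrome_score(c("x3", "x2", "x1"), "S", tab), 0.5)
  expect_equal(syndrome_score(c("x1", "x1", "x2", "x3"), "S", tab), 0.5)
  expect_error(syndrome_score(character(0), "S", tab), "empty")
  expect_error(syndrome_score(c("x1", "zz"), "S", tab), "zz")
})

test_that("syndrome score agrees with a brute-force oracle on exhaustive tiny tables", {
  # every weight assignment in {primary, secondary, none} for 2 symptoms
  # x 2 syndromes, enumerated exhaustively
  roles <- c("primary", "secondary", "none")
  grid <- expand.grid(a11 = roles, a12 = roles, a21 = roles, a22 = roles,
                      stringsAsFactors = FALSE)
  rw <- c(primary = 2, secondary = 1)
  for (g in seq_len(nrow(grid))) {
    asg <- unlist(grid[g, ])
    ent <- data.frame(
      symptom = c("x1", "x1", "x2", "x2"),
      syndrome = c("S1", "S2", "S1", "S2"),
      role = asg, stringsAsFactors = FALSE)
    ent <- ent[ent$role != "none", , drop = FALSE]
    # both symptoms need a defined maximum weight
    if (!all(c("x1", "x2") %in% ent$symptom)) next
    tab <- syndrome_weight_table(ent, rw)
    for (s in c("S1", "S2")) {
      expect_equal(syndrome_score(c("x1", "x2"), s, tab),
                   oracle_syndrome_score(c("x1", "x2"), s, ent, rw))
    }
  }
})

test_that("adding a non-contributing symptom strictly lowers the score", {
  tab <- hand_table()
  base <- syndrome_score(c("x1", "x2"), "S", tab)
  grown <- syndrome_score(c("x1", "x2", "x3"), "S", tab)
  expect_lt(grown, base)
})

test_that("syndrome ranking retains above-threshold scores, sorted and truncated", {
  tab <- hand_table()
  cfg <- selection_config(tau = 0.3, top_k = 3)
  r <- rank_syndromes(c("x1", "x2"), tab, cfg)
  # S: (2+1)/4 = 0.75; T and U: 2/4 = 0.5, tie broken by id
  expect_equal(r$syndrome, c("S", "T", "U"))
  expect_equal(r$score, c(0.75, 0.5, 0.5))
  # all at or below threshold -> NA sentinel
  expect_null(rank_syndromes(c("x1", "x2"), tab,
                             selection_config(tau = 0.9)))
  expect_null(rank_syndromes(character(0), tab, cfg))
  # top_k truncation
  expect_equal(nrow(rank_syndromes(c("x1", "x2"), tab,
                                   selection_config(tau = 0.1, top_k = 1))), 1)
})

test_that("syndrome ranking agrees with exhaustive enumeration on random tables", {
  set.seed(101)
  rw <- c(primary = 2, secondary = 1)
  for (rep in 1:30) {
    n_sym <- sample(3:8, 1)
    n_syn <- sample(2:6, 1)
    syms <- paste0("m", seq_len(n_sym))
    syns <- paste0("p", seq_len(n_syn))
    ent <- expand.grid(symptom = syms, syndrome = syns,
                       stringsAsFactors = FALSE)
    ent$role <- sample(c("primary", "secondary", "none"), nrow(ent),
                       replace = TRUE)
    ent <- ent[ent$role != "none", , drop = FALSE]
    covered <- unique(ent$symptom)
    if (length(covered) < 2) next
    tab <- syndrome_weight_table(ent, rw)
    x <- sample(covered, min(3, length(covered)))
    tau <- runif(1, 0, 0.6)
    k <- sample(1:4, 1)
    got <- rank_syndromes(x, tab, selection_config(tau = tau, top_k = k))
    want <- vapply(sort(syns, method = "radix"), function(s)
      oracle_syndrome_score(x, s, ent, rw), numeric(1))
    want <- want[want > tau]
    if (length(want) == 0) {
      expect_null(got)
    } else {
      ord <- order(-want, names(want), method = "radix")
      keep <- head(ord, k)
      expect_equal(got$syndrome, names(want)[keep])
      expect_equal(got$score, unname(want[keep]))
    }
  }
})

test_that("questionnaire transform maps raw subscale sums onto 0-100", {
  db <- small_db()
  spec <- db$questionnaire
  # all items at the scale minimum after reverse-coding -> 0
  lo <- make_questionnaire_response(spec, "qi-deficiency", intensity = 1)
  sc <- score_questionnaire(lo, spec)
  expect_equal(unname(sc["qi-deficiency"]), 100)
  expect_true(all(sc[setdiff(names(sc), "qi-deficiency")] == 0))
  # a 4-item subscale answered 3,3,3,3 -> (12 - 4) / 16 * 100 = 50
  mid <- lo
  mid[grepl("^q-damp-heat-", names(mid))] <- 3
  sc2 <- score_questionnaire(mid, spec)
  expect_equal(unname(sc2["damp-heat"]), 50)
  # missing item and off-scale responses are errors naming the problem
  expect_error(score_questionnaire(lo[-1], spec), "missing item")
  bad <- lo
  bad[1] <- 7
  expect_error(score_questionnaire(bad, spec), "1-5 scale")
})

test_that("constitution distribution normalizes scores into probabilities", {
  nine <- constitution_types()
  one_hot <- stats::setNames(c(80, rep(0, 8)), nine)
  expect_equal(unname(constitution_distribution(one_hot)[1]), 1.0)
  uniform <- stats::setNames(rep(35, 9), nine)
  expect_equal(unname(constitution_distribution(uniform)),
               rep(1 / 9, 9))
  mixed <- stats::setNames(c(50, 25, 25, rep(0, 6)), nine)
  expect_equal(unname(constitution_distribution(mixed))[1:3],
               c(0.5, 0.25, 0.25))
  # all-zero falls back to uniform; always sums to 1
  zero <- stats::setNames(rep(0, 9), nine)
  expect_equal(sum(constitution_distribution(zero)), 1, tolerance = 1e-9)
  expect_equal(unname(constitution_distribution(zero)), rep(1 / 9, 9))
})

test_that("the categorical label applies the balanced mutual-exclusivity rule", {
  db <- small_db()
  nine <- constitution_types()
  calm <- stats::setNames(c(75, rep(10, 8)), nine)
  expect_equal(constitution_label(calm, db$questionnaire), "balanced")
  # a biased score at the cutoff vetoes the balanced label
  biased <- calm
  biased["yang-deficiency"] <- 40
  expect_equal(constitution_label(biased, db$questionnaire),
               "yang-deficiency")
})

test_that("the smoothed multiplicative combination is the exact product", {
  expect_equal(combined_score(0, 0.7, 1e-3), 0)
  expect_equal(combined_score(1, 1, 1e-3), 1.001)
  expect_equal(combined_score(0.5, 0.2, 1e-3), 0.1005)
  expect_error(combined_score(0.5, 0.2, 0), "epsilon")
})

test_that("candidate pairs match exhaustive enumeration of the 18-pair grid", {
  tab <- hand_table()
  cfg <- selection_config(tau = 0.2, top_k = 5, epsilon = 1e-3)
  syn <- rank_syndromes(c("x1", "x2"), tab, cfg)   # S 0.75, T 0.5, U 0.25
  nine <- constitution_types()
  dist <- constitution_distribution(
    stats::setNames(c(0, 40, 20, 0, 0, 20, 0, 0, 0), nine))
  got <- select_candidates(syn, dist, cfg)
  # independent exhaustive enumeration
  grid <- expand.grid(i = seq_len(nrow(syn)), ct = nine,
                      stringsAsFactors = FALSE)
  comb <- syn$score[grid$i] * (cfg$epsilon + as.numeric(dist[grid$ct]))
  ord <- order(-comb, syn$syndrome[grid$i], grid$ct, method = "radix")
  keep <- head(ord, cfg$top_k)
  expect_equal(got$syndrome, syn$syndrome[grid$i][keep])
  expect_equal(got$constitution, grid$ct[keep])
  expect_equal(got$combined, comb[keep])
  # empty syndrome input propagates the NA sentinel
  expect_null(select_candidates(NULL, dist, cfg))
})

test_that("raising a pair's constitution probability never lowers its rank", {
  tab <- hand_table()
  cfg <- selection_config(tau = 0.2, top_k = 27)
  syn <- rank_syndromes(c("x1", "x2"), tab, cfg)
  nine <- constitution_types()
  base_scores <- stats::setNames(c(10, 20, 30, 5, 5, 10, 10, 5, 5), nine)
  rank_of <- function(scores) {
    cand <- select_candidates(syn, constitution_distribution(scores), cfg)
    which(cand$syndrome == "S" & cand$constitution == "yang-deficiency")
  }
  before <- rank_of(base_scores)
  bumped <- base_scores
  bumped["yang-deficiency"] <- 80
  expect_lte(rank_of(bumped), before)
})
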