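test_that("exact mapping needs the identical concept; flexible reaches sub-terms", {
  h <- hierarchy(vasculitis_chain_df())

  s_abdo <- signal_set_fixture("C_ABDO")
  kb_abdo <- kb_fixture("C_ABDO", codes = "M_ABDO", names = "Abdominal discomfort")
  m <- match_signals(s_abdo, kb_abdo, h, "EXACT")
  expect_equal(m$matched, "C_ABDO")

  # a specific vasculitis is missed exactly but found through the hierarchy
  s_skin <- signal_set_fixture("C_SKINVASC")
  kb_vasc <- kb_fixture("C_VASC", codes = "V1", names = "Vasculitides")
  m_exact <- match_signals(s_skin, kb_vasc, h, "EXACT")
  m_flex <- match_signals(s_skin, kb_vasc, h, "FLEXIBLE")
  expect_length(m_exact$matched, 0)
  expect_equal(m_flex$matched, "C_SKINVASC")

  m_empty <- match_signals(signal_set_fixture(character(0)), kb_vasc, h, "EXACT")
  expect_length(m_empty$matched, 0)
})

test_that("metrics follow the matched/discovered/confirmed arithmetic", {
  confirmed <- c("D1", "D2", paste0("K", 3:8))  # 8 confirmed, 2 discovered
  m <- structure(list(strategy = "EXACT",
                      discovered = paste0("D", 1:5),
                      confirmed = confirmed,
                      confirmed_exact = confirmed,
                      matched = c("D1", "D2")),
                 class = "match_result")
  r <- compute_metrics(m)
  expect_equal(r$precision, 0.4)
  expect_equal(r$recall, 0.25)
  expect_equal(r$f1, 4 / 13)

  all_match <- structure(list(strategy = "EXACT", discovered = c("A", "B"),
                              confirmed = c("A", "B"),
                              confirmed_exact = c("A", "B"),
                              matched = c("A", "B")),
                         class = "match_result")
  expect_equal(unlist(compute_metrics(all_match)[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))

  none <- structure(list(strategy = "EXACT", discovered = paste0("D", 1:3),
                         confirmed = paste0("K", 1:4),
                         confirmed_exact = paste0("K", 1:4),
                         matched = character(0)),
                    class = "match_result")
  expect_equal(unlist(compute_metrics(none)[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("f1 equals the harmonic mean whenever precision + recall > 0", {
  set.seed(21)
  for (rep in 1:50) {
    universe <- sprintf("C%03d", 1:40)
    discovered <- sample(universe, sample(1:20, 1))
    confirmed <- sample(universe, sample(1:20, 1))
    m <- structure(list(strategy = "EXACT", discovered = discovered,
                        confirmed = confirmed, confirmed_exact = confirmed,
                        matched = intersect(discovered, confirmed)),
                   class = "match_result")
    r <- compute_metrics(m)
    if (r$precision + r$recall > 0) {
      expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
    } else {
      expect_equal(r$f1, 0)
    }
  }
})

test_that("combining sources takes the union and keeps both scores", {
  f <- signal_set_fixture(c("X", "Y"), "FAERS", score = c(3, 2))
  e <- signal_set_fixture(c("Y", "Z"), "EMR", score = c(5, 4))
  comb <- combine_sources(f, e)
  expect_setequal(comb$entries$outcome_cui, c("X", "Y", "Z"))
  y <- comb$entries[comb$entries$outcome_cui == "Y", ]
  expect_true(y$in_faers && y$in_emr)
  expect_equal(y$ror, 2)
  expect_equal(y$or, 5)
  expect_equal(y$score, 5)  # case-crossover score preferred for ranking

  disjoint <- combine_sources(signal_set_fixture(c("A", "B", "C"), "FAERS"),
                              signal_set_fixture(c("D", "E", "F", "G"), "EMR"))
  expect_equal(nrow(disjoint$entries), 7)

  one_empty <- combine_sources(signal_set_fixture(character(0), "FAERS"),
                               signal_set_fixture(c("D", "E"), "EMR"))
  expect_setequal(one_empty$entries$outcome_cui, c("D", "E"))

  mismatched <- signal_set_fixture(c("X"), "EMR", drug = "OTHERDRUG")
  expect_error(combine_sources(f, mismatched), "different")
})

test_that("venn regions enumerate correctly and conserve set sizes", {
  v <- venn_partition(c("1", "2"), c("2", "3"), c("3", "4"))
  expect_equal(v[["faers_only"]], 1)
  expect_equal(v[["faers_emr"]], 1)
  expect_equal(v[["emr_kb"]], 1)
  expect_equal(v[["kb_only"]], 1)
  expect_equal(v[["faers_kb"]], 0)
  expect_equal(v[["all"]], 0)

  same <- venn_partition(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(same[["all"]], 2)
  expect_equal(sum(same), 2)

  disj <- venn_partition("a", "b", "c")
  expect_equal(unname(disj[c("faers_only", "emr_only", "kb_only")]), c(1, 1, 1))
  expect_equal(sum(disj), 3)

  set.seed(8)
  for (rep in 1:50) {
    u <- sprintf("C%03d", 1:30)
    f <- sample(u, sample(0:20, 1))
    e <- sample(u, sample(0:20, 1))
    k <- sample(u, sample(0:20, 1))
    v <- venn_partition(f, e, k)
    expect_equal(unname(v[["faers_only"]] + v[["faers_emr"]] +
                          v[["faers_kb"]] + v[["all"]]), length(f))
    expect_equal(unname(v[["emr_only"]] + v[["faers_emr"]] +
                          v[["emr_kb"]] + v[["all"]]), length(e))
    expect_equal(unname(v[["kb_only"]] + v[["faers_kb"]] +
                          v[["emr_kb"]] + v[["all"]]), length(k))
  }
})

test_that("novel candidates exclude the expanded KB and rank by score then p", {
  f <- signal_set_fixture(c("N1", "N2", "K1"), "FAERS", score = c(8.02, 6.02, 3))
  e <- signal_set_fixture(character(0), "EMR")
  comb <- combine_sources(f, e)
  out <- novel_candidates(comb, kb_cuis_flexible = "K1")
  expect_equal(out$outcome_cui, c("N1", "N2"))
  expect_equal(out$score, c(8.02, 6.02))

  none <- novel_candidates(comb, kb_cuis_flexible = c("N1", "N2", "K1"))
  expect_equal(nrow(none), 0)

  # OR tie broken by the smaller p-value
  e2 <- signal_set_fixture(c("T1", "T2"), "EMR", score = c(4, 4),
                           p = c(0.03, 0.001))
  comb2 <- combine_sources(signal_set_fixture(character(0), "FAERS"), e2)
  out2 <- novel_candidates(comb2, kb_cuis_flexible = character(0))
  expect_equal(out2$outcome_cui, c("T2", "T1"))

  expect_equal(nrow(novel_candidates(comb2, character(0), top_k = 1)), 1)
})

test_that("flexible matching dominates exact and union recall dominates both", {
  set.seed(31)
  for (rep in 1:100) {
    df <- random_dag_df(c(1, 3, 7, 14, 25))
    h <- hierarchy(df)
    cuis <- unique(df$cui)
    f <- signal_set_fixture(sample(cuis, sample(1:15, 1)), "FAERS")
    e <- signal_set_fixture(sample(cuis, sample(1:15, 1)), "EMR")
    picked <- unique(df[sample(nrow(df), sample(2:8, 1)),
                        c("cui", "meddra_code")])
    kb <- kb_fixture(picked$cui, codes = picked$meddra_code)

    for (s in list(f, e)) {
      m_ex <- match_signals(s, kb, h, "EXACT")
      m_fl <- match_signals(s, kb, h, "FLEXIBLE")
      expect_true(all(m_ex$matched %in% m_fl$matched))
      expect_gte(compute_metrics(m_fl)$recall, compute_metrics(m_ex)$recall)
    }

    comb <- combine_sources(f, e)
    for (strat in c("EXACT", "FLEXIBLE")) {
      r_f <- compute_metrics(match_signals(f, kb, h, strat))$recall
      r_e <- compute_metrics(match_signals(e, kb, h, strat))$recall
      r_c <- compute_metrics(match_signals(comb, kb, h, strat))$recall
      expect_gte(r_c, max(r_f, r_e))
    }
  }
})
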