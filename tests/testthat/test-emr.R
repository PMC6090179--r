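test_that("the semantic-type filter touches only concept mentions", {
  ev <- rbind(
    event_row("P1", 10, "CONCEPT_MENTION", "C1", "T184"),
    event_row("P1", 11, "CONCEPT_MENTION", "C2", "T121"),
    event_row("P1", 12, "DRUG_EXPOSURE", "D", "")
  )
  out <- filter_concepts_semantic(ev)
  expect_equal(out$code, c("C1", "D"))
})

test_that("cohort extraction requires diagnosis strictly before first exposure", {
  ev <- rbind(
    # qualifies: dx day 0, exposures 100 and 400
    event_row("P1", 0, "DIAGNOSIS", "C_IND"),
    event_row("P1", 100, "DRUG_EXPOSURE", "D"),
    event_row("P1", 400, "DRUG_EXPOSURE", "D"),
    # exposed before diagnosis: no control window
    event_row("P2", 80, "DIAGNOSIS", "C_IND"),
    event_row("P2", 50, "DRUG_EXPOSURE", "D"),
    # diagnosed, never exposed
    event_row("P3", 0, "DIAGNOSIS", "C_IND")
  )
  cohort <- extract_cohort(ev, "D", "C_IND")
  expect_equal(cohort$patient_id, "P1")
  expect_equal(cohort$t_dx, 0)
  expect_equal(cohort$t_first, 100)
  expect_equal(cohort$t_last, 400)

  expect_error(extract_cohort(ev[4:6, ], "D", "C_IND"), "empty cohort")
})

test_that("windows follow the control [t_dx, t_first) / case [t_first, t_last] convention", {
  ev <- rbind(
    event_row("P1", 0, "DIAGNOSIS", "C_IND"),
    event_row("P1", c(100, 250, 400), "DRUG_EXPOSURE", "D"),
    event_row("P2", 0, "DIAGNOSIS", "C_IND"),
    event_row("P2", 100, "DRUG_EXPOSURE", "D")  # single exposure
  )
  w <- build_windows(ev, "D", "C_IND")
  expect_equal(w$t_first, c(100, 100))
  expect_equal(w$t_last, c(400, 100))  # one-day case window for P2

  # a mention on the first-exposure day is a case event, not a control event
  cohort <- extract_cohort(ev, "D", "C_IND")
  boundary <- rbind(ev, event_row("P1", 100, "CONCEPT_MENTION", "C_OUT", "T184"))
  t <- count_outcome(cohort, "C_OUT", boundary)
  expect_equal(c(t$a, t$c), c(1, 0))

  # exposure_tail_days stretches only the case window
  w_tail <- build_windows(ev, "D", "C_IND", exposure_tail_days = 30)
  expect_equal(w_tail$t_last, c(430, 130))
  expect_equal(w_tail$t_first, w$t_first)
})

test_that("count_outcome counts patients once per window and conserves the cohort", {
  ev <- cohort_fixture(10, n_case = 3, n_control = 1)
  cohort <- extract_cohort(ev, "D", "C_IND")
  t <- count_outcome(cohort, "C_OUT", ev)
  expect_equal(c(t$a, t$b, t$c, t$d), c(3, 7, 1, 9))
  expect_equal(t$context, "CASE_CROSSOVER")

  t0 <- count_outcome(cohort, "C_NEVER", ev)
  expect_equal(c(t0$a, t0$b, t0$c, t0$d), c(0, 10, 0, 10))

  # duplicate mentions in one window still count the patient once ...
  ev_dup <- rbind(ev, event_row("P001", c(210, 220), "CONCEPT_MENTION",
                                "C_OUT", "T184"))
  t_dup <- count_outcome(cohort, "C_OUT", ev_dup)
  expect_equal(c(t_dup$a, t_dup$c), c(3, 1))
  # ... and a patient mentioned in both windows contributes to a and to c
  ev2 <- rbind(ev, event_row("P005", c(210, 60), "CONCEPT_MENTION",
                             "C_OUT", "T184"))
  t2 <- count_outcome(cohort, "C_OUT", ev2)
  expect_equal(c(t2$a, t2$c), c(4, 2))
  expect_equal(t2$a + t2$b, t2$c + t2$d)
})

test_that("every outcome table conserves a+b = c+d = cohort size", {
  scen <- gen_scenario(synth_config(seed = 33, n_patients = 300L))
  s <- detect_signals_emr(scen$events, scen$cfg$drug,
                          scen$terms$indication_cui)
  n <- unique(s$entries$a + s$entries$b)
  expect_length(n, 1)
  expect_equal(s$entries$a + s$entries$b, s$entries$c + s$entries$d)
})

test_that("shifting all dates by a constant changes nothing", {
  scen <- gen_scenario(synth_config(seed = 34, n_patients = 200L))
  s1 <- detect_signals_emr(scen$events, scen$cfg$drug,
                           scen$terms$indication_cui)
  shifted <- scen$events
  shifted$date <- shifted$date + 5000L
  s2 <- detect_signals_emr(shifted, scen$cfg$drug, scen$terms$indication_cui)
  expect_equal(s1$entries, s2$entries)
})

test_that("dropping a mention-free patient shifts only b and d", {
  ev <- cohort_fixture(10, n_case = 3, n_control = 1)
  cohort <- extract_cohort(ev, "D", "C_IND")
  t_full <- count_outcome(cohort, "C_OUT", ev)
  # P010 has no C_OUT mention in either window
  ev_drop <- ev[ev$patient_id != "P010", ]
  t_drop <- count_outcome(extract_cohort(ev_drop, "D", "C_IND"), "C_OUT",
                          ev_drop)
  expect_equal(t_drop$a, t_full$a)
  expect_equal(t_drop$c, t_full$c)
  expect_equal(t_drop$b, t_full$b - 1)
  expect_equal(t_drop$d, t_full$d - 1)
  expect_equal(sign(log(or_score(t_drop)$estimate)),
               sign(log(or_score(t_full)$estimate)))
})

test_that("detect_signals_emr ranks by OR and applies the joint rule", {
  scen <- gen_scenario(synth_config(seed = 35))
  s <- detect_signals_emr(scen$events, scen$cfg$drug,
                          scen$terms$indication_cui,
                          hierarchy = scen$hierarchy)
  expect_equal(s$source, "EMR")
  expect_false(is.unsorted(rev(s$entries$or)))
  expect_true(all(scen$truth$planted_cuis %in% signal_cuis(s)))
  expect_equal(s$entries$is_signal,
               s$entries$ci_low > 1 & s$entries$p < 0.05)
  # Bonferroni column defaults to m = number of candidates
  expect_equal(s$entries$p_bonferroni,
               pmin(1, s$entries$p * nrow(s$entries)))

  s40 <- detect_signals_emr(scen$events, scen$cfg$drug,
                            scen$terms$indication_cui, bonferroni_m = 40)
  expect_equal(s40$entries$p_bonferroni, pmin(1, s40$entries$p * 40))
})

test_that("min_patients above the cohort size empties the signal set", {
  scen <- gen_scenario(synth_config(seed = 36, n_patients = 100L))
  expect_warning(
    s <- detect_signals_emr(scen$events, scen$cfg$drug,
                            scen$terms$indication_cui,
                            min_patients = 10000),
    "candidate")
  expect_equal(nrow(s$entries), 0)
})

test_that("outcomes under the indication term are flagged as possible confounders", {
  # indication PT with one LLT child mentioned as an outcome
  df <- vasculitis_chain_df()
  h <- hierarchy(df)
  ev <- rbind(
    event_row("P1", 0, "DIAGNOSIS", "C_VASC"),
    event_row("P1", 100, "DRUG_EXPOSURE", "D"),
    event_row("P1", 400, "DRUG_EXPOSURE", "D"),
    event_row("P1", 200, "CONCEPT_MENTION", "C_SKINVASC", "T047"),
    event_row("P1", 210, "CONCEPT_MENTION", "C_OTHER", "T047")
  )
  s <- detect_signals_emr(ev, "D", "C_VASC", hierarchy = h)
  e <- s$entries
  expect_true(e$possible_indication_confounder[e$outcome_cui == "C_SKINVASC"])
  expect_false(e$possible_indication_confounder[e$outcome_cui == "C_OTHER"])
})

test_that("event tables round-trip through the TSV dialect with ISO dates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ev <- data.frame(patient_id = "P1", date = c("2001-03-05", "2001-06-01"),
                   kind = c("DIAGNOSIS", "DRUG_EXPOSURE"),
                   code = c("C_IND", "D"), semantic_type = "",
                   stringsAsFactors = FALSE)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_events(path)
  expect_equal(diff(out$date), 88L)
})
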