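# Synthetic study generator: a five-level hierarchy, spontaneous-report and
# patient-timeline tables with planted drug-ADE effects of known magnitude,
# and SIDER/ADReCS-dialect knowledge bases covering part of the truth. All
# outputs are deterministic in the master seed; each table draws from its
# own derived sub-stream so regenerating one does not perturb the others.

.stream_seed <- function(seed, stream) {
  offsets <- c(hierarchy = 1L, reports = 2L, timelines = 3L, kb = 4L)
  (as.integer(seed) * 1009L + offsets[[stream]] * 97L) %% 2147483587L
}

.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Configuration of a synthetic pharmacovigilance study
#'
#' Defines one reproducible scenario: hierarchy shape, report and cohort
#' sizes, background rates, and the planted (drug, outcome) effects whose
#' analytic ROR / odds ratio the generator guarantees in expectation.
#'
#' Outcomes are the first `n_outcomes` leaf (LLT) terms of the generated
#' hierarchy; the study indication is the last PT term. A planted effect
#' names an outcome by its index in that pool and carries `target_ror`
#' (spontaneous reports) and `p_case` / `p_control` (per-window occurrence
#' probabilities in the timelines, giving analytic odds ratio
#' `p_case (1 - p_control) / ((1 - p_case) p_control)`).
#'
#' @param seed master seed; every output is bit-reproducible in it.
#' @param n_reports number of spontaneous reports.
#' @param n_patients number of patients in the timeline table.
#' @param n_outcomes size of the outcome pool.
#' @param hierarchy_shape branching factors SOC->HLGT, HLGT->HLT, HLT->PT,
#'   PT->LLT.
#' @param drug focal drug code.
#' @param n_background_drugs number of comparator drug codes.
#' @param p_drug probability a report lists the focal drug.
#' @param background_reaction_p per-outcome reaction probability in reports
#'   with no planted effect (and in non-exposed reports).
#' @param indication_p probability a report carries the study indication.
#' @param background_mention_rate per-window occurrence probability of a
#'   non-planted outcome in the timelines, identical in case and control
#'   windows (Bernoulli per patient, outcome and window).
#' @param planted_effects list of `list(outcome =, target_ror =, p_case =,
#'   p_control =)`.
#' @param kb_covered indices (into `planted_effects`) of the planted ADEs
#'   recorded in the knowledge bases.
#' @param kb_parent_level logical, parallel to `kb_covered`: store that ADE
#'   as its PT parent instead of the LLT itself, so only flexible mapping
#'   can recover it.
#' @param kb_extra_terms number of knowledge-base-only ADE terms (confirmed
#'   but never planted, capping attainable recall).
#' @param observation_span_days length of the observation period.
#' @param sider_drug_id STITCH-style compound id used in the SIDER-dialect
#'   files.
#' @param mention_mode `"bernoulli"` (default): one mention at most per
#'   (patient, outcome, window), matching the binary occurrence counting of
#'   the case-crossover table and giving closed-form truth odds ratios;
#'   `"poisson"`: background outcomes instead draw mention counts from a
#'   Poisson process at `background_mention_rate` per patient-year, scaled
#'   by window length, for more realistic mention streams (planted
#'   outcomes stay Bernoulli).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_reports = 5000L,
                         n_patients = 2000L,
                         n_outcomes = 30L,
                         hierarchy_shape = c(3L, 3L, 3L, 3L),
                         drug = "D001",
                         n_background_drugs = 4L,
                         p_drug = 0.3,
                         background_reaction_p = 0.02,
                         indication_p = 0.9,
                         background_mention_rate = 0.05,
                         planted_effects = list(
                           list(outcome = 1L, target_ror = 8, p_case = 0.30, p_control = 0.05),
                           list(outcome = 2L, target_ror = 8, p_case = 0.30, p_control = 0.05),
                           list(outcome = 3L, target_ror = 8, p_case = 0.30, p_control = 0.05),
                           list(outcome = 4L, target_ror = 8, p_case = 0.30, p_control = 0.05),
                           list(outcome = 5L, target_ror = 8, p_case = 0.30, p_control = 0.05)
                         ),
                         kb_covered = c(1L, 2L, 3L),
                         kb_parent_level = c(FALSE, FALSE, TRUE),
                         kb_extra_terms = 2L,
                         observation_span_days = 7300L,
                         sider_drug_id = "CID100000001",
                         mention_mode = c("bernoulli", "poisson")) {
  mention_mode <- match.arg(mention_mode)
  cfg <- list(seed = as.integer(seed), n_reports = as.integer(n_reports),
              n_patients = as.integer(n_patients),
              n_outcomes = as.integer(n_outcomes),
              hierarchy_shape = as.integer(hierarchy_shape), drug = drug,
              n_background_drugs = as.integer(n_background_drugs),
              p_drug = p_drug, background_reaction_p = background_reaction_p,
              indication_p = indication_p,
              background_mention_rate = background_mention_rate,
              planted_effects = lapply(planted_effects, function(pe) {
                pe$outcome <- as.integer(pe$outcome)
                pe
              }),
              kb_covered = kb_covered,
              kb_parent_level = kb_parent_level,
              kb_extra_terms = as.integer(kb_extra_terms),
              observation_span_days = as.integer(observation_span_days),
              sider_drug_id = sider_drug_id, mention_mode = mention_mode)
  if (length(cfg$hierarchy_shape) != 4 || any(cfg$hierarchy_shape < 1)) {
    stop("hierarchy_shape must be 4 branching factors >= 1")
  }
  n_llt <- prod(cfg$hierarchy_shape)
  if (cfg$n_outcomes > n_llt - cfg$hierarchy_shape[4]) {
    stop("n_outcomes exceeds the leaf terms available outside the ",
         "indication branch; enlarge hierarchy_shape")
  }
  probs <- c(cfg$p_drug, cfg$background_reaction_p, cfg$indication_p)
  if (mention_mode == "bernoulli") {
    probs <- c(probs, cfg$background_mention_rate)
  } else if (cfg$background_mention_rate <= 0) {
    stop("background_mention_rate must be positive")
  }
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("probabilities must lie strictly in (0, 1)")
  }
  for (pe in cfg$planted_effects) {
    if (pe$target_ror <= 0) stop("target_ror must be positive")
    if (pe$p_case <= 0 || pe$p_case >= 1 || pe$p_control <= 0 ||
        pe$p_control >= 1) {
      stop("p_case and p_control must lie strictly in (0, 1)")
    }
    if (pe$outcome < 1 || pe$outcome > cfg$n_outcomes) {
      stop("planted outcome index out of range")
    }
    # reaction probability implied by the target ROR given exposure
    q <- cfg$background_reaction_p
    p1 <- pe$target_ror * q / (1 - q + pe$target_ror * q)
    if (p1 <= 0 || p1 >= 1) {
      stop("target_ror ", pe$target_ror, " implies an exposed reaction ",
           "probability outside (0, 1)")
    }
  }
  if (length(cfg$kb_parent_level) != length(cfg$kb_covered)) {
    stop("kb_parent_level must parallel kb_covered")
  }
  structure(cfg, class = "synth_config")
}

#' Generate the synthetic hierarchy table
#'
#' A perfect multi-way tree over SOC, HLGT, HLT, PT, LLT with deterministic
#' codes (`Mxxxxxxx`) and CUIs (`Cxxxxxxx`); the term count is
#' `1 + b1 + b1 b2 + b1 b2 b3 + b1 b2 b3 b4`.
#'
#' @param cfg a [synth_config()].
#' @return Data frame in the hierarchy TSV dialect (`meddra_code, cui,
#'   level, name, parent_code`).
#' @export
gen_hierarchy <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  b <- cfg$hierarchy_shape
  levels_down <- c("SOC", "HLGT", "HLT", "PT", "LLT")
  sizes <- c(1, cumprod(b))
  start <- cumsum(c(0, sizes[-5]))
  rows <- lapply(seq_along(levels_down), function(l) {
    n <- sizes[l]
    id <- start[l] + seq_len(n)
    parent <- if (l == 1) "" else {
      sprintf("M%07d", start[l - 1] + ((seq_len(n) - 1) %/% b[l - 1]) + 1)
    }
    data.frame(meddra_code = sprintf("M%07d", id),
               cui = sprintf("C%07d", id),
               level = levels_down[l],
               name = paste0(levels_down[l], "_", seq_len(n)),
               parent_code = parent, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Outcome pool, indication and decoy indication of a generated hierarchy.
# The indication is the last PT term; the decoy indication the one before
# it; outcomes are the first n_outcomes LLT terms (never under the
# indication PT because n_outcomes is capped below the indication branch).
.scenario_terms <- function(cfg, hier_df) {
  llt <- hier_df[hier_df$level == "LLT", , drop = FALSE]
  pt <- hier_df[hier_df$level == "PT", , drop = FALSE]
  list(outcome_cuis = llt$cui[seq_len(cfg$n_outcomes)],
       outcome_codes = llt$meddra_code[seq_len(cfg$n_outcomes)],
       indication_cui = pt$cui[nrow(pt)],
       indication_code = pt$meddra_code[nrow(pt)],
       indication_name = pt$name[nrow(pt)],
       decoy_indication_cui = pt$cui[nrow(pt) - 1],
       decoy_indication_code = pt$meddra_code[nrow(pt) - 1],
       decoy_indication_name = pt$name[nrow(pt) - 1])
}

#' Generate a spontaneous-report table with planted reporting odds ratios
#'
#' Reports carry the focal drug with probability `p_drug` and one comparator
#' drug always. Each outcome is included as a reaction with probability
#' `background_reaction_p` in non-exposed reports; for a planted effect the
#' exposed probability is raised so that the analytic 2x2 cell probabilities
#' attain exactly the target ROR. Infeasible configurations are rejected
#' analytically at [synth_config()] time.
#'
#' @param cfg a [synth_config()].
#' @param hier_df hierarchy table from [gen_hierarchy()] (regenerated when
#'   omitted).
#' @return List with `reports` (report-dialect data frame) and `truth`
#'   (planted pairs with their analytic cell probabilities and ROR).
#' @export
gen_reports <- function(cfg, hier_df = gen_hierarchy(cfg)) {
  stopifnot(inherits(cfg, "synth_config"))
  terms <- .scenario_terms(cfg, hier_df)
  n <- cfg$n_reports
  K <- cfg$n_outcomes
  q <- cfg$background_reaction_p

  set.seed(.stream_seed(cfg$seed, "reports"))
  has_drug <- stats::runif(n) < cfg$p_drug
  bg_drug <- paste0("BG", sprintf("%03d", sample.int(cfg$n_background_drugs,
                                                     n, replace = TRUE)))
  drug_ids <- ifelse(has_drug, paste(cfg$drug, bg_drug, sep = ";"), bg_drug)
  has_ind <- stats::runif(n) < cfg$indication_p
  indication_cuis <- ifelse(has_ind, terms$indication_cui,
                            terms$decoy_indication_cui)

  p_exposed <- rep(q, K)
  truth <- NULL
  for (pe in cfg$planted_effects) {
    p1 <- pe$target_ror * q / (1 - q + pe$target_ror * q)
    p_exposed[pe$outcome] <- p1
    cui <- terms$outcome_cuis[pe$outcome]
    truth <- rbind(truth, data.frame(
      drug = cfg$drug, outcome_cui = cui, target_ror = pe$target_ror,
      p_a = cfg$p_drug * p1, p_b = cfg$p_drug * (1 - p1),
      p_c = (1 - cfg$p_drug) * q, p_d = (1 - cfg$p_drug) * (1 - q),
      analytic_ror = (p1 / (1 - p1)) / (q / (1 - q)),
      stringsAsFactors = FALSE
    ))
  }

  prob <- matrix(q, n, K)
  planted_cols <- which(p_exposed != q)
  for (k in planted_cols) prob[has_drug, k] <- p_exposed[k]
  hit <- matrix(stats::runif(n * K), n, K) < prob
  idx <- which(hit, arr.ind = TRUE)
  reaction_cuis <- rep("", n)
  if (nrow(idx) > 0) {
    dt <- data.table::data.table(row = idx[, 1],
                                 cui = terms$outcome_cuis[idx[, 2]])
    data.table::setorder(dt, row, cui)
    agg <- dt[, list(s = paste(cui, collapse = ";")), by = "row"]
    reaction_cuis[agg$row] <- agg$s
  }

  gender <- sample(c("F", "M", "U"), n, replace = TRUE,
                   prob = c(0.70, 0.27, 0.03))
  age <- pmin(pmax(round(stats::rnorm(n, 55, 15)), 18), 90)

  reports <- data.frame(
    report_id = sprintf("R%06d", seq_len(n)),
    drug_ids = drug_ids, reaction_cuis = reaction_cuis,
    indication_cuis = indication_cuis, gender = gender, age = age,
    stringsAsFactors = FALSE
  )
  list(reports = reports, truth = truth)
}

#' Generate patient timelines with planted case-crossover effects
#'
#' Each patient receives one indication diagnosis, a first and a last
#' exposure to the focal drug (diagnosis strictly first, so every patient
#' has a non-empty control window), and per-outcome Bernoulli occurrences:
#' probability `p_case` of at least one mention in the case window and
#' `p_control` in the control window for planted outcomes (independently),
#' and `background_mention_rate` in both windows otherwise. Occurrence per
#' window, not mention counts, is what the case-crossover table consumes,
#' so the analytic odds ratio `p_case (1 - p_control) / ((1 - p_case)
#' p_control)` is exact. A sprinkling of pharmacologic-substance (T121)
#' mentions exercises the semantic-type filter without touching the
#' outcome pool.
#'
#' @inheritParams gen_reports
#' @return List with `events`, `demographics` (event-dialect data frames)
#'   and `truth` (planted pairs with analytic odds ratios).
#' @export
gen_timelines <- function(cfg, hier_df = gen_hierarchy(cfg)) {
  stopifnot(inherits(cfg, "synth_config"))
  terms <- .scenario_terms(cfg, hier_df)
  n <- cfg$n_patients
  K <- cfg$n_outcomes
  span <- cfg$observation_span_days

  set.seed(.stream_seed(cfg$seed, "timelines"))
  pid <- sprintf("P%06d", seq_len(n))
  t_dx <- sample.int(max(1L, span %/% 4L), n, replace = TRUE) - 1L
  gap <- sample(30:365, n, replace = TRUE)
  t_first <- t_dx + gap
  duration <- sample(90:1500, n, replace = TRUE)
  t_last <- pmin(t_first + duration, t_first + (span - t_first))

  p_case <- rep(cfg$background_mention_rate, K)
  p_control <- rep(cfg$background_mention_rate, K)
  truth <- NULL
  for (pe in cfg$planted_effects) {
    p_case[pe$outcome] <- pe$p_case
    p_control[pe$outcome] <- pe$p_control
    truth <- rbind(truth, data.frame(
      drug = cfg$drug, outcome_cui = terms$outcome_cuis[pe$outcome],
      p_case = pe$p_case, p_control = pe$p_control,
      analytic_or = (pe$p_case * (1 - pe$p_control)) /
        ((1 - pe$p_case) * pe$p_control),
      stringsAsFactors = FALSE
    ))
  }

  sem_types <- rep_len(semantic_type_default(), K)
  # mention counts per (patient, outcome, window); occurrence is count > 0
  n_case <- matrix(as.integer(matrix(stats::runif(n * K), n, K) <
                                matrix(p_case, n, K, byrow = TRUE)), n, K)
  n_ctl <- matrix(as.integer(matrix(stats::runif(n * K), n, K) <
                               matrix(p_control, n, K, byrow = TRUE)), n, K)
  if (cfg$mention_mode == "poisson") {
    # background outcomes get a Poisson mention process at
    # background_mention_rate per patient-year, scaled by window length;
    # planted outcomes stay Bernoulli so their analytic OR is exact
    planted <- vapply(cfg$planted_effects, `[[`, integer(1), "outcome")
    bg <- setdiff(seq_len(K), planted)
    case_years <- (t_last - t_first + 1L) / 365.25
    ctl_years <- gap / 365.25
    for (k in bg) {
      n_case[, k] <- stats::rpois(n, cfg$background_mention_rate * case_years)
      n_ctl[, k] <- stats::rpois(n, cfg$background_mention_rate * ctl_years)
    }
  }

  ic <- which(n_case > 0, arr.ind = TRUE)
  ic <- ic[rep(seq_len(nrow(ic)), n_case[ic]), , drop = FALSE]
  case_len <- t_last - t_first  # >= 0; closed window has case_len + 1 days
  case_dates <- t_first[ic[, 1]] +
    floor(stats::runif(nrow(ic)) * (case_len[ic[, 1]] + 1L))
  iv <- which(n_ctl > 0, arr.ind = TRUE)
  iv <- iv[rep(seq_len(nrow(iv)), n_ctl[iv]), , drop = FALSE]
  ctl_dates <- t_dx[iv[, 1]] +
    floor(stats::runif(nrow(iv)) * gap[iv[, 1]])  # in [t_dx, t_first)

  mention <- data.frame(
    patient_id = c(pid[ic[, 1]], pid[iv[, 1]]),
    date = as.integer(c(case_dates, ctl_dates)),
    kind = "CONCEPT_MENTION",
    code = c(terms$outcome_cuis[ic[, 2]], terms$outcome_cuis[iv[, 2]]),
    semantic_type = c(sem_types[ic[, 2]], sem_types[iv[, 2]]),
    stringsAsFactors = FALSE
  )

  # noise mentions of a pharmacologic substance; dropped by the type filter
  noisy <- which(stats::runif(n) < 0.1)
  noise <- data.frame(
    patient_id = pid[noisy],
    date = t_first[noisy] + 1L,
    kind = "CONCEPT_MENTION", code = "C9999001", semantic_type = "T121",
    stringsAsFactors = FALSE
  )

  fixed <- data.frame(
    patient_id = rep(pid, 3),
    date = as.integer(c(t_dx, t_first, t_last)),
    kind = rep(c("DIAGNOSIS", "DRUG_EXPOSURE", "DRUG_EXPOSURE"), each = n),
    code = rep(c(terms$indication_cui, cfg$drug, cfg$drug), each = n),
    semantic_type = "", stringsAsFactors = FALSE
  )

  events <- rbind(fixed, mention, noise)
  events <- events[order(events$patient_id, events$date, events$kind,
                         events$code), , drop = FALSE]
  rownames(events) <- NULL

  demographics <- data.frame(
    patient_id = pid,
    gender = sample(c("F", "M", "U"), n, replace = TRUE,
                    prob = c(0.68, 0.30, 0.02)),
    race = sample(c("White", "Black or African American", "Asian",
                    "American Indian/Alaskan Native", "Other", "Unknown",
                    "Choose not to disclose"),
                  n, replace = TRUE,
                  prob = c(0.86, 0.01, 0.01, 0.005, 0.015, 0.09, 0.01)),
    stringsAsFactors = FALSE
  )
  list(events = events, demographics = demographics, truth = truth)
}

#' Generate SIDER- and ADReCS-dialect knowledge-base files
#'
#' One indication-annotated label for the focal drug carries the covered
#' planted ADEs (each stored either as the LLT itself or as its PT parent,
#' so flexible mapping is exercised) plus `kb_extra_terms` confirmed ADEs
#' that are never planted; a decoy label with a different indication carries
#' unrelated terms that must not leak through the indication-restricted
#' extraction. The ADReCS-dialect file lists the same confirmed terms
#' keyed by drug name.
#'
#' @inheritParams gen_reports
#' @return List with `sider_indications`, `sider_se`, `adrecs` data frames
#'   and `covered_cuis` / `covered_llt_cuis` (the stored terms and the
#'   planted LLT concepts they validate).
#' @export
gen_kb <- function(cfg, hier_df = gen_hierarchy(cfg)) {
  stopifnot(inherits(cfg, "synth_config"))
  terms <- .scenario_terms(cfg, hier_df)
  rownames(hier_df) <- hier_df$meddra_code

  planted_idx <- vapply(cfg$planted_effects, `[[`, integer(1), "outcome")
  covered_outcomes <- planted_idx[cfg$kb_covered]

  stored <- data.frame(cui = character(0), meddra_code = character(0),
                       name = character(0), level = character(0),
                       stringsAsFactors = FALSE)
  for (j in seq_along(covered_outcomes)) {
    code <- terms$outcome_codes[covered_outcomes[j]]
    if (cfg$kb_parent_level[j]) {
      llt_row <- hier_df[hier_df$meddra_code == code, ]
      code <- llt_row$parent_code
    }
    row <- hier_df[code, ]
    stored <- rbind(stored, data.frame(cui = row$cui, meddra_code = code,
                                       name = row$name, level = row$level,
                                       stringsAsFactors = FALSE))
  }
  # confirmed-but-never-planted terms: LLTs outside the outcome pool
  llt <- hier_df[hier_df$level == "LLT", ]
  pool <- setdiff(llt$meddra_code,
                  c(terms$outcome_codes,
                    unlist(lapply(stored$meddra_code, descendants,
                                  h = hierarchy(hier_df)), use.names = FALSE)))
  extra_codes <- utils::head(pool, cfg$kb_extra_terms)
  extra <- hier_df[extra_codes, ]
  stored <- rbind(stored, data.frame(cui = extra$cui,
                                     meddra_code = extra$meddra_code,
                                     name = extra$name, level = extra$level,
                                     stringsAsFactors = FALSE))

  # decoy label for a different indication
  decoy_codes <- setdiff(utils::tail(llt$meddra_code, 4), stored$meddra_code)
  decoy <- hier_df[decoy_codes, ]

  lab_main <- "LBL0001"
  lab_decoy <- "LBL0002"
  cid <- cfg$sider_drug_id
  sider_indications <- data.frame(
    label_id = c(lab_main, lab_decoy),
    stitch_flat = cid, stitch_stereo = cid,
    cui = c(terms$indication_cui, terms$decoy_indication_cui),
    meddra_term_type = "PT",
    meddra_code = c(terms$indication_code, terms$decoy_indication_code),
    name = c(terms$indication_name, terms$decoy_indication_name),
    stringsAsFactors = FALSE
  )
  sider_se <- data.frame(
    label_id = c(rep(lab_main, nrow(stored)), rep(lab_decoy, nrow(decoy))),
    stitch_flat = cid, stitch_stereo = cid,
    cui = c(stored$cui, decoy$cui),
    meddra_term_type = c(stored$level, decoy$level),
    meddra_code = c(stored$meddra_code, decoy$meddra_code),
    name = c(stored$name, decoy$name),
    stringsAsFactors = FALSE
  )
  adrecs <- data.frame(
    drug_name = cfg$drug, ade_name = stored$name,
    meddra_code = stored$meddra_code, cui = stored$cui,
    stringsAsFactors = FALSE
  )
  list(sider_indications = sider_indications, sider_se = sider_se,
       adrecs = adrecs, covered_cuis = stored$cui,
       covered_llt_cuis = terms$outcome_cuis[covered_outcomes])
}

#' Generate a full synthetic scenario
#'
#' @param cfg a [synth_config()].
#' @return List of class `synth_scenario` holding the configuration, the
#'   hierarchy table and object, the report, event, demographics and
#'   knowledge-base tables, the indication/outcome term map, and the truth
#'   records of every planted effect.
#' @export
gen_scenario <- function(cfg = synth_config()) {
  hier_df <- gen_hierarchy(cfg)
  rep_out <- gen_reports(cfg, hier_df)
  tl_out <- gen_timelines(cfg, hier_df)
  kb_out <- gen_kb(cfg, hier_df)
  terms <- .scenario_terms(cfg, hier_df)
  planted_idx <- vapply(cfg$planted_effects, `[[`, integer(1), "outcome")
  truth <- list(
    reports = rep_out$truth, timelines = tl_out$truth,
    planted_cuis = terms$outcome_cuis[planted_idx],
    kb_covered_cuis = kb_out$covered_llt_cuis,
    novel_cuis = setdiff(terms$outcome_cuis[planted_idx],
                         kb_out$covered_llt_cuis)
  )
  structure(
    list(cfg = cfg, hierarchy_df = hier_df, hierarchy = hierarchy(hier_df),
         reports = rep_out$reports, events = tl_out$events,
         demographics = tl_out$demographics,
         sider_indications = kb_out$sider_indications,
         sider_se = kb_out$sider_se, adrecs = kb_out$adrecs,
         terms = terms, truth = truth),
    class = "synth_scenario"
  )
}

#' Write a scenario to disk in the package's file dialects
#'
#' Writes `hierarchy.tsv`, `reports.tsv`, `events.tsv`, `demographics.tsv`,
#' `kb_sider_indications.tsv`, `kb_sider_se.tsv`, `kb_adrecs.tsv` and
#' `truth.json` under `dir`.
#'
#' @param scenario a `synth_scenario`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synth_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_hierarchy(scenario$hierarchy, file.path(dir, "hierarchy.tsv"))
  write_reports(scenario$reports, file.path(dir, "reports.tsv"))
  tsv(scenario$events, "events.tsv")
  tsv(scenario$demographics, "demographics.tsv")
  tsv(scenario$sider_indications, "kb_sider_indications.tsv")
  tsv(scenario$sider_se, "kb_sider_se.tsv")
  tsv(scenario$adrecs, "kb_adrecs.tsv")
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
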