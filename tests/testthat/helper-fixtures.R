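# Shared fixtures, built in code at test time.

# perfect binary five-level tree: 1 SOC, 2 HLGT, 4 HLT, 8 PT, 16 LLT
binary_tree_df <- function() {
  gen_hierarchy(synth_config(hierarchy_shape = c(2L, 2L, 2L, 2L),
                             n_outcomes = 10L))
}

# five-term chain ending in the vasculitis example terms
vasculitis_chain_df <- function() {
  data.frame(
    meddra_code = c("S1", "G1", "T1", "V1", "V2"),
    cui = c("C_SOC", "C_HLGT", "C_HLT", "C_VASC", "C_SKINVASC"),
    level = c("SOC", "HLGT", "HLT", "PT", "LLT"),
    name = c("Disorders", "Vascular disorders", "Vasculitis group",
             "Vasculitides", "Skin vasculitis NOS"),
    parent_code = c("", "S1", "G1", "T1", "V1"),
    stringsAsFactors = FALSE
  )
}

# random five-level multi-parent hierarchy (a DAG, not a tree)
random_dag_df <- function(n_per_level = c(2, 5, 12, 30, 60)) {
  levels_down <- c("SOC", "HLGT", "HLT", "PT", "LLT")
  rows <- list()
  offset <- 0
  prev_codes <- character(0)
  for (l in seq_along(levels_down)) {
    n <- n_per_level[l]
    codes <- sprintf("N%04d", offset + seq_len(n))
    if (l == 1) {
      rows[[l]] <- data.frame(meddra_code = codes,
                              cui = sub("N", "C", codes),
                              level = levels_down[l],
                              name = codes, parent_code = "",
                              stringsAsFactors = FALSE)
    } else {
      n_parents <- sample(1:min(2, length(prev_codes)), n, replace = TRUE)
      rows[[l]] <- do.call(rbind, lapply(seq_len(n), function(i) {
        data.frame(meddra_code = codes[i], cui = sub("N", "C", codes[i]),
                   level = levels_down[l], name = codes[i],
                   parent_code = sample(prev_codes, n_parents[i]),
                   stringsAsFactors = FALSE)
      }))
    }
    prev_codes <- codes
    offset <- offset + n
  }
  do.call(rbind, rows)
}

# independent descendant oracle: graph reachability via igraph
igraph_descendants <- function(df, code) {
  edges <- df[df$parent_code != "", c("parent_code", "meddra_code")]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = unique(df$meddra_code))
  out <- igraph::subcomponent(g, code, mode = "out")
  sort(setdiff(names(out), code))
}

# tiny in-memory report table; sets given as ;-joined strings
report_fixture <- function(drug_ids, reaction_cuis, indication_cuis,
                           gender = "F", age = 50) {
  n <- length(drug_ids)
  data.frame(report_id = sprintf("R%03d", seq_len(n)),
             drug_ids = drug_ids, reaction_cuis = reaction_cuis,
             indication_cuis = indication_cuis,
             gender = rep_len(gender, n), age = rep_len(age, n),
             stringsAsFactors = FALSE)
}

# reports realizing exact 2x2 counts for drug D / event E
reports_from_cells <- function(a, b, c, d, drug = "D", event = "E",
                               indication = "IND") {
  n <- a + b + c + d
  report_fixture(
    drug_ids = c(rep(drug, a + b), rep("OTHER", c + d)),
    reaction_cuis = c(rep(event, a), rep("", b), rep(event, c), rep("", d)),
    indication_cuis = rep(indication, n)
  )
}

event_row <- function(patient_id, date, kind, code, semantic_type = "") {
  data.frame(patient_id = patient_id, date = as.integer(date), kind = kind,
             code = code, semantic_type = semantic_type,
             stringsAsFactors = FALSE)
}

# cohort of n patients: dx day 0, exposures days 100 and 400, with
# case-window mentions for the first n_case patients and control-window
# mentions for the first n_control
cohort_fixture <- function(n, n_case = 0, n_control = 0, outcome = "C_OUT",
                           drug = "D", indication = "C_IND") {
  pid <- sprintf("P%03d", seq_len(n))
  ev <- rbind(
    event_row(pid, 0, "DIAGNOSIS", indication),
    event_row(pid, 100, "DRUG_EXPOSURE", drug),
    event_row(pid, 400, "DRUG_EXPOSURE", drug)
  )
  if (n_case > 0) {
    ev <- rbind(ev, event_row(pid[seq_len(n_case)], 200, "CONCEPT_MENTION",
                              outcome, "T184"))
  }
  if (n_control > 0) {
    ev <- rbind(ev, event_row(pid[seq_len(n_control)], 50, "CONCEPT_MENTION",
                              outcome, "T184"))
  }
  ev
}

# the closed-form Woolf interval written independently of the package
oracle_or <- function(a, b, c, d, z = 1.96) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  est <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(estimate = est, ci_low = exp(log(est) - z * se),
       ci_high = exp(log(est) + z * se))
}

# a signal_set built directly from flagged CUIs (for evaluation tests)
signal_set_fixture <- function(cuis, source = "FAERS", drug = "D",
                               indication = "IND", score = NULL, p = NULL) {
  entries <- data.frame(outcome_cui = cuis,
                        is_signal = rep(TRUE, length(cuis)),
                        stringsAsFactors = FALSE)
  if (source == "FAERS") {
    entries$ror <- if (is.null(score)) rep(2, length(cuis)) else score
  } else {
    entries$or <- if (is.null(score)) rep(2, length(cuis)) else score
    entries$p <- if (is.null(p)) rep(0.01, length(cuis)) else p
    entries$p_bonferroni <- entries$p
  }
  pharmsig:::.new_signal_set(drug, indication, source, entries)
}

kb_fixture <- function(cuis, codes = cuis, names = cuis,
                       drug_id = "DRUG", indication = NA_character_) {
  pharmsig:::.new_kb(drug_id, indication,
                     data.frame(cui = cuis, meddra_code = codes, name = names,
                                stringsAsFactors = FALSE),
                     "SYNTHETIC")
}
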