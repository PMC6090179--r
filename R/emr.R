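# Case-crossover signal detection from longitudinal patient event streams.
# Each patient acts as their own control: the period between the indication
# diagnosis and the first drug exposure is the control window, the period
# from first to last exposure is the case window, and outcome occurrence is
# compared between the two windows over the same cohort.

#' Default UMLS semantic-type filter
#'
#' Concept mentions are restricted to types describing findings and clinical
#' outcomes: Finding (T033), Laboratory or Test Result (T034), Sign or
#' Symptom (T184), Disease or Syndrome (T047), Mental or Behavioral
#' Dysfunction (T048), Neoplastic Process (T191) and Cell or Molecular
#' Dysfunction (T049).
#'
#' @return Character vector of semantic-type codes.
#' @export
semantic_type_default <- function() {
  c("T033", "T034", "T184", "T047", "T048", "T191", "T049")
}

#' Read a clinical event table
#'
#' Dialect: TSV with header and columns
#' `patient_id  date  kind  code  semantic_type`, where `kind` is one of
#' DRUG_EXPOSURE, CONCEPT_MENTION, DIAGNOSIS, `date` is an integer day index
#' or an ISO date, and `semantic_type` is empty for non-mention events.
#'
#' @param path path to the TSV.
#' @return A data frame with `date` converted to an integer day index.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  req <- c("patient_id", "date", "kind", "code", "semantic_type")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("event table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_kind <- setdiff(unique(df$kind),
                      c("DRUG_EXPOSURE", "CONCEPT_MENTION", "DIAGNOSIS"))
  if (length(bad_kind) > 0) {
    stop("unknown event kind(s): ", paste(bad_kind, collapse = ", "))
  }
  df$date <- .as_day(df$date)
  df
}

# integer day index; ISO dates are converted to days since 1970-01-01
.as_day <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  num <- suppressWarnings(as.integer(x))
  if (!anyNA(num)) return(num)
  d <- as.integer(as.Date(x))
  if (anyNA(d)) stop("dates must be integer day indices or ISO dates")
  d
}

#' Read a patient demographics table
#'
#' Dialect: TSV with header and columns `patient_id  gender  race`.
#'
#' @param path path to the TSV.
#' @return A data frame, one row per patient.
#' @export
read_demographics <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  req <- c("patient_id", "gender", "race")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("demographics table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Restrict concept mentions to allowed semantic types
#'
#' Only CONCEPT_MENTION events are filtered; exposures and diagnoses pass
#' through untouched.
#'
#' @param events event data frame.
#' @param allowed_types character vector of UMLS semantic-type codes;
#'   defaults to [semantic_type_default()].
#' @return The filtered event data frame.
#' @export
filter_concepts_semantic <- function(events,
                                     allowed_types = semantic_type_default()) {
  keep <- events$kind != "CONCEPT_MENTION" |
    events$semantic_type %in% allowed_types
  events[keep, , drop = FALSE]
}

#' Case-crossover windows for each patient
#'
#' For every patient with at least one diagnosis of the indication and one
#' exposure to the drug, computes t_dx (earliest indication diagnosis),
#' t_first and t_last (first and last exposure). The control window is the
#' half-open interval [t_dx, t_first) and the case window the closed
#' interval [t_first, t_last]: a mention on the first-exposure day is an
#' on-treatment, case-window event. Patients whose first exposure does not
#' strictly follow the diagnosis have an empty control window and are
#' dropped by [extract_cohort()].
#'
#' @param events event data frame.
#' @param drug drug code of the exposure events.
#' @param indication CUI of the diagnosis events.
#' @param exposure_tail_days days added to t_last to model drug persistence
#'   beyond the last recorded exposure (default 0).
#' @return Data frame `patient_id, t_dx, t_first, t_last`, one row per
#'   patient with both event types.
#' @export
build_windows <- function(events, drug, indication, exposure_tail_days = 0) {
  ev <- data.table::as.data.table(events)
  dx <- ev[ev$kind == "DIAGNOSIS" & ev$code == indication,
           list(t_dx = min(date)), by = "patient_id"]
  ex <- ev[ev$kind == "DRUG_EXPOSURE" & ev$code == drug,
           list(t_first = min(date), t_last = max(date)), by = "patient_id"]
  w <- merge(dx, ex, by = "patient_id")
  w$t_last <- w$t_last + as.integer(exposure_tail_days)
  as.data.frame(w)
}

#' Extract the analyzable (drug, indication) cohort
#'
#' Keeps the patients of [build_windows()] whose earliest indication
#' diagnosis strictly precedes the first drug exposure, so that the control
#' window is non-empty.
#'
#' @inheritParams build_windows
#' @return Window data frame (`patient_id, t_dx, t_first, t_last`) for the
#'   cohort; an error with count diagnostics when the cohort is empty.
#' @export
extract_cohort <- function(events, drug, indication, exposure_tail_days = 0) {
  w <- build_windows(events, drug, indication, exposure_tail_days)
  cohort <- w[w$t_dx < w$t_first, , drop = FALSE]
  if (nrow(cohort) == 0) {
    stop("empty cohort for drug ", drug, " / indication ", indication, ": ",
         nrow(w), " patient(s) with both diagnosis and exposure, ",
         "0 with a non-empty pre-exposure control window")
  }
  rownames(cohort) <- NULL
  cohort
}

#' Case-crossover 2x2 table for one outcome
#'
#' Counts patients, not mentions: a patient with at least one mention of the
#' outcome in the case window counts once in `a`, and independently counts
#' in `c` if the control window also carries a mention. Both rows cover the
#' full cohort, so `a + b = c + d = n`.
#'
#' @param cohort_windows window data frame from [extract_cohort()].
#' @param outcome_cui outcome concept code.
#' @param events event data frame providing the concept mentions.
#' @return A [contingency_table()] with context `"CASE_CROSSOVER"`.
#' @export
count_outcome <- function(cohort_windows, outcome_cui, events) {
  if (nrow(cohort_windows) == 0) stop("empty cohort")
  n <- nrow(cohort_windows)
  m <- events[events$kind == "CONCEPT_MENTION" & events$code == outcome_cui, ,
              drop = FALSE]
  m <- merge(m, cohort_windows, by = "patient_id")
  in_case <- m$date >= m$t_first & m$date <= m$t_last
  in_control <- m$date >= m$t_dx & m$date < m$t_first
  a <- length(unique(m$patient_id[in_case]))
  c <- length(unique(m$patient_id[in_control]))
  contingency_table(a = a, b = n - a, c = c, d = n - c,
                    context = "CASE_CROSSOVER")
}

#' Detect case-crossover OR signals from patient timelines
#'
#' Applies the semantic-type filter, extracts the cohort, builds the pooled
#' (unconditional) case-crossover table for every candidate outcome, and
#' scores each with [or_score()]. Candidates are the concept CUIs mentioned
#' in at least `min_patients` case windows. A signal requires both the lower
#' 95% confidence bound above 1 and p < 0.05; p-values are additionally
#' Bonferroni-corrected over the number of candidates (or `bonferroni_m`
#' when given). When a hierarchy is supplied, outcomes lying below the
#' indication term are annotated as possible confounding-by-indication
#' findings rather than excluded.
#'
#' @param events event data frame.
#' @param drug drug code.
#' @param indication indication CUI.
#' @param allowed_types semantic-type filter, default
#'   [semantic_type_default()].
#' @param min_patients minimum number of case-window patients for a
#'   candidate outcome (default 1).
#' @param z normal quantile for the interval.
#' @param p_method `"auto"`, `"chi2"` or `"fisher"` (see
#'   [outcome_pvalue()]).
#' @param bonferroni_m override for the number of comparisons; default is
#'   the number of candidate outcomes.
#' @param exposure_tail_days case-window extension, see [build_windows()].
#' @param hierarchy optional [hierarchy()] used to flag indication
#'   descendants.
#' @return A `signal_set` with source `"EMR"`; entries sorted by descending
#'   OR, ties by ascending p then CUI.
#' @export
detect_signals_emr <- function(events, drug, indication,
                               allowed_types = semantic_type_default(),
                               min_patients = 1, z = 1.96,
                               p_method = c("auto", "chi2", "fisher"),
                               bonferroni_m = NULL, exposure_tail_days = 0,
                               hierarchy = NULL) {
  p_method <- match.arg(p_method)
  events <- filter_concepts_semantic(events, allowed_types)
  cohort <- extract_cohort(events, drug, indication, exposure_tail_days)
  n <- nrow(cohort)

  # per (patient, outcome): any mention in each window
  m <- data.table::as.data.table(
    events[events$kind == "CONCEPT_MENTION", c("patient_id", "date", "code")]
  )
  m <- merge(m, data.table::as.data.table(cohort), by = "patient_id")
  m[, `:=`(in_case = date >= t_first & date <= t_last,
           in_control = date >= t_dx & date < t_first)]
  per <- m[, list(case = any(in_case), control = any(in_control)),
           by = c("code", "patient_id")]
  counts <- per[, list(a = sum(case), c = sum(control)), by = "code"]
  counts <- counts[counts$a >= min_patients, ]

  empty <- data.frame(outcome_cui = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      or = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0), is_signal = logical(0),
                      possible_indication_confounder = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(counts) == 0) {
    warning("no candidate outcome mentioned in >= ", min_patients,
            " case windows")
    return(.new_signal_set(drug, indication, "EMR", empty))
  }

  m_comp <- if (is.null(bonferroni_m)) nrow(counts) else bonferroni_m
  scores <- lapply(seq_len(nrow(counts)), function(i) {
    t <- contingency_table(counts$a[i], n - counts$a[i],
                           counts$c[i], n - counts$c[i],
                           context = "CASE_CROSSOVER")
    or_score(t, z = z, p_method = p_method)
  })

  tab <- data.frame(
    outcome_cui = counts$code,
    a = counts$a, b = n - counts$a, c = counts$c, d = n - counts$c,
    or = vapply(scores, `[[`, numeric(1), "estimate"),
    ci_low = vapply(scores, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(scores, `[[`, numeric(1), "ci_high"),
    p = vapply(scores, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  tab$p_bonferroni <- bonferroni(tab$p, m_comp)
  tab$is_signal <- vapply(scores, `[[`, logical(1), "is_signal")

  confounder_cuis <- character(0)
  if (!is.null(hierarchy)) {
    ind_codes <- codes_for_cuis(hierarchy, indication)
    desc <- unique(unlist(lapply(ind_codes, descendants, h = hierarchy),
                          use.names = FALSE))
    confounder_cuis <- hierarchy$terms[desc, "cui"]
  }
  tab$possible_indication_confounder <-
    tab$outcome_cui %in% c(confounder_cuis, indication)

  tab <- tab[order(-tab$or, tab$p, tab$outcome_cui), , drop = FALSE]
  .new_signal_set(drug, indication, "EMR", tab)
}
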