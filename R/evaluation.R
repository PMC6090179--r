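# Evaluation of detected signal sets against ADE knowledge bases: exact and
# hierarchy-expanded (flexible) matching, precision/recall/F1, combination
# of sources, Venn partitioning and ranked novel-ADE hypotheses.

#' Match detected signals against a knowledge base
#'
#' Under `"EXACT"` matching, a discovered signal matches when its CUI is a
#' confirmed knowledge-base CUI. Under `"FLEXIBLE"` matching the confirmed
#' side is first expanded downward through the hierarchy
#' ([expand_kb_flexible()]), so a fine-grained signal (e.g. a specific skin
#' vasculitis) matches a coarser label term (vasculitides). Only the
#' confirmed side is ever expanded; the discovered set is used as is, and a
#' discovered CUI counts at most once however many expanded parents cover
#' it.
#'
#' @param signals a `signal_set`; the discovered set is its flagged CUIs.
#' @param kb an `ade_kb`.
#' @param h a [hierarchy()] (required for flexible matching).
#' @param strategy `"EXACT"` or `"FLEXIBLE"`.
#' @return An object of class `match_result`: the strategy, the discovered,
#'   confirmed (possibly expanded), and matched CUI sets, plus the
#'   un-expanded confirmed set used as the recall denominator.
#' @export
match_signals <- function(signals, kb, h = NULL,
                          strategy = c("EXACT", "FLEXIBLE")) {
  strategy <- match.arg(strategy)
  discovered <- sort(unique(signal_cuis(signals)))
  confirmed_exact <- sort(unique(kb_cuis(kb)))
  confirmed <- if (strategy == "FLEXIBLE") {
    if (is.null(h)) stop("flexible matching needs a hierarchy")
    expand_kb_flexible(kb, h)
  } else {
    confirmed_exact
  }
  structure(
    list(strategy = strategy, discovered = discovered, confirmed = confirmed,
         confirmed_exact = confirmed_exact,
         matched = intersect(discovered, confirmed)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result ", x$strategy, "> discovered ", length(x$discovered),
      ", confirmed ", length(x$confirmed_exact),
      if (x$strategy == "FLEXIBLE") paste0(" (expanded ", length(x$confirmed), ")"),
      ", matched ", length(x$matched), "\n", sep = "")
  invisible(x)
}

#' Precision, recall and F1 of a match result
#'
#' Precision = matched / discovered; recall = matched / confirmed, where the
#' recall denominator is always the *un-expanded* knowledge-base set so that
#' exact and flexible recalls stay comparable (flexible expansion affects
#' which signals match, not how many ADEs there are to find). F1 is the
#' harmonic mean, computed as 2m / (2m + |discovered unmatched| +
#' |confirmed unmatched|).
#'
#' @param m a `match_result`.
#' @return A list with `precision`, `recall`, `f1`, `n_discovered`,
#'   `n_confirmed`, `n_matched`. All-zero with a warning when both
#'   denominators are empty.
#' @export
compute_metrics <- function(m) {
  stopifnot(inherits(m, "match_result"))
  nd <- length(m$discovered)
  nc <- length(m$confirmed_exact)
  nm <- length(m$matched)
  if (nd == 0 && nc == 0) {
    warning("no discovered and no confirmed ADEs; metrics set to 0")
  }
  precision <- if (nd > 0) nm / nd else 0
  recall <- if (nc > 0) nm / nc else 0
  denom <- 2 * nm + (nd - nm) + (nc - nm)
  f1 <- if (denom > 0) 2 * nm / denom else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_discovered = nd, n_confirmed = nc, n_matched = nm)
}

#' Union of FAERS and EMR signal sets
#'
#' The combined set flags every outcome flagged by either source; when both
#' flag an outcome both scores are kept, with the case-crossover OR (and its
#' p-value) preferred as the ranking `score` because it carries the
#' within-patient design.
#'
#' @param s_faers `signal_set` with source `"FAERS"`.
#' @param s_emr `signal_set` with source `"EMR"`.
#' @return A `signal_set` with source `"COMBINED"`; entries carry
#'   `in_faers`, `in_emr`, the per-source estimates, and the ranking
#'   `score`/`p`.
#' @export
combine_sources <- function(s_faers, s_emr) {
  stopifnot(inherits(s_faers, "signal_set"), inherits(s_emr, "signal_set"))
  if (!identical(s_faers$drug, s_emr$drug) ||
      !identical(s_faers$indication, s_emr$indication)) {
    stop("signal sets describe different (drug, indication) pairs")
  }
  fa <- s_faers$entries[s_faers$entries$is_signal, , drop = FALSE]
  em <- s_emr$entries[s_emr$entries$is_signal, , drop = FALSE]
  cuis <- union(fa$outcome_cui, em$outcome_cui)
  fi <- match(cuis, fa$outcome_cui)
  ei <- match(cuis, em$outcome_cui)
  entries <- data.frame(
    outcome_cui = cuis,
    in_faers = !is.na(fi), in_emr = !is.na(ei),
    ror = fa$ror[fi],
    or = em$or[ei], p = em$p[ei], p_bonferroni = em$p_bonferroni[ei],
    stringsAsFactors = FALSE
  )
  entries$score <- ifelse(entries$in_emr, entries$or, entries$ror)
  entries$is_signal <- TRUE
  entries <- entries[order(-entries$score, entries$p, entries$outcome_cui), ,
                     drop = FALSE]
  .new_signal_set(s_faers$drug, s_faers$indication, "COMBINED", entries)
}

#' Venn partition of FAERS signals, EMR signals and knowledge-base ADEs
#'
#' Cardinalities of the seven regions of the three-set Venn diagram over
#' CUIs, by inclusion-exclusion; region sums reconstruct each input set's
#' size exactly.
#'
#' @param s_faers `signal_set` (or character vector of CUIs).
#' @param s_emr `signal_set` (or character vector of CUIs).
#' @param kb_cuis character vector of knowledge-base CUIs (expanded or not,
#'   as desired).
#' @return Named integer vector with regions `faers_only, emr_only, kb_only,
#'   faers_emr, faers_kb, emr_kb, all`.
#' @export
venn_partition <- function(s_faers, s_emr, kb_cuis) {
  f <- if (inherits(s_faers, "signal_set")) signal_cuis(s_faers) else s_faers
  e <- if (inherits(s_emr, "signal_set")) signal_cuis(s_emr) else s_emr
  f <- unique(f); e <- unique(e); k <- unique(kb_cuis)
  all3 <- length(intersect(intersect(f, e), k))
  fe <- length(intersect(f, e)) - all3
  fk <- length(intersect(f, k)) - all3
  ek <- length(intersect(e, k)) - all3
  c(faers_only = length(f) - fe - fk - all3,
    emr_only = length(e) - fe - ek - all3,
    kb_only = length(k) - fk - ek - all3,
    faers_emr = fe, faers_kb = fk, emr_kb = ek, all = all3)
}

#' Ranked novel-ADE hypotheses
#'
#' Flagged outcomes of the combined signal set that are absent from the
#' (flexibly expanded) knowledge base: likely false positives or genuinely
#' new adverse events, ordered for follow-up. Ranking is by descending
#' score (case-crossover OR when the outcome was detected in the patient
#' timelines, else the reporting odds ratio), ties by ascending p-value then
#' CUI.
#'
#' @param s_combined `signal_set` from [combine_sources()].
#' @param kb_cuis_flexible expanded knowledge-base CUI set.
#' @param top_k number of hypotheses to keep (default 10); `Inf` keeps all.
#' @return Data frame `outcome_cui, score, in_faers, in_emr, p,
#'   p_bonferroni`, at most `top_k` rows.
#' @export
novel_candidates <- function(s_combined, kb_cuis_flexible, top_k = 10) {
  stopifnot(inherits(s_combined, "signal_set"))
  e <- s_combined$entries
  e <- e[e$is_signal & !(e$outcome_cui %in% kb_cuis_flexible), , drop = FALSE]
  e <- e[order(-e$score, e$p, e$outcome_cui), , drop = FALSE]
  cols <- intersect(c("outcome_cui", "score", "in_faers", "in_emr",
                      "p", "p_bonferroni"), names(e))
  out <- e[seq_len(min(top_k, nrow(e))), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}
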