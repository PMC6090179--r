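# Spontaneous-report signal detection: 2x2 report counts and the reporting
# odds ratio for every candidate reaction of a (drug, indication) pair.

.split_set <- function(x) strsplit(x, ";", fixed = TRUE)

#' Read a spontaneous-report table
#'
#' Dialect: TSV with header and columns
#' `report_id  drug_ids  reaction_cuis  indication_cuis  gender  age`,
#' where the three set-valued columns are `;`-separated and may be empty.
#' `gender` is one of F, M, U; `age` may be empty.
#'
#' @param path path to the TSV.
#' @return A data frame, one row per report.
#' @export
read_reports <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  req <- c("report_id", "drug_ids", "reaction_cuis", "indication_cuis",
           "gender", "age")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("report table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$report_id)) stop("duplicate report_id values")
  df$age <- suppressWarnings(as.numeric(df$age))
  df
}

#' Write a report table in its TSV dialect
#'
#' @param reports data frame as returned by [read_reports()] or
#'   [gen_reports()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  out <- reports
  out$age[is.na(out$age)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.has_member <- function(set_col, value) {
  vapply(.split_set(set_col), function(s) value %in% s, logical(1))
}

#' Reports for a (drug, indication) pair
#'
#' Selects the reports that mention the drug among their suspect drugs and
#' the indication among their indications. The comparator cells of the 2x2
#' are taken from a companion background set, controlled elsewhere by the
#' `comparator` option of [detect_signals_faers()].
#'
#' @param reports report data frame.
#' @param drug drug code.
#' @param indication indication CUI.
#' @return The matching subset; a warning is given when it is empty.
#' @export
filter_reports_by_indication <- function(reports, drug, indication) {
  keep <- .has_member(reports$drug_ids, drug) &
    .has_member(reports$indication_cuis, indication)
  out <- reports[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no report mentions drug ", drug, " with indication ", indication)
  }
  out
}

#' Report-level 2x2 table for one (drug, event) pair
#'
#' a = reports with the drug and the event; b = with the drug, without the
#' event; c = other drugs with the event; d = other drugs without the event.
#' Cells always sum to the number of input reports.
#'
#' @param reports report data frame (the full comparator population).
#' @param drug drug code.
#' @param ade_cui event (reaction) CUI.
#' @return A [contingency_table()] with context `"REPORTS"`.
#' @export
build_contingency_reports <- function(reports, drug, ade_cui) {
  if (nrow(reports) == 0) stop("no reports supplied")
  has_drug <- .has_member(reports$drug_ids, drug)
  has_ade <- .has_member(reports$reaction_cuis, ade_cui)
  contingency_table(
    a = sum(has_drug & has_ade), b = sum(has_drug & !has_ade),
    c = sum(!has_drug & has_ade), d = sum(!has_drug & !has_ade),
    context = "REPORTS"
  )
}

.new_signal_set <- function(drug, indication, source, entries) {
  stopifnot(source %in% c("FAERS", "EMR", "COMBINED"))
  if (anyDuplicated(entries$outcome_cui)) {
    stop("duplicate outcome CUIs in signal set")
  }
  rownames(entries) <- NULL
  structure(list(drug = drug, indication = indication, source = source,
                 entries = entries),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat("<signal_set ", x$source, "> drug ", x$drug, ", indication ",
      x$indication, ": ", nrow(x$entries), " outcomes, ",
      sum(x$entries$is_signal), " flagged\n", sep = "")
  invisible(x)
}

#' Flagged outcome CUIs of a signal set
#'
#' @param s a `signal_set`.
#' @return Character vector of CUIs with `is_signal = TRUE`.
#' @export
signal_cuis <- function(s) {
  stopifnot(inherits(s, "signal_set"))
  s$entries$outcome_cui[s$entries$is_signal]
}

#' Detect ROR signals from spontaneous reports
#'
#' Candidate outcomes are every reaction CUI seen in the (drug, indication)
#' report subset whose drug-and-event cell reaches `min_a`. Each candidate
#' gets a 2x2 table against the comparator population and a [ror_score()];
#' a signal is an outcome whose lower 95% confidence bound exceeds 1.
#'
#' @param reports report data frame.
#' @param drug drug code.
#' @param indication indication CUI.
#' @param min_a minimum drug-and-event report count for a candidate
#'   (default 1; 3 is common practice for spontaneous-report mining).
#' @param z normal quantile for the confidence interval.
#' @param comparator `"all"` (default): c and d are counted over all loaded
#'   reports; `"indication_restricted"`: over indication-matched reports
#'   only.
#' @return A `signal_set` with source `"FAERS"`; entries are sorted by
#'   descending ROR, ties by ascending CUI.
#' @export
detect_signals_faers <- function(reports, drug, indication, min_a = 1,
                                 z = 1.96,
                                 comparator = c("all", "indication_restricted")) {
  comparator <- match.arg(comparator)
  subset <- filter_reports_by_indication(reports, drug, indication)
  background <- if (comparator == "all") reports else {
    reports[.has_member(reports$indication_cuis, indication), , drop = FALSE]
  }

  empty <- data.frame(outcome_cui = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      ror = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), is_signal = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(subset) == 0) {
    warning("empty candidate set for drug ", drug)
    return(.new_signal_set(drug, indication, "FAERS", empty))
  }

  candidates <- sort(unique(unlist(.split_set(subset$reaction_cuis),
                                   use.names = FALSE)))
  candidates <- candidates[candidates != ""]

  # vectorized counting over the background population
  has_drug <- .has_member(background$drug_ids, drug)
  n_bg <- nrow(background)
  rx <- .split_set(background$reaction_cuis)
  long <- data.table::data.table(
    idx = rep.int(seq_len(n_bg), lengths(rx)),
    cui = unlist(rx, use.names = FALSE)
  )
  long <- unique(long[long$cui %in% candidates])
  long[, drug_row := has_drug[idx]]
  counts <- long[, list(a = sum(drug_row), ac = .N), by = "cui"]
  tab <- data.frame(outcome_cui = counts$cui,
                    a = counts$a,
                    c = counts$ac - counts$a, stringsAsFactors = FALSE)
  # candidates never seen in the background (possible under
  # indication-restricted comparison) keep zero counts
  missing_cand <- setdiff(candidates, tab$outcome_cui)
  if (length(missing_cand) > 0) {
    tab <- rbind(tab, data.frame(outcome_cui = missing_cand, a = 0L, c = 0L))
  }
  tab$b <- sum(has_drug) - tab$a
  tab$d <- (n_bg - sum(has_drug)) - tab$c
  tab <- tab[tab$a >= min_a, , drop = FALSE]

  if (nrow(tab) == 0) {
    warning("no candidate outcome reaches min_a = ", min_a)
    return(.new_signal_set(drug, indication, "FAERS", empty))
  }

  scores <- lapply(seq_len(nrow(tab)), function(i) {
    ror_score(contingency_table(tab$a[i], tab$b[i], tab$c[i], tab$d[i],
                                context = "REPORTS"), z = z)
  })
  tab$ror <- vapply(scores, `[[`, numeric(1), "estimate")
  tab$ci_low <- vapply(scores, `[[`, numeric(1), "ci_low")
  tab$ci_high <- vapply(scores, `[[`, numeric(1), "ci_high")
  tab$is_signal <- vapply(scores, `[[`, logical(1), "is_signal")

  tab <- tab[order(-tab$ror, tab$outcome_cui),
             c("outcome_cui", "a", "b", "c", "d", "ror", "ci_low", "ci_high",
               "is_signal")]
  .new_signal_set(drug, indication, "FAERS", tab)
}

#' Write a signal table to TSV
#'
#' @param s a `signal_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(s, path) {
  stopifnot(inherits(s, "signal_set"))
  utils::write.table(s$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
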