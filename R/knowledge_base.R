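# Knowledge bases: per-drug sets of confirmed adverse events, keyed by CUI.
# CUI is the join key across every source; hierarchy codes are internal.

.new_kb <- function(drug_id, indication, ade_terms, provenance) {
  stopifnot(provenance %in% c("SIDER", "ADRECS", "SYNTHETIC"))
  ade_terms <- as.data.frame(ade_terms, stringsAsFactors = FALSE)
  if (nrow(ade_terms) > 0) {
    ade_terms <- ade_terms[!duplicated(ade_terms$cui), , drop = FALSE]
    # a drug's indication is never one of its confirmed adverse events
    ade_terms <- ade_terms[is.na(indication) | ade_terms$cui != indication, ,
                           drop = FALSE]
    rownames(ade_terms) <- NULL
  }
  structure(
    list(drug_id = drug_id, indication = indication,
         ade_terms = ade_terms, provenance = provenance),
    class = "ade_kb"
  )
}

#' Confirmed-ADE set of a knowledge base
#'
#' @param kb an `ade_kb` object.
#' @return Character vector of the CUIs of the knowledge base's confirmed
#'   adverse events (un-expanded).
#' @export
kb_cuis <- function(kb) {
  stopifnot(inherits(kb, "ade_kb"))
  kb$ade_terms$cui
}

#' @export
print.ade_kb <- function(x, ...) {
  cat("<ade_kb> drug ", x$drug_id, " (", x$provenance, "), ",
      nrow(x$ade_terms), " confirmed ADE terms", sep = "")
  if (!is.na(x$indication)) cat(", indication ", x$indication, sep = "")
  cat("\n")
  invisible(x)
}

.read_sider_file <- function(path) {
  cols <- c("label_id", "stitch_flat", "stitch_stereo", "cui",
            "meddra_term_type", "meddra_code", "name")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else path
  df <- utils::read.delim(con, header = TRUE, colClasses = "character",
                          na.strings = NULL, quote = "", fileEncoding = "UTF-8")
  if (ncol(df) != length(cols)) {
    stop("SIDER dialect file must have ", length(cols), " columns, found ",
         ncol(df), ": ", path)
  }
  names(df) <- cols
  ok <- df$cui != "" & df$label_id != ""
  if (any(!ok)) {
    message(sum(!ok), " malformed row(s) skipped in ", basename(path))
    df <- df[ok, , drop = FALSE]
  }
  df
}

#' Build a knowledge base from SIDER-dialect label files
#'
#' Reproduces the indication-restricted label extraction: only package-insert
#' labels of the given compound whose indications include `indication_name`
#' contribute side-effect terms. Matching on the indication name is exact and
#' case-insensitive. Side-effect rows are ingested regardless of their MedDRA
#' term type (LLT and PT duplicates of one concept collapse when
#' de-duplicating by CUI).
#'
#' @param indications_path TSV (optionally gzipped) in the SIDER 4.1 column
#'   layout: label id, STITCH flat id, STITCH stereo id, UMLS concept id,
#'   MedDRA term type, MedDRA code, name.
#' @param se_path side-effect file in the same layout.
#' @param drug_id STITCH compound identifier (flat or stereo), e.g.
#'   `"CID100004112"`.
#' @param indication_name indication to restrict labels to, e.g.
#'   `"Rheumatoid arthritis"`.
#' @return An `ade_kb` with provenance `"SIDER"`. An unknown `drug_id` gives
#'   an empty knowledge base with a warning, not an error.
#' @export
load_sider_kb <- function(indications_path, se_path, drug_id, indication_name) {
  ind <- .read_sider_file(indications_path)
  se <- .read_sider_file(se_path)

  drug_rows <- ind$stitch_flat == drug_id | ind$stitch_stereo == drug_id
  hit <- drug_rows & tolower(ind$name) == tolower(indication_name)
  labels <- unique(ind$label_id[hit])
  indication_cui <- if (any(hit)) ind$cui[hit][1] else NA_character_

  if (length(labels) == 0) {
    warning("no ", indication_name, " label found for ", drug_id,
            "; knowledge base is empty")
    terms <- data.frame(cui = character(0), meddra_code = character(0),
                        name = character(0), stringsAsFactors = FALSE)
    return(.new_kb(drug_id, indication_cui, terms, "SIDER"))
  }

  keep <- se$label_id %in% labels &
    (se$stitch_flat == drug_id | se$stitch_stereo == drug_id)
  terms <- se[keep, c("cui", "meddra_code", "name")]
  .new_kb(drug_id, indication_cui, terms, "SIDER")
}

#' Build a knowledge base from an ADReCS-style flat file
#'
#' The dialect is a 4-column TSV: `drug_name  ade_name  meddra_code  cui`.
#' All rows whose drug name matches case-insensitively are kept and
#' de-duplicated by CUI.
#'
#' @param path path to the flat TSV.
#' @param drug_name drug name to select.
#' @return An `ade_kb` with provenance `"ADRECS"`.
#' @export
load_adrecs_kb <- function(path, drug_name) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          na.strings = NULL, quote = "", fileEncoding = "UTF-8")
  if (ncol(df) != 4) {
    stop("ADReCS dialect file must have 4 columns, found ", ncol(df))
  }
  names(df) <- c("drug_name", "ade_name", "meddra_code", "cui")
  ok <- df$cui != "" & df$drug_name != ""
  if (any(!ok)) {
    message(sum(!ok), " malformed row(s) skipped in ", basename(path))
    df <- df[ok, , drop = FALSE]
  }
  rows <- df[tolower(df$drug_name) == tolower(drug_name), , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no rows for drug ", drug_name, "; knowledge base is empty")
  }
  terms <- data.frame(cui = rows$cui, meddra_code = rows$meddra_code,
                      name = rows$ade_name, stringsAsFactors = FALSE)
  .new_kb(drug_name, NA_character_, terms, "ADRECS")
}

#' Flexible (hierarchy-expanded) CUI set of a knowledge base
#'
#' Expands every knowledge-base term downward through the hierarchy to all
#' its sub-level terms and returns the union of CUIs. Expansion is downward
#' only (no ancestors), matching the direction in which a high-level label
#' term should cover the finer-grained concepts detected in the data. Terms
#' not resolvable in the hierarchy are kept as exact-only CUIs and counted in
#' a message.
#'
#' @param kb an `ade_kb` object.
#' @param h a [hierarchy()] object.
#' @return Character vector of CUIs, a superset of [kb_cuis()].
#' @export
expand_kb_flexible <- function(kb, h) {
  stopifnot(inherits(kb, "ade_kb"), inherits(h, "hierarchy"))
  exact <- kb_cuis(kb)
  if (length(exact) == 0) return(character(0))

  # resolve by hierarchy code first, then by CUI
  codes <- kb$ade_terms$meddra_code
  resolved <- codes[codes %in% h$terms$meddra_code]
  unresolved_cuis <- kb$ade_terms$cui[!codes %in% h$terms$meddra_code]
  resolved <- union(resolved, codes_for_cuis(h, unresolved_cuis))

  still_unresolved <- setdiff(unresolved_cuis, h$terms$cui)
  if (length(still_unresolved) > 0) {
    message(length(still_unresolved),
            " knowledge-base term(s) not in the hierarchy; kept exact-only")
  }

  desc <- unique(unlist(lapply(resolved, descendants, h = h), use.names = FALSE))
  desc_cuis <- h$terms[desc, "cui"]
  sort(union(exact, desc_cuis))
}
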