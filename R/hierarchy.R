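#' @import data.table
NULL

# Level order, leaf to root. Every edge must connect adjacent levels.
.HIER_LEVELS <- c("LLT", "PT", "HLT", "HLGT", "SOC")

#' Construct a term hierarchy from a table
#'
#' Builds a validated five-level term hierarchy (SOC > HLGT > HLT > PT > LLT,
#' as in MedDRA) from a data frame with one row per (term, parent) pair.
#' Terms may have multiple parents, so the structure is a DAG, not a tree;
#' acyclicity is guaranteed by requiring every edge to connect adjacent
#' levels, which is checked.
#'
#' @param df data frame with columns `meddra_code`, `cui`, `level`, `name`,
#'   `parent_code`. A term with several parents repeats its row with a
#'   different `parent_code`; root (SOC) rows leave `parent_code` empty.
#' @return An object of class `hierarchy`: a list with `terms` (one row per
#'   term), `parents` and `children` (named lists of character vectors keyed
#'   by `meddra_code`).
#' @export
hierarchy <- function(df) {
  req <- c("meddra_code", "cui", "level", "name", "parent_code")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("hierarchy table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in req) df[[col]] <- as.character(df[[col]])
  df$parent_code[is.na(df$parent_code)] <- ""

  bad_level <- setdiff(unique(df$level), .HIER_LEVELS)
  if (length(bad_level) > 0) {
    stop("unknown hierarchy level(s): ", paste(bad_level, collapse = ", "))
  }
  if (any(df$meddra_code == "" | df$cui == "")) {
    stop("meddra_code and cui must be non-empty for every row")
  }

  terms <- unique(df[, c("meddra_code", "cui", "level", "name")])
  if (anyDuplicated(terms$meddra_code)) {
    dup <- unique(terms$meddra_code[duplicated(terms$meddra_code)])
    stop("duplicate meddra_code with conflicting attributes: ",
         paste(dup, collapse = ", "))
  }
  rownames(terms) <- terms$meddra_code

  edges <- df[df$parent_code != "", c("meddra_code", "parent_code")]
  edges <- unique(edges)
  unknown <- setdiff(edges$parent_code, terms$meddra_code)
  if (length(unknown) > 0) {
    stop("parent code(s) absent from the table: ", paste(unknown, collapse = ", "))
  }

  # Adjacent-level constraint: parent level index must be child level index + 1.
  lvl <- match(terms$level, .HIER_LEVELS)
  names(lvl) <- terms$meddra_code
  if (nrow(edges) > 0) {
    non_adjacent <- lvl[edges$parent_code] != lvl[edges$meddra_code] + 1L
    if (any(non_adjacent)) {
      bad <- edges[non_adjacent, , drop = FALSE]
      stop("non-adjacent-level edge(s): ",
           paste(bad$meddra_code, "->", bad$parent_code, collapse = "; "))
    }
  }

  no_parent <- setdiff(terms$meddra_code[terms$level != "SOC"], edges$meddra_code)
  if (length(no_parent) > 0) {
    stop("non-SOC term(s) without a parent: ", paste(no_parent, collapse = ", "))
  }
  soc_with_parent <- intersect(terms$meddra_code[terms$level == "SOC"],
                               edges$meddra_code)
  if (length(soc_with_parent) > 0) {
    stop("SOC term(s) must not have a parent: ",
         paste(soc_with_parent, collapse = ", "))
  }

  parents <- split(edges$parent_code, edges$meddra_code)
  children <- split(edges$meddra_code, edges$parent_code)
  structure(
    list(terms = terms, parents = parents, children = children),
    class = "hierarchy"
  )
}

#' Read a term hierarchy from a TSV file
#'
#' The dialect is a UTF-8 TSV with a header row and columns
#' `meddra_code  cui  level  name  parent_code` (parent_code empty for SOC
#' rows). Rows referencing an unknown parent, duplicated codes with
#' conflicting attributes, and edges that skip levels are all structural
#' errors.
#'
#' @param path path to the hierarchy TSV.
#' @return A [hierarchy()] object.
#' @export
load_hierarchy <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  hierarchy(df)
}

#' Serialize a hierarchy back to its TSV dialect
#'
#' Writes rows in canonical order (level from SOC down, then code, then
#' parent code) so that loading and re-serializing a canonical file is
#' byte-identical.
#'
#' @param h a [hierarchy()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "hierarchy"))
  rows <- do.call(rbind, lapply(seq_len(nrow(h$terms)), function(i) {
    code <- h$terms$meddra_code[i]
    par <- h$parents[[code]]
    if (is.null(par)) par <- ""
    data.frame(meddra_code = code, cui = h$terms$cui[i],
               level = h$terms$level[i], name = h$terms$name[i],
               parent_code = sort(par), stringsAsFactors = FALSE)
  }))
  ord <- order(-match(rows$level, .HIER_LEVELS), rows$meddra_code,
               rows$parent_code)
  rows <- rows[ord, , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' All descendant codes of a term
#'
#' Transitive closure of the child relation, excluding the term itself.
#' This is the downward expansion used by flexible mapping: a high-level
#' knowledge-base term is expanded to every sub-level term below it.
#'
#' @param h a [hierarchy()] object.
#' @param code a `meddra_code` present in `h`.
#' @return Character vector of descendant codes, sorted; empty for leaves.
#' @export
descendants <- function(h, code) {
  stopifnot(inherits(h, "hierarchy"))
  if (!code %in% h$terms$meddra_code) {
    stop("unknown term code: ", code)
  }
  seen <- character(0)
  frontier <- h$children[[code]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(h$children[frontier], use.names = FALSE))
  }
  sort(unique(seen))
}

#' Map concept identifiers to hierarchy codes
#'
#' @param h a [hierarchy()] object.
#' @param cuis character vector of concept identifiers.
#' @return Character vector of the `meddra_code`s whose CUI is in `cuis`
#'   (a CUI may label several codes).
#' @keywords internal
codes_for_cuis <- function(h, cuis) {
  h$terms$meddra_code[h$terms$cui %in% cuis]
}

#' @export
print.hierarchy <- function(x, ...) {
  tab <- table(factor(x$terms$level, levels = rev(.HIER_LEVELS)))
  cat("<hierarchy> ", nrow(x$terms), " terms (",
      paste(names(tab), tab, sep = ":", collapse = ", "), "), ",
      length(unlist(x$parents)), " edges\n", sep = "")
  invisible(x)
}
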