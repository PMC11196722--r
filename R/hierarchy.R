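#' @title LLT/PT/SOC term hierarchies
#' @description
#' A `pv_hierarchy` holds a simplified MedDRA-style hierarchy: a map from
#' lowest-level terms (LLT) to preferred terms (PT), and multi-axial PT to
#' system-organ-class (SOC) links with at most one primary SOC per PT. The
#' HLT/HLGT intermediate levels are not modeled; no operation in this
#' pipeline uses them.
#' @name pv_hierarchy
NULL

#' Load a term hierarchy from a TSV fixture
#'
#' Expects columns `llt_name`, `pt_name`, `soc_name`, `primary_soc_flag`
#' (0/1). Names are normalized with [normalize_terms()]. Duplicate identical
#' rows collapse; an LLT mapped to two different PTs, conflicting primary
#' flags for one (PT, SOC) link, or two primary SOCs for one PT are
#' integrity errors.
#'
#' @param path TSV file path.
#' @return An object of class `pv_hierarchy` with elements `llt_to_pt`
#'   (named character) and `pt_to_socs` (data frame `pt`, `soc`, `primary`).
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  require_columns(df, c("llt_name", "pt_name", "soc_name", "primary_soc_flag"),
                  "hierarchy TSV")
  df$llt_name <- normalize_terms(df$llt_name)
  df$pt_name <- normalize_terms(df$pt_name)
  df$soc_name <- normalize_terms(df$soc_name)
  df$primary <- as.integer(df$primary_soc_flag) == 1L

  llt_pairs <- unique(df[, c("llt_name", "pt_name")])
  dup_llt <- unique(llt_pairs$llt_name[duplicated(llt_pairs$llt_name)])
  if (length(dup_llt))
    stop(sprintf("hierarchy integrity error: LLT(s) mapped to multiple PTs: %s",
                 paste(dup_llt, collapse = ", ")), call. = FALSE)
  llt_to_pt <- setNames(llt_pairs$pt_name, llt_pairs$llt_name)

  links <- unique(df[, c("pt_name", "soc_name", "primary")])
  key <- paste(links$pt_name, links$soc_name, sep = "\r")
  if (anyDuplicated(key))
    stop("hierarchy integrity error: conflicting primary flags for a (PT, SOC) link",
         call. = FALSE)
  n_primary <- tapply(links$primary, links$pt_name, sum)
  if (any(n_primary > 1))
    stop(sprintf("hierarchy integrity error: PT(s) with multiple primary SOCs: %s",
                 paste(names(n_primary)[n_primary > 1], collapse = ", ")),
         call. = FALSE)
  structure(list(llt_to_pt = llt_to_pt,
                 pt_to_socs = data.frame(pt = links$pt_name,
                                         soc = links$soc_name,
                                         primary = links$primary,
                                         stringsAsFactors = FALSE)),
            class = "pv_hierarchy")
}

#' @export
print.pv_hierarchy <- function(x, ...) {
  cat(sprintf("<pv_hierarchy> %d LLTs -> %d PTs -> %d SOCs\n",
              length(x$llt_to_pt), length(unique(x$pt_to_socs$pt)),
              length(unique(x$pt_to_socs$soc))))
  invisible(x)
}

#' Roll a preferred term up to its system organ class(es)
#'
#' MedDRA PTs are multi-axial: a PT may link to several SOCs, one of them
#' primary. `primary_only` returns the single primary SOC (falling back to
#' the first listed SOC, with a warning, if none is flagged); `all` returns
#' every linked SOC.
#'
#' @param pt PT name (normalized internally).
#' @param hierarchy A [pv_hierarchy].
#' @param mode `"primary_only"` (default) or `"all"`.
#' @return Character vector of SOC names.
#' @export
pt_to_soc <- function(pt, hierarchy, mode = c("primary_only", "all")) {
  mode <- match.arg(mode)
  pt <- normalize_terms(pt)
  rows <- hierarchy$pt_to_socs[hierarchy$pt_to_socs$pt == pt, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("unknown PT: %s", pt), call. = FALSE)
  if (mode == "all") return(rows$soc)
  if (any(rows$primary)) return(rows$soc[rows$primary][1])
  warning(sprintf("PT %s has no primary SOC flagged; using first listed", pt))
  rows$soc[1]
}

#' Read a keyword list
#'
#' One keyword per line; `#` starts a comment; blank lines ignored.
#'
#' @param path Text file path.
#' @return Character vector of normalized keywords.
#' @export
read_keywords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  kw <- normalize_terms(lines)
  kw[nzchar(kw)]
}

#' Screen lowest-level terms against a keyword list
#'
#' An LLT matches when any normalized keyword is a substring of its
#' normalized name (case-insensitive by construction). Matched PTs are the
#' image of the matched LLTs under the LLT-to-PT map. This is the mechanism
#' used to assemble developmental-toxicity term sets from keyword lists.
#'
#' @param hierarchy A [pv_hierarchy].
#' @param keywords Nonempty character vector of keywords (normalized
#'   internally), e.g. from [read_keywords()].
#' @return A `pv_keyword_screen` list: `keywords`, `matched_llts`,
#'   `matched_pts`, `n_llt`, `n_pt`.
#' @export
screen_llt_keywords <- function(hierarchy, keywords) {
  keywords <- normalize_terms(keywords)
  keywords <- keywords[nzchar(keywords)]
  if (length(keywords) == 0L)
    stop("keyword list is empty", call. = FALSE)
  llts <- names(hierarchy$llt_to_pt)
  hit <- vapply(llts, function(l)
    any(vapply(keywords, grepl, logical(1), x = l, fixed = TRUE)), logical(1))
  matched_llts <- sort(llts[hit])
  matched_pts <- sort(unique(unname(hierarchy$llt_to_pt[matched_llts])))
  structure(list(keywords = keywords, matched_llts = matched_llts,
                 matched_pts = matched_pts,
                 n_llt = length(matched_llts), n_pt = length(matched_pts)),
            class = "pv_keyword_screen")
}

#' @export
print.pv_keyword_screen <- function(x, ...) {
  cat(sprintf("<pv_keyword_screen> %d keywords -> %d LLTs -> %d PTs\n",
              length(x$keywords), x$n_llt, x$n_pt))
  invisible(x)
}
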