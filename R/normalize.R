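#' Normalize drug, event and leaflet term names
#'
#' Applies the single normalization rule used everywhere names are joined:
#' uppercase, collapse internal whitespace to one space, and strip leading
#' and trailing punctuation/whitespace. Using the same rule for drug names,
#' MedDRA terms and leaflet terms keeps every join in the pipeline
#' consistent.
#'
#' @param x Character vector of raw names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_terms(c("  Foetal   death ", "rash."))
#' @export
normalize_terms <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+", "", x)
  x <- gsub("[[:punct:][:space:]]+$", "", x)
  x
}

# Split a delimiter-joined field into a normalized, sorted, unique set.
# Empty strings drop out; sets are stored sorted so collections compare
# and serialize canonically.
split_terms <- function(x, sep = ";") {
  lapply(strsplit(as.character(x), sep, fixed = TRUE), function(v) {
    v <- normalize_terms(v)
    v <- v[nzchar(v)]
    sort(unique(v))
  })
}

join_terms <- function(lst, sep = ";") {
  vapply(lst, function(v) paste(sort(unique(v)), collapse = sep), character(1))
}

# Round half away from zero (Table-style percentage rounding), as opposed to
# base round()'s round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

percent_of <- function(n, total, digits = 2) {
  round_half_up(100 * n / total, digits)
}
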