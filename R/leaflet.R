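#' @title Leaflet comparison of positive signals
#' @description
#' A drug's information leaflet lists its known adverse reactions. Signals
#' whose PT does not appear in that list are "unlisted" — candidate new
#' adverse reactions. Matching is exact on normalized PT names: leaflet
#' terms pass through the same [normalize_terms()] rule as report events,
#' and no fuzzy or synonym matching is attempted, so the listed/unlisted
#' split is fully reproducible.
#' @name leaflet_compare
NULL

#' Load a drug's known-ADR leaflet list
#'
#' Plain text, one PT per line, `#` comments allowed. Terms are normalized
#' and deduplicated. An empty file yields an empty set with a warning.
#'
#' @param path Text file path.
#' @param drug Generic drug name the leaflet belongs to.
#' @return A `pv_leaflet` list: `drug`, `terms`.
#' @export
read_leaflet <- function(path, drug) {
  terms <- read_keywords(path)
  if (length(terms) == 0L)
    warning(sprintf("leaflet file %s contains no terms", path))
  structure(list(drug = normalize_terms(drug), terms = sort(unique(terms))),
            class = "pv_leaflet")
}

#' @export
print.pv_leaflet <- function(x, ...) {
  cat(sprintf("<pv_leaflet> %s: %d listed terms\n", x$drug, length(x$terms)))
  invisible(x)
}

#' Flag positive signals absent from the leaflet
#'
#' Every input row must belong to the leaflet's drug. A row is unlisted iff
#' its PT (exact normalized match) is not among the leaflet terms. Output is
#' sorted by ROR point estimate descending — the conventional ordering when
#' signals are compared against product information.
#'
#' @param signal_rows Data frame of positive signals for one drug (columns
#'   `drug`, `pt`, `ror` at minimum).
#' @param leaflet A [read_leaflet()] object.
#' @return `signal_rows` with a logical `unlisted` column, sorted by `ror`
#'   descending.
#' @export
flag_unlisted_signals <- function(signal_rows, leaflet) {
  stopifnot(inherits(leaflet, "pv_leaflet"))
  if (nrow(signal_rows)) {
    rd <- unique(normalize_terms(signal_rows$drug))
    if (!identical(rd, leaflet$drug))
      stop(sprintf("signal rows are for %s but leaflet is for %s",
                   paste(rd, collapse = ", "), leaflet$drug), call. = FALSE)
  }
  signal_rows$unlisted <- !normalize_terms(signal_rows$pt) %in% leaflet$terms
  out <- signal_rows[order(-signal_rows$ror), , drop = FALSE]
  rownames(out) <- NULL
  out
}
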