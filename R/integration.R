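# Multi-source interaction-list integration: union with deduplication on
# unordered normalized pair keys, and generic known-item subtraction.

.norm_id <- function(x) toupper(trimws(as.character(x)))

#' Union of interaction lists with deduplication
#'
#' Interaction pairs are keyed on the unordered, case-normalized pair of
#' partner identifiers, so (A, B) and (B, A) collapse to one pair and
#' within-source duplicates are removed. Rows with an empty partner id are
#' skipped with a warning naming their source and line. Source provenance
#' is concatenated per unique pair.
#'
#' @param sources Named list of data frames, each with columns `partner_a`,
#'   `partner_b` (an `evidence` column, if present, is carried along).
#' @return A list with `pairs` (data frame `partner_a`, `partner_b`,
#'   `sources`), `per_source_counts` (named input row counts) and
#'   `n_unique`.
#' @export
dedup_union <- function(sources) {
  stopifnot(is.list(sources), length(sources) >= 1)
  nm <- names(sources)
  if (is.null(nm) || any(nm == "")) nm <- paste0("source", seq_along(sources))
  rows <- list()
  counts <- integer(length(sources))
  for (i in seq_along(sources)) {
    src <- sources[[i]]
    stopifnot(all(c("partner_a", "partner_b") %in% names(src)))
    counts[i] <- nrow(src)
    a <- .norm_id(src$partner_a); b <- .norm_id(src$partner_b)
    bad <- which(a == "" | b == "" | is.na(a) | is.na(b))
    if (length(bad) > 0) {
      warning(sprintf("source '%s': skipped malformed row(s) %s",
                      nm[i], paste(bad, collapse = ", ")), call. = FALSE)
    }
    keep <- setdiff(seq_len(nrow(src)), bad)
    if (length(keep) == 0) next
    rows[[i]] <- data.frame(partner_a = pmin(a[keep], b[keep]),
                            partner_b = pmax(a[keep], b[keep]),
                            source = nm[i], stringsAsFactors = FALSE)
  }
  names(counts) <- nm
  all_rows <- do.call(rbind, rows)
  if (is.null(all_rows) || nrow(all_rows) == 0) {
    return(list(pairs = data.frame(partner_a = character(0),
                                   partner_b = character(0),
                                   sources = character(0)),
                per_source_counts = counts, n_unique = 0L))
  }
  key <- paste(all_rows$partner_a, all_rows$partner_b, sep = "\t")
  prov <- vapply(split(all_rows$source, key),
                 function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  uk <- sort(unique(key))
  parts <- strsplit(uk, "\t", fixed = TRUE)
  pairs <- data.frame(partner_a = vapply(parts, `[`, character(1), 1),
                      partner_b = vapply(parts, `[`, character(1), 2),
                      sources = prov[uk], stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, per_source_counts = counts, n_unique = nrow(pairs))
}

#' Remove known items from a set
#'
#' @param items,known Character vectors of normalized identifiers.
#' @return A list with `remaining` (items not in `known`) and `n_removed`.
#' @export
subtract_set <- function(items, known) {
  items <- unique(as.character(items))
  remaining <- setdiff(items, as.character(known))
  list(remaining = remaining, n_removed = length(items) - length(remaining))
}
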