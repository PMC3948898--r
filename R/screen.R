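# Conformer-ensemble virtual screening: two-phase rank/re-rank selection,
# per-conformer cutoff evaluation, valid-conformer selection against a
# reference structure, and k-of-N consensus hit calling.

.check_score_table <- function(table) {
  need <- c("compound_id", "conformer_id", "primary_score", "secondary_score")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    stop(sprintf("score table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(table)
}

#' Two-phase rank/re-rank ordering of compounds for one conformer
#'
#' Reproduces the two-phase docking selection logic on a score table: the
#' primary (grid-phase) score nominates poses, the secondary (re-rank
#' phase) score orders the final list. Compounds with both scores are
#' ranked by secondary score; compounds with only a primary score follow,
#' ordered by primary score; compounds with neither score (failed docking)
#' are placed last. Ties break lexicographically on compound id, so the
#' ranking is deterministic. Lower score = better by the docking-energy
#' convention; set `better = "higher"` for score types where larger wins.
#'
#' @param table Long-format score table: data frame with columns
#'   `compound_id`, `conformer_id`, `primary_score`, `secondary_score`
#'   (either score may be `NA` for a failed phase).
#' @param conformer Conformer id to rank within.
#' @param better `"lower"` (default) or `"higher"`.
#' @return Character vector of compound ids, best first.
#' @export
two_phase_rank <- function(table, conformer, better = "lower") {
  .check_score_table(table)
  better <- match.arg(better, c("lower", "higher"))
  sub <- table[table$conformer_id == conformer, , drop = FALSE]
  if (nrow(sub) == 0) stop(sprintf("unknown conformer '%s'", conformer), call. = FALSE)
  sgn <- if (better == "lower") 1 else -1
  id <- as.character(sub$compound_id)
  sec <- sgn * sub$secondary_score
  pri <- sgn * sub$primary_score
  tier <- ifelse(!is.na(sec), 1L, ifelse(!is.na(pri), 2L, 3L))
  key <- ifelse(tier == 1L, sec, ifelse(tier == 2L, pri, 0))
  id[order(tier, key, id)]
}

#' Top fraction of a ranked list
#'
#' The first `ceiling(q * n)` compounds; ceiling guarantees a non-empty
#' positive set at the 10% cutoff for any non-empty list.
#'
#' @param ranked Character vector, best first.
#' @param q Fraction in (0, 1\].
#' @return Character vector of the top compounds.
#' @export
top_fraction_set <- function(ranked, q) {
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q <= 0 || q > 1) {
    stop("q must be a fraction in (0, 1]", call. = FALSE)
  }
  utils::head(ranked, ceiling(q * length(ranked)))
}

#' Evaluate one conformer's screening performance across cutoffs
#'
#' For each cutoff fraction the compounds in the top fraction of the
#' conformer's two-phase ranking are called positive and scored against the
#' active/decoy truth labels.
#'
#' @param table Long-format score table (see [two_phase_rank()]).
#' @param conformer Conformer id.
#' @param truth A [truth_set()] whose true set are the actives and false
#'   set the decoys; it must label every compound of the table.
#' @param cutoffs Numeric vector of fractions (default the ten cutoffs
#'   10%, 20%, ..., 100%).
#' @param better Score direction, as in [two_phase_rank()].
#' @return Data frame with one row per cutoff: `conformer`, `cutoff`,
#'   `tp`, `fp`, `tn`, `fn`, `acc`, `ppv`, `fpr`, `positives`.
#' @export
evaluate_conformer_at_cutoffs <- function(table, conformer, truth,
                                          cutoffs = seq(0.1, 1, by = 0.1),
                                          better = "lower") {
  stopifnot(inherits(truth, "truth_set"))
  ranked <- two_phase_rank(table, conformer, better)
  universe <- c(truth$true_set, truth$false_set)
  unlabeled <- setdiff(ranked, universe)
  if (length(unlabeled) > 0) {
    stop(sprintf("%d compound(s) lack an active/decoy label", length(unlabeled)),
         call. = FALSE)
  }
  do.call(rbind, lapply(cutoffs, function(q) {
    pos <- top_fraction_set(ranked, q)
    cc <- confusion_from_sets(pos, truth)
    m <- compute_metrics(cc)
    data.frame(conformer = conformer, cutoff = q,
               tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               acc = m$acc, ppv = m$ppv, fpr = m$fpr,
               positives = cc$tp + cc$fp, stringsAsFactors = FALSE)
  }))
}

#' Select valid conformers against a reference structure
#'
#' A candidate conformer is valid when, at the operative cutoff, it beats
#' the reference structure strictly on all three metrics at once: higher
#' accuracy, higher positive predictive value and lower false-positive
#' rate. Conformers with an undefined PPV never qualify. The reference is
#' always retained.
#'
#' @param evals Data frame of per-conformer evaluations (rows of
#'   [evaluate_conformer_at_cutoffs()] output), all at the same cutoff.
#' @param reference Conformer id of the reference structure.
#' @return Character vector of valid conformer ids (reference first).
#' @export
select_valid_conformers <- function(evals, reference) {
  stopifnot(is.data.frame(evals),
            all(c("conformer", "cutoff", "acc", "ppv", "fpr") %in% names(evals)))
  if (length(unique(evals$cutoff)) != 1) {
    stop("all conformers must be evaluated at the same cutoff", call. = FALSE)
  }
  ref <- evals[evals$conformer == reference, , drop = FALSE]
  if (nrow(ref) != 1) stop("missing (or duplicated) reference evaluation", call. = FALSE)
  cand <- evals[evals$conformer != reference, , drop = FALSE]
  beats <- !is.na(cand$ppv) & !is.na(cand$fpr) & !is.na(ref$ppv) & !is.na(ref$fpr) &
    cand$acc > ref$acc & cand$ppv > ref$ppv & cand$fpr < ref$fpr
  c(reference, as.character(cand$conformer[beats]))
}

#' Consensus hit calling over valid conformers
#'
#' A compound is a consensus hit when it ranks in the top fraction `q` for
#' at least `k` of the valid conformers; `k` equal to the number of valid
#' conformers reproduces the all-valid-conformers model.
#'
#' @param table Long-format score table.
#' @param valid_conformers Character vector of conformer ids.
#' @param q Top fraction in (0, 1\] (default 0.1).
#' @param k Required number of conformer hits, `1 <= k <= length(valid_conformers)`.
#' @param better Score direction.
#' @return A list of class `consensus_result`: `k`, `q`, `valid_conformers`,
#'   `hits` (character vector of compound ids).
#' @export
consensus_hits <- function(table, valid_conformers, q = 0.1, k = length(valid_conformers),
                           better = "lower") {
  stopifnot(length(valid_conformers) >= 1)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) ||
      k < 1 || k > length(valid_conformers)) {
    stop("k must satisfy 1 <= k <= number of valid conformers", call. = FALSE)
  }
  top_sets <- lapply(valid_conformers, function(cf)
    top_fraction_set(two_phase_rank(table, cf, better), q))
  counts <- table(unlist(lapply(top_sets, unique)))
  hits <- sort(names(counts)[counts >= k])
  structure(list(k = as.integer(k), q = q,
                 valid_conformers = valid_conformers, hits = hits),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus hits: %d compound(s) in top %.0f%% of >= %d of %d conformers\n",
              length(x$hits), 100 * x$q, x$k, length(x$valid_conformers)))
  invisible(x)
}

#' Compare k-of-N consensus strategies
#'
#' Builds one validation report per required hit count k = 1..N over the
#' valid conformers. Because hit sets are nested in k, false positives and
#' the false-positive rate are non-increasing in k.
#'
#' @inheritParams consensus_hits
#' @param truth A [truth_set()] of actives (true) and decoys (false).
#' @return List of [strategy_report()] objects, one per k.
#' @export
k_of_n_comparison <- function(table, valid_conformers, q = 0.1, truth,
                              better = "lower") {
  stopifnot(inherits(truth, "truth_set"))
  n <- length(valid_conformers)
  lapply(seq_len(n), function(k) {
    res <- consensus_hits(table, valid_conformers, q, k, better)
    strategy_report(sprintf("hit >= %d of %d conformers", k, n),
                    confusion_from_sets(res$hits, truth))
  })
}
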