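#' Confusion-matrix counts
#'
#' Container for the four counts (TP, FP, TN, FN) from which accuracy,
#' positive predictive value and false-positive rate are computed.
#'
#' @param tp,fp,tn,fn Non-negative integer counts of true positives, false
#'   positives, true negatives and false negatives.
#' @return An object of class `confusion_counts`: a named list with elements
#'   `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(3, 1, 5, 2)
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("tp, fp, tn, fn must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], tn = counts[3], fn = counts[4]),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d (total %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Truth set of known-true and known-false items
#'
#' A validation truth set: two disjoint sets of item identifiers, the
#' known-true items (e.g. experimentally supported interactions, or active
#' compounds) and the known-false items (e.g. contradicted interactions, or
#' decoy compounds).
#'
#' @param true_set,false_set Character vectors of item identifiers;
#'   duplicates are removed. The two sets must be disjoint.
#' @return An object of class `truth_set` with elements `true_set` and
#'   `false_set`.
#' @export
truth_set <- function(true_set, false_set) {
  true_set <- unique(as.character(true_set))
  false_set <- unique(as.character(false_set))
  overlap <- intersect(true_set, false_set)
  if (length(overlap) > 0) {
    stop(sprintf("truth sets overlap on %d item(s), e.g. '%s'",
                 length(overlap), overlap[1]), call. = FALSE)
  }
  if (length(true_set) + length(false_set) == 0) {
    stop("truth universe is empty", call. = FALSE)
  }
  structure(list(true_set = true_set, false_set = false_set),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth set: %d true, %d false items\n",
              length(x$true_set), length(x$false_set)))
  invisible(x)
}

#' Build confusion counts from a predicted-positive set and a truth set
#'
#' Items predicted positive that are absent from the truth universe carry no
#' label and are dropped with a warning; evaluation is restricted to the
#' labelled universe.
#'
#' @param predicted_positive Character vector of items called positive.
#' @param truth A [truth_set()].
#' @return A [confusion_counts()] object.
#' @examples
#' tr <- truth_set(c("a", "b", "c"), c("d", "e", "f", "g"))
#' confusion_from_sets(c("a", "b", "d"), tr)
#' @export
confusion_from_sets <- function(predicted_positive, truth) {
  stopifnot(inherits(truth, "truth_set"))
  pred <- unique(as.character(predicted_positive))
  universe <- c(truth$true_set, truth$false_set)
  outside <- setdiff(pred, universe)
  if (length(outside) > 0) {
    warning(sprintf("%d predicted item(s) outside the truth universe dropped",
                    length(outside)), call. = FALSE)
    pred <- intersect(pred, universe)
  }
  confusion_counts(
    tp = length(intersect(pred, truth$true_set)),
    fp = length(intersect(pred, truth$false_set)),
    tn = length(setdiff(truth$false_set, pred)),
    fn = length(setdiff(truth$true_set, pred))
  )
}

#' Accuracy, positive predictive value and false-positive rate
#'
#' Computes the three validation metrics from confusion counts, each as a
#' percentage:
#' \deqn{ACC = 100 (TP + TN) / (TP + FP + TN + FN)}
#' \deqn{PPV = 100\, TP / (TP + FP)}
#' \deqn{FPR = 100\, FP / (FP + TN)}
#' PPV is undefined (`NA`) when no positives were called (TP + FP = 0), and
#' FPR is undefined when there are no negative-labelled items (FP + TN = 0);
#' the remaining metrics are still reported.
#'
#' @param counts A [confusion_counts()] object.
#' @return A named list of class `metric_triple` with elements `acc`, `ppv`,
#'   `fpr`, each a percentage in \[0, 100\] or `NA` where undefined.
#' @examples
#' compute_metrics(confusion_counts(0, 0, 1458, 15))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stop("cannot compute metrics on zero total count", call. = FALSE)
  acc <- 100 * (counts$tp + counts$tn) / total
  ppv <- if (counts$tp + counts$fp == 0) NA_real_ else
    100 * counts$tp / (counts$tp + counts$fp)
  fpr <- if (counts$fp + counts$tn == 0) NA_real_ else
    100 * counts$fp / (counts$fp + counts$tn)
  structure(list(acc = acc, ppv = ppv, fpr = fpr), class = "metric_triple")
}

#' @export
print.metric_triple <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f%%", v)
  cat(sprintf("ACC=%s PPV=%s FPR=%s\n", fmt(x$acc), fmt(x$ppv), fmt(x$fpr)))
  invisible(x)
}

# Orient scores so that larger = better.
.orient_scores <- function(x, better) {
  better <- match.arg(better, c("lower", "higher"))
  x <- as.numeric(x)
  if (anyNA(x)) stop("scores must be numeric and non-missing", call. = FALSE)
  if (better == "lower") -x else x
}

#' Rank-based AUC for an actives-versus-decoys benchmark
#'
#' The area under the ROC curve computed from ranks:
#' \deqn{AUC = 1 - \frac{1}{N_a N_d} \sum_i N^i_{d>}}
#' where \eqn{N^i_{d>}} is the number of decoys ranked better than active
#' \eqn{i}, ties counting one half. This equals the Mann-Whitney probability
#' that a random active outranks a random decoy.
#'
#' @param active_scores,decoy_scores Numeric score vectors; both non-empty.
#' @param better Either `"lower"` (docking-energy convention, the default)
#'   or `"higher"`: which direction of the score means a better rank.
#' @return AUC as a fraction in \[0, 1\].
#' @examples
#' auc_rank(c(1, 3), c(2, 4), better = "lower")  # 0.75
#' @export
auc_rank <- function(active_scores, decoy_scores, better = "lower") {
  if (length(active_scores) == 0 || length(decoy_scores) == 0) {
    stop("active and decoy score lists must be non-empty", call. = FALSE)
  }
  a <- .orient_scores(active_scores, better)
  d <- .orient_scores(decoy_scores, better)
  na <- length(a); nd <- length(d)
  r <- rank(c(a, d))  # midranks handle ties at half credit
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nd)
}

#' ROC curve over all score thresholds
#'
#' Builds the stepwise ROC curve of the actives-versus-decoys benchmark and
#' its trapezoidal area, which equals [auc_rank()] to numerical precision.
#'
#' @inheritParams auc_rank
#' @return An object of class `roc_curve`: a list with `points` (data frame
#'   of `fpr`, `tpr`, starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_curve <- function(active_scores, decoy_scores, better = "lower") {
  if (length(active_scores) == 0 || length(decoy_scores) == 0) {
    stop("active and decoy score lists must be non-empty", call. = FALSE)
  }
  a <- .orient_scores(active_scores, better)
  d <- .orient_scores(decoy_scores, better)
  na <- length(a); nd <- length(d)
  # sweep thresholds from best to worst score; ties enter together
  thr <- sort(unique(c(a, d)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(a >= t) / na, numeric(1))
  fpr <- vapply(thr, function(t) sum(d >= t) / nd, numeric(1))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Bundle a strategy's validation result
#'
#' @param strategy Label of the prediction strategy.
#' @param counts A [confusion_counts()] object.
#' @return An object of class `strategy_report` with the counts, the derived
#'   [compute_metrics()] triple, and the number of positive calls.
#' @export
strategy_report <- function(strategy, counts) {
  stopifnot(is.character(strategy), length(strategy) == 1,
            inherits(counts, "confusion_counts"))
  structure(list(strategy = strategy, counts = counts,
                 metrics = compute_metrics(counts),
                 positives = counts$tp + counts$fp),
            class = "strategy_report")
}

#' Compare validation strategies in one table
#'
#' Collates strategy reports over a common truth set into a table sorted by
#' accuracy (descending) and flags the best strategy on each metric.
#' Undefined (`NA`) metrics never win a flag and sort last.
#'
#' @param reports A list of [strategy_report()] objects (at least two) that
#'   share one truth universe (equal TP+FN and FP+TN margins).
#' @return A data frame with columns `strategy`, `tp`, `fp`, `tn`, `fn`,
#'   `acc`, `ppv`, `fpr`, `positives`, `best_acc`, `best_ppv`, `best_fpr`.
#' @export
compare_strategies <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 2,
            all(vapply(reports, inherits, logical(1), "strategy_report")))
  margins <- vapply(reports, function(r)
    c(r$counts$tp + r$counts$fn, r$counts$fp + r$counts$tn), numeric(2))
  if (any(margins[1, ] != margins[1, 1]) || any(margins[2, ] != margins[2, 1])) {
    stop("strategy reports come from different truth universes", call. = FALSE)
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(strategy = r$strategy,
               tp = r$counts$tp, fp = r$counts$fp,
               tn = r$counts$tn, fn = r$counts$fn,
               acc = r$metrics$acc, ppv = r$metrics$ppv, fpr = r$metrics$fpr,
               positives = r$positives, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$acc), , drop = FALSE]
  best_if <- function(v, best) !is.na(v) & v == best
  tab$best_acc <- best_if(tab$acc, max(tab$acc, na.rm = TRUE))
  tab$best_ppv <- if (all(is.na(tab$ppv))) FALSE else
    best_if(tab$ppv, max(tab$ppv, na.rm = TRUE))
  tab$best_fpr <- if (all(is.na(tab$fpr))) FALSE else
    best_if(tab$fpr, min(tab$fpr, na.rm = TRUE))
  rownames(tab) <- NULL
  tab
}
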