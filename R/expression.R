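# Expression-context filtering: SAM-style two-class unpaired statistic with
# permutation FDR, fold-change filter, context intersection, and the
# hypergeometric fold-enrichment annotation filter.

#' Log2-transform and median-centre an expression matrix
#'
#' Raw intensities are log2 transformed, then each sample (column) is
#' centred on its median so that array-wide intensity shifts are removed —
#' the minimal assumption-free normalization for two-colour/one-colour
#' intensity data.
#'
#' @param raw Numeric matrix of positive raw intensities, genes x samples.
#' @return Numeric matrix of normalized log2 values, same dimensions.
#' @export
normalize_log2 <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw) || anyNA(raw) || any(raw <= 0)) {
    stop("raw intensities must be positive and non-missing", call. = FALSE)
  }
  lg <- log2(raw)
  sweep(lg, 2, apply(lg, 2, stats::median))
}

.split_classes <- function(classes) {
  classes <- as.character(classes)
  lev <- unique(classes)  # order of appearance defines class1 vs class2
  if (length(lev) != 2) stop("exactly two classes are required", call. = FALSE)
  idx <- list(which(classes == lev[1]), which(classes == lev[2]))
  if (any(lengths(idx) < 2)) stop("each class needs at least 2 samples", call. = FALSE)
  names(idx) <- lev
  idx
}

# d and fold change for one class assignment; s0 may be supplied so
# permutation statistics reuse the observed fudge constant.
.sam_d <- function(m, idx1, idx2, s0 = NULL) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(m[, idx1, drop = FALSE])
  m2 <- rowMeans(m[, idx2, drop = FALSE])
  ss1 <- rowSums((m[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, idx2, drop = FALSE] - m2)^2)
  si <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  if (is.null(s0)) s0 <- stats::median(si)
  list(d = (m2 - m1) / (si + s0), diff = m2 - m1, si = si, s0 = s0)
}

#' SAM-style moderated d statistic and fold change
#'
#' Two-class unpaired statistic \eqn{d_i = (\bar x_{i2} - \bar x_{i1}) /
#' (s_i + s_0)} with \eqn{s_i} the pooled standard error of the mean
#' difference and the fudge constant \eqn{s_0} set to the median of all
#' \eqn{s_i}, stabilizing genes with near-zero variance. The fold change is
#' \eqn{2^{\bar x_{i2} - \bar x_{i1}}} on log2 data (class 2 over class 1,
#' classes taken in order of appearance in `classes`).
#'
#' @param m Normalized log2 expression matrix, genes x samples.
#' @param classes Character/factor vector of length `ncol(m)` with exactly
#'   two levels, each represented by at least 2 samples.
#' @param s0 Optional fudge constant; by default the median of the `s_i`.
#' @return Data frame with columns `gene`, `d`, `fold_change`, `si`, and
#'   attribute `s0`.
#' @export
sam_statistics <- function(m, classes, s0 = NULL) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == length(classes))
  idx <- .split_classes(classes)
  st <- .sam_d(m, idx[[1]], idx[[2]], s0)
  out <- data.frame(gene = if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m),
                    d = st$d, fold_change = 2^st$diff, si = st$si,
                    stringsAsFactors = FALSE)
  attr(out, "s0") <- st$s0
  out
}

# all two-class label assignments (as index sets of class1) when few enough,
# otherwise a seeded random sample of them
.permutation_sets <- function(n, n1, n_perm) {
  n_total <- choose(n, n1)
  if (n_total <= n_perm) {
    asplit(utils::combn(n, n1), 2)
  } else {
    lapply(seq_len(n_perm), function(i) sample(n, n1))
  }
}

#' Differential-expression filter with permutation FDR and fold-change rule
#'
#' Genes are flagged significant when their |d| statistic reaches a delta
#' threshold and their linear fold change is at least `min_fold` in either
#' direction. The delta threshold is chosen as the smallest value on the
#' grid of observed |d| values whose estimated false discovery rate —
#' median permutation-null exceedance count divided by the observed
#' exceedance count — is at most `fdr_max`. Label permutations are fully
#' enumerated when at most `n_perm` distinct assignments exist, otherwise
#' `n_perm` random assignments are drawn; the observed fudge constant s0 is
#' reused for the permutation statistics. If no delta achieves the FDR
#' bound the significant set is empty (with a notice, not an error).
#'
#' @param m Normalized log2 expression matrix, genes x samples.
#' @param classes Two-class sample labels (see [sam_statistics()]).
#' @param min_fold Minimum linear fold change (default 2.0); genes must
#'   change at least this factor up or down. `min_fold = 1` disables the
#'   fold-change rule.
#' @param fdr_max Maximum estimated FDR (default 0.05).
#' @param n_perm Number of permutations (default 200, minimum 50).
#' @param seed Integer seed making the permutation draw reproducible.
#' @return A list of class `de_result`: `table` (per-gene `gene`, `d`,
#'   `fold_change`, `significant`), `delta`, `fdr` (estimated at that
#'   delta, `NA` if no delta qualified), `s0`, `significant` (gene ids).
#' @export
de_filter <- function(m, classes, min_fold = 2.0, fdr_max = 0.05,
                      n_perm = 200, seed = 1) {
  if (n_perm < 50) stop("n_perm must be at least 50", call. = FALSE)
  m <- as.matrix(m)
  idx <- .split_classes(classes)
  obs <- sam_statistics(m, classes)
  s0 <- attr(obs, "s0")
  absd <- abs(obs$d)

  n <- ncol(m); n1 <- length(idx[[1]])
  perms <- withr::with_seed(seed, .permutation_sets(n, n1, n_perm))
  null_absd <- vapply(perms, function(p) {
    abs(.sam_d(m, p, setdiff(seq_len(n), p), s0)$d)
  }, numeric(nrow(m)))  # genes x perms

  delta_grid <- sort(unique(absd))
  sorted_null <- lapply(seq_len(ncol(null_absd)), function(j) sort(null_absd[, j]))
  n_genes <- nrow(m)
  # count of null |d| >= delta in each permutation, via binary search
  null_ge <- function(delta) {
    vapply(sorted_null, function(s) n_genes - findInterval(delta - 1e-12, s),
           numeric(1))
  }
  fdr_at <- vapply(delta_grid, function(delta) {
    obs_ge <- sum(absd >= delta)
    if (obs_ge == 0) return(NA_real_)
    stats::median(null_ge(delta)) / obs_ge
  }, numeric(1))

  ok <- which(!is.na(fdr_at) & fdr_at <= fdr_max)
  if (length(ok) == 0) {
    message("no delta achieves the FDR bound; significant set is empty")
    delta <- Inf; fdr <- NA_real_
  } else {
    delta <- delta_grid[min(ok)]
    fdr <- fdr_at[min(ok)]
  }
  fold_ok <- obs$fold_change >= min_fold | obs$fold_change <= 1 / min_fold
  sig <- absd >= delta & fold_ok
  tab <- data.frame(gene = obs$gene, d = obs$d, fold_change = obs$fold_change,
                    significant = sig, stringsAsFactors = FALSE)
  structure(list(table = tab, delta = delta, fdr = fdr, s0 = s0,
                 significant = obs$gene[sig]),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("DE filter: %d significant gene(s); delta=%.4g, estimated FDR=%s, s0=%.4g\n",
              length(x$significant), x$delta,
              if (is.na(x$fdr)) "NA" else sprintf("%.3f", x$fdr), x$s0))
  invisible(x)
}

#' Restrict a gene set to a differential-expression context
#'
#' Keeps only the genes that appear in at least one of the differential
#' gene sets (union semantics across experiments).
#'
#' @param gene_set Character vector of gene symbols.
#' @param differential_sets List of character vectors of differential genes.
#' @return Character vector, the context-confirmed subset of `gene_set`.
#' @export
context_filter <- function(gene_set, differential_sets) {
  stopifnot(is.list(differential_sets))
  intersect(unique(gene_set), unique(unlist(differential_sets)))
}

#' Hypergeometric annotation enrichment with a fold-enrichment filter
#'
#' For each annotation term the over-representation of the study set is
#' tested with the hypergeometric upper tail \eqn{P(X \ge k)} and the fold
#' enrichment \eqn{(k/n)/(K/N)} is computed, where k = term hits in the
#' study set, n = study-set size, K = term hits in the universe and N =
#' universe size. Terms pass when `p_value < alpha` and
#' `fold_enrichment >= min_fe` (both raw, no multiplicity adjustment —
#' the two-rule filter is the method).
#'
#' @param study Character vector of study-set genes; must be contained in
#'   `universe`.
#' @param term_map Data frame with columns `term`, `gene` mapping genes to
#'   annotation terms.
#' @param universe Character vector of all assayed genes.
#' @param alpha P-value threshold (default 0.05).
#' @param min_fe Minimum fold enrichment (default 2.0).
#' @param keep_all If `TRUE` return all terms with a `significant` column
#'   instead of only the passing ones.
#' @return Data frame with columns `term`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_value` (and `significant` when `keep_all`),
#'   sorted by p-value.
#' @export
enrichment_test <- function(study, term_map, universe,
                            alpha = 0.05, min_fe = 2.0, keep_all = FALSE) {
  stopifnot(is.data.frame(term_map), all(c("term", "gene") %in% names(term_map)))
  study <- unique(as.character(study))
  universe <- unique(as.character(universe))
  if (length(setdiff(study, universe)) > 0) {
    stop("study set contains genes outside the universe", call. = FALSE)
  }
  tm <- term_map[term_map$gene %in% universe, , drop = FALSE]
  n <- length(study); N <- length(universe)
  terms <- split(as.character(tm$gene), as.character(tm$term))
  res <- do.call(rbind, lapply(names(terms), function(t) {
    genes <- unique(terms[[t]])
    K <- length(genes)
    k <- length(intersect(genes, study))
    fe <- if (k == 0) 0 else (k / n) / (K / N)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, n = n, K = K, N = N,
               fold_enrichment = fe, p_value = p, stringsAsFactors = FALSE)
  }))
  res$significant <- res$p_value < alpha & res$fold_enrichment >= min_fe
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  if (keep_all) res else {
    out <- res[res$significant, setdiff(names(res), "significant"), drop = FALSE]
    rownames(out) <- NULL
    out
  }
}
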