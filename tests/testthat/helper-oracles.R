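# Independent brute-force oracles used to freeze expected values.

# all-pairs AUC: fraction of (active, decoy) pairs the active wins,
# ties counting one half
oracle_auc <- function(active, decoy, better = "lower") {
  sgn <- if (better == "lower") -1 else 1
  a <- sgn * active
  d <- sgn * decoy
  wins <- 0
  for (x in a) for (y in d) {
    wins <- wins + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  wins / (length(a) * length(d))
}

# item-by-item confusion recount
oracle_confusion <- function(pred, true_items, false_items) {
  tp <- fp <- tn <- fn <- 0
  for (it in true_items) {
    if (it %in% pred) tp <- tp + 1 else fn <- fn + 1
  }
  for (it in false_items) {
    if (it %in% pred) fp <- fp + 1 else tn <- tn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# hypergeometric upper tail P(X >= k) by direct pmf summation
oracle_hyper_upper <- function(k, K, N, n) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# a small complete score table (no missing cells) plus labels
make_toy_dock <- function(seed, n_actives = 5, n_decoys = 25, n_conformers = 4,
                          delta = -1, lambda = 0.5) {
  gen_docking_scores(synthetic_config(
    seed = seed,
    dock = list(n_actives = n_actives, n_decoys = n_decoys,
                n_conformers = n_conformers, delta = delta,
                lambda = lambda, phi = 0)))
}
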