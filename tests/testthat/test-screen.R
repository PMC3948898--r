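toy_table <- function() {
  data.frame(
    compound_id = c("A", "B", "C", "D"),
    conformer_id = "ref",
    primary_score = c(1.0, 0.5, 0.2, NA),
    secondary_score = c(5.0, 7.0, NA, NA),
    stringsAsFactors = FALSE
  )
}

test_that("two-phase ranking orders by re-rank score with tiered fallbacks", {
  # both-scored by secondary, primary-only next, failed last
  expect_equal(two_phase_rank(toy_table(), "ref"), c("A", "B", "C", "D"))

  # higher-is-better direction flips within tiers
  expect_equal(two_phase_rank(toy_table(), "ref", better = "higher"),
               c("B", "A", "C", "D"))

  # equal secondary scores: id-lexicographic, stable
  tab <- data.frame(compound_id = c("z", "y", "x"), conformer_id = "c1",
                    primary_score = 1:3, secondary_score = c(2, 2, 2))
  expect_equal(two_phase_rank(tab, "c1"), c("x", "y", "z"))
  expect_equal(two_phase_rank(tab[3:1, ], "c1"), c("x", "y", "z"))

  expect_error(two_phase_rank(toy_table(), "nope"), "unknown conformer")
  expect_error(two_phase_rank(toy_table()[, 1:3], "ref"), "secondary_score")
})

test_that("top fraction uses ceiling rounding", {
  ranked10 <- paste0("c", 1:10)
  expect_equal(top_fraction_set(ranked10, 0.1), "c1")
  expect_length(top_fraction_set(paste0("c", 1:15), 0.1), 2)  # ceil(1.5)
  expect_equal(top_fraction_set(ranked10, 1.0), ranked10)
  expect_error(top_fraction_set(ranked10, 0), "fraction")
  expect_error(top_fraction_set(ranked10, 1.1), "fraction")
})

test_that("per-conformer cutoff evaluation matches hand enumeration", {
  tab <- data.frame(
    compound_id = c(paste0("act", 1:2), paste0("dec", 1:8)),
    conformer_id = "c1",
    primary_score = 0,
    secondary_score = c(-5, -4, 1:8))
  truth <- truth_set(paste0("act", 1:2), paste0("dec", 1:8))
  ev <- evaluate_conformer_at_cutoffs(tab, "c1", truth, cutoffs = c(0.2, 1.0))
  # both actives inside top 20%: perfect
  expect_equal(unlist(ev[1, c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 0, tn = 8, fn = 0))
  expect_equal(ev$acc[1], 100)
  # everything positive at 100%: acc = prevalence, fpr = 100
  expect_equal(ev$acc[2], 20)
  expect_equal(ev$fpr[2], 100)
  expect_equal(ev$positives, c(2, 10))

  expect_error(
    evaluate_conformer_at_cutoffs(tab, "c1", truth_set("act1", "dec1")),
    "label")
})

test_that("random scores give chance-level positive rate at a 10% cutoff", {
  sim <- gen_docking_scores(synthetic_config(
    seed = 21, dock = list(n_actives = 100, n_decoys = 900,
                           n_conformers = 1, delta = 0, lambda = 0, phi = 0)))
  ev <- evaluate_conformer_at_cutoffs(sim$table, "conf00", sim$truth,
                                      cutoffs = 0.1)
  # no signal: the top decile is a random sample, FPR ~ 10%
  se <- 100 * sqrt(0.1 * 0.9 / 900)
  expect_lt(abs(ev$fpr - 10), 3 * se)
})

test_that("valid-conformer selection is strict on all three metrics", {
  evals <- data.frame(
    conformer = c("ref", "c1", "c2", "c3", "c4", "c5", "c6"),
    cutoff = 0.1,
    acc = c(89.4, 90.0, 91.0, 92.0, 95.0, 89.4, 90.0),
    ppv = c(5.512, 6.0, 7.0, 8.0, NA, 9.0, 6.0),
    fpr = c(8.602, 8.0, 7.5, 7.0, 0.5, 1.0, 8.602))
  # c1..c3 strictly better on all three; c4 has undefined PPV; c5 ties on
  # acc; c6 ties on fpr -- none of those qualify
  expect_equal(select_valid_conformers(evals, "ref"),
               c("ref", "c1", "c2", "c3"))
  # no candidate better: reference alone
  expect_equal(select_valid_conformers(evals[c(1, 5, 7), ], "ref"), "ref")
  expect_error(select_valid_conformers(evals[-1, ], "ref"), "reference")
  evals2 <- evals; evals2$cutoff[2] <- 0.2
  expect_error(select_valid_conformers(evals2, "ref"), "same cutoff")
})

test_that("consensus hits respect at-least-k semantics and nestedness", {
  # 10 compounds, 2 conformers, both top-1 sets are the same compound
  tab <- data.frame(
    compound_id = rep(paste0("c", 1:10), 2),
    conformer_id = rep(c("k1", "k2"), each = 10),
    primary_score = 0,
    secondary_score = c(c(5, 4, -9, 3, 2, 6, 7, 8, 9, 10),
                        c(5, 4, -9, 3, 2, 6, 7, 8, 9, 10) + 0.1))
  both <- consensus_hits(tab, c("k1", "k2"), q = 0.1, k = 2)
  expect_equal(both$hits, "c3")
  # k = 1 is the union of top sets
  union1 <- consensus_hits(tab, c("k1", "k2"), q = 0.3, k = 1)
  tops <- lapply(c("k1", "k2"), function(cf)
    top_fraction_set(two_phase_rank(tab, cf), 0.3))
  expect_setequal(union1$hits, unique(unlist(tops)))
  # disjoint top sets at full strictness
  tab2 <- tab
  tab2$secondary_score[11:20] <- rev(tab$secondary_score[1:10])
  expect_length(consensus_hits(tab2, c("k1", "k2"), q = 0.1, k = 2)$hits, 0)

  expect_error(consensus_hits(tab, c("k1", "k2"), q = 0.1, k = 3), "k must")
  expect_error(consensus_hits(tab, c("k1", "k2"), q = 0.1, k = 0), "k must")
})

test_that("k-of-N hit sets are nested and counts match brute force", {
  sim <- make_toy_dock(seed = 31, n_actives = 3, n_decoys = 9, n_conformers = 3)
  q <- 0.25
  hits <- lapply(1:3, function(k)
    consensus_hits(sim$table, sim$conformers, q = q, k = k)$hits)
  expect_true(all(hits[[3]] %in% hits[[2]]))
  expect_true(all(hits[[2]] %in% hits[[1]]))

  # independent enumeration: complete table, so ranking is just the order
  # of secondary scores with id tie-break
  n <- 12
  m <- ceiling(q * n)
  count <- setNames(integer(n), sort(unique(sim$table$compound_id)))
  for (cf in sim$conformers) {
    sub <- sim$table[sim$table$conformer_id == cf, ]
    top <- sub$compound_id[order(sub$secondary_score, sub$compound_id)][1:m]
    count[top] <- count[top] + 1L
  }
  reports <- k_of_n_comparison(sim$table, sim$conformers, q = q, truth = sim$truth)
  for (k in 1:3) {
    expected <- names(count)[count >= k]
    cc <- reports[[k]]$counts
    expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
                 oracle_confusion(expected, sim$truth$true_set,
                                  sim$truth$false_set))
  }
  # false positives cannot increase with k
  fps <- vapply(reports, function(r) r$counts$fp, numeric(1))
  expect_true(all(diff(fps) <= 0))
})

test_that("single-conformer consensus reproduces the cutoff evaluation", {
  sim <- make_toy_dock(seed = 32, n_actives = 4, n_decoys = 16, n_conformers = 2)
  q <- 0.2
  res <- consensus_hits(sim$table, "conf01", q = q, k = 1)
  ev <- evaluate_conformer_at_cutoffs(sim$table, "conf01", sim$truth, cutoffs = q)
  expect_setequal(res$hits,
                  top_fraction_set(two_phase_rank(sim$table, "conf01"), q))
  expect_equal(length(res$hits), ev$positives)
})

test_that("failed-docking compounds never enter a top set but keep list length", {
  tab <- data.frame(compound_id = paste0("c", 1:10), conformer_id = "c1",
                    primary_score = c(NA, 1:9), secondary_score = c(NA, 1:9))
  ranked <- two_phase_rank(tab, "c1")
  expect_equal(ranked[10], "c1")       # failed compound ranked last
  expect_length(ranked, 10)            # still counted in the ranked length
  expect_false("c1" %in% top_fraction_set(ranked, 0.5))
})
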