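test_that("program criteria apply each program's threshold rules", {
  microt <- data.frame(mirna = "hsa-miR-1", gene = c("A", "B", "C"),
                       mitg_score = c(0.8, 0.7, 0.69))
  # strictly greater than 0.7: only the first passes
  expect_equal(apply_program_criteria(microt, program_criteria("microt")),
               mti_pair_id("hsa-miR-1", "A"))

  miranda <- data.frame(mirna = "m", gene = c("A", "B", "C"),
                        mirsvr_score = c(-0.05, -0.1, -0.5))
  # inclusive at-or-below -0.1
  expect_equal(apply_program_criteria(miranda, program_criteria("miranda")),
               mti_pair_id("m", c("B", "C")))

  ts <- data.frame(mirna = "m", gene = c("A", "B", "C", "D"),
                   contextplus_score = c(-1.0, -1.67, -1.7, -0.5),
                   conserved_site_count = c(1, 2, 3, 0),
                   pct_value = c(0.5, 0.5, 0.5, 0.5))
  # literal at-or-above -1.67; zero conserved sites always fails
  expect_equal(apply_program_criteria(ts, program_criteria("targetscan")),
               mti_pair_id("m", c("A", "B")))
  # conventional more-negative-is-stronger reading
  expect_equal(apply_program_criteria(
    ts, program_criteria("targetscan", contextplus_direction = "at-or-below")),
    mti_pair_id("m", c("B", "C")))
  # optional conserved-targeting probability filter
  ts$pct_value <- c(0.9, 0.1, 0.5, 0.9)
  expect_equal(apply_program_criteria(
    ts, program_criteria("targetscan", pct_min = 0.5)),
    mti_pair_id("m", "A"))

  expect_error(apply_program_criteria(
    data.frame(mirna = "m", gene = "A"), program_criteria("microt")),
    "mitg_score")
})

test_that("consensus prediction intersects programs and subtracts knowns", {
  sets <- list(c("a", "b", "c"), c("b", "c", "d"), c("c", "b"))
  res <- consensus_predict(sets, known_items = "b")
  expect_equal(res$consensus, "c")
  expect_equal(res$intersection_size, 2)

  # full subtraction
  expect_equal(consensus_predict(sets, known_items = c("b", "c"))$consensus,
               character(0))
  # identical sets, nothing known: idempotence
  expect_setequal(consensus_predict(list(c("a", "b"), c("a", "b")))$consensus,
                  c("a", "b"))
  # order-independence over set arguments
  set.seed(5)
  for (i in 1:10) {
    s <- lapply(1:3, function(j) sample(letters, sample(5:15, 1)))
    ref <- sort(consensus_predict(s)$consensus)
    perm <- sample(3)
    expect_equal(sort(consensus_predict(s[perm])$consensus), ref)
  }
  expect_error(consensus_predict(list(c("a"))))
})

test_that("truth sets follow the fold-change and direct-evidence rules", {
  downreg <- data.frame(mirna = "hsa-let-7b",
                        gene = c("UP1", "UP2", "DOWN1", "CONFL"),
                        log_fold_change = c(0.3, 0.01, -0.5, 0.2))
  evidence <- data.frame(mirna = "hsa-let-7b",
                         gene = c("T1", "CONFL", "WEAK"),
                         evidence_class = c("Reporter assay", "reporter assay",
                                            "microarray"))
  expect_message(tr <- build_truth_sets(downreg, evidence), "direct evidence wins")
  # up-regulated pairs are false; strictly positive fold change required
  expect_setequal(tr$false_set, mti_pair_id("hsa-let-7b", c("UP1", "UP2")))
  # direct-evidence pairs are true; the conflicting pair stays true only
  expect_setequal(tr$true_set, mti_pair_id("hsa-let-7b", c("T1", "CONFL")))
  # down-regulated, non-evidenced pairs are in neither set
  expect_false(mti_pair_id("hsa-let-7b", "DOWN1") %in%
                 c(tr$true_set, tr$false_set))

  bad <- downreg; bad$log_fold_change <- c("0.3", "x", "1", "2")
  expect_error(build_truth_sets(bad, evidence), "non-numeric")
})

test_that("all seven strategies are reported with exact confusion counts", {
  tr <- truth_set(paste0("t", 1:4), paste0("f", 1:6))
  sets <- list(A = c("t1", "t2", "t3", "f1", "f2"),
               B = c("t1", "t2", "f1", "f3"),
               C = c("t1", "t3", "f1", "f4", "outside"))
  reports <- validate_strategies(sets, tr)
  expect_length(reports, 7)
  labels <- vapply(reports, `[[`, character(1), "strategy")
  expect_true(any(grepl("\\(model\\)$", labels)))

  # hand-checked: every strategy against a brute-force recount
  strat_sets <- list(sets$A, sets$B, sets$C,
                     intersect(sets$A, sets$B), intersect(sets$A, sets$C),
                     intersect(sets$B, sets$C),
                     Reduce(intersect, sets))
  universe <- c(tr$true_set, tr$false_set)
  for (i in seq_along(reports)) {
    pred <- intersect(strat_sets[[i]], universe)
    cc <- reports[[i]]$counts
    expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
                 oracle_confusion(pred, tr$true_set, tr$false_set))
  }

  # triple intersection: {t1, f1} -> tp=1 fp=1 tn=5 fn=3
  model <- reports[[7]]$counts
  expect_equal(unlist(model[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 1, tn = 5, fn = 3))
})

test_that("the consensus model never has more false positives than any strategy", {
  for (seed in 1:5) {
    sim <- gen_mti_scores(synthetic_config(
      seed = seed, mti = list(n_true = 60, n_false = 300, rho = 0.3)))
    sets <- list(
      microt = apply_program_criteria(sim$predictions$microt,
                                      program_criteria("microt")),
      miranda = apply_program_criteria(sim$predictions$miranda,
                                       program_criteria("miranda")),
      targetscan = apply_program_criteria(sim$predictions$targetscan,
                                          program_criteria("targetscan")))
    reports <- validate_strategies(sets, sim$truth)
    fps <- vapply(reports, function(r) r$counts$fp, numeric(1))
    fprs <- vapply(reports, function(r) r$metrics$fpr, numeric(1))
    expect_true(all(fps[7] <= fps))
    expect_true(all(fprs[7] <= fprs, na.rm = TRUE))
  }
})

test_that("a zero-positive consensus reproduces the high-accuracy silent model", {
  # truth universe shaped like a small-true/large-false validation set
  tr <- truth_set(paste0("t", 1:15), paste0("f", 1:1458))
  f <- function(i) paste0("f", i)
  sets <- list(A = c(paste0("t", 1:5), f(1:20), f(31:100)),
               B = c(paste0("t", 6:10), f(1:10), f(21:30), f(101:170)),
               C = c(paste0("t", 11:15), f(11:30), f(171:240)))
  reports <- validate_strategies(sets, tr)
  model <- reports[[7]]
  expect_equal(model$positives, 0)
  expect_true(is.na(model$metrics$ppv))
  expect_equal(round(model$metrics$acc, 3), 98.982)
  tab <- compare_strategies(reports)
  expect_equal(tab$strategy[1], model$strategy)  # highest ACC despite no calls
})
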