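# miRNA-target consensus prediction: per-program reliability criteria,
# three-way intersection with known-item subtraction, validation harness.

.norm_mirna <- function(x) tolower(trimws(as.character(x)))
.norm_gene  <- function(x) toupper(trimws(as.character(x)))

#' Canonical (miRNA, gene) pair identifiers
#'
#' miRNA names are lower-cased, gene symbols upper-cased, then joined as
#' `mirna|GENE` so set operations are identifier-case robust.
#'
#' @param mirna,gene Character vectors of equal length.
#' @return Character vector of pair keys.
#' @export
mti_pair_id <- function(mirna, gene) {
  paste(.norm_mirna(mirna), .norm_gene(gene), sep = "|")
}

#' Per-program reliability criteria
#'
#' Threshold rules defining a "reliable" prediction for each of the three
#' supported programs:
#' \describe{
#'   \item{microt}{miTG confidence score strictly greater than
#'     `mitg_threshold` (default 0.7, a high-precision cut; higher = more
#'     confident).}
#'   \item{miranda}{mirSVR downregulation score at or below
#'     `mirsvr_threshold` (default -0.1; more negative = stronger
#'     predicted repression).}
#'   \item{targetscan}{context+ score compared against
#'     `contextplus_threshold` (default -1.67), at least
#'     `min_conserved_sites` conserved seed sites (default 1), and a
#'     conserved-targeting probability `pct_value` of at least `pct_min`
#'     (default 0, i.e. no filter). `contextplus_direction` selects how the
#'     context+ threshold is read: `"at-or-above"` keeps scores >= the
#'     threshold, while `"at-or-below"` applies the conventional
#'     more-negative-is-stronger reading and keeps scores <= the threshold.}
#' }
#'
#' @param program One of `"microt"`, `"miranda"`, `"targetscan"`.
#' @param mitg_threshold,mirsvr_threshold,contextplus_threshold Numeric
#'   thresholds (see Details).
#' @param contextplus_direction `"at-or-above"` (default) or `"at-or-below"`.
#' @param pct_min Minimum conserved-targeting probability in \[0, 1\].
#' @param min_conserved_sites Minimum number of conserved sites (integer).
#' @return An object of class `program_criteria`.
#' @export
program_criteria <- function(program = c("microt", "miranda", "targetscan"),
                             mitg_threshold = 0.7,
                             mirsvr_threshold = -0.1,
                             contextplus_threshold = -1.67,
                             contextplus_direction = c("at-or-above", "at-or-below"),
                             pct_min = 0,
                             min_conserved_sites = 1L) {
  program <- match.arg(program)
  contextplus_direction <- match.arg(contextplus_direction)
  stopifnot(is.finite(mitg_threshold), is.finite(mirsvr_threshold),
            is.finite(contextplus_threshold),
            pct_min >= 0, pct_min <= 1, min_conserved_sites >= 0)
  structure(list(program = program,
                 mitg_threshold = mitg_threshold,
                 mirsvr_threshold = mirsvr_threshold,
                 contextplus_threshold = contextplus_threshold,
                 contextplus_direction = contextplus_direction,
                 pct_min = pct_min,
                 min_conserved_sites = as.integer(min_conserved_sites)),
            class = "program_criteria")
}

.require_field <- function(records, field, program) {
  if (!field %in% names(records) || anyNA(records[[field]])) {
    stop(sprintf("program '%s' records require a complete '%s' column",
                 program, field), call. = FALSE)
  }
  records[[field]]
}

#' Select reliable predictions under a program's criteria
#'
#' Applies every threshold relevant to `criteria$program` and returns the
#' pair identifiers of records passing all of them.
#'
#' @param records Data frame of predictions from one program, with columns
#'   `mirna`, `gene`, and the score columns that program requires:
#'   `mitg_score` (microt), `mirsvr_score` (miranda), or
#'   `contextplus_score`, `conserved_site_count` and optionally `pct_value`
#'   (targetscan; `pct_value` is required only when `pct_min > 0`).
#' @param criteria A [program_criteria()] object.
#' @return Character vector of passing [mti_pair_id()] keys.
#' @export
apply_program_criteria <- function(records, criteria) {
  stopifnot(is.data.frame(records), inherits(criteria, "program_criteria"))
  if (nrow(records) == 0) return(character(0))
  for (col in c("mirna", "gene")) .require_field(records, col, criteria$program)
  pass <- switch(
    criteria$program,
    microt = {
      s <- .require_field(records, "mitg_score", "microt")
      s > criteria$mitg_threshold
    },
    miranda = {
      s <- .require_field(records, "mirsvr_score", "miranda")
      s <= criteria$mirsvr_threshold
    },
    targetscan = {
      cx <- .require_field(records, "contextplus_score", "targetscan")
      ns <- .require_field(records, "conserved_site_count", "targetscan")
      ok_cx <- if (criteria$contextplus_direction == "at-or-above") {
        cx >= criteria$contextplus_threshold
      } else {
        cx <= criteria$contextplus_threshold
      }
      ok <- ok_cx & ns >= criteria$min_conserved_sites
      if (criteria$pct_min > 0) {
        pct <- .require_field(records, "pct_value", "targetscan")
        ok <- ok & pct >= criteria$pct_min
      }
      ok
    }
  )
  unique(mti_pair_id(records$mirna, records$gene)[pass])
}

#' Consensus prediction by intersection with known-item subtraction
#'
#' Intersects the per-program reliable sets and removes already-known items,
#' the model that yields novel consensus predictions.
#'
#' @param per_program_sets List (length >= 2) of character vectors, one
#'   reliable-item set per program.
#' @param known_items Character vector of known items to subtract.
#' @return A list with `consensus` (the novel items), `intersection` (the
#'   pre-subtraction intersection) and `intersection_size`.
#' @export
consensus_predict <- function(per_program_sets, known_items = character(0)) {
  stopifnot(is.list(per_program_sets), length(per_program_sets) >= 2)
  inter <- Reduce(intersect, lapply(per_program_sets, unique))
  list(consensus = setdiff(inter, known_items),
       intersection = inter,
       intersection_size = length(inter))
}

#' Build validation truth sets from fold changes and evidence codes
#'
#' Known-false interactions are pairs whose protein log fold change under
#' the miRNA's over-expression exceeds zero (the protein went up, which
#' contradicts targeting). Known-true interactions are pairs carrying a
#' direct functional evidence class (e.g. reporter gene assay). A pair
#' qualifying for both is kept as true only — direct experimental evidence
#' overrides the expression-based rule — with the conflict count reported
#' via `message()`, so the two sets stay disjoint as the metrics require.
#'
#' @param downreg_table Data frame with columns `mirna`, `gene`,
#'   `log_fold_change` (one value per pair, numeric).
#' @param evidence_table Data frame with columns `mirna`, `gene`,
#'   `evidence_class`.
#' @param direct_classes Character vector of evidence classes accepted as
#'   direct functional evidence.
#' @return A [truth_set()] over [mti_pair_id()] keys.
#' @export
build_truth_sets <- function(downreg_table, evidence_table,
                             direct_classes = c("reporter assay",
                                                "western blot",
                                                "qrt-pcr")) {
  stopifnot(is.data.frame(downreg_table), is.data.frame(evidence_table))
  lfc <- suppressWarnings(as.numeric(downreg_table$log_fold_change))
  if (anyNA(lfc)) stop("non-numeric log_fold_change value", call. = FALSE)
  false_set <- unique(mti_pair_id(downreg_table$mirna,
                                  downreg_table$gene)[lfc > 0])
  ev <- tolower(trimws(as.character(evidence_table$evidence_class)))
  true_set <- unique(mti_pair_id(evidence_table$mirna,
                                 evidence_table$gene)[ev %in% tolower(direct_classes)])
  conflict <- intersect(true_set, false_set)
  if (length(conflict) > 0) {
    message(sprintf("%d pair(s) in both truth categories kept as true (direct evidence wins)",
                    length(conflict)))
    false_set <- setdiff(false_set, conflict)
  }
  truth_set(true_set, false_set)
}

#' Validate all intersection strategies against a truth set
#'
#' Given the three per-program reliable sets, evaluates the seven candidate
#' strategies — each single program, each pairwise intersection, and the
#' triple intersection (the consensus model) — against the truth set.
#' Positives are each strategy's set restricted to the truth universe.
#'
#' @param per_program_sets Named list of exactly 3 character vectors.
#' @param truth A [truth_set()].
#' @return List of 7 [strategy_report()] objects; the triple intersection is
#'   labelled with a `" (model)"` suffix.
#' @export
validate_strategies <- function(per_program_sets, truth) {
  stopifnot(is.list(per_program_sets), length(per_program_sets) == 3,
            inherits(truth, "truth_set"))
  nm <- names(per_program_sets)
  if (is.null(nm) || any(nm == "")) nm <- paste0("program", 1:3)
  universe <- c(truth$true_set, truth$false_set)
  sets <- lapply(per_program_sets, function(s) intersect(unique(s), universe))
  combos <- c(lapply(1:3, identity),
              list(c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3)))
  lapply(combos, function(idx) {
    pred <- Reduce(intersect, sets[idx])
    label <- paste(nm[idx], collapse = " ∩ ")
    if (length(idx) == 3) label <- paste0(label, " (model)")
    strategy_report(label, confusion_from_sets(pred, truth))
  })
}
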