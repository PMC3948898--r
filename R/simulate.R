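# Seeded synthetic-data generators reproducing the statistical structure
# each pipeline stage assumes, so every stage runs without external
# resources. All outputs are fully determined by the config seed.

#' Configuration for the synthetic-data generators
#'
#' Bundles a seed with the distribution parameters of the four generators.
#' Defaults mirror the study conditions the pipeline is designed for:
#' a DUD-style benchmark of 39 actives and 1448 decoys over an ensemble of
#' 26 receptor conformers, and an miRNA-target validation set with a few
#' dozen true pairs against ~1500 expression-contradicted false pairs.
#'
#' @param seed Integer seed; all generator output is a deterministic
#'   function of the config (including this seed).
#' @param mti List: `n_true`, `n_false` (pair counts), `sensitivity` and
#'   `specificity` (length-3 per-program probabilities), `rho`
#'   (inter-program latent correlation in \[0, 1)).
#' @param dock List: `n_actives`, `n_decoys`, `n_conformers`, `delta`
#'   (active-class mean shift of the re-rank score, in score units;
#'   negative = actives score better), `lambda` (compound latent loading in
#'   \[0, 1); between-conformer score correlation is `lambda^2`), `phi`
#'   (per-cell missing/failed-docking probability in \[0, 1)).
#' @param expr List: `n_genes`, `n_de` (planted differential genes),
#'   `n_per_class` (length-2 sample counts), `effect` (log2 shift added to
#'   planted genes in class 2), `sd` (residual noise standard deviation on
#'   the log2 scale).
#' @param annot List: `n_terms`, `universe_size`, `term_size`, `study_size`,
#'   `factor` (planted fold enrichment of the first term in the study set).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             mti = list(),
                             dock = list(),
                             expr = list(),
                             annot = list()) {
  defaults <- list(
    mti = list(n_true = 40, n_false = 1500,
               sensitivity = c(0.8, 0.8, 0.8),
               specificity = c(0.9, 0.9, 0.9),
               rho = 0),
    dock = list(n_actives = 39, n_decoys = 1448, n_conformers = 26,
                delta = -1.0, lambda = 0.5, phi = 0),
    expr = list(n_genes = 500, n_de = 20, n_per_class = c(4, 4),
                effect = 2.0, sd = 0.25),
    annot = list(n_terms = 20, universe_size = 1000, term_size = 50,
                 study_size = 50, factor = 10)
  )
  cfg <- list(seed = as.integer(seed),
              mti = utils::modifyList(defaults$mti, mti),
              dock = utils::modifyList(defaults$dock, dock),
              expr = utils::modifyList(defaults$expr, expr),
              annot = utils::modifyList(defaults$annot, annot))
  with(cfg$mti, stopifnot(n_true >= 1, n_false >= 1,
                          length(sensitivity) == 3, length(specificity) == 3,
                          all(sensitivity >= 0 & sensitivity <= 1),
                          all(specificity >= 0 & specificity <= 1),
                          rho >= 0, rho < 1))
  with(cfg$dock, stopifnot(n_actives >= 1, n_decoys >= 1, n_conformers >= 1,
                           delta <= 0, lambda >= 0, lambda < 1,
                           phi >= 0, phi < 1))
  with(cfg$expr, stopifnot(n_genes >= 1, n_de >= 0, n_de <= n_genes,
                           length(n_per_class) == 2, all(n_per_class >= 2),
                           sd > 0))
  with(cfg$annot, stopifnot(n_terms >= 1, universe_size >= term_size,
                            term_size >= 1, study_size >= 1,
                            study_size <= universe_size, factor >= 0))
  structure(cfg, class = "synthetic_config")
}

# Latent-factor pass/fail indicators: one shared N(0,1) factor per item and
# an independent residual per program give each program marginal pass
# probability `prob` with inter-program latent correlation rho.
.latent_pass <- function(n, probs, rho) {
  u <- stats::rnorm(n)
  sapply(seq_along(probs), function(p) {
    z <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
    stats::pnorm(z) < probs[p]
  })
}

# Map a pass indicator to a score uniform within the passing or failing
# region of each program's threshold rule.
.place_score <- function(pass, pos, pass_fun, fail_fun) {
  ifelse(pass, pass_fun(pos), fail_fun(pos))
}

#' Generate per-program miRNA-target predictions with a planted truth set
#'
#' Each true pair passes program p's reliability thresholds with
#' probability `sensitivity[p]`, each false pair with probability
#' `1 - specificity[p]`; cross-program dependence comes from a shared
#' latent factor with correlation `rho`. Scores are placed inside the
#' passing or failing region of each program's threshold rule, so
#' [apply_program_criteria()] with default [program_criteria()] recovers
#' exactly the planted indicators.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `predictions` (named list of data frames for programs
#'   `microt`, `miranda`, `targetscan`), `truth` (a [truth_set()] of pair
#'   ids), `planted` (logical pass matrix, pairs x programs).
#' @export
gen_mti_scores <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  p <- cfg$mti
  withr::with_seed(cfg$seed, {
    n <- p$n_true + p$n_false
    is_true <- c(rep(TRUE, p$n_true), rep(FALSE, p$n_false))
    mirna <- "hsa-mir-sim"
    gene <- sprintf("G%05d", seq_len(n))
    probs_true <- p$sensitivity
    probs_false <- 1 - p$specificity
    pass <- matrix(NA, n, 3)
    pass[is_true, ] <- .latent_pass(p$n_true, probs_true, p$rho)
    pass[!is_true, ] <- .latent_pass(p$n_false, probs_false, p$rho)
    pos <- matrix(stats::runif(3 * n), n, 3)  # position within score region

    predictions <- list(
      microt = data.frame(
        program = "microt", mirna = mirna, gene = gene,
        mitg_score = .place_score(pass[, 1], pos[, 1],
                                  function(u) 0.7 + 0.3 * (0.001 + 0.999 * u),
                                  function(u) 0.7 * u),
        stringsAsFactors = FALSE),
      miranda = data.frame(
        program = "miranda", mirna = mirna, gene = gene,
        mirsvr_score = .place_score(pass[, 2], pos[, 2],
                                    function(u) -0.1 - 2 * u,
                                    function(u) -0.099 + u),
        stringsAsFactors = FALSE),
      targetscan = data.frame(
        program = "targetscan", mirna = mirna, gene = gene,
        contextplus_score = .place_score(pass[, 3], pos[, 3],
                                         function(u) -1.67 + u,
                                         function(u) -1.671 - 2 * u),
        conserved_site_count = sample(1:3, n, replace = TRUE),
        pct_value = stats::runif(n, 0.3, 0.9),
        stringsAsFactors = FALSE)
    )
    pair <- mti_pair_id(mirna, gene)
    list(predictions = predictions,
         truth = truth_set(pair[is_true], pair[!is_true]),
         planted = pass)
  })
}

#' Generate a conformer-ensemble docking score table with labels
#'
#' Re-rank scores follow a shifted bi-normal latent-factor model:
#' \deqn{s_{ic} = \mu_{class(i)} + \lambda z_i + \sqrt{1-\lambda^2}\,
#' \epsilon_{ic}}
#' with \eqn{z_i} and \eqn{\epsilon_{ic}} independent standard normal,
#' \eqn{\mu_{active} = \Delta \le 0} (lower = better) and
#' \eqn{\mu_{decoy} = 0}. The primary (grid-phase) score is the re-rank
#' score plus independent unit-variance noise. Each (compound, conformer)
#' cell fails (both scores missing) independently with probability `phi`.
#' With `lambda = 0` the single-conformer AUC has closed form
#' \eqn{\Phi(-\Delta/\sqrt 2)}, and the between-conformer score
#' correlation is \eqn{\lambda^2}.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `table` (long data frame `compound_id`, `conformer_id`,
#'   `primary_score`, `secondary_score`), `labels` (data frame
#'   `compound_id`, `class`), `truth` (a [truth_set()]: actives true,
#'   decoys false), `conformers` (ids; the first, `"conf00"`, is the
#'   reference structure).
#' @export
gen_docking_scores <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  p <- cfg$dock
  withr::with_seed(cfg$seed, {
    n <- p$n_actives + p$n_decoys
    compound <- sprintf("cmp%05d", seq_len(n))
    class <- c(rep("active", p$n_actives), rep("decoy", p$n_decoys))
    mu <- ifelse(class == "active", p$delta, 0)
    conf <- sprintf("conf%02d", seq_len(p$n_conformers) - 1L)
    z <- stats::rnorm(n)
    tab <- do.call(rbind, lapply(seq_along(conf), function(j) {
      eps <- stats::rnorm(n)
      sec <- mu + p$lambda * z + sqrt(1 - p$lambda^2) * eps
      pri <- sec + stats::rnorm(n)
      failed <- stats::runif(n) < p$phi
      data.frame(compound_id = compound, conformer_id = conf[j],
                 primary_score = ifelse(failed, NA_real_, pri),
                 secondary_score = ifelse(failed, NA_real_, sec),
                 stringsAsFactors = FALSE)
    }))
    list(table = tab,
         labels = data.frame(compound_id = compound, class = class,
                             stringsAsFactors = FALSE),
         truth = truth_set(compound[class == "active"],
                           compound[class == "decoy"]),
         conformers = conf)
  })
}

#' Generate a two-class expression matrix with planted differential genes
#'
#' Log2 values are a per-gene baseline plus Gaussian noise; the first
#' `n_de` genes additionally receive the `effect` log2 shift in class 2
#' samples, so their expected linear fold change is `2^effect`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `matrix` (genes x samples log2 values), `classes`
#'   (sample labels `"class1"`, `"class2"`), `planted` (planted gene ids).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  p <- cfg$expr
  withr::with_seed(cfg$seed, {
    n1 <- p$n_per_class[1]; n2 <- p$n_per_class[2]
    genes <- sprintf("gene%04d", seq_len(p$n_genes))
    baseline <- stats::rnorm(p$n_genes, mean = 7, sd = 1)
    m <- baseline + matrix(stats::rnorm(p$n_genes * (n1 + n2), sd = p$sd),
                           p$n_genes, n1 + n2)
    if (p$n_de > 0) {
      m[seq_len(p$n_de), n1 + seq_len(n2)] <-
        m[seq_len(p$n_de), n1 + seq_len(n2)] + p$effect
    }
    dimnames(m) <- list(genes, sprintf("s%02d", seq_len(n1 + n2)))
    list(matrix = m,
         classes = rep(c("class1", "class2"), c(n1, n2)),
         planted = genes[seq_len(p$n_de)])
  })
}

#' Generate an annotation universe with one enriched term
#'
#' Terms are assigned `term_size` genes uniformly from the universe. The
#' study set over-samples the first (planted) term's genes so that its
#' expected fold enrichment equals `factor`; the remaining study genes are
#' drawn uniformly from the rest of the universe.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `term_map` (data frame `term`, `gene`), `study`
#'   (character vector), `universe` (character vector), `planted_term`.
#' @export
gen_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  p <- cfg$annot
  withr::with_seed(cfg$seed, {
    universe <- sprintf("U%05d", seq_len(p$universe_size))
    terms <- sprintf("TERM%03d", seq_len(p$n_terms))
    term_map <- do.call(rbind, lapply(terms, function(t) {
      data.frame(term = t, gene = sample(universe, p$term_size),
                 stringsAsFactors = FALSE)
    }))
    planted_genes <- term_map$gene[term_map$term == terms[1]]
    # expected hits under enrichment factor f: k = f * n * K / N
    k_target <- round(p$factor * p$study_size * p$term_size / p$universe_size)
    k_target <- min(k_target, p$term_size, p$study_size)
    if (k_target < 1) stop("study set would be empty of planted-term genes",
                           call. = FALSE)
    hits <- sample(planted_genes, k_target)
    rest <- sample(setdiff(universe, planted_genes), p$study_size - k_target)
    list(term_map = term_map,
         study = sample(c(hits, rest)),
         universe = universe,
         planted_term = terms[1])
  })
}
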