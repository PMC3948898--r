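---
title: "Consensus evidence models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus evidence models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conscreen)
```

This vignette documents the statistical models the package implements,
the parameters that matter, the numerical conventions adopted where a
choice had to be made, and what the synthetic-data generators do and do
not emulate.

## 1. Validation metrics

Every model in the package is validated against a *truth set*: disjoint
sets of known-true and known-false items (interaction pairs, or
active/decoy compounds). A strategy's positive calls, restricted to the
truth universe, yield the confusion counts TP, FP, TN, FN, from which

$$\mathrm{ACC} = 100\,\frac{TP+TN}{TP+FP+TN+FN},\qquad
  \mathrm{PPV} = 100\,\frac{TP}{TP+FP},\qquad
  \mathrm{FPR} = 100\,\frac{FP}{FP+TN}.$$

Conventions:

* **PPV with no positive calls is undefined (`NA`), not 0 or 100.** A
  consensus model that calls nothing is still a meaningful strategy — it
  attains the prevalence-driven accuracy $\,100\,|F|/(|T|+|F|)$ — so the
  metrics are kept independent: ACC and FPR are reported, PPV is `NA`.
  `NA` metrics never win a best-strategy flag and serialize as `NA` (TSV)
  or `null` (JSON).
* **Predictions outside the truth universe are dropped with a warning**,
  not counted as errors: unlabelled items carry no evidence either way.
* **Percentages are rendered to 3 decimals** in reports, matching the
  precision at which such validation tables are conventionally printed.

The ranked-screen summary is the rank-based AUC, the Mann–Whitney
probability that a random active outranks a random decoy; **ties
contribute 1/2**, the standard midrank convention. The stepwise ROC
curve's trapezoidal area equals this statistic to numerical precision
(asserted at 1e-9 in the tests), and reversing the score direction maps
AUC to 1 − AUC on tie-free data.

## 2. miRNA–target consensus prediction

Each program has its own reliability rule, applied to its native score:

| program | rule | default |
|---|---|---|
| microT-style | confidence (miTG) score strictly above threshold | > 0.7 |
| miRanda-style | mirSVR downregulation score at or below threshold | ≤ −0.1 |
| TargetScan-style | context+ score vs threshold, ≥ 1 conserved site, optional P~CT~ minimum | ≥ −1.67, ≥ 1 site, no P~CT~ filter |

Two rules deserve comment. The miTG comparison is strict (`>`), while the
mirSVR and context+ comparisons are inclusive, following the usual
phrasing of each program's recommended cutoffs. The context+ rule is
applied **literally as "at or above −1.67"** by default; because context+
scores are conventionally more-negative-is-stronger, a
`contextplus_direction = "at-or-below"` flag implements the inverted
reading. We default to the literal rule and expose the flag rather than
silently deciding which was intended. The optional P~CT~ filter defaults
to "off" (`pct_min = 0`) because no specific probability cutoff is
standard.

The consensus model intersects the per-program reliable sets and
subtracts known items. Validation compares seven strategies — 3 single
programs, 3 pairwise intersections, the triple intersection — against a
truth set in which:

* **false MTIs** are pairs whose protein log fold change under the
  miRNA's over-expression is strictly positive (the protein went *up*,
  contradicting targeting); a fold change of exactly zero is evidence of
  nothing and enters neither set;
* **true MTIs** are pairs carrying direct functional evidence (reporter
  assay and similar evidence classes, configurable).

A pair qualifying for both categories is kept as **true only**: direct
experimental evidence overrides a single expression measurement, and the
metrics require disjoint truth sets. The conflict count is reported. This
resolution rule is a package design choice — the alternative (dropping
conflicted pairs entirely) changes counts only marginally but discards
usable positives.

Identifiers are normalized before any set operation (miRNA names
lower-cased, gene symbols upper-cased); no alias resolution is attempted,
a documented limitation when mixing sources that use different symbol
generations.

## 3. Conformer-ensemble screening

The two-phase procedure ranks compounds within one conformer by the
secondary (re-rank) score; compounds that only survived the primary
(grid) phase follow, ordered by primary score; compounds that failed
docking entirely are placed last. Ties break lexicographically on
compound id so rankings are deterministic. Lower score = better by the
docking-energy convention (a direction flag covers higher-is-better
scores).

Numerical conventions:

* **Top-fraction rounding is `ceiling(q·n)`**: the top-10% set is never
  empty for a non-empty list, and `n = 10, q = 0.1` selects exactly one
  compound.
* **A failed compound can never enter that conformer's top set, but it
  still counts in the ranked length.** A failed docking is treated as
  evidence against binding, not as missing data; denominators therefore
  stay fixed across conformers.
* **Valid-conformer selection is strict on all three metrics
  simultaneously**: a candidate must beat the reference's ACC *and* PPV
  *and* FPR at the operative cutoff (default 10%, the operative choice
  for this kind of screen). Equality on any metric disqualifies; an
  undefined PPV disqualifies. The reference is always retained.
* **k-of-N consensus uses at-least-k semantics**, so hit sets are nested
  in k and FP/FPR are non-increasing in k by construction — the property
  that makes the strategy comparison monotone and interpretable. Exact-k
  semantics would break nestedness and is not offered.

## 4. Expression context and annotation enrichment

The differential filter is a SAM-style two-class unpaired analysis on
log2-transformed, per-sample median-centred data. Median centring is the
minimal assumption-free normalization; quantile or loess normalization of
raw microarray feature files is out of scope. Per gene,

$$d_i = \frac{\bar x_{i2}-\bar x_{i1}}{s_i + s_0},$$

with $s_i$ the pooled standard error of the mean difference and the fudge
constant $s_0$ set to the **median of all $s_i$** — a common
simplification of the original quantile-search tuning, adequate because
$s_0$ only needs to be on the scale of typical standard errors to tame
near-zero-variance genes. Significance uses a delta threshold on $|d|$
**and** a linear fold-change requirement (default ≥ 2.0 in either
direction). Delta is chosen by exact search on the grid of observed
$|d|$ values: the smallest delta whose estimated FDR — median
permutation-null exceedance count over observed exceedances — is within
the bound (default 5%). Class labels are permuted 200 times by default,
with full enumeration whenever at most 200 distinct assignments exist
(at 4+4 samples there are 70, so the estimate is exact); the observed
$s_0$ is reused in permutations. If no delta meets the bound the
significant set is empty with a notice — an honest "nothing passes", not
an error.

Context filtering intersects a gene set with the union of the
differential sets from the available experiments; it is idempotent and
monotone in both arguments.

Annotation enrichment uses the raw hypergeometric upper tail
$P(X \ge k)$ and fold enrichment $(k/n)/(K/N)$, retaining terms with
$p < 0.05$ **and** fold enrichment ≥ 2.0. No multiplicity adjustment is
applied: the two-rule filter *is* the method being reproduced, and the
raw hypergeometric tail (rather than an EASE-style adjusted score) is the
plain reading of "P value". Both choices are deliberate and documented
rather than hidden behind an FDR option.

## 5. Synthetic-data generators

The generators reproduce the *statistical structure* each stage assumes,
at the scale of the study conditions, so that closed-form expectations
are testable:

* **MTI scores**: each true pair passes program *p* with probability
  sensitivity~p~, each false pair with probability 1 − specificity~p~
  (defaults 0.8 / 0.9); cross-program dependence comes from one shared
  latent normal factor with correlation ρ (default 0). Scores are placed
  inside the passing/failing region of each program's threshold rule, so
  criteria application recovers the planted indicators exactly. With
  independent programs the triple intersection's sensitivity is s³
  (0.512) and its FPR (1−p)³ (0.1%) — both asserted within 3 binomial
  standard errors at 2000 + 2000 pairs.
* **Docking scores**: re-rank score = class mean + λ·z~compound~ +
  √(1−λ²)·ε, a one-factor bi-normal model; active mean shift Δ ≤ 0
  (default −1), decoy mean 0, default ensemble 26 conformers over 39
  actives and 1448 decoys, matching the benchmark shape such screens are
  reported on. Single-conformer AUC has closed form Φ(−Δ/√2) ≈ 0.760 at
  Δ = −1, and the between-conformer score correlation is λ². Cells go
  missing (failed docking) independently with probability φ.
* **Expression**: gene baseline + class-2 effect on the planted genes +
  Gaussian noise; defaults (500 genes, 20 planted, log2 effect 2.0, sd
  0.25, 4+4 samples) give a filter that should recover ≥ 90% of planted
  genes.
* **Annotations**: uniform term assignment with one term over-represented
  in the study set by a configured factor (default 10).

Everything is a deterministic function of the config seed
(`withr::with_seed`; no global RNG state is disturbed).

What the generators do **not** emulate — and hence what passing tests do
not show about real data: docking-energy physics and pose geometry,
miRNA seed-match biology and 3'-UTR structure, probe-level microarray
artefacts, correlated annotation terms (the GO DAG), and identifier
aliasing across databases. The generators validate the *inference
machinery*; they cannot validate the upstream scoring programs whose
outputs the pipeline consumes.

## 6. Problem sizes

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen to make the closed-form checks sharp but quick: 2000 + 2000
pairs for the consensus operating point, the 39/1448 × 26-conformer
benchmark for the ensemble pipeline, 500 × 8 expression matrices with 200
permutations, and 100-replicate property sweeps for nestedness. These are
the documented conditions for every reported number; the estimators
themselves are size-agnostic.

## 7. Known limitations

* Pair deduplication is symbol-level; no accession mapping or alias
  resolution.
* The enrichment filter tests terms independently; clustered or
  hierarchically related terms are reported as-is.
* No confidence intervals on AUC (a bootstrap would be the natural
  extension).
* The SAM delta search uses the symmetric $|d|$ rule; asymmetric
  (one-sided) delta cuts are not implemented.
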