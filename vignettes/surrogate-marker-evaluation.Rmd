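---
title: "Evaluating surrogate markers of a bimodal reference gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating surrogate markers of a bimodal reference gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surromark)
```

## The problem

In luminal breast cancer, the clinical decision to offer hormonal
therapy rests on the estrogen receptor (ER, gene *ESR1*). Because the
progesterone receptor (PR, gene *PGR*) is an ER target gene, PR
positivity is read in the clinic as evidence of ER activity — yet a
tumor can silence *PGR* (copy-number loss, promoter methylation,
cofactor imbalance) while the rest of the ER program stays active.
A candidate replacement surrogate, such as carbonic anhydrase 12
(*CA12*/CAXII, driven by both ER and the luminal factor GATA3), should
therefore be judged not merely by correlation but by a clinically
phrased question: *if we set the surrogate's cut-off so that it rules
out almost all reference-low tumors, how many reference-high tumors
does it wrongly rule out too?*

`surromark` implements that evaluation as a reusable pipeline over
three tabular inputs — a log2 expression matrix, a clinical status
table, and (for the protein arm) per-tumor immunostaining summaries —
plus a fully synthetic cohort generator so that every stage can be
exercised, with known ground truth, on a laptop.

## Low/high classification by a two-component mixture

Candidate and reference genes are split into `low`/`high` by fitting a
two-component univariate Gaussian mixture with EM
(`fit_two_component_mixture()`). Numerical choices:

* **Initialisation.** A deterministic median split plus one random
  restart drawn from the user's seed; the better log-likelihood wins.
  Reproducibility first, robustness second.
* **Model selection.** The two-component fit must beat a single
  Gaussian by BIC (penalties 5 vs 2 parameters). BIC rather than AIC:
  the stronger penalty avoids spurious splits on unregulated genes.
  When the one-component model wins, no threshold is reported and
  classification refuses to run — a gene that is not bimodal has no
  defensible low/high boundary.
* **Threshold.** The point between the two component means where the
  posterior membership probabilities are equal (closed-form root of
  the quadratic log-density ratio; for mirror-image components this is
  the midpoint). Ties at the threshold are classed `low` on the RNA
  side; the IHC side uses `>=` on its rounded cut-offs, matching how
  staining cut-offs are quoted. The two conventions are deliberate and
  documented side by side.
* **Convergence.** Relative log-likelihood tolerance `1e-8`, default
  cap of 2000 iterations. On genuinely unimodal data EM can drift
  along a flat ridge without formally converging; the fit then
  withholds its threshold and warns, which is the behaviour we want.
  The per-iteration log-likelihood trace is kept so monotonicity is
  assertable.

## The exclusion statistic

`exclusion_at_reference_specificity()` formalises the boxed scatterplot
reading: the candidate threshold *t* is the smallest observed candidate
value such that at least a fraction *q* (default 0.90) of
reference-low samples fall at or below *t* — the empirical inverse CDF
with no interpolation, so the statistic is exactly reproducible by a
brute-force scan and independent of quantile dialects. "Excluded"
means value ≤ *t* (closed at the threshold). Reported alongside the
guaranteed `excluded_low_fraction ≥ q` are the excluded fraction of
the reference-high group and of all samples, because those two
denominators answer different questions and published percentages mix
them.

Supporting statistics share the same sample alignment: Pearson
correlation between candidate and reference; discordance between a
gene's RNA class and its clinical status (unknown statuses leave the
denominator, with counts kept); and the rescue cross-tabulation — among
reference-high/primary-low tumors, the fraction called high by each
alternative target gene and by their union. Alternative genes reuse
the same *q*-specificity construction rather than their own mixture
fits, so every gene's box is built identically.

Enrichment of a selected tumor subset in a subtype label
(`hypergeometric_enrichment()`) uses the exact upper hypergeometric
tail with Benjamini–Hochberg q-values across labels. One caution
discovered while testing: BH is *not* idempotent on arbitrary adjusted
vectors (re-adjusting `(0.1, 0.2)` gives `(0.2, 0.2)`); it is a fixed
point only where the adjusted values are constant.

## The IHC arm

Staining summaries arrive as a proportion of positive cells in [0,1]
and a mean intensity in [0,3]. `composite_score()` digitises the
proportion to a 0–5 bin (edges 0; 0.01; 0.10; 1/3; 2/3 — the standard
Allred-style scheme, overridable since image-analysis pipelines may
bin differently) and adds the intensity kept as a real value, for a
ceiling of 8. Replicate cores are averaged on the raw scales *before*
binning (`aggregate_replicates()`, default mean; median and max
available): binning after averaging is less quantisation-noisy than
averaging bins.

Cut-offs are calibrated per marker from the trough of the bimodal
score histogram (`trough_cutoff_from_scores()`): a kernel density on
[0,8] with Silverman's-rule bandwidth, the deepest local minimum
between the two highest modes, rounded **up** to the score increment
(0.5) so that the `>=` positivity rule never captures the trough
itself. Local maxima under 1% of the main peak are ignored as
numerical wiggle; a density with no interior trough is an error
directing the user to a fixed cut-off. Group comparisons use the
tie-corrected Kruskal–Wallis test with Dunn's pairwise z statistics,
Bonferroni-adjusted by default (the common software behaviour behind
"Dunn's multiple comparisons"), Holm by option.

## What the synthetic cohort emulates

`generate_cohort()` draws, from a single seeded RNG stream in a fixed
documented order: a subtype (defaults LumA 0.45, LumB 0.25, mApo 0.10,
Basal 0.20 — 70% luminal); latent ER and GATA3 activities from
subtype-conditional normals on a nonnegative scale (≈0 in
receptor-low subtypes, ≈3 in luminal; GATA3 in molecular apocrine
tumors from a two-point mixture, 40% high); then each gene as
`baseline + er_weight·ER + gata3_weight·GATA3 + noise`, with
subtype-specific dropout replacing the regulatory input by the
baseline floor. The defaults encode the phenomenology the pipeline is
meant to detect, chosen once at design time:

* *PGR* drops out in 35% of LumB (5% of LumA) — the reference-high /
  surrogate-low tumors the rescue analysis targets, and the source of
  the LumB enrichment of that group;
* *CA12* has two drivers (ER weight 0.9, GATA3 weight 0.9) and no
  dropout, so it tracks *ESR1* more faithfully than *PGR* and is
  elevated in the GATA3-high mApo subset;
* *TFF1* is a noisy readout (sd 2.0) and *GREB1* a faithful one
  (sd 1.0), giving the spread of per-gene fidelities;
* clinical ER/PR statuses are the true classes flipped independently
  with probabilities 0.054 and 0.134. A dropped *PGR* makes the
  sample's activity-driven mean its baseline, so its true PR class is
  `low` — loss of the transcript is loss of the protein, and the
  clinical PR call follows the (absent) protein, not the latent ER
  activity. ER-negative/PR-positive tumors arise only through status
  flips; a mechanistic variant is deliberately not modelled.

True low/high classes are the indicator that a sample's activity-driven
mean exceeds the gene's global midpoint (halfway between the lowest
and highest subtype-state means, a deterministic function of the
parameters). IHC scores are a monotone noisy ramp of expression
centred on that midpoint (half-range 2.5 log2 units, staining noise
sd 0.5, triplicate cores), clipped so that floor expression scores
exactly zero.

What the generator does **not** emulate: marginal distributions of any
real cohort gene-by-gene, copy-number and methylation structure,
intra-tumor heterogeneity, batch effects, or censored survival.
Passing tests therefore demonstrate that the statistics do what they
claim on data with the assumed latent structure — not that any
particular real-cohort percentage will be reproduced.

## Problem sizes and open choices

The test-suite and acceptance runs use cohorts of 750 tumors (the
scale at which the ordering properties stabilise), 5,000–10,000 for
parameter-recovery checks, and 100 seeded replicates for the
stochastic-ordering claims; these sizes are the package's own choice
of a desk-scale experiment. Where the underlying publications leave a
procedure unstated we committed to: ternary status tokens mapped
case-insensitively with unknowns excluded pairwise from denominators;
expression units treated as opaque log-scale values (Pearson r is only
affine-invariant, rank statistics fully so); per-core scores averaged
before binning; and the reference gene's classes taken from its own
mixture fit rather than from clinical status, keeping the RNA arm
self-contained (the CLI exposes the clinical alternative).

## Known limitations

The mixture model is strictly two-component and univariate; genes with
three expression states will fold the middle state into whichever
component is closer. The exclusion threshold is an observed value, so
with few reference-low samples it moves in visible steps. The trough
finder needs both modes populated (≥ 20 scores, two detectable maxima)
and will refuse degenerate histograms rather than guess. And all
end-to-end guarantees are statements about the generator's latent
structure, at the stated sample sizes and seeds.
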