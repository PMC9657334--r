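# surromark

Surrogate-marker evaluation for bimodal gene expression in tumor
cohorts.

## The problem

Clinical decisions in luminal breast cancer hinge on estrogen receptor
(ER, gene *ESR1*) status, with the progesterone receptor (PR, gene
*PGR*) — an ER target gene — read as a surrogate of ER activity. A
surrogate can fail asymmetrically: a tumor may silence *PGR* while the
rest of the ER program stays active, so a PR-based cut-off that
correctly rules out ER-low tumors also wrongly rules out ER-high ones.
`surromark` quantifies exactly that trade-off for any candidate
surrogate gene or immunostaining marker, at the RNA level and at the
protein (IHC) level.

## What it computes

Given a reference gene classed `low`/`high` by a two-component
Gaussian mixture (EM fit; threshold at the equal-posterior point
between the modes; BIC against a single Gaussian guards against
splitting unimodal genes), each candidate gene *g* is scored by:

- **Exclusion at fixed reference specificity.** Threshold
  *t* = min{observed *g* | F̂_low(*t*) ≥ *q*} (default *q* = 0.90,
  empirical inverse CDF, no interpolation); report the fraction of
  reference-high samples with *g* ≤ *t* — the tumors the surrogate
  wrongly excludes.
- **Pearson correlation** with the reference.
- **Status discordance** between *g*'s RNA class and its clinical
  ternary status (unknowns leave the denominator).
- **Rescue cross-tabulation:** among reference-high/primary-low
  tumors, the fraction called high by each alternative target gene and
  by their union.
- **Subtype enrichment** of any selected tumor subset by the exact
  upper hypergeometric tail, P(X ≥ k) for (N, K, n), with
  Benjamini–Hochberg q-values.

The IHC arm mirrors the RNA arm on composite (Allred-style) scores:
a 0–5 proportion bin plus a 0–3 intensity, ceiling 8; per-marker
cut-offs at the trough of the bimodal score histogram (kernel density,
Silverman bandwidth, rounded up to the 0.5 score step); positivity by
`score >= cutoff`; inter-marker least-squares regression (R²); and
Kruskal–Wallis with Dunn's post-hoc z tests across clinical receptor
groups.

A seeded synthetic cohort generator (`generate_cohort()`) provides
expression, clinical and IHC tables with full ground truth — latent
ER/GATA3 activities, subtype-conditional gene readouts, *PGR* dropout
concentrated in luminal-B, status flip rates 0.054 (ER) / 0.134 (PR) —
so the whole pipeline is testable without any external data.

## Worked example

```r
library(surromark)

co  <- generate_cohort(cohort_params(n_samples = 750, seed = 11))
rep <- evaluate_candidates(co$expression, reference_gene = "ESR1",
                           candidate_genes = c("PGR", "CA12", "TFF1", "GREB1"),
                           clinical = co$clinical, q = 0.9, seed = 11)
print(rep)
```

```
surrogate_report: reference ESR1 (threshold 7.535), q=0.90
  reference status discordance: 7.6%
   gene pearson_r threshold excluded_low_fraction excluded_high_fraction ...
    PGR     0.736      5.59                 0.901                0.16543
   CA12     0.914      7.64                 0.901                0.00743
   TFF1     0.708      7.59                 0.901                0.29182
  GREB1     0.858      6.82                 0.901                0.05762
rescue_result: target group n=89
  CA12 high: 96.6%
  TFF1 high: 64.0%
  GREB1 high: 88.8%
  union high: 97.8%
```

Reading: a *PGR* cut-off that excludes 90% of *ESR1*-low tumors also
excludes 16.5% of *ESR1*-high tumors, whereas the same construction on
*CA12* excludes only 0.7% — *CA12* is the more faithful surrogate.
Of the 89 *ESR1*-high/*PGR*-low tumors, 97.8% are high for at least
one alternative ER target gene, i.e. almost all retain an active ER
program despite low *PGR*. The same cohort's ESR1-high/PGR-low
selection is strongly enriched for the LumB subtype
(`hypergeometric_enrichment()`, q ≈ 1e-24 at this seed).

A command-line wrapper exposes the same pipeline as subcommands
(`simulate`, `threshold`, `evaluate`, `enrich`, `ihc`); see
`inst/scripts/surromark` and `run_cli()`.

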