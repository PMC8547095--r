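---
title: "Models and methods behind sigrevert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sigrevert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sigrevert` analyses genotype × age mouse cohorts for progressive disease
expression programs and scores drug treatments for reverting them. This
vignette explains the models, the choices behind their defaults, and what
the synthetic-data generator does and does not emulate.

## The expression model

All linear modelling operates on quantile-normalized log2 expression
(RPKM + 1). Two designs are used:

* **Pairwise contrasts** (`fit_moderated`): `~ genotype + batch` (or
  `~ treatment + batch`) on a subset of samples, e.g. mutant vs wild-type
  at one age, or drug vs vehicle within the mutant arm. Age is treated as
  categorical here because each contrast compares two cells of the
  design.
* **Signature derivation** (`fit_age_interaction`):
  `~ age + genotype + age:genotype + batch` with age continuous in
  months. The interaction coefficient is the extra log2 change per month
  in the mutant; its moderated t ranks genes for the top-k signatures.

Moderation follows the standard empirical-Bayes construction: per-gene
residual variances \(s^2\) with \(d\) df are assumed scaled inverse
chi-square around a prior \((d_0, s_0^2)\); the posterior variance is
\(\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)\) and the moderated t has
\(d_0 + d\) df. The prior is estimated by the method of moments on
\(e_g = \log s_g^2 - \psi(d/2) + \log(d/2)\): \(d_0\) solves
\(\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2)\) (trigamma inverse by
Newton iteration, relative tolerance 1e-10) and
\(s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))\). When the moment
estimate is non-positive there is no evidence of excess dispersion and
the estimator pools completely: \(d_0 = \infty\),
\(s_0^2 = \mathrm{mean}(s^2)\). Genes with numerically zero variance are
excluded from the moment step (they would drag the prior to absurd
values) and reported with \(t = 0, p = 1\) when their contrast is also
zero.

Thresholds are read literally: the detection filter "at least 0.2 RPKM in
90 % of samples" is inclusive on both boundaries; FDR < 5 % and
|logFC| > 0.5 (0.25 for proteins) are strict. P-values are floored at
1e-300 before the −log10 ranking metric so it stays finite; ranking ties
are broken by gene id ascending, making every downstream enrichment score
deterministic.

## Signatures and overlaps

`derive_signatures` ranks by the interaction **t-statistic** by default:
in a moderated framework "the strongest positive interaction" most
naturally means most significant, and the t-order is stable across
expression levels; ranking by raw coefficient is available via
`by = "coefficient"`. Up and down signatures are disjoint by
construction.

`overlap_enrichment` reports the cross-product odds ratio (Haldane–
Anscombe +0.5 only when a zero cell occurs, and flagged), the
conditional-MLE odds ratio, and the two-sided Fisher exact p (probability
mass of tables no more likely than the observed one). The universe should
be the set of genes passing the detection filter in both compared
datasets — printed odds ratios depend on this choice, so the universe
size is always part of the result.

## Proteomics

PSM-level reporter intensities pass four literal filters (contaminant
flag "False", average reporter S/N strictly > 3, reporter intensity
strictly > 1000, quan-usage "Use"; the intensity rule is applied per
reporter measurement). Peptides with several candidate accessions go to
the accession with the largest total intensity (ties: lexicographically
smallest, with a warning). Size factors are median ratios against the
per-protein mean reference, computed **within each processing batch** by
default (a `by_batch = FALSE` global option exists); intensities are
divided by their sample's factor and log2(x+1)-transformed.

Each protein then gets the richest model its data identify:

* peptide, fraction-within-peptide and sample random effects with
  age × genotype cell means and batch fixed ("mixed", REML via lme4),
* dropping random terms when only one peptide/fraction exists or no
  sample carries repeated measures,
* cascading mixed → fixed-with-peptide-covariate → simple on numerical
  failure (always logged via warning).

Contrasts are tested without adjustment (multcomp::glht) and BH is
applied a posteriori across proteins, per contrast.

## Reversion scoring

The running enrichment score is the weighted Kolmogorov–Smirnov statistic
of GSEA: walking down the ranking, a signature hit at rank *i* adds
\(|m_i|^w\) (normalized by the total hit weight; \(w = 1\) by default,
\(w = 0\) gives the classical KS statistic), a miss subtracts
\(1/(N - |S|)\). The ES is the signed maximum deviation from zero; when
the positive and negative extrema agree in magnitude within 1e-12 the
positive side is taken, in the implementation and in every oracle, so
floating-point accumulation order cannot flip the sign. The leading edge
contains the hits at or before the maximum (positive ES) or at or after
the minimum (negative ES).

The null model randomizes the **signature**, not the samples: B gene sets
of the same size drawn uniformly from the ranked universe (the sampled
null uses the same cumsum arithmetic as the observed score, so the two
are bit-comparable). The empirical p is the add-one tail probability of
the observed magnitude, \(p = (1 + \#\{|ES_{null}| \ge |ES_{obs}|\}) /
(B + 1)\): comparing magnitudes keeps p uniform under the null whatever
the null's asymmetry, p is never exactly zero, and the direction enters
the verdict through the sign of the observed ES — AD-UP is reverted when
its ES is negative and significant, AD-DW when positive and significant.
A side-restricted count over a fixed B+1 denominator would bound p near
0.5 and destroy calibration, which is why the magnitude convention is
used. Both a pointwise 95 % band on the null ES and the null quantiles
are reported since either may be wanted for plotting.

Reversion ranks count from the end of the ranking a reverting gene should
occupy: from the most-downregulated end for AD-UP, from the top for
AD-DW; `reversion_rank_table` keeps leading-edge genes shared by at least
two treatments and sorts by average rank. `restoration_check` compares
per-gene t-scores of drug-vs-wild-type and vehicle-vs-wild-type contrasts
sharing the wild-type reference; the restoration fraction
\(1 - t_{drug}/t_{vehicle}\) is 1 under full restoration and 0 under
none.

## Screening

The compound universe is an abstraction of large bioactivity resources:
typed spaces ("chemistry", "transcription", "cell-sensitivity") as
real-valued matrices with coverage masks, set-valued target annotations,
and knockdown profiles. Similarity defaults to cosine in vector spaces
and Jaccard for target sets. Every query's raw affinity is converted to
an empirical −log10 p over the covered universe,
\(p(c) = (1 + \#\{c' \ne c: v(c') \ge v(c)\})/(n+1)\), so the unique best
of n compounds scores \(-\log_{10}(1/(n+1))\) and ties share a p. The
shortlist is the union of per-query selections at p < 0.001 (score ≥ 3)
by default. Property classifiers use extremely randomized trees
(`ranger`, `splitrule = "extratrees"`) under stratified 5-fold CV with
ROC AUC per fold; continuous responses are binarized at stated cut-offs
(e.g. 0.8 for an amyloid readout).

## What the generator emulates — and what it does not

`simulate_expression_study` draws negative-binomial counts with
log2-mean \(= \text{baseline} + \text{batch} + \beta_1\,\text{age} +
\beta_2\,\text{genotype} + \beta_3\,\text{age}\times\text{genotype}\),
genotype coded 0/1 (wild-type reference). Defaults mirror the blocked
design the pipeline targets: 2 genotypes × ages {3, 6, 9} months ×
4 mice per cell, with biological replicates confounded with 4 processing
batches (replicate i sits in batch i). Key knobs, with units:

| parameter | default | meaning |
|---|---|---|
| `beta_interaction` | 0.15 | log2/month extra slope in the mutant for signature genes |
| `frac_up_sig`, `frac_dw_sig` | 0.05 each | fraction of genes with ±interaction |
| `dispersion` | 0.1 | NB dispersion, var = μ + φμ² |
| `batch_sd` | 0.1 | SD of per-gene log2 batch effects |
| `beta_age_sd`, `beta_genotype_sd` | 0.01, 0.05 | SDs of nuisance per-gene aging slopes and genotype offsets |
| `n_decoupled`, `decoupled_effect` | 40, 0.5 | null-mRNA genes whose protein gains a genotype×age effect |

Effect sizes are not published for the real signature genes, so these
defaults were chosen once as a realistic middle ground: a 0.15 log2/month
interaction accumulates to ~0.9 log2 across the 3–9-month window,
comparable to strong microglial induction, and φ = 0.1 is a conventional
bulk-RNA-seq dispersion. Worth knowing: with φ = 0.1 the residual log2
noise is ≈ √φ/ln 2 ≈ 0.46, so the per-gene interaction SE in this design
is ≈ 0.09 and planted genes sit only ~1.7 SDs above the null — top-250
recall against thousands of null genes is then intrinsically limited to
roughly 0.4 no matter the estimator. Recall approaching 1 requires either
larger effects or dispersions near 0.02; the test suite demonstrates the
monotone recall–effect-size relationship explicitly. This is a property
of the stated study conditions, not of the implementation.

The treatment simulator moves mutant signature-gene means a fraction ρ of
the way back to the wild-type mean at a single age; ρ = 0 reproduces the
vehicle arm, ρ = 1 the wild type. The proteomics simulator builds
log-normal PSM intensities around per-protein abundances with peptide,
fraction and sample offsets — the same variance components the
per-protein models assume — plus corrupted rows at configurable rates.
The compound simulator plants reverters (anti-signature transcriptional
vectors), look-alikes of reference drugs, and target binders.

Not emulated: read-level data (alignment and isoform quantification are
upstream of this pipeline), real biological covariance between genes
(genes are independent given the design), compositional library effects
beyond what RPKM induces, isotope-impurity structure in reporter
channels, and real chemical-space geometry. Passing tests therefore
demonstrate the statistical machinery on data satisfying the model's own
assumptions; they do not certify performance on violations of them
(correlated genes, outlier samples, unbalanced designs).

One consequence observed in testing: quantile normalization is not
rank-safe when a large fraction of a small gene universe carries
multi-log2 shifts (it forces identical sample distributions and
compresses genuine global change). Real cohorts, with tens of thousands
of genes and sub-percent signature fractions, are far from this regime;
simulations that concentrate 20 % of genes in signatures are analysed on
log2 RPKM directly where this matters.

## Numerical choices and degenerate inputs

* RNG flows through one seeded generator per simulator call and restores
  the caller's RNG state; identical configuration + seed reproduces
  byte-identical tables.
* Ranked-list ties: metric descending, gene id ascending — ES values are
  bit-reproducible.
* ES extremum ties (|max| = |min| within 1e-12): positive side.
* Empirical p: add-one smoothing, never 0; B < 100 warns.
* p = 0 before ranking: floored at 1e-300.
* Constant genes: t = 0, p = 1; excluded from prior moments.
* All-zero hit weights in the ES (all hit metrics 0 with w > 0): equal
  weights.
* Zero reference in size factors: protein skipped in the median.
* Values exactly at a decoupling threshold fall in neither strict branch
  and are classed `none`.
* Mixed-model non-convergence cascades one structural level at a time,
  each fall-back warned.

## Problem sizes

The test suite and the acceptance script run at deliberately compact
sizes chosen to keep full runs fast while leaving no estimator starved:
2,000–5,000 genes, 24-sample designs, 50-seed power loops with B = 500
randomized signatures, and a 5,000-compound screening universe. The same
code paths scale to full-cohort sizes unchanged; `B = 10,000` is the
default for single reversion analyses.

## Known limitations

* The per-protein mixed models fit proteins independently; no information
  is shared across proteins (no proteomics-side moderation).
* The interaction model assumes linear age trajectories on the log2
  scale; saturating trajectories will dilute the interaction coefficient.
* The screening universe is synthetic by design. Real bioactivity
  signatures can be dropped into the same matrices, but no external
  resource is bundled or required.
* `shortlist` thresholds other than the p < 0.001 chemical-similarity
  query are conventions, exposed as parameters and logged, not published
  constants.
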