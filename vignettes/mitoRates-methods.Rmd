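---
title: "Methods: phylogeny-corrected analysis of mitogenomic rate variation"
author: "mitoRates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny-corrected analysis of mitogenomic rate variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoRates)
```

# The scientific problem

Parasitic animals — especially endoparasites — tend to show elevated
mitochondrial substitution rates, and so do lineages with low
locomotory capacity. Because endoparasitism essentially implies low
locomotory capacity, the two classifications are partially collinear,
and species are phylogenetically related, so naive category
comparisons overstate the evidence. `mitoRates` implements the full
analytical chain needed to study this question rigorously:

1. **Curation** of mitogenome records into per-gene protein-coding
   sequence sets, resolving duplicated gene annotations and removing
   unusable records.
2. **Rate extraction**: each species' molecular rate proxy is its
   root-to-tip branch length (`brl`) on a phylogram, i.e. the expected
   substitutions per site accumulated since the common root. On a
   tree of contemporaneous tips, differences in `brl` are differences
   in average lineage rate.
3. **Trait handling**: closed life-history (F, MP, Parasitoid, EctoP,
   EndoP) and locomotory-capacity (H, I, L) vocabularies, exclusion
   bookkeeping, binary recodings, and per-phylum composition ratios.
4. **Ancestral states**: maximum-likelihood Mk reconstruction to count
   independent origins of states such as endoparasitism.
5. **Phylogeny-aware statistics**: PGLS, a kinship-based linear mixed
   model, likelihood-ratio R², AIC, χ² likelihood-ratio tests, Tukey
   HSD with compact letters, Cohen's d and power.
6. **Synthetic data**: a seeded generator producing chronograms, trait
   histories, rate-multiplied phylograms and toy GenBank records, so
   the whole pipeline is testable without downloads.

# Models and estimators

## Root-to-tip rates

For a rooted phylogram with non-negative branch lengths, `brl(i)` is
the sum of branch lengths from the root to leaf `i`
(`rootToTipLengths()`). Zero-length edges are allowed; negative ones
are rejected. Outliers are flagged by the boxplot rule (Tukey hinges,
fences at `k = 1.5` interquartile ranges, `flagOutliersIQR()`), and a
descriptive long-branch threshold is defined as twice the mean `brl`
(`longBranchThreshold()`).

## Mk ancestral states

`mkLogLikelihood()` evaluates the tip-data likelihood of a k-state
continuous-time Markov model by post-order pruning with per-branch
transition matrices $e^{Qt}$; for the equal-rates generator the
closed form $P_{ij}(t) = 1/k + (\delta_{ij} - 1/k)e^{-kqt}$ is used,
otherwise a matrix exponential. The default model is equal-rates with
a uniform root prior — the simplest identifiable choice. Rates are
fitted by bounded 1-D search on the log scale (`fitMkModel()`);
because the profile over the rate need not be unimodal at small n,
the search starts from a coarse grid. `marginalAncestralStates()`
combines the pruning pass with a pre-order pass so that every node's
marginal conditions on all tips. Origin counting
(`countStateOrigins()`) operates on max-marginal assignments (ties
resolved toward the parent), and reports the weakest marginal along
each origin edge as a confidence caveat, since published origin
counts are typically expert-curated rather than purely algorithmic.

## The phylogenetic linear mixed model

The central estimator (`plmmFit()`) is the kinship model

$$ y = X\beta + g + \varepsilon,\quad
   g \sim N(0, \sigma^2_g K),\quad
   \varepsilon \sim N(0, \sigma^2_e I), $$

with `y` the natural log of `brl` (log-transformation reduces the
strong right skew of branch lengths) and `K` the Brownian-motion
covariance of the tree scaled to unit maximum diagonal
(`bmCovariance(tree, "correlation")`). The BM covariance — shared
root-to-MRCA path length — is the only positive-semi-definite choice
that can serve as a kinship matrix; pairwise cophenetic distances are
not PSD, which is why the covariance convention is used.

Fitting is full maximum likelihood, not REML, because every
downstream quantity (AIC, χ² LRT, likelihood-ratio R²) consumes total
log-likelihoods that must be comparable across fixed-effect
structures. After an eigendecomposition of `K` the likelihood is
profiled over the variance ratio $\lambda = \sigma^2_g/\sigma^2_e$ on
a coarse log-scale grid followed by local refinement; boundary
solutions (no phylogenetic signal, or no residual variance) are
flagged. The parameter count (`DF`) is the number of fixed effects
plus the two variance components, so intercept-only = 3, adding a
3-level factor = 5, a 5-level factor = 7, both = 9, and
`AIC = 2 DF − 2 logLik`.

Treatment coding uses free-living (F) and High locomotory capacity
(H) as reference levels, so coefficients are contrasts against the
free-living, highly-mobile baseline.

Explained variance is the likelihood-ratio R²,
$R^2 = 1 - \exp(-\tfrac{2}{n}(\ell_{full} - \ell_{null}))$
(`lrRSquared()`). The Nagelkerke rescaling is implemented but off by
default: the raw form reproduces the published style of
model-comparison tables, the rescaled form does not. The default null
is the intercept-plus-random-effect model fitted to the same data.

## PGLS and pairwise comparisons

`pglsFit()` is generalized least squares with the BM covariance and
ML error variance; the factor effect is tested by a Wald χ² on the
coefficient block (the test statistic used by GLS ANOVA
implementations varies; Wald χ² is explicit and deterministic). With
`C = I` it reduces exactly to OLS.

`tukeyPairwise()` performs Tukey–Kramer comparisons with the
studentized range (base R's `ptukey`), supports unequal group sizes,
and produces a compact letter display by the insert-and-absorb
algorithm; two groups share a letter exactly when their pair is not
significant at `alpha`. Cohen's d uses the pooled (n−1)-weighted sd;
magnitude labels follow the Sawilowsky scale (0.2 small … 2.0 huge)
and are configurable, because published usage sometimes calls
d > 0.8 "very large". Power for two-sample comparisons uses the
noncentral t with ncp $d\sqrt{n_1 n_2/(n_1+n_2)}$; note that effect
size and power are distinct quantities and are reported separately.

# The synthetic-data generator

`makeBenchmarkDataset()` composes:

* `sampleYuleTree()` — a pure-birth chronogram (birth rate 1). A Yule
  process is the simplest generator with controllable size; the
  empirical tree is fixed data, so any reasonable topology model
  serves.
* `simulateMkStates()` — trait histories under an equal-rates Mk
  process. The default rate is `4 * birth / (nTips − 1)`, i.e. about
  four expected transitions per tree: life-history and locomotory
  categories are deeply conserved, clade-level traits (whole phyla are
  uniformly endoparasitic; high locomotory capacity originated in only
  a handful of clades), not fast-flickering characters. Histories are
  redrawn until every state reaches `minStateFrac` of the tips —
  default 2% for the 5-state life-history trait (the rarer empirical
  categories hold 66–276 of 10,906 species), 8% in the 3-state
  benchmark settings (the smaller locomotory classes hold >900 of
  10,906). Endoparasite tips are forced into locomotory class L,
  mirroring the empirical constraint.
* `simulatePhylogram()` — each branch's length is the sum over its
  state segments of duration × base rate × state multiplier ×
  $e^{\varepsilon}$, $\varepsilon \sim N(0, 0.3^2)$ per segment. The
  default life-history multipliers (F 1.0, MP 1.05, Parasitoid 1.44,
  EctoP 2.34, EndoP 3.82) are the ratios of the reported category mean
  branch lengths 2.37 / 2.50 / 3.42 / 5.54 / 9.05.
* `simulateMitogenomeRecords()` — toy GenBank flatfiles with 13 clean
  protein-coding ORFs per species (nad6 on the minus strand), species
  arranged in two-species genera so a genus-level reference ortholog
  always exists, and duplicated genes planted with either internal
  stop codons or heavy divergence, plus optional unannotated, hybrid
  and byte-identical records for the dataset filters. Truth logs
  record the copy that must survive resolution.

What the generator does **not** emulate: sequence-level evolution
(multipliers act on branch lengths directly), gene-order
rearrangement, correlated evolution between the two traits beyond the
EndoP→L constraint, non-uniform taxon sampling, and tree estimation
error. Passing tests therefore validate the statistical machinery
under the assumed mechanism, not the biological conclusions of any
particular empirical dataset.

# Operating characteristics, and a deliberate red flag

Three seeded studies ship with the package (also recomputed by
`scripts/acceptance.R`):

* `nullCalibrationStudy()` — with equal multipliers the trait has no
  effect; across 200 replicates (100 tips) the mixed-model LRT
  p-values are consistent with Uniform(0,1) (Kolmogorov–Smirnov).
* `tukeyFweStudy()` — under iid normal groups the Tukey family-wise
  error stays at its nominal level (500 replicates).
* `recoveryStudy()` — 50 replicates of 500-tip trees, a 3-state trait
  with multipliers (1, 2, 4) and noise sd 0.3. The simulated
  group-mean ordering is recovered in every replicate, and the trait
  effect is strongly significant. However, the mixed-model **contrast
  estimates do not equal the log multipliers**: the rate elevation of
  a switched clade accumulates gradually with time spent in the
  state, which the model's Brownian covariance cannot distinguish
  from phylogenetic drift. Maximum likelihood therefore pushes
  $\sigma^2_e$ to its boundary, the fit degenerates to GLS under the
  BM correlation, and the fixed contrast estimates the step change at
  the origin edges — far below $\log m$ (measured ≈ 0.15 and 0.35
  against 0.69 and 1.39). This is a property of regressing cumulative
  root-to-tip lengths on tip states with phylogenetic correction, not
  an implementation defect: the likelihood matches an independent
  dense multivariate-normal grid search to 1e−4, and the estimator is
  well calibrated under the null. The corresponding acceptance test
  asserts the nominal 2-standard-error recovery and is expected to
  fail; it is retained unweakened as an honest record of this
  behaviour. Practically, the mixed model's strength here is variance
  partitioning and hypothesis testing (R², LRT), and category effect
  *sizes* should be read from the descriptive group means.

# Numerical choices and degenerate inputs

* Quartiles for outlier flagging are Tukey hinges, matching boxplot
  statistics.
* Genetic codes are taken from the CDS `/transl_table` qualifier; a
  missing qualifier is an error rather than a guessed default, since a
  wrong code silently corrupts stop-codon detection. Codes 2, 4, 5,
  9, 13 and 14 cover bilaterian mitogenomes.
* Ambiguity codes translate as unknown and are never counted as stop
  codons.
* The conservation score is the mean proportion of identical aligned
  positions after global alignment with match 1 / mismatch 0 / linear
  gap −1 — simple, deterministic and monotone in similarity; the
  "lowest available identical taxon" is operationalized as the first
  rank, walking from genus upward, that contains another species
  carrying the gene.
* When every duplicate copy carries internal stops the stop rule is
  inconclusive and the conservation rule decides; residual ties keep
  the lower start coordinate, so resolution is always deterministic.
* Hybrid records are detected by organism-name markers (`" x "`,
  `"hybrid"`) only.
* Zero branch lengths are tolerated everywhere except a zero
  root-to-tip total under the log transform, which errors rather than
  being epsilon-padded.
* All stochastic functions accept explicit seeds and restore the
  caller's RNG state; equal seeds give byte-identical outputs.

# Problem sizes used in the shipped studies

The test-suite and acceptance studies use 500-tip trees with 50
replicates for recovery, 100-tip trees with 200 replicates for null
calibration, 500 iid replicates for the Tukey family-wise error, and
enumeration oracles on trees of up to 6 tips (likelihoods) and 8 tips
(mixed-model fits). These sizes give Monte-Carlo standard errors
small enough for the stated checks while keeping a complete run on a
single CPU in minutes.

# Known limitations

* No Bayesian estimation, no Pagel's λ or Ornstein–Uhlenbeck
  covariance alternatives, and no hidden-state Mk models.
* Missing tip states are not handled in the Mk machinery.
* The GenBank reader targets the flatfile subset produced by RefSeq
  mitogenome records (LOCUS/ACCESSION/ORGANISM/FEATURES/ORIGIN, CDS
  with `gene`/`product`/`transl_table` qualifiers, `join`/
  `complement` locations); it is not a general GenBank parser.
* Origin counts from max-marginal assignments can differ from
  expert-curated counts when marginals are ambiguous; the reported
  minimum marginal per origin flags such cases.
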