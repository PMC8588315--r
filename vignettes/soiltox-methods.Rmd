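---
title: "Methods: indices, inference and simulation in soiltox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indices, inference and simulation in soiltox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soiltox)
```

`soiltox` analyses pot-experiment soil-ecotoxicology studies with a
dose x time x biostimulant factorial layout: a contaminant is applied at
graded doses (mg kg^-1^ dry matter of soil), half of the pots additionally
receive an organic biostimulant (mussel-shell meal), and the soil is sampled
on several days for culture-based microbial counts, enzyme activities, 16S
OTU profiles and contaminant residues. This vignette documents the models
and conventions behind each analysis stage, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the methodology left room.

## Culture-based community indices

Plated soil dilutions are observed for ten days and the number of colonies
*newly appearing* on each day $i$ is recorded as $N_i$. With
$p_i = N_i / \sum_j N_j$, the package computes

* the **colony development index**
  $\mathrm{CD} = 100\sum_{i=1}^{10} p_i / i$, which up-weights early
  emergence: $\mathrm{CD} = 100$ when everything appears on day 1,
  $\mathrm{CD} = 10$ when everything appears on day 10, and
  $10\,H_{10} \approx 29.29$ under uniform emergence;
* the **ecophysiological diversity index**
  $\mathrm{EP} = -\sum_i p_i \log_{10} p_i$, a Shannon-type entropy of the
  emergence-day distribution that spans $[0, 1]$ for a 10-day window in
  base 10.

Two readings of the day counts are possible: daily increments or running
cumulative totals. The package uses increments, because only that reading
produces the documented 10–100 range for CD (cumulative counts would weight
every colony repeatedly), and the entropy is likewise only well defined on
the increment distribution. Both indices are undefined on an empty series
and return `NA` rather than 0 — a plate with no colonies carries no
information about growth dynamics.

The `log_base` of EP is a parameter (default 10). Base 10 is the convention
under which reported EP values for 10-day windows live in $[0, 1]$; natural
log simply rescales by $\ln 10$.

Communities with front-loaded emergence (high CD) are interpreted as
*r-strategists*, back-loaded ones as *K-strategists*. No numeric CD
boundary is established in the literature; `classify_strategy()` defaults
to an inclusive threshold of 35, which cleanly separates the fast
organotroph-like presets (CD near 50) from the slow actinobacteria-like
presets (CD below 20) in the packaged scenarios. The threshold is exposed
and should be read as a reporting convenience, not a biological constant.

Indices can be computed per replicate and then averaged, or on counts
pooled within a treatment cell; both paths are provided
(`colony_index_table(pooled = )`) because the right choice depends on
whether plate-level variation is of interest.

## The biostimulation impact factor

For every response $A$ (an enzyme activity or a microbial count) the impact
factor of the biostimulant is the ratio of replicate means
$\mathrm{IF} = A_{\mathrm{bs}} / A_{\mathrm{baseline}}$, with
$\mathrm{IF} > 1$ read as stimulation and $\mathrm{IF} < 1$ as inhibition.
Two baseline conventions are genuinely defensible and the package
implements both behind `baseline_mode`:

* `"paired"` (default): the baseline is the same dose x day cell *without*
  the biostimulant. This is the convention under which the
  stimulation/inhibition reading is exact, because dose effects cancel.
* `"control-soil"`: the baseline is the uncontaminated (dose 0) cell of the
  same day *with* the biostimulant — the literal "amended control soil"
  reading. Here IF mixes the amendment's effect with the dose response.

The pipeline computes both so their disagreement is visible rather than
hidden. Replicate aggregation is the arithmetic mean by default (`agg =`
accepts `median`). Zero or missing baseline cells yield `NA`, never
infinities.

## Post-hoc homogeneous groups

Treatment levels are compared with all-pairs Tukey HSD built on the one-way
ANOVA pooled mean-square error; unequal replication uses the Tukey–Kramer
harmonic-mean standard error. The default family-wise level is
$\alpha = 0.01$, the stringent convention for soil enzyme and microbial
screening. Two degenerate regimes are defined explicitly rather than left
to floating point: with zero within-group variance, identical means give
$p = 1$ and distinct means give $p = 0$ (every pair separated).

Letters are assigned by the insert–absorb algorithm: start from one letter
covering all levels, split every letter still joining a significantly
different pair, absorb letter columns that became subsets, and label the
columns a, b, c, … in first-use order over levels sorted by descending
mean — so "a" sits on the highest mean, the common display convention. The
resulting display encodes the significance relation exactly: two levels
share a letter iff they are not significantly different. This equivalence
is property-tested against a brute-force verifier on random relations.

Dose trends are flagged with the ordinary Pearson product-moment
correlation and a two-sided $t$-test at $\alpha = 0.05$; constant inputs
raise an undefined-correlation condition instead of returning a number.

## PCA of impact-factor matrices

The IF matrix (responses x treatment cells) is transposed so cells are
cases, then decomposed with `stats::prcomp`. The default is
correlation-matrix PCA (`standardized = TRUE`), appropriate because the
responses live on incommensurate scales; covariance PCA is selectable.
Explained-variance percentages always sum to 100 and loadings are unit
norm. Because the sign of a principal axis is arbitrary, each component is
oriented so its largest-magnitude loading is positive — printed loadings
are therefore reproducible across platforms, but their absolute signs
should not be compared with other software. Cases with missing IF cells
are dropped and reported (`dropped_cases`), never silently imputed.

## OTU profile analytics

OTU tables enter with a 5-rank lineage (phylum → genus). Aggregation at a
rank sums counts over the rank label and pools OTUs unresolved at that rank
into an `"Unclassified"` bucket, so per-sample totals are conserved
exactly — an invariant asserted across the suite. The rare-taxon filter
eliminates taxa whose relative abundance is *strictly below* the threshold
(default 1%) in every sample; the boundary is inclusive because the
convention eliminates shares "lower than" the cut-off. Removed mass is
reported per sample, and retained proportions stay expressed against the
original totals rather than being re-normalised, so filtered tables remain
comparable across samples.

Profile differences between two samples (typically control vs top dose on
one day) are screened with the |difference between proportions| ≥ 1% rule,
and tested per taxon with a two-proportion hybrid:

* the **G-test with Yates continuity correction** on the 2x2 table, with
  each observed cell shifted 0.5 toward its expectation (the shift is
  clamped at $|O - E|$ so an exact fit keeps $G = 0$ and $p = 1$), referred
  to $\chi^2_1$;
* the **two-sided Fisher exact test** (full hypergeometric enumeration)
  whenever any expected cell falls below `fisher_threshold` (default 20,
  the convention of the usual profiling software).

The confidence interval for the proportion difference is the asymptotic
normal (Wald) interval with continuity correction
$\pm\left(z\sqrt{\hat p_1 \hat q_1/n_1 + \hat p_2 \hat q_2/n_2} +
\tfrac12(1/n_1 + 1/n_2)\right)$. The Newcombe hybrid interval would be a
reasonable alternative but is not the named convention, so it is not
implemented. Note that the continuity correction moves $p$-values by
$O(1/\sqrt n)$: for near-tie tables the corrected and uncorrected G can
differ by a few $10^{-3}$ even at libraries of $10^4$ reads, while for
tables past the 1% difference filter the two agree to well under $10^{-3}$.

"Samples" for these tests are pooled read counts per treatment cell,
because replicate-level libraries are not part of the data model. Filters
are applied at the analysis rank (after aggregation), not at the raw OTU
level — the alternative reading exists, but filtering where the comparison
happens keeps the filter and the test consistent.

## The synthetic-data generator

The generator produces datasets with the statistical structure the analysis
assumes, so every stage is testable without external data. It emulates a
150-pot factorial: 5 doses (0, 0.1, 1, 10, 50 mg kg^-1^ DM), days
15/30/45, both biostimulant arms, 3 replicates per cell by default
(analytical assays in such studies are typically run in triplicate).

* **Colony counts** are negative-binomial around
  `baseline x effect(dose, day) x bs_mult`, spread over emergence days
  1–10 by a truncated-geometric distribution — front-loaded for
  fast-growing groups, mirrored (back-loaded) for slow ones. Setting
  `dispersion = Inf` switches the cell to a fully deterministic regime
  (counts at the rounded mean, emergence days by largest-remainder
  apportionment), which is what a "zero dispersion" null scenario means
  here.
* **Enzyme activities** are lognormal with mean exactly the configured
  surface (the noise factor has unit mean), at a default CV of 5%.
* **OTU libraries** are Dirichlet-multinomial: expected compositions are
  `softmax(baseline + shift * s(dose))` with the saturating dose scale
  `s(dose) = log1p(dose)/log1p(max dose)`, overdispersed by a Dirichlet
  draw at concentration 200, and sampled multinomially at a library size
  of 10,000. The built-in 32-taxon mock taxonomy spans the phyla and
  genera a contaminated-soil survey typically resolves (it is synthetic,
  not a reference database).
* **Residues** follow first-order decay `dose * exp(-k t)` with
  `k = -ln(0.04)/15 ≈ 0.2146 d^-1`, i.e. 96% of the dose is gone by day
  15, with optional lognormal measurement noise (off by default).

The effect presets are calibrated to the kind of anchors such a study
reports — a 76% fungal suppression at the top dose on day 15 (multiplier
0.24), a 65% urease stimulation at 0.1 mg on day 15 (multiplier 1.65), a
monotone glucosidase dose response, biostimulant multipliers above 1 —
so pipeline outputs are directionally comparable to real studies. They are
configuration, not truth: within-cell variance levels in particular are
not reported by such studies, so the default noise levels (NB size 15,
CV 5%) are a modelling choice and flagged as such.

What the generator does **not** emulate: spatial or temporal correlation
between pots, replicate-level OTU libraries (one library per cell),
taxon–taxon interactions, secondary metabolite chemistry, or any
mechanistic growth model. Passing tests on synthetic data therefore
demonstrate the *computational* correctness and calibration-recovery of
the pipeline, not field validity of any biological conclusion.

## Determinism and the run report

`run_pipeline()` executes load/generate → validation → indices → impact
factors (both baselines) → Tukey/letters per response x day → dose
correlations → PCA → taxa analytics (all five ranks, filters, shared
genera, control-vs-top-dose tests per day) → residue summary, and
serialises everything as CSV plus a JSON manifest. The manifest records
the seed, a hash of the configuration and the package version — and
deliberately no wall-clock timestamp, so a rerun with the same
`(config, seed)` is byte-identical; determinism is the stronger and more
useful provenance guarantee. All randomness flows from the single master
seed through fixed per-generator offsets.

A null scenario (`null_scenario()`) sets every effect to 1 and all noise
to zero. On it the pipeline must find nothing: every letter display
collapses to "a" (equal means with zero variance give $p = 1$ by the
degenerate-variance rule), the dominant-taxa lists are empty (the enlarged
200,000-read library keeps multinomial noise far below the 1% filter), and
dose correlations are reported as undefined. This is the package's
negative control and is exercised in the test suite.

## Problem sizes used in the checks

The test suite validates index bounds on 10^4 random emergence series,
letter displays on 500 random relations up to 8 levels, Tukey p-values
against `stats::TukeyHSD` on 100 random layouts, the Fisher branch against
`stats::fisher.test` on every 2x2 table with grand total ≤ 30, PCA against
a raw SVD on 100 random matrices, read conservation on 1,000 random OTU
tables, and effect-size recovery on 1,000 Monte-Carlo replicates — sizes
chosen so each property is exercised at scale while the whole suite stays
fast enough to run routinely.

## Known limitations

* Tukey HSD assumes a one-way layout with homoscedastic errors; strongly
  unbalanced or heteroscedastic designs need a different post-hoc method.
* The Wald-with-CC interval can overshoot $[-1, 1]$ near boundary
  proportions; bounds are reported as computed.
* The compact letter display is minimal for the insert–absorb order used;
  letter *strings* (not the encoded relation) may differ from other
  software that processes labels in another order.
* OTU analytics treat libraries as fixed-size multinomial pools; no
  rarefaction or compositional (log-ratio) treatment is applied.
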