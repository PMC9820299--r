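---
title: "Methods: WQI modelling and pollution-source apportionment"
author: "wqsource"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WQI modelling and pollution-source apportionment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wqsource)
```

## Overview

`wqsource` implements a complete analysis chain for routine surface-water
monitoring data: (1) an additive water quality index (WQI) that condenses a
station-month record of up to fourteen parameters into a single 0–100
score; (2) a regression forest that models WQI from the raw parameters and
ranks them by mean-decrease-impurity (MDI) importance, supporting
minimal-parameter surrogate models (`WQI_RFmin`); (3) an
uncertainty-weighted positive matrix factorization (PMF) that decomposes
the sample-by-species concentration matrix into nonnegative source
contributions and profiles; and (4) a combination statistic that attributes
the variation in WQI values to the identified pollution sources. A
synthetic monitoring-data generator with planted source structure provides
ground truth for validating every stage.

## The water quality index

For one record the index is the weighted mean of parameter sub-indices,

$$\mathrm{WQI} = \frac{\sum_i C_i P_i}{\sum_i P_i},$$

where $C_i \in [0, 100]$ is parameter $i$'s concentration mapped through a
normalization curve and $P_i$ its weight. Missing parameters drop out of
both sums, so the index remains a proper weighted mean of whatever was
measured. Scores are graded Excellent (91–100), Good (71–90), Moderate
(51–70), Poor (26–50) and Very poor (0–25). Because the integer bands
leave real-valued gaps (e.g. between 90 and 91), grading applies the
thresholds Excellent $\ge 91$, Good $\ge 71$, Moderate $\ge 51$, Poor
$\ge 26$ to the unrounded score; this preserves the integer bands while
totally ordering all reals, which is what the band-partition tests check.

The shipped default configuration follows the additive-index tradition of
Pesce and Wunderlin: breakpoint curves per parameter (piecewise-linear by
default, piecewise-constant step tables also supported), weights 3 for the
trace metals Fe and Mn, CODMn, NH3-N and faecal coliform, 4 for dissolved
oxygen (the usual convention in this index family), and 1–2 for the
remaining parameters, plus GB3838-2002 class I–V standards where the
national surface-water standard defines them. The exact curve tables and
the 1-vs-2 weight split are conventions of this package's default
configuration, not normative values: everything is overridable through
`parameter_spec()` or a YAML file (`read_parameter_specs()`), and the test
suite depends only on contract properties (bounds, monotonicity,
weight-rescaling invariance, band partition), never on specific default
curve entries.

## The regression forest and MDI importance

Trees are grown CART-style with mean-squared-error impurity. At a node
with $N_s$ samples, a candidate split $(x_i, v_{ij})$ is scored by the
weighted child impurity

$$G(x_i, v_{ij}) = \frac{n_{left}}{N_s} H(X_{left}) +
  \frac{n_{right}}{N_s} H(X_{right}),$$

with $H$ the child MSE. Candidate thresholds are midpoints between
consecutive distinct sorted feature values; the minimizing split is chosen
with ties broken by lowest feature index then lowest threshold, which
makes trees fully deterministic and lets the test suite compare every
chosen split against exhaustive enumeration on small instances. Score
comparisons treat candidates within a $10^{-12}$ relative tolerance as
tied so the tie rule, not floating-point rounding, decides.

Node importance is $n_k = w_k H_k - w_{left} H_{left} - w_{right}
H_{right}$ with all weights expressed as a node's share of the tree's
training samples. With this convention the per-tree node importances
telescope: they sum to the root-weighted impurity minus the weighted leaf
impurities, an identity the tests assert. A feature's importance is the
sum of $n_k$ over nodes splitting on it, normalized over all internal
nodes, and renormalized so the per-tree vector sums to one; the
forest-level importance is the mean of per-tree normalized vectors. (An
alternative reading of the node-importance weights — children weighted
relative to their parent rather than the total — breaks the telescoping
identity and does not match the standard MDI computed by mainstream
forest implementations, so the standard convention is used.)

Forest defaults are the usual regression conventions: 500 trees, bootstrap
resampling, per-node feature subsets of size $\max(1, \lfloor m/3
\rfloor)$, unlimited depth, minimum two samples to split and one per leaf.
Performance is evaluated with $R^2$, MSE, MAE and MAPE (percent) on a
held-out split drawn by uniform random assignment at a 9:1
training-to-testing ratio, without stratification. MAPE is undefined and
flagged `NA` when any observed value is zero; all metrics are computed on
the test split and that choice is recorded in the selection report's
metadata.

## Minimal-parameter model selection

Parameters are ranked by descending forest importance (alphabetical
tie-break). For each subset size $k$ the top-$k$ prefix of the ranking is
used to fit a fresh forest predicting WQI, always on the same train/test
partition so rows are comparable, and the subset's summed full-model
importance is reported as cumulative feature importance (the subset-sum
reading reproduces the expected monotone approach to 1; the alternative —
re-computing importances inside each sub-model — would not, and the choice
is recorded in the report metadata). Only prefixes of the ranking are
considered: non-prefix subsets are never part of this selection procedure.

"Comprehensive evaluation" across the four metrics is operationalized as:
choose the smallest subset whose metrics are all within a configurable
slack of the best value attained per metric. With zero slack this returns
the metric-optimal row; when no row is simultaneously within slack on
every metric, the row with the best mean rank (smallest $k$ on ties) is
returned. This rule is a design choice of the package, since no formal
criterion is standard.

## Uncertainty-weighted PMF

The receptor model decomposes the $n \times m$ concentration matrix as
$X = GF + E$ with $G \ge 0$ ($n \times p$ source contributions) and
$F \ge 0$ ($p \times m$ source profiles), minimizing

$$Q = \sum_{ij} \left(\frac{(X - GF)_{ij}}{U_{ij}}\right)^2 .$$

Uncertainties follow the receptor-modelling convention: $u =
\sqrt{(ef \cdot x)^2 + (MDL/2)^2}$ for uncensored entries (error fraction
$ef = 0.1$ by default, per-parameter configurable), and $u = \frac{5}{6}
MDL$ for below-detection entries, whose stored value is $MDL/2$ — the same
substitution the censoring stage applies, so the two conventions are
consistent by construction.

The optimizer is exact alternating nonnegative least squares: each
iteration solves every row of $G$ given $F$, then every column of $F$
given $G$, to optimality under nonnegativity with a Lawson–Hanson
active-set solver on the normal equations (the subproblems have only $p$
unknowns). Because each block update is exactly optimal, $Q$ is
non-increasing across iterations — a contract the tests assert — and on
noiseless exact-rank data the best start reaches $Q$ at numerical zero.
Convergence is declared when the relative $Q$ change falls below `tol`
(default $10^{-8}$) within `max_iter` (default 5000); the best of
`n_starts` (default 20) random nonnegative initializations is retained and
all per-start $Q$ values are reported. Runs that exhaust `max_iter` are
flagged, not raised as errors.

Factorizations are only identifiable up to permutation and scale, so
solutions are reported in canonical form: profile rows scaled to sum to
one (mass carried by $G$) and factors ordered by total modeled mass,
descending. Recovery tests always match factors under the best
permutation (enumerated; $p$ is small) before scoring. The species
contribution matrix is

$$c_{ji} = \frac{\sum_n G_{nj} F_{ji}}{\sum_{j'} \sum_n G_{nj'} F_{j'i}},$$

the share of species $i$'s modeled mass attributed to source $j$; columns
sum to one and the matrix is invariant to the factorization's mass units.

The factor count $p$ is a user decision; `pmf_p_sweep()` reports $Q$ and
$Q$ per degree of freedom ($nm - p(n+m)$) over candidate counts to support
it. Data from all stations are pooled into one matrix and every species is
kept at full weight (no "weak"/"bad" down-weighting), which the run
manifest records. pH is included as a species column even though it is
not a mass concentration — the standard caveat applies and is the user's
to weigh; the synthetic generator likewise treats pH and water temperature
outside the mass-mixture model (below). No rotational tooling (Fpeak-style)
is provided; canonical ordering only.

## Apportioning WQI variation to sources

The bridge between the forest and the receptor model is

$$p_j = (1 - \mathrm{MAPE}) \sum_i fn_i \, c_{ji},$$

reported in percent: source $j$'s contribution to WQI variation is the
importance-weighted sum of its species shares, shrunk by the surrogate
model's error, with the MAPE itself reported as an explicit model-error
row. MAPE enters as a fraction and is printed as a percent, resolving the
mixed usage cleanly. Since $\sum_i fn_i = 1$ and each $c$ column sums to
one, the source rows plus the model-error row total exactly 100% — the
conservation identity the acceptance tests check to $10^{-9}$. Parameters
carrying importance but absent from the PMF species set are not silently
renormalized; their mass appears as an explicit "uncovered importance"
row. Factors are labelled by dominance rules (mean share over a species
set above a threshold, 0.6 by default): faecal coliform for microbial
contamination, Fe/Mn for heavy metals, the nitrogen species and major ions
for non-point agriculture, TP for nutrient pollution, with "unexplained
variability" as the fallback label.

## The synthetic generator

The generator plants a known source structure so every downstream stage
can be scored against truth. Its defaults define the reference scenario:
four stations ordered upstream to downstream, 107 monthly samples per
station (428 records), five sources over the twelve mass species with
sparse-ish dominance signatures (a microbial source on faecal coliform, an
agricultural source on TN/NO3-N/SO4/Cl/F-, a background source on DO and
CODMn, a nutrient source on TP, a heavy-metal source on Fe and Mn), and
target long-run species means matching a typical subtropical urban river
(e.g. TN 1.54 mg/L). Per-sample source activities are the product of a
seasonal sinusoid (amplitude per source), a per-station log-linear
gradient factor normalized to mean one (so heavy-metal and microbial
pressure grows downstream without shifting overall means), and lognormal
source-level variability (CV 0.35); concentrations are activities times
profiles under multiplicative lognormal measurement noise with CV 0.10.
The multiplicative noise model keeps concentrations positive and
right-skewed without truncation artifacts, matching how such data behave.

pH and water temperature are not source-mass species: a mass-balance
receptor model does not physically generate them. They are simulated as
bounded baseline-plus-seasonal processes (pH as a clamped AR(1) around a
weakly acidic mean of 6.95; WT as an annual sinusoid around 17 °C) and
appended as columns, entering the forest and the PMF like any other
parameter. Censoring replaces below-detection values by MDL/2 and flags
them, matching the PMF uncertainty rule. Because real monitoring series
have gaps, the generator exposes a missing-at-random dropout rate (default
0) rather than guessing a completeness figure.

What the generator does not emulate — and hence what passing tests cannot
show about real data: hydrological routing and rainfall-runoff dynamics,
serial correlation in source activities beyond the seasonal cycle,
correlated analytical errors, geochemical speciation, long-term trends,
and structured (non-random) missingness. Recovery results on this
generator demonstrate correctness of the algorithms under the planted
model, not field validity of any particular source interpretation.

## Numerical choices and degenerate inputs

* Tree candidate thresholds are midpoints of consecutive distinct values;
  constant features and constant responses yield leaves, never errors.
* A forest in which no tree splits has undefined importance: all-`NA` with
  an `undefined` flag, rather than a silently uniform vector.
* CV is flagged `NA` (not an error) for zero-mean series; MAPE likewise
  for responses containing zeros.
* NNLS subproblems use a $10^{-12}$-scaled dual-feasibility tolerance; a
  factor that collapses to zero mass is kept (its profile row cannot be
  normalized and simply stays zero) and yields an effectively smaller
  model.
* The WQI engine validates that inputs are finite and that grading stays
  within $[0, 100]$; out-of-range requests raise errors rather than clamp
  silently.

## Problem sizes used by the test suite

The validation suite exercises the reference scenario at full size where
the contract demands it (428 samples, 14 parameters, 500-tree forests,
20-start PMF for recovery and determinism checks; 20 independent seeds for
the ranking-stability check; 10,000 randomized records for the index
contracts) and reduced sizes elsewhere (small forests and short series for
I/O and pipeline plumbing), chosen so the whole suite completes in a few
minutes on a single CPU while still covering every contract at the scale
it is stated.

## Known limitations

* MDI importance is biased toward high-cardinality features; all fourteen
  parameters here are continuous, which limits but does not remove the
  concern. Permutation importance and out-of-bag error are deliberately
  out of scope.
* PMF solutions are local minima; multi-start mitigates but does not
  guarantee global optimality, and rotational ambiguity can persist even
  at the optimum when the data are not sufficiently scattered.
* The apportionment statistic inherits both the forest's and the PMF's
  modelling error; only the forest's part is made explicit via the MAPE
  term, and no uncertainty propagation from the factorization is
  attempted.
* No alternative index formulations (NSF-WQI, CCME-WQI), no stepwise
  linear-regression surrogate baseline, and no classification mode.
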