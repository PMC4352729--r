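---
title: "Methods: integrative multi-omics network inference with vifnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative multi-omics network inference with vifnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vifnet)
```

`vifnet` infers, for each gene, a sparse set of non-mRNA regulators —
microRNAs, per-gene methylation values, gene-level copy-number calls — and
composes the per-gene models into a typed directed network, which is then
anchored to a seed-gene set, rescored jointly as a Gaussian Bayesian
network, and validated by survival analysis. This vignette documents the
model, the tunable parameters, the numerical choices, and what the
synthetic benchmark does and does not establish.

## Data model

Each molecular layer is a feature × sample matrix with a declared support:
expression layers are finite log2 values, methylation lies in [0, 1], and
copy-number calls are integers in {−2, …, 2}. Node identity is
layer-qualified (`methylation:TP53` and `mrna:TP53` are distinct nodes),
because the same gene symbol legitimately appears on three layers. Samples
are aligned by exact string intersection across the four layers; only
subjects measured on all four levels enter the analysis. Missing cells are
kept as missing; each per-gene regression drops incomplete samples for
that model only, which preserves the maximal n per model.

## Streamwise VIF regression

With p candidate predictors far exceeding n samples, per-gene subset
search is hopeless and even the lasso is costly at genome scale.
The engine therefore evaluates candidates in a single streamwise pass
(configurable via `n_passes`). Target and candidates are standardized
(`standardize = TRUE`), and for each candidate x the marginal t-statistic
against the current residual is divided by √ρ̂, where ρ̂ estimates the
fraction of x's variance orthogonal to the current model — the
variance-inflation correction that makes the cheap residual t-test agree
with the partial t-test of a joint refit. ρ̂ is estimated on a fixed
random subsample of `m = 200` rows (capped at n) and floored at 1e−8 to
avoid division blow-ups for near-collinear candidates.

Error control is alpha-investing: wealth starts at `w0 = 0.50`, the i-th
test runs at α_i = w_i/(2i), rejection spends α_i, and each acceptance
pays `dw = 0.05` back. These are the published defaults of the streamwise
algorithm and are kept as package defaults. Two consequences matter for
interpretation. First, the procedure controls the marginal false
discovery rate, not a per-gene familywise rate: the first few tests of a
stream run at liberal thresholds (0.25, ~0.06, ~0.03, …), so on short
streams roughly a quarter of genes admit one extra regulator beyond the
truth. Exact-set agreement with exhaustive best-subset search therefore
plateaus well short of certainty (the acceptance script reports the
measured rate as `oracle_match_rate`) even though the true
regulators themselves are essentially always recovered; the false
positives are supersets, not substitutions. Second, on genome-scale
streams the thresholds decay quickly, which is what keeps whole-genome
false positives rare. Zero-variance candidates are skipped without
spending alpha, a `max_selected = 50` cap guards pathological streams,
and the candidate order is a random permutation under a per-gene seed
derived from the global seed and the gene symbol — so batch results are
independent of execution order and batch composition.

After the pass, the selected set is refit jointly by OLS on the original
scale and adjusted R² = 1 − (1 − R²)(n − 1)/(n − p − 1) of that refit is
reported; the joint refit (rather than the streamwise fit) is used because
it is the quantity the downstream cutoff is meant to certify. Degenerate
inputs are defined: a constant target yields an empty selection with
adjusted R² = 0, and fewer than 10 complete samples flags the result
unusable rather than failing the batch.

## Network assembly

Models with adjusted R² ≥ 0.4 (the cutoff is inclusive, a declared choice)
contribute one edge per selected regulator, carrying the refit coefficient
as the edge weight — the sign distinguishes repressive methylation or
miRNA effects from activating copy-number effects. Raising the cutoff can
only remove edges; every edge traces to exactly one (gene, regulator)
pair of one passing model. No multiplicity correction is applied across
genes beyond the R² cutoff itself; the refinement stage is the mechanism
that removes edges unsupported by the joint distribution.

## Seed subnetwork and Bayesian refinement

The subnetwork of a seed-gene list contains the seed genes' mRNA nodes
plus their direct regulators — strictly one hop; regulators of regulators
are excluded — together with the supplied prior gene–gene regulations.
Refinement assembles the node × sample matrix for those nodes and runs
score-based structure learning: hill climbing over single-edge additions,
deletions and reversals, with `restarts = 10` random restarts (the first
start is the whitelist-only graph; the others perturb it with a random
~15 % of the allowed edges), a `max_parents = 5` cap, BIC-penalized
Gaussian local scores (ML variance; `log(n)/2` per parameter, counting
slope, intercept and variance), and prior edges whitelisted — never
deleted, never reversed. All four data types enter as continuous
variables, including the integer copy-number calls; a discretization rule
would add assumptions the data do not force, and the linear-Gaussian
score is the one the regression stage already presumes.

By default the search is restricted to the candidate edges: the
regression and prior edges *in their proposed orientations*, with a
reversal legal only where the reversed pair is itself a candidate. The
orientation-strict rule is deliberate. The refinement exists to prune
indirect regulations — when B drives both A and m, the regression may
report both B→A and m→A, and conditioning on B should eliminate m→A. If
the search were free to add the reversed edge A→m, the score would keep
the spurious adjacency in reversed orientation (the marginal m–A
correlation is real, and a chain B→A→m captures it), and the pruning the
stage exists for would essentially never happen. Restricting additions to
the regulator→gene hypothesis space makes the conditional-independence
pruning effective; the unrestricted search (`candidate_edges_only =
FALSE`) remains available and is used in the equivalence-class tests. An
optional `layer_blacklist` forbids edges into copy-number and methylation
nodes; it is off by default, since cross-layer edges in several
orientations are biologically interpretable and the whitelist already
encodes the hard prior knowledge.

The learned DAG is reported as a partially directed graph: v-structure
edges and whitelist edges are pinned, the orientation closure applies
Meek rules R1–R3, and the remaining edges — those whose orientation
differs across the score-equivalence class — are emitted as undirected
("two-arrow") regulations. Starting from a DAG's v-structures, the R1–R3
closure is exactly the completed PDAG of the equivalence class; with
whitelist pinning the labeling remains sound, though in rare
background-knowledge configurations (the province of rule R4) it may
leave an edge undirected that is in fact compelled — a conservative
failure mode.

## Survival validation

Candidate drivers are validated by median dichotomization: covariate
values strictly above the median go to the high group, values equal to
the median go low (a declared tie rule). The Kaplan-Meier estimator and
the two-group log-rank test are implemented from first principles — the
product-limit curve steps only at event times, censoring at an event time
counts as at-risk for that time, tied events are aggregated per distinct
time with the standard hypergeometric moments, and the statistic
(O − E)²/V is referred to chi-square(1). The test suite verifies both
against the `survival` package to ~1e−9 and against hand-evaluated O/E/V
sums to 1e−10, and checks the empirical size of the test at α = 0.05
over 500 null replicates.

## The synthetic benchmark

The generator draws miRNA expression as Gaussian log2 values, methylation
as Beta variables (concentration 10, means uniform on [0.2, 0.8]), and
copy-number calls categorically with 70 % diploid mass and symmetric
tails. A configurable fraction of genes (default 0.5) receives k
regulators (k uniform on 2–5) drawn uniformly without replacement across
the three regulator layers; regulated expression is intercept + weighted
standardized regulators + Gaussian noise, with the noise SD set so the
signal explains `target_r2 = 0.6` of the realized signal variance.
Effect signs default to repressive for miRNA and methylation and
activating for copy number, and effect magnitudes are uniform on
[0.5, 1.5] on the standardized scale — so each regulated gene carries
both strong and weak regulators. Survival times are exponential with
log-hazard linear in the designated driver gene's standardized
expression; censoring is an independent exponential clock calibrated to
the requested censoring fraction at a null effect. Everything is
bit-reproducible under the configuration seed.

The default desk-scale dimensions — 200 genes, 50 miRNAs, 200 methylation
and 200 copy-number features, 150 samples — keep p ≫ n (650 candidates
per gene) while running in seconds. What passing on this benchmark shows:
the selection engine separates true linear regulators from 650 correlated
alternatives at realistic sample sizes, the assembly cutoff excludes
pure-noise genes, the refinement prunes indirect edges, and the survival
machinery has correct size and power. What it does not show: robustness
to nonlinear regulation, batch effects, probe-level methylation
structure, copy-number segment correlation, feedback loops (the truth
here is acyclic by construction), or mis-specified likelihoods — real
multi-omics data violate all of these to some degree, and results there
warrant the usual skepticism.

## Problem sizes and numerical choices

The test suite and the acceptance script use the default study above for
recovery checks (one fit of 200 genes takes a few seconds), 100
replicates of 20-candidate instances for the exhaustive-search
comparison, 50 replicates of the three-node indirect-regulation scenario
at n = 500, exhaustive 25-DAG enumeration as the structure-learning
oracle, and 500 null replicates for the log-rank size check. Fixed seeds
make every one of these deterministic. Ties in hill climbing are broken
by first-encountered move at equal score delta (score improvements below
1e−8 stop the climb); the whitelist is validated to be acyclic before
search; and pipeline artifacts are written with MD5 checksums so a rerun
under the same seed can be verified bit-identical.

## Limitations

Per-gene models are marginal: a regulator acting only jointly with
another can be missed, and shared regulators induce correlated residuals
across genes that the assembly ignores. The Bayesian stage treats
GISTIC integers as Gaussian, which is a pragmatic approximation; its
equivalence-class output means some regulations are reported without
orientation, by design. The survival module implements exactly the
median-split log-rank comparison — no Cox adjustment for covariates — so
it validates prognostic association, not independent prognostic value.
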