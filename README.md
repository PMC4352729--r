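# vifnet

Integrative multi-omics regulatory network inference in R: streamwise
VIF regression, adjusted-R² network assembly, seed-gene subnetwork
extraction, Bayesian-network refinement with prior edges, and
median-split survival validation.

## The problem

Tumour gene expression is shaped simultaneously by microRNAs, promoter
methylation and copy-number change. Given four matched feature × sample
matrices — log2 gene expression, log2 miRNA expression, per-gene
methylation levels in [0, 1], and GISTIC-style gene-level copy-number
calls in {−2, …, 2} — `vifnet` asks, for every gene, which of the tens of
thousands of non-mRNA features regulate it, and assembles the answers into
one typed directed network. The package is aimed at computational
biologists who want the whole chain — variable selection at p ≫ n, network
assembly, pathway-anchored refinement, survival validation — as tested,
seedable R functions, plus a synthetic-data generator with known ground
truth so every stage can be benchmarked without any restricted data.

## The method

For each gene *g* with expression *y*, all miRNA/methylation/CNV features
are candidate predictors. Candidates are streamed in random order; for
candidate *x* the marginal t-statistic against the current residual *r*,

&nbsp;&nbsp;&nbsp;&nbsp;t = xᵀr / (σ̂ √(xᵀx)),

is corrected by the estimated variance inflation factor, t* = t / √ρ̂,
where ρ̂ is the share of x's variance not explained by the already-selected
predictors (estimated on a random subsample of m rows). The corrected
p-value is tested against an alpha-investing threshold αᵢ = wᵢ / (2i):
acceptance adds the candidate and pays Δw into the wealth, rejection
spends αᵢ. Selected sets are refit by OLS and genes with

&nbsp;&nbsp;&nbsp;&nbsp;adjusted R² = 1 − (1 − R²)(n − 1)/(n − p − 1) ≥ 0.4

contribute their regulator → gene edges to the integrative network. A
seed-gene list (e.g. a pathway) induces the subnetwork of seed genes and
their direct regulators; hill-climbing Gaussian Bayesian-network learning
with the prior gene–gene regulations whitelisted rescores that subnetwork,
prunes regression edges the joint model does not support, and labels each
surviving edge as compelled (directed) or reversible (undirected) via its
Markov-equivalence class. Candidate drivers are validated by splitting
samples at the median of the driver's expression and comparing the two
Kaplan-Meier curves with the log-rank test (implemented from first
principles; it agrees with `survival::survdiff` to machine precision).

## Worked example

```r
library(vifnet)
study <- simulate_study(sim_config(n_genes = 60, n_meth = 60, n_cnv = 60,
                                   n_mirna = 20, n_samples = 150, seed = 42))
study$dataset
#> <multiomics_dataset> 150 common samples
#>   mrna: 60  mirna: 20  methylation: 60  cnv: 60 features

fits <- fit_all(study$dataset, vif_config(seed = 42))
glance(fits)
#> # A tibble: 1 × 5
#>   n_genes n_usable n_selected_total median_adj_r2 max_adj_r2
#> 1      60       60              120         0.284      0.717

net <- assemble_network(fits, cutoff = 0.4)
net
#> <integrative_network> 105 nodes, 104 edges (0 undirected)

score_edges(net, study$truth)
#> # A tibble: 1 × 5
#>   n_true n_found    tp precision recall
#> 1    111     104    95     0.913  0.856

val <- survival_validation(study$survival)
val$logrank
#> Log-rank test: chi-square = 34.1290 (1 df), p = 5.158e-09
#>   groups low/high: n = 75/75; O = 45, E = 72.01
```

Half of the 60 simulated genes carry 2–5 true regulators tuned to explain
60 % of their variance; the rest are noise. The assembled network recovers
95 of the 111 true regulator → gene edges (precision 0.91, recall 0.86)
and no noise gene passes the 0.4 cutoff. The survival table couples the
hazard to the designated driver gene, and the median split detects it at
p ≈ 5 × 10⁻⁹; here the high-expression group has fewer observed deaths
than expected (O = 45 vs E = 72) because the driver's effects are
repressive in the default sign convention. `extract_subnetwork()`,
`refine_network()` and `run_pipeline()` continue the chain; results come
back as tibbles (`tidy()`, `glance()`) and plots (`autoplot()`).

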