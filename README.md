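# mirlasso

Network-based prediction of miRNA-mRNA interactions from paired expression
profiles.

A miRNA represses its target mRNAs, and one miRNA can regulate many genes.
Given a miRNA and an mRNA expression matrix over the same tumor samples plus
a clinical table, `mirlasso` (i) splits the samples into two groups by a
clinical endpoint (1-year survival, ER status, or pathological stage),
(ii) keeps the features that differ between the groups — Student's *t*-test
*P* < 0.05, then fold change > 1.5 or < 0.667, (iii) estimates one sparse
Gaussian graphical model over the retained miRNAs and mRNAs jointly by
maximizing the L1-penalized log-likelihood

```
log det θ − tr(Sθ) − ρ‖θ‖₁
```

(graphical lasso; S is the empirical covariance of the integrated matrix Z,
θ its estimated inverse), and (iv) reads the bipartite miRNA-mRNA edges of
θ as predicted interactions: a nonzero off-diagonal entry of the precision
matrix means the two features remain dependent after conditioning on all
others. miRNAs are ranked by their number of connected mRNAs (hub degree),
and mRNAs connected to several miRNAs are reported as multi-target genes.

The solver is an authored block-coordinate-descent graphical lasso in
compiled code (Rcpp/RcppArmadillo) with KKT certification on every fit, and
the package ships a synthetic-data generator that plants known differential
effects and a known sparse precision matrix, so every stage can be tested
against ground truth.

## Worked example

Simulate a cohort with four planted hub miRNAs of degrees 14, 11, 8, 5 and
run the full pipeline (tab-separated files work the same way — pass paths
instead of objects):

```r
library(mirlasso)

sim <- simulate_dataset(n_mirna = 10, n_mrna = 120,
                        hubs = data.frame(mirna = 1:4, degree = c(14, 11, 8, 5)),
                        offdiag = 0.25, n_per_group = 300, de_effect_log2 = 2,
                        seed = 42)

man <- run_pipeline(list(
  expr_mirna = sim$mirna, expr_mrna = sim$mrna, clinical = sim$clinical,
  rule = "survival_1yr", transform = "none", scale = "correlation",
  rho = 0.12, out_dir = "demo"))
#> read: 10 miRNAs, 120 mRNAs, 600 clinical samples
#> groups (survival_1yr): 300 vs 300 samples, 0 excluded
#> differential: 4/10 miRNAs, 35/120 mRNAs pass
#> glasso: rho = 0.12, 4 sweeps, converged
#> network: 88 edges (39 bipartite), 4 ranked hubs, 0 multi-target mRNAs

read.table("demo/hubs.tsv", header = TRUE, sep = "\t")
#>     mirna degree
#> 1 mir-001     14
#> 2 mir-002     12
#> 3 mir-003      8
#> 4 mir-004      5
```

The differential filter keeps the 4 planted hub miRNAs and 35 mRNAs (the
planted targets plus a couple of false positives at the nominal
thresholds); the graphical lasso at ρ = 0.12 on the correlation-scaled,
group-centered covariance yields 39 bipartite edges, and the degree ranking
recovers the planted hub order — degrees 14, 12, 8, 5 against the planted
14, 11, 8, 5. Outputs land in `demo/`: per-feature DE tables, the θ matrix,
full and bipartite edge lists, the hub ranking, the multi-target report,
and `manifest.json` with per-stage counts and timings. Reruns of the same
config on the same inputs are byte-identical.

Lower-level pieces compose the same way:

```r
g    <- assign_groups(sim$clinical, "survival_1yr")
de   <- select_differential(sim$mrna, g)             # tibble: P, FC, passes
z    <- integrate_expression(sim$mirna, sim$mrna)
fit  <- graphical_lasso(empirical_covariance(z, "none", "correlation"),
                        rho = 0.12)
tidy(fit)      # edge table with precision entries and partial correlations
glance(fit)    # one-row fit summary (edges, objective, KKT residual)
net  <- bipartite_view(build_network(fit))
rank_hubs(net, top_k = 20)
multi_target_genes(net, min_mirnas = 3)
```

`autoplot()` methods exist for DE tables (volcano), hub rankings (degree
bars), and penalty paths (sparsity profile). A flat-file entry point is
`scripts/run_pipeline.R --config run.cfg` (see `?read_run_config` for the
format). The methods vignette (`vignettes/network-inference.Rmd`) documents
the model, every default, and the generator's scope.

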