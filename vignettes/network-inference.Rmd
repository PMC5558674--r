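---
title: "Inferring miRNA-mRNA interaction networks with mirlasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring miRNA-mRNA interaction networks with mirlasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlasso)
```

## The problem

MicroRNAs repress mRNAs post-transcriptionally, and a single miRNA can
regulate many genes. Given paired miRNA and mRNA expression matrices from a
tumor cohort, we want to propose candidate miRNA-mRNA regulatory
interactions and to rank miRNAs by how many genes they appear to regulate.
mirlasso implements a network strategy for this: filter both molecule
classes down to the features that differ between two clinically defined
patient groups, then estimate a single sparse Gaussian graphical model over
the retained miRNAs and mRNAs jointly, and read the miRNA-mRNA edges of
that model as predicted interactions.

The appeal of a graphical model over plain correlation is conditional
independence: an entry of the precision matrix $\theta = \Sigma^{-1}$ is
zero exactly when the two features are independent given all the others, so
an edge survives only if the association is not explained away by the rest
of the profile.

## The pipeline

1. **Group assignment** (`assign_groups()`). Samples are split in two by a
   clinical endpoint: survival $\le$ 365 days vs longer (`survival_1yr`;
   day 365 counts as the high-risk side), estrogen-receptor negative vs
   positive (`er_status`), or pathological stage III/IV vs I/II (`stage`).
   Samples missing the endpoint are excluded and reported. Survival is used
   as recorded; censoring is out of scope and flagged with a warning.
2. **Differential filter** (`select_differential()`). Per feature, a
   two-sided pooled-variance (Student's) $t$-test between the groups, then,
   among features with $P < 0.05$, a fold-change gate: group-A mean over
   group-B mean strictly above 1.5 or strictly below 0.667. The bounds are
   used as printed rather than as exact reciprocals (0.667 vs $1/1.5$);
   the difference is negligible but the choice must be deterministic. No
   multiple-testing correction is applied — the cutoff is deliberately
   nonstringent, since the network stage provides the real selectivity.
3. **Integration** (`integrate_expression()`). The surviving miRNAs (block
   first) and mRNAs are column-bound into one matrix $Z$ over the shared
   samples.
4. **Graphical lasso** (`empirical_covariance()` + `graphical_lasso()`).
   $S$ is the maximum-likelihood ($1/n$) covariance of $Z$, and $\theta$
   maximizes the penalized log-likelihood
   $\log\det\theta - \mathrm{tr}(S\theta) - \rho\lVert\theta\rVert_1$ with
   the entrywise L1 norm.
5. **Network** (`build_network()` and friends). Features are nodes; pairs
   with $|\theta_{ab}|$ above a numerical floor are edges. The bipartite
   miRNA-mRNA view drives all reports: miRNAs ranked by the number of
   connected mRNAs (`rank_hubs()`), and mRNAs connected to at least 3
   miRNAs (`multi_target_genes()`).

`run_pipeline()` executes the stages in order, writes one file per stage
plus a JSON manifest (config, per-stage counts, convergence, timings), and
is byte-reproducible across reruns of the same config on the same inputs.

## Decisions worth knowing about

**Degenerate t-test.** If both groups are constant the statistic is
undefined; we return $P = 1$ when the means are equal (no evidence of
difference) and $P = 0$ otherwise (the zero-variance limit). Fold change is
undefined when the denominator group mean is zero; such features never pass.

**Fold-change direction.** The numerator is always group A (high-risk /
ER-negative / stage III-IV). The symmetric thresholds make the pass set
essentially direction-free; the convention only fixes labels.

**Covariance divisor.** $1/n$, not $1/(n-1)$: the penalized log-likelihood
is the ML objective, and a different divisor would silently rescale the
effective penalty.

**Transforms and scale.** Read counts are far from Gaussian, so the default
for network estimation is `log2(x + 1)` followed by correlation scaling
(unit diagonal). Both are overridable (`transform = "none"`,
`scale = "covariance"`) for strict literalism. On correlation input the
edge set is invariant to per-feature rescaling of the data, which is the
property one actually wants from a penalty applied uniformly across
features.

**The penalty scale.** The reference analysis fixes $\rho = 2.0$, which is
meaningful on the raw-count covariance scale where entries are in the
hundreds or thousands. On a correlation-scaled $S$ every off-diagonal is at
most 1, so any $\rho \ge 1$ returns an empty network; sensible values there
are roughly 0.05-0.5. `run_config()` keeps 2.0 as the documented default;
`glasso_path()` explores a penalty grid with warm starts when the scale is
in doubt. No automatic selection policy is provided.

**Entrywise penalty.** The L1 term is the entrywise sum
$\sum_{ij}|\theta_{ij}|$ (diagonal included, which pins the dual diagonal
at $S_{ii} + \rho$) — the penalty of the standard graphical-lasso
formulation — not the induced maximum-column-sum matrix norm.

**Within-group centering.** Features that survive the differential filter
carry a group-mean difference *by construction*. Pooling both groups into
one covariance therefore adds a dense between-group component to every pair
of differential features, which can dominate the within-group dependence
structure the graphical model is supposed to capture (in simulations it
visibly scrambles hub degrees). `empirical_covariance(groups = ...)`
centers each feature within each group first, and the pipeline does this by
default (`center_groups = TRUE`). Disabling it reproduces the literal
pool-then-estimate behavior.

**Edges.** A pair is connected iff $|\theta_{ab}| > 10^{-8}$ after
convergence: solvers produce numerically small values rather than hard
zeros, and any genuinely selected edge is orders of magnitude above this
floor. Hub ties are broken lexicographically by miRNA ID so that top-$k$
cuts are reproducible; zero-degree miRNAs are not listed.

## The solver

`graphical_lasso()` is a block coordinate descent in compiled code: sweep
over columns in input order; for column $j$, solve the lasso subproblem
$\min_\beta \tfrac12\beta^\top W_{11}\beta - s_{12}^\top\beta +
\rho\lVert\beta\rVert_1$ by cyclic coordinate descent with
soft-thresholding (inner tolerance $10^{-6}$, cycling in input order — no
randomization, so runs are bit-reproducible); update the dual covariance
iterate $W$. Convergence is declared when the mean absolute off-diagonal
change of $W$ per sweep drops below `tol` ($10^{-4}$ by default) times the
mean absolute off-diagonal of $S$, within at most 100 sweeps. $\theta$ is
recovered from $(W, B)$ at the end, symmetrized, and checked for positive
definiteness.

Every fit carries a KKT certificate: off-diagonally
$|W_{ij} - S_{ij}| \le \rho$ with equality of sign-consistent magnitude
where $\theta_{ij} \ne 0$, and $W_{ii} = S_{ii} + \rho$; the largest
violation is reported as `kkt_residual`. The test suite additionally checks
the solver against an independently written ADMM solver of the same
objective, against closed forms (diagonal $S$; the $2\times 2$
soft-threshold solution; full shrinkage at $\rho \ge \max|s_{ij}|$), and
for permutation equivariance. `glasso_path()` warm-starts along a
decreasing penalty grid and agrees with cold starts to within $10\times$
the tolerance.

Non-convergence at `max_iter` is not an error: the estimate is returned
with `converged = FALSE` and the residual, `build_network()` refuses it
unless forced, and the pipeline proceeds with a warning plus a manifest
flag.

## The synthetic-data generator

Real tumor cohorts come with no ground truth, so the generator plants one.
`make_precision()` builds a joint precision matrix with unit diagonal and
$\pm$`offdiag` entries connecting chosen hub miRNAs to mRNA targets sampled
without replacement, then adds the smallest ridge $\delta I$ keeping the
minimum eigenvalue at or above 0.1. `sample_expression()` draws
$N(\mu_g, \theta_{\mathrm{true}}^{-1})$ latent log2 profiles for two
equal-sized groups, shifting group A's mean by `de_effect_log2` on the
planted differential features — by default exactly the features incident to
planted edges, mirroring the sequential design in which the differential
filter gates what the network stage sees. Gaussian output emits the latent
values; `nb_counts` emits negative-binomial counts with mean
$2^{\mathrm{latent}}$ and fixed dispersion 0.1 (the generator's job is
structure, not realism). The clinical table encodes the planted split
redundantly in all three endpoints, so every grouping rule reconstructs it.

The baseline latent level is 3 (on the log2 scale, a moderately expressed
feature). It was chosen once so that the planted shifts used throughout
(+2 and +3) put the expected fold change at $5/3 \approx 1.67$ and $2$ —
clear of the 1.5 gate rather than exactly on it, which a baseline of 4
with a +2 shift would produce.

Everything is driven by a single stated RNG (Mersenne-Twister with
inversion normals) under an explicit seed; identical seeds give identical
data on any platform.

What the generator does **not** emulate: library-size and batch effects,
count overdispersion structure per gene, censored survival, missing data,
sequence-based targeting, and correlated (non-hub) background structure.
Passing tests therefore validate the statistics and the software on data
satisfying the model's assumptions; they do not certify biological
recovery rates on real cohorts.

## Problem sizes in the test suite

The suite validates solver accuracy on 50 random problems of 3-6 features
against the ADMM oracle ($\le 10^{-4}$ max-abs agreement), KKT certificates
on 100 random problems, differential-filter calibration on 20 null cohorts
of 500 features at 200 samples per group, support recovery on ten
20-miRNA/200-mRNA cohorts with five planted degree-10 hubs at 600 samples
(mean best-penalty bipartite F1 $\ge 0.7$ along a seven-point penalty
path), network algebra on 1000 random graphs, and byte-identical pipeline
reruns. These sizes keep the full suite under a couple of minutes on one
CPU while leaving each check statistically meaningful.

## Limitations

- The Gaussian model is a working approximation for transformed counts; the
  default transform helps but heavy tails and zero inflation remain.
- A single fixed $\rho$ is a modeling choice, not an estimate; the path
  utility explores it but deliberately does not select.
- Degree-based hub ranking counts mRNA neighbors only; miRNA-miRNA and
  mRNA-mRNA edges are retained in the full network output but excluded
  from rankings and reports.
- Edge signs (activation vs repression) are available through the sign of
  $\theta_{ab}$ (`tidy()` reports the partial correlation) but are not
  interpreted by the pipeline.
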