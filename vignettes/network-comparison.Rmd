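---
title: "Comparing functional connectivity networks between groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing functional connectivity networks between groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnetdiff)
```

## The problem

Resting-state fMRI studies summarize each subject's brain as a functional
connectivity (FC) network: `V` regions of interest, and for every region
pair an edge weight given by the Fisher z-transformed Pearson correlation of
the two regional time series. With `E = V(V-1)/2` edges, the question
"do cases and controls differ in their connectivity pattern?" is a
two-sample comparison of `E`-dimensional mean vectors. Three features make
this hard:

* the edges are correlated with each other, and their dependence follows the
  latent community (cluster) structure of the nodes rather than spatial
  distance;
* `E` grows quadratically in `V`, so an unstructured `E x E` edge
  covariance has far more parameters than subjects;
* subjects within a group are heterogeneous — each individual's network
  deviates from the group mean by more than measurement noise.

`fcnetdiff` addresses all three: a Dirichlet-process (DP) mixture clusters
the *nodes* and thereby ties the `E x E` edge covariance to a handful of
correlation factors; a low-dimensional between-subject component
(scaled identity or compound symmetry) is estimated iteratively together
with the edge effects; and inference is by permutation, at the
whole-network and single-edge levels, with Benjamini–Hochberg FDR control
across edges.

## Model

### Edge covariance through node clustering

Per subject `n`, the edge vector `Y_n` (length `E`) is modelled as
multivariate normal. After removing the design (intercept-only by default:
each group's edge means), the residuals `R_n ~ MVN(0, Lambda)` carry an
`E x E` correlation structure determined by a node partition `omega` and
correlation factors `rho = (rho_0, rho_1, ..., rho_K)`:

* entry `(e_{ij}, e_{i'j'})` of `Lambda` equals `rho_k` when all four
  regions `i, j, i', j'` lie in cluster `k`;
* every other off-diagonal entry equals `rho_0`;
* the diagonal is 1.

The partition follows a DP prior with concentration `alpha` (marginalized
to its Chinese-restaurant-process conditionals), and each correlation
factor has a normal prior. The posterior kernel is

```
-N/2 * ( log|Lambda| + tr(H Lambda^{-1}) ) + log CRP(omega) + log priors(rho)
```

with `H` the correlation-standardized residual cross-product
`H = D^{-1/2} H0 D^{-1/2}`, `H0 = R'R/(N-p)`, `D = Diag(H0)`.

`Lambda` is never manipulated densely inside the sampler. Writing
`Lambda = A + rho_0 11'` with `A` block-equicorrelated over the
within-cluster edge sets gives closed-form block eigenvalues, a closed-form
`A^{-1}`, and the Sherman–Morrison identity for the rank-one term — one
likelihood evaluation costs `O(E^2)` instead of `O(E^3)`. The same
decomposition defines which states are admissible: a state is treated as
valid exactly when every block eigenvalue of `A` is positive and the
rank-one denominator `1 + rho_0 1'A^{-1}1` is positive; anything else gets
log-posterior `-Inf`. This is slightly conservative (a structure can be
positive definite while `A` is not, when `rho_0` exceeds a within-cluster
factor), but it keeps validity checkable in closed form and is the region
the sampler explores.

The sampler alternates (i) a Gibbs sweep over nodes in ascending index
order — each node may join an existing cluster with weight proportional to
the cluster's size (excluding the node) times the likelihood, or open a new
cluster with weight proportional to `alpha`, the new cluster's factor drawn
from its prior (a node currently alone keeps its factor) — and (ii) one
Gaussian random-walk Metropolis step per correlation factor. The sweep
order is fixed for reproducibility. The point estimate is plug-in, as the
downstream GLS needs a single covariance: the retained draw with the
highest log posterior gives the partition (earliest draw on ties), and the
factors average the retained draws sharing that partition. Finally
`Sigma_hat = D^{1/2} Lambda_hat D^{1/2}` returns to the covariance scale;
in the simulation design the residual variances are near 1 and
`Sigma_hat` is close to `Lambda_hat`.

The inner loop is compiled (RcppArmadillo) and draws from R's RNG, so a
seed makes estimation bit-reproducible. Exported R implementations of the
single sweeps (`gibbs_update_omega()`, `mh_update_rho()`,
`log_posterior_kernel()`) mirror the compiled chain and are what the test
suite checks against enumeration and grid oracles; a dedicated test pins
the compiled likelihood to the R closed form.

### Heterogeneity and GLS

Subject-level deviation from the group covariance is captured by `psi`,
either `sigma^2 I` (scaled identity) or compound symmetry (`sigma^2` on
the diagonal, `b` off it). Under the subject-wise model
`Y_n ~ MVN(X_n' beta, Sigma + psi)` with independent subjects, the common
`E x E` weight cancels and GLS for `beta` reduces to ordinary least
squares, with `var(vec beta_hat) = (X'X)^{-1} (x) (Sigma_hat + psi)`; for
the intercept-only design, `beta_hat` is the vector of per-edge group means
and `var(beta_hat) = (Sigma_hat + psi)/N`. This Kronecker reading is the
only dimensionally coherent way to combine a per-subject `E x E` covariance
with the variance sum used by the network statistic, and it is what
`estimate_beta()` implements (a dense stacked-system GLS oracle confirms it
in the tests).

`fit_group()` alternates the effect estimate, residual formation, and the
moment update of `psi`: `sigma^2` is the mean diagonal of
`Omega_hat - Sigma_hat` (with `Omega_hat` the average residual outer
product), `b` the mean off-diagonal. Because the intercept-only `beta_hat`
is free of `psi`, the second pass is a fixed point and the iteration stops
there; the loop remains in place for future designs. Negative moment
estimates are clamped — `sigma^2` floored at 0, `b` clipped to
`[-sigma^2/(E-1) + 1e-10, sigma^2]` so `psi` stays positive semidefinite.
The clamp choice is recorded in the fit object; the estimators themselves
say nothing about negative values.

### Inference

The whole-network hypothesis uses the Hotelling-type quadratic form

```
T = (b1 - b2)' ( var(b1) + var(b2) )^{-1} (b1 - b2)
```

with the identity contrast over all `E` edges, and each edge `e` uses the
squared plug-in z-score
`(b1(e) - b2(e))^2 / (var(b1)(e,e) + var(b2)(e,e))`. Neither statistic is
referred to a parametric distribution: the null is rebuilt by permuting
group labels (sizes preserved). For every permutation the edge effects and
`psi` are re-estimated; the two `Sigma_hat` matrices are *frozen* at their
observed-label estimates (pseudo-group 1 paired with group 1's estimate,
and so on). Re-running the MCMC inside each of hundreds of permutations is
computationally out of reach, and freezing the slowly varying covariance
while re-estimating the mean and heterogeneity parameters preserves the
exchangeability the test needs; the choice is flagged in every output.
p-values use the add-one convention `(1 + #{perm >= obs})/(B + 1)`, so
they never reach 0 and are bounded below by `1/(B+1)`. Edge-wise p-values
use each edge's own permutation distribution and are then FDR-adjusted
(Benjamini–Hochberg step-up, via `stats::p.adjust`).

Because `Sigma_hat` and the group sizes are fixed across permutations, the
`psi`-free part of the variance sum `C0 = Sigma1/N1 + Sigma2/N2` is
eigendecomposed once; each permutation then costs one `E`-vector rotation
and a diagonal solve (plus one rank-one correction under compound
symmetry). A test asserts that this fast path coincides with literally
re-running `fit_group()` and `network_statistic()` per permutation.

## Simulation engine

`scenario_config()` encodes the study conditions: `V` in 20–30 with two
equal latent node clusters (first half / second half; `ceiling`/`floor`
for odd `V`), within-cluster correlation `rho` in {0.3, 0.5, 0.7},
between-structure correlation 0, per-subject scalar `u ~ Uniform(-delta,
delta)` added to every diagonal entry (delta 0.15 = low, 0.3 = high
heterogeneity), per-group sizes 10 or 25, and a sparse alternative: `d =
0.8` at `round(0.05 E)` edges drawn once per scenario, the control group's
mean shifted by it. Power and type-I error are rejection proportions over
`n_reps = 100` replicates of `B = 500` permutations at `alpha = 0.05`;
a null run is the same code path with `effect_size = 0`. The shift support
is fixed across replicates, so a power estimate refers to a single
alternative — redrawing it per replicate would average over alternatives
instead. The subject effect is one scalar per subject (consistent with the
scaled-identity heterogeneity model), not an independent perturbation per
edge.

Two knobs exist for desk-scale work and are first-class configuration, not
test-time hacks: `sigma_method = "oracle"` injects the true structure as
`Sigma_hat`, isolating the inference layer from MCMC noise (used for
type-I calibration); and reduced replication (e.g. 50 replicates of 200
permutations) widens the Monte-Carlo tolerance accordingly. The scenario
default for the DP chain is 400 sweeps with 200 burn-in, against
2000/1000 for one-off estimation: at these dimensions the two-block
partition is typically identified within tens of sweeps, and a replicated
experiment multiplies any excess chain length by hundreds of runs. The
acceptance script documents the problem sizes it runs (50 replicates, 200
permutations per target scenario).

What the generator deliberately does not emulate: temporal autocorrelation
of the underlying time series (edge vectors are drawn directly), site or
motion artefacts, non-Gaussian tails, and within-group mixtures of
distinct connectivity phenotypes. Passing the simulation-based checks
therefore says the method is calibrated and powerful under its own data
model, not that real resting-state data satisfy that model.

## Defaults and numerical choices

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` (DP) | 1 | concentration; prior mean number of clusters ~ `log V` |
| `mu0`, `tau0_sq` | 0, 0.25 | prior on the between-structure correlation |
| `muk`, `tauk_sq` | 0, 0.25 | prior on each within-cluster correlation |
| `proposal_sd` | 0.05 | random-walk step for the factor updates |
| `n_iter`, `n_burn` | 2000, 1000 | chain length (400/200 in scenario runs) |
| `tol`, `max_iter` | 1e-6, 100 | heterogeneity iteration |
| asymmetry tolerance | 1e-8 | inputs symmetrized below it, rejected above |
| ridge | `1e-8 tr(M)/E` | only if the variance sum is numerically singular |

The factor priors are weakly informative on the correlation scale (sd 0.5
around 0); they keep proposals inside plausible ranges without pulling the
posterior noticeably at `N >= 10`. Chain initialization is a single
cluster with all factors at 0 (the identity structure, always admissible);
tie-breaks in the point estimate go to the earliest retained draw. Cluster
labels are canonicalized to first-occurrence order after every sweep, so
reported partitions are label-invariant.

## Known limitations

* Beyond `V ≈ 30` the `O(E^2)` likelihood evaluations make the sampler
  expensive; this mirrors the method's intended operating range.
* Covariates other than the intercept are plumbed through `estimate_beta()`
  but not through the test statistics; group comparison is of means only.
* The plug-in point estimate ignores posterior uncertainty in
  `(omega, rho)`; no uncertainty is propagated into the test statistics.
* Only whole-network and single-edge hypotheses are addressed — no
  cluster/subnetwork-level inference.
* `Sigma_hat` frozen under permutation (see above) is an approximation to
  full re-estimation; it is recorded in every result object.

## A worked miniature

```{r example, eval = FALSE}
cfg <- scenario_config(V = 10, rho_within = 0.7, delta = 0.15, N = 12,
                       B = 99, seed = 7,
                       mcmc = dp_hyperparameters(n_iter = 300, n_burn = 150))
model <- make_true_model(cfg)
ds <- simulate_dataset(model, cfg, rep_seed = 7)

sig <- lapply(split(seq_len(nrow(ds$Y)), ds$groups), function(rows) {
  Yg <- ds$Y[rows, ]
  estimate_edge_covariance(sweep(Yg, 2, colMeans(Yg)), 1,
                           dp_hyperparameters(n_iter = 300, n_burn = 150,
                                              seed = 7), ds$map)$Sigma_hat
})
res <- permutation_test(ds, sig, "scaled_identity",
                        permutation_plan(B = 99, seed = 7))
res
```

The same workflow is scriptable from a shell through the bundled
launcher (`inst/cli/fcnet.R`): `generate` writes a simulated dataset as
per-subject TSV matrices plus a manifest, `compare` runs the full
estimation and test on any manifest, and `simulate` runs a whole scenario;
every output embeds the seed and configuration that produced it.
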