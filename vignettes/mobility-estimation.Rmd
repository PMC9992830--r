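---
title: "Estimating mobility from interpolated ancestry fields: models, parameters, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mobility from interpolated ancestry fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobfield)
```

## The problem and the model

Ancient genomes come with three coordinates that matter here: where an
individual was buried, when they lived, and where their genotype sits in a
low-dimensional space of genetic distance. `mobfield` treats the first two
as independent variables and the third as a set of dependent variables, and
asks, for each individual: *where on the map, some generations earlier, was
ancestry like mine at home?* The displacement between burial place and the
most probable such location is a per-individual proxy for mobility — the
individual's own, or their recent ancestors'.

The chain has three models in it:

**Ancestry components.** Pairwise distances are
`1 − mean per-locus IBS share` over pairwise-complete loci, with the
diploid share `1 − |g_i − g_j|/2` (opposite homozygotes share nothing, a
heterozygote shares half with either homozygote). Classical MDS (Torgerson
double-centering plus eigendecomposition) turns the distance matrix into
`k` centred, orthogonal components; `k = 2` by default. These are axes of
genetic distance, deliberately not admixture proportions: no reference
panel is assumed, and the components' meaning is relative to the sample
set. Pairs with no overlapping loci are an error, not an imputation —
after the ≥ 25,000-SNP quality filter such pairs indicate something is
wrong with the input, and silently guessing a distance would distort the
embedding.

**The field.** Each component is an independent Gaussian process over
(easting, northing, time) with constant mean (the component's training
mean) and the anisotropic squared-exponential kernel

$$\mathrm{Cov}(x, x') = \tau^2 \exp\!\Big(-\sum_{k=1}^{3}
\frac{(x_k - x'_k)^2}{\theta_k}\Big) + \eta\,\delta(x - x'),$$

on an equal-area plane (ETRS89-LAEA / EPSG:3035 parameters), implemented
from the standard ellipsoidal formulas and verified against the published
projection test vector and independent geodesic distances. Equal-area
matters downstream: it makes a uniform prior over grid cells a uniform
spatial prior. Time is one continuous axis in calendar years, negative BC,
positive AD, with no year-zero correction — the ±1-year discrepancy is far
below any temporal lengthscale worth fitting.

**The similarity surface.** For a sample with component values $z$ and a
time slice $t^\ast$ in its past, every grid cell contributes the Gaussian
likelihood of $z_c$ under the field's predictive mean and variance there,
with the nugget added to the predictive variance. Likelihoods are
multiplied across components and normalised over cells (Bayes with a
uniform cell prior; under that prior normalise-then-multiply and
multiply-then-normalise coincide, and the latter is implemented in a
single log-space pass). The surface therefore concentrates only where the
field is both *similar* and *supported by data* — far from observations
the predictive sd reverts to $\sqrt{\tau^2 + \eta}$ and the likelihood
flattens, which is what makes the method usable on severely uneven
sampling.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `theta_x`, `theta_y` | m² (divisor of squared distance) | configuration | Spatial reach; entered most naturally as lengthscales via `lengthscale_to_theta()` (`theta = l²`; correlation `exp(−1)` at separation `l`). Order-of-magnitude defaults of a few hundred km suit continental ancient-DNA data, but these are non-canonical and should be fitted (`mle_kernel`) or cross-validated (`loocv_score`) per dataset. |
| `theta_t` | years² | configuration | Temporal reach, same conventions. |
| `tau2` | component variance | configuration / profiled | Process variance; profiled in closed form during MLE (`τ̂² = yᵀC⁻¹y/n`). |
| `eta` | component variance | configuration / fitted | Per-observation nugget: different individuals at one site can carry different ancestry. Also added to the likelihood variance of the similarity surface, so locally heterogeneous ancestry keeps support and the surface cannot collapse onto training locations. |
| retrospection | years | 667 | How far into a sample's past the field is sliced; tied to the temporal lengthscale of the fitted kernel. A tunable analysis choice, not an estimate. |
| `n_runs` | — | 25 | Age-uncertainty resampling runs per sample. |
| window / step | years | 400 / 50 | Regional moving mean. The window is the reporting grain of the diachronic curves; the step is a visualisation grain left open by the method and fixed here at 50 y. |
| grid spacing | m | 25–50 km | Cell edge of the analysis lattice; cells are centred, ordered northing-ascending/easting-fastest, and capped by a cell budget. |

QC thresholds (≥ 25,000 autosomal SNPs; male X-contamination < 0.1;
relatedness distance < 0.245, keeping the highest-SNP-count sample per
connected group, ties to the lexicographically smallest id) are the
field-standard values for this kind of data and are arguments, not
constants.

## Numerical conventions

These are the choices a reimplementation would need to match our outputs
exactly.

- **Nugget placement.** In the training covariance the Kronecker delta is
  realised per observation (diagonal): two observations at the same site
  carry independent nugget noise, so duplicated data with `eta > 0` are
  well-posed, and exact duplicates with conflicting values and `eta = 0`
  raise a singularity error advising a positive nugget. In point-to-point
  and query-to-training covariances the delta fires on exact (bitwise)
  coordinate equality — no fuzzy matching — so a query at a training
  coordinate reproduces the observation exactly when `eta = 0`.
- **Mean handling.** Constant mean per component, estimated as the
  training mean; predictions revert to it. `loocv_score` uses the
  closed-form identity `e_i = α_i / [K^{-1}]_{ii}` on the full
  factorization, which presumes a fixed prior mean; `fit_gp(mean_offset=)`
  exists so a refit-based check can hold the same mean.
- **Factorization.** Cholesky of the training covariance; jitter of
  `1e-8·τ²` is added only if factorization fails, with a warning.
  Predictive variance is floored at 0 and can never exceed `τ² + η`.
- **MLE.** Optimisation over `log(θ_x, θ_y, θ_t, g)` with `g = η/τ²` and
  `τ²` profiled out; L-BFGS-B with bounds derived from the coordinate
  spans; multi-start from the supplied initialisation, a deterministic
  pure-noise start (shortest admissible lengthscales, maximal nugget
  ratio), and seed-derived random starts. Among optima within
  `χ²₃(0.95)/2 ≈ 3.91` log-likelihood units of the best, the largest
  nugget ratio wins: under pure noise the three lengthscales are
  unidentified and can earn a spurious likelihood gain of about that size,
  and when signal and noise are statistically indistinguishable the
  noisier reading is the conservative one for every downstream surface.
  Genuinely structured data clear this bar by orders of magnitude.
- **Determinism.** MDS signs are fixed (largest-magnitude loading of each
  component positive); surface argmax ties break in row-major cell order
  (smallest northing, then easting) and are flagged; compass bins are
  half-open starting at North; all RNG consumption is seeded and restores
  the caller's RNG state, and the pipeline draws one sub-seed per sample
  up front, so runs are byte-reproducible.
- **Ages.** Without a calibrated probability table, ages resample from a
  normal centred on the median with `sd = (hi − lo)/4`, truncated to the
  2-sigma bounds by inverse-CDF sampling; a degenerate interval is a point
  mass. The window anchor for regional curves is the resampled sample age
  (the quantity on the time axis), not the slice time.
- **Mean vectors.** The per-sample summary is the component-wise mean of
  `(dx, dy)` across runs — which can legitimately cancel when runs
  disagree on direction — with the sd of per-run lengths as the y-error.
  Regional curves pool run-level lengths by default (`pool = "runs"`);
  per-sample pooling is available. The uncertainty band is `2·SE` of the
  per-sample means and is infinite below two samples per window.

Two design points were genuinely open and are resolved as follows: each
component carries its own kernel by default (components are modelled
individually; a shared kernel is a one-argument change), and the regional
moving mean weights resampled runs equally rather than samples, matching
the run-pooled reading of the summary statistic.

## What the simulator shows — and what it does not

`simulate_dataset()` places populations in rectangular planar regions,
moves each population's ancestry centroid along a piecewise-linear
trajectory in component space, adds independent Gaussian observation noise
per component, and injects migration events: individuals buried in a
destination region whose ancestry is drawn around the *source* population's
centroid. The documented reference scenario (`two_pop_reference()`) uses
two adjacent 500 km × 500 km regions, temporally stable centroids four
observation-noise standard deviations apart in component space, 100
non-migrants per population over 2,000 years, 20 migrants at mid-span, a
250 km / 500 y kernel with nugget equal to the noise variance, a 25 km
grid, and 500 y retrospection. The four-sd separation is this package's
own calibration point for what "distinguishable populations" means;
recovery is empirically monotone in that separation and in the noise, so
the scenario sits comfortably inside, not at, the identifiable regime.

Passing the simulator-based checks establishes that the machinery —
interpolation, surface normalisation, argmax, vector bookkeeping —
recovers planted structure under the stated conditions. It does *not*
establish that real archaeogenetic mobility estimates are accurate:
component-space simulation bypasses genotype sampling noise and reference
bias; rectangular regions and stable centroids are far simpler than real
clines; coexisting ancestries in one place (a cultural admixture barrier,
say) are exactly what a smooth interpolation cannot represent, and the
field will average them into a profile nobody carried. Center–periphery
geometry can also bias argmax locations toward well-sampled interiors.
These caveats transfer directly to real-data use.

## Problem sizes

The shipped tests and the acceptance script run at deliberately desk-scale
sizes: GP oracle checks at n ≤ 50 with dense-inverse references; kernel
recovery at n = 300 over 20 replicates; origin recovery over 20 scenario
replicates of 220 samples each on an 800-cell grid; the full-pipeline
determinism check at ~80 samples. These sizes keep every check exact
(dense linear algebra throughout) while exercising the same code paths a
real analysis would use; the dense Cholesky is the reference
implementation, and a local-approximation speed path is an optional future
addition whose contract (agreement with the dense GP on n ≤ 500 fixtures)
is already stated in the GP module's design.

## Known limitations

- No posterior over time: the retrospection distance is an input, and the
  package will not tell you *when* an ancestry match is best.
- The exact-coincidence nugget rule means near-duplicate coordinates (for
  example, post-projection rounding differences) are treated as distinct
  sites; collapse them upstream if they should share a nugget.
- EIGENSTRAT is the only genotype format read; convert PLINK/VCF inputs
  externally.
- The regional SE band treats per-sample mean lengths as independent,
  which understates uncertainty when samples share training data — it is
  a visualisation aid, not an inferential interval.
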