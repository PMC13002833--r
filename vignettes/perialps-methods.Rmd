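---
title: "Methods: perivascular diffusion indices, free water, PSMD and sparse FPCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perivascular diffusion indices, free water, PSMD and sparse FPCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `perialps`, the defaults
and why they were chosen, the numerical decisions that affect results, and
what the synthetic generators do and do not emulate.

## Units and conventions

Diffusivities are carried in units of 10⁻³ mm²/s and b-values in s/mm², so
the signal exponent is `b * D * 1e-3`. Gradient directions live in the
image frame (no reorientation); FSL-style bval/bvec files are read in both
the 3×N and the transposed N×3 layout (auto-detected). Voxel coordinates
map to mm as `(index − 1) * voxel_mm`; spherical ROIs include a voxel when
its center lies within the radius.

## Tensor and kurtosis fitting

Both models are fitted by two-pass weighted least squares on the log
signal: an ordinary pass first, then weights equal to the squared predicted
signals (the standard correction for the log-transformed Rician/Gaussian
noise variance). The DKI design is the 22-parameter linearization in
(ln S0, six tensor elements, fifteen elements of MD²·W). This estimator is
deterministic and needs no iterative optimizer. Intensities are floored at
`1e-6 * S0` before the logarithm; eigenvalues of the fitted tensor are
clipped at zero for FA/MD derivation only (the raw tensor is kept), which
keeps FA inside [0, 1] on noisy data.

Axis kurtoses are reported in the directional *apparent kurtosis*
convention `K(n) = (MD/D(n))² W(n)`; this is the quantity usually called
"kurtosis along an axis". Because the raw-element reading `W_xxxx` is also
defensible, `directional_kurtosis(..., convention = "raw")` exposes it; the
two coincide for isotropic tensors. No positivity constraint is imposed by
default; `floor_kurtosis = TRUE` applies a documented post-hoc floor at
zero rather than a constrained refit.

**Truncation bias is physics, not a bug.** `D(n)` and `K(n)` are the b → 0
cumulants of the signal. A quadratic-in-b fit over shells up to
2000 s/mm² estimates *apparent* values which, for strongly non-Gaussian
mixtures (e.g. tissue plus free water, directional K of 3–5), sit well
below the analytic cumulants: for the 50/50 mixture of isotropic 1.0 and
3.0 ×10⁻³ mm²/s compartments (analytic K = 0.75) every least-squares
variant we examined returns K ≈ 0.45–0.48 on shells {0, 500, 1000, 2000}.
The package therefore validates its fitters against the analytic mixture
oracle on a *low-b validation acquisition* (shells {0, 100, 200, 400}
s/mm²), inside the cumulant expansion's validity range, where the fitted
mixture kurtosis lands within 0.1 of the oracle and the kurtosis-corrected
tensor reproduces the analytic ALPS index to 1% across the whole
glymphatic-parameter grid. On study-style shells the indices are apparent
indices — exactly the situation of clinical ALPS work, and the reason the
kurtosis-corrected variant exists.

## The ALPS indices

`alps_index` is the ratio `mean(x_proj, x_assoc) / mean(y_proj, z_assoc)`;
`compute_alps` evaluates it per hemisphere from four ROI means (sentinel
voxels excluded) and averages the hemispheres. DKI-ALPS substitutes the
axis kurtoses literally into the same ratio. Because diffusivity and
kurtosis are expected to move in opposite directions under a glymphatic
change, the orientation of the kurtosis ratio is genuinely ambiguous;
`invert_kurtosis = TRUE` computes the reciprocal-orientation variant, and
the default (literal substitution) is a documented choice, not a claim
about which variant matches any particular published value. ROI centers
are fixed configuration (no manual adjustment), radius 2.5 mm (5-mm
diameter); on a 1-mm grid such a sphere holds 81 voxels.

## PSMD and free water

The skeleton is threshold-based: FA above 0.2 intersected with the
stricter CSF-guard threshold 0.3. This is deliberately *not* the
tract-based perpendicular-projection skeletonization, which needs a
population template pipeline; externally computed skeleton masks are
accepted (`as_skeleton_mask`) when fidelity to that pipeline matters. PSMD
is the 5th–95th percentile width with linear-interpolation percentiles
(R quantile type 7) — the convention is fixed so results are
bit-reproducible.

The bi-tensor fit minimizes the signal-domain residual over `f ∈ [0, 1]`,
`S0 > 0` and a tissue tensor parameterized by its lower-triangular
square-root (PSD by construction), with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, at most 200 iterations; non-convergence raises an
error carrying the best iterate). Initialization is deterministic: a
free-water-naive DTI fit supplies the apparent tensor; the starting
fraction maps the naive MD linearly between a nominal tissue MD of 0.6 and
`d_iso`; the starting tissue tensor is the apparent tensor with the
isotropic part removed and eigenvalues clipped to [0.05, 0.95·d_iso].
`d_iso` defaults to 3.0×10⁻³ mm²/s (free water at body temperature) and is
configurable. At least two nonzero shells are required — the single-shell
problem is ill-posed without regularization and is out of scope.
`fit_fw_volume` can cap the number of fitted voxels (seeded subsample) so
that mask means stay affordable on large masks.

## The ALPS phantom

Two mirrored hemispheres each carry a projection block (tissue tensor
axially symmetric about z; axial 1.4, radial 0.4) and an association block
(about y). Each block mixes three Gaussian compartments: tissue, an
isotropic free-water pool (`f_fw`, default 0.1, diffusivity 3.0), and a
perivascular compartment elongated along x whose fraction is `g · f_pv_max`
(default `f_pv_max = 0.2`) and whose axial diffusivity rises linearly from
1.0 to 3.0 as the glymphatic conductance `g` goes 0 → 1 — one monotone knob
for perivascular fluid mobility. The truth record stores the analytic
`D(n)` and `K(n)` per block and axis (exact mixture cumulants) and the
analytic DTI-/DKI-ALPS indices; the analytic DTI-ALPS is strictly
increasing in `g`. Defaults: 40³ voxels at 1 mm, shells
{0, 500, 1000, 2000} with {1, 6, 48, 60} directions (Fibonacci sphere with
a seeded per-shell rotation — deterministic, near-uniform, no optimizer),
SNR = S0/σ = 30 at b = 0 with Rician noise, ROI radius 2.5 mm. An optional
`md_het_sd` scales each white-matter voxel's diffusivities by
`1 + N(0, sd)`, providing controlled MD heterogeneity for PSMD testing.
The phantom emulates the ALPS *geometry* and compartment mixing; it does
not emulate anatomy, susceptibility or eddy artifacts, or pulse-sequence
physics, so passing tests demonstrate correctness of the estimators under
the stated signal model, not robustness to real-world preprocessing
failures.

## The longitudinal cohort generator

Defaults emulate a two-group aging cohort: 128 healthy controls (HC) and
83 cognitively impaired (CI) subjects, 1–3 visits with probabilities
(0.5, 0.3, 0.2) (≈1.7 sessions/subject), visit gaps uniform on
[0.9, 2.1] years, baseline ages N(71.5, 7.3) and N(72.2, 6.5). Each
index follows `y = μ_g(age) + ξ₁φ₁ + ξ₂φ₂ + ε` with quadratic group mean
functions in (age − 70), φ₁ constant and φ₂ centered-linear (orthonormal
on the 55–95 y domain). The stated group levels are anchored to the
*expected baseline value*: the generator removes the offset that the
group's baseline-age spread induces under the quadratic, so the defaults
deliver baseline DTI-ALPS ≈ 1.37 (HC) vs 1.28 (CI), DKI-ALPS ≈ 1.63 vs
1.37, PSMD ≈ 0.25 vs 0.26 (10⁻³ mm²/s) and FW ≈ 0.28 vs 0.29, with HCs
declining faster (converging ALPS trajectories) and CIs rising faster in
PSMD/FW. A shared latent factor couples the subject scores across indices
(positively for the ALPS pair, negatively for PSMD/FW) and drives amyloid
SUVR and the cognitive scores, producing the characteristic
ALPS–injury–amyloid–cognition correlation structure. Measurement noise
SDs (0.10, 0.15, 0.015, 0.015) correspond to test–retest reliability
(ICC) near 0.8 per index; combined with the mean separations above this
yields baseline standardized effects of roughly 0.4 (DTI-ALPS) and 0.77
(DKI-ALPS). Because first-component scores average over a subject's
visits, their group effect exceeds the single-measurement baseline effect
in expectation; at 211 subjects this ordering is nonetheless a stochastic
property — individual seeds can invert it.

The generator does not model dropout that depends on outcome, scanner or
protocol changes across visits, practice effects in cognition, or
non-Gaussian score distributions.

## Sparse FPCA

Estimation is PACE-style. The mean is a Gaussian-kernel local linear
smoother on the pooled observations (default bandwidth 10% of the time
range). Raw off-diagonal covariances (subjects need ≥ 2 visits to
contribute) are smoothed by a 2D local linear fit (default bandwidth 15%);
the smoother inflates its bandwidth locally (×1.5, ×2, ×3, ×5) wherever
the kernel-effective number of raw points falls below 150, which tames the
variance at the sparse corners of the domain. The noise variance σ² is the
average gap, over the central half of the grid, between the smoothed
diagonal of the raw second moments and the surface diagonal, floored at
zero.

The eigendecomposition uses *uniform* Riemann quadrature weights (grid
spacing h): eigenvalues are `h` times the matrix eigenvalues and
eigenfunctions are the eigenvectors divided by √h. With uniform weights
the dense balanced design reduces *exactly* to multivariate PCA of the
data matrix — with trapezoid weights the endpoint rows would differ at
O(h) and the correspondence would only be approximate, which is why
uniform weights were chosen. Negative eigenvalues are truncated and
excluded from the fraction-of-variance denominator; eigenfunction signs
are fixed by a non-negative integral; K is the smallest k whose cumulative
FVE reaches 95% (with a 1e-12 epsilon so exact-threshold constructions are
not lost to rounding). Scores are best linear predictors; when σ² = 0
makes the within-subject covariance rank-deficient (dense noiseless data)
a Moore–Penrose pseudo-inverse is used, under which the BLUP reduces to
the quadrature projection; σ² = 0 with duplicated observation times is
reported as a singular-system error. When every subject is observed on
exactly the same grid, `smoother = "auto"` switches to cross-sectional
sample estimates (and σ² = 0), making the PCA correspondence exact. The
default grid has 51 points spanning the observed time range; age at scan
is the default time variable.

Known limitations: kernel covariance estimates at the extreme corners of
sparse designs remain noisy (the adaptive bandwidth mitigates but cannot
remove this — each subject contributes a single score draw to all its
products); eigenvector rotation of order √(λ₁λ₂/n)/(λ₁ − λ₂) is
irreducible at finite n; bandwidths are fixed rules rather than
cross-validated.

## Statistics layer

`smd_continuous` uses the average-variance denominator
√((s₁² + s₂²)/2) — the convention that reproduces the reference baseline
table's printed SMD column from its printed means and SDs; `cohens_d`
defaults to the classical pooled-df denominator, and every effect records
its convention. χ² tests are uncorrected (no Yates continuity
correction). The Kolmogorov–Smirnov normality check plugs in the sample
mean and SD; its p-value does not account for parameter estimation
(documented caveat). Spearman correlations use midranks with the
t-approximation `t = ρ√((n−2)/(1−ρ²))`, so ties need no exact-p
machinery. Adjusted group differences are OLS fits `outcome ~ group +
covariates` with the group coefficient's t-test (coefficient tests, not
type-III ANOVA), standardized by the residual SD; rank-deficient designs
are rejected with the offending columns named; missing data are handled by
listwise deletion with dropped-row counts reported. FDR control is
Benjamini–Hochberg step-up, applied within each analysis family in the
pipeline output.

## Pipeline and problem sizes

`run_pipeline` chains a noise-free phantom pair (g = 0.3 and 0.9 by
default) through DKI fitting, ALPS, PSMD and a capped free-water stage
(300 voxels by default — the subsample mean estimates the mask mean),
then the cohort, per-index FPCA and the statistics layer, and writes CSVs,
model JSONs and a SHA-256 manifest; outputs are byte-identical under a
fixed seed. The test suite exercises reduced problem sizes chosen for
desk-scale turnaround — 24³-voxel phantoms with 2-mm ROIs and {0, 500,
1000}-shell tables where full resolution adds nothing, the 40³ default
where the geometry matters, 200 noisy phantom realizations for the
noise-consistency check, and 5000 null simulations for the type-I-error
check — sizes that keep the full suite under a few minutes while leaving
every estimator's accuracy claim tested at the tolerance stated in the
test.
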