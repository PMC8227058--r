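---
title: "Models and methods behind foragehtp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foragehtp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`foragehtp` validates an image-based high-throughput phenotyping (HTP)
workflow for forage dry matter yield (DMY) end to end on simulated trials.
This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made, and what the
simulation does and does not demonstrate.

## 1. The generative trial model

A trial is a resolvable incomplete-block progeny design: `g` full-sib
families (random genetic entries) plus genitors and cultivar checks (fixed
entries), each appearing once per replication, with replications cut into
equal incomplete blocks. The default dimensions — 86 families, 10 + 10
genitors, 4 checks, 3 replications of 11 blocks × 10 plots, 330 plots of
4.5 m² — describe a realistic guineagrass progeny trial.

Plot-level total DMY on the kg/ha scale is assembled additively:

y = μ + rep + (family | check) + block + e,
  family ~ N(0, Vg), block ~ N(0, Vb), e ~ N(0, Ve·R)

with a separable first-order autoregressive residual correlation
`R[i, j] = ρ_row^|Δrow| · ρ_col^|Δcol|` over the occupied field
coordinates. The residual field is drawn exactly through the Cholesky
factor of `R` (n = 330 makes exactness cheap; no sparse approximation is
needed). Check-class entries receive fixed deviations instead of family
draws, so they inform the residual and block components but not `Vg` —
the standard augmented-design treatment.

Defaults (`genetic_params()`): μ = 2000 kg/ha, Vg = 44258, Vb = 20000,
Ve = 100000 (kg/ha)², ρ_row = ρ_col = 0.3. These are the study conditions
for every simulation-based test in the package: the genetic variance and
heritability they imply (single-trial Cullis H ≈ 0.6) are typical of
replicated forage progeny trials, and the acceptance-tier parameter
recovery is run at exactly these values.

Two deliberate simplifications, made once:

* **Lattice internals.** The incomplete-block generator shuffles entries
  into equal blocks within each replication rather than constructing a
  formal alpha-lattice concurrence scheme. The downstream mixed model
  consumes only the rep/block/genotype labels, so the concurrence
  structure is irrelevant to everything the package computes.
* **Field geometry.** Plots are laid on a rectangular 22 × 15 grid in
  plot-id order (row-major or serpentine). Real trials rarely publish
  their coordinate maps; the grid shape is configurable, and the AR1⊗AR1
  machinery only needs coordinates.

Negative simulated yields are truncated at zero (a biological floor); the
truncation rate is attached to the result and a warning is raised when it
is nonzero. At the default parameters truncation is essentially absent.

## 2. Harvest arithmetic and its inverse

Conventional phenotyping weighs the fresh harvest (TGMW, kg/plot), takes a
300–500 g sample (SGW), and dries and separates it into leaf, sheath+stem
and dead components (LDMW, SSDMW, DMDMW). Per-plot yields follow by
sample-ratio scaling, e.g. `LDMY = TGMW · LDMW / SGW`, with
`TDMY = LDMY + SSDMY + DMDMY`, then `kg/ha = kg/plot · 10000 / area`.

All sample weights are carried in grams internally; the equations only
need a consistent ratio, so the unit choice is documentation, not
computation. `derive_field_samples()` inverts the arithmetic: per plot it
draws a moisture fraction m ~ U(0.65, 0.80) (drawn in `simulate_trial()`,
where it defines green matter = dry matter / (1 − m)) and a sample weight
SGW ~ U(300, 500) g (capped at the harvested mass), and sets the component
dry weights so that re-applying the yield equations reproduces the true
component yields exactly. This round-trip identity — tested to 1e-9
relative on full trials — is what lets every downstream stage be verified
against known truth. Moisture and component fractions (leaf share
N(0.55, 0.05²), dead share N(0.10, 0.03²), clipped and renormalized to the
simplex) are drawn per plot, the simplest model consistent with per-plot
sampling.

## 3. Synthetic imagery

The renderer produces the *minimum* image structure the learning problem
needs: two jittered rows of five plant canopies over a soil background,
where the canopy-pixel count is exactly `round(cover · px²)` with
`cover = cover_max · (1 − exp(−green_matter / canopy_gain))`
(cover_max = 0.9, canopy_gain = 3 kg). The canopy pixels are those nearest
the plant centres, so cover is strictly monotone in green matter up to
single-pixel discreteness, before per-pixel Gaussian colour noise
(sd 0.05 canopy, 0.03 soil) is added. Patches default to 64 px — small
enough for CPU training, large enough for pooling stacks.

The mosaic assembler places patches on the field grid with a uniform
background gap and records origin/patch/gap metadata; `extract_plots()`
slices with pixel-copy semantics (0-based, half-open windows), so the
render→extract round trip is bit-exact in memory. Mosaics are stored as
PNG plus a JSON sidecar of the grid metadata; an 8-bit PNG round trip is
exact to 1/255 per channel.

What the imagery does *not* emulate: photogrammetric artefacts, rolling
shutter, illumination gradients, occlusion between plots, radiometric
calibration, or any real canopy texture. Consequently, a high out-of-fold
correlation here demonstrates that the pipeline wiring (augmentation,
fold hygiene, out-of-fold prediction, metric and genetic plumbing) is
correct and that the network can extract a planted monotone signal — it
says nothing about accuracy on real UAV imagery.

## 4. Convolutional regression

No deep-learning framework is assumed: the package ships its own compact
engine (RcppArmadillo) with im2col+GEMM convolutions, per-channel batch
normalization, non-overlapping average/max pooling, ReLU, dropout, fully
connected layers, and Adam on a mean-squared-error loss. Backward passes
are verified against numerical differentiation in the tests.

Presets: `macnn`, a four-block convolution stack (batch normalization,
average pooling, one dropout+FC head) whose default widths (8/16/32/64
filters, ~41k parameters) are deliberately CPU-light — widened to
32/64/128/256 filters with a 512-unit head it reaches the
million-parameter regime of its published namesake; `lfcnn`, a five-stream
late-fusion network (per stream: one 8-filter convolution, global max
pooling, FC-16, a single ReLU neuron) fused by two final layers; and
`alexnet`, build-only, for parameter-count comparisons. Training defaults
follow the conventional small-network recipe: Adam with learning rate
0.001, β₁ = 0.9, β₂ = 0.999, ε = 1e-8, up to 500 epochs, batch 256, early
stopping evaluated every 100 epochs.

Choices worth recording:

* **"Rotation (horizontally and vertically)"-style augmentation** is
  implemented as the four axis flips (identity, left-right, up-down,
  both). Flips preserve the patch geometry; 90° rotations would too, but
  flips are the conservative reading and are exactly involutive, which
  the tests exploit.
* **Fold hygiene.** The random k-fold partition (purely random, not
  stratified) is drawn *before* augmentation; flips are applied to
  training folds only, so no augmented copy of a test plot ever reaches
  the model that predicts it.
* **Early stopping** holds out a 10% slice of the training fold, grouped
  by plot so a plot's flips never straddle the split; the best-validation
  weights are restored on deterioration.
* **Target standardization.** Targets are centred and scaled inside the
  trainer (predictions are returned in trait units). On kg/ha scales
  (~10³) raw MSE gradients would dwarf the default learning rate.
* **Predictions are not clamped at zero** — the raw regression output is
  the HTP trait.
* **Problem sizes.** The package's standard demonstration scale is
  330 plots at 64 px with the compact `macnn`, 10 folds, batch 64, 10
  epochs with validation checks every 5 — chosen so a full
  cross-validation completes in a few minutes on one CPU while clearing
  an out-of-fold r of 0.7 on the default synthetic trial with a wide
  margin. The paper-scale defaults (500/300 epochs, batch 256) remain
  available through `train_config()`.

## 5. REML, BLUPs, heritability, genetic correlation

For each trait the mixed model above is refitted to data (real or HTP) by
restricted maximum likelihood over θ = (Vb, Vg, Ve, ρ_row, ρ_col). The
restricted log-likelihood uses Harville's form, including the
θ-constant + ½·log|X′X| term, which makes it invariant to the fixed-effect
parameterization (lme4, which omits that constant, is reconciled in the
cross-check test by adding it back).

The optimizer is Average-Information REML: score and AI matrix assembled
from P = V⁻¹ − V⁻¹X(X′V⁻¹X)⁻¹X′V⁻¹, the AI system solved after symmetric
diagonal scaling (variances and correlations live on scales ~10⁹ apart; a
raw ridge would crush the variance block), Newton steps with up to 12
halvings, variances floored at 1e-8·var(y), correlations boxed to ±0.99.
Convergence requires |Δℓ| < 1e-6 and relative parameter change < 1e-4; if
an AI step cannot improve the likelihood, a Nelder-Mead fallback on the
transformed scale (log-variances, atanh-correlations) finishes the fit.
On 330-plot trials the AI path typically converges in ~8 iterations. The
likelihood trace is retained and is monotone by construction (only
improving steps are accepted).

Fixed effects are the intercept, replication contrasts and one indicator
per check-class genotype (checks are fixed; their plots still inform the
spatial residual). X is checked for rank and aliased columns are named in
the error. A `Vg` estimate within two orders of magnitude of its floor is
reported as a boundary solution and heritability is flagged undefined
rather than reported as an enormous negative number.

Family BLUPs come from ĝ = Vg·Z₂′Py with prediction-error covariance
PEV = Vg·I − Vg²·Z₂′PZ₂. Broad-sense heritability uses the Cullis form,
`H = 1 − PEV̄ / (2Vg)` with PEV̄ the mean variance of pairwise BLUP
differences (`mean(PEV_ii + PEV_jj − 2PEV_ij)` over unordered pairs); the
mean-diagonal variant is available via `pev = "diagonal"`. Negative H is
reported as-is — it is informative (prediction error exceeding genetic
variance), and the estimator genuinely produces such values for weak HTP
traits. The approximate genetic correlation between a real and an HTP
trait is the Pearson correlation of their family-BLUP vectors; note it
estimates the planted correlation *attenuated by the BLUP reliability*,
which is why the recovery tests run it at a high-accuracy setting.

Whether the spatial correlations should be estimated or held fixed is
left to the caller (`fix_rho`); both modes are supported because either
is defensible when the true field layout is unknown.

## 6. Selection response

For truncation selection of a proportion p under a normal trait,
`i = φ(z)/p` with `z = Φ⁻¹(1 − p)`. Quantitative-genetics practice quotes
i from three-decimal tables and presents two decimals with half-up
rounding (1.755 → 1.76); `printed_intensity()` reproduces exactly that
convention, and `scenario_table()` uses it by default (full precision via
`intensity_digits = NULL`). Direct response is `DR = i·√H·√Vg`; correlated
response through an HTP trait is `CR = i·√H_HTP·r·√Vg_real`. The scenario
table fixes DR at the baseline scenario and computes CR at each intensity
(10%, 5%, 1% by default, with the evaluated population scaled ×1, ×2,
×10); CR/DR is the efficiency of indirect selection, and is algebraically
independent of `Vg_real` — a property the tests check on randomized
inputs. Genetic parameters are treated as constant across scenario sizes;
plot and family counts are carried as metadata only. Negative
heritabilities are rejected in the response formulas (no real square
root) rather than silently zeroed.

## 7. Evaluation metrics

MAE, RMSE and Pearson r are computed in their textbook forms (the
correlation denominator carries the square root; a printed formula
without it would not produce values in [−1, 1]). Zero-variance inputs
flag r as undefined instead of returning 0. Fold aggregation reports the
unweighted mean and *sample* standard deviation (n−1) across folds, with
a single fold yielding an undefined spread.

Histogram intersection bins both samples on shared equal-width edges
spanning their union range and sums per-bin minimum *proportions*, so the
measure is symmetric, lives in [0, 1], and admits unequal sample sizes;
`edges = "real_only"` reproduces the alternative of building bins from
the observed values alone. The elbow rule for the bin count scores each
candidate by the within-bin sum of squares and returns the first
candidate whose relative improvement to the next falls below 10% — a
diminishing-returns criterion chosen over curvature maximization because
it is stable when the candidate range is extended (the tests check
invariance under extending 5:40 to 5:60). On large uniform or normal
samples it lands near 20 bins, the conventional choice, which remains
directly settable.

## 8. What passing tests do and do not show

The suite establishes: exact reproduction of the selection-response
arithmetic from published-style genetic parameters; REML agreement with
closed-form ANOVA estimators, a dense brute-force likelihood, and lme4 on
overlapping model classes; recovery of (Vg, ρ, H) from 50 replicate
330-plot simulations at the default conditions; exact yield round trips;
pixel-exact mosaic round trips; fold-partition and no-leakage invariants;
and an out-of-fold image-regression correlation ≥ 0.7 on the default
synthetic trial. Because the imagery is synthetic and its yield signal
planted, the last result validates the machinery, not field performance;
transferring the pipeline to real orthomosaics would additionally require
rectification, radiometric normalization, and a network and input
resolution tuned to real canopy texture — all outside what simulation can
certify.
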