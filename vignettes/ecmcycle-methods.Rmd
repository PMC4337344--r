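---
title: "Methods: eigenvector centrality mapping across the menstrual cycle"
author: "ecmcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eigenvector centrality mapping across the menstrual cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmcycle)
```

## The analysis problem

`ecmcycle` implements a longitudinal, single-subject resting-state fMRI
analysis that asks whether day-to-day fluctuations of ovarian hormones are
associated with changes in whole-brain functional connectivity. The design
it targets is a dense within-subject protocol: 32 BOLD scans collected in
two scanning sessions of 16, every second or third day across menstrual
cycles, with serum estradiol, progesterone, LH and cortisol drawn at every
scan. Two analysis levels are provided:

1. a **whole-brain hub analysis** via eigenvector centrality (EC) mapping
   of the voxel-wise correlation network, followed by a scan-level general
   linear model (GLM) with hormone covariates; and
2. a **seed-based connectivity analysis** that probes whether the regions
   identified at the first level change their coupling with specific remote
   regions as hormone levels change.

## Eigenvector centrality of the voxel network

For the $N$ in-mask voxels of one scan, let $R$ be the $N \times N$ matrix
of Pearson correlations between voxel time courses. The network similarity
matrix is

$$C = R + 1,$$

which is entrywise positive whenever no correlation is exactly $-1$. By the
Perron–Frobenius theorem $C$ then has a unique largest real eigenvalue whose
eigenvector $v$ can be chosen strictly positive; the components of $v$ are
the voxel centralities: a voxel scores high when it is strongly correlated
with many voxels that are themselves central.

`ec_dense()` materializes $C$ and eigendecomposes it — the exact reference,
usable up to a few thousand voxels. `ec_fast()` computes the same vector
without ever forming $C$. With $Z$ the row-centered, row-normalized data
matrix (so $Z Z^\top = R$ exactly, including the unit diagonal),

$$C v = Z (Z^\top v) + \mathbf{1} \textstyle\sum_i v_i,$$

so one power-iteration step costs $O(NT)$ instead of $O(N^2)$. Iteration
starts from the uniform positive vector — inside the convergence cone of
the Perron vector of a positive matrix, so convergence is guaranteed — and
stops when the maximum absolute componentwise change of the normalized
iterate falls below `tol` ($10^{-10}$ by default, `max_iter = 1000`). The
dominant eigenvalue is reported as the final Rayleigh quotient and must lie
in $[2, 2N]$ (diagonal and row-sum bounds of $C$). The test suite holds the
two paths to within $10^{-8}$ of each other across a randomized sweep.

Numerical choices worth stating:

* **EC normalization.** The eigenvector is defined up to scale; maps are
  fixed to unit Euclidean norm. Any one consistent rule works for the
  second level — what matters is that all 32 maps share it.
* **Zero-variance voxels** make Pearson undefined, so they are a hard error
  by default; `on_zero_variance = "drop"` removes them from the mask for
  that scan and records them. Silent imputation is deliberately not
  offered: replacing a row of $R$ perturbs the Perron vector in ways that
  are hard to reason about.
* **Sign fix.** The computed eigenvector is flipped, if needed, to the
  positive orientation before use.

## Preprocessing stages in scope

The pipeline starts from spatially normalized volumes. Two imaging stages
are implemented here because their exact semantics matter downstream:

* **Gaussian smoothing** (`gaussian_smooth()`): separable convolution with
  per-axis $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2}\, \cdot$ voxel
  size$)$, kernel truncated at $4\sigma$ and renormalized, zero padding at
  the grid edge (the background convention of common neuroimaging
  smoothers). The BOLD series is smoothed frame by frame at 8 mm FWHM by
  default. The truncation and boundary rule are an explicit package choice:
  the upstream software's exact kernel is not documented, so voxels near
  the brain edge may differ slightly from an analysis run elsewhere.
* **Gray-matter masking** (`make_gm_mask()`): the tissue-probability image
  is smoothed at 4 mm FWHM and thresholded at a minimum probability of
  0.12. The retained voxels receive a fixed linear ordering (ascending
  column-major index) recorded in the mask object, so every row of every
  downstream matrix is traceable to a voxel and every run is reproducible.

## The second-level GLM

EC maps are stacked into a scan-by-voxel matrix $Y$ and fitted voxel-wise
by ordinary least squares against a design with one indicator column per
scanning session (absorbing per-session means — there is no global
intercept) plus covariates. The "factorial" structure is additive:
session indicators + covariates, no session-by-hormone interaction by
default (an `interaction` flag exists). Hormone covariates enter
z-standardized by default; because the contrast t statistic is invariant to
affine rescaling of a covariate, raw-unit covariates give identical
inference (this is tested, not assumed).

For contrast $c$: $t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top
(X^\top X)^{-1} c}$ with $\hat\sigma^2 = \mathrm{RSS}/(n - \mathrm{rank}\,
X)$. Tests are one-sided by default (positive and negative hormone
associations are tested as separate contrasts); p values are computed on
the log scale and converted to equivalent Z scores so extreme t values do
not underflow. Estradiol and progesterone are fitted in **separate models**
by default: both covariates are locked to cycle phase and partially
collinear, and the analysis they mirror reports results per hormone.
Cortisol is carried as a covariate of no interest.

## Thresholding, clusters, and family-wise error

Voxels below the cluster-forming threshold (default $p < 0.001$,
uncorrected) are grouped into connected components under 18-connectivity
(faces + edges, the convention of the SPM family; 6 and 26 are available).
An extent filter keeps components with $k_E$ strictly greater than the
threshold (so `extent = 20` implements "$k > 20$"). Each cluster reports
its extent, peak t/Z/p, and the peak's world-mm coordinates via the mask
affine (0-based voxel convention).

Peak-level FWE correction is Bonferroni (or Šidák) over an effective
comparison count. When the user supplies a **resolution-element count**
(e.g. one estimated from residual smoothness by the original analysis
software, via `ecm_config(fwe_n = ...)`), correction runs over resels —
the effective number of independent spatial units after smoothing. When no
count is supplied the pipeline defaults to the in-mask **voxel count**:
strict Bonferroni, valid under any spatial dependence. A
`naive_resel_count()` helper (mask volume / FWHM³) exists for rough
sensitivity checks but is never the silent default — it ignores
data-driven smoothness estimation and substantially under-counts
comparisons when the mask is dominated by boundary voxels, making the
correction anti-conservative (random-field theory is not implemented, and
cluster-level corrected p values are left empty unless a plug-in supplies
them). Benjamini–Hochberg adjusted peak p values are available as a
column.

## Seed-based second level

Seeds are 6 mm-radius spheres (configurable) containing every in-mask voxel
centre within the radius; by default they are placed at the peak
coordinates of the whole-brain analysis, mirroring the workflow of running
EC first and interrogating the identified regions second. For each scan the
seed's unweighted mean time course is correlated with every in-mask voxel
and Fisher-transformed, $z = \operatorname{atanh}(r)$ with $|r|$ clamped at
$1 - 10^{-7}$ so seed voxels stay finite (they are flagged in the map).
The Fisher transform is the package's choice for variance stabilization; a
raw-`r` mode exists for sensitivity checks. The per-scan z maps then go
through the same GLM machinery with the hormone covariate, thresholded
uncorrected at $p < 0.005$ and $p < 0.001$ with $k > 20$.

## The synthetic-study generator

No scan data ships with the package, so `simulate_study()` generates
studies in which the correct answer is known, at the study conditions the
pipeline targets: 32 scans in 2 sessions of 16, alternating 2/3-day
spacing, each session starting on a different cycle day (days 2 and 6), a
24×24×12 grid of 3 mm voxels, 120 frames at TR = 2 s by default (a
300-frame run is one argument away; 120 frames keeps desk-scale suites
fast while leaving correlation estimates well-conditioned).

**Hormones.** Per-day curves over a 28-day cycle with ovulation on day 14:
estradiol as a dominant periovulatory Gaussian bump (day 13) plus a smaller
mid-luteal bump (day 21); progesterone as a smoothed rectangle — near zero
follicular, plateau from about day 16, falling premenstrually; LH as a
narrow surge on day 14, one day after the estradiol peak; cortisol as
independent noise. Values carry multiplicative log-normal measurement noise
(8% CV). Units are arbitrary: the pipeline consumes z-standardized values,
and a test asserts the invariance. Phase labels derived from the LH surge
(`label_phase()`: surge = LH maximum exceeding the panel median by two
panel standard deviations; ovulation = surge day + 1) reproduce the
follicular → periovulatory → luteal partition.

**BOLD.** Every voxel carries AR(1) noise (coefficient 0.3, unit marginal
variance) — enough temporal autocorrelation to stress realistic correlation
variance without modeling hemodynamics. Six 48-voxel box regions emulate a
bilateral layout (prefrontal, sensorimotor, hippocampal). A coupling is a
region pair whose voxels share a latent standard-normal signal with
scan-specific weight

$$w_{\text{scan}} = \alpha + \beta \cdot z_{\text{progesterone}}(\text{scan}),$$

the simplest mechanism that raises pairwise correlation, and hence EC, in
the coupled regions as progesterone rises. $\beta = 0$ defines the null
study. Defaults are $\alpha = 0.25$, $\beta = 0.15$, chosen once so that
scan-level pairwise correlations stay in the quasi-linear range (roughly
$r \lesssim 0.5$ after 8 mm smoothing): stronger coupling pushes within-pair
correlations toward their ceiling, where the steepest hormone response
migrates to the region boundary and the planted effect is no longer
strongest where it was planted. The matching gray-matter probability volume
is 1 on the regions and a one-voxel shell, 0 elsewhere, so the default mask
retains every region voxel plus background for null statistics.

**What the generator does not emulate** — and therefore what passing tests
do not establish about scanner data: hemodynamic response shape,
physiological noise and motion, scanner drift, spatial noise correlation
beyond the applied smoothing, anatomical geometry, and physiologically
calibrated hormone concentrations. The generator validates the *machinery*
(does the pipeline recover a known coupling and stay quiet under a true
null?), not the biology.

## Study-scale validation

The test suite ties the implementation to independent oracles (dense
eigendecomposition, closed-form regression, brute-force kernels, an
igraph-based flood fill) and then validates at study scale: across 20
seeded coupled studies the progesterone-positive EC contrast must place a
supra-threshold peak inside a coupled region and the seed-based second
level must recover the partner region in at least 18, while the estradiol
contrast may do so in at most 2; across 20 seeded null studies at most 2
may show any FWE-significant peak. The voxel-wise one-sided false-positive
rate of the GLM at $p < 0.001$ is checked against its nominal level within
three Monte-Carlo standard errors (10 runs × 5000 voxels).
`scripts/acceptance.R` re-runs a coupled study, a null study, and these
calibration checks from scratch at a caller-supplied seed.

## Known limitations

* Resel counts are user-supplied or naive; no smoothness estimation, no
  random-field cluster p values.
* The session-offset mechanism in the generator is a global shared signal
  per session; pure mean or gain offsets would be invisible to EC (Pearson
  correlation is affine-invariant per voxel), which is also why the session
  indicator columns mostly matter for real data, not simulations.
* Phase labeling needs an LH surge sampled within ~2 days; sparse panels
  without one are left unlabeled rather than guessed.
* The pipeline assumes spatially normalized, motion-corrected input;
  nothing upstream of smoothing is implemented.
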