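---
title: "Methods: patch-based super-resolution of fODF images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based super-resolution of fODF images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`fodfsr` upsamples fiber-orientation-distribution (fODF) images estimated
from single-shell diffusion MRI. The fODF at each voxel is represented by 45
real spherical-harmonic (SH) coefficients (even orders up to 8) obtained by
constrained spherical deconvolution (CSD), probability-normalized to 44
coefficients, and a fully connected network maps the 3×3×3 neighborhood of a
low-resolution voxel (27 × 44 = 1188 values) to the 2×2×2 block of
high-resolution voxels it covers (8 × 44 = 352 values). Spline interpolation
of orders 0–2 on the matching half-voxel-offset grid serves as the baseline,
and an angular earth-mover's distance (EMD) between extracted fODF peaks
quantifies orientation fidelity.

# Representation

**SH basis.** We use the real symmetric basis common in q-ball and CSD work:
for each even degree $\ell$ and order $m$, the element is
$\sqrt2\,\mathrm{Re}(Y_\ell^{|m|})$ for $m<0$, $Y_\ell^0$ for $m=0$, and
$\sqrt2\,\mathrm{Im}(Y_\ell^{m})$ for $m>0$, with Condon–Shortley phase and
indices ordered $\ell$ ascending then $m$ ascending. The convention is fixed
once and pinned by a golden-value test against an independent
special-function implementation. With $\ell_{\max}=8$ there are
$(\ell_{\max}+1)(\ell_{\max}+2)/2 = 45$ coefficients.

**Probability normalization.** Proton-density and relaxation effects make
raw fODFs integrate to arbitrary values. Dividing all coefficients by
$\sqrt{4\pi}A_0$ makes the spherical integral exactly 1 and the constant
coefficient redundant ($A_0 \to 1/\sqrt{4\pi}$), so normalized voxels carry
44 values. Voxels with $|A_0| \le 10^{-8}$ (background, failed fits) cannot
be normalized; they are zeroed and tracked in a validity mask — a choice of
ours, since degenerate voxels admit no principled normalization.

# Synthetic data

The phantom generator stands in for real brain data so that the entire
pipeline is testable at desk scale. Each phantom is a deterministic function
of `(shape, seed)` with three regions along x: a single-fiber slab, an
orthogonal equal-weight (0.5/0.5) crossing, and an isotropic free-water
region ($D_{\mathrm{iso}} = 3.0\times10^{-3}\,$mm²/s). The orientation
field of each region sweeps its full fundamental domain smoothly across the
volume (the single-fiber angle covers the whole circle, the crossing pair a
quarter turn), so *every* phantom covers the complete orientation space —
as whole-brain training data does — while per-seed random phases shift the
spatial arrangement. This matters for the learning experiment: training
phantoms whose orientations cluster around a few base angles leave the
held-out phantom's orientations unsupported and make the network's
advantage an accident of the seed.

Signal follows the standard prolate-tensor mixture on a single shell
($b = 3000$ s/mm², 60 directions from seeded electrostatic repulsion plus
one b0): $S(\mathbf g) = \sum_k f_k \exp[-b(\lambda_\perp +
(\lambda_\parallel-\lambda_\perp)(\mathbf g\cdot\mathbf u_k)^2)]$ with
defaults $\lambda_\parallel = 1.7\times10^{-3}$,
$\lambda_\perp = 0.2\times10^{-3}$ mm²/s — typical coherent white matter
values, configurable because response functions are usually estimated from
data we do not model. The noiseless b0 is exactly 1, so volumes are
attenuations and SNR conventions are simple: Rician noise takes
$|S + \sigma(\varepsilon_1 + i\varepsilon_2)|$ with $\sigma = 1/\mathrm{SNR}$.
Low-resolution companions are built by 2×2×2 block averaging (voxel 1.25 mm
→ 2.5 mm) and carry $\mathrm{SNR}_{lr} = 8\sqrt2\,\mathrm{SNR}_{hr}$: an
8-fold voxel-volume gain times a $\sqrt2$ repetition gain, both exposed as
arguments.

What the phantom does **not** emulate: anatomical geometry (gyri, fanning,
partial-volume gradients), spatially varying response functions, multi-shell
contrast, and acquisition artifacts. Passing tests therefore demonstrate
correctness of the algorithms and the direction of the method's advantages
under controlled conditions, not clinical performance.

# Constrained spherical deconvolution

The forward model convolves the fODF with an axially symmetric single-fiber
response; by the Funk–Hecke theorem this multiplies each degree-$\ell$
coefficient by $r_\ell\sqrt{4\pi/(2\ell+1)}$, where $r_\ell$ are the $m=0$
SH coefficients of the response on the shell (computed by Gauss–Legendre
quadrature). The fit minimizes
$\|F a - s\|^2 + \lambda_{\mathrm{eff}}^2\|L a\|^2$, where $L$ holds the
rows of a ~321-direction hemisphere constraint tessellation whose current
fODF amplitude falls below $\tau$ times the mean amplitude of an
unconstrained order-4 initial fit, iterated until the constrained set is
stable (at most 50 iterations). Defaults $\lambda = 1$, $\tau = 0.1$, with
$\lambda_{\mathrm{eff}} = \lambda\,K\,\hat r_0/n_{\mathrm{constraint}}$
(the scaling used by the standard Python implementation of CSD) are the
published standard settings. Signal is normalized to attenuation by the
per-voxel mean b0 before fitting; voxels with nonpositive b0 are marked
invalid.

A note on nonnegativity: the soft constraint suppresses but does not
eliminate negative lobes. A band-limited representation of a sharp fODF
necessarily rings (an order-8 truncated delta has sidelobes near −9% of its
peak), and the converged soft-constrained fit of a noiseless single fiber
retains lobes around −3% of the maximum. Forcing residual negativity
below ~0.1% requires penalizing sub-threshold amplitudes toward equality
with zero, which measurably collapses the main lobe; we therefore keep the
standard estimator and document nonnegativity at the few-percent level.

# The upsampling network

Architecture: three blocks of dense(1000) → batch normalization → ReLU,
then a dense output of 352 with no activation — 3,549,352 trainable
parameters (dense weights and biases plus two batch-norm parameters per
hidden unit). A 5×5×5-input variant would count 7,861,352 by the same
closed form. Training uses mean-squared-error loss and Adam (learning rate
$10^{-3}$, the optimizer default, as none is published for this
architecture), batch size 512. Batch normalization uses per-batch statistics
in training and exponentially averaged running statistics (momentum 0.99,
$\varepsilon = 10^{-3}$) at inference; dense layers before batch
normalization keep their biases (they are absorbed by normalization but
included in the parameter count). Initialization is Glorot-uniform; the
whole procedure is a pure function of the seed, so training is exactly
reproducible.

Patches flatten voxel-major with the z offset fastest, then the 44
coefficients per voxel — an arbitrary but fixed and documented order, with a
bijection test guaranteeing that target layout and scatter are mutually
inverse. Border neighborhoods are zero-padded so every brain voxel
contributes an example. Splits are assigned at phantom ("subject") level to
avoid leakage between neighboring patches.

# Interpolation baselines

Block averaging places a low-resolution center at $y_j = 2j - 0.5$ relative
to high-resolution integer coordinates $x_i = i$. Spline upsampling of
orders 0/1/2 (nearest, trilinear, quadratic) evaluates the tensor-product
spline defined at those offset coordinates, one SH coefficient at a time.
Order 2 uses exact B-spline prefiltering (pole $z = \sqrt8 - 3$, gain 8)
with mirror boundary extension — the boundary rule is ours, as only the
coordinate mapping is prescribed; order 0 reproduces 2×2×2 block
replication exactly, which also makes it a proxy for the raw low-resolution
data.

# Evaluation

**Peaks.** fODF amplitudes are evaluated on a subdivided-icosahedron
hemisphere (1281 directions, dense enough for order-8 extrema); local
maxima over the antipodally wrapped adjacency are kept if they reach 0.5 of
the global maximum, greedily suppressed within 25°, and capped at 5 —
the extraction settings used for every peak statistic here. Equal-amplitude
ties order lexicographically by direction components; extraction is
invariant to positive rescaling.

**Angular EMD.** Peak sets are compared as discrete mass distributions
(amplitudes normalized to unit total) under the orientation ground cost
$c(\mathbf u,\mathbf v) = \arccos|\mathbf u\cdot\mathbf v|$ in degrees
(antipodally symmetric, so costs lie in [0, 90]). The transportation LP is
solved exactly by an in-package transportation simplex (peak sets have at
most 5 atoms); supplies are perturbed by $10^{-11}$ against degeneracy,
changing optima by well under $10^{-8}$°. Conventions of ours, flagged in
the output: one empty set against a nonempty one scores 90° (all mass at
maximal cost); two empty sets score 0.

**Other metrics.** Per-coefficient MSE, Pearson correlation (undefined on
constant maps, reported as `NA`) and MAE over masked voxels, with PSNR and
SSIM (uniform 7³ window, unbiased local moments, per-coefficient
ground-truth dynamic range) per coefficient map. Generalized anisotropy uses
the analytic variance of the fODF over the sphere,
$V_Y = \sum_{\ell\ge2,m} A_{\ell m}^2/4\pi$ for probability-normalized
coefficients, mapped through $\mathrm{GA} = \tanh(V_Y)$. Best-method tallies
mark every method within $10^{-9}$° of the per-voxel minimum, so fractions
may sum to more than 1.

# The end-to-end experiment

`run_experiment()` wires the stages together at desk scale: 24³
high-resolution phantoms (12³ after downsampling), a reduced network
(three 256-unit blocks, 30 epochs) trained on three phantoms (~5,200
patches), evaluated on a held-out phantom at
$\mathrm{SNR}_{hr} \in \{2, 5, 20\}$. The network is trained **once** on
high-quality data ($\mathrm{SNR}_{hr} = 20$ for the training phantoms,
hence $\mathrm{SNR}_{lr} \approx 226$) and then applied across the sweep —
mirroring the intended use, where a network trained on a high-quality
corpus is deployed on noisier low-resolution acquisitions. Training it
per-noise-level on very noisy targets instead teaches the network the
label noise and measurably degrades its output. Ground truth is the peak
field of the clean high-resolution fit; errors are mean angular EMD over
white matter. These sizes keep the full pipeline in the minutes range on a
single CPU while preserving the qualitative comparisons: the network should
beat nearest-neighbor upsampling and, at low SNR, the noisy high-resolution
acquisition itself, with that advantage shrinking as SNR grows.

```{r}
library(fodfsr)
res <- run_experiment(experiment_config(snr_sweep = c(2, 5, 20), seed = 1))
res$sweep
plot_snr_sweep(res)
```

# Known limitations

* The phantom's geometric simplicity flatters interpolation baselines
  (large homogeneous regions) and understates the network's advantage on
  convoluted anatomy; conversely it cannot show generalization to real
  tissue.
* Isotropic-region fODFs are essentially random after CSD (the model
  assumes fiber-like diffusion), so peak statistics there describe noise
  behavior; white-matter masks exclude them from headline numbers.
* The network operates per 3×3×3 neighborhood with no larger context, and
  repeated application compounds its biases (peak counts drop with each
  doubling).
* Only single-shell, single-tissue CSD is implemented; multi-shell and
  multi-tissue variants, asymmetric ODFs, and tractography-based evaluation
  are out of scope.
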