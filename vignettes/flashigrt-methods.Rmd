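---
title: "Methods: volumetric image guidance and WET evaluation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric image guidance and WET evaluation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Proton FLASH radiotherapy delivers its dose in a fraction of a second, which
leaves no room for mid-delivery imaging or correction: the patient's anatomy
must be verified volumetrically *immediately* before the beam fires. On-board
kV imagers can acquire a pair of orthogonal planar projections in seconds,
but a pair of radiographs is not a CT. `flashigrt` implements, end to end
and at desk scale, a framework that closes this gap for lung targets:

1. **Projection synthesis** — digitally reconstructed radiographs (DRRs) of
   a (synthetic) 4D CT, acquired as orthogonal pairs from four clinical
   source-angle pairs (112/202, 135/225, 157/247, 180/270 degrees).
2. **2D-to-3D reconstruction** — a residual encoder-decoder network maps the
   two projections to a full CT volume.
3. **Image evaluation** — ME, MAE, PSNR, SSIM and CT-number histograms
   against the reference CT.
4. **Treatment evaluation** — ray-traced water-equivalent thickness (WET)
   through the target for an anteroposterior proton beam, summarizing
   anatomical fidelity in the quantity protons actually care about.

Every stage is driven by one seed, so a whole study is a pure function of
its configuration.

## The synthetic 4D phantom

Clinical 4D CT cohorts cannot ship with a package, so the `phantom` module
generates a breathing thorax: an elliptic soft-tissue body (+40 HU), two
lung ellipsoids (-750 HU), a spine cylinder (+700 HU), a heart surrogate
(+50 HU) and a spherical lung tumor (+40 HU, radius 15 mm) over a -1000 HU
air background. Respiration is a one-dimensional superior-inferior
translation of the tumor and the diaphragm with displacement
$A\,(1-\cos(2\pi k/10))/2$ at phase $k$ — phase 0 is full inhale, phase 5
full exhale, peak-to-peak amplitude $A = 10$ mm by default, a typical
lower-lobe excursion. Additive Gaussian noise (default SD 15 HU,
representative of thoracic CT) is drawn from the configured seed.

The default grid is $64 \times 64 \times 48$ voxels at 4 mm — a
$256 \times 256 \times 192$ mm field of view. These sizes make a ten-fold
training study a desk-scale computation; all organs are positioned in world
millimeters, so finer grids refine the same anatomy.

What the phantom does *not* emulate: deformable motion (breathing here is a
rigid translation with a sliding diaphragm cut), cardiac motion, tissue
texture, scanner artifacts, and the anatomical variability of real
patients. Consequently, passing tests demonstrate the *mechanics* of the
framework — geometry, losses, cross-validation hygiene, metric definitions,
WET physics — not clinical-grade reconstruction accuracy on real anatomy.

## Projection model

Projections are cone-beam line integrals $\int \mu \, dl$ of attenuation
relative to water, using the CT-number identity $\mathrm{HU} = 1000(\mu-1)$
(clamped at vacuum). Integration is exact Siddon-style voxel traversal, so
slab and cube oracles hold to floating-point precision; there is no scatter,
spectrum or detector model, and projections live in the log (line-integral)
domain. The source angle is measured about the superior-inferior axis, 0
degrees anterior, increasing toward patient-left; source-axis and
source-detector distances default to 1000/1500 mm (typical kV arm values)
and the panel scales from the clinical 768 x 1024 at 0.39 mm down to the
128 x 128 at 3.5 mm panel used in the desk-scale pipeline, which covers the
phantom's field of view at isocenter magnification.

## The reconstruction network

Two convolutional encoders (one per projection; the projections are
resampled to $128\times128$ and scaled to $[0,1]$ by their own maximum)
downsample with stride-2 convolutions to $8\times8$, apply `n_residual_blocks`
residual blocks of the form $x + \mathrm{conv}(\phi(\mathrm{conv}(x)))$, and
pool to $4\times4$. The flattened features of both encoders are fused by two
dense layers (bottleneck width 256) into a coarse
$(X/8)\times(Y/8)\times(Z/8)$ grid, which three transposed convolutions
(zero-insertion upsampling followed by stride-1 convolution) upscale to the
reference CT shape. Volumes are normalized to $[-1,1]$ over the intensity
window (-1000, 600) HU and de-normalized on inference; the window round-trip
is exact.

The loss is mean absolute error plus a gradient (edge) term: the mean over
axes of the mean absolute difference of forward finite differences, weighted
by `gradient_loss_weight` (default 1). Optimization is Adam.

Numerical and design choices that mattered:

* **Activation** — leaky rectifier (slope 0.1) rather than a hard ReLU. At
  desk-scale widths a hard ReLU can leave the narrow fusion layer entirely
  dead at initialization, making the whole decoder inert; the leaky slope
  guarantees gradient flow.
* **Output prior** — the output bias is initialized at the normalized air
  value, so optimization spends its steps on anatomy rather than on
  re-deriving the empty background.
* **Learning rate and batch** — with 9 training samples and 50 epochs the
  optimizer takes only 450 steps per fold. Measured on the phantom
  protocol, Adam at 2e-4 cannot move a fresh network appreciably in that
  budget, while 1e-2 diverges; the defaults are 1e-3 with batch size 1.
  Held-out-phase MAE lands around 130-140 HU under the default conditions.
* **Determinism** — weight initialization, batch order and everything
  downstream derive from `seed` (plus the fold index), so training twice
  yields bit-identical variants, and inference is a pure function.
* **Implementation** — layers, backpropagation (verified against central
  finite differences) and Adam are implemented in the package, with C++
  kernels for patch extraction, direct 3D convolution and in-place
  parameter updates; matrix products run in BLAS.

### Leave-phase-out protocol

For a 10-phase study, ten model variants are trained, variant $k$ on the
nine phases other than $k$, and each held-out phase is reconstructed by the
model that never saw it. The trainer asserts fold hygiene (the held-out
phase never enters a batch) and logs per-epoch losses. `plan_leave_phase_out()`
enumerates a multi-subject campaign — 30 subjects x 10 phases is 300
training runs.

## Evaluation metrics

ME and MAE are evaluated over the whole volume; PSNR and SSIM over the
target contour, mirroring the usual clinical reporting convention. PSNR uses
the reference maximum over the evaluated region as its peak, exactly as the
formula $10\log_{10}[\max^2(x_{ref})/\mathrm{MSE}]$ states (a fixed scanner
peak can be passed instead); identical volumes return an infinite-PSNR
sentinel rather than an error. SSIM is a 3D Gaussian-window (11^3,
$\sigma = 1.5$, $k_1 = 0.01$, $k_2 = 0.03$) local statistic averaged over
mask voxels whose window fits inside the volume; the masked path crops to
the mask's bounding box dilated by the window radius, growing the crop
toward the interior when the mask touches the volume edge. The dynamic range
defaults to the reference range over the evaluated region. A division of a
mean error by 10 restates it as a percent error in relative attenuation
(`percent_me`), via the same CT-number identity the projector uses.

CT-number histograms default to 100 bins over [-1000, 1000] HU; counts
conserve the number of in-range voxels.

## WET evaluation

CT numbers convert to relative stopping power through a monotone
piecewise-linear HLUT pinned at (0 HU, RSP 1). The packaged default table
(air 0.001, water 1.0, 1000 HU at 1.55, 3000 HU at 2.40) is a generic
calibration for demonstration; any commissioned two-column CSV drops in.

WET is integrated along parallel anteroposterior rays (the standard WET
convention for an anteroposterior beam; no divergence) from the volume's
anterior boundary to each ROI voxel's *center* — a defined, testable
endpoint convention. On the piecewise-constant CT grid this accumulation is
exact, which the tests confirm against analytic slabs (1e-6 mm) and a
fine fixed-step midpoint oracle (0.5%). $\Delta$WET is the mean signed
difference over the ROI in mm; $\epsilon_{WET}$ expresses it relative to the
mean reference WET in percent. Histogram summaries use a least-squares
Gaussian fit (50 bins, moment initialization, `minpack.lm`), falling back to
sample moments with a flag when the fit degenerates.

## Pipeline and reproducibility

`run_framework()` chains all stages for each configured angle pair and
reports one row per (phase, angle pair) with aggregates as mean and sample
(n-1) SD over phases; `summarize_reports()` averages subjects into a
patient-level table. A debug switch injects the reference as its own
reconstruction, which must null every error metric — the end-to-end
identity check. Reports are written as CSV/JSON with a YAML configuration
snapshot, and two runs from one seed produce byte-identical files.

Problem sizes used by the shipped verification runs: the default phantom
(64 x 64 x 48 at 4 mm, 10 phases), the 128 x 128 desk panel, one angle pair
(135/225, the best-performing pair for volumetric reconstruction) for the
trained study in `scripts/acceptance.R`, and all four pairs for the identity
check. The four-pair trained study runs with the same call by passing
`standard_angle_pairs()`.

## Known limitations

* The phantom's rigid motion and piecewise-constant anatomy make the
  reconstruction task easier than clinical data; reported metric values
  characterize the pipeline, not clinical performance.
* At the default training budget (450 optimizer steps per fold) the network
  recovers the global anatomy — whole-volume MAE in the low hundreds of HU —
  but only partially resolves the small moving tumor, so target-contour
  PSNR/SSIM and the WET agreement are markedly weaker than their
  whole-volume counterparts. They are reported as computed; tightening them
  is a matter of training scale, not of the framework's mechanics.
* The projector is monoenergetic and scatter-free.
* The default HLUT is not a commissioned calibration.
* The network is intentionally small; scaling to clinical grids requires
  larger panels, wider layers and far more compute than the defaults target.
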