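---
title: "Detecting small vascular bundles in stem cross-sections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small vascular bundles in stem cross-sections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbdetect)
```

## The problem

A transverse micrograph of a rice stem internode shows a ring-structured
anatomy: a stem perimeter ("out"), a central cavity ("in"), an inner ring of
large vascular bundles ("big") and a peripheral ring of small vascular
bundles ("small").  Counting and measuring these bundles is a routine
phenotyping task, and the small bundles are the hard part: they are tiny
(often under 10 px at typical magnifications), densely arranged, soft-edged
and low-contrast.  `vbdetect` implements a one-stage, anchor-free object
detector specialized for this regime, together with everything needed to
exercise it end to end on a CPU: annotation I/O, a synthetic scene
generator with exact ground truth, a full detection evaluation suite, and a
training harness.

## Architecture

The detector follows the familiar one-stage layout: a convolutional
backbone emits a feature pyramid P2/4, P3/8, P4/16, P5/32 (name/stride), a
fusion neck mixes the levels, and per-level heads predict boxes and scores
on their grids.  Three design elements target small objects specifically.

### Dynamic snake convolution

Backbone C2f blocks replace their dense convolutions with *snake*
(serpentine) kernels: `k` taps march along one image axis while a learnable
fractional offset `Δy[t]` displaces each tap along the perpendicular axis,

    K(i ± c) = (x_i ± c, y_i + Δy_c)        (horizontal axis; vertical swaps roles)

Sampling at fractional positions uses linear interpolation with zero
padding, the convention of deformable convolutions; the interpolation makes
the response differentiable in the offsets, so they are trained end to end
like any other parameter.  Offsets are per-tap, per-layer, shared across
channels, and clamped to `[-offset_clamp, offset_clamp]` (default 1 px)
after every optimizer step; the two convolutions of each bottleneck
alternate horizontal and vertical axes so the composed receptive field
grows in both directions.  The intent is a kernel that can bend along thin,
curved boundaries instead of integrating over a rigid square.

The snake kernels also carry a functional weight-quantization path:
weights are linearly mapped onto a signed `b`-bit integer grid
(`w_q ∈ [-2^(b-1), 2^(b-1)-1]`, round half to even, range-fit step), then
reconstructed through a *kernel distribution shift* (KDS): per block of
`BLK` weights (default 64) a scale `ξ` is the closed-form least-squares
minimizer of `Σ (w_q ξ − w)²`, i.e. `ξ = Σ w_q w / Σ w_q²`, and a bias
`ξ_s` absorbs the mean residual.  A *channel distribution shift* (CDS)
then applies the same least-squares recipe per output channel.  Degenerate
blocks (`Σ w_q² = 0`) fall back to `ξ = 1`, `ξ_s = mean(w)`.  The package
treats quantization as a fidelity-preserving re-parameterization — the
reconstruction direction is the only reading under which the dequantized
kernel approximates the original tensor — and makes no claim about integer
arithmetic speedups; training always runs on the float path.

### Multi-scale feature fusion with a stride-4 head

Small objects die at coarse strides: a 6-px bundle occupies a fifth of a
stride-32 cell.  The neck therefore extends the usual FPN/PAN pattern one
level shallower.  Top-down, upsample-fuse steps (nearest-neighbor 2×
upsampling, channel concatenation in the fixed order *(upsampled deep,
shallow)*, C2f mixing) produce F4 from P5+P4, F3 from F4+P3 and — the
extra step — F2 from F3+P2 at stride 4.  Bottom-up, stride-2 convolutions
(T2, T4, T5) re-descend the pyramid, fusing F2 into F3, then onward through
F4 and P5.  Four heads sit at strides 4/8/16/32.  The fusion operator is
channel concatenation by default; element-wise addition is available as a
configuration switch.  With `use_mff = FALSE` the network reduces to the
3-head baseline (strides 8/16/32) used as the ablation reference, and
`use_dsconv = FALSE` swaps the snake kernels for plain dense convolutions,
so all eight ablation combinations of (snake backbone, fusion neck, box
loss) are constructible from flags.

Channel widths per stage are not architecturally constrained; the package
ships a `"tiny"` preset (4/8/12/16/24) for CPU work and a default preset
(16/32/48/64/96).  Activation is SiLU throughout; head outputs are linear.

### Box regression losses

The CIoU baseline is

    L_CIoU = 1 − IoU + ρ²(b, b_gt)/c² + αv,
    v = (4/π²)(arctan(w_gt/h_gt) − arctan(w/h))²,   α = v/((1 − IoU) + v),

with `ρ` the center distance and `c` the diagonal of the smallest enclosing
axis-aligned box (the universal convention for "diameter of the enclosing
box"); `α` is defined as 0 when both `1 − IoU` and `v` vanish.

The PIoU alternative multiplies an overlap/penalty factor by the focusing
prefactor `3u·e^{−u²}` with `u = λq`, which peaks at `u = 1/√2` — λ tunes
where along the penalty scale the loss concentrates its gradient.  Two
ambiguities in the circulating formulations are kept explicit as
configuration switches rather than silently resolved:

* **Penalty mode.**  The *printed* equations build the penalty `P` from the
  four quantities `|w₁−w₂|`, `|w₁+w₂|`, `|h₁−h₂|`, `|h₁+h₂|` normalized by
  the ground-truth size — a function of box sizes only, hence invariant
  under translation (a regression test documents this).  The *corner* mode
  uses the distances between matching corner coordinates, which matches the
  stated motivation of penalizing corner displacement and does respond to
  translation.  Default `"printed"` for fidelity; `"corner"` recommended
  and used for training.
* **Loss form.**  The *printed* combination `(1 − IoU − e^{−P²})` is
  negative at perfect overlap (it evaluates to `−3/e` at `λ = 1`, `P = 0`,
  `IoU = 1` — asserted as a documented-anomaly test), so it cannot serve as
  a minimized training objective as written.  The *corrected* form
  `(1 − IoU) + (1 − e^{−P²})` is nonnegative and vanishes exactly at
  perfect overlap.  Default `"printed"`; `"corrected"` used for training.
* The focusing factor is `q = e^{−P²}` by default, with `q = e^{−P}`
  available.

`λ` defaults to 1.3 and is configurable; no canonical value is fixed by the
formulation.

## Target assignment, decoding, training

Assignment is anchor-free scale routing: a ground-truth box goes to the
head with the smallest stride `s` satisfying `max(w, h) ≤ 4s` (clamped to
the available strides), claiming its center cell plus the nearest neighbor
cell along each axis; collisions resolve first-come in ground-truth order.
A cell decodes to a box via `center = (cell + 2σ(t) − 0.5)·s` and
`size = (2σ(t))²·s`, so offsets span (−0.5, 1.5) cells and sizes (0, 4s) —
the routing rule guarantees every assigned box is representable.  Scores
are `σ(objectness)·σ(class)`; decoding clips to the image and applies
per-class greedy non-maximum suppression.

The training loss is binary cross-entropy on objectness over all cells
(positive cells weighted 3), binary cross-entropy on class logits at
positive cells, and the selected box loss at positive cells, weighted
1 / 0.5 / 5 respectively — the box-heavy weighting is the standard recipe
for detection heads.  The classification/objectness terms are inherited
plumbing, not a contribution of the method.

The network runs on a small tape-based reverse-mode autodiff engine written
for this package, with compiled (Rcpp) kernels for dense convolution, snake
convolution (including gradients with respect to the offsets) and
upsampling.  Gradients of the network are analytic and verified against
finite differences to ~1e−5 relative error; the box-loss gradient with
respect to a cell's four raw activations is evaluated by central
differences (step 1e−3) at the few assigned cells, which keeps every IoU
variant pluggable without hand-deriving its derivative.  One caveat is
inherent to deformable sampling: linear interpolation is piecewise linear
in the offset, so at exactly integer sampling positions the offset gradient
is a one-sided subgradient.  Optimization is Adam (β = 0.9/0.999,
ε = 1e−8).  The faithful protocol preset is 100 epochs, learning rate
0.01, batch 16, input 640×640; the tiny preset trains at 0.001, which is
better behaved at very small widths.  Weight decay, schedules and warmup
are deliberately absent (constant learning rate); augmentation is off by
default, with optional horizontal flips behind a flag.  Runs are fully
seeded — initialization, data order, augmentation — and bit-reproducible
on CPU.

## The synthetic scene generator

The generator emulates the statistical structure of a stem cross-section
dataset rather than its histology: a bright-field disk with a central
cavity, ~28.3 small and ~30.9 large bundles per image (Poisson counts by
default — the per-image rates of a 1091-image reference corpus with 30854
small and 33692 big annotations), small bundles of 3–8 px radius at a
640-px image placed on an outer ring (0.78–0.95 of the stem radius), large
bundles of 9–16 px on an inner ring, exactly one "in" and one "out" region.
Bundles are axis-aligned ellipses with jittered radii, placed by rejection
sampling with an overlap bound; infeasible packings fail loudly naming the
constraint.  Degradations apply in a fixed order — render → Gaussian blur →
multiplicative illumination ramp → additive texture noise → contrast
compression toward mid-gray — because the order controls edge softness, the
property that makes small-bundle detection hard.  Geometry is frozen before
degradation, so every annotation box tightly bounds its rendered ellipse by
construction, and the whole scene is a deterministic function of the
configuration seed.

What the generator does *not* emulate: xylem/phloem substructure, staining
variability, sectioning artifacts, rotated or non-elliptical bundles, and
annotation noise.  Tests passing on synthetic scenes therefore demonstrate
that the pipeline is correct and trainable under the stated statistics, not
that any particular accuracy transfers to real micrographs.

The `"easy"` preset (high contrast, no blur, a handful of larger bundles,
no big-bundle ring) exists for CPU smoke training; `"paper-like"` keeps the
low-contrast defaults.

## Evaluation conventions

* Matching is greedy one-to-one in descending confidence; a prediction
  claims the unmatched same-class ground truth of highest IoU above the
  threshold.  Ties break deterministically (ground-truth index; prediction
  index for equal confidences).
* AP integrates the precision–recall curve with the 101-point
  interpolation of the monotone precision envelope (the dominant
  convention); an `"exact"` all-points staircase mode exists and is what
  the oracle tests compare against.  mAP pools detections per class over
  all images, then averages classes — the alternative per-image reading of
  "average AP of all images" is noted but not used.  Classes without
  ground truth are excluded from the mean with a warning.
* Dice and region IoU are computed by rasterizing the per-class unions of
  boxes into binary masks (pixel centers on the integer grid) — the only
  region definition computable from box-level outputs; the identity
  `Dice = 2·IoU/(1 + IoU)` holds per class pair and is tested.
* MAPE excludes zero-valued actuals with a warning (relevant on synthetic
  data, where a sparse preset can produce empty images); RMSE is computed
  on all entries.

## Problem sizes used by the shipped checks

The test suite and the acceptance script exercise the full pipeline at
sizes chosen for CPU determinism and quick iteration: gradient and oracle
checks on inputs up to 32×32, architecture contracts at 640×640 on the
tiny width preset, generator statistics over 200 default scenes, and an
end-to-end run — 100 easy 64×64 scenes, single small-bundle class, tiny
widths, 18 epochs, corrected-PIoU loss, evaluated on 20 held-out scenes —
that reaches mAP@.5 well above the 0.3 smoke bar (≈0.7 at the default
seed).  The identical run with the CIoU loss completes and is reported
alongside for qualitative comparison; at this scale the two losses land
within noise of each other, consistent with the expectation that the PIoU
advantage concerns harder, denser regimes than the easy preset.

## Known limitations

* The engine is a correctness-first CPU implementation; the default-width
  preset at 640×640 trains orders of magnitude slower than a GPU framework
  and is not intended for production training runs.
* Objectness targets are binary (not IoU-aware), assignment is static
  rather than task-aligned, and no augmentation beyond optional flips is
  provided — deliberate simplifications documented here so their absence
  is not mistaken for a claim.
* Box-level Dice/IoU is a coarse proxy for segmentation quality.
* The printed PIoU form is kept verbatim behind its flag for fidelity,
  anomaly included; training should use the corrected form.
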