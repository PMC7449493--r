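---
title: "Methods: phantom-validated lung-nodule CAD with a multiscale dense 3D U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated lung-nodule CAD with a multiscale dense 3D U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lungcad)
```

lungcad implements a complete computer-aided-detection (CAD) workflow for
pulmonary nodules on thoracic CT: volume I/O and preprocessing, lung
parenchyma segmentation, a multiscale dense/dilated U-Net with its own CPU
training engine, and FROC-based detection evaluation. Because the full-scale
public datasets (LUNA16, TIANCHI) require GPU-scale training, every component
is exercised end to end on *synthetic thorax phantoms* with exact ground
truth; this vignette explains the models, the parameters that matter, and
what phantom-scale validation does and does not establish.

## Volume model and preprocessing

A `ct_volume` is a 3-D voxel grid in `(z, y, x)` index order with per-axis
spacing (mm) and a world origin; world coordinates are
`origin + index * spacing`, and annotation CSVs use the public
`seriesuid, coordX, coordY, coordZ, diameter_mm` dialect with world-mm
`(x, y, z)` centres. Conversions are explicit (`xyz_to_zyx()`,
`world_to_voxel()`) and tested, because silently mixed index orders are the
classic failure mode with `.mhd` lung data.

Preprocessing follows the standard recipe: resample to 1.0 mm isotropic
(trilinear for intensities, nearest neighbour for masks), then standardize
gray values to zero mean and unit variance. Whether the standardization
statistics should be pooled over the training set or computed per volume is
genuinely open; both are supported (`volume_stats()` pools over any set of
volumes), and the pooled "dataset-global" mode is the default workflow
because a detector must see absolute attenuation differences between
volumes. Training patches are 40 x 40 x 26 voxels `(x, y, z)`, large enough
to contain any annotated nodule (3-30 mm), padded with -1000 (air) where
they overrun the grid.

## The thorax phantom

`phantom_spec()` / `generate_phantom()` produce a stylized thorax at 1 mm
isotropic resolution (so radii in mm equal voxels): air background (-1000),
an elliptical soft-tissue body (+40) with a thin bright bone ring (+700),
two ellipsoidal lungs (-800), a vertical air-filled trachea reaching the top
axial slice with optional bronchus stubs, bright spherical nodules
(lung + `contrast`, default -100, a solid nodule), an optional lung-density
bridge that fuses the two lungs, and an optional bright juxtapleural
indentation ("notch"). Two deliberate design choices:

* every airway tube is wrapped in a 2 mm soft-tissue wall, as the bronchial
  wall is anatomically, so airway lumen and parenchyma are distinct dark
  structures and each pipeline stage has an unambiguous target;
* the pleural notch is a sphere whose centre sits three quarters of a radius
  inside the lung surface - a pit deeper than its mouth is wide, which is
  the shape a juxtapleural nodule indentation takes and which a rolling
  ball of radius larger than the mouth can bridge. A hemispherical bite
  open at the surface would leave a lens at its mouth that *no* ball-based
  closing can fill; that is a property of the morphology, not of the
  implementation.

The default phantom is noiseless; Gaussian noise of configurable sd can be
added (seeded, so phantoms are bit-reproducible). The phantom's histogram
contains exactly the configured intensity levels, which the tests assert.
Phantoms do *not* emulate: partial-volume blur at boundaries, anatomical
airway trees, vessels, texture, or ground-glass (non-solid) nodules - the
last mirrors a stated limitation of the approach for pure ground-glass
nodules. Passing the phantom suite therefore demonstrates algorithmic
correctness under idealized attenuation geometry, not clinical performance.

## Lung segmentation

`segment_lungs()` composes four steps, retaining every stage mask:

1. **Rough thoracic segmentation.** Global Otsu thresholding over a 256-bin
   histogram (the "adaptive threshold" appropriate for the bimodal lung CT
   histogram) marks the dark class; connected components touching a
   *lateral* (x/y) boundary face - ambient air and tray - are removed.
   Axial faces are exempt because the trachea legitimately exits the scan
   through the top slice. Enclosed bright structures (vessels, nodules) are
   then filled slice by slice.
2. **Airway removal.** The main trachea is grown in 3-D from the most
   circular dark region of the top slices, raising the intensity threshold
   in steps of 20 until the grown volume jumps by more than a factor 1.5
   between steps (the classic leak-explosion guard; both knobs sit in
   `seg_config()`, and the increment/criterion are this package's own
   defaults since only the method, not its constants, is prescribed).
   Bronchi are then recovered by grayscale *closing-by-reconstruction*: a
   closing with a 4 mm ball erases dark structures thinner than the ball,
   reconstruction by erosion under the original restores everything
   connected to a surviving dark minimum, and the difference image is
   non-zero precisely over thin isolated dark tubes. Voxels with
   difference > 200 are subtracted; residual specks below 64 voxels are
   dropped (the two principal components are always kept, so a 3 mm nodule
   inside a lung is never discarded).
3. **Fusion detection and separation.** With T = 4, the lungs count as
   fused when the largest dark component exceeds the second largest by more
   than a factor T. The ratio reading (A1/max(A2,1) > 4) is used because an
   absolute-difference reading of "difference of the first and second
   largest areas" would make a threshold of 4 voxels meaningless at CT
   scale; the absolute variant remains available in `seg_config()`. The
   dividing line is the per-slice minimum of the vertical integral
   projection (column-wise foreground sums) within the central third of the
   x-range, interpolated across undefined slices, slope-limited to one
   column per slice, and cleared two columns wide - the width that
   guarantees disconnection under 26-connectivity.
4. **Rolling-ball repair.** Morphological closing with a disc of radius
   12.5 mm, applied per axial slice *and per component*: per-component
   closing can never bridge the inter-lung gap (which is narrower than two
   ball radii), while concavities narrower than the ball - juxtapleural
   nodule notches - are filled. A 3-D ball variant sits behind
   `seg_config(ball_3d = TRUE)`. Closing is forced extensive
   (output contains input) by union with the input, which removes border
   artefacts of finite-grid erosion.

On the default noiseless phantom the final mask reaches Dice 0.9997 against
truth with zero trachea contamination; the acceptance thresholds (Dice at
least 0.90, trachea overlap at most 5%, notch restoration at least 90%) are
deliberately looser because they must also hold for fused and notched
variants.

## The multiscale dense/dilated U-Net

Architectures are *data*: an `arch_table` tibble with one row per layer
(kind, kernel, dilation, channels, scale, sources), from which
`build_network()` instantiates trainable layers and `shape_trace()` derives
the symbolic (spatial, channels) record at every named layer. The normative
`default_multiscale_table()` pins the reference channel counts exactly -
Conv1 32; D1/T1 128; dilated branches 96; Conv2/Conv3 concats 224; Conv4
concat 480; Conv6 480; Up6 = 512 + 480 = 992; Up8 = 1376 + 224 = 1600;
Up12 = 224 + 32 = 256; output head of two 1 x 1 convolutions with a
sigmoid. The reference *spatial* narrative is internally inconsistent, so the
table defines spatial scales by successive halving (512, 256, ..., 8, with
the bottleneck convolution Conv5 at 4 x 4 and each encoder level spanning a
x4 downsample: one pool before the dense block and one inside the
transition). Three widths are unstated in the source material and are this
package's explicit choices: Conv5 = 512 (which makes the upconv into Up6
512 wide, matching the reference), the Up8 upconv 1600 - 224 = 1376, and the
non-anchor decoder upconv widths (512/128/224).

Each encoder level runs two branches on the pooled input: a *dense branch*
(dense block of growth rate 3 with a 16-channel 1 x 1 bottleneck, four
densely connected 3 x 3 layers, and a channel-setting 1 x 1 projection -
the projection is required because growth rate 3 cannot reach the reference
128/384 outputs in any plausible layer count) followed by a transition and
a 3 x 3 convolution, and a *dilated branch* (pooling then a 3 x 3
convolution of dilation 2), concatenated per level. The decoder upsamples
continuously - one 2 x upconv (nearest-neighbour upsample + 2 x 2
convolution) per halving - with skip concatenations alternating between
level concats and dense-block outputs, and two decoder-side dense blocks.
Dropout (rate from the training configuration, default 0.5) is applied
after the deepest encoder concat and after the bottleneck; placement is
unstated in the source and is a design choice here. ReLU is used
throughout, max pooling for all pools.

The engine is rank-agnostic: `mode = "2d"` keeps kernels single-slice (the
configuration in which the 512 x 512 shape narrative applies and is
traced), `mode = "3d"` extends kernels and pools isotropically. Forward
inputs are zero-padded up to the network's pooling factor and cropped back;
training excludes padded voxels from the loss. Convolution, pooling and
upsampling forward/backward passes are C++ (im2col + BLAS GEMM); gradients
are validated against central finite differences in the tests.

### Desk-scale training

No deep-learning framework exists in this environment's R stack, so the
trainer is part of the package: weighted binary cross-entropy on the
sigmoid output (positive voxels weighted 20:1 by default - nodules occupy
about 1% of a patch, and unweighted BCE collapses to the background class),
Adam exactly as specified in the reference design (mu = 0.9, upsilon = 0.9999, eta = 0.01,
eps = 1e-8, both moments bias-corrected, eps inside the denominator; the
"weight attenuation" wording is resolved in favour of the explicit formula),
or plain SGD for transfer-learning fine-tuning. The learning-rate grid
{0.00075, 0.001, 0.005}, dropout 0.5, checkpointing every 10000 steps and
early stopping on the overfitting ratio TrainAcc/ValAcc (bound 1.15,
patience 3 - the bound and patience are package choices; only "stop on
overfitting" is prescribed) are all in `train_config()`. An image counts as
"correctly detected" for the accuracy metrics when its predicted mask
reaches Dice >= 0.5, a package definition since image-level correctness is
otherwise undefined for segmentation output. Six-fold augmentation
(original, two flips, three rotations) is exact and volume-preserving.
Freeze groups name contiguous spans of the layer sequence
(conv1...conv5, Up6...Up12, with the output head in the Up12 group), so
"Up12" fine-tunes only the final block and "conv1-Up12" trains everything.

The full table's pooling factor is 128, so 40 x 40 x 26 patches cannot feed
it; desk-scale runs use the parameterised constructor
`multiscale_table(levels = 2, level_stride = 2, width = 1/8)` - two dense
levels, one dilated branch each, pooling factor 8, every channel count an
eighth of a base profile chosen for this depth (Conv1 32, dense 128,
dilated 96, last concat 480, bottleneck 512). On 100 nodule-centred
noiseless phantom patches, Adam at lr 0.001 with batch 2 reaches training
Dice 0.8 in roughly 80 steps (about 1.5 CPU minutes); the acceptance suite
allows 500 steps. This demonstrates that the architecture, gradients and
optimizer form a working learning system at reduced scale - it says
nothing about full-scale detection accuracy, which is explicitly out of
scope.

## FROC evaluation

Candidates come from thresholding a probability map, labelling 26-connected
components, and taking each component's score-weighted centroid with its
maximum probability as score. A candidate hits a nodule when it lies within
the nodule radius of the centre (the public-challenge convention); each
nodule counts once, extra candidates inside an already-hit nodule are
neither true nor false positives, and everything else is a false positive
of its scan. `froc()` sweeps all distinct scores and reads sensitivity off
the step curve at the seven standard operating points 0.125-8 FP/scan
(last value carried forward along the FP/scan axis). The scalar summary is
the arithmetic mean of the seven sensitivities - a bounded score in [0, 1]
consistent with how the headline "area under the FROC curve" is used - with
a trapezoidal variant over log2(FP/scan) reported alongside. Size strata
use the 5 mm / 15 mm cut points with both boundaries assigned to "middle"
("between 5 and 15 mm" read inclusively). `kfold_split()` provides the
seeded five-fold protocol. The FROC implementation is checked *exactly*
against a brute-force threshold-enumeration oracle on random fixtures.

## Numerical choices and degenerate inputs

* Connectivity is 26 in 3-D and 8 in-plane (permissive, so thin necks do
  not spuriously split a lung); background flood fills use 4/6.
* Otsu on a constant volume, an all-air volume, an empty mask for fusion
  testing, zero-diameter nodules, all-ignored losses and non-finite
  gradients all raise classed errors rather than propagating nonsense.
* A missing trachea signals `lungcad_trachea_not_found` and the pipeline
  continues without removal.
* MetaImage I/O writes MET_DOUBLE by default so round-trips are bit-exact;
  16-bit output is available for compactness.
* All randomness (phantom noise, dataset seeds, weight init, batching,
  dropout, k-fold) flows from explicit seeds; identical seeds give
  identical volumes, loss histories and final parameters.

## Reported problem sizes

The test and acceptance suites run, by design, at desk scale: phantoms of
64 x 96 x 120 voxels (the diameter-distribution check uses 200 phantoms at
56 x 80 x 112), 100 training patches of 40 x 40 x 26, FROC fixtures of up
to 50 candidates over up to 3 scans, and the reduced-depth 1/8-width
network (about 235k parameters). These sizes were chosen so that every
claim a desk machine can verify is verified exhaustively (exact oracles
wherever one exists) while the full 512-scale architecture is validated
symbolically through its shape trace.
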