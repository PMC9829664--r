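---
title: "Fracture-aware 3D femur reconstruction from biplanar radiographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fracture-aware 3D femur reconstruction from biplanar radiographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Preoperative planning for proximal femoral fractures benefits greatly from 3D
visualization of the bone fragments, but CT — the usual source of 3D shape —
is slower, costlier, and higher-dose than plain radiography. `bonerecon`
implements a pipeline that learns to reconstruct a voxel-based 3D proximal
femur shape, including fracture detail, from a pair of simulated Judet-view
radiographs taken at −45° and +45° about the patient's vertical axis (the
oblique pair avoids overlap with the contralateral leg). Two ideas make the
fracture itself learnable:

1. **An auxiliary fracture-gap class.** Voxel-wise reconstruction that only
   distinguishes bone from background tends to fuse nearby fragments — the
   fracture gap is a vanishing fraction of the volume, so the loss barely
   sees it. We synthesize a third voxel class that explicitly marks the
   gap between nearby fragments and train the network to reconstruct it
   together with the bone.
2. **Fractural augmentation.** Real fractured-femur volumes are scarce.
   Nondisplaced fracture training samples are manufactured from intact ones
   by cutting the bone mask with a randomly generated, randomly placed rough
   surface and replacing the gap's intensities with soft-tissue values, so
   the simulated radiographs show a plausible fracture line.

Everything runs on synthetic femur phantoms, so the full pipeline —
data synthesis, augmentation, projection, training, evaluation — is testable
on a desk machine with no clinical data.

# The auxiliary class

Given disjoint fragment masks $m_b^{(k)}$, $k = 1..n$, each fragment is
dilated with a discrete spherical structuring element $b_r$ (all integer
offsets with Euclidean norm ≤ r; r = 2 voxels by default). The auxiliary
mask is

$$m_f = \bigcup_{k \ne l} \left[ (m_b^{(k)} \oplus b_r) \cap (m_b^{(l)} \oplus b_r) \right] \;-\; \bigcup_k m_b^{(k)},$$

i.e. the voxels reachable by the dilations of at least two distinct
fragments, minus the bone itself. Consequences worth knowing:

* an intact bone (n = 1) has an empty auxiliary mask — there are no pairs;
* fragments separated by more than the two dilations can bridge (gap wider
  than about 2r voxels) contribute nothing;
* $m_f$ is disjoint from every fragment by construction, symmetric under
  fragment relabeling, and monotone in r.

The radius is in voxel units: morphology is grid-native, and the method is
used at whatever resolution the volumes have. Dilation clips at the grid
boundary — fragments near the border do not wrap. The test suite checks the
implementation against a literal set-arithmetic evaluation of the
definition on random multi-fragment masks.

# Fractural augmentation

**Rough surfaces.** Fracture surfaces of brittle materials are well
described as self-affine: their roughness power spectrum falls as a power
law $PSD(q) \propto q^{-2-2H}$ with Hurst exponent $H$. We synthesize
height fields spectrally: complex Gaussian Fourier amplitudes shaped by
$q^{-(1+H)}$ between two frequency cutoffs, inverse-transformed, and
rescaled to an exact RMS roughness σ. Defaults: $H = 0.8$ (typical of
brittle fracture), σ = 2 voxels on a 32-voxel bone (scaled proportionally
with grid size so the relative gap width is resolution-independent),
cutoffs 0.02–0.3 cycles/voxel. The suite verifies that the synthesized
fields recover both σ and the log–log spectral slope $-(2+2H)$.

**Voxelization.** The height sheet is voxelized as a slab of thickness t
(default 2 voxels): a voxel belongs to the surface mask G when it lies
within t/2 of the sheet vertically. Where the sheet jumps by more than a
voxel between neighbouring columns, the slab is extended to the local 3×3
height range; without this the cut can leak — fragments stay 26-connected
diagonally through a steep cut — and the draw is wasted. A flat sheet
reduces exactly to a plane of thickness t.

**Placement.** The surface is placed by a rigid transform drawn per AO/OTA
fracture location: translation uniform in the region's bounding box
(trochanteric 31A, femoral neck 31B, femoral head 31C, diaphyseal 32), and
a rotation tilting the surface normal from vertical — near-transverse for
shaft fractures (0–20°), oblique for the neck (30–70°), moderate (0–30°)
for trochanteric and head fractures. These angular ranges are package
configuration: the AO codes constrain location, not exact pose. The placed
mask is produced by inverse mapping with nearest-neighbour height lookup,
which preserves binarity and leaves no holes.

**Splitting and intensity.** The fracture mask is $m_f^* = m_b \cap T(G)$
and the fragment set is the connected-component relabeling of
$m_b - T(G)$. A draw that fails to produce at least two components, or
produces a sliver below 1% of the bone volume, is a *rejection* (a typed
result, not an error); the driver resamples the placement up to a bounded
retry budget and reports failure explicitly with the AO code and seed.
Accepted splits satisfy two exact set identities — the fragments plus the
gap reassemble the intact bone, and they are disjoint — which the tests
assert verbatim. Gap intensities are replaced by independent draws from
Uniform(63, 193) HU (mean 128 HU), the soft-tissue range consistent with
reported intensity drops at fracture sites; all other voxels are untouched
bit for bit. Fragments keep their anatomical pose, so augmentation
produces *nondisplaced* samples only — displaced fractures (fragments
moved from anatomical alignment) cannot be manufactured this way and are a
stated limitation.

# Phantoms and DRR simulation

The phantom is the minimal geometry exhibiting the anatomy the AO codes
reference: a vertical shaft capsule, an angled neck capsule (neck–shaft
angle default 128°, range 120–135° across cohorts), a head sphere, and two
trochanteric bumps, all overlapping into a single 26-connected component.
Bone intensities are N(700, 100) HU and the soft-tissue background
N(40, 20) HU, placing the augmentation's 63–193 HU replacement band between
them. Cohorts draw geometry uniformly from mild anatomical ranges with
per-sample derived seeds. Grid defaults are 64³ at 1 mm for demonstration
and 16³–32³ for tests; resolution is entirely configuration since the
method is scale-free in voxel units.

Radiographs are parallel-beam digitally reconstructed radiographs: the
volume is rotated about the vertical axis, Hounsfield values are mapped to
a nonnegative attenuation proxy max(HU + 1000, 0) so air contributes
nothing, and attenuation is integrated along rays perpendicular to the
detector, then min–max normalized per image. Parallel geometry (rather
than cone-beam) keeps the rotation–projection commutation exact up to
interpolation, which the tests exploit as an oracle; source geometry,
image size and intensity windowing of clinical systems are not modelled,
and neither are scatter, beam hardening, or detector noise. The Judet pair
is (−45°, +45°); an optional rotational error applied to the second view
supports the misalignment sensitivity protocol (the fusion module assumes
exactly orthogonal views, so reconstruction degrades as the error grows).

# The reconstruction network

Each view passes through a 2D encoder: an initial convolution, then one
dense block per abstract level (default L levels with four
IN → ReLU → 3×3 conv layers, each concatenating its output onto its
input), with 2×2 max-pooling between levels. The decoder walks back up:
at each level a 3×3 convolution (+ IN + ReLU) forces the channel count to
(level extent × c3d) so that reshaping channels into a depth axis yields a
*cubical* 3D feature block; decoded features are upsampled with 2×2
transposed convolutions and concatenated with the same-scale encoder
features on the way. The reshape convention (channel index = depth × c3d +
channel) is fixed by a tracer test.

Fusion combines the two views' 3D pyramids. View 2 is physically rotated
90° about the vertical axis relative to view 1, so its features are
permuted by a quarter-turn about z before concatenation (the permutation
is a 4-cycle; its axis convention is pinned by a single-voxel tracer
test). At the deepest level only the two views are fused; every shallower
level additionally concatenates the 2×-upsampled previous fusion (3D
transposed convolution + IN + ReLU) and applies a set of 3×3×3
convolutions (+ IN + ReLU; two by default). A final 1×1×1 convolution
produces per-voxel class scores and softmax yields probabilities; argmax
with ties to the lower class index gives the reconstructed label volume.

Channel widths, growth rate, and the 3D channel count are configuration
with small defaults — the architecture is intentionally narrow enough to
train on one CPU at phantom scale. Weights use fan-in-scaled normal
initialization from a fixed seed; the final classification bias is
initialized to log class priors (0.94/0.05/0.01), the standard practice
for focal-loss training of rare classes — without it the softmax starts
uniform, early optimization is spent suppressing the auxiliary class
everywhere, and the rare-class probability then recovers only very
slowly. Inside dense layers the order is
IN → ReLU → conv (normalization first), and the decoder's lateral encoder
concatenation sits after upsampling, before the level's convolution.

The network, its tape-based reverse-mode autograd, and Adam are
implemented in the package (R with C++ im2col/col2im kernels); gradients
of every layer are verified against finite differences, and an
architecture shape oracle checks every intermediate tensor against the
closed-form kernel/stride/pool arithmetic for L ∈ {3, 4, 5} and input
extents {16, 32, 64}.

# Loss

Training minimizes a weighted voxel-wise focal loss. Per class i
(one-vs-rest on the softmax channel, following the per-class sum in the
loss definition):

$$fl_i = \mathrm{mean}_v\left[-y_{iv}(1-p_{iv})^{\gamma}\log p_{iv} - (1-y_{iv})\,p_{iv}^{\gamma}\log(1-p_{iv})\right],
\qquad FL = \sum_i w_i\, fl_i.$$

The focusing exponent γ = 2 suppresses easy voxels; the class weights
w = (0.15, 0.25, 0.6) for (background, bone, auxiliary) counteract the
extreme imbalance (background ≫ bone ≫ auxiliary, roughly 10⁴ : 10² : 1 in
fractured volumes). Two-class runs renormalize the first two weights.
We use the conventional nonnegative sign (−(1−p)^γ log p) so minimization
is well-posed, reduce per class by the mean over voxels so the weights are
scale-free in volume size, and clamp probabilities at ε = 10⁻⁷.

# Training protocol and variants

Three variants mirror the ablation of interest:

* **base** — 2 output classes, no auxiliary, no augmentation;
* **aux** — 3 classes, trained with the auxiliary fracture-gap class;
* **fracaug** — the aux network additionally trained with fractural
  augmentation of the intact training samples.

Optimization is full-batch Adam (default learning rate 10⁻⁴,
β₁ = 0.9, β₂ = 0.99; demo runs use a larger rate since they take only
tens of steps), with early stopping on a held-out validation sample
(patience 10 validation rounds by default — the policy stops training when
validation loss stops improving; the patience value is package
configuration). Cross-validation is stratified per sample type so each
fold preserves the intact/nondisplaced mix. Augmented samples are
pre-generated per training fold with fold-derived seeds rather than
re-drawn every epoch: at desk scale the fold's sample count is small and
pre-generation keeps runs exactly reproducible from the experiment seed;
fresh-per-epoch drawing would maximize diversity at full scale and can be
emulated by raising `augment_per_intact`.

# Evaluation

Reconstruction quality uses two metrics, both computed on the bone class
after merging the auxiliary class into the background on both prediction
and ground truth (the fracture gap is not bone; it is excluded from
overlap scoring by convention):

* **IoU** — $|A \cap B| / |A \cup B|$; defined as 1 when both masks are
  empty;
* **ASSD** — surfaces are the mask voxels with a face neighbour outside
  (grid boundary counts as outside), as voxel-center coordinates in mm;
  the metric is the grand mean of nearest-neighbour distances in both
  directions, weighted by surface sizes:
  $(\sum_{a \in S_A} d(a, S_B) + \sum_{b \in S_B} d(b, S_A)) / (|S_A| + |S_B|)$.
  ASSD is an error for empty masks — deliberately explicit, since the
  degenerate case has no sensible value.

Cohort results aggregate mean ± SD per sample type (intact,
nondisplaced, displaced) and overall; variants are compared with a paired
two-sided t-test across fold means, with degenerate inputs (zero-variance
differences) flagged rather than crashing.

# What the phantoms do and do not show

The phantom cohort emulates the *statistical role* of a clinical CT
cohort — shape variation, intact/fractured strata, extreme class
imbalance, the augmentation's input contract — so that every algorithmic
property (set identities, spectra, metric correctness, architecture
shapes, trainability, the direction of the auxiliary class's benefit) is
testable end-to-end. It does not establish clinical accuracy: phantoms
lack cortical/trabecular substructure, the pelvis and contralateral
anatomy, realistic DRR physics, and displaced fractures. Numbers obtained
at 16³–32³ on phantoms are not comparable to values measured on hospital
CT data at clinical resolution; only the qualitative behaviours (e.g.
3-class ≥ 2-class on fractured samples, degradation with inter-view
rotational error) are expected to transfer.

# Numerical choices and problem sizes

* Connected components use 26-connectivity (oblique fracture surfaces
  produce diagonal adjacencies; 6-connectivity would over-split);
  fragment labels are ordered by size, ties by smallest linear index, so
  labels are deterministic.
* All randomness funnels through explicitly passed seeds; derived seeds
  stay below 2³¹.
* Test problem sizes were chosen to exercise each property at the
  smallest scale at which it is meaningful: morphology and metric oracles
  on ≤16³ grids, spectral checks at 256², trainability at L = 4 /
  extent 32 (about 10⁵ weights), the variant comparison at L = 3 /
  extent 16 on a 12-phantom cohort.
* Degenerate inputs have explicit contracts: empty masks error in
  connected components and ASSD, both-empty IoU is 1, non-splitting
  augmentation draws are typed rejections, zero-variance t-tests are
  flagged, non-finite training loss aborts with a diagnostic.

# Known limitations

* Augmentation cannot create displaced fractures or comminuted fractures
  from one surface; the displaced stratum must come from data.
* The DRR model is parallel-beam without scatter or noise; matching real
  radiograph appearance is out of scope.
* The network reconstructs shape only, not Hounsfield intensity.
* The fusion permutation assumes exactly orthogonal views; rotational
  error between views degrades reconstruction (the package includes the
  protocol to quantify this).
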