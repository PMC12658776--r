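---
title: "Seed-based dynamic connectivity states and 3D-CNN severity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based dynamic connectivity states and 3D-CNN severity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`strokedfc` implements an end-to-end analysis of resting-state fMRI in
chronic stroke built around the ipsilesional primary motor cortex (M1).
The scientific chain is:

1. **Preprocessing** of 4D BOLD runs: discarding equilibration volumes,
   flipping right-lesion subjects across the midsagittal plane so the
   lesioned hemisphere is always on the same side, regressing out a
   24-parameter motion model plus mean white-matter and CSF signals and a
   linear trend, Gaussian smoothing, detrending, and 0.01–0.1 Hz
   band-pass filtering.
2. **Sliding-window dynamic functional connectivity (dFC)**: Pearson
   correlation between the mean time series of a 6 mm sphere at MNI
   (−38, −22, 56) and every brain voxel outside the lesion, in 22-TR
   (44 s) windows advanced by 1 TR, Fisher-z transformed. A 230-volume
   run yields 209 connectivity maps per subject.
3. **Connectivity states**: L1 (cityblock) k-means over all subjects'
   windowed maps, initialized from exemplar windows (local maxima of the
   spatial connectivity variance over time), with the number of states
   chosen from subject participation rates rather than an elbow
   criterion.
4. **Severity classification**: a width-scalable VGG-style 3D
   convolutional network (thirteen 3×3×3 convolutions with pre-activation
   batch normalization, five 2×2×2 max-pool stages, a 4096–4096–2 fully
   connected head with 0.7 dropout) trained with Adam (ε = 0.001,
   learning rate 0.001 halved every 10 epochs, 32-sample batches,
   cross-entropy) under stratified 10-fold cross-validation to separate
   mild/moderate (UL-FMA > 20) from severe (UL-FMA ≤ 20) subjects.
5. **Statistics**: per-fold label-permutation tests of classification
   accuracy; voxelwise two-sample t-tests on per-subject state-mean maps
   adjusted for age, sex and illness duration, thresholded at |t| > 2
   with a 50-voxel cluster-extent minimum (uncorrected, and labelled as
   such); and the usual demographic comparisons (pooled-variance t from
   summary statistics, uncorrected Pearson χ², correlation with the
   t-transform p-value).

Because no patient data ship with the package, a **synthetic-cohort
generator** is a first-class module: every downstream stage is validated
against cohorts whose connectivity structure is known exactly.

# The synthetic cohort model

Each subject's BOLD signal is built from a band-limited (0.01–0.1 Hz)
Gaussian-process seed signal $s(t)$. A voxel $v$ in one of two designated
target regions follows $y_v(t) = \beta_v\,s(t) + \varepsilon_v(t)$ with
unit-variance white innovations, where $\beta_v$ is chosen so that the
model correlation equals the planted value: on the Fisher-z scale, a
state- and group-dependent target amplitude plus a subject-level random
effect (SD `subject_sd`, default 0.3) plus a subject-specific spatial
fingerprint (SD `signature_sd`, default 0.15) shared by all of that
subject's windows. Hidden connectivity states follow a discrete-time
Markov chain at volume resolution with a mean dwell time long relative to
the window length, so most windows are state-pure and clustering is
well-posed. On top of the signal sit the nuisances preprocessing is meant
to remove: AR(1) noise (coefficient 0.3) mixed with white noise, a
per-voxel linear drift, smoothed-random-walk motion traces that leak into
voxel time series, tissue-specific WM/CSF signals, and an initial
equilibration transient. Lesions are contiguous deep blobs planted in one
hemisphere whose voxels carry no seed-locked signal; lesion voxels are
excluded from all connectivity maps.

Two aspects deserve emphasis:

* **The subject fingerprint is the leakage channel.** With windows of one
  subject on both sides of a window-level cross-validation split, a
  classifier can recognize the subject rather than the group. The
  generator plants this structure deliberately so the package can
  *demonstrate* the gap between window-level and subject-level
  cross-validation rather than merely assert it.
* **Windowed estimation bias.** The band-limited seed signal is strongly
  autocorrelated, so a 22-sample window holds few effective degrees of
  freedom; windowed correlation estimates of a planted $z$ are biased
  slightly toward zero (about 0.03–0.05 at $z \approx 0.8$ in the
  noise-free setting). Tests of planted-effect recovery use tolerances
  that accommodate this known bias rather than asserting exact equality.

What the generator does **not** emulate: biophysical hemodynamics, EPI
distortion, realistic anatomy, spatially structured physiological noise,
or realistic lesion shapes. A test suite that passes on these cohorts
shows the estimators are correct and the pipeline is coherent; it does
not show that the classifier would reach comparable accuracy on real
patients.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_len_tr` | 22 | TR (2 s) | 44 s window, below the 0.5/f_lower = 50 s bound (reported by `window_length_check()`, not enforced) |
| `seed_radius_mm` | 6 | mm | sphere seed around the M1 coordinate; 0 gives the single nearest voxel |
| `pr_threshold` | 0.5 | – | participation rate at which a state counts as population-level; a package choice, not an empirical constant |
| `rare_max` | 1 | subjects | a state visited by at most this many subjects counts as idiosyncratic |
| `dropout` | 0.7 | – | on the fully connected layers only, training only |
| `adam_epsilon` | 0.001 | – | the optimizer's ε, taken at face value |
| `t_threshold`, `min_cluster_voxels` | 2.0, 50 | –, voxels | voxelwise and cluster-extent thresholds, uncorrected |
| `n_perm` | 1000 | – | label shuffles per fold; the add-one estimator bounds p below by 1/1001 |

# Design decisions in the open

**Choosing the number of states.** Elbow-type criteria do not guarantee
that every subject is represented in the retained states, so k is chosen
from subject participation rates (PR). The rule implemented here: a
k-solution is *admissible* when each of its states is either
population-level (PR ≥ `pr_threshold`) or idiosyncratic (at most
`rare_max` subjects); among admissible solutions with at least two
retained states and every subject contributing to a retained state, the
largest k wins. The bimodality requirement is the load-bearing part: a
state with middling participation (say a third of subjects) signals that
a population state has been over-split, whereas a near-singleton state is
a genuine idiosyncrasy that should be isolated and then excluded from
group tests. A simpler rule that only requires two retained states fails
in practice, because splitting one population state into two halves that
both retain high participation stays admissible at every k. On synthetic
cohorts with two common states, one near-singleton state and realistic
subject fingerprints, the rule selects k = 3 and retains two states, with
the rare state at PR = 1/n.

**The rectified output head.** The published layer table ends with a
2-unit fully connected layer followed by a ReLU and then softmax. That
head admits a catastrophic failure mode: if training drives both logits
negative for every input — which gradient descent readily does while the
convolutional trunk is still random, since clamping both logits at zero
yields the locally attractive loss log 2 — every gradient vanishes
permanently and the network never recovers. This is reproducible on
every configuration we tried, which is strong evidence the published
model cannot have trained with such a head active. `output_relu = FALSE`
is therefore the default; the flag reproduces the printed variant
exactly for anyone who wants to watch it collapse.

**Other fixed choices.** Convolutions pad to preserve spatial size; the
final max-pool keeps its printed stride of 1; pool stages whose input is
thinner than 4 voxels in any axis are demoted to stride 1 so small grids
remain usable (logged on the model object); motion derivatives are
backward differences with a zero first row and the quadratic terms are
the squares of all twelve columns; the band-pass filter is an order-4
Butterworth applied forward and backward (zero phase) with odd-mirror
padding, because an unpadded forward–backward pass fails the in-band
amplitude contract near the series edges; WM/CSF means are taken over
one-voxel-eroded masks; the positive class is the severe (SSP) group;
constant voxel series correlate as 0 rather than NaN so maps stay finite
for the network; Fisher z is clipped at |r| = 1 − 10⁻⁷, bounding |z| by
about 8.4.

# Problem sizes

The canonical configuration — 61×73×61 voxels at 3 mm, 240-volume runs,
the full-width network — is fully supported through `run_config(preset =
"canonical")` but is a GPU-scale computation. Everything the package
demonstrates runs at the desk scale: a 20×24×20 grid at 9 mm (same mm
origin, so the M1 seed and target coordinates are meaningful), 20
subjects, runs long enough for the windows in play, and the width-1/8
network.

The scaled classification experiment (`run_severity_experiment()`) uses
10 windows per subject and 36 epochs per fold, about 180 optimizer steps
with 32-sample batches. Three sizing facts drive this. First, steps, not
epochs, are the relevant axis: more windows per subject at
proportionally fewer epochs changes nothing, so the full-scale protocol
(hundreds of windows, tens of epochs, thousands of steps per fold) is
scaled by preserving step structure; the learning-rate half-period is
held at ~120 steps whatever the window count, so the rate stays at its
initial value through the plateau-escape window of the slowest fold
initializations and then halves, stabilizing the final-epoch weights
that the protocol reports.
Second, inputs are z-scored voxelwise against each fold's training set
(one of the two standard input normalizations of volumetric image-input
layers); without it, some fold initializations spend hundreds of steps
on a plateau before the loss moves. Third, across fold initializations the held-out accuracy settles at
100% by roughly 110–130 steps (most folds far earlier) — window-level
splitting with planted subject fingerprints is, by design, an easy
problem once the network has learned anything at all — so 180 steps
covers the slowest initialization we measured. Even a fully trained fold
occasionally misclassifies one stubborn held-out window, and at 20 test
windows per fold a single error costs half a point of mean balanced
accuracy — a quantization the full-scale protocol, with seventy times
more windows per fold, does not suffer. The
scaled experiment skips the per-epoch validation pass (the capability
remains, and the pipeline's default keeps it on).
The subject-level companion run uses five folds of four held-out
subjects each, the natural fold size at twenty subjects; its balanced
accuracy hovers at chance at every training length we measured, so the
test suite runs it short and the full-length comparison lives in
`analysis/04_classify.R`.

Numerical notes: the network trains in single precision (the
convolutional engine is im2col-free: activations live in a halo-padded
transposed layout where every convolution tap is one strided BLAS sgemm,
chunked so the working set stays in cache); training is deterministic
given the seed and a fixed thread count; all randomness fans out from
one global seed through a fixed per-stage counter.

# Known limitations

* Synthetic cohorts only; no claim about real-data accuracy transfers.
* The participation-rate thresholds are package choices; the
  source analyses that motivate the PR rule report only qualitative
  criteria.
* Cluster tables report peak coordinates, not atlas labels.
* The voxelwise tests are uncorrected by design, and every report says
  so.
* Slice-timing correction, motion realignment and nonlinear spatial
  normalization are out of scope: synthetic runs are generated already
  aligned on a common grid.
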