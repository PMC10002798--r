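---
title: "Transmission-less attenuation compensation for myocardial perfusion SPECT: models, parameters, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission-less attenuation compensation for myocardial perfusion SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(slacspect)
```

## The problem

Photon attenuation is the dominant image-degrading factor in myocardial
perfusion SPECT (MPS). Compensating it during reconstruction requires a map
of linear attenuation coefficients (a "mu map", cm^-1 at the 140 keV
emission energy of ^99m^Tc), conventionally derived from a co-registered CT
scan. Many SPECT systems have no CT, and a CT adds dose and misregistration
risk. The SLAC approach (scatter-window + learned segmentation attenuation
compensation) estimates the mu map from emission data alone: Compton-scattered
photons recorded in a secondary energy window (114-126 keV) carry information
about where attenuating tissue lies, because the probability of scatter at a
location grows with the attenuation there. A reconstruction of the
scatter-window projections therefore shows body/lung/background contrast; a
segmentation network carves it into six tissue classes (skin and subcutaneous
adipose, muscles and organs, lungs, bones, patient table, background), and
predefined per-class attenuation coefficients — class means estimated from a
training set — turn the segmentation into a usable mu map.

`slacspect` implements this pipeline end to end on synthetic digital thorax
phantoms, together with the task-based evaluation used to judge it: insertion
of parametric perfusion defects, reconstruction of three arms (SLAC, CT-based
compensation, no compensation) from identical projection data, a channelized
Hotelling observer (CHO) reading 32x32 short-axis regions of interest, ROC
analysis with empirical and binormal fits, and RMSE/SSIM fidelity metrics.

## The digital phantom cohort

`generatePhantom(seed)` builds a 64x64x64 thorax at 0.68 cm voxels: an
elliptic body cylinder with a skin/adipose rind, two lungs, spine and
sternum, a liver, a half-ellipsoidal left-ventricular (LV) myocardial shell
with a blood-pool cavity, and a flat patient table. Anatomy is jittered per
seed, as are the per-class attenuation coefficients (nominal values:
background 0, lungs 0.04, skin/adipose 0.14, muscles/organs 0.154,
bones 0.25, table 0.20 cm^-1; multiplicative jitter of +/-5% per class per
phantom so that class-mean estimation from training data is a nontrivial
estimation problem). Myocardial uptake defaults to six times the
soft-tissue background, the typical stress-MPS regime.

The population variability deserves emphasis, because the comparison of
compensated and uncompensated arms hinges on it. Uncompensated MPS fails
clinically not only through lower counts but through *patient-varying*
attenuation artifacts — the diaphragmatic shadow over the inferior wall
changes with diaphragm level, body habitus and sub-diaphragmatic uptake,
so the artifact cannot be learned away as a fixed background. The cohort
therefore varies, per seed: body semi-axes and organ scales by +/-12%
(a realistic habitus spread), the diaphragm level by +/-2.5 cm (lungs and
liver shift together along the scanner axis, the normal range of
diaphragm position), sub-diaphragmatic (liver) uptake by +/-40% around
2.2x soft tissue (stress-study variability), and heart position and
long-axis orientation within typical anatomical ranges. A cohort with
materially less variability than this makes the no-compensation arm look
spuriously good to a population-trained linear observer, because the
attenuation artifact becomes a constant background; with the ranges above
the experiment exhibits the confound the clinical task contains.

What the generator emulates: the gross attenuation geometry of a thorax, the
organ-level uptake pattern of a ^99m^Tc perfusion study, count-limited
two-window projection data, and patient-to-patient anatomical variation.
What it does not emulate: fine anatomical texture, respiratory or cardiac
motion, septal penetration, or inter-scanner effects. Tests passing on this
cohort show the pipeline's machinery is correct and the method's premises
hold under controlled conditions; they do not by themselves establish
clinical performance.

Perfusion defects follow a 27-entry catalog: circumferential extents of 30,
60 and 90 degrees, severities of 10%, 25% and 50% activity reduction, at the
anterior, inferior and lateral LV walls. `insertDefect()` multiplies the
activity of shell voxels whose circumferential angle (measured in the
short-axis plane about the LV long axis; lateral 0, anterior 90,
inferior 270 degrees) falls within the sector by `1 - severity`. Sector
edges are sharp — the catalog defines no feathering — and the defect spans
the shell from apex to base, since only the circumferential extent is
parameterized.

## Forward model

`forwardProject()` is a rotation-based parallel-beam projector: per view the
volume is rotated about the scanner axis (bilinear interpolation), weighted
by the survival probability `exp(-integral of mu)` from each voxel to the
detector, blurred in-plane by a depth-dependent Gaussian
(`sigma = cdrSigma0 + cdrSlope * depth`, defaults 0.35 cm + 0.018/cm,
a typical low-energy high-resolution collimator response), and summed along
the detector normal. `backProject()` is the exact matrix transpose — every
factor of the composition is either self-adjoint (symmetric blur with zero
padding, diagonal attenuation weighting) or implemented as an explicit
scatter with the gather's weights. Exact adjointness is what makes the
multiplicative OSEM updates correct, and it is asserted in the tests to
1e-5 on random volumes. The default acquisition covers 180 degrees; view
counts are configurable (the type default is 60 views; the desk-scale
experiment uses 32).

The scatter window is modeled phenomenologically in the effective-scatter-
source spirit: the scatter source is a photon-flux surrogate — the activity
smoothed with a 6 cm FWHM Gaussian plus a diffuse component of 1.5 times its
in-support mean, standing in for the pervasive multiply-scattered pool —
modulated voxelwise by `mu / mu_water`, projected with broad-beam
attenuation `0.4 * mu` (scattered photons experience substantially less than
the narrow-beam coefficient because of buildup), and scaled so total scatter
counts are 30% of total primary counts. The diffuse fraction and buildup
factor were fixed once so that the model satisfies the premise it exists to
express: a no-compensation reconstruction of the scatter window correlates
with the true mu map over the body (Pearson 0.53-0.61 across seeds, checked
in the acceptance suite at a 0.5 gate). A purely local, narrow-beam scatter
source fails that premise — its reconstruction is dominated by the hot
cardiac and hepatic blobs and by depth suppression — which is worth knowing
when reading the rest of the pipeline: the scatter channel here is a
physically-motivated caricature, not transport.

Counting noise is Poisson, applied after scaling each study to a total of
4e6 photopeak counts (low-dose clinical order of magnitude); the scatter
window is scaled by the same factor, preserving the scatter fraction.

## Reconstruction and post-processing

`osem()` implements ordered-subsets expectation maximization with the
matched projector pair, bit-reversed subset ordering, and a sensitivity
exclusion mask instead of division by zero. With one subset it is MLEM, and
its Poisson log-likelihood is non-decreasing on noiseless data (tested over
50 iterations). Output is nonnegative by construction.

Post-processing follows the clinical protocol: a 3-D radially symmetric
Butterworth low-pass filter of order 5 with 0.44 cm^-1 cutoff (DC gain
exactly 1, half-power exactly at the cutoff), rigid reorientation of the
volume into short-axis slices about the LV long axis (trilinear resampling;
the rotation is the identity when the axis is already the slice normal),
and extraction of a 32x32 region of interest from the short-axis slice
containing the defect centroid, with the centroid at pixel (16, 16)
(0-based). The centroid is taken from phantom ground truth, which the
simulation knows by construction.

Iteration counts are configurable; the package defaults (6 subsets x 10
iterations photopeak, 4 x 5 scatter window) reflect typical MPS practice.
The desk-scale experiment configuration uses 32 views with 8 x 2 (photopeak)
and 4 x 5 (scatter) so that a complete three-arm cohort study runs in
minutes on a single CPU; these are deliberate problem-size choices for a
desk-scale reproduction, stated here once rather than hidden in code.

## Attenuation-map machinery

* `bilinearHuToMu()` converts Hounsfield units piecewise-linearly with the
  breakpoint at 0 HU: mu(-1000) = 0, mu(0) = mu_water = 0.1537 cm^-1 at
  140 keV, and a bone branch calibrated so 1000 HU maps to 0.25 cm^-1.
  `simulatePseudoCT()` is its exact inverse plus optional Gaussian HU noise,
  providing the synthetic CT input.
* `mrfSegment()` segments a mu map into the six classes with a Potts-model
  Markov random field solved by iterated conditional modes: energy =
  Gaussian intensity misfit `(I - m_c)^2 / (2 sigma^2)` plus
  `beta = 0.5` per disagreeing 6-neighbor, checkerboard update schedule
  (guaranteeing a non-increasing energy, which the tests assert), class
  means re-estimated per sweep, k-means initialization with centers at the
  nominal tissue coefficients. Initializing at nominal values matters:
  size-agnostic k-means on a thorax map tends to split the dominant air
  class and merge bone with the table. The table class is resolved by a
  spatial prior — among non-air clusters it is the one lying lowest along
  the anterior-posterior axis.
* `fitTissueModel()` pools voxels per class over training (map,
  segmentation) pairs; the class means are the predefined coefficients that
  `assignMu()` later assigns to a predicted segmentation, producing a
  piecewise-constant map with at most six values.

## The segmentation network

`buildMcEUN()` constructs the multi-channel-input, multi-decoder
attention-gated U-Net: one shared encoder reads the stacked (scatter-window,
photopeak) no-compensation reconstructions, each normalized to unit mean
over its support; six decoders — one per tissue class — receive the encoder
skips through additive attention gates (gating signal from the coarser
level); voxelwise class probabilities come from a softmax across the six
decoder outputs. Kernel weights are Glorot-normal, every bias is initialized
to the constant 0.03, and dropout is applied at the bottleneck during
training. The layer algebra (im2col convolutions, max-pooling, nearest
upsampling, the gates, softmax cross-entropy) and its backward pass are
implemented directly in R and verified against finite differences to 1e-4;
Adam is the optimizer, the loss is class-weighted cross entropy with
inverse-frequency weights normalized to mean 1 (the weighting scheme is a
package default; only "optimized weights" is known of the original), and
five-fold cross-validation logs per-fold validation losses. Training is
bit-reproducible given (seed, data, config).

The network runs slice-by-slice along the scanner axis at desk scale
(depth 3, base 8 filters by default) so that training completes in minutes
on one CPU. The "multi-encoder" name admits two readings — one shared
multi-channel encoder or one encoder per channel; the shared-encoder reading
is implemented, matching the architecture's own description of "an encoder
with multi-channel input".

`classicalFallbackSegment()` is a deterministic, training-free segmenter of
the same inputs (body by thresholding the scatter reconstruction and
filling interior holes; table by a dim-slab-below-body rule; lungs as
flat-fielded low-intensity interior; spine by a posterior-central geometric
prior; skin as the body's outer shell). It exists so the complete
attenuation-compensation pipeline can be exercised, and its results
audited, without any training run; the default experiment uses it.

## Task-based evaluation

The observer study follows the standard model-observer methodology.
`makeChannelBank()` builds four rotationally symmetric square-profile octave
channels, (1/64, 1/32] through (1/8, 1/4] cycles/pixel, realized on the DFT
grid of the 32x32 ROI (bands are right-closed so the lowest band contains
the ROI's fundamental frequency). `choScores()` is the channelized Hotelling
observer with leave-one-out estimation: for each image, class means and the
pooled within-class channel covariance are estimated from all other images
(exact rank-one downdates), and the statistic is
`(m1 - m0)' S^-1 v`. A relative ridge of 1e-6 x trace(S)/4 guards
near-singular covariances; no internal observer noise is added.
`empiricalRocAuc()` computes the Mann-Whitney AUC (ties counted one half)
with a class-stratified percentile bootstrap CI; `binormalFit()` fits the
conventional two-parameter binormal ROC by maximum likelihood after
truth-run discretization of the continuous ratings (runs merged to at most
20 categories for a well-conditioned optimization), reporting
`AUC = Phi(a / sqrt(1 + b^2))` and falling back, flagged, to the empirical
AUC on non-convergence. `fidelityMetrics()` reports RMSE and mean SSIM
(Gaussian window, sigma 1.5 voxels; standard constants on the
max-normalized dynamic range) against the CT-compensated reference.

## The three-arm experiment

`runFullExperiment()` orchestrates the controlled comparison. Training
patients (default 10) provide CT-derived maps; the MRF segments them and the
tissue model is fitted. Test patients (default 12 defect-present + 12
defect-absent, disjoint from training by construction) are simulated once;
each patient's two-window noisy data yield the SLAC map (initial estimates,
segmentation backend, `assignMu`), and the pseudo-CT yields the CTAC map.
Defect-present records insert each in-scope catalog entry (default: the nine
inferior-wall types, the wall used in the evaluation design) and share one
noise realization across all three arms; defect-absent records reuse the
patient's single defect-free reconstruction, since records from the same
patient are identical. The arms differ in exactly one input: the attenuation
map (SLAC: segmentation-derived; CTAC: bilinear-converted pseudo-CT; NAC:
none). Observer statistics, ROC/AUC with CIs, and per-patient RMSE/SSIM
against the CTAC arm complete the report, which records every seed and is
regenerable bit-identically from its manifest.

## Numerical choices and degenerate inputs

* OSEM masks voxels with zero subset sensitivity rather than dividing by
  zero; all-zero projections are a fixed point.
* The Butterworth filter clamps (with a warning) cutoffs at or above the
  Nyquist frequency of the grid.
* ROI crops that exceed the volume are zero-padded with a warning.
* The binormal fit refuses degenerate inputs (a single class, constant
  ratings) and flags non-convergent or runaway fits (|a| > 10, extreme b)
  instead of reporting them.
* Bootstrap CIs are clamped to bracket the point estimate, keeping the
  result object's invariant under extreme resampling.
* Defect insertion with an empty sector-shell intersection is an error, not
  a silent no-op; severity 0 is the explicit degenerate control.

## Known limitations

The scatter channel is a calibrated phenomenological model, not photon
transport; absolute scatter-window image texture should not be
over-interpreted. The phantom lacks motion and fine texture, so observer
AUCs here are systematically higher than clinical values at matched counts.
The McEUN is desk-scale (tens of thousands of parameters, 2-D slice mode);
it demonstrates the architecture and training machinery, not a
clinical-capacity network. The binormal fit uses category merging rather
than the full truth-run parameterization of the original LABROC lineage;
for the well-separated statistics this pipeline produces, the practical
difference is below the reporting precision of the AUC.

One limitation deserves a pointed warning. In clinical cohorts,
uncompensated imaging loses detection performance because diaphragm-edge
and habitus-driven attenuation shadows mimic and mask defects at the
defect's own spatial scale, differently in every patient. A parametric
six-class phantom produces attenuation variability that is spatially much
smoother: in channel space it concentrates below the defect's frequency
band, where a population-trained linear observer can whiten it. The
consequence, which the acceptance suite reports rather than hides, is that
on this synthetic cohort the no-compensation arm can tie the CT-compensated
arm on AUC even while losing badly on fidelity (RMSE/SSIM), and the
transmission-less arm pays an AUC penalty proportional to its patient-
varying attenuation-map error. Detection-task conclusions about
compensation methods should therefore not be read off this phantom class;
the pipeline's value is that every stage of the methodology is exercised,
verified against oracles, and reproducible.
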