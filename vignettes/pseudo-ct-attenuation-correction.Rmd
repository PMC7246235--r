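---
title: "Independent PET attenuation correction with pseudo-CT synthesis: methods and design"
author: "petacgan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Independent PET attenuation correction with pseudo-CT synthesis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petacgan)
```

## The problem

PET quantification requires attenuation correction (AC): annihilation
photons are absorbed and scattered along each line of response, so without
correction deep tissue appears falsely cold. Clinically the correction
comes from a co-acquired CT, converted to a map of 511-keV linear
attenuation coefficients ($\mu$, cm$^{-1}$). When the CT is corrupted — or
was acquired in a different respiratory state than the PET — the
reconstructed PET inherits artifacts, the best known being the curvilinear
"banana" band along the diaphragm.

This package implements an *independent* AC route: a conditional
generative adversarial network is trained on paired slices of
non-attenuation-corrected PET (PET$_{NAC}$) and CT, and at test time
synthesises a pseudo-CT (CT$_{GAN}$) from PET$_{NAC}$ alone. The pseudo-CT
is converted to $\mu$ at 511 keV and used in ordinary iterative
reconstruction. Because the pseudo-CT is derived from the PET data itself,
it is spatially aligned with the PET by construction.

Everything here runs at desk scale on synthetic phantoms: clinical PET/CT
cohorts of this kind are not redistributable, so the package pairs the
method with a phantom generator and a small PET physics engine that make
every stage testable end-to-end.

## Synthetic phantoms

`generatePhantom()` rasterizes a 2D coronal whole-body-like slice (default
64 × 64 voxels at 4 mm) from ellipse parameters expressed as grid
fractions: body outline, two lungs, liver, spine, bladder, plus random
air-filled bowel pockets and optional focal lesions. Each voxel carries a
tissue class, a Hounsfield value (class mean + seeded Gaussian texture,
clipped to $[-1024, 3071]$) and an FDG-like activity concentration
(kBq/mL). With the emulated cohort's dose and weight distribution
(317.3 ± 8.6 MBq, 75.1 ± 16 kg) the default activities put soft tissue
near SUV 1, the bladder highest and the lungs lowest, with the liver
moderately above soft tissue.

Two cohort-level properties matter downstream:

* **Respiratory state.** A scalar in $[0, 1]$ displaces the lung's lower
  boundary caudally by up to `maxShiftVox` voxels (default 4) with the
  smooth lateral falloff of the lung ellipse; 0 is the expiration
  reference. `makeDataset()` can generate the CT of a pair at a different
  state than the activity map, emulating PET/CT respiratory mismatch.
* **Bowel gas.** One to three air ellipses of roughly 1–2 voxels radius
  are placed in the abdominal box under an independent seed, and relocated
  on the CT of mismatched pairs. The load is kept at a few percent of the
  abdominal area: gas is genuinely unpredictable from PET, and a
  generator trained against an abdomen that is a third air (an early
  configuration we tried) learns to hedge the whole abdomen toward air —
  an failure mode no clinical abdomen would induce.

The texture fields are drawn per class on the full grid from the phantom
seed, so deterministic re-deformation (e.g. `applyRespiratoryState()`)
changes only voxels whose label changes.

What the phantoms deliberately do not model: realistic organ shapes,
3D motion, scatter/metal/contrast artifacts, continuous HU histograms.
Passing tests on these phantoms therefore demonstrates that the *method*
(translation → $\mu$ map → reconstruction → quantification) is implemented
correctly and behaves as the clinical study describes, not that the
trained network would transfer to patients.

## PET physics engine

A 2D parallel-beam model, deliberately minimal (no TOF, scatter, randoms
or detector blur):

* **Projector.** Joseph-style length-weighted system matrix, assembled
  sparsely once per geometry and cached. Forward projection is
  $P x$, back projection $P^T s$, so the adjoint-consistency the EM
  update requires holds to machine precision by construction (and is still
  asserted in the tests). Path lengths are in cm; $\mu$ in cm$^{-1}$ — the
  classic 10× unit error is guarded by an endpoint test
  ($HU = -1000 \mapsto \mu = 0$, $0 \mapsto 0.096$,
  $1000 \mapsto 0.146$).
* **HU → $\mu$.** The standard bilinear curve with water
  $\mu_w = 0.096$ cm$^{-1}$ and a bone slope of $5\times10^{-5}$
  cm$^{-1}$/HU, both configurable; vendor curves are unpublished, and this
  stand-in is stated as such.
* **Acquisition.** Expected counts are
  `countScale` · (line integral) · (Beer–Lambert transmission); observed
  counts are seeded Poisson draws. The default `countScale = 20` yields
  roughly $2\times10^6$ expected counts per slice, a plausible
  whole-body-slice count level.
* **Reconstruction.** Multiplicative OSEM with the attenuation factors in
  the system model; 1 subset is plain MLEM, and an all-ones ACF produces
  the PET$_{NAC}$ image. Voxels with zero sensitivity are excluded. The
  desk defaults are 8 subsets × 4 iterations with a 2-mm Gaussian
  post-filter on a 64–128 grid; the clinical protocol the defaults are
  scaled from (400 × 400, 21 subsets, 2 iterations, 2-mm filter) ships as
  `clinicalReconParams()`. The post-filter renormalizes its truncated
  kernel at image borders, so constants are exactly invariant.

## The translator

**Generator.** Four cascaded U-Nets trained end-to-end. Cascade 1 maps the
normalized PET$_{NAC}$ slice to a pseudo-CT estimate; every later cascade
receives the PET$_{NAC}$ slice stacked with the previous estimate and
refines it. Each U-Net has 2 pooling levels and 8 base channels, one
convolution + instance-norm + leaky-ReLU block per level, and a tanh
output. Instance normalization is the load-bearing choice at this scale:
the PET$_{NAC}$ input occupies a tiny intensity range once the bladder
sets the normalization scale, and without per-channel standardisation the
short schedules below leave the body interior at a washed-out mean value.

**Discriminator.** A conditional classifier on the (CT candidate,
PET$_{NAC}$) channel-stacked pair: three stride-2 convolutions (8, 16, 32
channels, instance norm from the second on), a 1-channel convolution head,
global average, sigmoid. Its probability feeds the adversarial loss
$$L_{adv} = E[\log D(x_{CT}, y_{NAC})] + E[\log(1 - D(\hat x_{CT}, y_{NAC}))],$$
maximized by D and minimized by G through the second term (probabilities
clamped at $10^{-7}$).

**Feature losses.** The perceptual loss is a weighted feature-space MSE
and the style-content loss combines squared differences of
channel-normalized Gram matrices with a feature MSE. Both need a feature
extractor; the construction they cite admits either a pretrained network
or task features. We use the discriminator's own strided-layer activations
plus the raw image as "layer 0", which keeps the build hermetic (no
downloaded weights) and makes the content term contain a plain pixel MSE —
the stabilising signal on CPU-scale schedules. Default weights are
$\lambda_{adv} = 1$, $\lambda_{perc} = \lambda_{style} = \lambda_{content}
= 10$ (none are published; all are config).

**Normalization.** CT maps affinely $[-1024, 3071] \to [-1, 1]$.
PET$_{NAC}$ is scaled by its slice-wise 99.5th percentile and then
gamma-compressed with exponent 0.5. The compression matters: the bladder
is an order of magnitude hotter than soft tissue, and without it lung
(≈ 0.02 of the input range) and deep soft tissue (≈ 0.04) are nearly
indistinguishable to the first convolution. All parameters are stored on
the generator and inverted on output, which is clipped to valid HU.

**Optimisation.** Adam ($\beta_1 = 0.5$), alternating one discriminator
and one generator step per minibatch, with random left-right flips of each
training pair. `trainConfig()` defaults to the conventional
lr $2\times10^{-4}$ / batch 8 of this architecture family; the package's
own desk-scale experiments (`translationExperiment()`, 200 pairs × 20
epochs ≈ 1000 updates) use lr $10^{-3}$ (G), $5\times10^{-4}$ (D) and
batch 4 — at a thousand updates the conventional schedule has not left
the mean-image regime, and halving the batch doubles the update count at
constant cost. Runs are seeded and CPU-deterministic; training aborts on
non-finite losses.

Slices are translated strictly independently (`translateVolume()`), which
is asserted as a property — the clinical study attributes its
z-direction step artifacts to exactly this independence.

## The dual-reconstruction experiment

For each held-out case: simulate the acquisition with the *PET-state*
anatomy's true $\mu$; reconstruct PET$_{NAC}$ (ACF ≡ 1); translate it to
CT$_{GAN}$; copy the acquired CT's background into CT$_{GAN}$ outside the
body mask (largest connected component above −500 HU, holes filled — the
protocol transfers the scanner hardware's attenuation, and the threshold
and mask rule are our reading of an unspecified step); then reconstruct
the *same* counts twice, once with $\mu$(CT) and once with
$\mu$(CT$_{GAN}$), giving PET$_{AC}$ and PET$_{GAN}$.

`evaluateRun()` implements the quantitative protocol: body-weight SUV
($SUV = C \cdot w / D$, unit factors cancelling for kBq/mL, kg, MBq);
circular organ ROIs defined once and applied to both images (identical
voxel sets — the "copy" semantics); 50% isocontour lesion VOIs recomputed
per image (face-connected component of voxels ≥ half the local maximum);
the four deviation metrics (difference, absolute difference, percent,
absolute percent, with percent metrics flagged undefined at zero
reference); voxel-wise percent-difference maps with a validity floor
(default 1% of the reference maximum) instead of dividing by air;
Bland–Altman agreement with limits at mean ± 2 sample SD (n − 1); and
box-plot summaries (linear-interpolation quartiles, 1.5 IQR whiskers).

ROI sites are placed to stay inside their organ under the dataset's
anatomical jitter, i.e. organ-central placement as a physician would:
lung-boundary and bowel regions are exactly where the clinical study
reports its largest deviations, and a "soft-tissue" ROI straddling the
lung border measures partial-volume geometry, not translation fidelity.
The phantom has no cardiac structure, so the blood-pool analog is a deep
pelvic soft-tissue site. Spine ROIs are narrower than the spine column.

The headline experiment (`translationExperiment()`) trains on a cohort
with 15% respiratory-mismatched CTs (mismatch is part of realistic
training data) and evaluates translation fidelity on respiratory-matched
held-out cases. Mismatch at test time is analysed separately as the
banana-artifact scenario: there, the reconstruction using the mismatched
CT is compared against the ground-truth-aligned reconstruction within a
diaphragm band (`diaphragmBandMask()`), against a PET-state-aligned
pseudo-CT that differs from truth only in bowel layout. With PET caught
at inspiration and the CT in expiration, the CT-based $\mu$ map has soft
tissue where the PET-state anatomy has lung, and the mismatched
reconstruction shows the positive (overestimation) band along the
diaphragm; the aligned pseudo-CT suppresses it.

## Numerical choices and degenerate inputs

* Log-loss clamp $\varepsilon = 10^{-7}$; instance-norm
  $\varepsilon = 10^{-5}$.
* EM ratio at zero expected counts is set to 0 (consistent with Poisson
  likelihood); zero-sensitivity voxels stay 0 and are excluded.
* HU below −1024 clamp with a warning; $\mu$ is floored at 0.
* Degenerate circular ROIs (radius below half a voxel) fall back to the
  single containing voxel.
* `boxStats()` drops non-finite values; `deviationMetrics()` flags rather
  than propagates division by zero.
* Projector oracle tests use supersampled (fractional-coverage) disks
  (`diskPhantom()`), the standard way to compare a discrete projector
  against continuous chord integrals.

## Problem sizes

The test suite and the acceptance script run the projector oracles at
128 × 128 with 96 angles, MLEM fidelity at 64 × 64 with 50 iterations,
and the end-to-end experiment at 200 training + 10 held-out 64 × 64
slices for 20 epochs — the sizes at which the package's own quantitative
gates are calibrated and which a single CPU handles comfortably.

## Known limitations

* 2D slices only; the z-direction step artifact of slice-wise translation
  is asserted as slice independence, not rendered visually.
* The phantom's discrete tissue classes make translation easier than
  continuous clinical HU distributions; headline deviations here are not
  comparable in difficulty to the clinical study's numbers.
* No scatter, randoms, TOF or detector blur; vendor $\mu$ curves are
  approximated by the bilinear stand-in.
* The discriminator-feature perceptual loss drifts as D trains; at much
  longer schedules a frozen pretrained extractor may behave differently.
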