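---
title: "Measuring diffusion and perfusion abnormalities in MS: models and methods"
author: "dppmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diffusion and perfusion abnormalities in MS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppmri)
```

# What the pipeline measures

Multiple sclerosis produces focal white-matter lesions whose evolutionary
stage matters clinically: lesions that enhance after gadolinium are acute
(active blood–brain-barrier breakdown), while chronically T1-hypointense,
non-enhancing lesions ("black holes") mark irreversible tissue loss.
`dppmri` implements a semi-automated measuring system that

1. ingests a per-patient acquisition set (FLAIR, non-enhanced T1,
   Gd-enhanced T1, DWI b0 plus three orthogonal b=1000 s/mm²
   acquisitions, a 4D DSC bolus-tracking series),
2. segments FLAIR-hyperintense lesions semi-automatically and classifies
   each into one of four evolution classes from its T1/Gd-T1 intensities,
3. computes quantitative maps — apparent diffusion coefficient (ADC) and
   relative cerebral blood flow / volume / mean transit time (CBF, CBV,
   MTT) — and
4. reports per-region statistics (lesions by class and individually,
   normal-appearing grey and white matter, deep grey structures) as a
   CSV with a full provenance log.

Everything is testable without patient data through a built-in digital
phantom with known ground truth (`generate_phantom()`), and
`run_phantom_pipeline()` exercises the complete path end to end.

# Lesion segmentation and classification

Lesions are grown from operator-supplied seed voxels on FLAIR by a local
threshold rule: the region is the 26-connected component containing the
seed among voxels at or above `local_factor` (default 0.5) times the peak
intensity of the seed's 3×3×3 neighbourhood. The local-peak reference
makes the rule robust to the global intensity scale; the exact fraction a
commercial tool applies is not published, so the fraction is exposed as a
parameter.

A reference region of normal-appearing white matter (NAWM) is outlined by
the operator. For each T1-weighted modality independently, the classifier
derives two thresholds from the NAWM mean intensity $\bar I$ and sample
standard deviation $s$ with a configurable multiplier factor $M_f$
(default 2):

$$\mathrm{Thre}_{High} = \bar I + M_f\, s, \qquad
  \mathrm{Thre}_{Low} = \bar I - M_f\, s.$$

A lesion's summary intensity (mean by default, median optionally) is
compared with these thresholds: *enhancing* means its Gd-T1 summary
exceeds the Gd-T1 high threshold; *T1-hypointense* means its T1 summary
falls below the T1 low threshold. The four classes are C1
(enhancing/isointense), C2 (enhancing/hypointense), C3
(non-enhancing/isointense) and C4 (non-enhancing/hypointense — black
holes); C1/C2 are flagged acute, C3/C4 chronic. Comparisons are strict,
so a value exactly on a threshold counts as isointense/non-enhancing; a
lesion *above* the T1 high threshold has no class in this scheme and is
mapped to isointense with a `t1_hyperintense` warning flag. Because the
thresholds are affine in the NAWM statistics, classification is invariant
to any global intensity rescaling $aI+b$ ($a>0$) — a property the test
suite asserts.

The classified set round-trips through a human-editable text file
(`write_roiset()` / `read_roiset()`), which is the manual-revision
checkpoint: an operator can flip class codes in the file and the pipeline
resumes from the revised set.

# Diffusion

With two b-values the mono-exponential Stejskal–Tanner model gives, per
axis,

$$\mathrm{ADC} = \frac{1}{b}\,\ln\frac{S_0}{S_b} \quad [\mathrm{mm^2/s}],$$

and the reported map is the voxelwise arithmetic mean of the three axis
maps (computed after the per-axis ADC, not as a geometric mean of the
signals before it). Voxels where $S_b > S_0$ would give a negative ADC;
they are clamped to 0, counted, and excluded from downstream region
statistics via a validity mask — masks and CSVs stay simple and no NaNs
propagate. Units are mm²/s throughout; display layers may prefer
×10⁻³ mm²/s.

# Perfusion

DSC-MRI tracks a gadolinium bolus through T2\*-weighted signal drop.
The chain is:

* **Arrival detection.** The per-volume mean intensity over the brain
  mask is scanned with a running cumulative-mean baseline; arrival is the
  first volume whose absolute deviation from the baseline exceeds
  `fraction` (default 0.1) of the curve's max–min range. A range
  fraction, not an absolute level, keeps the detector independent of
  scanner scaling, and the absolute deviation makes it agnostic to
  drop- versus rise-type contrast. The cumulative (never reset) baseline
  was chosen for maximal noise averaging.
* **Concentration.** $C(t) = -\ln(S(t)/S_0)/T_E$ with $S_0$ the
  per-voxel mean over baseline volumes, discarding `skip` (default 1)
  initial non-steady-state volumes.
* **AIF selection.** Arterial voxels are ranked by a composite of high
  peak concentration, early time-to-peak and narrow full width at half
  maximum (rank-normalized and summed), after a physiological gate
  (peak at or after arrival, peak at least 30 % of the global maximum).
  The AIF is the mean curve of the top `n_voxels` (default 10)
  candidates; the chosen voxels are written to JSON for visual
  verification, and a user-supplied ROI bypasses selection entirely.
  The exact scoring a commercial tool uses is unpublished; this scoring
  is the package's own documented stand-in.
* **Deconvolution.** With $A$ the lower-triangular Toeplitz matrix of the
  AIF scaled by TR ($A_{ij} = TR \cdot \mathrm{AIF}_{i-j}$, $j \le i$),
  the tissue curve satisfies $C = A k$ and $k$ (the CBF-scaled residue
  function) is recovered by truncated SVD, zeroing singular values below
  `svd_threshold` (default 0.2) of the largest. Numerically-zero singular
  values are always dropped: a bolus AIF with a pre-arrival baseline of
  zeros makes $A$ rank-deficient by construction and the pseudoinverse is
  intended.
* **Maps.** CBF $= \max_t k(t)$; CBV $= \int C\,dt / \int \mathrm{AIF}\,dt$
  (trapezoidal); MTT $= $ CBV/CBF (central volume theorem) where CBF is
  positive. All maps are relative — no hematocrit or density constants.

## Discretization: a known, quantified bias

The phantom's DSC forward model uses an exponential residue
$R(t) = e^{-t/\mathrm{MTT}}$ — chosen so MTT is an exact closed-form time
constant — discretized at TR by the same rectangle-rule Toeplitz operator
the deconvolution inverts. That consistency makes the deconvolution an
exact oracle (impulse and exponential residues invert to machine
precision at zero truncation, and CBF recovers to < 1 % at threshold
0.05), but it places a quadrature bias on the integral ratio: the
recovered CBV equals

$$\mathrm{CBF}\cdot TR \sum_k e^{-k\,TR/\mathrm{MTT}}
 = \mathrm{CBV}_{true}\,\frac{TR/\mathrm{MTT}}{1-e^{-TR/\mathrm{MTT}}}
 \approx 1.13\,\mathrm{CBV}_{true}$$

at TR = 1 s, MTT = 4 s — a left-endpoint excess of about
$TR\,R(0)/2$. The alternative discretizations were measured: sampling
the residue at interval midpoints or generating the curve from the
continuous convolution moves CBV to within 0.5 % but multiplies the
recovered residue peak — and hence CBF — by the same ≈ 0.88 factor (or
worse, −25 % for the fully continuous curve under a rectangle-consistent
inverse). The trade-off is structural, not a coding choice: one of
(CBF, CBV) inherits the quadrature factor. The package keeps the
deconvolution-consistent scheme, reports CBF near-exactly, and documents
the +13 % CBV (and MTT) recovery bias; the corresponding recovery test is
asserted at the nominal 5 % tolerance and therefore fails by design,
rather than being silently widened. At clinical sampling ratios
(TR/MTT ≤ 0.2) the bias shrinks proportionally.

# Spatial normalization

All transforms are 6-degree-of-freedom rigid world-coordinate mappings
(mm, RAS, 0-based voxel indices). The built-in estimator maximizes
normalized mutual information over a 32-bin joint histogram in three
deterministic stages: an integer-voxel translation scan at half
resolution, a coarse rotation scan at full resolution (fine rotational
structure does not survive decimation), and a pattern search over all six
parameters with steps shrinking from 2 to 0.05 voxel/degree-scale units —
a derivative-free local search that is robust on the piecewise-flat
histogram metric where a simplex stalls. Both images are pre-smoothed
with a 3×3×3 mean filter; smoothing both sides symmetrizes interpolation
blur, without which the metric can peak at zero motion for
nearly-symmetric scenes. The estimator is pluggable: any function
returning an `affine_transform` (e.g. a wrapper around an external
registration tool) can stand in. Labels and masks are always resampled
nearest-neighbour (value sets preserved), quantitative maps always
trilinearly; an estimated FLAIR→T1 transform is reused unchanged for
lesion masks (`apply_to_mask()`), never re-estimated. On phantoms the
recovery accuracy is 0.2 voxel for translations and 0.5° for rotations.

# Tissues and volumetry

Normal-appearing masks are exact set subtractions: NAGM = GM ∧ ¬lesion,
NAWM = WM ∧ ¬lesion, with the registered lesion mask. Deep grey
structures (caudate, putamen, globus pallidus and thalamus, left/right)
are accepted as label volumes from upstream tools; the phantom provides
them with known truth. Skull-size volume normalization is reduced to its
interface: a supplied scaling factor multiplies raw volumes into the
`normalized_volume` CSV column (default 1), since estimating the factor
itself belongs to external brain-extraction tooling.

For data without an external segmentation, a fallback 3-class T1
intensity segmentation is included. It thresholds at the saddles
separating the three most *persistent* modes of the kernel density of
masked intensities, then polishes boundaries with one-dimensional Lloyd
iterations. Persistence (peak height minus merge saddle) was chosen
deliberately: CSF occupies a tiny fraction of the phantom brain, and
both a within-variance criterion (k-means) and a deepest-valley rule
measurably fail under that imbalance — k-means prefers splitting white
matter over isolating an 8σ-distant micro-class, and the deepest valleys
land inside the sparse CSF cluster's sampling noise. The method is
deterministic and invariant to positive affine intensity rescaling, both
asserted by tests. Its assumptions: three well-separated intensity modes
and no bias field; it is a stand-in for atlas- or shape-model-based
segmentation, not a replacement on real data, and lesion-bearing images
contaminate the GM mode (the pipeline subtracts the lesion mask from the
resulting tissue masks afterwards, mirroring how external tools are fed).

# Reporting and provenance

`region_stats()` reports voxel count, volume (voxels × voxel volume,
exact), normalized volume, mean, SD, median, IQR and range per region ×
map, with upstream-invalid voxels (clamped ADC, zero-flow) excluded from
intensity statistics but not from volumetry; empty regions carry missing
values, never zeros. The CSV has a fixed column order and round-trips
exactly. Every pipeline step appends an immutable provenance record
(parameters, md5 content hashes of inputs/outputs, package version,
timestamps) serialized as JSON-lines; reruns write to versioned
directories and inputs are snapshot-copied before modification, so any
intermediate state can be reconstructed and verified
(`verify_provenance()`).

Dataset intake mirrors clinical practice: DICOM de-identification under a
configurable tag policy (blank, replace, or deterministically re-hash
UIDs under a per-run salt into a `2.25.`-rooted namespace whose
signature makes re-anonymization a no-op), a per-patient sequence
inventory that excludes incomplete datasets and emits a missing-sequence
checklist, and a copy-based canonical layout normalization that never
mutates its input. The DICOM codec handles explicit-VR little-endian
files with defined lengths — sufficient for tag-level editing with pixel
data passed through byte-identical — and is not a general DICOM
implementation.

# The phantom: what it emulates, and what it does not

`phantom_spec()` defaults define the reference study conditions used
throughout the tests:

| Parameter | Default | Meaning |
|---|---|---|
| grid, voxel | 32³ voxels, 2 mm | whole "brain" at desk-test scale |
| tissue means (T1) | CSF 30, GM 80, WM 100 | typical T1 contrast ordering |
| lesions | 8 spheres, radius 4 mm, 2 per class | offsets: FLAIR +200; T1 −40 if hypointense; Gd-T1 +60 if enhancing |
| NAWM reference | 5×5×4 box in pure WM | operator's reference region |
| ADC truth | CSF 3.0, GM 0.8, WM 0.7, lesion 1.0 ×10⁻³ mm²/s | literature-typical magnitudes |
| perfusion truth | WM (0.010/s, 0.040, 4 s), GM ×1.5, lesion ×2 | CBV = CBF·MTT by construction |
| bolus | gamma-variate, t0 = 10 s, α = 1.5, β = 1.8 | onset sharp enough that the first post-arrival volume exceeds the 0.1 range-fraction of the mean curve, so arrival is detectable exactly |
| DSC | 60 volumes, TR 1 s, TE 50 ms | first-pass coverage |
| b-value | 1000 s/mm² | standard clinical DWI |

Geometry is concentric ellipsoids (CSF core, WM interior, GM shell) with
a designated arterial sphere carrying the AIF itself (ten-fold tissue
amplitude, earliest peak) and deep-structure spheres inside WM. Lesions
are embedded in WM by construction — their voxels are relabelled WM
before intensities are laid down — so "offset relative to the WM mean"
holds at every lesion voxel even where a sphere would straddle a shell
boundary, matching the white-matter nature of the lesions being modelled.
Overlapping lesion spheres are rejected so truth labels stay unambiguous.
Noise is additive Gaussian per modality; same seed, same bundle,
bit-identically.

Deliberate non-goals: realistic anatomy, partial-volume effects, Rician
noise, motion, baseline drift, and bolus recirculation. Passing tests on
this phantom therefore demonstrate *algorithmic* correctness (forward
models inverted to stated tolerances, invariants held), not performance
on clinical data, where registration backends, segmentation quality and
noise statistics all differ.

## Problem sizes and noise conditions used by the test suite

Tests run the 32³ reference phantom; Monte-Carlo sweeps use 20 seeds per
condition, with structural sweeps at 32³ with a shortened DSC series
(12 volumes, t0 = 2 s) and perfusion sweeps on a 16³ lesion-free variant.
The noisy-ADC condition sets the noise SD to the WM b=1000 signal
divided by 50 (SNR 50 with respect to the diffusion-weighted signal the
map is computed from); the "mild noise" tissue-segmentation condition
uses SD 4 on T1 (a 5σ GM/WM separation). Monotonicity properties
(classification error vs structural noise, perfusion bias vs DSC noise)
are asserted on averages over the 20 seeds. The perfusion Monte-Carlo
conditions on the true arrival volume, isolating map recovery from
arrival detection, which has its own exact-recovery tests.

# Known limitations

* The CBV/MTT discretization bias quantified above.
* The arrival detector tests single volumes against the baseline; on
  very small masks (few hundred voxels) and strong noise its
  false-trigger rate grows, since the volume-mean noise approaches the
  range fraction.
* The NMI-based estimator assumes a decent overlap and a roughly rigid
  relation; it performs a local search and can be trapped by symmetric
  scenes beyond its coarse-scan range (±4 voxels, ±6°).
* The fallback segmentation is intensity-only (no spatial regularization
  or bias-field model).
* DICOM support is limited to explicit-VR little-endian with defined
  lengths.
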