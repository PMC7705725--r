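---
title: "Quantifying hippocampal lesions and electrode positions in micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hippocampal lesions and electrode positions in micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`lesionscope` implements a quantitative analysis chain for volumetric
micro-CT scans of rodent brains built around three questions:

1. **Does a brain carry a hippocampal lesion, and how far does it extend?**
   Answered without any voxel-wise segmentation, by masked slice-wise
   structural similarity (SSIM) between all pairs of brains, single-linkage
   clustering of the dissimilarity `1 - SSIM`, and nearest-control
   similarity profiles along the anatomical axis.
2. **Where are implanted tetrodes relative to the hippocampal cell layer?**
   Answered in a normalized two-dimensional anatomical frame anchored on two
   landmarks of the bright pyramidal/granule cell layer, with automatic
   matching of detected electrode rods to the cannula grid of the microdrive.
3. **How do theta-band phase offsets in the LFP relate to those positions?**
   Answered by the standard hippocampal theta chain: decimation to 1.5 kHz,
   zero-phase equiripple band-pass (4-10 Hz), Hilbert phase, gating to
   running periods (speed > 10 cm/s), and two-stage circular averaging.

Because no public micro-CT cohort accompanies the methodology, the package
ships a first-class synthetic cohort generator with exact ground truth.
Every downstream stage is exercised and tested against that ground truth.

# The synthetic cohort generator

`generate_brain_volume()` renders one subject on a grid of
128 (AP) x 96 (DV) x 96 (ML) voxels by default — a desk-scale stand-in for
full-brain scans at micron pitch; the voxel pitch is abstracted to 1 unit.
A subject consists of:

- an **ellipsoidal tissue region** (intensity 0.35) over a zero background,
  with an optional skull shell (off by default; the analyses never use it);
- a **curved bilateral hippocampal cell layer** at intensity 1.0: per
  hemisphere, an elliptical arc swept along the AP axis, parameterized by a
  septo-temporal fraction `t` in [0, 1]. Anterior sections carry two arcs
  (dorsal and ventral sheets) separated by an angular gap that narrows with
  `t` and closes at the fusion fraction `t = 0.55`, where the sheets merge
  into the single intermediate-hippocampus arc. An inner dentate sheet at
  0.55 of the CA radius is rendered wherever a 3.5-voxel radial clearance
  fits. Arc centers, radii, and angular spans are recorded in
  `cohort_config()$geometry`;
- **additive Gaussian noise** (sd 0.04 by default, about 6% of the
  layer-tissue contrast) and a **rigid pose jitter** of up to 2 degrees per
  axis and 2 voxels translation, emulating placement variability. All
  stochastic draws derive from `(config, subject_seed)`; `derive_seed()`
  maps a master seed and subject index to per-subject streams.

Two geometric details exist purely to make the anatomical landmarks
well-defined at any grid size. First, the pre-fusion gap between the dorsal
and ventral sheets is held at a minimum of 4 voxels (a physical length, not
an angle), so the painting brush (radius 1.2 voxels) can never bridge the
sheets before the nominal fusion slice. Second, the dentate sheet is skipped
wherever it would come within 3.5 voxels of the CA arc; on the default grid
this only affects its anterior-most sections.

**Ground truth** records the pose, the painted layer voxels with their
septo-temporal fractions, the landmark coordinates (anterior CA1 tip, lateral
fusion point, and the posterior-ventral extreme, per side), the lesioned
voxel set, and electrode tip positions.

**Lesions.** `apply_lesion()` carves a cavity anchored to the 24 bilateral
NMDA infusion sites (`infusion_sites()`): the sites' AP span is mapped
affinely onto the septo-temporal parameter so that they cover fractions
0.25-0.65 of the model layer — the dorsal plus dorsal-intermediate segment,
leaving the ventral-most layer untouched. Layer voxels inside that window,
dilated by a 2-voxel margin, drop to the cavity intensity (0.05) with a
randomized ragged boundary (35% of the boundary shell retained). The cavity
is clipped to the targeted AP slices, so the set of altered voxels is exactly
the recorded mask and AP slices outside the window are untouched. The cavity
intensity is a free parameter: the source imaging does not quantify cavity
grayscale relative to tissue.

**Electrodes.** `insert_electrodes()` paints vertical rods (intensity 4.0,
far above the layer) from just above the dorsal tissue surface to per-slot
tip depths, at the occupied slots of a `cannula_layout()` grid; skipped
slots model the empty cannula positions of a real microdrive.

**LFP sessions.** `generate_lfp_session()` synthesizes channels
`sin(2*pi*8*t + offset_k)` plus white noise at a requested RMS SNR, and a
body-speed trace alternating running (25 cm/s) and still (3 cm/s) blocks,
20 s / 10 s by default.

What the generator does *not* emulate: radiographic physics (phase contrast,
beam hardening, ring artifacts), anatomical shape variability between
subjects beyond rigid pose, skull sutures, and histology-scale texture.
Passing tests therefore demonstrate the correctness and stability of the
analysis chain under controlled conditions, not robustness to every
real-scanner artifact.

# Rigid alignment

The source methodology registered whole brains interactively. Here the
shared coordinate system is realized deterministically: landmarks are
detected in each volume, and `estimate_rigid()` computes the closed-form
least-squares rotation + translation (orthogonal Procrustes with the
standard reflection sign fix) onto the canonical template landmarks.
`resample_to_reference()` then pulls intensities onto the reference grid by
trilinear interpolation (out-of-domain voxels receive the tissue background;
resampling can be restricted to the analysis region for economy).

Landmark detection (`detect_anatomical_landmarks()`) is scale-invariant: the
layer threshold is `tissue + 0.5 * (layer - tissue)` with both levels taken
from intensity quantiles, and voxels brighter than 1.5x the layer estimate
(electrodes) are excluded. Per hemisphere it returns:

- the **anterior CA1 tip** — centroid of the anterior-most layer voxels;
- the **fusion point** — lateral-most layer voxel of the first slice at
  which the dorsal-most and ventral-most layer pixels share one 4-connected
  in-slice component, taken as the first slice of the final persistent
  (3-slice) fused run so that isolated discretization bridges and
  fragmentary boundary slices cannot trigger it early;
- the **posterior-ventral extreme** — centroid of the layer voxels within
  one voxel of the side's ventral-most layer voxel.

Only the tips and ventral extremes drive alignment. This matters: the
fusion point sits inside the default lesion window and is destroyed in
lesioned brains, whereas the anterior tip (t < 0.25) and the ventral extreme
(t near 1) survive by construction of the surgical targeting, so lesioned
brains align as reliably as controls. The fusion points are reserved for the
electrode coordinate frame, exactly where the methodology uses them. An
additional image-based refinement (e.g. maximizing normalized
cross-correlation over small perturbations) was considered and omitted:
landmark alignment already recovers the pose to sub-voxel residuals on every
tested cohort.

# Masked slice-wise SSIM

`make_region_mask()` builds the generous bilateral hippocampal mask by
dilating the canonical layer template by 4 voxels. For every AP slice in the
mask and each hemisphere separately, all aligned volumes are cropped to the
mask's bounding box and `ssim_pair()` scores every unordered pair:

$$\mathrm{SSIM}(a,b) = \frac{(2\mu_a\mu_b + C_1)(2\sigma_{ab} + C_2)}
{(\mu_a^2+\mu_b^2+C_1)(\sigma_a^2+\sigma_b^2+C_2)}$$

with Gaussian-weighted local moments, \(C_1 = (k_1 L)^2\),
\(C_2 = (k_2 L)^2\), \(k_1 = 0.01\), \(k_2 = 0.03\). Numerical conventions:
the Gaussian window is truncated at 3.5 sigma; borders are handled by
symmetric reflection; every crop pixel counts in the unweighted mean; the
map never exceeds 1 and equals 1 only for identical inputs.

Parameter scaling: the reference methodology smoothed with sigma = 50 px on
slices on the order of 1000 px across. The default here is
`sigma = 50 * crop_width / 1000`, preserving the neighborhood size relative
to the image; with the default mask the crops are ~24 px wide, giving
sigma = 1.2 px (recorded in the result object). The dynamic range defaults
to the cohort-wide max-min over the masked crops. Left and right crops enter
the pooled mean as separate slices with equal weight ("bilateral"
averaging); crop-box semantics (rather than pixel-wise masking) are used, as
the mask is a generous bounding region by design.

# Clustering and nearest-control profiles

`linkage_single()` clusters the dissimilarity `1 - S̄`, where `S̄` averages
the per-slice matrices over the lesioned septo-temporal window (the portion
of the hippocampal formation actually targeted). Single linkage merges the
closest pair at each step with the update
`d(A∪B, C) = min(d(A,C), d(B,C))`; exact ties resolve to the smallest
cluster creation indices, so results are fully deterministic.
`cut_groups(k)` removes the `k - 1` tallest merges; `k = 2` (lesion vs
control) is the default and is exposed as a parameter, since nothing in the
method fixes how many "major groups" a dendrogram holds. Ties straddling the
cut height are flagged.

`nearest_control_profile()` gives, per subject and slice, the maximum
similarity to any control brain. Controls exclude themselves — otherwise
every control would trivially score 1 — which is the only sensible reading
when controls need a comparator. Group summaries are per-slice medians and
quartiles using R's default inclusive linear-interpolation quantile
(type 7).

One boundary subtlety: the continuous lesion window maps to fractional slice
coordinates, so the two slices straddling its ends are genuinely partially
lesioned. `extent_to_slices()` therefore distinguishes the *inner* slice set
(entirely inside the window; where the lesion dip is asserted) from the
*outer* set (any overlap; its complement is where the control/lesion medians
are expected to converge within the pooled interquartile range).

# Electrode localization

The normalized 2-D frame (`make_frame()`) sends the anterior CA1 tip to
(0,0) and the fusion-point lateral extent to (1,1) by independent affine
maps on the AP and ML axes — the only map those two points fully determine.
Consequences: invariance holds for axis-aligned translation and scaling
(volumes are rigidly aligned first, so rotations are already removed), and
frames are built per hemisphere. DV is deliberately excluded: tetrodes are
advanced between scan and recording, so the scanned DV coordinate does not
represent the recording site.

`extract_layer_curves()` samples, per slice and hemisphere, the lateral-most
layer pixel (lateral hippocampal curve) and the medial-most pixel of the
inner dentate sheet (medial curve). The inner sheet is identified as an
in-slice connected component that contains neither the dorsal-most nor the
ventral-most layer pixel, sits strictly inside the slice's DV range, and
lies clearly medial of the lateral envelope; slices without such a component
are recorded as gaps, never interpolated.

`detect_electrode_tips()` thresholds at a high intensity quantile (default
0.9995), labels 26-connected components, keeps those with at least 5 voxels,
and reports each rod's tip as the centroid of its ventral-most voxels (the
tip, rather than the dorsal track, is what anchors the recording position).
Components with a horizontal footprint wider than a single brush (>= 3
voxels) are flagged as possibly-merged neighbors.

`match_cannula()` fits a similarity transform (rotation, uniform scale,
translation) from layout slots to detections. The correspondence search
seeds from the two mutually farthest detections tried against every ordered
slot pair; each hypothesis is scored by greedy nearest-neighbor assignment,
the best is refined by complex least squares and the assignment recomputed.
For rotationally symmetric layouts several hypotheses tie at zero residual;
near-ties resolve to the smallest rotation angle. Users can override the
seeding with explicit anchor pairs. Unoccupied slots and surplus detections
remain unassigned.

# Theta phase offsets

`decimate_lfp()` low-passes at 400 Hz (zero-phase FIR, unit DC gain) and
resamples to 1.5 kHz. `design_theta_bandpass()` builds the Parks-McClellan
equiripple FIR with pass band 4-10 Hz and stop bands below 3 / above 11 Hz
at 1.5 kHz. The tap count starts from the standard Kaiser order estimate for
the default attenuation target (40 dB combined stopband over the
forward-plus-reverse application) and increases along a small ladder until
the realized design verifies: combined stopband response at most 0.01,
combined gain at least 0.99 at 8 Hz, symmetric coefficients. The accepted
design is normalized to unit single-pass gain at 8 Hz, so the equiripple
passband ripple cannot bias the theta-band response; zero-phase filtering
makes the ripple irrelevant to phase in any case. The realized design (1449
taps) attains a combined stopband of 0.0061 (-44 dB). Filtering applies the
kernel forward and reverse (`filtfilt_zero_phase()`), with odd-reflection
padding of three filter lengths absorbing edge transients.

`instantaneous_phase()` is the angle of the FFT-based analytic signal.
`detect_run_periods()` takes maximal intervals with speed strictly above
10 cm/s, resampled to LFP indices (half-open `[start, end)`), dropping
periods shorter than 1 s (the minimum duration is not fixed by the source
methodology; 1 s is configurable).

`pairwise_theta_offsets()` forms unit phasors `e^{i phi}` per channel, takes
the instantaneous pairwise difference `angle(e^{i phi_a} e^{-i phi_b})`,
circularly averages it within each running period, and then takes the
circular mean of the per-period means — the two-stage definition, which
weighs every running period equally regardless of duration. A
duration-weighted variant exists but is off by default, and the two
definitions demonstrably diverge when period lengths are unbalanced. Unit
(not amplitude-weighted) phasors are used, matching the phrase "instantaneous
phase differences"; amplitude weighting would let high-amplitude epochs
dominate. Degenerate per-period resultants are flagged.

# Problem sizes and runtime choices

The test and reproduction workloads use the generator's study conditions
directly: 12 control + 13 lesion subjects on the 128 x 96 x 96 grid,
clustering repeated over 20 master seeds; full-extent profiles on one seed;
theta recovery over 10 seeds of 600 s three-channel sessions at SNR 5.
Resampling is restricted to the mask's bounding region and SSIM moments are
precomputed per subject and slice, which keeps a full cohort run around half
a minute and the complete suite within ordinary interactive patience.

# Known limitations

- Alignment is landmark-based; grossly corrupted layers (e.g. a lesion
  window covering the anterior tip or the ventral extreme) would defeat it.
  The infusion-site anchoring makes that impossible under the default
  configuration but custom windows spanning [0, 1] would need image-based
  registration instead.
- SSIM values under synthetic noise sit lower than on real tissue (flat
  regions are noise-dominated), so absolute similarity levels are not
  comparable to published real-data figures; the group structure is.
- The per-axis affine frame ignores residual rotation between hemispheres;
  it is exactly as strong as the upstream rigid alignment.
- The cannula matcher assumes at least two true detections and a roughly
  rigid drive; heavily distorted implants would need manual anchors.
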