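---
title: "Methods: quantifying synaptic and extrasynaptic AMPAR puncta on motor neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying synaptic and extrasynaptic AMPAR puncta on motor neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaquant)
```

## The measurement problem

After a complete spinal cord injury, peripheral nociceptive input can drive
maladaptive plasticity in ventral-horn motor circuits by changing where
AMPA-receptor (AMPAR) subunits sit on motor neurons: at synapses (apposed to
presynaptic terminals) or at extrasynaptic membrane sites. The measurement
this package automates is the pixel-level version of that question: in a
two-channel confocal z-stack — one channel a presynaptic vesicle marker
(synaptophysin), the other an AMPAR subunit (GluA1 or GluA2) — how much AMPAR
signal is there in total, how much of it colocalizes with the presynaptic
marker ("synaptic"), and how much of the membrane-proximal AMPAR signal does
not ("extrasynaptic")?

Because studies of this kind deposit no raw imaging data, the package pairs
every analysis stage with a synthetic-data generator that plants known
ground truth, so the whole chain is testable end to end.

## Sampling model

Neurons are selected by **systematic geometric sampling**, not by the
analyst. Four landmarks entered at the microscope — central canal, anterior
spinal artery, left and right tissue edges — define an orthonormal tissue
frame: origin at the canal, one axis toward the artery (ventral), the
second orthogonal toward the right edge. `build_grid()` tiles the ventral
half-plane (the side containing the artery, clipped laterally to the edge
projections, ventrally to the artery's depth) with square windows on a
100 µm lattice.

Two window sizes circulate in descriptions of this protocol, 90 × 90 µm and
80 × 80 µm; both are retained as presets (`window_size` argument, default
90) and no attempt is made to decide which a given laboratory used. With
100 µm spacing, neither preset produces overlapping windows; grid
construction is rigid-motion equivariant (tested over random rotations and
translations), so the grid always follows the orientation of the tissue
rather than the stage. When a window holds several candidate neurons,
`select_neuron()` picks one uniformly at random under a seed.

"Ventral half" is operationalized as the half-plane through the central
canal perpendicular to the canal-to-artery axis: the source protocol does
not define the boundary more precisely, and only four landmarks are
available, so no curved tissue outline is inferred.

## Image quantification

**Thresholds** come from control tissue: `derive_threshold()` returns
mean + *k*·SD over all pixels of the named channel of a control stack
(*k* = 2 by default). The underlying protocol says only that thresholds were
"predetermined … based on control tissue"; the mean + *k*·SD rule is this
package's explicit, monotone, configurable realization. Thresholds are
derived once and held constant across an experiment; classification is
strict (`>`), so a pixel exactly at threshold does not count.

**Deconvolution** is Richardson–Lucy with a fixed, known PSF
(`gaussian_psf()`), applied channel-wise with a per-target iteration count —
4 for GluA1, 2 for GluA2, mirroring per-antibody iteration choices fixed
*a priori*. Blind PSF estimation is deliberately out of scope; the
fixed-kernel maximum-likelihood iteration is the classical
`est ← est · (obs / (est ⊗ psf)) ⊗ psf̃`, with convolutions done by FFT
(circular boundary; see numerical notes). Zero iterations is the identity,
and estimates are clamped non-negative every iteration.

**Counting** is pixel-wise. Per plane: AMPAR pixels strictly above the AMPAR
threshold; presynaptic likewise; colocalized = both at once. `stack_counts()`
applies this to every plane and totals over z; invariantly,
colocalized ≤ min(AMPAR, presynaptic) on every plane, and raising either
threshold never increases any count. Colocalization is defined on pixels,
not objects — no spot fitting, no Manders/Pearson coefficients — because the
quantity of interest is the amount of overlapping signal, and that is what
the synthetic ground truth can pin down exactly.

**Large-neuron detection** finds the distinctive presynaptic ring: threshold
the presynaptic channel, morphologically close (disc radius 0.5 µm by
default) to bridge ring gaps, fill holes, label components, and keep regions
whose equivalent diameter 2·√(area/π) exceeds 40 µm. A ring score — the
fraction of the filled region's perimeter that is suprathreshold — is
reported so weakly outlined blobs can be screened.

## Membrane optical fraction

The membrane analysis runs on a single optical plane: the plane with the
**highest colocalized pixel count** (`select_peak_plane()`, argmax with
lowest-index tie-break). Human monitoring of plane selection for staining
artifacts is replaced by an explicit `exclude` argument. The membrane is
traced either automatically (`trace_membrane()`: largest closed contour of
the closed-and-filled suprathreshold mask that encloses the soma centroid)
or supplied as a manual polyline CSV, mirroring blinded manual tracing;
manual traces pass through unchanged.

`band_cutout()` marks every pixel whose exact Euclidean distance to the
closed polyline is ≤ `half_width` (point-to-segment distance, computed per
segment over its padded bounding box). "2 µm-thick cutout" is interpreted as
total thickness: ±1 µm around the trace at the default `half_width = 1`.
Increasing the half-width can only grow the band and its counts. Within the
band, `classify_band_puncta()` splits AMPAR pixels into synaptic
(colocalized) and extrasynaptic (remainder); the two always sum to the band
total. Whether real analyses restricted the band to somatic membrane is
unstated in the source protocol; here the trace itself defines the extent.

## Western-blot stage

`normalize_band()` divides band fluorescence by the median background pixel
density; the background is parameterized per membrane by default (a per-lane
background is a caller choice, since the protocol does not say which was
used). `select_linear_setting()` fits OLS of fluorescence on protein loaded
for each scanning-intensity setting of a 1:2 dilution curve and picks the
setting with maximal R²; R² is the squared Pearson correlation of the fit,
defined as 0 for a zero-variance response, and a calibration is considered
usable when R² > 0.98. Image-based densitometry is out of scope — band
intensities enter as tables.

## Stimulation schedule and behavioral metrics

`generate_schedule()` places the first pulse at t = 0 and appends 80 ms
pulses, each onset one uniformly drawn interstimulus interval (0.2–3.8 s;
mean 2 s) after the previous onset, while the pulse still ends within the
6-min session. The uniform distribution is this package's choice — only the
range and mean are stated by the protocol, and the uniform on that range has
exactly the stated mean. Starting at t = 0 makes the degenerate ISI ≡ 2 s
schedule deliver exactly 180 pulses; under the uniform draw the mean count
over many sessions is ≈180.5 (a renewal-process correction of about half a
pulse), matching the protocol's "~180 presentations" at its printed
precision.

`response_duration()` is the learning metric
(60 − time in solution)/(response number + 1) per 1-min bin, monotone
decreasing in both arguments and bounded in [0, 60] s.
`summarize_session()` derives both inputs from a raw contact-electrode event
log: in-solution time is integrated exactly within each bin (events split at
bin boundaries), and a lift counts toward the bin where it began, since
lifts are point events. The session is assumed to start with the electrode
in solution, so logs must alternate up/down starting with "up".

## Statistical battery

`ancova_interaction()` fits
`response ~ covariate + replication + stimulation * time` by least squares
and tests the stimulation × time interaction as the last sequential term.
The replication (independent blot run) enters as a **fixed additive block**
rather than a random factor: for the balanced designs this machinery
targets, the interaction point estimate and F are identical, and the
contract is far simpler than REML estimation. Partial eta squared
(SS_effect / (SS_effect + SS_error)) and observed power accompany the F.

`pairwise_lsd()` compares stimulation groups within each time level on
covariate-adjusted estimated marginal means with **unadjusted** p values —
the least-significant-difference convention for planned comparisons
following an omnibus test. A `adjust = "holm"` flag is available for users
who want multiplicity control. `tukey_hsd()` provides studentized-range
post-hoc comparisons for group means (confocal/behavioral endpoints);
`students_t()` (pooled variance) and `mann_whitney_u()` (midrank ties, U of
the first sample, normal approximation) cover ratio endpoints.
`observed_power()` uses the SPSS convention λ = F·df₁ against the central
critical value, so a null F of 0 gives power exactly α. All tests are
two-sided with α = 0.05 by default.

## Synthetic-data generator

`simulate_puncta_field()` plants the ground truth: a circular soma (default
45 µm — a large motor neuron) whose membrane trace is outlined by
presynaptic signal; synaptic AMPAR puncta on the trace, each given a
presynaptic partner within the colocalization radius (0.1 µm); extrasynaptic
AMPAR puncta inside the ±1 µm membrane band but at least the colocalization
radius away from every presynaptic punctum; and neuropil puncta uniform
outside the soma. The number of synaptic puncta is binomial in
`synaptic_fraction`. `generate_confocal_stack()` renders each punctum as a
3-D Gaussian spot (σ_xy = 0.15 µm, σ_z = 0.4 µm — a diffraction-scale
punctum), convolves with a Gaussian PSF (σ_xy = 0.2 µm, σ_z = 0.5 µm),
adds a constant background of 5 photons, Poisson shot noise, and Gaussian
read noise (SD 2). Ground truth is recorded before blur and noise, so
pipeline outputs can be compared to exact tallies.

Default geometry is 0.1 µm/pixel (the acquisition optics' pixel pitch is
not public; it is configurable and carried in metadata) and 0.25 µm
z-spacing. Tests and the bundled pipeline run at 0.2 µm/pixel to keep
rendering and deconvolution fast; that halves lateral sampling without
changing any algorithmic behavior.

What the generator deliberately does **not** emulate: the membrane outline
is rendered as a continuous ring, whereas real synaptophysin labeling is
punctate; the blurred ring therefore colocalizes with membrane-proximal
AMPAR pixels regardless of their planted label, compressing estimated
synaptic fractions toward the middle of the range (planted fractions
0.05–0.95 map to estimates of roughly 0.5–0.8 at default noise). Rank order
is preserved — the end-to-end Spearman correlation between planted and
estimated fractions is ≥ 0.9 over 20 study-scale neurons — and planted group
differences come out in the right direction, but absolute synaptic fractions
from this pipeline should be read as relative, not calibrated, quantities on
real data too, where the same optical mixing occurs. Also not modeled:
optical aberrations, bleaching, anatomy beyond a ringed soma in neuropil,
and non-circular somata.

`generate_western_dataset()` draws a balanced 2 × T × replication design
with target = cell mean + slope·(centred loading control) + noise, and
`generate_behavior_cohort()` uses a clipped exponential-acquisition
recurrence `d[i+1] = d[i] + α(asymptote − d[i]) + noise` — an invention
sufficient to exercise the metric and statistics, since only group curves
are published for the behavior.

## Numerical choices

* Convolution (rendering PSF and Richardson–Lucy) is FFT-based and circular;
  kernels larger than the image are centrally cropped and renormalized.
  Wrap-around is negligible for somata well inside the field, which the
  generator enforces by rejecting somata that do not fit with their band.
* Rendered Gaussian spots are truncated at 4σ; voxel centres sit at
  (index − 0.5) × pitch.
* Peak-plane ties break to the lowest plane index; `which.max` semantics.
* Band membership uses exact point-to-segment distance with a ≤ comparison,
  so a straight trace at 1 µm half-width and 0.1 µm pixels yields a band
  exactly 21 pixels wide.
* Degenerate statistics: a flat response reports F = 0, p = 1, η² = 0;
  zero-variance dilution responses report R² = 0; a zero-sum PSF, empty
  candidate lists, non-alternating event logs, and out-of-range metric
  inputs all raise immediate errors.
* Grid lattice bounds include a 10⁻⁶·spacing tolerance so windows whose
  centres fall exactly on the landmark extent survive floating-point
  rotation.
* Child seeds for pipeline stages are derived as
  (seed·48271 + offset) mod (2³¹ − 1), keeping every derived seed a valid
  32-bit integer.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to finish in minutes on one
CPU while keeping the study's geometry where it matters: 20 neurons with
45 µm somata at 0.2 µm/pixel for fraction-recovery, an 80-cell end-to-end
cohort (20 cells/group × 2 targets, planted GluA1-up / GluA2-down) for the
direction-of-effect demonstration, 500-replicate null simulations for each
test's type-I calibration, 1000 seeded sessions for the schedule statistics,
and small dense-oracle scenes (8 µm fields) where counts are compared
voxel-for-voxel against an independent rendering.

## Known limitations

Pixel-wise colocalization counts pixels, not receptor clusters; object-level
counts require spot detection, which is out of scope. The automatic tracer
assumes one dominant closed membrane contour around the given centroid and
will fail (by design, with an error inviting a manual trace) on broken
rings. The fixed-PSF deconvolution cannot correct depth-varying blur. The
"mixed-model" replication factor is fixed, so variance components of blot
runs are not estimated. Repeated-measures behavioral ANOVAs are computed as
uncorrected univariate F tests.
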