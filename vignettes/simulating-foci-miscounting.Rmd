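---
title: "Simulating foci miscounting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating foci miscounting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focisim)
```

`focisim` asks a narrow question with a fully simulated answer: if the
true number and positions of DNA double-strand breaks (DSBs) in a nucleus
are known exactly, how many *foci* would a standard fluorescence-imaging
pipeline report, and how does the gap between the two depend on radiation
quality, dose, repair time, marker chemistry and microscope? This
vignette documents the models behind each stage, the tunable parameters
with their defaults and units, the numerical choices, and the places
where the design was genuinely open.

## Nuclear geometry

The nucleus is a flattened ellipsoid with semi-axes (11.8, 11.8, 1.0) μm
— an adherent-fibroblast-like shape with the optical axis along z —
populated by hard spheres, one per TAD. Chromatin enters the model only
through these beads: each carries a genomic interval, its volume is
proportional to its genomic content at a packing density of
`bead_density_bp_per_um3 = 1e7` bp/μm³ (so the default genome occupies
roughly 10% of the nuclear volume, and a 1-Mbp TAD has a ~0.29 μm
radius), and there is no sub-TAD structure.

The genome is synthetic. `build_genome()` tiles each chromosome with TAD
sizes drawn from a truncated normal (default mean 1 Mbp, SD 0.25 Mbp,
matching the upper range of mammalian TAD calls), and the default genome
is reduced to six chromosomes totalling 600 Mbp so that hundreds of
geometries build in seconds; full-size chromosome lengths are a
parameter, not a code change. `pack_geometry()` places beads by rejection
sampling with hard-sphere overlap rejection, keeping each bead's centre
inside the ellipsoid shrunk by its radius, and placing successive beads
of a chromosome within twice the summed radii of their predecessor to
mimic polymer connectivity. After 1,000 failed attempts the overlap
constraint is relaxed with a warning (and, as a last resort, the
connectivity constraint), which guarantees termination at any density.
A packing whose beads cannot fit the ellipsoid at all is an error.

What this generator does *not* emulate: Hi-C-derived chromosome
territories, A/B compartments, loops, or any correlation between genomic
and spatial neighbourhood beyond nearest-predecessor adjacency. Passing
tests therefore validate the counting machinery on plausible bead
configurations, not the realism of any particular cell line's chromatin
architecture; the downstream mathematics consumes only bead positions,
radii and intervals, so externally supplied geometries can be substituted
via `read_geometry()`.

## Damage induction

**Photons.** The number of DSBs per nucleus is Poisson with mean
`photon_yield_per_gy = 30` per Gy. Each DSB picks a chromosome with
probability proportional to its length, a bead within the chromosome
proportional to its genomic content, a uniform position inside the bead
sphere, and a uniform bp within the bead's interval.

**Charged particles.** Tracks are straight lines parallel to the optical
axis crossing the nucleus at uniform random (x, y) — a deliberately
minimal stand-in for track-structure transport, flagged as synthetic so
that externally produced SDD damage listings can replace it. The track
count follows from energy bookkeeping: `n = round(dose × mass / (LET ×
mean chord))`, with the nuclear mass from the ellipsoid volume at
1 g/cm³ and mean z-chord 4c/3. Depositions form a Poisson process along
each chord with linear density LET/`mean_deposit_ev` and exponential
energies (default mean 60 eV, an effective per-interaction scale chosen
so deposition spacings at the study LETs straddle the 3.2-nm pairing
window). A deposition becomes a strand break iff it falls inside a bead,
survives a Bernoulli(0.141) chromatin-sampling draw, and survives an
energy-ramp draw with p(E) linear from 0 at 5 eV to 1 at 37.5 eV —
stated as endpoint anchors; the linear interpolation is the conventional
choice. Surviving breaks get a strand (½ each) and a uniform bp within
the bead.

**Break pairing.** A DSB is a pair of opposite-strand breaks in the same
bead separated by at most 3.2 nm (the printed genomic equivalent is
10 bp). The default pairing criterion is *spatial*. This is a considered
choice: because bp positions are assigned uniformly at random within a
~1-Mbp TAD, the probability that two breaks fall within 10 bp of each
other genomically is ~2 × 10⁻⁵, and a genomic pairing rule would yield
essentially zero DSBs from any realistic track; the spatial rule applied
to deposition positions reproduces the intended physics. The genomic
rule remains available (`by = "genomic"`) for damage listings that carry
meaningful bp coordinates. Pairing is greedy in ascending order (z
within a bead for spatial, bp for genomic) with each break used at most
once — deterministic, and optimal for this 1D interval-compatibility
structure, which the test suite verifies against an exhaustive
maximum-matching oracle on instances up to 12 breaks.

## Repair kinetics

Every radiation quality shares one bi-exponential remaining fraction
f(t) = a₁e^(−t/τ₁) + a₂e^(−t/τ₂) with a₁ = 0.711, a₂ = 0.289, τ₁ =
1.54 h, τ₂ = 10 h, and the surviving count is ⌈N₀ f(t)⌉, evaluated on
the experiment's grid (0, 15 min, 30 min, 2 h, 6 h, 24 h by default).
Because a single rate applies to all breaks, the breaks are
exchangeable, and *which* DSBs are repaired is taken uniformly at random
without replacement, nested across time points (a repaired break never
reappears). Repair-time resolution is the grid itself — images are only
rendered at grid points, so continuous repair times would add nothing.

`fit_repair_params()` refits (a₁, τ₁, τ₂) from observed surviving
counts by least squares. One numerical subtlety: the ceiling operator
makes observed counts sit on average ½ above N₀f(t) at t > 0, which
alone biases a naive fit of τ₂ upward by more than 10% at N₀ ≈ 60; the
fitter therefore subtracts this analytic offset before optimising
(`bias_correct = TRUE`), giving an unbiased moment estimator.

## Marker fields

The **direct marker** (Ku70/80 / DNA-PKcs antibodies at break ends) is
one unit-intensity point source per surviving DSB, with a labelling
efficiency parameter defaulting to 1 (a perfectly efficient antibody).

The **γ-H2AX marker** is built from an explicit histone model. Beads
containing at least one surviving DSB receive
`round(0.10 × 2 × bead_bp / 146)` histones (10% H2AX variant fraction,
two H2A copies per nucleosome, 146 bp per nucleosome; rounding is
half-away-from-zero — the formula's source states the fractions, not a
rounding rule) placed uniformly in the bead. Each DSB adds to every
histone *of its own bead* the activation `0.23 + 0.38/(1 + 4(d/0.45)²)`
where d is the genomic distance in Mbp obtained from the Euclidean
histone–DSB distance via the bead's content-per-diameter ratio.
Activation is additive across breaks with no upper cap, and strictly
TAD-restricted — cross-boundary spreading is excluded. Histone placement
is seeded per (nucleus, bead), so positions are identical across time
points, while activation is recomputed from the surviving set at each
time point: dephosphorylation is assumed to track repair instantaneously,
since no decay lag is specified for the signal of an already-repaired
break.

## Microscope emulation

The registry (`registry_all()`) transcribes 24 (microscope,
magnification) configurations — XY/Z pixel spacings in μm and numerical
apertures for Airyscan, gSTED, Lowlight, MultiPhoton, Phenix and STED
systems — including the footnoted magnification substitutions (gSTED
×23 for ×20, MultiPhoton ×25 for ×20) and the additional STED ×25 entry.
The values are used exactly as printed, including the gSTED ×100 XY
spacing of 0.44 μm; because that spacing is an order of magnitude off
its column neighbours and is most plausibly a transcription slip in the
source table, gSTED ×100 is the configuration excluded from the default
23-entry run matrix (`default_microscope_set()`, configurable).

PSFs are parametric anisotropic Gaussians with scalar-diffraction widths
σ_xy = 0.21 λ/NA and σ_z = 0.66 λn/NA² (λ = 0.519 μm GFP-like emission,
n = 1.515 oil immersion), sampled on each configuration's voxel grid out
to 4σ and normalised to sum one. Two numerical floors matter:

* **Sampling floor.** The per-axis σ in *pixels* is floored at 1 voxel.
  A PSF distilled from bead images can never be narrower than its
  sampling pitch, and an unfloored sub-voxel kernel would collapse point
  sources onto single voxels. A one-voxel impulse is a degenerate input
  for scale-space blob detection: its LoG response at scale σ is only
  1/(πσ²) ≈ 7.96% of its own peak at σ = 2, fractionally *below* the 8%
  detection threshold, so detectability would hinge on sub-voxel phase
  rather than optics. The floor keeps every configuration's rendered
  point source a well-sampled blob.
* **Deconvolved rendering.** "Perfect deconvolution" is the image formed
  before the PSF applies. A mathematical delta cannot be represented on
  a voxel grid — nearest-voxel binning of a delta reproduces exactly the
  degenerate one-voxel case above — so the deconvolved renderer draws
  each source as a one-voxel-sigma in-plane Gaussian footprint (the
  band-limited representation of a point at the grid's Nyquist limit) in
  its *nearest z-plane only*. In-plane, the image remains a digital
  image; across planes, deconvolution is credited with ideal optical
  sectioning, which is what makes the deconvolved mode informative about
  out-of-plane over-counting.

Rendering bins sources to their nearest voxel on a grid covering the
nucleus bounding box plus the kernel half-extent (so border placement
loses no intensity; stack totals are conserved to 1e−6 relative), then
convolves in 3D. Sparse fields are rendered by direct kernel placement
(exactly equivalent to binning + convolution); dense fields, e.g.
γ-H2AX with tens of thousands of histone sources, switch automatically
to FFT convolution with zero-padded boundaries. No detector or photon
noise is added by default; a seeded Poisson photon-noise option exists
behind `noise_seed` and is off in every shipped analysis. Slices take
the voxel plane nearest the requested z (default 0, the nuclear
mid-plane).

## Foci detection

Counting uses canonical scale-space Laplacian-of-Gaussian blob
detection, implemented from its definition so behaviour does not depend
on any external imaging library: for each scale σ (single scale
min_sigma when num_sigma = 1, otherwise log-spaced in [min_sigma,
max_sigma]), the image is convolved with the sampled, zero-sum,
scale-normalised kernel −σ²∇²G_σ; local maxima in space (and across
adjacent scales at the same voxel, for multi-scale runs) strictly above
the threshold are detections; overlapping detections (blob radii σ√2 in
2D, σ√3 in 3D; >50% overlap of the smaller blob) are pruned keeping the
stronger response. Sigma is in pixels, which is what lets identical
parameter sets serve every magnification and both 2D and 3D analyses.

The threshold is a percentage of a *reference* intensity, not of each
image's own maximum: `reference_max()` takes the maximum voxel intensity
of the set-up's image(s) at the 15-min time point and that anchor is
reused for all later time points, so dimming images can never gain
detections from a shrinking threshold. With one geometry per run the
anchor is that geometry's own 15-min image; pooling the anchor across a
set-up's geometries is reachable by passing more images. An all-dark
anchor (no break near the focal plane at 15 min) makes the threshold
undefined; the pipeline records zero foci for such set-ups rather than
failing.

## Metrics and statistics

Ground truth "in the slice" is the half-open one-z-pixel window
[z_c − Δz/2, z_c + Δz/2) — the volume a single voxel plane samples; the
optical-section alternative was considered and rejected because the
rendered slice *is* one voxel plane. Percentage miscount is the
symmetric difference (counted − simulated)/((counted + simulated) ×
0.5) × 100, bounded in (−200, 200], undefined (NA, excluded from
aggregates) when both are zero. Clustering is the average number of
other DSBs within 200 nm of each DSB, computed over the whole nucleus;
the implementation is checked against an O(n²) double-loop oracle.
Kinetics series are normalised to 15 min. Group comparisons use
two-sided Mann–Whitney U (exact for combined n ≤ 20 without ties,
normal approximation with tie correction otherwise; fully tied groups
are reported as p = 1), Bonferroni-adjusted as min(1, m·p), and binned
as ns > 0.05 ≥ * > 0.01 ≥ ** > 10⁻³ ≥ *** > 10⁻⁴ ≥ ****. The source
caption's star notation is internally inconsistent as printed; the
nested-bin reading above is the only coherent one. Spearman rank
correlation is used for the clustering–miscount relationship because it
is monotone, not linear.

## Problem sizes and reproducibility

Every stochastic stage takes an explicit seed, and `run_pipeline()`
expands a single master seed into per-(stage, geometry, set-up) sub-seeds
via a small integer recurrence (`derive_seed()`), so any single run can
be reproduced in isolation; the per-run seeds are recorded in the results
table. The shipped analyses choose desk-scale sizes: the yield check
uses 2,000 nuclei on a 50-Mbp four-chromosome genome (the photon yield is
geometry-independent, so a small genome serves), detector checks use a
2 × 2 × 1 μm test nucleus, the clustering analysis uses 50 full-size
nuclei spanning 1–10 Gy across Co-60 photons and protons at 1.7, 7.15
and 27.95 keV/μm, and parameter recovery uses 500 nuclei at N₀ ≈ 60.
The full reference grid — 200 geometries × 16 radiation set-ups × 23
microscope configurations × 6 time points × 2 markers, 883,200 images —
is expressible with `run_matrix()` defaults and enumerable in memory,
but is intentionally not executed by any shipped test.

## Known limitations

Geometry realism is the weakest link: beads are uniformly packed, not
Hi-C-constrained, so absolute clustering values (and hence absolute
miscount distributions) should not be compared quantitatively against
cell-line-specific data. Track structure is a straight-line caricature
without secondary-electron physics, so LET dependence is directional
rather than dosimetric. Break ends are stationary over repair; there is
no damage-complexity-dependent repair rate, no 53BP1/MDC1-specific
spreading model, no antibody sterics, and no camera noise by default.
The Gaussian PSF omits aberrations and side lobes of measured PSFs;
externally measured PSFs can be supplied via `read_psf()`.
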