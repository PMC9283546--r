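# focisim

Counting fluorescent foci is the standard way to quantify radiation-induced
DNA double-strand breaks (DSBs): each bright spot in a γ-H2AX or
Ku/DNA-PKcs immunofluorescence image is conventionally read as one break.
That reading is not exact. Light from breaks in neighbouring optical
sections leaks into the evaluated slice (over-counting), and spatially
clustered breaks blur into a single spot (under-counting), so the measured
foci count is a biased estimate of the true DSB number — with a bias that
depends on radiation quality, dose, time after irradiation, marker
chemistry and the microscope itself.

`focisim` quantifies that bias *in silico*. It simulates nuclei where the
ground truth is known exactly, renders the corresponding microscope images,
counts foci the way an image-analysis pipeline would, and reports the
miscount. It is aimed at radiation biologists and microscopists who want
error bars on foci-based dosimetry, and at modellers who need to compare
simulated DSB yields against foci data on equal terms.

## What is simulated

1. **Nuclear geometry** — a flattened ellipsoid (semi-axes
   11.8 × 11.8 × 1.0 μm) packed with spherical beads, one per TAD
   (topologically associating domain), each carrying a genomic interval.
2. **Damage induction** — photons: DSB count per nucleus
   ~ Poisson(30 × dose), distributed over chromosomes ∝ length and beads ∝
   genomic content; protons: straight tracks whose energy depositions
   convert to strand breaks via a 14.1% chromatin-sampling factor and a
   linear energy ramp (probability 0 at 5 eV → 1 at 37.5 eV), with
   opposite-strand breaks within 3.2 nm (≡ 10 bp) paired into DSBs.
   Damage can be exported/imported in the Standard DNA Damage (SDD)
   format.
3. **Repair kinetics** — one bi-exponential law for every radiation
   quality,

   ⌈N(t)⌉ = N₀ (a₁ e^(−t/τ₁) + a₂ e^(−t/τ₂)),  a₁ = 0.711, a₂ = 0.289,
   τ₁ = 1.54 h, τ₂ = 10 h,

   so that any difference in *perceived* kinetics is attributable to
   miscounting alone.
4. **Marker fields** — direct marker: one point source per surviving DSB;
   γ-H2AX marker: histones placed in damaged TADs (10% H2AX variant
   fraction, 2 H2A copies per 146-bp nucleosome) and activated by a
   Cauchy–Lorentz curve of genomic distance d (Mbp):

   Activation = 0.23 + 0.38 / (1 + 4 (d / 0.45)²),

   additive across breaks and restricted to the break's own TAD.
5. **Microscope emulation** — a registry of 24 (microscope, magnification)
   configurations with published pixel spacings and numerical apertures;
   Gaussian PSFs (σ_xy = 0.21 λ/NA, σ_z = 0.66 λn/NA²); 3D convolution
   with out-of-plane light; single z-slice or full z-stack output; a
   "perfect deconvolution" mode; TIFF export.
6. **Foci counting** — scale-space Laplacian-of-Gaussian blob detection
   (direct marker: min_sigma 2, max_sigma 20, num_sigma 1, threshold 8%;
   γ-H2AX: 2/20/3/4%), thresholds anchored at each set-up's 15-min image
   maximum, identical parameters in 2D and 3D.
7. **Metrics** — miscount (counted − simulated-in-slice), symmetric
   percentage miscount `(counted − simulated)/((counted + simulated)·0.5)·100`,
   a 200-nm clustering metric, kinetics normalisation to 15 min, and
   Mann–Whitney comparisons with Bonferroni correction.

## Worked example

A 2 Gy photon exposure imaged 15 min later with an Airyscan ×63:

```r
library(focisim)

genome   <- build_genome(seed = 1)            # reduced 600 Mbp genome
geometry <- pack_geometry(genome, seed = 2)   # ~600 TAD beads in the nucleus
dsbs     <- induce_photon_damage(geometry, dose_gy = 2, seed = 3)
timeline <- schedule_repair(dsbs, seed = 4)
vapply(timeline$surviving, length, 1L)
#>  0.00  0.25  0.50  2.00  6.00 24.00
#>    52    47    42    23     9     2

config <- registry_lookup("Airyscan", 63)
psf    <- synthetic_psf(config)
surv   <- surviving_dsbs(timeline, 0.25)
image  <- render_image(direct_marker_field(surv, time_h = 0.25),
                       geometry, config, psf, mode = "slice")
foci   <- detect_foci(image, log_params_for_marker("direct"),
                      reference_max(list(image)))
sim    <- dsbs_in_slice(surv, 0, config$z_spacing_um)
c(simulated = sim, counted = foci$count,
  pct_miscount = percent_miscount(foci$count, sim))
#>    simulated      counted pct_miscount
#>       4.0000      41.0000     164.4444
```

The nucleus drew 52 DSBs (Poisson mean 60); 47 survive at 15 min, of which
4 sit inside the single 0.12-μm z-slice — but the detector reports 41
foci, because the 3D PSF pulls fluorescence from breaks in neighbouring
planes into the evaluated slice. Rendering with `deconvolved = TRUE`
removes the out-of-plane light and collapses the count back towards the
in-slice truth; conversely, clustered high-LET damage
(`induce_track_damage(geometry, 2, let_kev_per_um = 27.95, ...)`) pushes
the miscount negative as merging spots become indistinguishable.
`run_pipeline(demo_matrix())` executes the whole grid (5 geometries ×
2 doses × 2 markers × 6 time points) and returns the tidy results table;
`inst/cli/focisim.R` exposes the same machinery on the command line.

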