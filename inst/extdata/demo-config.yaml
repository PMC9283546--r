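# focisim run configuration (annotated example, desk scale).
# Any key may be omitted; the run-matrix defaults then apply.

n_geometries: 5          # number of synthetic nuclear geometries
seed: 1                  # master seed; all stage seeds derive from it

radiation:               # one entry per radiation set-up
  - radiation: Co-60     # photon model (Poisson, 30 DSB/Gy)
    let_kev_um: ~        # ~ (null) selects the photon model
    dose_gy: 1.0
  - radiation: Co-60
    let_kev_um: ~
    dose_gy: 2.0

microscopes:             # must exist in the registry (registry_all())
  - microscope: Airyscan
    magnification: 63

time_points_h: [0.0, 0.25, 0.5, 2.0, 6.0, 24.0]
markers: [direct, gh2ax] # direct = Ku/DNA-PKcs; gh2ax = gamma-H2AX

mode: slice              # slice (single z-plane) or stack (3D)
z_center_um: 0.0         # evaluated plane, um from the nuclear mid-plane
deconvolved: false       # true renders without the microscope PSF
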