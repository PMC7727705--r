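# gpcrdyn

Quantifying the fast equilibrium dynamics of membrane proteins from
solid-state NMR observables and molecular-dynamics trajectories.

Class A G-protein-coupled receptors are strikingly mobile molecules even
within a single activation state: their backbone C–H bond vectors fluctuate
with amplitudes of tens of degrees on the ns–µs time scale. Two complementary
windows onto these motions are (i) solid-state NMR of the uniformly labeled
receptor in lipid membranes — static CSA powder patterns, cross-polarization
(CP) buildup, and separated-local-field (DipShift) dipolar dephasing under
magic-angle spinning — and (ii) long all-atom MD trajectories, which add the
site resolution the spectra lack. `gpcrdyn` implements both analysis arms,
plus a seeded synthetic-data generator with analytically known ground truth
so every stage is testable without spectrometer or supercomputer output.

## What it computes

**NMR side**

- `simulate_csa_powder()` / `deconvolve_static_spectrum()` — static powder
  lineshapes of span Δσ and asymmetry η, and their least-squares
  decomposition into isotropic (mobile) and anisotropic (rigid) pools with
  quantified areas.
- `is_model_intensity()`, `fit_cp_buildup()`, `optimum_contact_time()` — the
  two-pool *I–S* CP buildup model
  `I(t) = I0 (e^{-t/T1ρ} − e^{-t/T_IS}) / (1 − T_IS/T1ρ)`, yielding the
  transfer time `T_IS`, the rotating-frame relaxation time `T1ρ`, and the
  true mobile fraction `I0_iso / (I0_iso + I0_aniso)`.
- `simulate_dephasing()` / `fit_dipolar_coupling()` — powder-averaged
  dipolar dephasing over one MAS rotor period (FSLG-scaled), fitted for the
  motionally averaged coupling; the order parameter is
  `S = coupling / rigid limit` per group class (CH, CH2, CH3).
- `cone_semi_angle()` — converts S to the wobbling-in-a-cone motional
  amplitude by inverting `S = cos θ (1 + cos θ) / 2`.

**MD side**

- `residue_CH_order()` / `remove_global_motion()` — per-residue Cα–Hα order
  parameters from trajectories, raw (`S_total`) or after rigid-body
  superposition onto the starting structure (`S_internal`).
- `builtin_y1r_segments()`, `fit_line_axis()`, `fit_cylinder_axis()`,
  `segment_orientation_series()` — the Y1R segment registry and per-frame
  segment axes (variance-of-radii cylinder criterion for TM helix halves,
  total-least-squares line for loops, termini, Helix 8).
- `order_parameter_total()`, `p2_acf()`, `fast_slow_split()`,
  `fit_acf_monoexp()`, `decompose_motion()` — P2 orientation autocorrelation
  analysis: `S_total`, the fast/slow factorization
  `S_total² = S_fast² · S_slow²` (motions faster than the first ACF lag
  count as fast), and the correlation time τ from a monoexponential fit with
  the plateau fixed at `S_total²`.
- `welch_ttest()`, `paired_ttest()`, `summarize_segments()` — the replica
  statistics used to compare receptor states.

**Synthetic ground truth** — `gen_cone_orientations()`,
`gen_composite_orientations()`, `gen_helix_trajectory()`, `gen_cp_curve()`,
`gen_dephasing_curve()`, `gen_powder_spectrum()`: seeded generators whose
outputs have closed-form expected values (cone order parameter
`S = cos θc (1 + cos θc)/2`, product rule, I–S law, rotor echo), used
throughout the test suite.

## Worked example

```r
library(gpcrdyn)

# motional amplitudes implied by backbone order parameters of 0.57 and 0.67
cone_semi_angle(c(0.57, 0.67))
#> [1] 47.23581 40.45180        # i.e. cone semi-angles of 47 and 40 degrees

# a composite fast+slow segment motion with known truth S_fast=0.9, S_slow=0.8
spec <- composite_spec(
  cone_spec(cone_semi_angle(0.9), tau = 0.5, dt = 1, n_frames = 2e5),
  cone_spec(cone_semi_angle(0.8), tau = 100, dt = 1, n_frames = 2e5),
  seed = 11)
series <- gen_composite_orientations(spec)
decompose_motion(series, max_lag = 2000)
#> Order decomposition 'composite fast+slow cone'
#>   S_total = 0.7197  (S_fast = 0.8983, S_slow = 0.8012)
#>   ACF fit: A = 0.2835, tau = 99.54 ns

# a noisy DipShift curve at S = 0.57 x rigid limit, fitted back
curve <- gen_dephasing_curve(0.57 * 21.5, mas_kHz = 5, noise_sd = 0.01, seed = 7)
fit_dipolar_coupling(curve)
#> DipShift coupling fit (CH, rigid limit 21.5 kHz)
#>   coupling = 12.128 kHz, S = 0.564, cone semi-angle = 47.6 deg
```

The decomposition recovers the constructed fast/slow order parameters within
the sampling error of a 200 µs series, and the dephasing fit returns the
generating coupling to ~1% despite the added noise — the amplitude of the
backbone motion (the cone semi-angle) follows directly.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models, the
estimators, the synthetic generators and their calibration, numerical
choices, and known limitations.
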