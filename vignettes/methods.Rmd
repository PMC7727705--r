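---
title: "Models and methods behind gpcrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpcrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gpcrdyn` quantifies the fast (ns to tens of µs) equilibrium dynamics of
membrane proteins from two directions: solid-state NMR observables of the
uniformly labeled protein in lipid membranes, and segment- or
residue-resolved analysis of molecular-dynamics trajectories. This vignette
documents the models, the estimators, the synthetic generators that provide
ground truth, and the numerical decisions a user or maintainer should know
about.

## Order parameters and the cone model

A second-rank order parameter S describes the orientational averaging of a
bond or segment axis: S = 1 for a rigid vector, S = 0 for isotropic motion.
For diffusion inside a cone of semi-angle θc with uniform equilibrium
density over solid angle, the closed form is

    S = cos θc (1 + cos θc) / 2.

`cone_semi_angle()` inverts this via cos θ = (−1 + √(1 + 8S)) / 2; the
inversion and the forward form are exact inverses to 1e−10 (tested). This is
how a measured backbone order parameter translates into a motional
amplitude: S = 0.57 corresponds to a 47° cone, S = 0.67 to 40°.

## Static CSA powder lineshapes (`powder_lineshape`)

Static spectra of a uniformly labeled membrane protein are a superposition
of narrow isotropic lines (mobile sites) and a chemical-shift-anisotropy
powder pattern (rigid sites). The pattern is parametrized by its span Δσ
(ppm, edge-to-edge for η = 0), asymmetry η ∈ [0, 1], isotropic shift, and a
Gaussian broadening; internally the reduced anisotropy δ = 2Δσ/3 gives
principal values iso + δ and iso − δ(1 ± η)/2.

*Orientation averaging* uses a deterministic golden-spiral (Fibonacci)
lattice on the sphere, default 10⁴ points, rather than Monte-Carlo sampling:
results are reproducible and converge smoothly (area changes < 0.5% on grid
doubling, tested). The ~15° tilt of the CSA tensor relative to the N–H bond
is not modeled explicitly; η is a free lineshape parameter, which is how
such spectra are fitted in practice.

*Deconvolution* (`deconvolve_static_spectrum()`) is Levenberg–Marquardt
least squares over a configurable list of Gaussian isotropic lines plus one
powder pattern. Areas, line widths, span and broadening are free (η
optionally); line positions and the pattern's isotropic shift come from the
initial guess. Positivity is enforced by log-parametrization. Because the
powder forward model is a histogram, the finite-difference Jacobian uses an
enlarged step (`epsfcn = 1e-6`) — with the default step the span parameter
sees a flat gradient and never moves. Non-convergence is flagged in the
result (`flag = "not_converged"`), never silently ignored. An all-zero
spectrum is an error. Noiseless mixtures with isotropic fractions 0–0.5 are
recovered within 1% absolute (tested).

## CP buildup and the I–S model (`cp_buildup`)

Cross-polarization transfers ¹H magnetization to the rare spin at a rate set
by the dipolar coupling, so CP spectra over-represent rigid sites. Fitting
the contact-time dependence of the isotropic and anisotropic areas with the
two-time-constant I–S law

    I(t) = I0 (exp(−t/T1ρ) − exp(−t/T_IS)) / (1 − T_IS/T1ρ)

yields the transfer time T_IS, the rotating-frame relaxation time T1ρ, and —
from the fitted equilibrium amplitudes — the true mobile fraction
I0_iso/(I0_iso + I0_aniso). The removable singularity at T_IS = T1ρ is
evaluated through its continuous limit I0 (t/T_IS) e^{−t/T_IS}. The
closed-form optimum contact time is t* = ln(T1ρ/T_IS)/(1/T_IS − 1/T1ρ).

The two pools are fitted fully independently (three parameters each). The
I–S law is symmetric under exchanging T_IS and T1ρ, which creates a mirror
local minimum; the fit multistarts over log-spaced initial time constants
and reports the physically ordered branch (T_IS < T1ρ). Standard errors come
from the Jacobian at the optimum. Fewer than four contact times, or all-zero
intensities, are errors.

A note on attainable precision: with 8 contact times spanning 0.05–8 ms and
2% Gaussian noise, the asymptotic (Cramér–Rao) relative standard errors of
the time constants are 6–7%. The least-squares fit attains essentially this
bound, so the test suite asserts the recovery *scale* (RMS error over 100
seeded replicates ≤ 10% per time constant) rather than a per-replicate
bound, which no estimator could guarantee at that design. The mobile
fraction is much better determined (within 0.02 per replicate).

## DipShift dephasing under MAS (`dipshift`)

The separated-local-field (DipShift) experiment records signal dephasing
under the ¹H–¹³C dipolar coupling across one rotor period. For a crystallite
whose coupling tensor has polar angles (β, γ) in the rotor frame, the
instantaneous frequency under magic-angle spinning is the standard
second-harmonic modulation

    ω(t) = (δ/2) [ √2 sin 2β cos(ωr t + γ) + sin²β cos(2ωr t + 2γ) ],

whose time integral is analytic, so the accumulated phase needs no numerical
quadrature. The observed intensity is the powder average of cos(phase),
computed over the same deterministic spiral grid as the lineshape module. At
t1 = 0 and t1 = one rotor period the phase integral vanishes identically —
the rotor echo — and the simulated intensity returns to 1 up to grid error
(< 1e−3 at the 10⁴-point default, tested). The simulation is cross-checked
in the tests against an independent Monte-Carlo powder average with
trapezoid phase integration (10⁵ random crystallites).

Conventions and constants:

* **Rigid limits** default to CH 21.5 kHz, CH₂ 21.5 kHz per bond, CH₃
  7.2 kHz (pre-averaged by fast methyl rotation); all configurable via
  `rigid_limits()`. Order parameters are S = fitted coupling / rigid limit.
* **FSLG scaling** defaults to the theoretical 1/√3 ≈ 0.577 and can be
  overridden by an experimental calibration.
* **Multi-proton groups**: CH₂ dephasing is the product of two independent
  per-bond dephasings at the tetrahedral angle; CH₃ (after methyl
  pre-averaging) the product of three identical couplings along the C3
  axis. The independent-proton product is a standard approximation — it
  neglects ¹H–¹H flip-flop terms surviving homonuclear decoupling.
* **Constant-time variant**: relaxation during t1 is assumed refocused;
  only pure dephasing is modeled.

`fit_dipolar_coupling()` is a one-parameter least-squares fit over the
coupling (golden-section search on [0, 1.4 × rigid limit]); couplings
round-trip within 0.5% across 2–21.5 kHz (tested). Fits implying S > 1.05
are flagged. The fitted S is converted to a cone semi-angle as above.

## Segment axes (`segment_geometry`)

Segment orientations are defined by axes fitted to Cα positions per frame:

* **Line fit** (loops, termini, Helix 8): total least squares — the first
  principal component through the centroid. Requires ≥ 3 non-coincident
  points.
* **Cylinder fit** (TM helix halves): minimizes the *variance* of the
  point-to-axis distances, Σᵢ(dᵢ − d̄)². A least-squares line through
  helical Cα positions tilts systematically toward the end residues; the
  cylinder criterion is immune to this because helix Cα atoms lie on a
  cylinder. The axis is parametrized by two spherical angles plus an
  in-plane center (4 parameters), initialized from the line fit with the
  center seeded by an algebraic (Kåsa) circle fit, and multistarted from ±7°
  angular perturbations because short arcs have local minima. Requires ≥ 5
  non-collinear points; collinear input is an error directing the caller to
  the line fit. On ≤ 8 points the optimizer agrees with an exhaustive
  1°-grid search within 0.5° (tested).

The axis sign follows the N→C convention (positive projection of last minus
first residue); `segment_orientation_series()` additionally enforces
frame-to-frame sign continuity. The sign matters because the mean-vector
order parameter is not sign-invariant even though the P2 ACF is.

The built-in Y1R registry (`builtin_y1r_segments()`) lists the seven TM
helices split at their kinks into extracellular/intracellular halves, loops
split into sub-segments of similar length, both termini and Helix 8, with
1-based inclusive residue ranges on the numbering of PDB entry 5ZBQ.
Residues falling between sub-segments (e.g. 171) stay unassigned, as
defined. Segment class is fixed by the registry — partial unfolding during a
simulation does not change the fit type.

## Per-residue order parameters (`trajectory_order`)

`residue_CH_order()` tracks the Cα–Hα unit vector u_t of each residue and
computes S from the time-averaged second-rank tensor: with
Q_t = (3 u_t u_tᵀ − I)/2,

    S = sqrt( (2/3) Σᵢⱼ ⟨Q⟩ᵢⱼ² ).

For uniaxial averaging this equals the motionally averaged coupling ratio
measured by DipShift. Because the residual tensor can in principle be
biaxial, a second estimator (`estimator = "dipshift"`) forward-simulates the
MAS dephasing of the averaged coupling tensor and fits an axially symmetric
coupling to it, mirroring the experimental analysis; the two agree within
0.02 for uniaxial synthetic motions (tested) and neither is silently
preferred.

Hα atoms are used when present; for Cα-only topologies the bond is rebuilt
along the local radial direction Cα_i − midpoint(Cα_{i−1}, Cα_{i+1}), which
moves rigidly with the backbone (chain ends are skipped). Glycine's two Hα
bonds are averaged. Values marginally above 1 from numerical noise are
clipped with a warning.

`remove_global_motion()` superposes every frame onto a reference frame by
rigid-body least squares over the Cα atoms (Kabsch, via `bio3d::fit.xyz`);
order parameters computed after alignment are internal order parameters.
Alignment is idempotent and reduces a purely rigid-body trajectory to its
reference frame exactly (tested).

## ACF analysis and fast/slow decomposition (`motion_decomposition`)

For an orientation series v_t:

* `order_parameter_total()`: S_total = ⟨3 (v̂_t · v̄̂)² − 1⟩/2 with v̄ the
  normalized arithmetic mean vector. If |v̄| < 1e−6 (no preferred
  direction, e.g. symmetric jumps) the dominant eigenvector of the averaged
  tensor is used instead and the result flagged — the mean-vector formula is
  undefined for symmetric distributions.
* `p2_acf()`: ACF(k) = ⟨3 (v̂_t · v̂_{t+k})² − 1⟩/2 over all valid frame
  pairs. The default path expands the square into the six unique
  outer-product components and evaluates their correlations by FFT — exactly
  equal (to 1e−10, tested) to the direct double loop, which remains
  available as `method = "direct"` for oracle comparison.
* `fast_slow_split()`: motions faster than the first lag (default 1 ns, the
  time resolution at which segment ACFs are evaluated) appear as the initial
  drop of the ACF, so S_fast = √ACF(first lag); assuming fast and slow
  motions are independent, S_total² = S_fast² · S_slow² gives
  S_slow = S_total/S_fast. When noise pushes ACF(first lag) below S_total²
  the split is clamped to S_fast = S_total, S_slow = 1 and flagged — this
  preserves the product identity without an unphysical S_slow > 1. A
  negative ACF at the first lag is an error.
* `fit_acf_monoexp()`: least squares of A·e^{−t/τ} + S_total² with the
  plateau fixed at the known S_total², two free parameters, Nelder–Mead on
  (A, log τ), fitted over the first third of the available lags only (long
  lags are noisy). A flat ACF (excess < 1e−4) yields A = 0 with τ undefined
  and flagged. Exact exponentials with τ of 10–5000 ns are recovered within
  1% (tested).

Replica statistics: `welch_ttest()` implements the two-sided Welch test from
summary statistics with Welch–Satterthwaite degrees of freedom (no installed
function accepts summaries); `paired_ttest()` delegates to `stats::t.test`
on the within-pair differences. Zero-variance degeneracies have fixed
conventions (equal means → p = 1; nonzero constant difference → flagged,
p → 0). P-values are two-sided throughout; directional claims should be read
accordingly. `summarize_segments()` averages per segment over runs, then per
topological class over segments, matching how segment-resolved results are
reported.

## The synthetic generators and their calibration

The generators produce data with the statistical structure the analyses
assume, with known ground truth:

* **Cone diffusion** (`gen_cone_orientations()`): a geodesic random walk on
  the unit sphere with a reflecting boundary at θc, started from the
  equilibrium density (cos θ uniform on [cos θc, 1]). Small tangential
  Gaussian steps of per-axis sd s give diffusion D = s²/(2 dt). The walk's
  equilibrium is uniform over solid angle within the cone
  (Kolmogorov–Smirnov-tested in the small-step regime).

  *Timescale calibration.* The requested τ is defined operationally as the
  decay time recovered by `fit_acf_monoexp()`. The cone ACF is
  multi-exponential; its integral effective time is the closed-form
  wobbling-in-a-cone result τ_eff D (1 − S²) = g(cos θc). The
  monoexponential-fit time exceeds the integral time by a small,
  angle-dependent factor (1.01–1.05 for θc between 20° and 75°), measured
  once from long fine-step simulations (2 × 10⁶ frames, τ ≈ 100 dt) and
  frozen as an interpolation table in the source. D is then set to
  (calibration × g(cos θc)) / ((1 − S²) τ). At the study conditions
  (θc ∈ {20°, 40°, 47.2°, 60°}, τ ∈ {10, 100, 1000} frames, 10⁶ frames) the
  fitted τ lands within 8% of the request and S within 0.007 of the closed
  form (tested at a 15% / 0.01 tolerance).

  *Discretization caveat.* When τ is within ~5 dt the reflecting boundary
  introduces a percent-level distortion of the stationary density near θc
  (the step size is no longer small against the cone). This is invisible at
  the S tolerances above but detectable by a KS test on thousands of
  decorrelated draws, which is why the equilibrium test runs at τ = 50 dt.

* **Composite motion** (`gen_composite_orientations()`): an independent fast
  cone wobble carried on a slow cone axis (the fast vector is rotated onto
  the instantaneous slow axis by the minimal rotation from +z). When
  fast τ ≤ dt the fast wobble is drawn i.i.d. from the cone equilibrium each
  frame — it is then exactly decorrelated between frames, which is the
  regime the fast/slow split assumes. Ground truth
  S_total = S_fast × S_slow by independence.

* **Helix fixture** (`gen_helix_trajectory()`): ideal α-helix Cα geometry
  (rise 1.5 Å, twist 100°, radius 2.3 Å by default) rotated rigidly so its
  cylinder axis follows a driving orientation series, with pseudo-Hα atoms
  placed radially so bond vectors move with the body. Trajectories
  round-trip through multi-model PDB files.

* **NMR curves** (`gen_cp_curve()`, `gen_dephasing_curve()`,
  `gen_powder_spectrum()`): the corresponding forward models plus additive
  seeded Gaussian noise — the simplest model consistent with spectral noise
  floors. All generators are bit-reproducible for a fixed spec and seed.

What the generators deliberately do **not** emulate: force-field physics,
lipid/water environments, spectral artifacts (baseline roll, phase errors,
t1 noise), inhomogeneous broadening beyond a Gaussian, or µs-intermediate
motions that would make dephasing curves decay over the rotor period (the
fast-limit averaged coupling is assumed). Passing tests therefore
demonstrate correctness of the estimators under the stated models, not
robustness to every artifact of real data.

## Units, defaults, problem sizes

Coordinates are Å; trajectory times ns; contact times µs; relaxation and
rotor periods ms internally, with `T1ρ` printed in ms; frequencies kHz;
chemical shifts ppm. Key defaults: orientation grids 10⁴ (warnings below
10³); DipShift t1 grid 16 intervals per rotor period; ACF first lag 1 ns;
monoexponential fit window one third of available lags; FSLG scaling 1/√3;
rigid limits CH/CH₂ 21.5 kHz, CH₃ 7.2 kHz.

The test suite exercises the full stack at 10⁶-frame series for the cone
recovery sweep, 10⁵–2 × 10⁵ frames for equilibrium and decomposition
properties, 100 noisy replicates for CP recovery, and 500-frame inputs for
exact oracle equivalence of the ACF paths — sizes chosen so the complete
suite runs in a few minutes on one CPU while keeping sampling error well
inside each tolerance.

## Known limitations

* The cone walk's reflecting boundary slightly distorts the stationary
  density when τ approaches dt (see above); treat series with τ < 5 dt as
  qualitative.
* The CH₂/CH₃ product-of-cosines dephasing ignores residual homonuclear
  couplings; fitted multi-proton couplings inherit that approximation.
* The mean-vector S_total estimator is biased upward by sampling noise of
  v̄ for short series (the bias decays with the number of independent
  frames); the tensor-based fallback is used only in the degenerate case.
* `fit_cp_buildup()` assumes exactly two independent pools; spin diffusion
  between pools is not modeled.
* Segment membership is positional; no secondary-structure re-detection is
  performed.
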