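---
title: "Methods: base-pair opening free-energy landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-pair opening free-energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscape)
```

# The model

A DNA base pair opening into the minor groove is described locally by two
*simple* base-pair parameters: Opening σ′ (a rotation about the pair
normal, degrees; negative values move the glycosidic edge toward the minor
groove) and Shear S′ₓ (a translation along the pair's short axis, Å, which
accompanies hydrogen-bond reorganization in mismatches). The free-energy
surface ΔG_r(σ′, S′ₓ) — relative to the most stable state — is estimated
from streams of (CV value, instantaneous generalized force) samples by
adaptive-biasing-force (ABF) style accumulation, integrated by Gaussian
process regression (GPR), and reduced to a 1D opening profile

$$\Delta G_w(\sigma') = -RT \ln \int e^{-\Delta G_r(\sigma', S'_x)/RT}\, dS'_x ,$$

re-referenced so its minimum is zero. The propensity for opening is
ΔG_w(Δσ′) on the axis Δσ′ = σ′ − σ′(global minimum), evaluated at
Δσ′ = −60° (the average experimentally observed opening in recognition
complexes), and the *discrimination gap* is the difference between a
canonical pair's and a mismatch's propensity, with errors combined in
quadrature. R = 0.0019872041 kcal mol⁻¹ K⁻¹ and T = 300 K throughout, so
0.5RT = 0.298 kcal/mol is the thermodynamic-state membership window.

# Base-pair frame algebra

Frames are fitted to base ring heavy atoms by Kabsch superposition of
embedded standard reference bases (standard-frame convention: origin at the
pair center, x toward the major groove, y along the pseudo-dyad; the
constants are the community-standard reference coordinates, embedded as
literals so no external geometry tool is required). Two design points
deserve explanation:

* **The syn transformation.** For a base in the *syn* glycosidic
  orientation the Watson–Crick edge faces away from the partner, so the
  fitted standard frame is composed with a 180° rotation about its own
  z-axis (and flagged). This is the documented fallback transformation; it
  restores the meaning of Opening/Shear for anti/syn and syn/anti pairs,
  and round-trips exactly through the coordinate builder.

* **Mid-frame decomposition.** Pair parameters use the hinge construction:
  flip the complementary frame 180° about its own x-axis, rotate both
  frames onto their common z by ±γ/2 about the hinge z₁×z₂, read Opening as
  the in-plane angle between the y axes, define the mid-frame y as their
  bisector, and decompose the bend γ into Buckle/Propeller by the hinge's
  mid-frame components; translations are mid-frame components of the
  origin difference (b minus a). This construction is *exactly* invertible
  — the builder `build_base_pair()`/`build_duplex()` is its inverse, and the
  build→measure round trip recovers 200 random parameter sets to 1e−6
  (asserted in the tests). Degenerate inputs: anti-aligned z axes (γ >
  179°) are refused; a vanishing hinge (γ ≈ 0) falls back to pure-twist
  decomposition.

* **Strand-swap symmetry.** With this (standard) convention, swapping the
  two bases negates Shear and Buckle and preserves Stretch, Stagger,
  Propeller and Opening. Opening *cannot* be odd under the swap: the
  pure-Opening configuration is congruent to its own strand swap by a
  proper rotation, and the parameters are rigid-motion invariant, so any
  implementation with both properties must leave Opening unchanged. The
  property test asserts this corrected invariant.

Glycosidic classification uses χ = O4′–C1′–N9–C4 (purines) or
O4′–C1′–N1–C2 (pyrimidines), IUPAC sign, wrapped to (−180°, 180°]; |χ| <
90° is *syn* (≈ +70°), otherwise *anti* (≈ −120°).

**Hydrogen bonds.** Donor–acceptor heavy-atom distance plus, when a
hydrogen is present, a donor–H⋯acceptor angle ≥ 135°. The MD-trajectory
convention of 3.0 Å sits exactly on the longest idealized Watson–Crick
contacts of the rigid standard-base geometry (G:C N1⋯N3 at 3.001 Å, A:T
N6⋯O4 at 3.023 Å — averages over ensembles fall below 3.0, a single
idealized structure does not), so the package default is 3.1 Å; both
cutoffs are arguments.

# Mean forces and GPR integration

Per-bin force statistics use the one-pass Welford scheme; walkers merge by
Chan–Golub–LeVeque pooling, which is exactly equivalent to accumulating
the concatenated stream (asserted to 1e−12). The statistical inefficiency
g = 1 + 2Στ ρ_τ (sum truncated at the first negative autocorrelation;
FFT autocovariance) inflates the per-bin noise variance of the mean force
to s²g/n; the blocking estimator is the cross-check. The truncation rule
is the simple documented one; it is noisy on strongly correlated series
(for AR(1) with φ = 0.9 at n = 10⁵ roughly 1 seed in 30 lands outside
±15% of the exact value 19).

The latent potential G carries a zero-mean GP prior with an anisotropic
squared-exponential kernel (per-dimension length scales in CV units,
signal sd in kcal/mol); periodic CV dimensions use the wrapped variant
exp(−2 sin²(πΔ/P)/ℓ²). The observations are the bin-center mean *forces*
(gradient observations −∇G), not raw samples, keeping the covariance at
(dims × sampled bins)². Hyperparameters maximize the log marginal
likelihood by multi-start L-BFGS-B on log parameters with the analytic
gradient (validated against central finite differences to better than
1e−4 relative). A jitter ladder 1e−10…1e−6 (relative to the mean kernel
diagonal) guards the Cholesky; failure past the ladder is an error naming
the level reached.

The posterior mean is evaluated at every bin center and referenced to the
minimum over unmasked bins (bins with fewer than 10 effective samples n/g
are masked by default). **Error convention:** the reported stderr is 3 ×
the posterior standard deviation *of the referenced value* G(x) −
G(x_min), computed from the full posterior covariance against the
reference bin. This makes the reference bin's error exactly zero —
consistent with "relative to the most stable state" — and gives honest 3σ
bands: on the noisy two-well oracle the band covers the analytic truth in
more than 95% of bins over 20 seeds (acceptance criterion 5). A constant
offset in a GP prior is otherwise unidentifiable from gradients alone, so
unreferenced posterior variances would be inflated by that arbitrary
constant.

# Reduction, states, gap

The Boltzmann reduction uses a log-sum-exp over composite-trapezoid
weights along the integrated axis (the quadrature rule is a package
decision; the integration runs over the full Shear range, not a per-column
window). It is exact for separable surfaces and reproduces the RT·ln 2 =
0.413 kcal/mol entropic offset between Gaussian wells of stiffness ratio
4. Errors propagate by the delta method with normalized Boltzmann
weights, stderr(x) = √(Σ_y w² stderr²); fully masked columns give masked
profile bins.

Minima are bins strictly below all unmasked 8-neighbors (periodic wrap
where applicable), pruned by topological persistence with a 0.5 kcal/mol
barrier (the labeled-minima convention gives no pruning rule; persistence
is the standard deterministic choice), boundary bins excluded on
non-periodic edges unless requested. State membership combines the ≤
0.5RT window with steepest-descent basin assignment (ties to the lowest
bin index); representatives are plain superpose-then-average structures —
no force-field regularization, which is out of scope.

The profile minimum used as the Δσ′ reference is refined by three-point
parabolic interpolation: with ~8° bins, snapping the reference to a bin
center shifts the −60° evaluation by up to half a bin and biases the gap
by several tenths of a kcal/mol; sub-bin refinement removes almost all of
it. Propensities at −60° are linear interpolations between the adjacent
bins (the evaluation point falls between centers; the choice is a package
decision), stderr interpolated likewise. Gap arithmetic is done on
unrounded values; when validating against printed tables the inputs are
the printed (rounded) numbers, where quadrature of rounded errors can
differ from a printed ±0.01.

# The synthetic world

The generator stands in for force-field MD; its defaults are fixed once:

* `canonical_like`: one basin at (0, 0), a bowl asymmetry (tanh switch,
  scale 25°) making the minor-groove side (σ′ < 0) steeper — one deep
  canonical state.
* `mismatch_like`: a gentle bowl plus five Gaussian wells (depths
  5.4…2.4 kcal/mol, widths 10° × 0.45 Å); brute-force grid search at
  0.5° × 0.05 Å finds exactly five minima, and the saddle separating the
  Shear-displaced wells from the global minimum sits at ≈ 5.4 kcal/mol,
  the stated scale of Shear barriers in mismatch landscapes.
* Sampler: overdamped Langevin (Euler–Maruyama), x′ = x + hF + √(2RT h)ξ,
  per-dimension mobility h, reflecting walls at the domain edges
  (wrapping on periodic dimensions). Only the stationary distribution
  matters downstream, so inertial dynamics is not modeled. Discretization
  biases the harmonic-well variance by 1/(1 − hk/2) ≈ 0.25% at the
  default step; equipartition holds within 5% and a thinned
  Kolmogorov–Smirnov test against the Boltzmann marginal passes for 19/20
  seeds. The recorded instantaneous force is −∇V plus optional AR(1)
  noise (default sd 2 kcal/mol/unit — of the order of the surface's own
  force scale; the AR(1) knob exists to exercise the inefficiency
  estimators). The ABF-like bias subtracts the running per-bin mean of
  the recorded forces, ramped linearly over the first 200 samples per
  bin; walkers run sequentially and share the accumulator
  (multiple-walker style). All noise is pre-generated from the R RNG, so
  a seed fixes the trajectory bit-for-bit.

What a green end-to-end test establishes: that the chain
sampler → accumulate → merge → GPR → reduce → gap recovers the gap of a
*known* landscape within its own 3σ in at least 8 of 10 seeds. What it
does not establish: anything about real DNA energetics — the synthetic
basins are qualitative stand-ins, MD-derived propensities for real sequences
(which require tens of microseconds of force-field sampling) are not
reproduced here, and the demo gap (~9 kcal/mol) is intentionally larger
than the few-kcal/mol gap expected for real DNA.

# Known limitations

* Base frames require all ring heavy atoms; modified or RNA nucleotides,
  sugar-pucker and backbone torsions beyond χ are out of scope.
* The duplex builder places bases, C1′ and an O4′ (to close χ); it does
  not build the full sugar–phosphate backbone, so backbone-selection CVs
  (δ) apply to externally supplied coordinates.
* The φ₁/φ₂ center-of-mass groups are configuration with documented
  defaults; the original atom groupings are defined pictorially in their
  sources and are not claimed verbatim.
* The GP noise model treats bins independently and forces within a bin as
  exchangeable; occupancy-weighted binning bias (samples are not uniform
  within a bin) is not corrected and is visible as a small residual bias
  at coarse grids.
* Config files are JSON rather than YAML (no YAML parser in the
  supported dependency set); the structure is identical.
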