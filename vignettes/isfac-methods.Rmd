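---
title: "Ionic scattering factor refinement: model, protocols and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionic scattering factor refinement: model, protocols and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isfac)
```

## The physical model

X-rays scatter from electron density; electrons scatter from the Coulomb
potential. A net-charged atom perturbs the potential of its surroundings
far more strongly than it perturbs the electron density, which is why
electron diffraction data are sensitive to partial charges at ordinary
resolution and data quality, while X-ray charge-density work needs
exceptional data. `isfac` exploits this by refining, for every atom, the
fraction of an *ionic* electron scattering factor mixed into its neutral
one.

### Ionic electron scattering factors

The electron scattering factor of a (possibly nonphysical) ion is obtained
from the charge-offset form of the Mott–Bethe relation,

$$f(s) \;=\; \frac{1}{8\pi^2 a_0}\,
  \frac{Z_0 + \Delta Z - f_X(s)}{s^2},$$

with $s = \sin\theta/\lambda$ (Å⁻¹), $a_0 = 0.529177210903$ Å the Bohr
radius (prefactor $1/(8\pi^2 a_0) = 0.02393366$ Å⁻¹), $Z_0$ the neutral
atomic number, $\Delta Z$ an integer charge offset, and $f_X$ the X-ray
form factor of the **neutral** atom. Using the neutral $f_X$ with an
explicit $\Delta Z$ has two virtues: ions with no tabulated X-ray form
factor (C⁻, N⁺, O⁺ …) are available uniformly, and the difference between
an ion and its neutral atom is *exactly* $K\,\Delta Z/s^2$, so the charge
signal is concentrated at low resolution and decays smoothly — while a
constant offset between the curves survives to high resolution, which
helps stability. For charged species $f(s) \to \pm\infty$ as $s \to 0$
with the sign of $\Delta Z$; curves are therefore never evaluated below
the low-resolution edge of the working window, and the $s = 0$ term of
Fourier syntheses is always supplied explicitly (see *ESP maps*).

The embedded X-ray form factors are the International Tables (1992)
4-Gaussian-plus-constant coefficients for H, C, N, O, F, Na, Al, Si, P, S,
Cl and Ca. Their documented defect ($f_X(0)$ matches $Z_0$ to about 0.01)
bounds the accuracy of the $s\to0$ limit.

### Cromer–Mann parametrization and its fit window

Structure-factor code consumes curves in the 9-coefficient Cromer–Mann
form $f(s) = c + \sum_{i=1}^4 a_i e^{-b_i s^2}$. Ionic Mott–Bethe curves
are fitted over a resolution window, by default 15–0.75 Å
($s \in [0.0333, 0.667]$ Å⁻¹, the range of typical data), sampled at 200
equally spaced $s$ values with unit weights. The optimizer is
Levenberg–Marquardt (`minpack.lm`) with an analytic Jacobian and a squared
reparametrization that keeps the exponents non-negative. Because the
divergent $1/s^2$ part needs very steep Gaussians, the fit multi-starts
from geometric exponent ladders reaching $b \sim 3000$ Å² and keeps the
best deviance; amplitudes enter each start through a linear solve at fixed
exponents.

**Fit-quality metric.** Anion curves cross zero inside the window (the
numerator $Z_0 + \Delta Z - f_X(s)$ changes sign), so a pointwise relative
residual $|\Delta f/f|$ is unbounded near the crossing for any finite
absolute error. The package therefore reports three numbers — max
$|\Delta f|$, pointwise max $|\Delta f/f|$, and the *scale-relative*
residual $\max|\Delta f| / \max|f|$ over the window — and uses the
scale-relative measure (typically 0.2–0.35 %, always below the 0.5 %
quality gate) as its fit-quality criterion.

### The mixing rule

Each non-hydrogen atom $j$ scatters as
$\nu_j f_j^{\mathrm{ionic}} + (1-\nu_j) f_j^{\mathrm{neutral}}$; each
hydrogen $k$ scatters as $\nu_k f^{\mathrm{H^+}}$ only. The neutral
hydrogen curve is too weak for a stable superposition, and the electron a
hydrogen shares with its bond partner is largely counted with the heavier
atom — treating H as a partial bare proton is what makes the non-hydrogen
charges meaningful. The H⁺ curve is built with $Z_0 = 1, \Delta Z = +1$,
consistent with the $\Delta Z$-equals-ionic-charge convention used for all
other species. The partial charge and its uncertainty follow directly:

$$\delta q_j = \nu_j \Delta Z_j, \qquad
  \sigma(\delta q_j) = |\Delta Z_j|\,\sigma(\nu_j).$$

A single site carries $\nu$ directly; the equivalent construction by two
superimposed pseudo-atoms with tied coordinates and ADPs (as one would set
it up in a host refinement program) is mathematically identical but
duplicates bookkeeping, so it is not used here.

## Refinement engine

The engine is a full-matrix weighted least-squares on intensities,
$I_{\mathrm{calc}} = k\,|F_{\mathrm{calc}}|^2$ (kinematical
approximation), with residuals $\sqrt{w}(I_o - I_c)$, $w = 1/\sigma^2(I)$
by default (an optional two-parameter scheme exists but is off: reference
weighting parameters are rarely transferable). Parameters are the overall
scale, then per site $x, y, z$, the ADP components, and $\nu$. All
structure-factor derivatives are analytic and are verified against central
finite differences in the test suite (relative agreement ~1e-8).

Iteration is Levenberg–Marquardt on the normal equations: steps that do
not decrease the weighted sum of squares are rejected and the damping
increased, so the objective is non-increasing by construction.
Convergence is declared at max |shift/esd| < 0.01 with a 200-cycle cap
(typical small-molecule practice); a second criterion (negligible absolute
steps) handles essentially perfect fits, where the esd's vanish and
shift/esd becomes meaningless. Estimated standard uncertainties come from
the inverse normal matrix scaled by the goodness of fit; the covariance
block of the fractions is retained so functional-group sums propagate
correlations.

### Restraints

Restraints enter as extra weighted residual rows (Gauss–Newton on the
augmented system), reproducing soft-restraint behaviour:

* **Total charge.** The physical unit cell is neutral. The restraint row
  is $(q_{\mathrm{target}} - \sum_j \Delta Z_j \nu_j)/\sigma$ with default
  target 0 and $\sigma = 0.001$. Coefficients are $\Delta Z_j$, which
  reduces to the familiar ±1 per free variable when all species carry unit
  charge and generalizes correctly to Si⁴⁺-type cards.
* **Distances.** Optional pairwise bond-length restraints
  $(d_{\mathrm{target}} - d_{\mathrm{model}})/\sigma$ with metric-tensor
  gradients and minimum-image convention. They matter when resolution is
  poor: freely refined protons then wander off their bonds, and mild
  restraints (σ ≈ 0.02 Å) restore both the geometry and the charges — the
  test suite demonstrates this regime at a 1.5 Å cut with 5 % noise.

### Hydrogen modes

With `free_h = TRUE` (the full mode) hydrogen coordinates and ADPs refine
like any other atom — the H⁺ term stabilizes them enough to drop the usual
geometric constraints. With `free_h = FALSE` hydrogens ride on their
parent (fixed fractional offset, ADP = 1.2 × parent) while their fractions
still refine. Riding is the appropriate mode when the data carry little or
no hydrogen signal — in the limiting case of a model whose hydrogens are
all neutral, the hydrogen term $\nu f^{\mathrm{H^+}}$ vanishes entirely
and free-H refinement would be unconstrained.

### Charge-assignment protocols

The method does not presume cation or anion. Three protocol elements make
the assignment automatic:

1. **Sign flip.** A site modelled with the wrong charge sign refines to a
   negative fraction; `apply_sign_flip()` negates its $\Delta Z$, restarts
   $\nu$ at $|\nu|$, and the driver re-refines (at most 5 rounds). Both
   signed curves for every element are kept in the scattering-factor table
   so no refit is needed.
2. **Fix neutral.** A site whose fraction changes sign across cycles while
   staying below 0.05 is fixed at exactly $\nu = 0$. A hydrogen fixed this
   way no longer scatters at all, so all its parameters are removed from
   the refinement.
3. **Multi-start.** The charge landscape can hold shallow local minima in
   which bonded atoms trade compensating charges (recognizable by a
   goodness of fit well above 1). `refine_charges(nu_starts = c(0.1, 0.05,
   0.2))` repeats the whole protocol from each starting fraction and keeps
   the run with the lowest weighted sum of squares. This is deterministic
   and escapes every such minimum we have observed in simulation.

### Numerical safeguards

* The Debye–Waller exponent is capped at +50: a transiently very negative
  ADP during refinement would otherwise overflow and poison the Jacobian.
* The normal matrix mixes parameters of wildly different units; it is
  inverted in Jacobi-scaled (correlation) form. If it is still singular —
  e.g. a parameter has lost all leverage — a small ridge on the unit
  diagonal gives the undetermined directions very large uncertainties
  instead of aborting.
* Structural singularities (a floating origin in a polar space group, an
  exactly duplicated parameter) are detected at the first cycle from the
  scaled normal matrix and reported with the offending parameter named.
* Anisotropic ADP tensors that are not positive semidefinite warn but
  evaluate; symmetry transformation of anisotropic ADPs uses the
  $\beta$-tensor convention with transformed indices $h' = hR$.

## Stability diagnostics

* **Leave-one-out (`r_complete`)**: every reflection is omitted in turn,
  the model re-refined from the converged baseline, and the omitted
  reflection's cross-validated residual plus every atom's charge recorded.
  The aggregate is an R1-type ratio on |F| with cross-validated calculated
  values. The stability property asserted in the tests is that every
  omit-one charge stays within ±3 esu of its mean, where the esu is the
  baseline parameter uncertainty — omitting any single reflection moves a
  charge by an order of magnitude less than its quoted uncertainty.
* **Resolution scans** repeat the refinement over a ladder of
  high-resolution cuts. Truncation inflates every esu (by ~2× from 0.75 Å
  to 1.2 Å on the zwitterion fixture) before it biases the charges.
* **Merging.** Replicate datasets are combined at the charge level by
  inverse-variance weighted means,
  $\bar q = \sum q_i/\sigma_i^2 \big/ \sum 1/\sigma_i^2$,
  $\bar\sigma = (\sum 1/\sigma_i^2)^{-1/2}$, which shrinks uncertainties
  like $1/\sqrt{k}$ for consistent sets. Merging is restricted to sets
  from the same structure; chemically similar polymorphs have genuinely
  different charges and are compared, not merged.
* **Reference comparison.** `charge_pearson()` pairs atoms by label
  (optionally through an alias map) and computes the standard Pearson
  coefficient, with or without hydrogens. `average_h_augmentation()`
  reproduces the control analysis in which a hydrogen-free set is
  augmented with $n_H$ equal hydrogen charges that counterbalance the
  non-hydrogen sum.

## ESP maps

The experimental electrostatic potential is synthesized as
$\rho(r) = V^{-1}\sum_{hkl} F(hkl)\,e^{-2\pi i h\cdot x}$ over the full
reflection sphere on an FFT mesh. Under ionic scattering factors F(000) is
ill-defined (the divergence at $s=0$), so the constant term must be
supplied explicitly — by convention the value from a conventional neutral
refinement. The map mean is then exactly F(000)/V. Default grids sample at
least 3 points per minimum resolution element per axis (Nyquist-safe).
Maps read and write Gaussian CUBE text (Bohr units, last axis fastest).
Grids with different spacings are compared by resampling one onto the
other's points with trilinear interpolation over the spatial overlap
(optionally masked to a radius around selected atoms — a radius-based
approximation to "central molecule only" selections) and taking the
Pearson coefficient, which is invariant under the arbitrary scale of
experimental maps.

## The synthetic generator

`make_structure()` builds four templates with known ground truth and zero
total charge: a single neutral carbon in P1; a Na⁺/Cl⁻ pair in P1 (±0.5 e,
first site pinned to fix the floating origin); a glycine-like zwitterion
in P2₁2₁2₁ (NH₃⁺/COO⁻ pattern, 10 atoms including 5 hydrogens, bonded
distances 0.9–1.8 Å); and a Pnma silicate-like framework with an Si⁴⁺-card
tetrahedral site (+0.4 e), a bridging oxygen, and a half-occupied oxygen
on the mirror plane. `simulate_dataset()` enumerates symmetry-unique
reflections in the requested window, computes kinematical intensities,
and adds seeded Gaussian noise with
$\sigma_I = \max(\mathrm{noise}\cdot I, \mathrm{floor})$ plus random
completeness thinning; replicates use seeds derived from the spec seed,
and every artifact embeds its seed and a spec hash. For noise = 0 the
intensities are exact and the reported sigmas stay proportional to I, so
the weighting scheme matches the noisy case.

The generator emulates counting-statistics-like noise, incomplete data and
replicate crystals. It does **not** emulate dynamical (multi-beam)
scattering, absorption, radiation damage, detector point spread, or
scaling errors between frames. Passing recovery tests therefore show that
the estimator and its uncertainties are correct *under the kinematical
model it fits*; on real electron-diffraction data the kinematical
approximation itself is the dominant systematic, mitigated in practice by
merging several thin crystals.

**Study conditions.** The default recovery experiment is the zwitterion at
0.75 Å with 2 % noise (1149 unique reflections, 51 parameters), ten
seeded replicates, perturbed starts (coordinates jittered 0.02 Å,
fractions multi-started at 0.1/0.05/0.2), the total-charge restraint at
σ = 0.001, and the sign-flip protocol active. Leave-one-out and merging
diagnostics run on the ionic-pair fixture (~200–375 reflections) to keep
the full suite in tens of seconds.

## Known limitations

* Kinematical intensities only; dynamical refinement is out of scope.
* The embedded X-ray table covers 12 light-to-mid-Z elements; extending it
  is a data, not a code, change.
* One ionic magnitude per site at a time ($|\Delta Z|$ fixed by the
  assignment; the sign is refined via the protocols).
* Instruction-file support is a documented dialect (CELL, LATT, SYMM,
  SFAC with ION tags, NU records, SUMP, SHEL, L.S., REM), not the full
  grammar of any host program; symmetry is supplied as operator triplets
  plus a lattice-centering code rather than space-group symbols.
* Charge merging assumes same-structure datasets; label matching against
  reference sets is exact-name based with a user alias map.
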