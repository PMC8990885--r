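---
title: "Methods: a data-driven carbon-ion dose engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a data-driven carbon-ion dose engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cionmc)
```

## Scope and model overview

`cionmc` computes absorbed dose of therapeutic carbon-ion pencil beams
(roughly 100--400 MeV/u) in voxelized phantoms with a Monte Carlo that
deliberately trades generality for speed and transparency.  Three
building blocks are simulated per charged particle:

1. **Continuous ionization energy loss** from pre-computed Bethe
   stopping-power tables, with Bohr energy-loss straggling;
2. **Multiple Coulomb scattering** (MCS) as a single Gaussian per step
   (Highland width), multiplied by an empirical per-species factor
   `f_mcs`;
3. **Nuclear interactions** of the primary carbon: an elastic channel
   on hydrogen only, and a phenomenological non-elastic fragmentation
   model built from measured production probabilities and energy--angle
   emission distributions of a 95 MeV/u carbon beam on thin H, C and O
   targets, rescaled to the actual beam energy.

Charged fragments are transported electromagnetically; neutrons enter
the event-level conservation bookkeeping but are not transported and
deposit no dose.  Fragmentation *of* fragments contributes negligibly
to dose and is off by default; an optional flag enables
attenuation-only removal of secondaries.

## Geometry conventions

Coordinates are right-handed with the beam along $+z$ by default and
the world origin at the centre of the phantom entrance face.  Voxels
are half-open intervals $[\mathrm{edge}, \mathrm{next\ edge})$; R-side
indices are 1-based (the C++ kernel uses the same edges with 0-based
indices).  The standard phantom is $10\times10\times40$ cm of water.
Heterogeneous geometries are supported as density maps over a single
material composition, which matches the CT workflow in which Hounsfield
units are converted to mass density only (`hu_to_density()`,
piecewise-linear, clamped at the end knots; the default two-knot curve
maps $-1000\,\mathrm{HU}\to0.00121$ and $0\,\mathrm{HU}\to1$ g/cm^3^
because no specific scanner curve is assumed).

## Stopping power and ranges

The mass stopping power is the Bethe formula with the Barkas-style
effective charge $z_\mathrm{eff} = z\,[1 - \exp(-125\,\beta
z^{-2/3})]$, evaluated with a water mean excitation energy of
$I = 78$ eV, pre-tabulated on a 700-point log grid over
0.025--460 MeV/u and interpolated linearly in $\log E$.  Shell and
density-effect corrections are omitted; with this choice the proton
stopping power at 200 MeV is within 1% of reference tabulations and
the 200 MeV/u carbon CSDA range in water is

```{r}
csda_range("12C", 200)
```

which places the simulated Bragg peak at $8.7$ cm, inside the
$8.6 \pm 0.2$ cm window used as the acceptance surface for the
energy-loss model.  The continuous-slowing-down range is the cumulative
trapezoid of $A/S(E)$ on the same grid; below the grid the sub-micron
residual range is continued as a power law to zero.

Energy-loss straggling is Bohr's Gaussian model,
$\sigma^2 = 0.1569\, z_\mathrm{eff}^2 (Z/A)\,\rho\,s$ MeV^2^ per step
$s$, whose variance is additive over sub-steps.  This reproduces a
realistic distal-falloff width without the Vavilov machinery, which
matters little for carbon because range straggling is sub-millimetre.

## Multiple Coulomb scattering and f_mcs

Highland's projected width
$\theta_0 = \frac{13.6\,\mathrm{MeV}}{p\beta c} z \sqrt{t/X_0}
\left[1 + 0.038 \ln(t/X_0)\right]$
is applied per step (two independent projected Gaussian deflections;
the logarithmic bracket is floored at 0.1 for very thin steps).  The
single-Gaussian approximation underestimates ion scattering, so the
width is multiplied by a configurable per-species factor `f_mcs`
restricted to $[1, 2]$.  Published tunings for light ions span 1.29
(alphas at 15% of range) to 1.43 (oxygen at 90% of range); because the
tuning procedure needs a reference full MC that this package does not
ship, the default is the midpoint 1.37 for all $Z \ge 2$ ions and 1.0
for singly charged particles, constant in depth.  The depth dependence
between the two published anchor points is not modelled — lateral
penumbra accuracy is therefore expected to be a few percent off at
depths far from mid-range, and `f_mcs` is exposed in the configuration
precisely so it can be re-tuned when reference data are available.

## Nuclear interaction probability

The probability of a nuclear interaction along a step follows the mass
attenuation coefficient
$\mu/\rho = \sum_i N_A\, w_i\, \sigma^i_t / A_i$, with the total
cross-section the sum of the elastic and non-elastic parts, and the
free path sampled exponentially (one draw per flight, decremented
across voxels, re-scaled implicitly by re-evaluating $\mu$ per voxel).
The non-elastic cross-sections are assembled from:

* **carbon targets**: a fitted energy dependence
  $\sigma(E) = (1 - e^{-E/E_c})(p_0 + p_1 E + e^{p_2 - p_3 E})$ with
  $E$ the *total* projectile kinetic energy in MeV and the packaged
  defaults $E_c = 30$ MeV, $p_0 = 762$ mb,
  $p_1 = 14.0\times10^{-4}$ mb/MeV, $p_2 = 6.7$,
  $p_3 = 13.4\times10^{-3}$ /MeV;
* **hydrogen targets**: an interpolated data table.  The source
  figure's numeric knots are not published, so the packaged table
  (`inst/extdata/xs_carbon_on_hydrogen_synthetic.tsv`) is a *synthetic*
  smooth approximation to the inverse-kinematics proton--carbon
  reaction cross-section, constrained to be nearly constant above
  250 MeV/u.  Absolute hydrogen-channel normalization therefore carries
  a documented uncertainty of order 10%;
* **all other targets**: the carbon-carbon fit scaled by the ratio of
  Kox reaction cross-sections,
  $K = \sigma_K(p, t, E)/\sigma_K(^{12}\mathrm{C}, ^{12}\mathrm{C}, E)$.
  The Kox parameterization (geometric + surface + Coulomb terms,
  $r_0 = 1.1$ fm, $a = 1.85$, $r_C = 1.3$ fm, energy-dependent
  transparency $c(E) = 2 - 10/x^5$ with $x = \log_{10} E$ above
  31.6 MeV/u and a cubic ramp below) is used *only as a ratio*, which
  suppresses sensitivity to its absolute normalization.

## Elastic scattering on hydrogen

Elastic collisions are modelled only for carbon on hydrogen (for
heavier targets fragmentation dominates).  The centre-of-mass
scattering angle is drawn isotropically ($\cos\theta_c$ uniform), and
lab-frame angles and energies follow the standard two-body relations
with the hydrogen mass number set to 1; kinetic energy is conserved
exactly, event by event.  Two documented caveats:

* the elastic magnitude is not published as a usable table, so it is a
  configurable fraction of the hydrogen-target non-elastic
  cross-section (default 0.25), exposed as `elastic_fraction`;
* the packaged recoil-angle relation
  $\cos\phi_l = \sqrt{(1 + \cos\theta_c)/2}$ assigns the *complement*
  of the momentum-conservation recoil angle (grazing collisions recoil
  forward, head-on collisions sideways).  It is implemented exactly as
  specified for fidelity, and the test suite asserts the complement
  relation against an independent velocity-vector oracle so the
  convention is machine-checked rather than silent.  Recoil energies
  are unaffected.

## Fragmentation model

### Struck nucleus and fragment set

The struck element is drawn with probability
$P_i = n_i \sigma_i / \sum_j n_j \sigma_j$ using number fractions
$n_i$; for water this reduces to
$P(H) = 2\sigma^H / (2\sigma^H + \sigma_K^O)$.  Production
probabilities per fragment species are packaged per target element
(H, C, O) as a normalized cumulative distribution over the fixed
18-species set (n, ^1^H...^12^C).  Entries are tagged `measured` where
the thin-target experiment constrained them and `fluka-filled` where a
general-purpose MC filled acceptance gaps (all neutrons; species
heavier than ^7^Be on hydrogen).  Targets without a packaged table map
to the nearest one by mass number (N→O, Ca→O) while their cross-section
is still computed for the actual nuclide.

The multiplicity rule is the least-specified part of the source model
and was fixed as follows, as this package's own design choice:

* **projectile side**: species are drawn sequentially from the
  cumulative table; a draw that would push $\sum A > 12$ or
  $\sum Z > 6$ is rejected and redrawn; the set closes when
  $\sum A = 12$ exactly;
* **target side**: *one* fragment per event is drawn from the same
  table (capped by the target's $A$ and $Z$); the remainder of the
  struck nucleus is an untracked residual.

The single-target-fragment rule was chosen because filling the target
nucleon budget the way the projectile side is filled produces 5--7
charged fragments per event and rejection rates above 90%, both
incompatible with the observed 2--4 charged fragments per primary
carbon at therapeutic energies; with one target fragment the engine
produces a grand mean of ≈3.9 charged fragments per event over
100--400 MeV/u with a ≈46% resample rate.

### Energy--angle sampling

Emission energies and angles at the 95 MeV/u calibration energy follow
a two-component density per (target, species),

$$f(E, \theta) = A_1 e^{-(\alpha_E E + \alpha_\theta \theta)} +
A_2 \exp\!\left(-\frac{(E - \langle E\rangle)^2}{2\sigma_E^2}
               -\frac{(\theta - \langle\theta\rangle)^2}{2\sigma_\theta^2}\right),$$

with the exponential term describing low-energy, quasi-isotropic
target fragments and the Gaussian term forward-peaked projectile
fragments near the projectile velocity.  Three transcription decisions
are baked in and documented: the exponent of the first term is
implemented as *decaying* (the printed form without the minus sign is
not normalizable); $\sigma_E$ and $\sigma_\theta$ are treated as
standard deviations (the printed denominators lack the square); and in
two of the three packaged parameter tables the sixth column is read as
$\sigma_\theta$ by symmetry with the first table's header.  Two
out-of-family $\alpha_E$ entries (^1^H and ^11^B on carbon) are kept
exactly as published; the event-level energy-conservation loop absorbs
the heavy tails they generate.

Hydrogen isotopes and neutrons are sampled from the full two-component
mixture regardless of origin (their components overlap too strongly to
separate), with the component chosen by its integrated weight over the
support $E > 0$, $\theta \in [0^\circ, 180^\circ]$; all other species
use the Gaussian component for projectile origin and the exponential
for target origin.  Angles are sampled over the full
$[0^\circ, 180^\circ]$ range, extrapolating beyond the measured
$[4^\circ, 43^\circ]$ window; Gaussian draws are truncated by
resampling, exponential angles by inverse CDF.

### Rescaling to the beam energy

Projectile-fragment energies per nucleon scale as
$E_i = E_i^{95} \cdot (E_\mathrm{proj}/95)(1 - k)$, with
$k = c\,(1 - R)$, $c = 0.4$, and $R$ the $A$-weighted mean energy per
nucleon of the *previously drawn* fragments of the same event divided
by $E_\mathrm{proj}$.  For the first fragment the printed sum bounds
would include the fragment itself; this package sets $R = 1$ (no
correction), which is the choice that keeps the scaling mean-preserving
— the average fragment energy per nucleon then equals the projectile's.
Target fragments scale by the plain $E_\mathrm{proj}/95$ factor.
Angles scale as $\theta_i = \theta_i^{95}\sqrt{95/E_\mathrm{proj}}$
(energy-independent transverse momentum), for every species except
protons and neutrons, target fragments included.  Azimuths are uniform.

An event whose fragments carry more total kinetic energy than the
projectile is discarded and redrawn (up to 1000 attempts, then a
sampling-failure error guards against corrupted tables).  Accepted
events conserve charge and mass on the projectile side by
construction.

## Transport engine

Tracks advance with adaptive steps: the distance to the next voxel
boundary, capped so no step loses more than 2% of the kinetic energy
(configurable in $(0, 0.25]$).  Energy loss uses a midpoint evaluation
of the stopping power; deposits are scored to the voxel where the step
starts.  Particles below 0.5 MeV/u (sub-millimetre residual range)
deposit locally and stop.  The inner stepping loop is compiled (Rcpp)
but draws all random numbers from R's global RNG stream, so runs are
bit-reproducible under `set.seed()`; a pure-R reference step
(`step_track()`) implements the same physics for inspection and
equivalence tests.  The engine processes tracks in generations
(primaries, then their secondaries, and so on), which is physically
identical to per-track recursion because fragment generation is
memoryless.

The energy ledger (deposited + escaped + neutron-carried +
event-deficit + optionally secondary-absorbed = injected) closes to
machine precision and is checked to 0.5% in the tests.  Statistical
uncertainty is accumulated as per-deposit sums of squares, an
uncorrelated-deposit approximation that underestimates true
history-by-history variance where one history deposits repeatedly in a
voxel; it is provided for relative weighting, not for formal error
bars.

## QA observables

`depth_dose()` integrates transversely ($\mathrm{Gy\,cm^2}$ per
primary) so its depth integral equals the dose-volume integral;
`lateral_profile()` resolves one transverse axis at a depth slice;
`find_bragg_peak()` refines the global maximum parabolically over
three bins and refuses flat or boundary-maximum profiles.

`build_sobp()` solves non-negative least squares (via
`pracma::lsqnonneg`) for layer weights on a matrix of per-primary
depth-dose kernels so the summed profile is flat at the prescription
over the target interval; the weighting method is this package's
choice.  Feasibility requires the deepest layer's peak to reach the
distal target edge.

`gamma_index()` implements the standard dose-comparison metric with
*global* dose-difference normalization (percent of the reference
maximum, matching the "cutoff of X% of the maximum dose" convention):
for each reference voxel the minimum over a search sphere of radius
$3\times$DTA of
$\sqrt{(\Delta D / \mathrm{dd})^2 + (r/\mathrm{DTA})^2}$, on a
sub-voxel lattice (`subdivision` per axis) with trilinear
interpolation of the evaluated distribution.  Offsets are visited in
increasing $|r|$ with a global early-exit, and `subdivision = 1`
reproduces an exhaustive voxel-level search exactly, which is the
correctness gate against the brute-force oracle in the tests.

## Problem sizes and what the tests show

The packaged checks run at desk scale, chosen so the full suite
completes in minutes on one core: the Bragg-peak acceptance run uses
$10^5$ primaries on a $40\times40\times800$ grid (0.5 mm depth bins,
2.5 mm transverse — the depth observable is transverse-integrated, so
lateral binning does not affect it); multiplicity statistics use
$10^5$ events per energy point; distribution-recovery tests use
$10^6$ draws; gamma oracle equivalence uses $32^3$ grids.  Statistical
claims are tested at 3-sigma or chi-square $p > 0.01$ thresholds.

The fragmentation tables *are* the model: passing tests demonstrate
that the engine reproduces the packaged parameterization and its
scaling laws plus textbook EM transport, not that it matches any
particular beam line.  In particular the hydrogen-channel table is a
synthetic digitization, the elastic fraction is an exposed guess, and
`f_mcs` is untuned; all three are the knobs a commissioning exercise
against measured depth-dose and penumbra curves would adjust.

## Known limitations

* No delta rays, no photons/electrons, no de-excitation gammas, no
  neutron transport: dose from these channels is either folded into
  the continuous loss or booked as non-deposited energy.
* Fragment emission tables exist for H, C and O targets only; other
  elements borrow the nearest table while keeping their own
  cross-section.
* Heterogeneous phantoms are density-scaled water (no composition
  segmentation).
* The gamma search is exact only up to the sub-voxel lattice spacing;
  pathological fields varying faster than a voxel can in principle be
  missed, as with any discrete gamma implementation.
* GPU-oriented acceleration (kernel batching, texture-memory table
  interpolation) is out of scope; the compiled kernel is serial by
  design so results are bit-reproducible.
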