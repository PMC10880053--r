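---
title: "Models and methods behind polylobe"
author: "polylobe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polylobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polylobe)
```

# The particle model

A lobed patchy colloid is a rigid composite of a central *seed* sphere
(diameter $\sigma_S = 2$ in reduced units) and $N_L$ smaller *lobe* spheres
anchored to it: two antipodal lobes for the dumbbell (DB), three coplanar
lobes at 120° for the trigonal planar (TP) particle, and four lobes at
tetrahedral vertices (pairwise angle $\arccos(-1/3) \approx 109.47°$) for
the tetrahedral (TH) particle.  The unit of length is the mean lobe
diameter, $\mu_G = \sigma_L = 1$.

Polydispersity enters through the lobe diameters: each lobe's diameter is
drawn independently from a Gaussian with mean $\mu_G$ and standard
deviation $\sigma_G$, truncated to $[\mu_G - \sigma_G,\, \mu_G + \sigma_G]$
so that even the most polydisperse systems contain no unphysically small or
large lobes.  The standard grid is $\sigma_G \in \{0, 0.1, \ldots, 0.5\}$
($\sigma_G = 0$ being the monodisperse reference).  Sampling is by
rejection from the parent normal, which is exact; truncation at one
standard deviation keeps about 68% of proposals, so the cost is
negligible.  Useful closed forms for validation: the truncated
distribution's variance is $\sigma_G^2\,E[Z^2 \mid |Z|\le 1] \approx
0.2911\,\sigma_G^2$, and the mean cubed diameter is
$1 + 3 \cdot 0.2911\,\sigma_G^2$, both verified in the test suite by
numeric quadrature.

Two geometric choices are not fully determined by the model description and
were fixed once here:

* **Anchor distance.** Lobe centres sit at $d = \sigma_S/2$ from the seed
  centre (on the seed surface, partially embedded), independent of the
  sampled lobe diameter.  Smaller-than-average lobes are therefore embedded
  slightly deeper relative to their own radius; re-anchoring by realized
  diameter is a plausible alternative, and `d` is exposed as a parameter of
  `build_blueprint()`.
* **Intra-particle correlation.** The $N_L$ diameters of one particle are
  drawn independently; nothing in the model constrains them jointly.

# Box sizing and the volume convention

The cubic box is sized by the volume-fraction rule
$V_0 = N\,(V_S + N_L V_L)/\phi$ at $\phi = 0.1$, with $V_L$ fixed at the
nominal (mean-diameter) lobe volume so that all systems of a shape share a
box regardless of $\sigma_G$.  A subtlety: the reference edges
75 (DB), 78 (TP), 80 (TH) for $N = 1000$ are only reproduced when $V_S$ and
$V_L$ are computed as $(4\pi/3)s^3$ *of the stated size parameters*
($s = \sigma_S, \sigma_L$) — i.e. treating the "diameter" as the sphere's
size parameter rather than using $(\pi/6)d^3$ — and when the real cube root
is rounded **up** to an integer.  `compute_box_edge()` implements exactly
this convention; `actual_volume_fraction()` uses the same additive
convention with the realized diameters, so the monodisperse round trip is
exact, and at $\sigma_G = 0.5$ the realized $\phi$ is
$\approx 0.104$ (the $E[s^3]$ inflation above).  Where a *physical* local
packing fraction is meant — the density rule of the pore-analysis sub-box
extraction — `polylobe` uses $(\pi/6)d^3$ instead; the two conventions are
deliberately kept separate.

# Pair interactions

All interactions act between sites (seeds and lobes) of different
particles; a particle's own sites are rigidly fixed and never interact.
The combined size of a pair is always the arithmetic mean
$\sigma_{ij} = (\sigma_i + \sigma_j)/2$, the only mixing rule compatible
with surface-shifting additive spheres.

**Repulsion (seed–seed and seed–lobe): surface-shifted Lennard-Jones.**

$$U_{SSLJ}(r) = 4\epsilon_{SL}\left[\left(\frac{\sigma_{ij}}{r-\Delta}\right)^{12}
 - \left(\frac{\sigma_{ij}}{r-\Delta}\right)^{6}\right] + \epsilon_{SL},
 \qquad r - \Delta < 2^{1/6}\sigma_{ij},$$

with $\Delta = \sigma_{ij} - 1$ and $\epsilon_{SL} = 1$ (in $k_BT$ units).
Truncating at the minimum and adding $+\epsilon$ makes the potential purely
repulsive and continuous with a continuous force at the cutoff (the
Weeks–Chandler–Andersen construction applied to the shifted coordinate).
Conventions for this potential vary in the literature and sometimes quote
a "depth at the energy minimum", which is incompatible with a purely
repulsive role; the offset is therefore switchable (`wca_shift`), with the
repulsive WCA reading as the default since the model uses these pairs as
repulsions only.

**Attraction (lobe–lobe): truncated-and-shifted Lennard-Jones.**

$$U_{LJ}(r) = 4\epsilon\left[\left(\frac{\sigma_{ij}}{r}\right)^{12}
 - \left(\frac{\sigma_{ij}}{r}\right)^{6}\right] - U_{LJ}^{bare}(3\sigma_{ij}),
 \qquad r < 3\sigma_{ij},$$

with $\epsilon = \epsilon_{LL} = 3$.  The energy shift at the cutoff is
$4\epsilon[(1/3)^{12} - (1/3)^6] \approx -0.00548\,\epsilon$ — negligible
for structure but it keeps the energy continuous; no tail corrections are
applied (the goal is structure formation in NVT, not free-energy
accuracy).  $\epsilon_{SL}$ and $\epsilon_{LL}$ are treated as fixed
reduced-energy constants with $T^*$ varying independently, so the
effective attraction strength is $\epsilon_{LL}/T^*$ (15 at $T^*$ = 0.2,
3 at $T^*$ = 1.0), which is what drives the condensation-to-gas contrast.

The interaction table (`build_interaction_table()`) enumerates the unique
realized (site kind, diameter) types and resolves every unordered pair to
its parameters; because every parameter follows analytically from the two
diameters and kinds, the MD inner loop computes them on the fly — the
table is the audit/query surface, round-trippable to JSON.

# Rigid-body Langevin dynamics

Each particle is one rigid body with 6 degrees of freedom, propagated in
the NVT ensemble at time step $dt = 0.005$ (reduced time) with periodic
boundaries and the minimum-image convention.

* **Forces and torques.** Site positions are the body centre plus the
  rotated body-frame anchors; pair forces accumulate into a body force and
  a torque $\sum_s (x_s - x_c)\times f_s$.  A linked-cell list with cell
  edge at least the largest interaction range makes the evaluation O(N);
  it falls back to the all-pairs loop when the box holds fewer than three
  cells per side, and the two paths are verified identical in the tests.
* **Integrator.** A BAOAB splitting: half kick, half drift, an *exact*
  Ornstein–Uhlenbeck velocity/angular-momentum refresh, half drift, half
  kick.  Rotations use a symmetric 3–2–1–2–3 free-rotor factorisation in
  exact single-axis rotations of the quaternion and the body-frame angular
  momentum, so quaternion norms are preserved to machine precision (they
  are additionally renormalised each substep — the documented policy).
  The OU step uses per-axis factors $e^{-\gamma\,dt/m}$
  (resp. $e^{-\gamma_r dt/I_k}$) with noise amplitude
  $\sqrt{(1-c^2)\,k_BT^*\,m}$, which satisfies fluctuation–dissipation
  exactly at any $dt$; the commonly quoted impulsive-noise variance
  $2\gamma k_BT^*/dt$ is its small-$dt$ limit.  With the thermostat off
  (or $\gamma = 0$) the scheme reduces to plain velocity-Verlet with a
  symplectic free rotor, and the suite checks a relative total-energy
  drift below $10^{-4}$ over $10^4$ steps for 27 dumbbells.
* **Friction, mass, inertia.** These coarse-grained dynamical constants
  are not part of the structural model; defaults are body mass 1,
  $\gamma_t = \gamma_r = 1$, and the principal inertia of the rigid
  composite with site masses proportional to sphere volumes.  The inertia
  uses the *nominal* (monodisperse) geometry: this keeps the body frame
  principal-diagonal and the centre of mass at the seed centre for every
  shape, and since equilibrium ensemble averages of configurational
  observables are independent of the mass matrix, it changes none of the
  structural metrics — only the (arbitrary) coarse-grained time scales.
  All are configurable through `integrator_params()`.
* **Initial conditions.** Random sequential insertion with rejection of
  any site pair inside its repulsive contact distance, uniform random
  orientations, Maxwell–Boltzmann velocities and angular momenta at
  $T^*$; a simple-cubic lattice placement is available as an alternative.
  Everything is deterministic given the seeds (R's RNG for construction, a
  dedicated Mersenne–Twister stream in the C++ core for the thermostat
  noise).

The reference production protocol is $5\times10^7 + 5\times10^7$ steps
with $N = 1000$; that is cluster-scale.  Package defaults are desk-scale
($N = 64$, $10^5 + 10^5$ steps), which suffice for every property gate in
the test suite and for the qualitative low-/high-temperature contrast; the
quantitative state-diagram morphologies at full scale are outside what the
desk-scale defaults can reproduce.

# Structural metrics

* **RDF.** $g(r)$ over particle (seed) centres — the peak structure lives
  at the particle scale — with bin width $0.05$, normalised by the
  ideal-gas shell count $\tfrac{N}{2}\rho\,\tfrac{4\pi}{3}[(r+\Delta
  r)^3-r^3]$ and averaged over frames.  $r_{max}$ is capped at half the
  box edge (minimum image).
* **Bonds per lobe.** Two lobes on different particles are bonded when
  closer than that pair's LJ cutoff $3\sigma_{ij}$.  Reported: per-lobe
  degrees, their mean, $P(n)$, and the joint (lobe-diameter bin × bond
  count) histogram whose marginals are checked to match the univariate
  distributions exactly.  Note the generous cutoff means a dense gas
  retains a small nonzero bond count by mere proximity.
* **Relative neighbor orientation.** For particle $i$ with neighbors $j,
  k$ (default criterion: sharing at least one lobe–lobe bond; a
  centre-distance criterion is available for gases), the angle
  $\theta_{jik} = \arccos(\hat r_{ij}\cdot\hat r_{ik})$ is histogrammed in
  2° bins over *all* unordered neighbor pairs, normalised to sum to 1
  (discrete convention, recorded in the metadata).  A two-nearest-only
  mode is provided for comparison with analyses that use exactly two
  neighbors; pair-complete statistics subsume it.  Per-particle versus
  global normalisation is a genuinely open convention; global (pooled
  angles) is used because it weights particles by the information they
  carry.
* **Clusters.** Connected components of the bond graph (via igraph), with
  deterministic labels ordered by the smallest member index; the suite
  checks the labels against a hand-rolled union-find.

# Pore-size distribution

The porosity analysis is a native voxel implementation of the
largest-included-sphere statistic: for each void voxel accessible to a
probe of radius $\tfrac12\mu_G$, the diameter of the largest sphere that
fits in void space and contains that voxel.

1. **Region.** The densest axis-aligned sub-box is grown greedily from the
   densest coarse cell (2$\mu_G$ cells), taking at each step the face
   expansion that keeps the *physical* packing fraction highest, while it
   stays ≥ `min_density` (default 0.05).  All cells tied for the maximum
   density are tried as seeds and the largest resulting region wins — this
   makes the selection deterministic and size-aware when several regions
   are equally dense.  There is no standardised operational rule for
   extracting such cuboids, so published pore-size ranges for these
   systems can only be compared qualitatively.
2. **Distance field.** For every voxel centre (default spacing
   $0.1\mu_G$, at most half the probe radius), the distance to the
   nearest site surface under the full box's minimum image, clamped at 0
   inside sites.
3. **Covering spheres by morphological opening.** For each candidate
   radius $r$ (the distinct field values when few, else a grid at half
   the voxel spacing): candidate centres are the voxels with field ≥ $r$
   (spheres that fit), and a voxel is covered if its distance to the
   nearest candidate centre — an exact Euclidean distance transform
   (Felzenszwalb's separable lower-envelope algorithm, in C++) — is at
   most $r$.  The per-voxel pore radius is the largest covering $r$;
   voxels with surface distance below the probe radius are inaccessible
   and excluded.  On a toy grid this reproduces the exhaustive
   all-centres × all-voxels search exactly.

Analytic fixtures anchor the method: a spherical cavity of diameter
$4\mu_G$ bounded by a dense spherical shell yields a PSD peak at exactly
$4\mu_G$; a slab void of thickness $t$ between sphere walls has its mode
at $\approx t$ (the walls are bumpy at the sphere scale, hence the ~4%
positive bias); refining the grid moves the cavity mode by less than one
coarse bin.  Parity with external pore-analysis software is established
through these constructions, not by numerical comparison against it.

# The sweep and the synthetic fixtures

`sweep_plan()`/`run_sweep()` tie the stages together over the
$(T^*, \sigma_G)$ grid, producing one summary row per condition — mean
bonds per lobe, largest-cluster fraction, first-RDF-peak height, modal
pore diameter — for the user to label; morphology labels for such state
diagrams are traditionally assigned by visual inspection, and automatic
labelling is explicitly out of scope.  Per-condition seeds derive deterministically from the
global seed and condition index; two runs of the same plan are identical,
including on-disk CSV output.  The monodisperse baseline $\sigma_G = 0$ is
included in the default grid as the monodisperse reference point even
though the polydispersity grid of interest starts at 0.1.

`make_fixture()` provides the deterministic ground-truth configurations
the metric tests rest on (bonded dimer at its numerically solved
zero-force separation, collinear trimer, equilateral triangle, hexagonal
sheet, simple-cubic lattice, pentagonal 5-ring with one bond per lobe,
Poisson ideal gas, cavity and slab porosity phantoms).  These fixtures
emulate the *geometry* the analyses assume — they are not thermalised
configurations, carry no velocity information, and the porosity phantoms
are hard-sphere walls rather than self-assembled aggregates.  Passing
tests on them therefore validates the estimators, not the physics of any
particular assembled structure.

# Numerical choices and limitations

* Problem sizes in the tests are chosen for a desk machine: 27–64
  particles, $10^4$–$5\times10^5$ steps, porosity grids ≤ ~$10^6$ voxels.
* The instability guard aborts a run when any body moves more than half
  the interaction range in one step (a symptom of too large a $dt$), and
  SSLJ evaluation below the surface-shift distance raises a hard-core
  error rather than returning garbage.
* Degenerate analysis inputs are first-class: empty trajectories, frames
  without lobes, regions without accessible voxels and empty sweep plans
  all return well-defined empty results or explicit errors, as tested.
* Thermostat implementation details differ between simulation engines,
  so coarse-grained dynamical time scales are not comparable across
  codes; only structural observables are.
* No shell CLI is shipped: the exported functions plus
  `scripts/acceptance.R` are the interface, which suits the library-style
  use of this package; `run_sweep()` is the one-call entry point for the
  full pipeline.
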