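---
title: "Modeling constrained motion of DNA-linked spheres on rounded cubes"
author: "FlexColloid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling constrained motion of DNA-linked spheres on rounded cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system and the question

Flexible colloidal molecules are finite clusters in which spherical
colloids ("ligands") adhere to a central anisotropic colloid through
surface-mobile DNA linkers. Here the central particle is a rounded cube
whose shape is the superball

$$\left|\frac{2x}{\sigma_c}\right|^{n} +
  \left|\frac{2y}{\sigma_c}\right|^{n} +
  \left|\frac{2z}{\sigma_c}\right|^{n} = 1,$$

with edge length $\sigma_c$ (the unit of length throughout) and
roundness exponent $n$; $n = 2$ is a sphere and $n \to \infty$ a sharp
cube. The default $n = 6$ captures a typical hematite cube. Spheres of
diameter $\sigma_s = \alpha\,\sigma_c$ bind through hybridization of an
11-nt single-stranded sticky end (`GTAGAAGTAGG` against its reverse
complement) carried by linkers of length $l = 0.025\,\sigma_c$ that
diffuse freely in the lipid bilayer coating both particles.

The question the package answers quantitatively: when is the motion of a
bound sphere on the cube surface *unconstrained* (free diffusion across
facets) and when is it *constrained* to one facet, as a function of the
size ratio $\alpha$ and temperature?

# The bond model

A single linker pair contributes a bond free energy

$$\beta\Delta G_{\gamma\delta} \;=\; \beta\Delta G_0 \;+\;
  \beta\Delta G_{\mathrm{cnf}},$$

where $\Delta G_0$ is the duplex hybridization free energy and
$\Delta G_{\mathrm{cnf}}$ the configurational cost of confining two
mobile strands into the bond region.

**Hybridization term.** $\Delta G_0(T)$ is computed from the sequence by
the unified nearest-neighbor model: enthalpy and entropy sums over
dinucleotide stacks plus duplex-initiation terms, an entropy-based
monovalent-salt correction $\Delta S(\textrm{salt}) = \Delta S(1\,M) +
0.368\,(N-1)\ln[\mathrm{Na}^+]$ with $N$ the duplex length, and an
optional constant inert-tail correction (in $k_BT$) modeling the
double-stranded backbone the sticky end is mounted on. The tail term
defaults to zero: the strand-number calibration described below absorbs
any constant offset, which is why a configurable additive constant is a
sufficient representation. Only perfectly complementary duplexes are
supported; mismatches and dangling ends are out of scope.

**Configurational term.** An unbound mobile strand explores a shell of
thickness $l$ around its own particle: volume $\Omega_\gamma$ for the
sphere (closed form) and $\Omega_\delta$ for the superball (Monte Carlo
with an exact-bounded distance test). A hybridized pair is restricted to
the overlap $\Omega_{\gamma\delta}$ of the two shells, and

$$\beta\Delta G_{\mathrm{cnf}} \;=\;
  -\ln\!\frac{\Omega_{\gamma\delta}}
             {\rho_0\,\Omega_\gamma\,\Omega_\delta},$$

with $\rho_0$ the 1 M standard-state concentration expressed in
$\sigma_c^{-3}$ (via $\sigma_c = 1.04\,\mu m$). The sphere sits at
normal distance $h = l + \alpha \sigma_c / 2$ above the surface, the
geometry at which repulsive contributions of inert strands can be
neglected.

**Multivalency.** With $n_\gamma$ sphere strands and $n_\delta$ cube
strands, all mobile and identical, the patch partition function is the
exact sum over bond matchings

$$Z \;=\; \sum_{b=0}^{\min(n_\gamma, n_\delta)}
  \binom{n_\gamma}{b}\binom{n_\delta}{b}\, b!\, q^{\,b},
  \qquad q = e^{-\beta\Delta G_{\gamma\delta}},$$

and $\beta F^{\mathrm{bond}} = -\ln Z \le 0$, evaluated with
log-sum-exp for large counts. This reduces to $-\ln(1+q)$ for a single
pair and is verified in the tests against brute-force enumeration of
matchings. For two spheres bound simultaneously the package also
provides the joint partition function in which both spheres draw bonds
from the same $n_\delta$ cube strands; comparing the resulting
per-sphere energy $\beta F_{\mathrm{pair}} = \beta F^{\mathrm{bond}}/N_s$
against the single-sphere calculation quantifies how weakly the
landscape depends on the number of bound spheres when $n_\delta$ is
large (the depletion of the shared pool is the only coupling; the
acceptance script reports its maximum relative effect at
$\alpha = 4.44$).

The free-energy landscape is
$\beta\Delta F(\mathbf{s}) = \beta F^{\mathrm{bond}}(\mathbf{s}) -
\beta F^{\mathrm{bond}}_{\mathrm{face}}$, reported with a positive sign
so that barriers are positive and the face-center minimum is zero; the
reference is the mean over the six per-face minima (exactly the global
minimum on the symmetric grid).

# Surface grid

The surface is discretized into approximately area-uniform sites:
directions from a Fibonacci sphere restricted to the octahedral
fundamental domain ($x \ge y \ge z \ge 0$), expanded by all 48 symmetry
operations of the cube, and projected radially onto the superball (the
radial projection has a closed form). Two consequences drive this
choice over projecting a full Fibonacci set:

* the grid is *exactly* 48-fold symmetric, so the expensive
  configurational integrals are evaluated once per orbit and shared,
  which is what makes ~60,000-site landscapes routine; and
* landscape symmetry, a property the physics demands, holds exactly
  rather than within Monte Carlo noise.

Sites are joined by a symmetrized k-nearest-neighbor move graph
(default $k = 6$, automatically increased if the graph comes out
disconnected). Radial projection stretches areas toward the corners by
a modest factor; the Metropolis dynamics corrects for the resulting
degree inhomogeneity through the neighbor-count factor below, and no
area weights enter the free energies (each site is a *position*, not a
quadrature cell).

# Monte Carlo integration of the configurational spaces

$\Omega_{\gamma\delta}$ is sampled per site, uniformly over the
spherical-cap slice of the sphere's shell that faces the surface site
(polar cosine at least $r/(r+l)$ toward the site). A convexity argument
shows this region contains the whole overlap: any point within $l$ of
the cube surface lies at most $l$ above the tangent plane at the site,
which bounds its polar angle in the sphere's frame. Restricting the
sampling region this way keeps the estimator unbiased while raising the
acceptance fraction from a few percent (bounding-box sampling) to
~40–50%, and the binomial standard error is reported per site.

Membership in the superball shell uses the Euclidean
distance-to-surface with two exact bounds before any iteration: the
radial chord through the query point is an upper bound, and the signed
distance to the tangent plane at the radial foot point is a lower bound
(the tangent plane of a convex body supports it). Only queries falling
between the bounds run the iterative tangential-walk projection
(position tolerance $l/100$). The tests validate the integrals against
an analytic two-shell overlap on the $n=2$ sphere and against
offset-averaged voxel counting on the rounded cube.

# Strand-number calibration

The effective number of hybridizable strands in the patch cannot be
measured directly, so it is calibrated from the observed mobility
boundary: the smallest spheres ($\alpha = 0.63$) diffuse across facets,
so $n_\gamma$ is chosen as the largest count for which that motion
remains unconstrained; one strand more would contradict the
observation. "Unconstrained" is defined as a facet-crossing probability
of at least $10^{-6}$ per MC sweep, and the crossing rate is computed
as the inverse mean first-passage time of the actual Metropolis chain
from the face-center site to any other face (a sparse linear solve).
The entropic prefactor that the chain carries (the sphere must first
reach the edge region at a cost of several $k_BT$ of occupancy
probability) reduces the rate by two to three orders of magnitude below
the bare barrier factor $e^{-\beta\Delta F_{\mathrm{edge}}}$; a
bare-barrier criterion would therefore misplace the calibration by
5–7 $k_BT$ of edge barrier. The rate is monotonically decreasing in
$n_\gamma$, so a bracketed binary search is exact, and the result is
deterministic given the integration seeds.

The calibrated quantity is a surface *density*: for other size ratios
the per-sphere count scales with the sphere area,
$n_\gamma(\alpha) = \mathrm{round}\!\big(n_\gamma^{\mathrm{ref}}
(\alpha/0.63)^2\big)$, while the cube count $n_\delta$ is fixed and tied
to the calibration through the experimental grafting-density ratio
(2×10^4^ versus 300 strands/µm²) and the two surface areas. We verified
the alternative reading — reusing the same *count* at every $\alpha$ —
and it fails to reproduce the central observation: the $\alpha = 0.93$
crossing rate stays near $10^{-7}$/sweep (leaky confinement) instead of
dropping below $10^{-13}$/sweep.

# Surface dynamics

Spheres hop on the site graph by Metropolis Monte Carlo. One MC step is
one attempted move per sphere, so time scales are independent of the
sphere count. A move from site $i$ to a uniformly chosen neighbor $j$
is accepted with probability

$$\min\!\left(1, \frac{k_i}{k_j}\,
  e^{-(\beta F_j - \beta F_i)}\right),$$

where $k$ is the neighbor count; the $k_i/k_j$ factor restores detailed
balance on the irregular graph, which the tests verify exactly on small
graphs and empirically against Boltzmann occupancy. Bound spheres
exclude each other at center–center distance $\sigma_s$ (the simplest
excluded-volume model consistent with spheres on adjacent facets
hindering each other), and for $\alpha \ge 1.49$ the top and bottom
faces are excluded to mimic the quasi-two-dimensional confinement by
gravity. Only nearest-neighbor hops are attempted.

**Initial conditions.** Spheres start uniformly at random on allowed
sites, with one refinement: each sphere must start on a distinct face
whose relaxed (face-center) position is compatible with every other
sphere at the $\sigma_s$ exclusion — for two large spheres
($\alpha \ge 3.19$) that forces opposite faces, as in the assembled
AB~2~ molecules. This mirrors what the assembly process produces.
Unrestricted uniform placement puts two spheres on one face in a large
fraction of draws at $\alpha = 0.93$ (six spheres, six faces); the
surplus sphere starts wedged on an edge, flickering between face labels
for longer than any reasonable equilibration, a configuration assembled
molecules never exhibit.

Default protocol: $10^5$ equilibration sweeps, $10^7$ production
sweeps, contact points recorded every 50 sweeps, 20 independent runs
(all configurable; the seeds are `base_seed + run`).

# Observables

* **Position autocorrelation**
  $C_r(t) = \langle \mathbf r_i(t_0)\!\cdot\!\mathbf r_i(t_0+t) /
  |\mathbf r_i(t_0)|^2 \rangle$, averaged over spheres, time origins
  (all records by default; a single-origin variant matches the
  ensemble-of-initial-conditions convention) and runs. Contact points
  on a single facet keep $C_r$ on a high plateau; decay to zero
  requires redistribution over facets. The decay *onset* is defined by
  the conventional 10%-decay criterion ($C_r < 0.9$). Because the time
  unit is one sweep of a lattice walk, the onset scales with the grid
  spacing as $a^{-2}$; onsets are therefore only comparable between
  runs at the same grid resolution, and the acceptance test pins the
  resolution at ~60,000 sites.
* **Mean in-plane displacement** $\Delta r$: the RMS excursion of a
  sphere's contact point about its mean, projected onto the facet plane
  (facets treated as flat), pooled over contiguous same-face segments
  (at least 10 records), spheres and runs. It is invariant under
  rotations about the face normal and equals $d/2$ for points
  alternating a distance $d$ apart.
* **Facet occupancy** and **facet-crossing counts** classify
  constrained versus unconstrained runs.

# Problem sizes and reproducibility

The package's own study sizes: landscapes and dynamics on a
~60,000-site grid (the per-orbit sharing reduces the configurational
integrals to ~1,250 sites); module tests run on 500–6,000-site grids;
the calibration uses 2–4×10^4^ overlap samples per orbit and the
acceptance script 10^5^ per evaluation point. Displacement statistics
at the largest size ratio need the full resolution: the face well at
$\alpha = 4.44$ is only a few grid spacings wide even at 60,000 sites,
and on a 6,000-site grid the sphere cannot leave its site at all.
Every stochastic component takes an explicit integer seed
(xoshiro256+ in the compiled samplers), and identical configurations
reproduce byte-identical artifacts.

# What the simulations do and do not emulate

The model retains the ingredients that control facet confinement —
sequence-level duplex thermodynamics, mobile-linker configurational
entropy on the exact superball geometry, multivalent saturation, hard
sphere–sphere exclusion and quasi-2D gravity masking — and reproduces
the qualitative transitions the tests assert: unconstrained facet
hopping at $\alpha = 0.63$ versus strict single-facet confinement at
$\alpha = 0.93$, barriers growing with $\alpha$ and falling with
temperature, and fully reversible behavior because the configurational
term is temperature independent.

It does not model explicit polymer conformations of the linkers (no
worm-like-chain stretching, no linker–linker excluded volume), linker
depletion kinetics, hydrodynamics, bilayer mechanics, off-lattice
motion, sphere unbinding, or polydispersity in strand numbers — the
last of these mainly sharpens the computed transitions relative to
experiments. Two quantitative consequences of the idealized multivalent
patch are worth flagging honestly: with the density-scaled strand
counts the barrier scale at the largest size ratio reaches
$\mathcal{O}(10^3)\,k_BT$ rather than a few hundred, and the ratio of
in-plane displacements between $\alpha = 0.93$ and $\alpha = 4.44$
comes out near 7.5 rather than near 5; both trace to the same cause
(the saturated patch at large $\alpha$ binds effectively all
area-scaled strands), and both leave every qualitative ordering
intact.

# Numerical choices

* Surface tolerance after closed-form radial projection: machine
  precision; validity checks enforce $|f| \le 10^{-8}$.
* Distance-to-surface refinement tolerance $l/100$; the exact
  upper/lower bounds decide all but a thin band of queries without
  iteration.
* $\Omega_{\gamma\delta} = 0$ (an unbindable site) maps to
  $\beta\Delta G_{\mathrm{cnf}} = +\infty$, $q = 0$,
  $\beta F^{\mathrm{bond}} = 0$: an unbindable site is simply a site
  with no adhesion free energy, which the barrier then reports as
  maximally unfavorable relative to the face center.
* Mean-first-passage solves that are numerically singular (barriers of
  hundreds of $k_BT$) return a crossing rate of zero.
* Ties in the degree-corrected acceptance are impossible on the
  symmetric grid; degenerate inputs (empty trajectories, single-record
  trajectories, zero spheres) raise errors or return empty states as
  documented.
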