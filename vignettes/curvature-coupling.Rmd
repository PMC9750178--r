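---
title: "Curvature coupling and the spatial organization of Piezo1 on the red blood cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature coupling and the spatial organization of Piezo1 on the red blood cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezorbc)
```

## The scientific question

Piezo1 is the stretch-activated Ca^2+^ channel of red blood cells (RBCs).
The channel trimer is intrinsically curved: it deforms its local membrane
into a dome, approximately a spherical cap of area 450 nm^2 with a relaxed
radius of curvature of about 42 nm.  The RBC, in turn, is a biconcave disk
whose surface mean curvature varies from weakly *concave-outward* in the
central dimple to convex on the peripheral rim.  If the channel's shape
couples energetically to the curvature of the membrane around it, Piezo1
should partition toward the dimple even though the cell-scale curvatures
(fractions of 1/um) are one to two orders of magnitude below the dome's own
curvature (about 24/um).  This package implements the quantitative machinery
to test that idea: a calibrated discocyte geometry, a Helfrich bending-energy
model of the dome-in-membrane system, the Boltzmann map from energies to a
predicted surface density, and the image-, tracking- and colocalization-level
analyses that connect the model to super-resolution data — each exercisable
on seeded synthetic data.

## The discocyte surface

Two axisymmetric parameterizations are provided.  The default,
`discocyte_arcs()`, builds each dimple face as a spherical cap joined
*tangentially* onto a toroidal rim.  Given the cell radius $R_0$, rim tube
radius $a$ (half the maximum thickness) and half central thickness $h_0$,
tangency fixes the dimple sphere radius:

$$R_d = \frac{(R_0-a)^2 + h_0^2 - a^2}{2\,(a-h_0)}.$$

For the standard cell (diameter 8.0 um, central thickness 1.0 um, maximum
thickness 2.5 um) this gives $R_d = 25/6$ um, and the construction closes
exactly: the distance between the sphere and tube centers equals $R_d + a$.
Every published dimension then drops out at once — total area 137.98 um^2,
dimple mean curvature exactly $+0.24$ um$^{-1}$, rim-equator mean curvature
$-0.525$ um$^{-1}$:

```{r}
m <- calibrate_discocyte()
m
```

We also implement the familiar smooth quartic profile
$z(\rho)=\tfrac12\sqrt{1-(\rho/R_0)^2}\,(C_0+C_2(\rho/R_0)^2+C_4(\rho/R_0)^4)$
(`profile = "quartic"`, with $C_2,C_4$ solved from the maximum-thickness and
area constraints).  It reproduces the printed thicknesses and area but
*over-curves the dimple* (its central mean curvature comes out near
0.39 um$^{-1}$); no quartic can satisfy the four printed dimensions and the
dimple curvature simultaneously.  That observation is why the tangent-arc
construction is the package default: the printed curvature extremes
adjudicate between the two shape families, and only the piecewise-circular
geometry reproduces them.  The cost is that the surface is only $C^1$ — the
meridional curvature jumps at the cap–torus junction — which is physically
inconsequential here because only the mean curvature enters the model, and
its full range $[-0.525, +0.24]$ um$^{-1}$ is what matters.

The sign convention makes the dimple positive: $H>0$ where the surface is
concave toward the cell exterior, so a sphere has $H=-1/R$.  Segmentation
into dimple and rim is geometric: by curvature sign (the default for model
predictions; on the tangent-arc cell the $H>0$ region is exactly the two
spherical caps, 21.9% of the area) or by a cylinder of radius 1.13 um (the
convention used for tracking analyses).  The experimental dimple fraction
estimated from F-actin-based image segmentation (~17%) falls between these
geometric conventions; we report both and force neither.

## The curvature-coupling energy

For each surface point with mean curvature $H$, the model asks: what is the
minimum bending energy of a membrane vesicle that contains the Piezo dome
and whose radius, if spherical, is $1/|H|$?  The vesicle area equals the
free-membrane area plus the 450 nm^2 cap.  Where the sign of $H$ matches the
dome's concave-outside orientation the dome is mounted inside-out
(orientation-matched); otherwise it is mounted with the reversed
tangent-angle boundary condition.  The free membrane minimizes the Helfrich
functional

$$G_M = \frac{K_b}{2}\int (c_1+c_2)^2\, dA, \qquad K_b \approx 20\,k_BT,$$

subject to position and tangent continuity at the dome edge, smooth closure
at the opposite pole, and the fixed-area constraint.

**Numerics.**  The Euler–Lagrange equations of the constrained functional
form a six-dimensional ODE system in the arclength parameterization
$(\psi, u=\psi', \gamma, r, A, E)$, where $\gamma$ is the multiplier
conjugate to $r'=\cos\psi$ and the area constraint enters through a
tension-like multiplier $\sigma$.  We shoot from the regular pole (where
$\gamma=0$ and a series expansion starts the integration) with an adaptive
Dormand–Prince RK5(4) integrator written in C++, and solve for the three
unknowns (pole curvature, $\sigma$, meridian length) by damped Newton
iteration on the three endpoint conditions (cap base radius, contact angle,
free area).  Continuation in the contact angle starts from the exactly
solvable tangent-sphere configuration, so convergence is robust for both
orientations; solutions at neighbouring curvatures warm-start each other.
Because bending energy is scale invariant, the problem is solved in units of
the vesicle radius and the energy is returned in units of $K_b$.

Three independent checks pin the solver down.  First, when the imposed
curvature matches the dome's own ($H = 1/42$ nm$^{-1}$) the vesicle remains
a sphere and the energy has the closed form
$8\pi K_b\,(A_{free}/A_{ves})$; the solver reproduces it to below $10^{-6}$
relative.  Second, the traced meridian's energy recomputed by independent
trapezoid quadrature agrees with the ODE's energy accumulator.  Third,
energies are stable to well under $10^{-3}\,k_BT$ when the integrator
tolerance is varied by two orders of magnitude.  (A design alternative — a
direct discretized-energy minimizer over the shape — was considered as a
cross-check but is redundant given the closed-form anchor plus the
quadrature consistency check, and far less accurate at the
$10^{-3}\,k_BT$ scale that matters here.)

Below $|H| = 0.01$ um$^{-1}$ the vesicle radius diverges; the profile takes
the planar-limit branch by linear interpolation between the solves at
$\pm 0.01$ um$^{-1}$.  Only energy *differences* enter the Boltzmann map, so
the alignment constant is immaterial; the interpolation keeps the profile
monotone and continuous across the floor.

The resulting energy profile $G(H)$ decreases strictly from rim-like to
dimple-like curvature, and its span across the cell's curvature range is
about $0.65\,k_BT \approx \ln 2$:

```{r}
prof <- energy_vs_curvature()
prof
```

## From energies to a predicted distribution

The Boltzmann map assigns each surface point a probability per unit area
$P(x) \propto \exp(-G(H(x))/k_BT)$, normalized over the surface.  The
headline prediction is the dimple/rim density ratio — the ratio of
region-averaged densities:

```{r}
cc <- curvature_coupling()
cc
```

The predicted enrichment is about 1.8-fold with curvature-sign segmentation,
i.e. "approximately two-fold", emerging from the membrane mechanics with no
fitted parameters: every constant in the model (cap area, intrinsic radius,
bilayer modulus, cell dimensions) is an independently known quantity.
`curvature_coupling()` returns a classed model object with `print`,
`summary`, `coef`, `predict`, `plot` and `simulate` methods; `simulate()`
draws synthetic spot patterns from the fitted density.

## Dome flexing

Piezo1 is not rigid.  Permitting the cap radius $R$ to flex at fixed cap
area, the joint energy

$$G_{tot}(R) = G_{free}(H;R) + \frac{K_P}{2}\,S_{cap}
\left(\frac{2}{R}-\frac{2}{R_{P0}}\right)^2$$

is minimized over $R$ (golden-section over a bracketed coarse scan, with a
modality check that fails loudly if the energy in $R$ is not unimodal).  The
quadratic form in total curvature $2/R$ is the simplest Helfrich-type dome
energy consistent with a flexing cap of fixed area; the dome bending modulus
$K_P$ is a configurable parameter whose default, $20\,k_BT$, equals the
bilayer modulus and places the flexed radii at 41.6 nm in the dimple and
42.9 nm at the rim — within 0.3 nm of the published estimates (41.4 and
42.7 nm).  No single $K_P$ reproduces both published radii exactly under
this functional form (about $13\,k_BT$ would match the dimple value,
$25\,k_BT$ the rim value), which bounds how literally the quadratic flexure
model should be taken; the package exposes $K_P$ so users can propagate
their own dome-stiffness estimates.  The physical conclusion is robust
across this range: the dome radius changes by less than ~2 nm across the
entire cell surface (1.3 nm at the default), so resting-cell curvature
differences alone cannot gate the channel.

## Spot-pattern statistics

`detect_spots()` reimplements scale-matched Laplacian-of-Gaussian blob
detection with sub-voxel centroid refinement and duplicate merging, with the
conventions of the original analysis as defaults (120 nm expected diameter;
raw-intensity threshold in the 3000–5000 range of the synthetic camera
model).  On synthetic stacks with 80 seeded emitters at realistic
signal-to-noise it achieves recall and precision above 0.95 against the
generator's ground truth; equivalence with the commercial detector used on
the real data is claimed only at that statistical level, not per spot.

Nearest-neighbour distances use the edge-masking convention that spots
within the margin of the mask boundary are excluded *as queries but retained
as neighbours* — edge spots neither bias the distances nor starve interior
spots of neighbours.  Across cells the summary is the mean ± SD of per-cell
means, matching per-cell reporting conventions.  The G-function
(nearest-neighbour CDF) is compared against pointwise envelopes of 39 CSR
simulations with the same point count in the same mask, a 5% rank test by
construction; the distance grid runs 0–1 um in 10 nm steps.  Power checks
show a Thomas cluster process (0.1 parents/um^2, 5 offspring, sigma = 50 nm)
escapes the envelope in over 90% of runs, while patterns sampled from the
smooth curvature-coupling density at the observed abundance (~26 spots per
unroofed patch) are judged "consistent with random" — the model's weak,
smooth density gradient is invisible to cluster statistics at realistic
counts, exactly as observed in the data.

Per-region densities use counts per um^2 of segmented area, and the
enrichment statistic is the *mean of per-cell ratios* (not the ratio of
pooled densities), again matching per-cell reporting.

## Single-particle tracking

`msd()` computes per-track time-averaged MSDs over all ordered frame pairs,
ensemble-averaged as the unweighted mean across tracks (the convention of
the standard trajectory-analysis tools; weighting is not specified in the
tracking literature consistently, and the unweighted mean is what per-track
averaging over equal-length recordings gives).  Diffusion coefficients are
slope/4 from ordinary least squares with a free intercept — the intercept
absorbs the $4\sigma_{loc}^2$ localization floor, which for fixed-cell
(immobile) controls is the entire signal.  The two standard windows are 5 s
("macroscopic", corral-to-corral transport) and 50 ms ("microscopic",
within-corral).  Confinement is assessed by fitting
$MSD(\tau)=A(1-e^{-\tau/\tau_c})+4\sigma_{loc}^2$ against a line (AIC); for
a circular domain the plateau is the squared radius, so the confinement
diameter is $2\sqrt{A}$.

The hop-diffusion generator places a Brownian walker in square corrals with
reflecting walls and a crossing probability per boundary encounter;
localization noise corrupts the reported positions.  Defaults emulate the
measured regime: microscopic D = 0.037 um^2/s, corral side 500 nm (the
observed scale of actin–spectrin voids and confinement), hop probability
0.07, sigma_loc = 20 nm, 100 Hz for 2 min across 14 tracks (a 1-hr, 1-Hz
protocol is a parameter change).  One property of confined tracking is worth
stating explicitly: the short-window D estimate carries an inherent downward
bias of order $(1-p)\sqrt{2D\tau}/L$ from wall encounters, about 12% at
these defaults.  The estimator therefore recovers the generator's D within
15% under paper-like confinement, and essentially without bias when the
corral dwarfs the 50 ms diffusion length; both regimes are tested.  This
also means measured "microscopic" coefficients in strongly corralled
membranes systematically understate the free-bilayer mobility.

`dimple_occupancy()` reports the fraction of frames within a 1.13 um circle
of the cell center (supplied, or estimated as the track's convex-hull
centroid — the center definition is parameterized because tracking data
rarely fix it).  An unbiased walker's occupancy matches the circle's area
fraction; a density-biased walker (hop acceptance modulated by a supplied
surface density, Metropolis style) exceeds it.  The utility
`dispersion_time(x, D) = x^2/6D` quantifies why colocalization of Piezo1
with the Gardos channel is not required for functional coupling: with
intracellular Ca^2+ diffusivities of 13–65 um^2/s, equilibration across a
cell-scale micron happens within tens of milliseconds.

## Optimal-transport colocalization

`otc_curve()` normalizes the two channels of a 64 x 64 pixel (12.5 nm/px)
section to unit mass and computes the *exact* optimal transport plan between
the pixel distributions — successive shortest augmenting paths with node
potentials, written in C++, on the support of above-background pixels
(background floor: median + 3 MAD, then the weakest pixels carrying 0.5% of
signal mass are pruned so isolated shot-noise pixels do not blow up the
support).  The OTC value at threshold $t$ is the transported mass moved no
farther than $t$; thresholds run from the pixel size (Nyquist floor) to
300 nm.  The ground cost is the Euclidean distance (a squared-cost switch is
provided; the degenerate anchors — identity, two-point step — are
cost-exponent invariant, and thresholding is always on distance).
Exactness is verified against exhaustive-permutation matching oracles on
small grids and by dual complementary-slackness certificates on random
instances.  Confidence bands across sections are per-threshold
t-distribution intervals, shrinking as $1/\sqrt{n}$.  Synthetic section
pairs with a controllable colocalized fraction reproduce the qualitative
contrast between a strongly complexed pair (OTC(100 nm) well above 0.5) and
an independent pair (below 0.3).

## Synthetic data: what it does and does not emulate

The generators provide every analysis stage with inputs whose *statistical
structure* matches its assumptions: spot abundance drawn from the observed
distribution (normal, mean 80.2, SD 26, truncated at zero), Gaussian PSFs
(120 nm lateral FWHM, 125 nm section spacing for the widefield-like stacks;
40 nm/12.5 nm for STED-like sections), Poisson shot noise plus a constant
camera offset (no read noise, so threshold units stay comparable to
raw-count conventions), corralled diffusion with hopping, and two-channel
sections with a controllable colocalized fraction.  Identical seeds give
byte-identical outputs, and generator parameters are recorded in the output
metadata.  They do **not** emulate structured-illumination reconstruction
artifacts, depletion-beam physics, fluorophore photophysics, antibody
labeling stoichiometry (the real data resolve trimeric triplets), membrane
undulations, or gold-particle hydrodynamics.  Passing tests therefore show
the *analyses* are correct and well calibrated, and that the physical model
is internally consistent — not that the generators reproduce every property
of real micrographs.

## Problem sizes and reproducibility

The default analysis scales are modest by construction: 2001 meridian
samples for the surface (refinement-stable to <0.1%), a 25-point energy
grid on $[-0.6, 0.3]$ um$^{-1}$ (interpolation accurate to <0.02 $k_BT$
against direct solves), 14 tracks of 2 min at 100 Hz for tracking studies,
and 64 x 64 sections for OTC.  A full curvature-coupling fit runs in well
under a second; the complete pipeline with sampling, tracking and OTC stages
completes in seconds.  `run_pipeline()` executes the stages in dependency
order from a validated configuration (YAML-serializable, unknown keys
rejected, every constant carrying its unit in the field name) and writes a
JSON report sufficient to rerun deterministic stages bit-identically.

## Known limitations

* The tangent-arc discocyte is $C^1$, not $C^2$; curvature-sign segmentation
  on it gives a crisp dimple boundary exactly at the cap–torus tangency.
* The vesicle construction imposes radial symmetry and uses only the mean
  curvature at each surface point (both principal curvatures enter only
  through their mean); membrane tension, spontaneous curvature, thermal
  undulations and inter-channel interactions are outside the model.
* No volume constraint is imposed on the vesicle — only the area is fixed,
  matching the model's specification of the free-membrane problem.
* The dome flexure functional is the minimal quadratic form; the spread of
  $K_P$ values needed to match both published flexed radii exactly (13 vs
  25 $k_BT$) measures its adequacy.
* The exact OT solver is quadratic-memory in the support size; sections much
  denser than STED-like sparsity should use coarser supports (or accept the
  documented mass-pruning).
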