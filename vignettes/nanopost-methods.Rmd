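---
title: "Methods: coarse-grained polymer dynamics in nanopost arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained polymer dynamics in nanopost arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

A long semiflexible polymer — the canonical example is double-stranded DNA
in a nanofluidic device — threaded into a regular array of parallel
nanoposts experiences a peculiar *quasi-biaxial* confinement. The space
between four neighbouring posts acts like a channel of diameter
$d_c = \sqrt{2}\,S_p - d_p$ (with $S_p$ the lattice spacing and $d_p$ the
effective post diameter), while the gap between two nearest posts acts like
a slit of width $w_p = S_p - d_p$. How the chain partitions itself among
these interstitial quasi-channels, how far it stretches along the posts,
and what structural fingerprints the array leaves in scattering-type
observables, are the questions this package addresses by simulation and by
analytic scaling theory.

`nanopost` implements, in one tested artifact:

* the standard Kremer–Grest-type bead-spring model of a flexible or
  semiflexible chain (WCA excluded volume, FENE bonds, discrete worm-like
  bending energy), of linear or circular topology;
* purely repulsive interactions between beads and an ideal, infinite
  square lattice of posts;
* leap-frog molecular dynamics with Nosé–Hoover, Langevin, or no
  thermostat;
* the structural observables used in this problem domain: span along the
  post axes, gyration tensor components, interstitial occupation number,
  single-chain structure factor, tangent–tangent orientation correlations
  and the persistence length estimated from them;
* the analytic confinement ladder: Odijk deflection regime, extended and
  classic de Gennes blob regimes, the channel/slit free-energy balance
  that predicts the single-to-multiple occupancy threshold, and a
  damped-oscillation model for orientation correlations under channel
  confinement, with a nonlinear fitting routine.

## Model and units

Everything is expressed in reduced Lennard-Jones units: bead diameter
$\sigma$ (length), pair energy $\epsilon$ (energy, with
$k_BT = \epsilon$ at the working temperature $T = 1$), bead mass $m = 1$,
time unit $\tau = \sigma\sqrt{m/\epsilon}$.

**Excluded volume.** All bead pairs (bonded pairs included) repel through
the cut-and-shifted Lennard-Jones (WCA) potential
$U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon$ for
$r < 2^{1/6}\sigma$, zero beyond. Posts repel beads through the same form
applied to the distance from the post *surface*, $r - D_p/2$, where $D_p$
is the bare post diameter; post forces act only in the plane perpendicular
to the post axes.

**Bonds.** FENE springs,
$U = -\tfrac{\kappa}{2}R_o^2\ln[1-(l/R_o)^2]$ with
$\kappa = 30\,\epsilon\sigma^{-2}$, $R_o = 1.5\,\sigma$, combined with the
WCA pair term. This combination equilibrates at an effective bond length
$l \approx 0.97\,\sigma$ and an effective bead width $w \approx 0.9\,\sigma$
— a touching-bead chain.

**Bending.** The discretized worm-like-chain energy per interior joint is
$b\,k_BT\,(1 - \mathbf{u}_i\cdot\mathbf{u}_{i+1})$, implemented directly
from bond unit vectors (no angle extraction). $b = 0$ is the flexible
chain, $b = 20$ the semiflexible chain, corresponding to a nominal
persistence length $P = b\,l = 19.4\,\sigma$; mapped to DNA at high ionic
strength ($w \approx 2.5$ nm, $P \approx 50$ nm) one simulation length unit
is about 2.5 nm.

**Geometry bookkeeping.** The chain contour sees posts of effective
diameter $d_p = D_p + w$. The model is specified to the package by any two
of $(S_p, d_p, w_p)$; `derived_params()` and `geometry_table()` produce the
derived quantities $d_c$, post volume fraction
$F = \pi d_p^2/(4 S_p^2)$ and the confinement ratio $d_c/w_p$ for the two
canonical geometry families (constant $S_p = 12$; constant $w_p = 2$).
There is one genuine ambiguity: the touching-bead model supports both
$w = 0.9$ (bead width) and $w = l = 0.97$ in the geometry mapping. We use
$w = 0.9$ as the default (so the canonical effective diameters like
$d_p = 1.9$ correspond to round bare diameters $D_p = 1.0$) and expose `w`
as a configuration parameter throughout.

## Integration and thermostats

The leap-frog scheme advances half-step velocities; on-step velocities for
kinetic-energy reporting are the average of the two adjacent half-step
values. The Nosé–Hoover friction obeys
$\dot\chi = (T_{\rm inst}/T_0 - 1)/\tau_T^2$ with relaxation time
$\tau_T = 0.1\,\tau$, integrated with a three-pass iterative
velocity/friction update. The Langevin thermostat is the BBK leap-frog
discretisation; it is offered because a deterministic global thermostat
equilibrates slow conformational modes poorly at desk scale. `thermostat =
"none"` gives NVE dynamics used purely for validation: the test suite
checks a secular energy drift below $10^{-4}$ over $10^4$ steps at
$\mathrm{d}t = 0.005\,\tau$, the $O(\mathrm{d}t^2)$ scaling of energy
fluctuations, and exact conservation of momentum along the post axes.

Initial conformations follow the standard protocol: a straightened
backbone for linear chains, a fully prolonged rectangular loop (two
strands of length $\approx L/2$ one bond apart) for rings, placed with the
principal axis parallel or perpendicular to the posts. In-array placement
requires every bead to start outside the WCA interaction range of every
post, so initial configurations carry no bead–post energy; a perpendicular
placement through an impassably narrow aperture fails with a placement
error rather than an exploding first step.

Integration aborts with an error naming the step if a bond reaches the
FENE divergence, a bead penetrates a post core, or the energy turns
non-finite. Nonbonded interactions use a Verlet neighbour list (skin
$0.3\,\sigma$, rebuilt when any bead has moved more than half the skin);
bead–post interactions are evaluated against the four posts at the
vertices of the bead's interstitial cell, which provably cover the
interaction range whenever $w_p \ge 0$ (a brute-force 25-post scan backs
this as a test oracle).

## Observables

* **Span** $R_s$: per-frame $\max(x_i) - \min(x_i)$ along the post axes;
  defined for both topologies, and approaching the end-to-end distance for
  a strongly channel-stretched linear chain.
* **Gyration components**: $R_{gx}$ along the posts and the lateral
  $R_{gyz} = \sqrt{(R_{gy}^2 + R_{gz}^2)/2}$, so that
  $R_g^2 = R_{gx}^2 + 2R_{gyz}^2$ (an identity the tests enforce).
* **Occupation number**: the yz-plane is partitioned into squares whose
  vertices are the post centres; the occupation number is the count of
  distinct squares holding at least one bead. A bead inside a passage
  aperture counts toward the cell it geometrically lies in; edge points
  follow a floor convention, making the partition exhaustive and
  deterministic. We report the time average with a block-averaged standard
  error (whether the full-scale study averaged or took a mode is not
  decidable from the reported material; the average is the conventional
  choice).
* **Structure factor**: the orientation-averaged Debye double sum
  $S(q) = N^{-2}\langle\sum_{ij}\mathrm{sinc}(q\,r_{ij})\rangle$. The
  $O(N^2)$ direct sum is the reference path; a distance-histogram variant
  (bin width $0.02\,\sigma$ by default) matches it to $10^{-3}$ on the
  test fixtures. The default $q$ grid is logarithmic from
  $2\pi/(2\,d_{\max})$ to $2\pi/(0.5\,l)$ with 200 points — the exact grid
  is a presentation choice, not physics. A local log–log slope utility
  (`sq_local_slope()`) supports reading the scaling regimes off $S(q)$;
  no automatic hump classifier is attempted.
* **Orientation correlations**: $C(n_s) = \langle\mathbf{u}_i\cdot
  \mathbf{u}_{i+n_s}\rangle$ over all frames and all bond pairs, computed
  via FFT-based autocorrelation (linear lags for open chains, circular
  lags with the exact inversion symmetry $C(n_s) = C(N_b - n_s)$ for
  rings).

## Persistence length: estimator and its pitfalls

For an ideal worm-like chain, $C(n_s) = e^{-n_s l/P}$, and a straight-line
fit of $\ln C$ through the origin recovers $P$ exactly (the generic
`estimate_persistence_length()` default window is $C \ge e^{-1}$, one
persistence length). Two real-data effects complicate this for the actual
excluded-volume chain:

1. **Swelling.** Excluded volume makes the decay slower than exponential
   beyond a fraction of a persistence length; the local decay rate drifts
   upward with $n_s$, so the fitted $P$ grows with the window.
2. **Slow global modes.** For a semiflexible chain of a few tens of
   persistence lengths, the global conformation decorrelates over times
   that dwarf any desk-scale run. From a straightened start, the chain
   drifts monotonically for more than $6\times10^4\,\tau$; single
   trajectories sit for long stretches in transiently extended or compact
   states that bias $C(n_s)$ at separations approaching $P/l$ bonds. (A
   three-bead chain, which has no global modes, reproduces the exact
   single-joint statistics $\langle\cos\varphi\rangle = \coth b - 1/b$ to
   four digits — the bias is ensemble sampling, not force physics.)

The calibration protocol in `calibrate_persistence_length()` therefore
(a) averages over several *independent replicas*, each initialised from an
overlap-free ideal worm-like-chain draw at the nominal stiffness so that
global statistics start near equilibrium rather than having to develop
from a rod; (b) relaxes each replica under a Langevin thermostat before
production; and (c) fits only the short-scale window $C \ge e^{-1/2}$
(about half a persistence length), where the decay is exponential and
insensitive to both effects above. The replica-to-replica scatter of the
fitted $P$ supplies the sampling uncertainty, which dominates the
within-fit error. At the default scale (N = 250, six replicas,
$5\times10^5$ relaxation plus $1.5\times10^6$ production steps each) the
estimate lands a few percent below the nominal $b\,l = 19.4$, with a
standard error of roughly $0.6\,\sigma$. The paper-faithful protocol
(straight start, Nosé–Hoover) remains available through `build_chain()` +
`run_md()` but does not converge at desk scale.

## Scaling theory

With the interstitial space approximated by a channel of diameter $D$:

* **Occupancy threshold** — a channel costs twice the confinement free
  energy of a slit of equal size, and both scale as $D^{-m}$ with
  $m = 5/3$ for a flexible chain, so the barrier to spreading vanishes at
  $d_c/w_p = 2^{1/m} = 2^{3/5} \approx 1.52$. The exponent is exposed
  because the semiflexible slit exponent is debated (values between 1/3
  and 1/2 for the stiffness dependence).
* **Odijk regime** ($D < P$): extension
  $R = L[1 - A(D/P)^{2/3}]$, $A = 0.1701$ for a cylindrical channel;
  a `circular = TRUE` option halves $L$, reflecting the two-strand
  conformation of a confined ring. Deflection length
  $\lambda = c(PD^2)^{1/3}$.
* **de Gennes regimes** ($D > P$): $R = L(wP/D^2)^{1/3}$, identical in the
  classic ($D > P^2/w$, isometric blobs) and extended
  ($P < D < P^2/w$, anisometric blobs) regimes; the log-log slope in $D$
  is exactly $-2/3$.
* **Regime classifier**: boundaries at $D = P$ and $D = P^2/w$, with ties
  assigned to the stiffer regime; it also returns the schedule of
  structure-factor slopes expected in each regime ($-1$ on the
  rod/persistence scale, $-2$ in anisometric blobs, $-5/3$ in isometric
  blobs, $-1$ again for the low-$q$ string of blobs). Note that with
  $P = 19.7$ the boundary $P^2/w$ is 400 for $w = 0.97$ and 432 for
  $w = 0.9$ — both far beyond any canonical array geometry, which is why
  the $-5/3$ blob statistics only appears for nearly free chains.
* **Damped orientation-correlation model**: under strong channel
  confinement,
  $C(n_s) = 1 - \frac{\lambda}{2P}\left[1 + 2e^{-n_s l/\lambda}
  \sin(n_s l/\lambda - \pi/4)\right]$. The first minimum — the first
  deflection off the wall — sits where $e^{-x}\sin(x - \pi/4)$ is
  stationary, i.e. at $n_s l = (\pi/2)\lambda$ exactly.
  `fit_orientation_profile()` fits $(P, c)$ with
  $\lambda = c(PD^2)^{1/3}$ substituted, by Levenberg–Marquardt least
  squares, using a default window of twice the first minimum; applying
  this linear-chain Odijk formula inside an interstitial volume is an
  approximation whose validity the model itself cannot guarantee, so
  fitted values should be read as effective parameters.

## Synthetic-data generator

`generate_fixture()` provides deterministic conformations with closed-form
observables, so every analysis routine is testable without dynamics: rods
(span and end-to-end known), rectangular and regular-polygon rings
(ring correlations $\cos(2\pi n_s/N)$, inversion symmetry), ideal
worm-like chains with a *planted* persistence length (the tilt-angle
distribution $p(\cos\theta) \propto e^{\kappa\cos\theta}$ with $\kappa$
solved so that $\langle\cos\theta\rangle = e^{-l/P}$ exactly, making the
tangent correlation exactly exponential in expectation), beads planted at
chosen interstitial cells (known occupation), and two-bead dumbbells
(closed-form structure factor). What these fixtures deliberately do *not*
emulate is excluded volume and confinement-induced non-exponential
correlations — which is exactly why the parameter-recovery tests on them
are clean: they validate the estimators, not the sampling of the physical
ensemble.

## Problem sizes and numerical choices

Simulation-based checks run at desk scale by design: calibration chains of
100–250 beads with $10^6$–$10^7$ total steps, and confined-trend chains of
80 beads in runs of $5\times10^5$ steps averaged over two seeds per
geometry — sizes at which local observables (bond length, short-scale
tangent correlations, kinetic temperature) are well converged and the
directional trends in occupation and span are resolvable, while full-scale
quantitative curves (occupation numbers of a 1000-bead chain, Fig-level
span values, confined-chain correlation profiles) are expressly out of
reach and are not asserted. Occupancy states of a confined chain are
metastable over long stretches, which is why trend checks are sign tests
on seed-averaged means, not value comparisons.

Other numerical choices: timestep $0.005\,\tau$ (stable against the
stiffest FENE+WCA bond modes at $T = 1$); neighbour-list skin
$0.3\,\sigma$; block averages with 10 blocks for every reported standard
error; stationarity of equilibration judged by agreement of the last two
fifths of the equilibration-phase potential energy and $R_g$ within three
combined standard errors (a quantitative stand-in for the qualitative
"satisfactory oscillations" criterion; failures flag the result rather
than abort). Tie-breaks: cell-edge points belong to the lower-index cell;
the regime classifier assigns boundary diameters to the stiffer regime.
All randomness flows from user-supplied integer seeds; trajectories are
bit-reproducible for a given seed and build.

## Known limitations

* No hydrodynamics, no electrostatics, no electric-field driving — the
  model addresses equilibrium structure only.
* The ideal-WLC replica initialisation samples global conformations from
  the ideal (non-excluded-volume) ensemble; production relaxation removes
  most but not all of the resulting bias at separations beyond the fit
  window. The short-window persistence estimate is robust to this; full
  $C(n_s)$ profiles at large $n_s$ from desk-scale runs are not.
* Fitted $(P, c)$ from the damped-oscillation model inside an interstitial
  volume are effective parameters; the formula's derivation assumes a true
  cylindrical channel and a linear chain.
* The square lattice is ideal and infinite; hexagonal or finite arrays and
  confining device walls are out of scope.
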