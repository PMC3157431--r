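---
title: "Modeling the boundary bias of static microarray hybridizations"
author: "spotbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the boundary bias of static microarray hybridizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotbias)
```

## The problem

In static (unmixed) DNA microarray hybridizations, spots at the edge of
the printed block systematically light up brighter than interior spots,
with the maximum at the block corners.  The cause is transport, not
chemistry: the chamber floor outside the printed block carries no probe,
so the fluid above that *spotless margin* is a reservoir of labeled
target that only the outer spot rings can tap by lateral diffusion.
Interior spots sit in the diffusional shadow of their neighbours and
receive little more than the target initially present in the fluid
column directly above them.  `spotbias` implements the quantitative
model of this effect and the position-wise statistics used to measure it
on real or synthetic arrays.

## Geometry and the ring-position bookkeeping

The hybridization chamber is a sealed square well of half-length $L$
(footprint $2L \times 2L$) and height $H$, with an $n_r \times n_c$ grid
of circular probe spots (diameter 150 µm, pitch 300 µm in all presets)
centered on its floor.  Spots are grouped into concentric square rings
("spot positions"): position 1 is the outermost ring, and the position
of the spot at row $r$, column $c$ (0-based) is

$$\mathrm{ring}(r,c) = \min(r,\; c,\; n_r-1-r,\; n_c-1-c) + 1 .$$

On the 30 x 30 block this yields positions 1–15 with 116 replicate
spots at position 1 down to 4 at position 15; on the full-coverage
70 x 72 block the innermost position is 35.  Spots within a position
are treated as replicates.  Two kinds of transects profile the bias:
the 4 half-diagonals from each corner to the center, and the 8
half-rows/half-columns along the two middle rows and columns.  The
center-line definition is the only reading that yields 8 paths each
visiting every position exactly once on an even grid; odd-dimension
grids are rejected rather than guessed at.  All internal coordinates
are SI (meters), chamber-centered.

## When is a spot a perfect sink?

Near a spot, target is consumed by hybridization at rate $k B_0 C$ and
replenished by diffusion.  Comparing the hybridization timescale
$(k B_0)^{-1}$ with the diffusion timescale set by the limiting length
(the spot radius $R$ when $R < h$, else the chamber height $h$) gives a
Damköhler-type dimensionless number

$$P = \frac{(k B_0)^{-1}}{R^2 / D}.$$

When $P \ll 1$, reaction is so much faster than diffusion that the
target concentration at the spot surface is effectively zero: the spot
is a *perfect sink*, and the full reaction–diffusion problem reduces to
pure diffusion with an absorbing boundary condition at the spots.  The
effective probe concentration $B_0$ in the dried spot is estimated by
conserving probe between the printed hemispherical droplet
(concentration $B_S$, radius $R$) and the dried disk (same radius,
height $h_D$): $B_0 = \tfrac{2}{3} (R/h_D) B_S$.

```{r scaling}
scalingReport(kineticParams())
```

With the default parameters (D = 1e-9 m²/s for single-stranded RNA,
k = 5e4 /M/s, R = 75 µm, B_S = 50 µM, h_D = 2 µm, giving B0 = 1.25 mM)
the package reports P = 2.8e-3, justifying the sink assumption.  The
rate constant `k` is an input: estimating it from sequence
thermodynamics is out of scope, and the default is the value used for
the 18-mer probe system the model was built around.  The "much less
than one" cut-off defaults to 0.01 (strict inequality); it is a
reporting convention, not a physical constant, and is configurable.

## The diffusion model

With perfect-sink spots the target concentration obeys the 3D unsteady
diffusion equation $\partial C/\partial t = D \nabla^2 C$ in the
chamber, with $C = 1$ initially (well-mixed, in units of the initial
concentration — the equation is linear, so results are relative),
$C = 0$ on the spot disks, and no-flux conditions on every other
surface.  The per-spot absorption rate is the Fickian flux
$-D A\, \partial C/\partial z$ summed over the spot, and the quantity
compared across positions is its time integral over the hybridization
time (24 h), the model's proxy for signal intensity.  Halving $D$ is
exactly equivalent to doubling all times.

### Numerical scheme

The chamber is discretized on a regular grid that tiles it exactly
(default 50 µm laterally — 3 cells across a spot — and one vertical
cell per 25 µm of height).  A floor cell is a sink iff its center lies
inside a spot disk; at the 300 µm pitch every spot receives an
identical rasterization, so no artificial spot-to-spot area variation
is introduced.  The Dirichlet value $C = 0$ is imposed at the floor
*face* of sink cells (a ghost value half a cell below the first cell
center), and the flux uses the matching one-sided two-point stencil, so
flux and field converge together under refinement.

Time stepping uses the Douglas–Gunn alternating-direction implicit
scheme with weight $\theta = 1/2$: one tridiagonal solve per direction
per step, unconditionally stable and second-order in time.  The choice
of splitting matters more than is commonly appreciated for this
problem: naive sequential backward-Euler sweeps (locally
one-dimensional splitting) let lateral transport proceed without seeing
the concurrent floor absorption within each step, which weakens the
shadowing of inner spots and, at practical step sizes, inflates the
inner/outer flux ratio several-fold.  The stabilizing-correction form
keeps that splitting error small at the same cost.  We validated the
implementation two ways: against the closed-form slab series solution
for a fully absorbing floor (agreement within 1% after refinement), and
against an independent unsplit sparse backward-Euler solver on a
miniature 8 x 8-spot chamber, where the Douglas–Gunn result at
dt = 3 s agrees with the independent solver to four significant digits
(19.25% inner/outer ratio).

The default base step is 30 s with the first ten steps subdivided
tenfold to resolve the initial boundary-layer transient (the absorption
rate is singular like $t^{-1/2}$ at start-up); the fine start-up steps
also serve the same purpose as a Rannacher start, damping the
oscillations a Crank–Nicolson-type scheme would otherwise exhibit on
the discontinuous initial data.  At these defaults the 24 h inner/outer
ratio of the default configuration is within about one percentage point
of its temporally converged value; `dt = 10` s is practically
converged.  Mass bookkeeping is exact by construction: the Neumann
sweeps conserve the discrete integral and the only loss term is the
per-spot sink flux, which is accumulated per step, so the mass-balance
error is at round-off level (the package still checks it, because it is
the canonical solver-defect detector).

Centered even-dimension layouts are solved on one quarter of the
chamber by default (symmetry planes carry the same no-flux condition as
walls; no spot straddles a plane because spot centers sit half a pitch
off the axes), and per-spot results are mirrored onto the full layout.
The full-domain mode is retained and tested against the quadrant mode.

### Chamber presets

Four preset geometries cover the design questions: `default`
(L = 10.8 mm, H = 150 µm, 30 x 30 spots, a wide spotless margin of
6.375 mm), `deep` (H = 750 µm, otherwise as default — a 5x height
increase isolates the effect of chamber depth), `small` (L = 4.5 mm:
the 8.85 mm spot block fills the 9 mm footprint, margin 75 µm), and
`full_coverage` (the physical chamber height of 250 µm with 5040
spots reaching the walls).  The block span is derived from the pitch:
29 pitches plus one spot diameter = 8.85 mm; rounded descriptions of
the block as "8.5 mm" are treated as nominal.

The simulations make three predictions, all driven by the spotless
margin: the default configuration shows a strong U-shaped profile with
the innermost positions receiving a few percent of the outermost flux;
deepening the chamber softens the shadowing (a deeper reservoir above
the spots reduces the outer rings' interception advantage) and roughly
doubles the inner/outer ratio; and removing the margin flattens the
profile.  The `small` preset makes the last point exactly: with a
75 µm margin (half the inter-spot gap) the 9 x 9 mm chamber is tiled
perfectly by identical 300 µm spot tiles, every spot is equivalent by
reflection symmetry, and the computed per-spot spread is at round-off
(~1e-15) — "the same within numerical error" is literal here.  The
`full_coverage` preset is more instructive than flat: its 72-column
axis tiles the 21.6 mm chamber exactly and is round-off flat, but the
70-row axis spans only 21.0 mm, leaving a genuine 375 µm spotless
strip, and the model confines the resulting enhancement to the
outermost two or three rows (+68%, +22%, +7%) with a flat interior.
Margin control, not spot count, is what matters.

A practical sensitivity worth knowing: by the time-rescaling property,
the inner/outer ratio depends on geometry and the product $D\,t$ only,
and it falls monotonically as $D\,t$ grows (boundary spots saturate
their supply while interior spots stay starved).  For the default
chamber the computed ratio is ~16% after the first hour, ~7% near 5 h,
and 3.7% at 24 h (all at D = 1e-9 m²/s).  Any comparison with scanned
or published figures therefore hinges on the effective diffusion
coefficient of the (fragmented, labeled) target, which is uncertain to
well over a factor of two in the literature; the package reports the
ratio for the parameters it is given and exposes the full time series
so users can judge this sensitivity themselves.  The headline
inner/outer percentages quoted in the README are recomputed from
scratch by `scripts/acceptance.R`.

## Position statistics

`summarizeByPosition()` averages unflagged spots per ring, pooling
replicate hybridizations; the error-bar convention is the standard
deviation of the per-hybridization ring means (`repMeanSd`).
Normalization is to the maximum ring mean (profile-fraction convention)
or the minimum (transect convention) — the two differ by one
multiplicative constant.  `innerOuterRatio()` reports
100 x mean(innermost ring)/mean(ring 1).  `positionTTest()` is the
classical pooled-variance Student's t-test; because the original
analyses do not state the unit of replication, the default treats the
replicate hybridization (not the spot) as the unit — ring means of
n = 3 triplicates — with a per-spot mode available.  With n = 2–3 per
group this is a deliberately blunt instrument; degenerate zero-variance
cases return t = 0, p = 1 when the means agree.  Two-colour ratios are
ratios of position means (not means of per-spot ratios, which are
noisier and biased under multiplicative noise); both statistics are
exposed.

## The synthetic-array generator

The generator exists so every analysis stage is testable without any
scanned image.  Its ring-mean model is phenomenological — a flat
interior plateau plus an exponentially decaying boundary enhancement,

$$\mu(\mathrm{ring}) = \mathrm{abundance} \times
  \bigl(\mathrm{base} + \mathrm{amplitude} \cdot
  e^{-(\mathrm{ring}-1)/\lambda}\bigr),$$

optionally hard-clipped at a saturation ceiling — while the mechanistic
prediction comes from the solver (`tableFromFlux()` bridges the two).
Spot intensities are the ring mean times lognormal multiplicative noise
with unit mean and fixed coefficient of variation: fluorescence
intensities are positive with roughly constant CV, and only standard
deviations, not distributional shapes, are available to calibrate
against, so the family is an implementation choice.  Defaults (base
5000 a.u., amplitude 15000 a.u., decay length 3 rings) give the ~3.9x
boundary-to-center contrast characteristic of target-limited
hybridizations on the 30 x 30 block; triplicate hybridizations, 10%
CV, and a 2% uniform-random bad-spot fraction mirror the experimental
design (visual-inspection flagging is not simulable, so flags are
random).  Setting the amplitude to zero gives the no-bias control
emulating a full-coverage or target-saturated array.

The two-colour fixture (`ratioBiasParams()`) encodes the ratio-bias
mechanism with the simplest device that reproduces it: channels at
effective abundances 2.9:1 and a ceiling placed so the boundary
position ratio is 2.6 while unclipped interior positions approach 2.9
— the measured boundary and center ratios of the calibration
experiment.  Clipping compresses the abundant channel exactly where
both signals are high (the boundary), so the ring-wise ratio rises
toward the center.  This is a calibrated illustration of
under-representation of low-abundance signals, not a mechanistic
saturation model, and those endpoint values are inputs here, not
predictions.

What passing tests on generator output do show: the estimators recover
known ring structure, normalization conventions behave, and the t-test
has approximately nominal size under the null.  What they cannot show:
robustness to spatially correlated artifacts (washing streaks, comet
tails, print-tip differences, inter-block gradients), none of which the
generator emulates.

## Numerical and design choices worth knowing

* Ring recovery fits (`fitBoundaryProfile()`) use Levenberg–Marquardt
  on the per-position means with non-negativity bounds; starting values
  come from the profile extremes.
* The solver rejects lateral resolutions coarser than the pitch and
  warns below 3 cells per spot diameter.  Quadrant symmetry requires
  even grid dimensions; odd grids must use `symmetry = "full"`.
* Degenerate inputs (empty rings after flagging, zero denominators in
  ratios and normalizations) produce warnings with dropped summaries or
  informative errors, never silent NaNs.
* Problem sizes used by the test suite and acceptance script: the
  24 h preset simulations run at 50 µm lateral resolution with quadrant
  symmetry (216 x 216 x 6 cells for the default chamber, 30 vertical
  cells for the deep one); solver property tests use a miniature
  8 x 8-spot chamber (L = 2.4 mm) where full-domain and quadrant runs
  take seconds.  These sizes were chosen so the whole refinement and
  oracle suite stays desk-scale while the headline ratios sit within a
  percentage point of their converged values.

## Limitations

The model deliberately omits finite hybridization rates at spots
(perfect sinks only — valid for P << 1 and target-limited conditions),
probe saturation, competition between different probe species,
advective mixing, temperature dependence, and any image-level
artifacts.  It predicts relative, not absolute, bound amounts.  The
experimental p-values and measured two-colour ratios of the original
arrays depend on scanned data this package does not ship; the package
reproduces the *model* quantities and provides calibrated fixtures for
the rest.
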