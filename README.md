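# spotbias

Diffusion-limited hybridization kinetics and spot-position bias in DNA
microarrays.

## The problem

Static (unmixed) microarray hybridizations show a reproducible spatial
artifact: spots at the boundary of the printed block are markedly
brighter than interior spots, peaking at the corners, and two-colour
intensity ratios drift with position.  The mechanism is lateral
diffusion: the spotless chamber floor around the block holds a
reservoir of labeled target that only the outer spot rings can reach,
while interior spots sit in their neighbours' diffusional shadow.
`spotbias` is for microarray users and chamber designers who want to
quantify this bias, test chamber geometries against it, and analyze
per-spot intensity tables position-wise.

The package provides:

* a **scaling analysis** that justifies treating spots as perfect
  sinks: the Damköhler-type number `P = (k B₀)⁻¹ / (R²/D)` compares the
  hybridization timescale with the diffusion timescale (`P ≪ 1` ⇒
  reaction is transport-limited, `C = 0` at the spot), with
  `B₀ = (2/3)(R/h_D) B_S` from hemisphere-to-disk probe conservation;
* a **3D unsteady diffusion solver** (`∂C/∂t = D∇²C`, Douglas–Gunn ADI,
  Rcpp) for a sealed chamber with absorbing spot disks on the floor and
  no-flux walls, integrating the per-spot Fickian flux `−DA ∂C/∂z` over
  the hybridization time;
* **ring-position bookkeeping** (concentric square "spot positions",
  diagonal and center-line transects) and **position statistics**
  (normalized ring profiles, inner/outer ratios, two-colour ratios by
  position, pooled-variance t-tests between positions);
* a **synthetic array-data generator** (boundary-enhanced ring profiles,
  replicate hybridizations, lognormal noise, optional saturation-driven
  two-colour ratio bias) so every stage is testable without scanned
  data;
* readers/writers for a minimal GenePix-results-style tab-delimited
  dialect and CSV, plus a thin CLI
  (`inst/scripts/spotbias-cli.R`).

## Worked example

```r
library(spotbias)

## Is the perfect-sink assumption justified for an 18-mer probe array?
scalingReport(kineticParams())
#> Scaling analysis (perfect-sink check):
#>   reaction timescale 1/(k B0):  0.016 s
#>   diffusion timescale R^2/D:   5.6 s (limiting length: R)
#>   P = 0.0028  (threshold 0.01): perfect-sink assumption JUSTIFIED
```

`P = 0.0028` means hybridization at the spot is ~350× faster than
diffusive resupply, so every arriving target strand is captured
immediately and the spots act as perfect sinks.

```r
## How strong is the boundary bias in a large, shallow chamber?
cfg <- configPreset("default")       # 21.6 x 21.6 mm, H = 150 um, 30x30 spots
fx  <- runSimulation(cfg$chamber, cfg$layout)   # 24 h, D = 1e-9 m^2/s
innerOuterRatio(fx)
#> [1] 3.691185
```

The innermost spots accumulate only ~3.7% of the outermost spots' 24 h
flux — a 27-fold position bias driven entirely by the 6.4 mm spotless
margin.  Shrinking the chamber so the spots tile it exactly removes the
bias completely:

```r
cfg <- configPreset("small")         # 9 x 9 mm chamber, same 900 spots
innerOuterRatio(runSimulation(cfg$chamber, cfg$layout))
#> [1] 100
```

Analysis of (here: synthetic) per-spot intensity tables works the same
way on real GPR/CSV tables:

```r
sim <- generateTables(syntheticArrayParams())   # 3 replicate hybridizations
head(normalizePositions(summarizeByPosition(sim$tables), "max"), 3)
#>   position   n     mean       sd repMeanSd relativeMean relativeSd relativeRepSd
#> 1        1 339 20111.64 2087.435  117.2198    1.0000000 0.10379240   0.005828457
#> 2        2 318 15650.17 1530.575  228.8660    0.7781651 0.07610397   0.011379779
#> 3        3 295 12864.59 1307.177  107.4796    0.6396590 0.06499606   0.005344152

positionTTest(sim$tables, ringA = 1, ringB = 15)$p   # boundary vs center
#> [1] 3.787105e-09
```

Here position 1 (the block perimeter, n = 339 unflagged spots over the
3 replicates) is ~29% brighter than its ring-2 neighbours and the
boundary-versus-center contrast is overwhelming (p ≈ 4e-9 on the
replicate ring means).

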