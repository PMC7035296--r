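# mycelia

Quantification of growing hyphal networks from whole-field time-lapse
panoramas.

A filamentous fungus expands as a planar network of hyphae: tips
("apexes") elongate, side branches appear, and tips that reach another
hypha fuse with it (anastomosis). From a time series of binary
whole-colony images this package extracts the centerline graph of the
thallus and the three global observables — apex count *A*, node count
*N*, total hyphal length *L* — fits their exponential growth laws, and
decomposes the exponents into the two biological rates via

    alpha_N = alpha_b + alpha_a        (every branching or fusion adds a node)
    alpha_A = alpha_b - alpha_a        (branching adds an apex, fusion removes one)

so that `alpha_b = (alpha_N + alpha_A)/2` is the branching rate and
`alpha_a = (alpha_N - alpha_A)/2` the anastomosis rate. Equivalently,
the log–log slope `rho` of *N* against *A* gives
`alpha_b/alpha_a = (rho + 1)/(rho - 1)`. The package also corrects
geometrical node counts for hyphal-overlap artifacts (two very close
degree-3 vertices) through a proximity criterion, reconstructs the
intra-thallus areas (the enclosed faces of the planar network) and
their fragmentation dynamics, and computes annulus/sector local
statistics with Mann–Whitney reproducibility tests.

Because raw microscope panoramas of this kind are not publicly
available, the package ships a first-class synthetic-data module: an
exact birth–death simulator of apex/node counts (the statistical
oracle) and a spatial lattice-free tip-growth simulator whose rendered
panoramas exercise the full image pipeline against known ground truth.

Audience: mycologists and biophysicists quantifying fungal growth
experiments, and modellers who need a tested reference implementation
of the branching/anastomosis rate decomposition.

## Worked example

Simulate a colony for eight hours, render the final panorama at the
microscope's resolution (3.516 µm/px, 7-px hyphae), vectorize it, and
compare with the simulation's ground truth:

```r
library(mycelia)

sim <- simulateNetwork(simParams(duration = 8, seed = 3))
sim
#> MyceliumSim: 17 hyphae, 7020 polyline points, 29 frames
#>   final tallies: A = 13 , N = 19.5 , L = 12.52 mm at t = 7.93 h

pan <- renderPanorama(sim)           # binary Panorama object
g   <- extractGraph(pan@pixels)      # centerline graph
classifyAndTally(g, time = 7.93)
#>   frame time_h  A Ng     L_mm  sigma_A sigma_Ng sigma_L n_decomposed n_boundary
#> 1    NA   7.93 12 20 12.39642 3.464102 4.472136      NA            1          0
```

The extracted tallies (A = 12, Ng = 20, L = 12.4 mm) sit within a few
percent of the ground truth (A = 13, N = 19.5, L = 12.52 mm): apexes
younger than ~15 min have not yet emerged from their parent's stroke,
and thinning erodes half a stroke width at each tip.

Rate decomposition at the reference merged-fit exponents:

```r
decomposeRates(alpha_N = 0.426, alpha_A = 0.322)
#> $alpha_b
#> [1] 0.374
#> $alpha_a
#> [1] 0.052
branchingAnastomosisRatio(1.28)
#> [1] 8.142857
doublingTime(c(A = 0.3283, Ng = 0.429, L = 0.3057))
#>        A       Ng        L
#> 2.111323 1.615728 2.267410
```

That is: branching (≈ 0.37 h⁻¹) outpaces anastomosis (≈ 0.05 h⁻¹)
roughly eightfold, and apexes, nodes and length double every ≈ 2.11,
1.62 and 2.27 hours.

The whole chain — simulate → binarize → vectorize → node correction →
rate fits → faces — is orchestrated by `runPipeline(pipelineConfig())`,
which writes `series.csv`, `rates.json` and `node_correction.json` with
a configuration hash for reproducibility.

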