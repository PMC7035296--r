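---
title: "Quantifying hyphal network growth from whole-field panoramas"
author: "mycelia package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyphal network growth from whole-field panoramas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycelia)
```

## The biological problem

A filamentous fungus colonizes its substrate as a growing planar network,
the thallus: hyphal tips (apexes) elongate at a few micrometres per
minute, sub-apical cells emit lateral branches, and tips that meet
another hypha fuse with it (anastomosis). Three global quantities
summarize the state of the network at any time: the number of apexes
$A$, the number of nodes $N$ (branch and fusion points, degree-3
vertices of the network), and the total hyphal length $L$. After a lag
phase of a few hours all three grow exponentially,
$A = A_0 e^{\alpha_A t}$, $N = N_0 e^{\alpha_N t}$,
$L = L_0 e^{\alpha_L t}$.

The central observation this package operationalizes is a bookkeeping
identity. Each branching event creates one apex and one node; each
anastomosis removes one apex and creates one node. Writing $\alpha_b$
and $\alpha_a$ for the per-apex branching and anastomosis rates,

$$\alpha_N = \alpha_b + \alpha_a, \qquad \alpha_A = \alpha_b - \alpha_a,$$

so the two biological rates follow from the two measurable exponents:
$\alpha_b = (\alpha_N + \alpha_A)/2$ and
$\alpha_a = (\alpha_N - \alpha_A)/2$ (`decomposeRates()`). Equivalently,
the log-log slope $\rho$ of $N$ against $A$ gives the rate ratio
$\alpha_b/\alpha_a = (\rho + 1)/(\rho - 1)$
(`branchingAnastomosisRatio()`). For the wild-type reference data
($\alpha_A = 0.322\ \mathrm{h^{-1}}$,
$\alpha_N = 0.426\ \mathrm{h^{-1}}$) this yields
$\alpha_b \approx 0.37\ \mathrm{h^{-1}}$ and
$\alpha_a \approx 0.05\ \mathrm{h^{-1}}$: branching outpaces fusion
roughly eightfold.

## Pipeline overview

The package mirrors the measurement chain of a whole-field imaging
experiment, every stage exposed as a function and orchestrated by
`runPipeline()`:

1. **Synthetic data** (`simulateCounts()`, `simulateNetwork()`,
   `renderPanorama()`): ground-truth generators standing in for the
   microscope.
2. **Image pipeline** (`maxEntropyThreshold()`, `binarizeAndClean()`):
   grayscale panorama to clean binary mask.
3. **Vectorization** (`extractGraph()`, `classifyAndTally()`,
   `totalLength()`): binary mask to centerline graph and per-frame
   tallies.
4. **Node correction** (`proximityNodeCount()`,
   `biologicalNodeEstimate()`, `lengthUncertainty()`): geometrical to
   biological node counts, with uncertainties.
5. **Growth dynamics** (`fitExponential()`, `mergedFit()`,
   `decomposeRates()`, `doublingTime()`): exponents and rates.
6. **Intra-thallus areas** (`extractFaces()`, `trackFragmentation()`):
   the enclosed faces of the planar network and their subdivision
   dynamics.
7. **Local statistics** (`buildSectorGrid()`, `sectorMeasures()`,
   `mannWhitneyCompare()`): annulus/sector measures and reproducibility
   tests.

## The two simulators and what they emulate

The package provides two deliberately different generators, decoupling
statistical correctness from geometric realism.

**The birth--death count model** (`simulateCounts()`) is the exact
stochastic counterpart of the rate equations: each apex independently
branches at $\alpha_b$ ($A \to A+1$, $N \to N+1$) and fuses at
$\alpha_a$ ($A \to A-1$, $N \to N+1$), scheduled event by event
(Gillespie). It is used wherever a statistical oracle is needed — rate
recovery, coverage of the fitted confidence intervals — because its
generating parameters are exactly the quantities the analysis estimates.
Extinct trajectories (the apex count absorbing at zero) are flagged and
excluded from ensemble fits by default; observed thalli never go
extinct. With the reference rates and three initial apexes over 18 h,
the fitted slope of the mean log apex count over 5--18 h lands at
$0.32 \pm 0.02\ \mathrm{h^{-1}}$; the slight downward shift from
averaging logs rather than counts is well inside that band.

**The spatial tip-growth model** (`simulateNetwork()`) grows an actual
planar network: tips advance at `elongation_speed` (default
180 µm/h, i.e. 3 µm/min) with a small zero-mean angular perturbation
per step (`direction_persistence`, default 0.35 rad/√h — hyphae are
nearly straight over a millimetre), branch at `branch_rate` at about
60° ± 20° from the parent, and fuse on proximity. The integration step
is 0.01 h. The default fusion distance is 25 µm, chosen to equal the
rendered stroke width (7 px at 3.516 µm/px): a tip fuses exactly when
its stroke would touch the target hypha in the raster, so the simulated
topology and the rendered topology agree. The colony starts as three
radial starter hyphae totalling 1 mm, matching the germinated-ascospore
initial condition ($A_0 = 3 \pm 1$, $N_0 = 1.5 \pm 1$, $L_0$ about one
millimetre).

In proximity mode the anastomosis rate is *emergent* — it depends on the
local density a tip experiences — so the realized $\alpha_A$ of a
spatial run differs from $\alpha_b - \alpha_a^{nominal}$, and recovery
tests compare pipeline estimates against the run's own event log, not
against the nominal parameters. In rate mode fusion is attempted as a
Poisson process but still requires a reachable hypha (within twice the
fusion distance), so its effective rate is below nominal early in
growth; the simulator's event log is again the reference.

What the simulator does *not* emulate: out-of-focus blur, illumination
gradients, stitching seams, the 30% optical thickening of hyphae, or
genuinely three-dimensional crossings. Passing round-trip tests
therefore demonstrates the internal consistency of the measurement
chain on geometrically clean data, not robustness to every optical
artifact of real panoramas.

```{r, eval = FALSE}
sim <- simulateNetwork(simParams(duration = 8, seed = 3))
tail(simTruth(sim), 3)
pan <- renderPanorama(sim)          # binary Panorama, 3.516 um/px
```

## Vectorization choices

`extractGraph()` computes the centerline by Zhang–Suen thinning and
reads the skeleton as a graph over its pixels. Two numerical details
matter:

* **Reduced adjacency.** A diagonal link between two skeleton pixels is
  kept only when no orthogonal two-step path connects them. Thinning
  leaves staircase triangles in which every pixel has three neighbours;
  under plain 8-adjacency these read as spurious junctions, under the
  reduced adjacency they are simple paths. This single choice removes
  almost all phantom apexes and junctions.
* **Junction clusters and micro-loops.** Junction pixels (three or more
  reduced neighbours) are clustered; clusters with centroids within
  2 px collapse to one vertex — one biological junction can split into
  junction pixels a couple of pixels apart, while genuinely distinct
  overlap nodes remain separate (and are handled downstream by the
  proximity correction). A chain shorter than 3 px that starts and ends
  on the same cluster is an artifact *unless* it encircles an enclosed
  background sliver; the implementation flood-fills the adjacent
  background (bounded at 25 px) and keeps the loop only when it bounds
  a real hole, which is what makes skeleton cycle counts agree exactly
  with face counts.
* **Spur pruning.** Terminal edges shorter than half a hypha width
  (3.5 px) are pruned as tip-cap artifacts; a real lateral branch
  younger than roughly 0.25 h has not yet emerged from its parent's
  stroke and is invisible to any raster-based method, so tally
  comparisons against simulation ground truth use events old enough to
  be resolvable.
* **Degree decomposition.** Vertices of degree $d \ge 4$ count as
  $d - 2$ nodes: a perfect crossing reads as two very close degree-3
  nodes, matching the convention under which the overlap correction is
  defined.
* **Boundary apexes** within 2 px of the raster edge are flagged and
  excluded from tallies; they are cut by the field of view.

`totalLength()` sums Euclidean polyline lengths; because chords
underestimate curved hyphae, each polyline is interpolated by a cubic
spline in chord-length parameterization and resampled on nested grids of
doubling density until two successive estimates differ by less than
0.1%. Nesting makes the estimate monotonically non-decreasing. On a
semicircle sampled at four points the refinement converges below 0.1%
per step and lands within about 0.8% of the true arc length; at nine
points, within 0.03%.

Accuracy on rendered simulations at the default 7-px stroke width:
apex counts within ±10% of truth, node counts within about ±10% of the
resolvable event count at moderate density (at high density merged
parallel strokes swallow junction structure and the node count drifts
low — the node-correction module's territory), total length within 5%
(thinning erodes half a stroke width at every tip).

## Node correction and uncertainties

A thick network pictured in 2-D shows overlaps of non-fusing hyphae as
*pairs of very close degree-3 nodes*, whereas real branch or fusion
nodes are isolated. `proximityNodeCount()` counts nodes with another
node within $n$ px (default $n = 20$ for 7-px hyphae, the reference
operating point); with $r = N^g_n / N^g$ approximately constant through
growth, `biologicalNodeEstimate()` reports $N = (1 - r) N^g$. At the
reference operating point $r \approx 20\%$ with $\sigma_r \approx
1.6\%$: at least ~80% of detected nodes are biological, with an
uncertainty of about 5% when the conservative $\Delta r = 3\sigma_r$
band is used. The uncertainty of $N$ combines
$\Delta N^g = \sqrt{N^g}$ (Poisson) and $\Delta r$ in quadrature —
the standard first-order completion, cross-checked against Monte-Carlo
propagation in the test suite. Count uncertainties are Poisson
($\sigma = \sqrt{\lambda}$); the length uncertainty is estimated by
re-summing after randomly excluding 10% of nodes (each removal deletes
that node's shortest incident edge — the least destructive reading of
"excluding nodes", selectable by flag), and its scaling exponent
against $L$ is reproduced near 0.61 on growing series, with the exact
binomial-thinning value 0.5 recovered on graphs of identical
independent edges.

## Growth-rate estimation

`fitExponential()` is ordinary least squares of $\ln y$ on $t$ inside
the window 5 h to $T_1$ (first apex at the panorama edge), with
uncertainties reported as twice the coefficient standard errors;
log-linear OLS was chosen over nonlinear least squares on raw counts
because it weights the early, information-rich frames sensibly, and a
flag switches conventions. `mergedFit()` pools experiments under a
single rate with the prefactor box-constrained (profile least squares:
for each rate the optimal log-prefactor is clamped to the box); when
the unconstrained optimum is interior the result coincides with the
plain pooled fit, and the pinned branch is verified against a grid
search. Reported rates are rounded to three decimals, doubling times
($\ln 2/\alpha$) to two, matching the precision of the reference
tables. Doubling times are computed from averaged rates rather than
averaged per-experiment doubling times; the two conventions agree at
print precision. The $N/A = 1$ crossing time is a diagnostic output,
not an asserted quantity — it is not reproducible from printed
prefactors alone.

## Intra-thallus areas

A face is a background region completely enclosed by the thallus:
`extractFaces()` takes the 8-connected foreground component containing
the colony centre, fills its holes, and labels the holes 4-connected —
the dual pairing that makes hole counting consistent with the
foreground topology. Areas are pixel counts (reported also in mm²);
representative interior points stand in for centroids of crescent
faces. Face statistics include the 8-class Fisher–Jenks natural-breaks
classification used for mapping (exact dynamic programme, inputs above
800 values condensed to weighted quantile bins, ties to the lower
class).

Two centroid conventions exist for dating faces through time, and the
package implements both in `appearanceTimes()`. The fragmentation
convention (default, `"child-in-parent"`) matches the cohort
bookkeeping of `trackFragmentation()`: a face inherits the age of the
earlier face containing its representative point, so subdivision
preserves age and only faces closed anew at the colony rim start a
cohort. The alternative (`"parent-in-child"`) dates a split so that
exactly one child keeps the parent's age. Cohort tracking with epochs
every five panoramas (1.6 h) reproduces, on a pixel-exact fixture, the
reference fragmentation figures: a region of 2 faces with mean
10905 px fragmenting to 9 faces with mean 1337 px between 4.9 h and
17.9 h. `densificationSlope()` fits face count against total length
(reference slope ≈ 1.7 mm⁻¹).

On simulated frames the face count equals the cycle rank $E - V + 1$ of
the extracted centerline graph exactly — the Euler-characteristic
consistency check run over 20 frames in the test suite. This holds at
the test's problem sizes (colonies up to ~7 h, a few hundred edges);
in denser thalli, slivers of background narrower than a stroke width
fall below the raster's resolving power and the correspondence can slip
by a face or two.

## Local sector statistics

`buildSectorGrid()` reproduces the reference layout: three annuli of
width 3516 µm (inner radii 1758, 3516, 5274 µm), each cut into 60
equal-area sectors, sector 1 starting at east, counterclockwise, the
centre fixed at the thallus centre of mass. `sectorMeasures()` counts
apexes and nodes by position and clips every edge analytically against
the annulus circles and sector rays, so clipped pieces sum exactly to
the original length (a dense-sampling clip validates this in the
tests). Standardized medians $(x - \mu_x)/\sigma_x$ flag degenerate
(all-equal) annuli as `NA` rather than 0. `mannWhitneyCompare()` runs
two-sided rank-sum tests on per-sector node densities $N_i/L_i$, using
alternate-sector subsets (odd vs even, 30 sectors each) for spatial
independence; zero-length sectors are dropped pairwise and the drop
count reported. Its type-I error is calibrated at ~5% on 200
identically-parameterized null pairs from `nullSectorMeasures()` — an
iid Poisson/gamma sector model, used because hundreds of spatial
simulation pairs would add hours of compute without changing what the
calibration measures, the behaviour of the test machinery under the
null.

## Problem sizes and determinism

The test suite and the acceptance script run simulations at desk scale:
colonies of 6.5--9 simulated hours (tens of apexes, 10--35 mm of
hypha, rasters under ~1200² px), 10-seed ensembles for the end-to-end
rate recovery, and 200+ replicates for count-model fits. These sizes
put every stochastic check well inside its tolerance while keeping the
full suite in the tens of minutes. Every stochastic function takes an
explicit integer seed, records it, and restores the caller's RNG state;
identical parameters give bit-identical simulations, panoramas and
pipeline outputs.

## Known limitations

* Tally accuracy degrades with raster density: merged parallel strokes
  swallow junctions and underestimate $N^g$ beyond what the proximity
  correction can restore. Real panoramas have the same physics; the
  package reports counts, it does not deconvolve blobs.
* Branches younger than ~0.25 h and spurs shorter than half a stroke
  width are below resolution by construction.
* Temporal apex tracking between frames is out of scope; each frame is
  processed independently, and ambiguous-apex resolution across frames
  (done by eye in the reference workflow) is represented only by the
  boundary/spur flags and the false-positive bookkeeping of
  `detectionErrorRates()`.
* The spatial simulator is 2-D with no nutrient field, tropism,
  septation or width dynamics; its defaults describe the reference
  wild-type conditions and are not meant to span other species or
  media.
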