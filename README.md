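# gibbsColoc

Object-based spatial interaction analysis for microscopy: infer
effective pairwise interaction potentials between two populations of
sub-cellular objects — e.g. virus particles (points) and endosome
outlines (closed polygons) inside a cell — from their nearest-neighbour
(NN) distance distribution.

## Why

The classical object-based co-localization measure counts the fraction
`C^t` of objects closer than a threshold `t` to their nearest reference
object. That number confounds interaction with the *cellular context*:
dense reference objects produce high `C^t` regardless of biology.
`gibbsColoc` separates the two with a spatial-statistics model built on
two quantities:

* the **state density** `q(d)`: the distribution of signed NN distances
  (negative inside a reference outline) for a *uniformly random* point
  in the cell region — the "no interaction" null that summarises the
  context;
* the **interaction potential** `φ(d) = ε f((d−t)/σ)`: observed
  distances follow the Gibbs distance model

  `p(d) = q(d) exp(−φ(d)) / Z`, with partition function
  `Z = ∫ q(d) exp(−φ(d)) dd`.

Threshold co-localization is the special case of a step-shaped `f`, and
its context-corrected strength estimate is the log odds ratio
`ε̂ = log[C(1−C0) / (C0(1−C))]` against the baseline
`C0 = ∫_{d<t} q(d) dd`. Non-step families (Plummer, Hermquist, two
linear ramps, plus a penalised non-parametric potential) capture
longer-ranged interactions, and their sufficient statistics
`T = −Σ f((d_i−t)/σ)` yield Monte-Carlo rank tests that can be several
times more sample-efficient than threshold counting.

The package provides: exact binomial tests and power analysis for the
step potential; MC rank tests, a non-parametric binned test, MC power
estimation and minimal-sample-size search; maximum-likelihood fitting
(per-cell strength, joint strength/scale, pooled fits with a common
scale across cells, penalised non-parametric potentials); a
Nadaraya-Watson smoother for time courses of per-cell estimates; CSV /
GeoJSON / PNG / TIFF input of points, outlines and domain masks; a
synthetic-scenario generator with known ground truth; and a small CLI
(`exec/gibbscoloc`).

## Worked example

A synthetic cell: 100 circular reference objects of radius 3.57 px in a
200 × 200 px domain (nominal covered area fraction 0.1), and 150 points
placed under a long-ranged attractive Plummer potential (`ε = 1`,
`σ = 5` px):

```r
library(gibbsColoc)
spec <- scenarioSpec(seed = 11, N = 150,
                     potential = interactionPotential("plummer", 1, 5, 0))
cd <- generateScenario(spec)           # objects, distances, q(d), truth

colocAnalysis(cd@distances, cd@q, t = 0)
#> Co-localization ('sim'): t = 0 px, N = 150
#>   C = 0.0933, C0 = 0.0968, epsilon_hat = -0.0406 (ok)

mcRankTest(cd@distances, cd@q, "plummer", sigma = 5, K = 999, seed = 1)
#> MC rank test ('sim'): statistic T_plummer = 101.5, N = 150, K = 999
#>   rank 991 of 1000, p = 0.01, alpha = 0.05 -> reject H0

fitStrength(cd@distances, cd@q, "plummer", sigma = 5)
#> Strength fit (plummer, sigma = 5, t = 0): epsilon = 0.6732 +/- 0.3124, loglik = -475.6123
```

Read bottom-up: the observed co-localization (9.3% of points inside an
outline) is indistinguishable from the context baseline (9.7%), so the
classical threshold measure finds nothing — the interaction acts over
~5 px and barely changes the *sign* of the distances. The rank test
with the matched Plummer statistic rejects "no interaction" at
p = 0.01, and the maximum-likelihood strength (0.67 ± 0.31) is
consistent with the generating ε = 1. See
`vignettes/interaction-analysis.Rmd` for the model, the estimators and
their assumptions.

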