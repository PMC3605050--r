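---
title: "Maximum-likelihood cline analysis for hybrid zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood cline analysis for hybrid zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hzcline)
library(dplyr)
```

## The problem

When two divergently adapted ecotypes meet and hybridize along a geographic
gradient, allele frequencies at loci under divergent selection change
steeply across the contact zone while neutral loci introgress freely. The
shape of each locus's *cline* — how allele frequency changes with position
along a one-dimensional transect — summarizes the balance between selection,
which steepens and anchors clines, and gene flow, which widens and shifts
them. Comparing cline shape across loci (and against a phenotypic cline
coded the same way) therefore separates loci that track the selected trait
from loci with an independent evolutionary history.

`hzcline` implements that analysis end to end: a parametric cline curve, a
binomial likelihood for per-population allele counts, bounded multi-start
maximum-likelihood fitting, profile-likelihood support limits, nested and
cross-locus likelihood-ratio tests, and the supporting population-genetic
computations (between-ecotype F_ST, F2 map distance, exact association
tests, phenotype-coded clines, transect projection). A seeded simulator
generates every input the pipeline consumes, so the whole analysis is
testable without field data.

## The cline model

The scaled cline $s(x) \in (0,1)$ is a logistic sigmoid in the centre,

$$ s_0(x) = \frac{1}{1 + e^{-4(x - c)/w}}, $$

where $c$ is the cline centre (the position of the maximum gradient) and
$w$ the cline width, defined as the inverse of the maximum slope so that
$s_0'(c) = 1/w$. Beyond junction points at $x_L = c - z_L$ and
$x_R = c + z_R$ the sigmoid is replaced by exponential tails. On the left,

$$ s(x) = s_0(x_L)\, e^{\theta_L \lambda_L (x - x_L)}, \qquad
   \lambda_L = \frac{4/w}{1 + e^{-4 z_L / w}}, $$

and symmetrically on the right with $1 - s$. Here $\lambda_L$ is the
log-slope of the sigmoid at the junction, so the tail is tangent to the
sigmoid in log space when the decay-rate ratio $\theta_L = 1$ and decays
more slowly (heavier introgression) when $\theta_L < 1$. The construction
guarantees value continuity for every admissible parameter vector and slope
continuity at a junction exactly when that side's $\theta$ is 1. The
observable allele frequency is an affine rescaling between the asymptotic
end frequencies,

$$ p(x) = p_L + (p_R - p_L)\, s(x), $$

so a descending cline is simply $p_L > p_R$; the internal scaled curve is
always ascending.

**A deliberate design point.** An exponential tail is never *equal* to the
logistic tail of $s_0$, even at $\theta = 1$, $z = 0$ — it is tangent at the
junction and heavier further out. The pure sigmoid model is therefore
selected by an explicit per-side `tails` flag on `cline_params()` (and by
`model = "sigmoid"` in `fit_cline()`), not by magic parameter values. The
tail algebra is isolated in `scaled_cline()` so an alternative
parameterization (e.g. $\sqrt{\theta}$ in the exponent, found in some
descendants of the Szymura–Barton model family) could be swapped in one
place. Equally, $z$ is interpreted as the distance from the centre to the
tail *junction*; nothing in the package encodes a vertical asymptote.

## Likelihood and fitting

Populations are assumed independent, with $k_i$ focal alleles out of $n_i$
sampled copies drawn binomially at probability $p(x_i)$. The log-likelihood
clamps model frequencies to $[10^{-9}, 1 - 10^{-9}]$ so that data fixed for
one allele at a boundary frequency keep a finite likelihood. Genotypes are
converted to allele counts assuming Hardy–Weinberg proportions within
populations (no inbreeding correction), and populations with $n = 0$
contribute nothing.

Two model families are exposed:

* the **two-parameter (sigmoid) model** frees only $c$ and $w$, with tails
  off and $p_L$, $p_R$ fixed (0 and 1 by default, overridable);
* the **eight-parameter (tails) model** frees all of
  $c, w, \theta_L, \theta_R, z_L, z_R, p_L, p_R$.

Fitting maximizes the likelihood with bounded L-BFGS-B from multiple
starts: one data-driven heuristic start plus Latin-hypercube draws over the
parameter box ($c \in [\min x - \mathrm{span}, \max x + \mathrm{span}]$,
$w \in [0.01, 10\,\mathrm{span}]$, $z \in [0, \mathrm{span}]$,
$\theta \in [10^{-3}, 1]$, $p \in [0, 1]$, with span the extent of the
sampled transect). The default of 20 starts is conservative for routine
use; the simulation studies in the test suite use 6–8 starts, which is
sufficient for well-identified simulated data of 20–30 populations.
Deviances are clipped at zero because optimizer noise can leave a
constrained optimum marginally above the free one. Replicate
eight-parameter fits of the same data can differ by about 0.1
log-likelihood units along the weakly identified $\theta$–$z$ ridge when a
cline has no real tails; this is negligible against the 6-d.f. chi-square
scale on which shape tests are read, but it is why a duplicated-data
comparison yields a deviance *near* rather than exactly zero.

Support limits are 2-log-likelihood profile intervals (analogous to 95%
confidence intervals): for each free parameter, the nearest point on each
side of the estimate where the profile log-likelihood (re-optimizing all
other free parameters, warm-started from the MLE) has dropped by 2 units,
located by bisection to a tolerance of $10^{-3}$ log-likelihood units. A
side on which the profile never drops by 2 inside the parameter box is
reported at the box bound and flagged unbounded.

```{r fit-example}
truth <- cline_params(center = 50, width = 8, tails = "none")
zone <- simulate_zone(truth, positions = seq(34, 66, length.out = 30),
                      n_alleles = 80, seed = 1)
fit <- fit_cline(select(zone, -locus), model = "sigmoid", n_starts = 8)
tidy(fit, support = TRUE) |> filter(free)
```

## Comparing cline shapes across loci

Whether two loci share a cline is tested with a constrained
likelihood-ratio statistic. Because the asymptotic frequencies are nuisance
parameters of each locus, the constrained model for the ordered pair
$(i, j)$ keeps locus $i$'s own $p_L, p_R$ and pins the six *shape*
parameters to locus $j$'s ML estimates; nothing is re-optimized (a
`reoptimize_p` flag offers re-fitting of the two nuisance frequencies as a
sensitivity analysis). The deviance

$$ D_{ij} = 2\,(\ln L_i^{\text{free}} - \ln L_i^{\text{constrained}}) $$

is compared to $\chi^2_6$. $D$ is ordered — $D_{ij} \ne D_{ji}$ in general
— and the matrix is deliberately not symmetrized. With $m$ markers all
$m(m-1)$ ordered pairs are tested, so the family-wise level is Bonferroni
split over $m(m-1)$ tests (the divisor is configurable; the ordered-pair
convention is the default because it matches the per-test level of about
$5.6\times10^{-4}$ for ten markers at a family level of 0.05, with critical
deviance 23.85). A phenotypic cline, coded as genotype counts
(red $\to$ 2, red-orange/orange $\to$ 1, yellow $\to$ 0 via
`phenotype_to_cline_counts()`), enters the comparison as an ordinary tenth
marker.

The same statistic in nested form (`lrt_nested()`) compares the
eight-parameter against the two-parameter fit of one locus at 6 d.f.

## Supporting computations

* **F_ST** uses Weir & Cockerham's $\theta$ with the two ecotypes as the
  two subpopulations, pooling populations within ecotype, computed from
  diploid dosages with missing genotypes excluded pairwise per locus. The
  estimator equals 1 exactly at a fixed difference and can be slightly
  negative without differentiation. Numerical agreement with AMOVA-based
  estimators from other software is expected only in the fixed-difference
  case.
* **Map distance** treats each recombinant F2 individual as carrying
  exactly one recombinant gamete, $r = \text{recombinants}/2N$; `direct`
  ($100r$) is the default map function, with Haldane and Kosambi available
  for $r < 0.5$.
* **Exact tests** delegate to the conditional exact test
  (point-probability two-sided rule for 2×2; exact enumeration for small
  2×K tables and seeded Monte-Carlo resampling above a total-count
  threshold, with the replicate count reported). A zero-margin table
  carries no information and returns $p = 1$ with a warning.
* **Geography** projects 2-D sampling localities to the 1-D transect as the
  shortest straight-line distance to a coastline polyline, computed on a
  local equirectangular projection centred at each point (error well under
  0.5% at the ~100 km extent of a coastal hybrid zone, verified against a
  geodesic computation in the test suite). Precomputed distances can be
  supplied directly, and a longitude-based fallback projection is provided.

## What the simulator does and does not emulate

`simulate_zone()` draws allele counts binomially from a true cline —
exactly the sampling model the likelihood assumes. `simulate_ecotype_panel()`
draws Hardy–Weinberg genotypes at each group's frequency, and
`simulate_f2()` draws two gametes per individual, each recombinant with
probability $r$. All generators are pure functions of their configuration
and seed.

Because simulation is model-consistent, passing tests demonstrate correct
inference *under the model's assumptions*. Real hybrid-zone data violate
those assumptions in known ways the simulator deliberately omits: spatial
autocorrelation among nearby populations, drift, inbreeding within
populations (F_IS), linkage disequilibrium between markers, and
heterogeneous per-population sampling. Coverage and calibration measured
here do not certify performance under those violations;
model-misspecification stressors are an extension, not a default.

Default simulated study conditions mirror the reference sampling design:
30 populations across the zone, 80 allele copies (40 diploids) per
population for recovery studies, 200 for null-calibration runs of the
shape test (a "large n" regime where both fits are well identified), and
fixed-ecotype panels of 267 and 107 diploids.

## Numerical choices and limitations

* Model frequencies are clamped at $10^{-9}$ in the likelihood; the scaled
  curve itself is clamped to the largest representable open interval so
  extreme tail positions cannot round to exactly 0 or 1.
* The profile-limit bisection stops at $10^{-3}$ log-likelihood units or 60
  iterations, whichever comes first.
* Monte-Carlo exact tests switch on above a total table count of 500 by
  default.
* The optimizer treats $\theta = 1$ as an admissible boundary value (not a
  limit), so a tail-free fit is representable.
* No selection or dispersal coefficients are estimated from $w$; the
  package stops at cline description and comparison. MCMC posterior
  sampling, spatial autocorrelation, inbreeding corrections, hierarchical
  AMOVA, and multi-allelic loci are out of scope.

## Session

```{r session}
sessionInfo()
```
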