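---
title: "Methods: BYM smoothing, hotspot classification and spatial autocorrelation in baymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BYM smoothing, hotspot classification and spatial autocorrelation in baymap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baymap)
```

## The problem and the model

Small-area disease mapping asks whether particular administrative areas
carry excess risk of disease incidence or mortality relative to a
reference population. The raw standardized ratio `O_i / E_i` answers
this badly in sparsely populated areas: a remote shire with two expected
cases swings wildly with every observed case. `baymap` implements the
Besag–York–Mollié (BYM) convolution model, the workhorse remedy:

$$O_i \sim \mathrm{Poisson}(E_i\,\theta_i), \qquad
  \log\theta_i = \alpha + u_i + v_i$$

with a spatially structured effect $u$ under an intrinsic conditional
autoregressive (ICAR) prior and an exchangeable unstructured effect
$v_i \sim N(0, 1/\tau_v)$. The ICAR prior has density
$\propto \exp\!\big(-\tfrac{\tau_u}{2}\sum_{i\sim j}(u_i-u_j)^2\big)$
over unordered contiguity pairs; it is improper (constant shifts within
each connected component are unpenalized), so the model is identified by
constraining $u$ to sum to zero within each component. Expected counts
come from internal indirect standardization,
$E_i = \mathrm{pop}_i \cdot \sum_j O_j / \sum_j \mathrm{pop}_j$, which
makes $\theta = 1$ the all-areas average by construction: no external
reference rate is needed, and $\sum E_i = \sum O_i$ exactly.

Assumptions worth stating plainly: counts are conditionally Poisson
(no extra-Poisson clustering beyond what $u$ and $v$ absorb), the adult
population is an adequate exposure denominator pooled over the study
period, and contiguity (shared land boundary) is an adequate notion of
neighborhood for the smoothing prior.

## Adjacency construction

Rook contiguity is computed combinatorially rather than geometrically:
every polygon ring is decomposed into directed segments, coordinates are
snapped to a grid of size `tol` (default 1e-8 coordinate units), segment
orientation is normalized, and two areas are neighbors when they share
at least one full snapped segment. This is deterministic, robust to
floating-point jitter on shared borders, and excludes corner-only
(queen) contacts by construction. The trade-off: two areas whose shared
border is digitized with *different* vertex sequences in the two
polygons will not be detected as neighbors. For that situation, or for
authoritative weights from other tools, GAL contiguity files can be read
and written directly (`read_gal` / `write_gal`), with symmetry and
degree consistency validated on read.

Island areas (no shared land boundary) are deliberately **not**
auto-connected. The ICAR prior is undefined for a degree-zero area, so
`fit_bym` stops and directs the user to `assign_neighbor()`, which adds
a symmetric edge to an explicitly chosen nearest neighbor and refuses
(without `force = TRUE`) to modify areas that already have neighbors.
Making the fix explicit mirrors how island adjustments are actually
documented in applied analyses and prevents silent graph edits.

## Priors, the sampler, and its numerical choices

Defaults follow common WinBUGS-style practice for BYM models:

| parameter | default | meaning |
|---|---|---|
| intercept prior | $N(0, 10^6)$ | vague; alpha is log overall risk |
| $\tau_u, \tau_v$ hyperprior | Gamma(0.5, 0.0005) | vague; shape/rate on precisions |
| schedule | 500,000 / 300,000 / 20 | iterations / burn-in / thinning → 10,000 draws |
| chains | 1 | single chain, Geweke-diagnosed |
| proposal target | 0.44 acceptance | scalar random-walk optimum |

The Gamma(0.5, 0.0005) choice is one widely used "noninformative"
convention for BYM precisions; Gamma(0.001, 0.001) is the usual
sensitivity alternative and both are plain `bym_config()` arguments.
Because vague Gamma hyperpriors are known to influence the variance
partition between $u$ and $v$ in small datasets, no test or reported
quantity in this package depends on the posterior values of the
precisions themselves.

The sampler is Metropolis-within-Gibbs, written in C++:

* `alpha`, each `u_i`, each `v_i`: random-walk Metropolis against the
  full conditional. For `u_i` the conditional prior is
  $N(\bar u_{N(i)}, 1/(\tau_u d_i))$ — mean of neighbors, precision
  proportional to degree.
* Proposal scales adapt by Robbins–Monro toward 0.44 acceptance
  **during burn-in only** and are frozen afterwards, so retained draws
  come from a fixed, valid Markov kernel.
* After every sweep, `u` is recentred to sum to zero per connected
  component and the subtracted mean is absorbed into `alpha` — the
  standard identifiability treatment of the intrinsic prior. On a
  connected graph the absorption leaves the likelihood exactly
  unchanged; with several components the overall mean is absorbed and
  the recentring acts as the prior's own sum-to-zero constraint.
* $\tau_u, \tau_v$: exact conjugate Gamma draws, with the ICAR's
  rank deficiency reflected in the `(n - G)/2` shape increment
  (G = number of components).

Correctness is tested against independent oracles rather than asserted:
conjugate draws against closed-form Gamma moments; the stationary
marginal of $u_1$ on a three-area path (precisions fixed) against
direct grid quadrature of the model density, with a Kolmogorov–Smirnov
distance under 0.02; and simulation-based recovery on a 20×20 lattice
(E ≈ 50 per area, $\alpha = 0.3$, $\tau_u = 2$, $\tau_v = 10$), where
95% credible intervals must cover at least 90% of true relative risks
and the posterior mean of $\alpha$ must land within ±0.1. The reduced
schedules used there (50,000/25,000/5 for recovery; one million sweeps
for the quadrature check) were chosen as the smallest runs that give
those checks stable Monte Carlo behaviour.

Relative-risk summaries are computed from `exp(alpha + u_i + v_i)` per
retained draw — never from summaries of the components, which Jensen's
inequality would bias. Quantiles use linear interpolation between order
statistics (R type 7); intervals are equal-tailed, matching the usual
reporting convention of WinBUGS-era analyses, not HPD.

## Hotspot classification

With internal standardization the reference risk is exactly 1, so
classification reads directly off the posterior summaries:

* `significant_low` — upper 95% limit < 1;
* `not_significant` — interval contains 1;
* lower limit > 1 (significantly high), subdivided:
  * `elevated_1_100` — median at most double the reference;
  * `high_over_100` — median more than double (median > 2);
  * `consistently_over_100` — the *entire* interval above double
    (lower > 2).

All inequalities are strict; a boundary value (lower limit exactly 1.0
or 2.0, median exactly 2.0) falls to the lower band. "Between 1% and
100% higher" is a statement about the *median*, not the interval —
this reading is pinned down by the worked example in the test suite
where a median of 1.87 with interval [1.38, 2.49] lands in the 1–100%
band even though its upper limit exceeds 2.

## Moran's I and LISA

Global Moran's I uses the cross-product form
$I = (n/S_0)\sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2$ on row-standardized
rook weights by default (binary weights by flag); the optimized edge-list
implementation is tested to 1e-12 against a dense double-sum oracle and
against `ape::Moran.I`. Local Moran uses $m_2$ with divisor $n$, which
preserves the exact identity $\tfrac1n\sum_i I_i = I$ under
row-standardized weights.

Permutation inference is Monte Carlo with pseudo p-value
$(m+1)/(M+1)$, one-sided in the direction of the observed departure
from $E[I] = -1/(n-1)$ — the convention of the GeoDa lineage of tools.
Two consequences are worth knowing. First, the smallest attainable p at
99,999 permutations is exactly 1/100,000. Second, a one-sided p in a
*data-chosen* direction is approximately uniform on (0, ½) under the
null, not on (0, 1); calibration must therefore be assessed either on
the positive-direction test alone (which rejects at the nominal rate)
or on the doubled value `min(2p, 1)`. The test suite does both; users
comparing p-values across tools should keep the convention in mind.

LISA inference is conditional: each area's own value is held fixed and
its neighbors are redrawn from the remaining $n-1$ values without
replacement. Each area consumes its own counter-based random substream
(splitmix64 keyed on the master seed and the area index), so per-area
p-values are reproducible and independent of processing order. No
multiple-testing correction is applied by default (matching standard
LISA practice); `fdr = TRUE` applies Benjamini–Hochberg. Neighborless
areas have no spatial lag and are excluded with a warning.

## The synthetic-data module

The generator exists so that every downstream stage is testable with no
restricted data. It emulates, deliberately:

* **Geography** — rectangular unit lattices of any size (the acceptance
  runs use 6×13 = 78 areas, the LGA count of the motivating setting);
* **Populations** — log-uniform between 500 and 500,000, reproducing
  the heavy right skew of real administrative areas;
* **Risk surfaces** — exact ICAR draws via spectral decomposition of
  the graph Laplacian (zero variance on each component's constant
  mode), plus independent Gaussian noise and Poisson counts, with true
  relative risks recorded for recovery tests;
* **A patient-level registry** — 23,917 records whose filtered cohort
  of 23,853 reproduces published cohort marginals *exactly* for every
  seed: sex 18,491/5,362; age bands 1,349/12,077/10,427; eight site
  groups (lip 6,512 … salivary 64); five grade levels; 9,721 alive /
  14,132 dead; 6,714 deaths within 36 months and 8,338 within 60.
  Survival months are drawn uniformly *within* the window each death
  must satisfy, with a 0.2-month guard band so that converting to dates
  and back (months = days / 30.4375, a fixed documented convention)
  can never move a record across a window boundary.

What it does **not** emulate: joint structure between attributes (site
× sex × age are independent given their marginals, because only
marginals are published); registry close-out (synthetic death dates may
fall after the nominal end of follow-up, which is irrelevant to window
counts); diagnosis-year trends (dates are uniform over 1982–2018); and
any real geography. Passing tests therefore demonstrate that the
*pipeline arithmetic and inference machinery* are correct under the
assumed data-generating process — not that any substantive
epidemiological finding transfers to real registry data.

Exclusion rules are code-driven: under-15 by age, branchial-cleft
tumours by ICD-10 code C10.4 (the branchial-cleft rubric, carved out of
the C09–C10 oropharynx group), unspecified sites by C14.x. The site
grouping table is a plain configurable list; C01 (base of tongue) sits
in the oral-cavity group by default, a convention the tests exercise as
overridable since published groupings differ on it.

## Pipeline and reproducibility

`run_pipeline()` is exactly the six stage functions run in order, with
files as the interchange contract (GeoJSON geometry, CSV counts and
draws, GAL adjacency, JSON diagnostics and Moran results). The manifest
records an md5 hash per artifact; the test suite asserts that a rerun
with the same seed is hash-identical and that stage-wise execution
equals the monolithic run. All randomness flows from a single master
seed through named substreams, so no result depends on execution order.

## Known limitations

* One spatial model (BYM with ICAR); no Leroux-type alternatives or
  model-comparison criteria, and no covariates or space–time terms.
* Single-denominator standardization (one pooled rate, one census
  population); no age-standardization against an external standard.
* Rook contiguity assumes consistently digitized shared borders; use
  GAL import when geometry quality is unknown.
* Single-chain defaults: between-chain diagnostics (Gelman–Rubin) are
  not computed by default, though multiple independent fits with
  different seeds are cheap for any schedule short of the full one.
* The full 500,000-iteration schedule is faithful but slow on large
  graphs; all correctness tests run on reduced schedules whose sizes
  are stated above.
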