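---
title: "Geogenetic maps: model, inference and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geogenetic maps: model, inference and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mapmix infers a *geogenetic map*: a two-dimensional embedding of sampled
populations in which pairwise distance predicts the covariance of
standardized allele frequencies, and in which covariance that is anomalously
strong over long distances is explained by explicit admixture from an
inferred source location. This vignette is the package's own account of the
model, the numerical and design decisions behind the implementation, and
what the validation suite does and does not demonstrate.

## The data layer

The input is a pair of K × L integer matrices: counted alleles $C_{k\ell}$
and totals $S_{k\ell}$ at L biallelic loci in K populations. With sample
frequencies $\hat f_{k\ell} = C_{k\ell}/S_{k\ell}$ and the size-weighted
pooled frequency $\bar f_\ell = \sum_k C_{k\ell} / \sum_k S_{k\ell}$,
`standardize_freqs()` forms

$$\hat X_{k\ell} = \frac{\hat f_{k\ell} - \bar f_\ell}
                        {\sqrt{\bar f_\ell (1 - \bar f_\ell)}},$$

and the sample covariance $\hat\Omega = \hat X \hat X^\top / L$. The
centering by $\bar f_\ell$ makes the result invariant to which allele was
counted, and removes one degree of freedom: $\hat\Omega$ has rank K − 1.
The likelihood therefore works with the projection $\Psi^\top \hat\Omega
\Psi$, where $\Psi$ (K × (K−1), orthonormal columns) spans the column space
of the mean-centering matrix $T_{ij} = \delta_{ij} - \bar S_j / \sum_k \bar
S_k$. $\Psi$ is taken from the QR decomposition of $T$ with the signs of
the triangular factor's diagonal forced nonnegative, so runs are bit
reproducible; the likelihood is provably invariant to the choice of
orthonormal basis, and the test suite asserts this to 1e-8 under random
rotations of the basis.

Choices a user can make here:

* `min_minor_count` (default 1): loci whose pooled minor-allele count falls
  below it are dropped and logged. Monomorphic loci (pooled frequency 0
  or 1) always fall in this class — their standardization is undefined. The
  original preprocessing is not documented; dropping is our choice.
* A locus with $S_{k\ell} = 0$ anywhere is dropped with a warning: the
  shared centering matrix assumes every population is observed at every
  locus. A warning is also emitted when mean sample sizes differ more than
  5-fold across populations (threshold ours), since one global $T$ built
  from $\bar S$ is then a poor approximation.

## The spatial covariance model

Covariance decays with distance by a powered exponential,
$F(D) = \alpha_0^{-1}\exp(-(\alpha_1 D)^{\alpha_2})$, with sill
$1/\alpha_0$ (covariance at distance zero), rate $\alpha_1$ (per unit
distance), and shape $\alpha_2 \in (0.1, 2]$. Each population adds a nugget
$\eta_k \ge 0$ (variance unexplained by the spatial model) and sampling
noise $1/\bar S_k$ on the diagonal. Under admixture, population $k$ draws a
fraction $w_k \in [0, 0.5]$ of its alleles from a source location $G^*_k$,
giving the four-term mixture covariance implemented in `admixed_cov()`;
with all $w = 0$ it reduces exactly to the no-admixture form (asserted in
tests, as is a second degeneracy: $w = 0.5$ with $G^* = G$ changes
nothing).

The sample covariance is modeled as Wishart:
$L\,\Psi^\top\hat\Omega\Psi \sim W(\Psi^\top\Omega^*\Psi,\ L)$, a
large-L central-limit approximation that makes all computation independent
of L after the covariance is formed. `wishart_loglik()` includes the full
normalizing constant (multivariate gamma), so log posteriors are comparable
across runs; it cancels in acceptance ratios.

Distances are great-circle arcs on a unit sphere (coordinates in degrees)
or Euclidean in an abstract plane; simulated lattices use the plane. The
powered exponential on great-circle distances is not guaranteed positive
definite for $\alpha_2 > 1$. Rather than restricting the prior support, any
state whose projected covariance fails its Cholesky factorization gets log
likelihood −∞ and is rejected by the sampler — no jitter, no silent
regularization. This keeps the accept/reject mechanics exact at the cost of
occasionally proposing into a dead zone.

## Priors

| parameter | prior | notes |
|---|---|---|
| $\alpha_0$ | Exp(rate 1/100) | weak; sill scale |
| $\alpha_1$ | Exp(1) | decay per unit distance |
| $\alpha_2$ | U(0.1, 2) | shape |
| $\eta_k$ | Exp(1) | nugget |
| $2 w_k$ | Beta(1, 100) | deliberately harsh: admixture must earn its keep |
| $G_k$ | N(center$_k$, $\bar D/2$) | isotropic in model distance |
| $G^*_k$ | N(centroid, $2\bar D$) | very weak |

$\bar D$ is the mean pairwise distance among the prior location centers.
Centers are the observed coordinates, or (`location_prior = "random"`)
uniform draws from their bounding box — the mode used for all lattice
validation runs, so the data rather than the prior anchor the map. The
two-dimensional location priors are specified only by a mean and scale; we
implement them as isotropic Gaussians in model distance
($\log p = -d^2/2\sigma^2 + \text{const}$), which is rotation invariant
and metric consistent. The Beta prior on $2w_k$ carries its
change-of-variables factor 2 so reported posteriors are proper densities;
both constants are irrelevant to acceptance ratios. The cap $w_k \le 0.5$
keeps the labels "location" and "source" identifiable; even so, chains can
(and do) swap a heavily admixed population's location with its source —
a genuine symmetry of the model, visible in validation runs.

## The sampler

One randomly chosen block is updated per iteration: a scalar
($\alpha_0, \alpha_1, \alpha_2$), or a single population's $\eta_k$,
$w_k$, $G_k$ or $G^*_k$ — uniform over the variant's free blocks (the four
model variants fix different subsets; fixed blocks never move, which the
tests assert over whole chains). Scalar proposals are symmetric normals
with scale $e^{\zeta_i}$. Location proposals on the sphere draw an arc
distance $|N(0, e^{2\zeta})|$ and a uniform bearing and take the standard
great-circle destination point — the textbook formula with the
$+$ between the two sine/cosine products; planar chains use an isotropic
Gaussian jitter. Support violations are handled by prior rejection, never
by reflection or clamping, so every proposal stays exactly symmetric and
the Hastings ratio is 1.

Each block's $\zeta_i$ adapts toward the one-dimensional optimum acceptance
proportion 0.44: after every window of 50 *proposals of that block*, add
$a = \min(0.01, n^{-1/2})$ if the window's acceptance exceeded 0.44,
subtract it otherwise (a tie counts as "not greater"); $n$ counts that
block's windows. Windows are per proposal, not per chain iteration: a given
block is touched only about once per $3 + 4K$ iterations, so fixed-length
iteration windows would mostly contain no information about it. $\zeta$ is
clamped to $[-10, 10]$ (proposal variance at most $e^{20} \approx 4.9
\times 10^8$), preventing absurd scales in either direction.

Two practical consequences are worth stating plainly. First, adaptation is
deliberately slow (at most 0.01 per window): with K populations a chain
needs on the order of $50 \cdot (3 + 4K) \cdot |\Delta\zeta| / 0.01$
iterations before proposal scales reach their equilibrium, several million
for K = 30. Acceptance proportions measured before that point reflect the
approach, not the target; the validation suite measures the 0.44
equilibrium on chains long enough to be there. Second, diminishing
adaptation ($a \to 0$) preserves ergodicity.

The engine itself is compiled (RcppArmadillo): per-iteration work is an
O(K²) covariance assembly, an O(K³) projection and Cholesky, plus
incremental distance/decay updates for single-location moves, about 3–20 µs
per iteration for K = 10–30. Every operation also exists as a plain R
function (`log_prior()`, `mh_step()`, `wishart_loglik()`, ...), and a test
recomputes log prior + log likelihood in R at every thinned sample of
compiled chains, agreeing to 1e-6 — the two implementations cross-check
each other.

Chains are initialized from the priors (scalars, nuggets, and — in
admixture variants — $w$), locations at the prior centers, sources uniform
in the observed coordinate range, redrawing a bounded number of times if
the likelihood is not finite. The analysis protocol (`run_protocol()`) runs
several independent location-only short chains, takes the final state with
the highest posterior ("best short run"), and starts the admixture-model
long chain there with $w = 0$ — admixture must then displace a competitive
non-admixed explanation, which is the conservative behavior the harsh Beta
prior is designed for.

## Post-processing

The displayed map is the maximum a posteriori thinned sample (ties: earliest
index) after a configurable burn-in (default 50% of thinned draws).
Translation, rotation, reflection and scale are unidentified, so
`summarize_map()` Procrustes-aligns the MAP locations to a reference;
the fit is computed on population locations only and then applied to the
admixture sources, so sources cannot distort the frame. Reflection is
allowed by default (likelihood depends on distances only) and can be
disabled. Location uncertainty ellipses align every post-burn-in draw to
the MAP configuration first, otherwise rotational drift of the whole map
masquerades as per-population uncertainty. Alignment treats (lon, lat) as
planar coordinates — a presentation-layer approximation for spherical
chains. Arrows from source to location are drawn with width and opacity
proportional to the posterior mean $w_k$, suppressed below 0.01.

## The lattice simulator

`build_scenario()`/`simulate_counts()` emulate stepping-stone validation
worlds: an 11 × 9 lattice of demes, migration to the four nearest neighbors
at rate m and the four diagonal neighbors at m/2, sampled at every other row
and column (30 populations on a 6 × 5 grid, numbered row-major from the
southwest; the sampled neighbors of population 30 are 24, 25 and 29). Ten
haploids are sampled per sampled deme, and each locus is an independent
genealogy under the structured coalescent carrying exactly one segregating
site — one mutation placed uniformly on the genealogy's total branch
length. The genealogies come from msprime; the scenario translation and the
single-site conditioning are package code (`inst/python/`).

Scaled parameters: deme size 1 and m = 0.25, i.e. 4Nm = 1 between adjacent
demes — a classic moderately connected stepping stone chosen once for
clearly visible isolation by distance (Spearman correlation between lattice
distance and sample covariance below −0.8 at full locus counts) at
practical runtime. Scenario embellishments follow the validation designs:
a barrier dividing migration by 5 across the grid's central boundary
(between full-lattice rows 6 and 7); a simultaneous recent expansion of the
five easternmost columns from the column west of them; a 50% ancestry pulse
from the SW corner population into the NE corner immediately before
sampling; and two cross-barrier pulses — 10% into population 23 (one
sampled row inland) and 40% into population 18 (barrier-adjacent), both
from population 13. "Immediately before sampling" is scaled time 1e-6.
Events are implemented backward in time as mass lineage movements.

What this generator does *not* emulate: linkage (loci are exactly
independent, so the Wishart degrees of freedom are exact here but would be
optimistic on real genomes), mutation model detail (one site per locus by
construction, no ascertainment), selection, and continuous space. Passing
validation on these lattices therefore demonstrates correct inference under
the model's own assumptions plus a realistic-but-idealized demography — not
robustness to LD or complex real-world sampling.

A second generator, `simulate_mvn()`, draws data exactly from the Gaussian
model (optionally with admixture) and bypasses the binomial layer entirely.
It closes the loop for calibration: 95% credible intervals for $\alpha_1$
cover the truth in at least 18 of 20 replicates, a variant-4 run on
admixture-free data keeps every posterior mean $w_k$ below 0.05, and a
single-free-parameter chain matches a grid-quadrature posterior with
Kolmogorov–Smirnov distance below 0.05.

## Problem sizes used in validation

The full admixture-recovery experiments simulate 10,000 loci (the design's
own locus count) and run the complete protocol — five short location-only
chains of 4 × 10⁵ iterations and a variant-4 long chain of several million
iterations with 50% burn-in; we use 6 × 10⁶, long enough that proposal
adaptation has equilibrated and the location/source mode structure has
settled, while a desk-scale fraction of the 10⁸ iterations one would run
for a publication-grade analysis. Unit and property tests use smaller
worlds (4–10 populations, hundreds to thousands of loci, 10³–10⁶
iteration chains) chosen so each test isolates one property.

On these lattices the inferred admixture proportions sit *below* the
simulated truth for the corner scenario (posterior CIs around 0.38–0.43
across seeds, against a true 0.5): the harsh Beta(1, 100) prior plus the
model's freedom to move a
recipient's location toward its source deliberately bias admixture
downward. That shrinkage is itself part of the validated behavior. The
same tradeoff makes heavily admixed populations' location and source
occasionally swap roles between runs — both modes describe the same
distance structure.

## Known limitations

* The Wishart likelihood treats loci as independent; with linked loci the
  effective degrees of freedom are lower and credibility intervals too
  tight. Window-averaged covariances or an effective-L correction are
  natural extensions, not implemented.
* One admixture source per population; populations whose ancestry draws on
  several distant regions will average over them.
* MAP-based maps summarize a multimodal posterior with one mode;
  independent protocol runs should be compared before interpreting fine
  structure.
* The coalescent backend requires the Python msprime package on the host;
  it is a validation tool, not part of inference on real data.
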