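---
title: "Methods: multi-optimum OU analysis of island body-size evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-optimum OU analysis of island body-size evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandOU)
```

## The scientific question

Island flying foxes (*Pteropus* and related frugivorous pteropodines) show a
striking pattern: species that share an island rarely overlap in body size.
Two very different histories can produce that pattern. Under **species
sorting**, size differences evolve before contact and similar-sized
colonists are competitively excluded — no in-situ size change is needed, and
trait evolution should look neutral (Brownian) on the phylogeny. Under
**character displacement**, sympatric species are pushed towards different
size optima after contact — trait evolution should look like an
Ornstein-Uhlenbeck (OU) process with several selective optima arranged along
the branches of the tree (the Hansen model).

islandOU turns that contrast into a model-selection problem on a dated
phylogeny with condylobasal length (CBL, mm) as the size proxy: fit neutral
models (BM, multi-rate BMS, early-burst EB), a single-optimum OU and
multi-optimum OU variants whose regimes encode sympatry-based size
categories, and compare them with small-sample AICc.

## Models and likelihoods

All models are Gaussian processes on the tree, so the tip vector
$y$ is multivariate normal with a mean and covariance determined by the
model:

* **BM**: $\operatorname{Cov}(y_i, y_j) = \sigma^2 s_{ij}$ with $s_{ij}$
  the shared root-to-MRCA time; mean $z_0$ everywhere. **BMS** lets
  $\sigma^2$ depend on the regime of each branch; **EB** decays the rate
  through time as $\sigma^2(u) = \sigma_0^2 e^{r u}$, $r \le 0$.
* **OU / Hansen**: each branch carries a regime with optimum
  $\theta_k$, pull $\alpha$ and intensity $\sigma^2$. A tip's expectation
  is a convex combination of the root state and the optima along its root
  path, weighted by exponentially discounted residence times; with a single
  $\alpha$ the covariance is
  $\frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}} (1 - e^{-2\alpha s_{ij}})$
  with $d_{ij}$ the patristic separation. The OUMV/OUMA/OUMVA variants let
  $\sigma^2$ and/or $\alpha$ vary by regime.

Internally every variant is assembled by one preorder recursion: with
$B(v)$ the integral of $\alpha$ from the root to node $v$,

$$V_n(c) = e^{-2\alpha\,\Delta t} V_n(p) + \sigma^2
  \tfrac{1 - e^{-2\alpha \Delta t}}{2\alpha},\qquad
  \operatorname{Cov}(y_i, y_j) = e^{2B(m) - B(i) - B(j)}\, V_n(m),$$

$m$ the MRCA of $i, j$. Every exponent is non-positive, so the recursion is
stable for arbitrarily strong pull (a direct evaluation of the residence
integrals overflows already at $\alpha \approx 100$ on an 8.7-Myr tree).
The $\alpha \to 0$ limits are handled analytically (`expm1`-based
integrals), never by division.

**Root handling.** By default the root state equals the optimum of the
root's regime (`rootMode = "stationary"`), so it is not a free parameter.
This is what makes the parameter counts $k$ = 2 (BM), 3 (EB, OU1),
$m+1$ (BMS), $m+2$ (OUM with $m$ regimes) reproduce the published AICc
values from the published log-likelihoods exactly; an `"estimated"` root
adds one parameter for sensitivity analyses.

**Fitting.** Everything linear is profiled out: the optima enter the mean
linearly, so $\hat\theta$ is a GLS estimate given the covariance shape, and
a single $\sigma^2$ is a pure scale parameter. What remains is a
one-dimensional profile in $\alpha$ (OU1/OUM) or $r$ (EB), optimised by a
deterministic coarse grid (15-20 points) plus local refinement — OU profile
likelihoods can be multimodal, and grid-plus-refine is reproducible without
a seed. The genuinely multi-dimensional models (BMS, OUMV, OUMA, OUMVA) use
L-BFGS-B from 10 Latin-hypercube starts in log-parameter space (bounds:
$\alpha \in [10^{-6}, 100]$ /Myr, $\sigma^2 \in [10^{-8}, 10^6]$); the
restart count and convergence flag are kept in the fit's diagnostics, and a
parameter at a search bound is flagged (a BMS rate at the lower bound is
reported as 0, matching how such degenerate rates are conventionally
printed). Optimum standard errors are the conditional GLS standard errors
given $(\hat\alpha, \hat\sigma^2)$ — the quantity usually printed next to
each $\theta$ — not full-information errors.

$\sigma$ ambiguity: published tables often label the rate parameter
$\sigma$. This package standardises on $\sigma^2$, the variance rate of the
Gaussian increments, everywhere (config, fits, reports).

## Regime assignment

Categories come from sympatry and relative size, not from the data-driven
regime searches (SURFACE/bayou) deliberately left out of scope:

* three co-occurring species are ranked S/M/L directly;
* areas with two or four-plus species are labelled by membership in global
  tercile bands spanning the size range of all sympatric taxa. Two species
  sharing a band are split into adjacent bands when their difference
  exceeds a minimum gap (default 5% of the global range) — bands alone
  would under-split clearly separated pairs;
* a widespread taxon takes its modal per-area label; ties are never
  resolved silently (`tieBreak = "error"` by default, `"prefer_middle"`
  opt-in) because published analyses resolved them by judgment, and
  judgment should be an input;
* taxa alone everywhere go to M (three-category scheme) or to their own
  I category (four-category scheme);
* extinct or unsequenced taxa with measurements ("context-only") join the
  per-area banding but never enter a likelihood.

The Hansen machinery needs regimes on internal branches too;
`paintInternalNodes()` paints all of them one category (default M, the
category closest to reconstructed ancestral sizes), and fits are typically
swept over S/M/L paintings. The OU3r null (`randomRegimeNull`) refits the
Hansen model under randomized tip categories; the default `"permute"` mode
preserves observed category counts (the stricter null), `"uniform"` is
available because the published description ("randomly assigned") does not
pin the choice down.

## Signal, ancestral states, disparity

* **Pagel's lambda** profiles the BM likelihood on the off-diagonal-scaled
  covariance; the admissible maximum (positive definiteness of the
  transform) is computed by eigendecomposition and reported. LR tests
  against both $\lambda = 0$ and $\lambda = 1$ are returned.
* **Blomberg's K** uses the ratio-of-ratios closed form; its permutation
  test shuffles tip labels and compares the variance of phylogenetically
  independent contrasts (lower observed variance means signal), with the
  add-one convention so p is never 0. Default 999 permutations; small
  quoted p-values need more (a p of 0.0002 requires at least 4999).
* **Pagel's delta** profiles on the depth-power transform
  $t \mapsto T (t/T)^\delta$ (total depth preserved); the default search
  interval is the customary $[0.01, 3]$ and a boundary estimate is
  flagged — an estimate pinned at 3 means "at least this late-weighted".
  Lambda and delta standardise the trait internally (the profile is
  affine-invariant, and standardising makes the estimate bit-identical
  under affine transforms rather than merely close).
* **Ancestral states** are GLS/BLUP estimates under BM; REML (default)
  takes the rate from mean squared standardized contrasts (divisor
  $n-1$), ML from the GLS quadratic form (divisor $n$) — point estimates
  agree, interval widths differ. Intervals use $t_{n-1}$ quantiles rather
  than normal ones: the rate is estimated, and the plug-in normal interval
  measurably undercovers at $n \approx 56$. Per-category change accounting
  compares each tip with its **direct parent node** (the simplest reading
  of "reconstructed most recent ancestor"); the 5% reporting threshold is
  a config constant. Note one subtlety checked by the tests: under
  neutrality the tip-minus-ancestor *differences* are exactly centred on
  zero, but the *percent* changes carry a small second-order bias because
  the reconstructed denominator is random and correlated with the
  numerator.
* **DTT/MDI**: relative subclade disparity (average squared pairwise
  difference, the common default; a variance metric is a flag) at each
  internal-node time, normalised by the whole-tree value so the curve
  starts at 1. The null envelope simulates BM at the ML rate; the MDI is
  the signed area between observed curve and null median over relative
  time. Because the published tail convention for MDI p-values is not
  recoverable, both one-sided p-values are reported.

## The synthetic-data module

`synthesizeInputs()` emulates the study conditions and is the truth
generator for every calibration: a Yule tree of 56 tips rescaled to a crown
age of 8.7 Myr; traits evolved by exact per-branch Gaussian transitions
(never Euler steps) under BM/EB/OU with regime-dependent optima defaulting
to the published scale ($\theta$ = 93.4/65.1/47.5/54.4 mm for L/M/S/I,
$\alpha = 0.60$ /Myr, $\sigma^2 = 52$ mm²/Myr, root at the M optimum); and
island communities of up to five species with planted minimum size gaps
(default 8 mm — roughly the separation between adjacent category means)
or size-blind random assembly. A forward (duration-conditioned) Yule mode
exists purely so the generator itself can be calibrated against the
closed-form expectation $E[N(T)] = 2e^{bT}$.

What the generator does **not** emulate: extinction (no birth-death
trees), fossil/ghost lineages, intraspecific structure beyond per-specimen
Gaussian noise, measurement error in the likelihood, and any correlation
between regime and phylogeny (planted categories are i.i.d. across tips).
Passing calibrations therefore demonstrate correctness of the machinery
under the stated generating processes, not robustness to the ways real
data violate them.

All generators derive per-operation seeds from one master seed through a
documented splitting rule (`deriveSeed`), so adding a simulation to a
pipeline never perturbs the others, and every output is bit-reproducible.

## Numerical and testing choices

* Dense Cholesky likelihoods throughout: with at most a few hundred tips
  the $O(n^3)$ cost is negligible. Zero-length *internal* branches (from
  polytomy resolution) leave the tip covariance non-singular, and
  zero-length terminal branches are rejected at validation, so no input
  this package admits needs a pruning-algorithm fallback.
* Profile grids: 20 points in $\log\alpha$ over $[10^{-6}, 100]$, then
  `optimize()` refinement in the best bracket; 25 points for
  $\lambda$/$\delta$.
* Test problem sizes are chosen to make every stochastic assertion sound
  (3-s.e. Monte-Carlo bands, binomial margins) while keeping the default
  suite a few minutes: e.g. 100 recovery replicates at the full 56-tip
  scale, 20 experiments of 100 random-regime refits, 200 replicates for
  the lambda consistency checks, 150 x 300 simulations for the MDI
  centring check.
* The likelihood test oracle rebuilds mean and covariance by per-tip path
  enumeration with numerical quadrature — an independent route from the
  production recursion — and must agree to $10^{-8}$.

## Known limitations

* No measurement-error term in the likelihoods (species with one specimen
  are treated like well-sampled ones).
* Ancestral reconstruction is BM-based even when an OU model fits best;
  OU-based reconstruction is out of scope.
* The two-species-area banding rule is a declared reconstruction of a
  procedure published in prose; hand-curated schemes can always be
  supplied via `readRegimeScheme()` to bypass it.
* AICc comparisons assume all fits share the same data (enforced by a
  fingerprint check) but not that any model in the set is true.
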