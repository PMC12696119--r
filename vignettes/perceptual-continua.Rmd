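---
title: "Designing and validating perceptually ordered stimulus continua"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating perceptually ordered stimulus continua}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perceptscale)
```

## The problem

Naturalistic images are hard to control parametrically: unlike a grating's
orientation or a patch's hue, there is no dial that moves a photograph of a
fish a fixed perceptual distance from another fish. One way to get such a
dial is to interpolate in the latent space of a generative image model and
then *measure* how far apart the resulting images are perceptually — first
with a model-based proxy, then with human similarity judgements. This
package implements the design and analysis machinery for that approach:

1. **Continuum construction** — spherical interpolation between two noise
   latents (an *anchor* and a *guide*), followed by distance-based
   subsampling so that the retained images step away from the anchor
   approximately linearly.
2. **Perceptual scaling** — triplet similarity judgements ("which of these
   two probes looks more like the reference?") analysed with three
   estimators (MLDS, SOE, t-STE), scored by cross-validated triplet error,
   and compared against the model-based ordering by rank agreement.
3. **Memory validation** — a delayed match-to-sample task whose foil
   difficulty is derived from the fitted perceptual scale, analysed with a
   Bayesian hierarchical logistic model.

The heavy neural components — the diffusion model that renders latents into
images and the learned perceptual metric (LPIPS) that scores image pairs —
stay behind pluggable interfaces: the manifest plans their work, the
distance matrix accepts any backend satisfying the distance contract, and
everything downstream is testable on synthetic inputs.

## Spherical interpolation

Noise latents for diffusion models are approximately Gaussian vectors, which
concentrate near a hypersphere; linear interpolation between two such
vectors cuts through a low-norm region the model was never trained on.
`slerp(u, v, t)` therefore follows the great circle:

$$\mathrm{slerp}(u, v; t) = \frac{\sin((1-t)\theta)\,u + \sin(t\theta)\,v}{\sin\theta},
\qquad \theta = \angle(u, v).$$

Uniform steps in $t$ are uniform steps in angle. `build_path()` places
`n_steps` *interior* points at $t_k = k/(n\_steps+1)$ — endpoints excluded —
so "anchor plus 200 interpolations" counts images the way a continuum is
assembled. Numerical choices: angles below $10^{-7}$ rad fall back to linear
interpolation with linearly interpolated norm (the $\sin\theta$ division is
unstable there); antiparallel endpoints are an error because the great
circle is not unique.

## Distance-based selection

`pairwise_distance()` produces a validated symmetric matrix from Euclidean,
cosine, or plugin backends; an LPIPS scorer plugs in as
`function(x, y) -> nonnegative scalar` and is checked for symmetry. From a
matrix over 60 exemplars, `select_anchor_guide()` picks the **medoid** (the
exemplar with minimal mean distance to the rest — the most representative
image) as the anchor, and the anchor's nearest neighbour as the guide. This
is a deliberately simple, auditable operationalisation of "representative
and mutually similar"; ties break to the lowest index so results are
deterministic.

`select_continuum()` then reduces the interpolation path to `k = 9` images
(ten with the anchor). Candidates are scored against the equispaced ladder
$jT/k$ where $T$ is the maximum candidate distance from the anchor, and the
subset minimizing the squared deviation, subject to distances non-decreasing
in path order, is found **exactly** by dynamic programming over
(candidate, slot) states — a brute-force-verifiable optimum rather than a
greedy approximation. The ladder targets distance-from-anchor spacing; an
alternative reading (equal successive steps) would change the objective, and
we chose the anchor ladder because it is the quantity the selection stage
measures. `detect_jumps()` flags consecutive increments exceeding twice the
median increment, the signature of a perceptual "jump" along an otherwise
smooth continuum.

## Triplet design and the synthetic observer

`generate_session()` builds a 288-trial session in six 48-trial blocks over
one or more ten-image object sets: triads sampled without replacement,
stratified so every image serves as reference equally often (±1), left/right
probe placement balanced within each unordered probe pair (±1), and fixation
jitter uniform on 500–1000 ms in 100-ms steps. Whether triad coverage should
be balanced within or across participants is genuinely underdetermined; the
generator balances within a session and accepts any object allocation, so
either policy can be composed on top.

The synthetic observer (`simulate_triplet_responses()`) perceives each
scale distance with Gaussian noise of SD $\sigma$ and picks the probe that
feels closer, so

$$P(\text{choose } j) =
\Phi\!\left(\frac{|\psi_i-\psi_k| - |\psi_i-\psi_j|}{\sigma\sqrt{2}}\right),$$

with an optional lapse rate mixing in coin flips. The $\sqrt 2$ places
$\sigma$ on the scale of a single perceived distance. This observer is
exactly the generative dual of the MLDS likelihood below, which makes
parameter recovery well-posed: the truth is a point in the fitted model's
own parameter space.

`ground_truth_scale(n, jitter)` generates truths for simulation studies:
approximately linear scales whose increments are uniform on
$[1-\text{jitter}, 1+\text{jitter}]$, mimicking continua built to be
roughly equispaced. The default `jitter = 0.3` keeps steps clearly unequal
(no exact distance ties — an *exactly* equispaced scale has equidistant
probe pairs whose judgements are unpredictable coin flips, putting a floor
of about 0.03 under any embedding's triplet error at $n = 10$) while
staying close to the designed linear spacing.

## Scaling estimators

All three estimators return an `embedding_scale` normalized to $[0,1]$ and
oriented with the anchor at the low end (a 1-D embedding is identified only
up to affine maps and reflection; this convention pins both down, and
normalization is idempotent).

* **MLDS (triads)** — maximizes the likelihood above over
  $\psi_2,\dots,\psi_{n-1}$ (endpoints fixed at 0 and 1) and
  $\log\sigma$, by L-BFGS-B with 5 restarts. The classic method uses
  quadruples; the triad decision variable — the difference of the two
  unsigned scale distances from the reference — is the natural adaptation
  to this task.
* **SOE** — squared hinge loss
  $\sum \max(0, d(r,\text{chosen}) + \text{margin} - d(r,\text{other}))^2$
  over point configurations; margin 0.1 on the normalized scale.
* **t-STE** — triplet likelihood under a Student-t kernel
  $w(x) = (1 + d^2/\alpha)^{-(\alpha+1)/2}$. The common
  $\alpha = \text{dim} - 1$ rule degenerates in one dimension. We default to
  $\alpha = \text{dim} + 1$ (2 in 1-D): in our simulations the very heavy
  $\alpha = 1$ tail visibly distorts the recovered spacing even at the
  *global* optimum on fully consistent data (verified by truth-initialized
  optimization), flipping small-margin distance comparisons; lighter tails
  preserve them.

The ordinal embeddings are non-convex, so the optimizer runs restarts at
mixed initialization scales (SD 0.1/0.3/1) and then polishes the best
candidates — best by loss *and* best by training triplet error — with a
longer quasi-Newton run. The two-criterion screening matters: an expanded
but mis-ordered configuration can transiently achieve a lower smooth loss
than a correct configuration that has not yet expanded.

`triplet_error()` is the fraction of judgements whose chosen probe is not
the nearer probe under the embedding (ties 0.5);
`cross_validated_error()` reports its mean over `k = 10` seeded folds
(k is a package default; any fold that loses an image errors with advice to
lower k rather than silently extrapolating). `rank_agreement()` pools
per-object (rank under metric A, rank under metric B) pairs into a Spearman
correlation and an $n\times n$ rank co-occurrence matrix.

## Memory task

`select_foils()` reduces a fitted ten-image scale to a target (the
anchor-end image) plus three foils whose scale gaps approximate the ladder
$j\cdot\text{span}/3$: the nearest foil is the *hard* discrimination, the
farthest the *easy* one. With only $\binom{9}{3} = 84$ subsets the search is
exhaustive, hence exactly optimal.

`generate_memory_session()` emits a 108-trial session — six blocks of 18 —
with nine repeated targets (each once per block) and 54 non-repeated targets
(each once per session); three easy/medium/hard trials per condition per
block; each repeated target covering all three difficulties within blocks
1–3 and again within 4–6 (a scrambled Latin design); and target
order / response-mapping side crossed 27 per cell, which yields exact 54/54
splits and equal correct-answer counts on the two response buttons.
`memory_session_violations()` re-checks every one of these constraints and
is property-tested against single-field mutations.

The accuracy model (`fit_hierarchical_model()`) is a Bernoulli–logit GLMM:
difficulty (easy reference), repetition, centred block, the
difficulty×block and repetition×block interactions, and per-participant
random intercepts and block slopes. Priors are weakly informative —
Normal(0, 1.5) on coefficients, half-Normal(1) on random-effect SDs. The
production profile runs 4 chains × 10,000 iterations with 2,000 warm-up
(32,000 post-warmup draws); a scaled-down test profile is the default for
interactive work. Convergence is reported per parameter as rank-normalized
split R-hat with bulk and tail ESS; any R-hat above 1.01 flags the fit with
a warning, never silently. Simulation defaults
(`memory_model_params()`) describe a plausible experiment — easy trials
near 80% correct, graded drops of 0.5/1.1 logits for medium/hard, repeated
targets level at first and improving by 0.15 logits per block, and
moderate participant heterogeneity ($\tau \approx 0.5$).

## What the synthetic generators do and do not show

The generators emulate the *statistical* structure the estimators assume: a
1-D ground-truth scale, Gaussian judgement noise, Bernoulli accuracy from a
logistic model. Passing recovery tests therefore demonstrates correctness of
the estimation machinery, not robustness to what real data add: perceptual
spaces that are not perfectly one-dimensional, observers whose noise is
neither Gaussian nor stationary, lapses concentrated in particular
participants, and images whose perceptual spacing drifts with context. The
rank-agreement between model-based and judgement-based orderings on real
data (reported around $\rho \approx 0.7$ in this literature) depends on the
human sample and cannot be reproduced from simulations; the package
supports it as an input path instead.

## Problem sizes used in the shipped checks

The package's own test-and-acceptance runs use sizes chosen to exercise the
estimators well inside a desk-scale budget: MLDS recovery at 1,500–2,000
triplets; ordinal-embedding held-out checks on 1,000 training / 300 held-out
noiseless triplets; CV-degradation sweeps with 400-triplet replicates at
$\sigma \in \{0.05, 0.1, 0.2, 0.4\}$; hierarchical-model coverage over 20
replicates of 60 simulated participants with 2 short chains each; and one
12-participant fit at the full 4×10,000 production profile. Exact,
sub-second identities (session counts, counterbalance splits, DP-vs-brute-
force equivalence) run at their natural sizes.

## Known limitations

* Distances are validated within an object set; cross-set calibration of
  perceptual distances is out of scope.
* The DP continuum selector assumes distances-from-anchor are meaningful
  along the path; severely non-monotone paths (long decreasing stretches)
  are rejected rather than repaired.
* MLDS is inherently 1-D; SOE/t-STE accept `dim` up to 3, but foil
  selection and ordering utilities require a 1-D scale.
* The hierarchical model's structure is fixed (no arbitrary formula
  interface); it matches the design generator's covariates.
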