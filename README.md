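# perceptscale

Tools for building and validating **perceptually ordered naturalistic
stimulus continua** — for visual psychophysicists and memory researchers who
need image sets whose members differ from an origin image in graded,
measured perceptual steps.

The pipeline the package implements:

1. **Continuum construction.** Between two generative-model noise latents —
   an *anchor* (the medoid of an exemplar set under a perceptual distance)
   and a *guide* (its nearest neighbour) — images are interpolated along
   the great circle,

   slerp(u, v; t) = [sin((1−t)θ)·u + sin(tθ)·v] / sin θ,  θ = ∠(u, v),

   and a ten-image subset is chosen whose perceptual distances from the
   anchor approximate the equispaced ladder j·T/k, solved **exactly** by
   dynamic programming. Perceptual "jumps" (increments above twice the
   median step) are flagged. The image synthesizer and the learned
   perceptual metric (e.g. LPIPS) are pluggable backends; everything here
   runs on plain matrices.

2. **Perceptual scaling.** Triplet judgements ("which probe is more similar
   to the reference?") are designed in counterbalanced 288-trial sessions
   and analysed with three estimators — MLDS adapted to triads
   (P(choose j) = Φ[(|ψᵢ−ψₖ| − |ψᵢ−ψⱼ|)/(σ√2)]), soft ordinal embedding
   (squared hinge), and t-STE (Student-t kernel) — scored by the
   cross-validated triplet error Eₜ and compared to any other ordering via
   pooled Spearman ρ and a rank co-occurrence matrix.

3. **Memory validation.** From a fitted scale, a target and three graded
   foils (hard/medium/easy) are subsampled exhaustively; a fully
   counterbalanced 108-trial delayed match-to-sample session is generated
   and validated; accuracy is modelled with a Bayesian hierarchical
   logistic regression (difficulty, repetition, block and interactions;
   participant random intercepts and slopes) fitted by MCMC with
   rank-normalized split R-hat and bulk/tail ESS diagnostics.

Synthetic generators — a Gaussian triplet observer that is the exact
generative dual of the MLDS likelihood, and a Bernoulli memory simulator
driven by the same logistic model the fitter assumes — make every estimator
testable end to end without human data, GPUs or network weights.

## Worked example

```r
library(perceptscale)

# Stage 1: anchor/guide + continuum selection on a toy feature backend
set.seed(1)
features <- matrix(rnorm(60 * 16), 60)   # stand-in exemplar features
D  <- pairwise_distance(features)        # any metric satisfying the contract
ag <- select_anchor_guide(D)
#> anchor = item044 (mean distance 4.765), guide = item043 (pair distance 3.327)

d_path <- sort(runif(200))               # candidate distances along the path
sel <- select_continuum(d_path, k = 9)
#> Continuum of 10 images (anchor + 9), objective 0.0001138
#> distances: 0.0000 0.1062 0.2273 0.3375 0.4377 0.5542 0.6635 0.7750 0.8874 0.9964

# Stage 2: triplet study simulated from a known scale, then recovered
psi       <- ground_truth_scale(10, seed = 11)
session   <- generate_session("fish", seed = 21)        # 288 trials, 6 x 48
responses <- simulate_triplet_responses(session, psi, sigma = 0.15, seed = 31)
fit       <- fit_mlds(responses, seed = 41)
#> Perceptual scale (mlds): n = 10, loss = 97.76, converged = TRUE
#> psi: 0.000 0.079 0.053 0.287 0.405 0.444 0.573 0.635 0.790 1.000
#> sigma_hat = 0.1407
sqrt(mean((fit$psi_hat - psi)^2))
#> 0.066

cross_validated_error(responses, "mlds", k = 10, seed = 51)
#> 10-fold CV triplet error: mean 0.1772 (folds 0.207 0.241 ... 0.214)

# Stage 3: foil subsampling from the fitted scale
select_foils(fit$psi_hat)
#> target = image 1; foils (hard, medium, easy) = 4, 8, 10; gaps = 0.287, 0.635, 1.000
```

Reading the output: the anchor is the most representative exemplar and the
guide its closest neighbour; the selected continuum steps from the anchor
in near-equal perceptual increments (objective ≈ 0 means the ladder is hit
almost exactly). The MLDS fit recovers the generating scale to RMSE 0.066
from one noisy 288-trial session (σ = 0.15 of the scale's span), and its
σ̂ = 0.141 estimates that noise. A CV triplet error of 0.18 means 18% of
held-out judgements disagree with the fitted scale — the irreducible share
for this noise level. The foil set turns the scale into three graded
discriminations: the *hard* foil sits 0.29 scale units from the target, the
*easy* one at the far end.

A thin command-line front end (`inst/cli/perceptscale`) exposes the verbs
`plan`, `interpolate`, `select`, `design-triplets`, `simulate-observer`,
`scale`, `compare-ranks`, `design-memory`, `simulate-memory`, `fit-memory`
and `report` over the same functions.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "perceptscale", load_package = "installed")'
```

The suite includes brute-force oracle checks for every discrete
optimization (continuum DP, medoid selection, foil search), closed-form
likelihood checks, seeded parameter-recovery simulations, and
property-based validation of the counterbalanced designs.

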