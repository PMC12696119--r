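#' Choice probability of the Gaussian triplet observer
#'
#' The synthetic observer perceives each scale distance with independent
#' Gaussian noise of standard deviation `sigma`, so the decision variable
#' (difference of the two perceived reference–probe distances) has noise
#' SD `sigma * sqrt(2)`. The probability of choosing the left probe is
#' \deqn{\Phi\big((|\psi_r - \psi_{right}| - |\psi_r - \psi_{left}|) /
#'       (\sigma\sqrt{2})\big),}
#' exactly the likelihood an MLDS triad model assigns to that choice — the
#' observer is the generative dual of the fitted model, which is what makes
#' parameter-recovery tests well posed. Choice probabilities are invariant
#' under joint affine maps `psi -> a*psi + b`, `sigma -> a*sigma` (a > 0).
#'
#' @param psi_ref,psi_left,psi_right scale values (vectorised).
#' @param sigma judgement noise SD (> 0), on the same scale as `psi`.
#' @param lapse probability of a uniform random guess in `[0, 0.5]`.
#' @return probability of choosing the left probe.
#' @export
triplet_choice_prob <- function(psi_ref, psi_left, psi_right, sigma, lapse = 0) {
  assert_scalar_number(sigma, "sigma")
  if (sigma <= 0) stop("`sigma` must be > 0")
  assert_scalar_number(lapse, "lapse", 0, 0.5)
  p <- stats::pnorm((abs(psi_ref - psi_right) - abs(psi_ref - psi_left)) /
                      (sigma * sqrt(2)))
  (1 - lapse) * p + lapse * 0.5
}

#' Generate a ground-truth perceptual scale for simulation studies
#'
#' Produces an approximately linear 1-D scale of `n` values, normalized to
#' `[0, 1]`: successive increments are drawn uniformly from
#' `[1 - jitter, 1 + jitter]` (then rescaled), mimicking a stimulus
#' continuum that was constructed to be roughly equispaced in perceptual
#' distance but is not exactly so. With `jitter > 0` no two scale distances
#' are exactly equal, so noiseless observers produce fully consistent,
#' tie-free judgements.
#'
#' @param n number of images (default 10).
#' @param jitter relative wobble of the step sizes, in `[0, 1)`; default
#'   0.3.
#' @param seed integer seed.
#' @return numeric scale of length `n`, increasing from 0 to 1.
#' @export
ground_truth_scale <- function(n = 10, jitter = 0.3, seed = NULL) {
  if (n < 3) stop("`n` must be >= 3")
  assert_scalar_number(jitter, "jitter", 0, 0.999)
  set_seed_if(seed)
  inc <- stats::runif(n - 1, 1 - jitter, 1 + jitter)
  normalize_embedding(c(0, cumsum(inc)))
}

#' Simulate triplet responses from a noisy observer
#'
#' Applies the Gaussian triplet observer (see [triplet_choice_prob()]) to
#' every trial of a session, drawing one choice per trial.
#'
#' @param session a `"triplet_session"` (or data.frame with columns `object`,
#'   `reference`, `probe_left`, `probe_right`).
#' @param psi ground-truth scale: a numeric vector (applied to every object)
#'   or a named list of vectors, one per object id in the session.
#' @param sigma,lapse observer parameters (see [triplet_choice_prob()]).
#' @param seed integer seed for reproducibility.
#' @return the session with an added `choice` column (`"left"`/`"right"`).
#' @export
simulate_triplet_responses <- function(session, psi, sigma, lapse = 0, seed = NULL) {
  set_seed_if(seed)
  df <- as.data.frame(session)
  lookup <- function(obj, idx) {
    v <- if (is.list(psi)) psi[[obj]] else psi
    if (is.null(v)) stop("no ground-truth scale for object '", obj, "'")
    if (any(idx < 1 | idx > length(v))) stop("image index outside psi range")
    v[idx]
  }
  psi_r <- mapply(lookup, df$object, df$reference)
  psi_l <- mapply(lookup, df$object, df$probe_left)
  psi_rt <- mapply(lookup, df$object, df$probe_right)
  p_left <- triplet_choice_prob(psi_r, psi_l, psi_rt, sigma, lapse)
  df$choice <- ifelse(stats::runif(nrow(df)) < p_left, "left", "right")
  class(df) <- c("triplet_responses", "data.frame")
  df
}

#' Parameters of the hierarchical memory-accuracy model
#'
#' Fixed effects of a logistic accuracy model on the delayed match-to-sample
#' task, plus participant random-effect SDs. Difficulty is dummy-coded with
#' *easy* as the reference level; the block covariate is centred
#' (`block - 3.5` for six blocks) before interactions, so the intercept is
#' the log-odds of a correct easy, non-repeated response mid-experiment.
#'
#' The defaults describe a plausible experiment: easy trials near 80%
#' correct at mid-experiment, a graded drop for medium and hard foils,
#' repeated targets starting level with non-repeated ones but improving
#' across blocks, and moderate between-participant variation.
#'
#' @param intercept log-odds of correct for easy/non-repeated at the centred
#'   block.
#' @param medium,hard difficulty effects relative to easy (log-odds).
#' @param repeated repetition main effect.
#' @param block per-block (centred) slope.
#' @param medium_block,hard_block,repeated_block interaction slopes.
#' @param tau_intercept,tau_slope SDs of participant random intercepts and
#'   random block slopes (>= 0).
#' @return a `"memory_model_params"` list.
#' @export
memory_model_params <- function(intercept = 1.4, medium = -0.5, hard = -1.1,
                                repeated = 0, block = 0.02,
                                medium_block = 0, hard_block = 0,
                                repeated_block = 0.15,
                                tau_intercept = 0.5, tau_slope = 0.1) {
  p <- list(intercept = intercept, medium = medium, hard = hard,
            repeated = repeated, block = block,
            medium_block = medium_block, hard_block = hard_block,
            repeated_block = repeated_block,
            tau_intercept = tau_intercept, tau_slope = tau_slope)
  for (nm in names(p)) assert_scalar_number(p[[nm]], nm)
  if (p$tau_intercept < 0 || p$tau_slope < 0) stop("random-effect SDs must be >= 0")
  structure(p, class = "memory_model_params")
}

memory_linear_predictor <- function(df, params, u0, u1) {
  blk_c <- df$block - mean(seq_len(max(df$block)))
  med <- as.numeric(df$difficulty == "medium")
  hrd <- as.numeric(df$difficulty == "hard")
  rep_ <- as.numeric(df$repeated)
  pid <- match(df$participant, unique(df$participant))
  params$intercept + params$medium * med + params$hard * hrd +
    params$repeated * rep_ + params$block * blk_c +
    params$medium_block * med * blk_c + params$hard_block * hrd * blk_c +
    params$repeated_block * rep_ * blk_c +
    u0[pid] + u1[pid] * blk_c
}

#' Simulate memory-task responses from the logistic accuracy model
#'
#' Draws per-trial correctness as Bernoulli with success probability
#' `plogis(eta)` where `eta` is the linear predictor of
#' [memory_model_params()], including participant random intercepts
#' `N(0, tau_intercept^2)` and random block slopes `N(0, tau_slope^2)`.
#'
#' @param design one `"memory_session"` or several row-bound sessions (the
#'   `participant` column distinguishes them).
#' @param params a `"memory_model_params"`.
#' @param seed integer seed.
#' @return the design with an added logical `correct` column.
#' @export
simulate_memory_responses <- function(design, params, seed = NULL) {
  stopifnot(inherits(params, "memory_model_params"))
  set_seed_if(seed)
  df <- as.data.frame(design)
  pids <- unique(df$participant)
  u0 <- stats::rnorm(length(pids), 0, params$tau_intercept)
  u1 <- stats::rnorm(length(pids), 0, params$tau_slope)
  eta <- memory_linear_predictor(df, params, u0, u1)
  df$correct <- stats::rbinom(nrow(df), 1, stats::plogis(eta)) == 1
  class(df) <- c("memory_responses", "data.frame")
  df
}
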