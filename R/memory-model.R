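memory_jags_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dbern(ilogit(
      b_intercept + b_medium * med[i] + b_hard * hrd[i] +
      b_repeated * rep[i] + b_block * blk[i] +
      b_medium_block * med[i] * blk[i] + b_hard_block * hrd[i] * blk[i] +
      b_repeated_block * rep[i] * blk[i] +
      u0[pid[i]] + u1[pid[i]] * blk[i]))
  }
  for (p in 1:P) {
    u0[p] ~ dnorm(0, prec0)
    u1[p] ~ dnorm(0, prec1)
  }
  b_intercept ~ dnorm(0, 0.4444)
  b_medium ~ dnorm(0, 0.4444)
  b_hard ~ dnorm(0, 0.4444)
  b_repeated ~ dnorm(0, 0.4444)
  b_block ~ dnorm(0, 0.4444)
  b_medium_block ~ dnorm(0, 0.4444)
  b_hard_block ~ dnorm(0, 0.4444)
  b_repeated_block ~ dnorm(0, 0.4444)
  tau_intercept ~ dnorm(0, 1) T(0,)
  tau_slope ~ dnorm(0, 1) T(0,)
  prec0 <- 1 / (tau_intercept^2 + 1e-9)
  prec1 <- 1 / (tau_slope^2 + 1e-9)
}"

memory_fixed_effects <- c("b_intercept", "b_medium", "b_hard", "b_repeated",
                          "b_block", "b_medium_block", "b_hard_block",
                          "b_repeated_block")

#' MCMC profile for the hierarchical memory model
#'
#' The `"full"` profile is the production configuration (4 chains of 10,000
#' iterations with 2,000 warm-up, 32,000 post-warmup draws); the `"test"`
#' profile is a scaled-down configuration for desk-scale runs.
#'
#' @param profile `"full"` or `"test"`.
#' @return list with `chains`, `iterations`, `warmup`, `adapt` and the
#'   implied `postwarmup_draws`.
#' @export
mcmc_profile <- function(profile = c("test", "full")) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    full = list(chains = 4L, iterations = 10000L, warmup = 2000L, adapt = 1000L),
    test = list(chains = 4L, iterations = 1500L, warmup = 500L, adapt = 500L)
  )
  cfg$postwarmup_draws <- cfg$chains * (cfg$iterations - cfg$warmup)
  cfg
}

#' Fit the Bayesian hierarchical logistic model of memory accuracy
#'
#' Fits per-trial correctness with a Bernoulli likelihood and logit link.
#' Fixed effects: intercept, difficulty (medium/hard vs easy), repetition,
#' centred block, and the difficulty-by-block and repetition-by-block
#' interactions. Random effects: per-participant intercepts and block
#' slopes. Priors are weakly informative — Normal(0, 1.5) on coefficients,
#' half-Normal(1) on the random-effect SDs. Sampling is by Gibbs/MH MCMC
#' (JAGS, with its block GLM samplers when available); `warmup` iterations
#' per chain are discarded, so the post-warmup draw count is
#' `chains * (iterations - warmup)`.
#'
#' Convergence is assessed per parameter with the rank-normalized split
#' potential scale reduction factor (R-hat) and the bulk and tail effective
#' sample sizes. If any monitored R-hat exceeds 1.01 the fit is returned
#' with `converged = FALSE` and a warning — never silently.
#'
#' @param responses data.frame with columns `participant`, `block`,
#'   `repeated`, `difficulty` and logical/0-1 `correct`; >= 2 participants.
#' @param chains,iterations,warmup,adapt MCMC configuration; `iterations`
#'   counts per-chain iterations *including* warm-up. Defaults follow
#'   `mcmc_profile("test")`; pass `profile = "full"` for the production
#'   configuration.
#' @param profile optional shorthand overriding the four numbers above.
#' @param seed integer seed (drives all chains' RNG streams).
#' @param quiet suppress JAGS progress output.
#' @return a `"posterior_fit"`: `draws` (a [coda::mcmc.list] of the fixed
#'   effects and random-effect SDs), `chains`, `iterations`, `warmup`,
#'   `postwarmup_draws`, `r_hat`, `bulk_ess`, `tail_ess`, `summary`
#'   (data.frame of posterior mean, sd, 2.5%/97.5% quantiles and
#'   diagnostics) and `converged`.
#' @export
fit_hierarchical_model <- function(responses, chains = NULL, iterations = NULL,
                                   warmup = NULL, adapt = NULL,
                                   profile = NULL, seed = 1, quiet = TRUE) {
  df <- as.data.frame(responses)
  needed <- c("participant", "block", "repeated", "difficulty", "correct")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) stop("responses missing columns: ", paste(missing, collapse = ", "))
  pids <- unique(df$participant)
  if (length(pids) < 2L) stop("hierarchical model needs >= 2 participants")
  cfg <- mcmc_profile(profile %||% "test")
  chains <- chains %||% cfg$chains
  iterations <- iterations %||% cfg$iterations
  warmup <- warmup %||% cfg$warmup
  adapt <- adapt %||% cfg$adapt
  if (warmup >= iterations) stop("`warmup` must be smaller than `iterations`")
  seed <- check_seed(seed) %||% 1L

  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  blk_c <- df$block - mean(seq_len(max(df$block)))
  data_list <- list(
    y = as.integer(df$correct),
    med = as.numeric(df$difficulty == "medium"),
    hrd = as.numeric(df$difficulty == "hard"),
    rep = as.numeric(df$repeated),
    blk = blk_c,
    pid = match(df$participant, pids),
    N = nrow(df), P = length(pids)
  )
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + ch) %% 2147483646L + 1L)
  })
  monitors <- c(memory_fixed_effects, "tau_intercept", "tau_slope")

  jm <- rjags::jags.model(textConnection(memory_jags_model), data = data_list,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = quiet)
  stats::update(jm, n.iter = warmup, progress.bar = "none")
  draws <- rjags::coda.samples(jm, variable.names = monitors,
                               n.iter = iterations - warmup,
                               progress.bar = "none")

  diag <- mcmc_diagnostics(draws)
  summ <- posterior_summary_table(draws, diag)
  converged <- all(diag$r_hat <= 1.01, na.rm = TRUE)
  if (!converged) {
    warning(sprintf("possible non-convergence: max R-hat = %.3f (%s)",
                    max(diag$r_hat), names(which.max(diag$r_hat))))
  }
  structure(
    list(draws = draws, chains = chains, iterations = iterations,
         warmup = warmup, postwarmup_draws = chains * (iterations - warmup),
         r_hat = diag$r_hat, bulk_ess = diag$bulk_ess,
         tail_ess = diag$tail_ess, summary = summ, converged = converged,
         seed = seed),
    class = "posterior_fit"
  )
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("Hierarchical logistic fit: %d chains x (%d - %d) = %d post-warmup draws\n",
              x$chains, x$iterations, x$warmup, x$postwarmup_draws))
  cat(sprintf("converged: %s (max R-hat %.3f, min bulk-ESS %.0f, min tail-ESS %.0f)\n",
              x$converged, max(x$r_hat), min(x$bulk_ess), min(x$tail_ess)))
  print(round(x$summary, 3))
  invisible(x)
}

# ---- convergence diagnostics -----------------------------------------------

# rank-normalization (normal scores of pooled ranks)
rank_normalize <- function(x) {
  stats::qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
}

split_chain_matrix <- function(mat) {
  # draws x chains -> draws/2 x 2*chains
  n <- nrow(mat)
  half <- n %/% 2
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1):n, , drop = FALSE])
}

rhat_split <- function(mat) {
  m <- split_chain_matrix(mat)
  z <- matrix(rank_normalize(as.vector(m)), nrow(m), ncol(m))
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  B <- nrow(z) * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(NA_real_)
  sqrt(((nrow(z) - 1) / nrow(z) * W + B / nrow(z)) / W)
}

ess_of <- function(mat) {
  ml <- coda::as.mcmc.list(lapply(seq_len(ncol(mat)), function(j) {
    coda::as.mcmc(mat[, j])
  }))
  sum(coda::effectiveSize(ml))
}

bulk_ess_split <- function(mat) {
  m <- split_chain_matrix(mat)
  z <- matrix(rank_normalize(as.vector(m)), nrow(m), ncol(m))
  ess_of(z)
}

tail_ess_split <- function(mat) {
  m <- split_chain_matrix(mat)
  x <- as.vector(m)
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  lo <- matrix(as.numeric(m <= q[1]), nrow(m), ncol(m))
  hi <- matrix(as.numeric(m >= q[2]), nrow(m), ncol(m))
  min(ess_of(lo), ess_of(hi))
}

#' Rank-normalized split R-hat and bulk/tail ESS for an mcmc.list
#'
#' @param draws a [coda::mcmc.list].
#' @return list of named vectors `r_hat`, `bulk_ess`, `tail_ess`.
#' @export
mcmc_diagnostics <- function(draws) {
  params <- colnames(draws[[1]])
  per_param <- function(fun) {
    vapply(params, function(p) {
      mat <- sapply(draws, function(ch) as.numeric(ch[, p]))
      fun(as.matrix(mat))
    }, numeric(1))
  }
  list(r_hat = per_param(rhat_split),
       bulk_ess = per_param(bulk_ess_split),
       tail_ess = per_param(tail_ess_split))
}

posterior_summary_table <- function(draws, diag) {
  pooled <- do.call(rbind, lapply(draws, as.matrix))
  data.frame(
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    q2.5 = apply(pooled, 2, stats::quantile, probs = 0.025),
    q97.5 = apply(pooled, 2, stats::quantile, probs = 0.975),
    r_hat = diag$r_hat[colnames(pooled)],
    bulk_ess = diag$bulk_ess[colnames(pooled)],
    tail_ess = diag$tail_ess[colnames(pooled)]
  )
}

#' Write a posterior summary as CSV
#'
#' @param fit a `"posterior_fit"`.
#' @param path file path.
#' @export
write_posterior_summary <- function(fit, path) {
  stopifnot(inherits(fit, "posterior_fit"))
  df <- data.frame(parameter = rownames(fit$summary), fit$summary,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
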