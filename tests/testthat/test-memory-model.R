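fit_small <- function(n_participants = 12, params = memory_model_params(),
                      seed = 1, chains = 2, iterations = 500, warmup = 200) {
  resp <- sim_memory_participants(n_participants, params, seed = seed)
  fit_hierarchical_model(resp, chains = chains, iterations = iterations,
                         warmup = warmup, adapt = 300, seed = seed)
}

test_that("post-warmup draw counts follow chains x (iterations - warmup)", {
  fit <- suppressWarnings(fit_small(8, seed = 301, chains = 2,
                                    iterations = 400, warmup = 150))
  expect_equal(fit$postwarmup_draws, 2 * (400 - 150))
  expect_equal(sum(sapply(fit$draws, nrow)), fit$postwarmup_draws)
  expect_equal(length(fit$draws), 2)
  # the production profile implies 32,000 draws
  full <- mcmc_profile("full")
  expect_equal(full$chains * (full$iterations - full$warmup), 32000)
  expect_equal(full$postwarmup_draws, 32000)
})

test_that("the fit recovers strong fixed effects and reports diagnostics", {
  params <- memory_model_params(intercept = 1.2, medium = -0.5, hard = -1.0,
                                repeated = 0.3, tau_intercept = 0.4)
  fit <- suppressWarnings(fit_small(25, params, seed = 302, chains = 2,
                                    iterations = 900, warmup = 300))
  s <- fit$summary
  expect_true(all(c("b_intercept", "b_medium", "b_hard", "b_repeated",
                    "tau_intercept", "tau_slope") %in% rownames(s)))
  # strong effects land inside their central 95% intervals
  expect_gt(s["b_hard", "q97.5"], -1.0 - 0.5)
  expect_lt(s["b_hard", "q2.5"], -1.0 + 0.5)
  expect_gt(s["b_intercept", "mean"], 0.5)
  # diagnostics present and sane
  expect_true(all(is.finite(fit$r_hat)))
  expect_true(all(fit$bulk_ess > 0))
  expect_true(all(fit$tail_ess > 0))
})

test_that("our split R-hat agrees with the coda PSRF on the same chains", {
  fit <- suppressWarnings(fit_small(10, seed = 303, chains = 2,
                                    iterations = 600, warmup = 200))
  gd <- coda::gelman.diag(fit$draws, autoburnin = FALSE, multivariate = FALSE)
  psrf <- gd$psrf[, 1]
  # rank-normalized split R-hat and classic PSRF agree near convergence
  common <- intersect(names(fit$r_hat), rownames(gd$psrf))
  expect_true(all(abs(fit$r_hat[common] - psrf[common]) < 0.2))
})

test_that("with no participant heterogeneity the posterior for tau shrinks to zero", {
  params <- memory_model_params(intercept = 1, tau_intercept = 0, tau_slope = 0)
  fit <- suppressWarnings(fit_small(20, params, seed = 304, chains = 2,
                                    iterations = 800, warmup = 300))
  pooled <- do.call(rbind, lapply(fit$draws, as.matrix))
  expect_lt(median(pooled[, "tau_intercept"]), 0.15)
})

test_that("the model demands the required inputs", {
  resp <- sim_memory_participants(1, seed = 305)
  expect_error(fit_hierarchical_model(resp), ">= 2 participants")
  expect_error(fit_hierarchical_model(data.frame(participant = 1:2)),
               "missing columns")
  resp2 <- sim_memory_participants(2, seed = 306)
  expect_error(fit_hierarchical_model(resp2, iterations = 100, warmup = 100),
               "smaller than")
})

test_that("posterior summaries export as CSV", {
  fit <- suppressWarnings(fit_small(6, seed = 307, chains = 2,
                                    iterations = 400, warmup = 150))
  f <- tempfile(fileext = ".csv")
  write_posterior_summary(fit, f)
  back <- read.csv(f)
  expect_true(all(c("parameter", "mean", "sd", "q2.5", "q97.5", "r_hat",
                    "bulk_ess", "tail_ess") %in% colnames(back)))
  expect_equal(nrow(back), nrow(fit$summary))
})
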