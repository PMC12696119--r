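test_that("choice probabilities follow the Gaussian difference-of-distances rule", {
  # closed form at a hand-picked triad
  p <- triplet_choice_prob(0.5, 0.4, 0.7, sigma = 0.2)
  expect_equal(p, pnorm((0.2 - 0.1) / (0.2 * sqrt(2))), tolerance = 1e-12)
  # equidistant probes -> exactly 0.5
  expect_equal(triplet_choice_prob(0.5, 0.3, 0.7, sigma = 0.1), 0.5)
  # lapse mixes towards 0.5
  expect_equal(triplet_choice_prob(0.5, 0.4, 0.7, sigma = 0.2, lapse = 0.5),
               0.5 * p + 0.25, tolerance = 1e-12)
})

test_that("observer choice rates match the closed form empirically", {
  psi <- seq(0, 1, length.out = 10)
  tr <- data.frame(object = "o", reference = 5, probe_left = 4, probe_right = 8)
  # near-deterministic: left probe strictly closer
  r <- simulate_triplet_responses(tr[rep(1, 200), ], psi, sigma = 1e-9, seed = 1)
  expect_true(all(r$choice == "left"))

  # sigma = 0.2: empirical rate matches Phi over many draws
  big <- tr[rep(1, 100000), ]
  r2 <- simulate_triplet_responses(big, psi, sigma = 0.2, seed = 2)
  expected <- triplet_choice_prob(psi[5], psi[4], psi[8], 0.2)
  expect_lt(abs(mean(r2$choice == "left") - expected), 0.01)

  # equidistant probes: empirical P(left) = 0.5 within 3 sigma binomial
  eq <- data.frame(object = "o", reference = 5, probe_left = 3, probe_right = 7)
  r3 <- simulate_triplet_responses(eq[rep(1, 10000), ], psi, sigma = 0.3, seed = 3)
  expect_lt(abs(mean(r3$choice == "left") - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("observer is invariant under joint affine maps of psi and sigma", {
  psi <- ground_truth_scale(seed = 4)
  tr <- sample_triplet_trials(10, 50, seed = 5)
  p1 <- triplet_choice_prob(psi[tr$reference], psi[tr$probe_left],
                            psi[tr$probe_right], sigma = 0.15)
  psi2 <- 3.2 * psi - 0.7
  p2 <- triplet_choice_prob(psi2[tr$reference], psi2[tr$probe_left],
                            psi2[tr$probe_right], sigma = 3.2 * 0.15)
  expect_equal(p1, p2, tolerance = 1e-12)
  # identical probabilities + identical seed -> identical responses
  r1 <- simulate_triplet_responses(tr, psi, sigma = 0.15, seed = 6)
  r2 <- simulate_triplet_responses(tr, psi2, sigma = 3.2 * 0.15, seed = 6)
  expect_identical(r1$choice, r2$choice)
})

test_that("a noiseless observer is perfectly consistent with the scale ordering", {
  psi <- ground_truth_scale(seed = 7)  # tie-free
  tr <- sample_triplet_trials(10, 500, seed = 8)
  r <- simulate_triplet_responses(tr, psi, sigma = 1e-9, seed = 9)
  expect_equal(triplet_error(psi, r), 0)
})

test_that("ground-truth scales are normalized, increasing and tie-free", {
  for (s in 1:5) {
    psi <- ground_truth_scale(10, jitter = 0.3, seed = s)
    expect_equal(range(psi), c(0, 1))
    expect_true(all(diff(psi) > 0))
    d <- as.vector(dist(psi))
    expect_equal(anyDuplicated(d), 0)
  }
})

test_that("memory simulation reproduces its generating probabilities", {
  # all coefficients zero -> accuracy 0.5
  null_params <- memory_model_params(intercept = 0, medium = 0, hard = 0,
                                     repeated = 0, block = 0,
                                     medium_block = 0, hard_block = 0,
                                     repeated_block = 0,
                                     tau_intercept = 0, tau_slope = 0)
  resp <- sim_memory_participants(30, null_params, seed = 10)
  n <- nrow(resp)
  expect_lt(abs(mean(resp$correct) - 0.5), 3 * sqrt(0.25 / n))

  # huge intercept -> all correct
  sure <- memory_model_params(intercept = 30, tau_intercept = 0, tau_slope = 0)
  resp2 <- sim_memory_participants(3, sure, seed = 11)
  expect_true(all(resp2$correct))

  # graded difficulty: easy > medium > hard over many participants
  graded <- memory_model_params(intercept = 1.2, medium = -0.6, hard = -1.2)
  resp3 <- sim_memory_participants(200, graded, seed = 12)
  acc <- tapply(resp3$correct, resp3$difficulty, mean)
  expect_true(acc[["easy"]] > acc[["medium"]])
  expect_true(acc[["medium"]] > acc[["hard"]])
})
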