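test_that("the triad likelihood equals hand-computed Phi terms", {
  psi <- c(0, 0.3, 0.55, 1)
  sigma <- 0.2
  resp <- data.frame(object = "o",
                     reference = c(2, 3),
                     probe_left = c(1, 1),
                     probe_right = c(4, 2),
                     choice = c("left", "right"))
  # trial 1 chose left: z = (|psi2-psi4| - |psi2-psi1|)/(sigma sqrt2)
  z1 <- (abs(psi[2] - psi[4]) - abs(psi[2] - psi[1])) / (sigma * sqrt(2))
  # trial 2 chose right: z = (|psi3-psi1| - |psi3-psi2|)/(sigma sqrt2)
  z2 <- (abs(psi[3] - psi[1]) - abs(psi[3] - psi[2])) / (sigma * sqrt(2))
  expect_equal(mlds_loglik(resp, psi, sigma),
               log(pnorm(z1)) + log(pnorm(z2)), tolerance = 1e-10)
})

test_that("MLDS recovers ordering exactly from noiseless judgements", {
  psi <- seq(0, 1, length.out = 10)
  triads <- enumerate_triads(10)
  all5 <- triads[rep(seq_len(nrow(triads)), 5), ]
  tr <- data.frame(object = "o", reference = all5$reference,
                   probe_left = all5$probe1, probe_right = all5$probe2)
  r <- simulate_triplet_responses(tr, psi, sigma = 1e-9, seed = 31)
  es <- fit_mlds(r, seed = 32)
  expect_equal(cor(es$psi_hat, psi, method = "spearman"), 1)
})

test_that("MLDS recovers psi and sigma from noisy judgements", {
  psi <- seq(0, 1, length.out = 10)
  r <- sim_responses(800, sigma = 0.1, psi = psi, seed = 33)
  es <- fit_mlds(r, seed = 34)
  expect_true(es$converged)
  expect_lt(sqrt(mean((es$psi_hat - psi)^2)), 0.06)
  expect_lt(abs(es$sigma_hat - 0.1) / 0.1, 0.35)
})

test_that("MLDS rejects degenerate data", {
  r <- data.frame(object = "o", reference = 1, probe_left = 2,
                  probe_right = 3, choice = "left")
  expect_error(fit_mlds(r, n = 5), "never judged")
  expect_error(fit_mlds(r[0, ]), "empty")
})

test_that("embedding normalization is idempotent and anchor-oriented", {
  es <- embedding_scale(c(5, 2, 8, 11), "mlds", sigma_hat = 0.6)
  expect_equal(range(es$psi_hat), c(0, 1))
  expect_equal(es$psi_hat[1], 1/3)  # (5-2)/9
  expect_equal(es$sigma_hat, 0.6 / 9)
  twice <- normalize_embedding(es)
  expect_identical(twice$psi_hat, es$psi_hat)
  expect_identical(twice$sigma_hat, es$sigma_hat)
  # anchor in the upper half -> reflected to the low end
  esr <- embedding_scale(c(10, 3, 1), "soe")
  expect_equal(esr$psi_hat[1], 0)
  expect_error(embedding_scale(c(1, 1, 1), "soe"), "degenerate")
})

test_that("SOE drives a consistent triplet set to zero loss and zero error", {
  psi <- ground_truth_scale(seed = 41)
  tr <- sample_triplet_trials(10, 600, seed = 42)
  r <- simulate_triplet_responses(tr, psi, sigma = 1e-9, seed = 43)
  es <- fit_soe(r, n = 10, seed = 44)
  expect_lt(es$loss, 1e-8)
  expect_equal(triplet_error(es, r), 0)
})

test_that("SOE loss is invariant to reflecting the configuration", {
  psi <- ground_truth_scale(seed = 45)
  r <- sim_responses(200, sigma = 0.2, psi = psi, seed = 46)
  pr <- r
  es <- fit_soe(pr, n = 10, seed = 47, n_restarts = 2)
  # distances are preserved under reflection, so the error must be too
  expect_equal(triplet_error(es$psi_hat, r),
               triplet_error(1 - es$psi_hat, r))
})

test_that("t-STE matches its closed-form loss and fits noiseless data", {
  # symmetric single triplet: p = 1/2, loss = log 2
  resp1 <- data.frame(object = "o", reference = 2, probe_left = 1,
                      probe_right = 3, choice = "left")
  X <- c(-1, 0, 1)
  expect_equal(tste_loss(resp1, X, alpha = 1), log(2), tolerance = 1e-12)

  # loss at a random configuration equals the direct formula
  set.seed(51)
  r <- sim_responses(100, sigma = 0.2, psi = ground_truth_scale(seed = 52),
                     seed = 53)
  Xr <- rnorm(10)
  w <- function(d, a) (1 + d^2 / a)^(-(a + 1) / 2)
  chosen <- ifelse(r$choice == "left", r$probe_left, r$probe_right)
  other <- ifelse(r$choice == "left", r$probe_right, r$probe_left)
  p <- w(abs(Xr[r$reference] - Xr[chosen]), 1) /
    (w(abs(Xr[r$reference] - Xr[chosen]), 1) +
       w(abs(Xr[r$reference] - Xr[other]), 1))
  expect_equal(tste_loss(r, Xr, alpha = 1), -sum(log(p)), tolerance = 1e-9)

  # noiseless data: held-out error small
  psi <- ground_truth_scale(seed = 54)
  tr <- sample_triplet_trials(10, 900, seed = 55)
  rr <- simulate_triplet_responses(tr, psi, sigma = 1e-9, seed = 56)
  es <- fit_tste(rr[1:700, ], n = 10, seed = 57)
  expect_lte(triplet_error(es, rr[701:900, ]), 0.02)
})

test_that("triplet error scores truth at zero, ties at half, noise at chance", {
  psi <- ground_truth_scale(seed = 61)
  tr <- sample_triplet_trials(10, 400, seed = 62)
  r <- simulate_triplet_responses(tr, psi, sigma = 1e-9, seed = 63)
  expect_equal(triplet_error(psi, r), 0)
  # reflection preserves distances hence the error
  expect_equal(triplet_error(1 - psi, r), 0)

  # random responses vs a fixed embedding: chance level
  set.seed(64)
  r2 <- sample_triplet_trials(10, 10000, seed = 65)
  r2$choice <- sample(c("left", "right"), nrow(r2), replace = TRUE)
  expect_lt(abs(triplet_error(psi, r2) - 0.5), 3 * sqrt(0.25 / 10000))

  # an exact tie scores one half
  tie <- data.frame(object = "o", reference = 2, probe_left = 1,
                    probe_right = 3, choice = "left")
  expect_equal(triplet_error(c(0, 0.5, 1), tie), 0.5)
  expect_error(triplet_error(psi, r[0, ]), "empty")
})

test_that("cross-validation partitions responses and is deterministic", {
  psi <- ground_truth_scale(seed = 71)
  r <- sim_responses(300, sigma = 0.1, psi = psi, seed = 72)
  cv <- cross_validated_error(r, "mlds", k = 5, seed = 73, n_restarts = 2)
  expect_equal(length(cv$fold_errors), 5)
  expect_equal(cv$mean_error, mean(cv$fold_errors))
  expect_equal(as.vector(table(cv$fold_id)), rep(60, 5))
  cv2 <- cross_validated_error(r, "mlds", k = 5, seed = 73, n_restarts = 2)
  expect_identical(cv$fold_errors, cv2$fold_errors)
  expect_identical(cv$fold_id, cv2$fold_id)
})

test_that("cross-validation flags folds that lose an image", {
  # image 10 appears exactly once -> its response's training folds are fine,
  # but the fold containing it leaves image 10 out of training
  r <- sim_responses(120, sigma = 0.1, psi = ground_truth_scale(seed = 74),
                     seed = 75)
  keep <- which(!(r$reference == 10 | r$probe_left == 10 | r$probe_right == 10))
  r2 <- rbind(r[keep[1:40], ],
              data.frame(object = "o", reference = 10, probe_left = 1,
                         probe_right = 2, choice = "left"))
  expect_error(cross_validated_error(r2, "mlds", k = 10, seed = 76),
               "smaller k")
})

test_that("noiseless cross-validated error is near zero for all methods", {
  psi <- ground_truth_scale(seed = 81)
  tr <- sample_triplet_trials(10, 500, seed = 82)
  r <- simulate_triplet_responses(tr, psi, sigma = 1e-9, seed = 83)
  for (m in c("mlds", "soe")) {
    cv <- cross_validated_error(r, m, k = 5, seed = 84, n_restarts = 2)
    expect_lte(cv$mean_error, 0.02)
  }
})

test_that("rank agreement recovers identity, reversal and the null", {
  orders <- replicate(108, sample(10), simplify = FALSE)
  ra <- rank_agreement(orders, orders)
  expect_equal(ra$spearman_rho, 1)
  expect_equal(sum(diag(ra$confusion)), 1080)
  expect_equal(sum(ra$confusion), 1080)

  rev_orders <- lapply(orders, rev)
  expect_equal(rank_agreement(orders, rev_orders)$spearman_rho, -1)

  # permutation null: mean rho near zero
  set.seed(91)
  rhos <- replicate(1000, {
    rank_agreement(sample(10), sample(10))$spearman_rho
  })
  expect_lt(abs(mean(rhos)), 0.04)

  expect_error(rank_agreement(list(1:10), list(1:9)), "length mismatch|must be permutations")
  expect_error(rank_agreement(list(c(1, 1, 3)), list(1:3)), "permutations")
})

test_that("embedding_order sorts images from the anchor end outward", {
  es <- embedding_scale(c(0.1, 0.9, 0.0, 0.5), "soe")
  expect_equal(embedding_order(es), c(3, 1, 4, 2))
})
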