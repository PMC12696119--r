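test_that("foil selection matches exhaustive search and the equispaced case", {
  # linspace scale: foils at ranks 4, 7, 10 (gaps 1/3, 2/3, 1), objective 0
  psi <- seq(0, 1, length.out = 10)
  fs <- select_foils(psi)
  expect_equal(fs$target_idx, 1)
  expect_equal(fs$foil_idxs, c(4, 7, 10))
  expect_equal(fs$gaps, c(1, 2, 3) / 3)
  expect_equal(fs$objective_value, 0)

  # random scales vs brute force
  for (s in 1:6) {
    psi_r <- ground_truth_scale(seed = 100 + s)
    fs_r <- select_foils(psi_r)
    bf <- brute_force_foils(psi_r)
    expect_equal(fs_r$objective_value, bf$val, tolerance = 1e-12)
    expect_setequal(fs_r$foil_idxs, bf$idx)
    expect_true(all(diff(fs_r$gaps) > 0))
  }
})

test_that("an isolated far point becomes the easy foil", {
  psi <- c(0, 0.02, 0.04, 0.05, 0.07, 0.08, 0.1, 0.11, 0.12, 1)
  psi <- normalize_embedding(psi)
  fs <- select_foils(psi)
  expect_equal(fs$foil_idxs[3], 10)  # farthest = easy
})

test_that("degenerate (tied) scales warn and tie-break by index", {
  psi <- c(0, 0, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
  expect_warning(fs <- select_foils(psi), "not strictly increasing|ties")
  expect_equal(fs$target_idx, 1)
})

test_that("a generated memory session satisfies every counterbalance constraint", {
  s <- generate_memory_session(sprintf("r%d", 1:9), sprintf("n%d", 1:54),
                               seed = 5)
  expect_equal(nrow(s), 108)
  expect_equal(as.vector(table(s$block)), rep(18, 6))
  expect_length(memory_session_violations(s), 0)
  expect_true(validate_memory_session(s))
  # difficulty totals: 3 per block x condition x 6 blocks x 2 conditions = 36
  expect_equal(as.vector(table(s$difficulty)), rep(36, 3))
  # exact 54/54 splits
  expect_equal(sum(s$target_position == "first"), 54)
  expect_equal(sum(s$mapping_side == "left"), 54)
  expect_equal(sum(correct_button(s) == "left"), 54)

  s2 <- generate_memory_session(sprintf("r%d", 1:9), sprintf("n%d", 1:54),
                                seed = 5)
  expect_identical(as.data.frame(s), as.data.frame(s2))
})

test_that("the validator rejects every single-field mutation", {
  s <- generate_memory_session(sprintf("r%d", 1:9), sprintf("n%d", 1:54),
                               seed = 6)
  mutate <- function(col, value, row = 1) {
    m <- as.data.frame(s)
    m[row, col] <- value
    m
  }
  # flip one trial's difficulty to another level
  row <- which(s$difficulty == "easy")[1]
  expect_gt(length(memory_session_violations(mutate("difficulty", "hard", row))), 0)
  # flip one side / position
  row2 <- which(s$mapping_side == "left")[1]
  expect_gt(length(memory_session_violations(mutate("mapping_side", "right", row2))), 0)
  row3 <- which(s$target_position == "first")[1]
  expect_gt(length(memory_session_violations(mutate("target_position", "second", row3))), 0)
  # flip a repetition flag
  expect_gt(length(memory_session_violations(mutate("repeated", !s$repeated[1]))), 0)
  # out-of-domain values
  expect_gt(length(memory_session_violations(mutate("iti_ms", 1234))), 0)
  expect_gt(length(memory_session_violations(mutate("block", 7))), 0)
  # dropping a trial breaks the count
  expect_gt(length(memory_session_violations(as.data.frame(s)[-1, ])), 0)
  expect_error(validate_memory_session(as.data.frame(s)[-1, ]), "invalid")
})

test_that("session generation validates the target assignment", {
  expect_error(generate_memory_session(sprintf("r%d", 1:8),
                                       sprintf("n%d", 1:54), seed = 1),
               "9 repeated")
  expect_error(generate_memory_session(sprintf("r%d", 1:9),
                                       sprintf("n%d", 1:50), seed = 1),
               "54 non-repeated")
  expect_error(generate_memory_session(c("a", sprintf("r%d", 1:8)),
                                       c("a", sprintf("n%d", 1:53)), seed = 1),
               "distinct")
})

test_that("accuracy summary aggregates participants first", {
  # two participants with cell accuracies 0.4 and 0.6 -> mean 0.5, sem 0.1
  cell <- expand.grid(trial = 1:5, participant = c("A", "B"))
  cell$block <- 1; cell$repeated <- TRUE; cell$difficulty <- "easy"
  cell$correct <- ifelse(cell$participant == "A",
                         c(TRUE, TRUE, FALSE, FALSE, FALSE),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE))
  out <- summarize_accuracy(cell)
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_accuracy, 0.5)
  expect_equal(out$sem, 0.1)
  expect_equal(out$n_participants, 2L)

  # all-correct input: every cell mean 1, sem 0
  resp <- sim_memory_participants(2, memory_model_params(intercept = 30,
                                                         tau_intercept = 0,
                                                         tau_slope = 0),
                                  seed = 7)
  out2 <- summarize_accuracy(resp)
  expect_true(all(out2$mean_accuracy == 1))
  expect_true(all(out2$sem == 0))
  expect_equal(nrow(out2), 36)  # 6 blocks x 2 conditions x 3 difficulties
})

test_that("simulated difficulty gradients survive aggregation in most replicates", {
  graded <- memory_model_params(intercept = 1.2, medium = -0.6, hard = -1.2)
  ok <- sapply(1:100, function(rep) {
    resp <- sim_memory_participants(12, graded, seed = 2000 + rep)
    acc <- tapply(resp$correct, resp$difficulty, mean)
    acc[["easy"]] > acc[["medium"]] && acc[["medium"]] > acc[["hard"]]
  })
  expect_gte(mean(ok), 0.95)
})
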