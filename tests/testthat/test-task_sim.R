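test_that("block advance: a near-perfect agent ends blocks at trial 30", {
  agent <- ideal_agent()
  plan <- session_plan(n_blocks = 2, rng_seed = 5)
  tr <- generate_session(plan, agent$model, agent$params)
  be <- block_summary(tr)
  # within the first block the ideal agent errs at most on trial 1, so the
  # 12-trial window is perfect at trial 30, the earliest trial at which the
  # advance rule can fire given the 30-trial minimum
  expect_equal(be$length[1], 30L)
  expect_equal(be$reason[1], "criterion")
  # after the un-cued reversal the agent first has to unlearn, so block 2
  # ends later, by criterion or cap, within the legal range
  expect_true(be$length[2] >= 30 && be$length[2] <= 50)
  # rewarded color flips between consecutive blocks
  cols <- tapply(tr$rewarded_color, tr$block_index, unique)
  expect_equal(length(unique(unlist(cols))), 2L)
  expect_true(cols[[1]] != cols[[2]])
})

test_that("a uniformly random agent earns reward at chance", {
  set.seed(21)
  tr <- simulate_condition(250, "FV", c(eta = 0, beta = 0),
                           condition = "x", block_length_min = 40)
  expect_gt(nrow(tr), 10000)
  rate <- mean(tr$reward)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / nrow(tr)))
})

test_that("sessions are deterministic under a fixed plan seed", {
  agent <- list(model = "FW+Decay", params = fwd_params("drug"))
  plan <- session_plan(n_blocks = 3, rng_seed = 99)
  a <- generate_session(plan, agent$model, agent$params)
  b <- generate_session(plan, agent$model, agent$params)
  expect_identical(a, b)
})

test_that("block lengths, dimming proportions and feature invariants hold", {
  set.seed(22)
  tr <- simulate_condition(80, "FW+Decay", fwd_params("control"),
                           condition = "x")
  be <- block_summary(tr)
  expect_true(all(be$length >= 30 & be$length <= 50))
  expect_true(all(tr$trial_in_block <= 50))
  # dimming proportions converge to 1/3 each (within 3 SE)
  n <- nrow(tr)
  expect_gt(n, 3000)
  props <- table(tr$dimming_condition) / n
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_true(all(abs(props - 1 / 3) < 3 * se))
  # reward is deterministic given choice and rewarded color
  chosen_color <- ifelse(tr$choice == "left", tr$left_color,
                         3L - tr$left_color)
  expect_identical(tr$reward, as.integer(chosen_color == tr$rewarded_color))
  # motion and color randomized independently at ~0.5
  expect_lt(abs(mean(tr$left_color == 1) - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(tr$left_motion == "up") - 0.5), 3 * sqrt(0.25 / n))
})

test_that("lapse trials are tagged and excluded from the advance window", {
  set.seed(23)
  plan <- session_plan(n_blocks = 3, lapse_rate = 0.15)
  tr <- generate_session(plan, "BI", c(beta = 60))
  lapses <- tr[tr$choice == "none", ]
  expect_gt(nrow(lapses), 0)
  expect_true(all(lapses$outcome_class %in% c("fixation_break", "premature")))
  expect_true(all(lapses$reward == 0))
  # completed-choice outcomes still label correctly
  done <- tr[tr$choice != "none", ]
  expect_true(all(done$outcome_class %in% c("rewarded_choice", "error_choice")))
})

test_that("trial tables round-trip through TSV exactly", {
  set.seed(24)
  tr <- simulate_condition(3, "FV", c(eta = 0.5, beta = 2), condition = "drug")
  path <- tempfile(fileext = ".tsv")
  write_trials(tr, path)
  back <- read_trials(path)
  attr(tr, "block_end") <- NULL
  rownames(tr) <- NULL
  expect_identical(back, tr[, names(back)])
  # empty table round-trips to an empty table
  empty <- tr[0, ]
  write_trials(empty, path)
  expect_equal(nrow(read_trials(path)), 0L)
})

test_that("validation rejects schema and invariant violations", {
  set.seed(25)
  tr <- simulate_condition(2, "FV", c(eta = 0.5, beta = 2), condition = "x")
  expect_error(validate_trials(tr[, -3]), "missing column")
  bad <- tr
  i <- which(bad$choice == "left" & bad$reward == 0)[1]
  bad$reward[i] <- 1L  # reward without the rewarded color chosen
  expect_error(validate_trials(bad), "inconsistent")
  bad2 <- tr
  bad2$choice[1] <- "middle"
  expect_error(validate_trials(bad2), "choice")
  expect_error(read_trials(tempfile()), "no such file")
  expect_error(session_plan(n_blocks = 0), "positive")
  expect_error(generate_session(session_plan(2), "NOPE", c(beta = 1)),
               "unknown model")
})
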