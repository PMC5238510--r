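test_that("identical data under both labels flags nothing", {
  set.seed(61)
  cur <- synthetic_curves(40)
  curves <- rbind(cur, cur)
  labels <- rep(c("a", "b"), each = 40)
  # pair rows so every permutation comparison is of identical samples
  r <- trialwise_permutation_test(curves, labels, n_perm = 200, seed = 3)
  expect_true(all(abs(r$diff) < 1e-12))
  expect_length(r$significant, 0)
})

test_that("permutation test is reproducible and order-invariant in its statistic", {
  set.seed(62)
  curves <- synthetic_curves(60)
  labels <- rep(c("a", "b"), 30)
  r1 <- trialwise_permutation_test(curves, labels, n_perm = 300, seed = 11)
  r2 <- trialwise_permutation_test(curves, labels, n_perm = 300, seed = 11)
  expect_identical(r1, r2)
  ord <- sample(nrow(curves))
  r3 <- trialwise_permutation_test(curves[ord, ], labels[ord],
                                   n_perm = 300, seed = 11)
  expect_equal(r1$diff, r3$diff)
})

test_that("a large localized shift is flagged at the shifted trials", {
  set.seed(63)
  curves <- rbind(synthetic_curves(150, shift = 0.3, shift_trials = 8:10),
                  synthetic_curves(150))
  labels <- rep(c("drug", "control"), each = 150)
  r <- trialwise_permutation_test(curves, labels, n_perm = 500, seed = 5,
                                  positive = "drug")
  expect_true(all(8:10 %in% r$significant))
  expect_error(trialwise_permutation_test(curves, rep("a", 300)),
               "two condition")
  expect_warning(trialwise_permutation_test(curves, labels, n_perm = 50,
                                            seed = 1), "coarse")
})

test_that("consistency statistic: forced ordering and label symmetry", {
  set.seed(64)
  # drug learns exactly 3 trials earlier in every block
  ctrl <- synthetic_lt_table(6, 8, "control",
                             function(s, b) sample(8:20, 1))
  drug <- ctrl
  drug$condition <- "drug"
  drug$session_id <- sub("control", "drug", drug$session_id)
  drug$learning_trial <- drug$learning_trial - 3L
  tab <- rbind(drug, ctrl)
  r <- consistency_randomization(tab, faster = "drug", n_perm = 100, seed = 2)
  expect_equal(r$statistic, 1)
  # reversing the roles maps the statistic to 1 - statistic (no ties here)
  r2 <- consistency_randomization(tab, faster = "control", n_perm = 100,
                                  seed = 2)
  expect_equal(r2$statistic, 0)
  expect_equal(nrow(r$position_medians), 15L)
})

test_that("consistency test is calibrated on label-symmetric data", {
  set.seed(65)
  tab <- rbind(
    synthetic_lt_table(8, 8, "drug", function(s, b) sample(5:25, 1)),
    synthetic_lt_table(8, 8, "control", function(s, b) sample(5:25, 1)))
  r <- consistency_randomization(tab, faster = "drug", n_perm = 300, seed = 4)
  expect_gt(r$p_value, 0.05)
  expect_lt(abs(r$statistic - 0.5), 0.35)
})

test_that("performance metrics summarize and recombine correctly", {
  set.seed(66)
  tr <- rbind(
    simulate_condition(4, "FW+Decay", fwd_params("drug"), condition = "drug",
                       lapse_rate = 0.1),
    simulate_condition(4, "FW+Decay", fwd_params("control"),
                       condition = "control", lapse_rate = 0.1))
  pm <- performance_metrics(tr)
  ps <- pm$per_session
  expect_equal(ps$n_blocks, rep(4L, 2))
  # dimming-split proportions recombine (weighted) to the overall proportion
  for (i in seq_len(nrow(ps))) {
    s <- tr[tr$session_id == ps$session_id[i] & tr$choice != "none", ]
    w <- table(s$dimming_condition)[c("simultaneous", "rewarded_first",
                                      "rewarded_second")]
    parts <- unlist(ps[i, c("prop_rewarded_simultaneous",
                            "prop_rewarded_rewarded_first",
                            "prop_rewarded_rewarded_second")])
    expect_equal(sum(parts * w) / sum(w), ps$prop_rewarded[i],
                 tolerance = 1e-12)
  }
  expect_true(all(ps$premature_rate + ps$fixation_break_rate > 0))
  expect_true(is.data.frame(pm$comparison))
  # all-rewarded toy table
  toy <- tr[tr$reward == 1, ]
  toy$trial_in_block <- ave(toy$reward, toy$session_id, toy$block_index,
                            FUN = seq_along)
  pm2 <- performance_metrics(validate_trials(toy))
  expect_true(all(pm2$per_session$prop_rewarded == 1))
  expect_error(performance_metrics(tr[0, ]), "empty")
})
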