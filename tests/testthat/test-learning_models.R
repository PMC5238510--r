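test_that("delta-rule, decay and two-rate updates follow their closed forms", {
  v <- rep(0.5, 6)
  # eta = 1 sets the value to the reward
  expect_equal(delta_update(v, 1:3, 1, 1)[1:3], rep(1, 3))
  # eta = 0 leaves values untouched
  expect_equal(delta_update(replace(v, 2, 0.7), 1:3, 1, 0)[2], 0.7)
  expect_equal(delta_update(v, c(1, 3, 5), 0, 0.5)[c(1, 3, 5)], rep(0.25, 3))
  # unchosen entries untouched
  expect_equal(delta_update(v, 1:3, 1, 0.8)[4:6], rep(0.5, 3))
  expect_error(delta_update(v, 1:3, 1, -0.1), "eta")

  expect_equal(decay_update(replace(v, 4, 0.8), 4:6, 1)[4], 0.8)
  expect_equal(decay_update(replace(v, 4, 0.8), 4:6, 2)[4], 0.4)
  expect_error(decay_update(v, 4:6, 0.9), "omega")
  # repeated decay is monotone geometric
  x <- 0.8
  for (i in 1:20) x <- decay_update(replace(v, 4, x), 4, 1.3)[4]
  expect_lt(x, 0.8 * 1.3^-19)

  expect_equal(two_eta_update(v, 1:3, 1, 0.7, 0.2),
               delta_update(v, 1:3, 1, 0.7))
  expect_equal(two_eta_update(v, 1:3, 0, 0.7, 0.2),
               delta_update(v, 1:3, 0, 0.2))
  expect_equal(two_eta_update(v, 1:3, 0, 0.2, 0.2)[1:3], rep(0.4, 3))
  expect_error(two_eta_update(v, 1:3, 1, -1, 0.2), "rates")
})

test_that("delta rule is unstable beyond eta = 2 (alternating outcomes)", {
  v <- 0.5
  gap <- numeric(20)
  for (t in 1:20) {
    r <- t %% 2
    gap[t] <- abs(r - v)
    v <- delta_update(c(v, rep(0, 5)), 1, r, 2.5)[1]
  }
  expect_true(all(diff(gap[5:20]) > 0))
  expect_gt(gap[20] / gap[5], 10)
})

test_that("softmax choice matches closed form and its limits", {
  expect_equal(softmax_choice(0.7, 0.7, 5), c(0.5, 0.5))
  expect_equal(softmax_choice(3, -1, 0), c(0.5, 0.5))
  expect_equal(softmax_choice(1, 0, 2),
               c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-12)
  # overflow-safe at extreme beta
  p <- softmax_choice(1000, 0, 50)
  expect_equal(sum(p), 1)
  expect_equal(p[1], 1)
})

test_that("Bayesian update matches hand enumeration and stays normalized", {
  b <- rep(1 / 6, 6)
  post <- bayes_update(b, c(1, 3, 5), 1, 0.99)
  expect_equal(post[c(1, 3, 5)], rep(0.33, 3), tolerance = 1e-12)
  expect_equal(post[c(2, 4, 6)], rep(1 / 300, 3), tolerance = 1e-12)
  # p_r = 0.5 is uninformative
  expect_equal(bayes_update(b, c(1, 3, 5), 1, 0.5), b)
  expect_equal(bayes_update(b, c(1, 3, 5), 0, 0.5), b)
  # opposite outcomes pull back toward (not onto) the prior, normalized
  post2 <- bayes_update(post, c(1, 3, 5), 0, 0.99)
  expect_equal(sum(post2), 1, tolerance = 1e-12)
  expect_true(all(abs(post2 - b) < abs(post - b) + 1e-12))
})

test_that("incremental Bayesian updates agree with brute-force enumeration", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 200
    chosen_list <- vector("list", n)
    rewards <- rbinom(n, 1, 0.5)
    b <- rep(1 / 6, 6)
    for (t in 1:n) {
      f <- stimulus_features(sample(1:2, 1), sample(c("up", "down"), 1))
      chosen_list[[t]] <- if (runif(1) < 0.5) f$left else f$right
      b <- bayes_update(b, chosen_list[[t]], rewards[t], 0.99)
      expect_equal(sum(b), 1, tolerance = 1e-10)
    }
    oracle <- brute_force_posterior(chosen_list, rewards, 0.99)
    expect_lt(max(abs(b - oracle)), 1e-12)
  }
})

test_that("Bayesian-integrator stimulus values are complementary", {
  b <- rep(1 / 6, 6)
  f <- stimulus_features(1, "up")
  expect_equal(bi_choice_value(b, f$left, f$right), c(0.5, 0.5))
  conc <- c(0, 0, 0, 0, 1, 0)  # certain the target is color1
  v <- bi_choice_value(conc, f$left, f$right, 0.99)
  expect_equal(v[1], 0.99)  # left carries color1
  set.seed(7)
  for (i in 1:20) {
    b <- runif(6); b <- b / sum(b)
    expect_equal(sum(bi_choice_value(b, f$left, f$right)), 1,
                 tolerance = 1e-12)
  }
})

test_that("dimension weights follow g^alpha normalization", {
  b <- rep(1 / 6, 6)
  expect_equal(dimension_weights(b, 2.7), rep(1 / 3, 3))
  expect_equal(dimension_weights(c(0.4, 0.1, 0.2, 0.1, 0.1, 0.1), 0),
               rep(1 / 3, 3))
  b2 <- c(0.025, 0.025, 0.025, 0.025, 0.45, 0.45)
  expect_equal(dimension_weights(b2, 1), c(0.05, 0.05, 0.9))
  expect_error(dimension_weights(b, -1), "alpha")
})

test_that("feature-weighted stimulus value and object-level update", {
  v <- rep(0.5, 6)
  f <- stimulus_features(1, "up")
  expect_equal(fw_stimulus_value(v, rep(1 / 3, 3), f$left), 0.5)
  v2 <- v; v2[f$left[3]] <- 0.9
  expect_equal(fw_stimulus_value(v2, c(0, 0, 1), f$left), 0.9)
  v3 <- numeric(6); v3[f$left] <- c(0.1, 0.4, 0.8)
  expect_equal(fw_stimulus_value(v3, c(0.2, 0.3, 0.5), f$left), 0.54)

  # zero prediction error leaves values unchanged
  expect_equal(fw_update(v, f$left, 1, 1, 0.7), v)
  out <- fw_update(v, f$left, 0.5, 1, 0.4)
  expect_equal(out[f$left], rep(0.7, 3))
  expect_equal(out[f$right], rep(0.5, 3))
})

test_that("choice-history filter reweights toward the previous color", {
  p <- c(0.7, 0.3)
  expect_equal(choice_history_filter(p, 2, 1), p)          # gamma = 1
  expect_equal(choice_history_filter(p, 2, 0), c(0, 1))    # perseveration
  expect_equal(choice_history_filter(p, 2, 0.5), c(0.35, 0.65))
  expect_equal(choice_history_filter(p, NA, 0.2), p)       # no history
  expect_error(choice_history_filter(p, 1, 1.2), "gamma")
})

test_that("every model assigns total choice probability 1 and log(0.5) at start", {
  set.seed(11)
  f <- stimulus_features(2, "down")
  for (m in model_names()) {
    params <- random_params(m)
    st <- init_state(m)
    p <- revlearn:::model_choice_probs(m, params, st, f)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, c(0.5, 0.5), tolerance = 1e-12)  # symmetric start
    tr <- list(left_color = 2L, left_motion = "down", choice = "left",
               reward = 0L)
    expect_equal(trial_loglik(m, params, st, tr)$loglik, log(0.5),
                 tolerance = 1e-12)
    # probabilities still sum to 1 after a few updates
    for (i in 1:10) {
      st <- revlearn:::model_update_state(m, params, st, f,
                                          sample(1:2, 1), rbinom(1, 1, 0.5))
      p <- revlearn:::model_choice_probs(m, params, st, f)
      expect_equal(sum(p), 1, tolerance = 1e-10)
    }
  }
})

test_that("non-choice trials contribute zero and leave state unchanged", {
  st <- init_state("FW+Decay")
  tr <- list(left_color = 1L, left_motion = "up", choice = "none",
             reward = 0L)
  res <- trial_loglik("FW+Decay", fwd_params("drug"), st, tr)
  expect_identical(res$loglik, 0)
  expect_identical(res$state, st)
})

test_that("compiled likelihood agrees with the R reference for all models", {
  set.seed(12)
  agent <- ideal_agent()
  tr <- rbind(
    simulate_condition(4, agent$model, agent$params, condition = "a",
                       session_prefix = "sa"),
    simulate_condition(4, "FV", c(eta = 0.4, beta = 1.5), condition = "b",
                       session_prefix = "sb")
  )
  for (m in model_names()) {
    params <- random_params(m)
    r_ll <- session_loglik_r(m, params, tr)
    cpp_nll <- session_nll(m, params, tr)
    expect_lt(abs(r_ll + cpp_nll), 1e-10)
  }
})

test_that("exact reductions: equal rates and gamma = 1", {
  set.seed(13)
  tr <- simulate_condition(6, "FW", c(eta = 0.6, beta = 2, alpha = 0.5),
                           condition = "x")
  expect_equal(session_nll("FV+2Eta", c(eta1 = 0.5, eta0 = 0.5, beta = 2), tr),
               session_nll("FV", c(eta = 0.5, beta = 2), tr),
               tolerance = 1e-12)
  expect_equal(session_nll("FW+ChoiceHistory",
                           c(eta = 0.6, beta = 2, alpha = 0.5, gamma = 1), tr),
               session_nll("FW", c(eta = 0.6, beta = 2, alpha = 0.5), tr),
               tolerance = 1e-12)
})

test_that("parameter validation catches missing and illegal values", {
  expect_error(model_spec("FOO"), "unknown model")
  expect_error(check_params("FV", c(eta = 0.5)), "missing")
  expect_error(check_params("FV+Decay", c(eta = 0.5, beta = 2, omega = 0.9)),
               "omega")
  expect_error(check_params("FW+ChoiceHistory",
                            c(eta = 0.5, beta = 2, alpha = 1, gamma = 2)),
               "gamma")
  expect_silent(check_params("BI", c(beta = 3)))
  expect_equal(model_spec("FW+Decay")$k, 4L)
  expect_equal(model_spec("BI")$k, 1L)
})
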