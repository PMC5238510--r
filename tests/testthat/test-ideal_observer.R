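test_that("degenerate all-correct blocks are detected immediately", {
  cv <- fit_learning_curve(rep(1, 30))
  expect_lte(cv$learning_trial, 3)
  expect_true(all(cv$pmode > cv$chance))  # entirely above chance
  expect_true(all(cv$lower <= cv$pmode & cv$pmode <= cv$upper))
  expect_true(all(cv$pmode > 0 & cv$pmode < 1))
  # all-wrong sequence never detects
  expect_true(is.na(fit_learning_curve(rep(0, 30))$learning_trial))
})

test_that("EM log-likelihood is non-decreasing (exact grid inference)", {
  set.seed(51)
  for (i in 1:5) {
    y <- rbinom(35, 1, runif(1, 0.3, 0.9))
    cv <- fit_learning_curve(y)
    expect_true(all(diff(cv$loglik) > -1e-9))
  }
})

test_that("learning-trial rule: first trial of the final above-chance run", {
  fake <- function(lower) {
    structure(list(lower = lower, chance = 0.5), class = "learning_curve")
  }
  expect_true(is.na(learning_trial(fake(rep(0.4, 20)))))          # never up
  expect_equal(learning_trial(fake(rep(0.6, 20))), 1L)            # always up
  lo <- c(rep(0.4, 11), rep(0.6, 9))
  expect_equal(learning_trial(fake(lo)), 12L)                     # crosses at 12
  lo2 <- c(rep(0.6, 5), rep(0.4, 5), rep(0.6, 10))
  expect_equal(learning_trial(fake(lo2)), 11L)  # early excursion ignored
  lo3 <- c(rep(0.4, 5), rep(0.6, 10), 0.4)
  expect_true(is.na(learning_trial(fake(lo3))))  # must hold to block end
})

test_that("chance-only blocks rarely trigger detection (scaled-down null)", {
  set.seed(52)
  det <- sum(replicate(100, {
    !is.na(fit_learning_curve(rbinom(40, 1, 0.5))$learning_trial)
  }))
  # nominal rate ~3% at the 95% criterion; 9/100 would be a gross failure
  expect_lte(det, 9)
})

test_that("appending correct trials never delays the learning trial", {
  set.seed(53)
  for (i in 1:8) {
    y <- c(rbinom(10, 1, 0.4), rbinom(15, 1, 0.85))
    lt1 <- fit_learning_curve(y)$learning_trial
    lt2 <- fit_learning_curve(c(y, rep(1, 8)))$learning_trial
    if (!is.na(lt1)) {
      expect_false(is.na(lt2))
      expect_lte(lt2, lt1)
    }
  }
})

test_that("grid smoother tracks the Gaussian-approximation reference", {
  set.seed(54)
  # gentle, non-saturated sequences where the Laplace approximation is valid
  for (i in 1:3) {
    y <- rbinom(40, 1, plogis(seq(-0.5, 1.2, length.out = 40)))
    a <- fit_learning_curve(y)
    b <- revlearn:::fit_learning_curve_gauss(y)
    expect_lt(max(abs(a$pmode - b$pmode)), 0.1)
  }
  # a clearly rising sequence: both paths must rise from near chance
  y2 <- c(0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, rep(1, 10))
  a2 <- fit_learning_curve(y2)
  b2 <- revlearn:::fit_learning_curve_gauss(y2)
  expect_lt(max(abs(a2$pmode - b2$pmode)), 0.1)
  expect_gt(tail(a2$pmode, 1), a2$pmode[1])
})

test_that("input validation", {
  expect_error(fit_learning_curve(c(1, 0, 1)), "at least 5")
  expect_error(fit_learning_curve(c(1, 0, 2, 1, 0)), "binary")
  expect_error(fit_learning_curve(rep(1, 10), chance = 0), "chance")
})

test_that("learning-trial tables and distributions summarize conditions", {
  set.seed(55)
  tr <- rbind(
    simulate_condition(8, "FW+Decay", fwd_params("drug"), condition = "drug"),
    simulate_condition(8, "FW+Decay", fwd_params("control"),
                       condition = "control"))
  lt <- learning_trials_table(tr)
  expect_equal(nrow(lt), 16L)
  expect_true(all(lt$condition %in% c("drug", "control")))
  learned <- lt[!is.na(lt$learning_trial), ]
  expect_gt(nrow(learned), 0)
  dist <- learning_trial_distribution(lt)
  for (cd in dist$condition) {
    expect_equal(dist$median_learning_trial[dist$condition == cd],
                 median(learned$learning_trial[learned$condition == cd]))
  }
  # identical blocks under two labels give identical distributions
  dup <- lt
  dup$condition <- "a"
  dup2 <- lt
  dup2$condition <- "b"
  dd <- learning_trial_distribution(rbind(dup, dup2))
  expect_equal(dd$median_learning_trial[1], dd$median_learning_trial[2])
  expect_equal(dd$prop_fast[1], dd$prop_fast[2])
  none <- lt
  none$learning_trial <- NA_integer_
  expect_error(learning_trial_distribution(none), "no blocks")
})

test_that("faster learners have earlier learning trials (eta monotonicity)", {
  set.seed(56)
  slow <- simulate_condition(60, "FV", c(eta = 0.15, beta = 3),
                             condition = "slow")
  fast <- simulate_condition(60, "FV", c(eta = 0.9, beta = 3),
                             condition = "fast")
  lt <- learning_trials_table(rbind(slow, fast))
  dist <- learning_trial_distribution(lt)
  expect_lt(dist$median_learning_trial[dist$condition == "fast"],
            dist$median_learning_trial[dist$condition == "slow"])
})
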