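# shared fixtures, all generated in code

# near-deterministic ideal agent: Bayesian integrator with a steep softmax
# (correct from trial 2 of every block onwards)
ideal_agent <- function() list(model = "BI", params = c(beta = 60))

# canonical generative vectors (drug/control) for the best model
fwd_params <- function(which = c("drug", "control")) {
  which <- match.arg(which)
  if (which == "drug") c(eta = 0.648, beta = 2.12, alpha = 0.41, omega = 1.179)
  else c(eta = 0.561, beta = 2.18, alpha = 0.44, omega = 1.043)
}

# random valid parameter vector for any model, uniform within the
# optimizer bounds (gamma kept off 0/1 edges)
random_params <- function(model) {
  b <- revlearn:::param_bounds(model)
  p <- setNames(runif(length(b$par), b$lower, b$upper), b$par)
  if ("gamma" %in% names(p)) p["gamma"] <- runif(1, 0.05, 0.95)
  p
}

# brute-force Bayesian posterior: explicit product over the whole history
# for each of the six candidate targets (independent of the incremental
# update path)
brute_force_posterior <- function(chosen_list, rewards, p_r = 0.99) {
  p_n <- 1 - p_r
  log_post <- rep(log(1 / 6), 6)
  for (t in seq_along(rewards)) {
    r <- rewards[t]
    inside <- seq_len(6) %in% chosen_list[[t]]
    lik <- ifelse(inside,
                  p_r * r + (1 - p_r) * (1 - r),
                  p_n * r + (1 - p_n) * (1 - r))
    log_post <- log_post + log(lik)
  }
  w <- exp(log_post - max(log_post))
  w / sum(w)
}

# synthetic per-block learning curves for the resampling statistics:
# logistic rise with block-specific learning trial, asymptote and offset
# (heterogeneous shapes, as real blocks are)
synthetic_curves <- function(n_blocks, n_trials = 30L, shift = 0,
                             shift_trials = integer(0)) {
  t <- seq_len(n_trials)
  m <- t(vapply(seq_len(n_blocks), function(i) {
    lt <- runif(1, 3, 25)
    asym <- runif(1, 0.7, 0.95)
    off <- rnorm(1, 0, 0.08)
    p <- 0.5 + (asym - 0.5) / (1 + exp(-(t - lt))) + off
    pmin(pmax(p, 0.01), 0.99)
  }, numeric(n_trials)))
  if (length(shift_trials)) {
    m[, shift_trials] <- pmin(m[, shift_trials] + shift, 0.99)
  }
  m
}

# learning-trial table built directly (session structure without curve fits)
synthetic_lt_table <- function(n_sessions, blocks_per_session, condition,
                               lt_fun) {
  rows <- list()
  for (s in seq_len(n_sessions)) {
    for (b in seq_len(blocks_per_session)) {
      rows[[length(rows) + 1]] <- data.frame(
        session_id = sprintf("%s_%02d", condition, s),
        condition = condition, block_index = b,
        learning_trial = lt_fun(s, b), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
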