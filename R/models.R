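#' @useDynLib revlearn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optim runif rbinom rnorm quantile qnorm sd cor setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Feature-value combination (FVC) indexing used throughout:
#   1 = L, 2 = R (location); 3 = up, 4 = down (motion); 5 = color1, 6 = color2.
# Dimensions: location = {1,2}, motion = {3,4}, color = {5,6}.
FVC_NAMES <- c("L", "R", "U", "D", "color1", "color2")
DIM_INDEX <- list(location = 1:2, motion = 3:4, color = 5:6)

#' Names of the eight learning models
#'
#' Model registry keys, in the canonical order: three feature-value
#' reinforcement-learning (RL) variants, the Bayesian integrator, and four
#' hybrid Bayesian feature-weighting RL variants.
#'
#' @return Character vector of length 8.
#' @export
model_names <- function() {
  c("FV", "FV+Decay", "FV+2Eta", "BI",
    "FW", "FW+ChoiceHistory", "FW+2Eta", "FW+Decay")
}

# free parameters per model, in the order the fitter uses
MODEL_PARAMS <- list(
  "FV"               = c("eta", "beta"),
  "FV+Decay"         = c("eta", "beta", "omega"),
  "FV+2Eta"          = c("eta1", "eta0", "beta"),
  "BI"               = c("beta"),
  "FW"               = c("eta", "beta", "alpha"),
  "FW+ChoiceHistory" = c("eta", "beta", "alpha", "gamma"),
  "FW+2Eta"          = c("eta1", "eta0", "beta", "alpha"),
  "FW+Decay"         = c("eta", "beta", "alpha", "omega")
)

# reward-emission probability assumed by the Bayesian models (not the task)
P_REWARD_MODEL <- 0.99

#' Model specification
#'
#' Looks up one of the eight learning models and returns its specification:
#' the free-parameter names (defining `k` for AIC), and whether the model
#' carries a Bayesian belief state and/or a feature-value table.
#'
#' @param name One of [model_names()].
#' @return A list with elements `name`, `params`, `k`, `has_belief`,
#'   `has_values`, `p_r`.
#' @export
model_spec <- function(name) {
  if (!name %in% names(MODEL_PARAMS)) {
    stop("unknown model name: ", name,
         " (expected one of: ", paste(model_names(), collapse = ", "), ")")
  }
  pars <- MODEL_PARAMS[[name]]
  list(
    name = name,
    params = pars,
    k = length(pars),
    has_belief = name %in% c("BI", "FW", "FW+ChoiceHistory", "FW+2Eta", "FW+Decay"),
    has_values = name != "BI",
    p_r = P_REWARD_MODEL
  )
}

#' Validate a parameter vector for a model
#'
#' Checks that all free parameters of `model` are present, finite and within
#' their admissible ranges (learning rates non-negative, `omega >= 1`,
#' `gamma` in `[0, 1]`).
#'
#' @param model Model name.
#' @param params Named numeric vector or list.
#' @return The parameter vector as a named numeric vector, invisibly usable.
#' @export
check_params <- function(model, params) {
  spec <- model_spec(model)
  params <- unlist(params)
  missing <- setdiff(spec$params, names(params))
  if (length(missing)) {
    stop("missing parameter(s) for model ", model, ": ",
         paste(missing, collapse = ", "))
  }
  p <- params[spec$params]
  if (any(!is.finite(p))) stop("non-finite parameter value")
  for (nm in intersect(c("eta", "eta0", "eta1", "beta", "alpha"), spec$params)) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  }
  if ("omega" %in% spec$params && p[["omega"]] < 1) stop("omega must be >= 1")
  if ("gamma" %in% spec$params &&
      (p[["gamma"]] < 0 || p[["gamma"]] > 1)) stop("gamma must be in [0, 1]")
  p
}

#' Initial model state
#'
#' Feature values start at 0.5 for all six feature-value combinations; the
#' Bayesian posterior over candidate targets starts uniform (1/6). State is
#' created once per session: values carry over across the un-cued reversals
#' within a session, the belief is reset only at session start.
#'
#' @param model Model name.
#' @return List with `V` (length-6 feature values), `belief` (length-6
#'   posterior), and `prev_color` (last chosen color, `NA` before the first
#'   completed choice).
#' @export
init_state <- function(model) {
  spec <- model_spec(model)
  list(
    V = if (spec$has_values) rep(0.5, 6) else NULL,
    belief = if (spec$has_belief) rep(1 / 6, 6) else NULL,
    prev_color = NA_integer_
  )
}

#' Feature-value combinations of the two stimuli
#'
#' @param left_color 1 or 2, the color carried by the left stimulus.
#' @param left_motion "up" or "down", the motion of the left stimulus.
#' @return List with integer index triples `left` and `right` into the FVC
#'   table (location, motion, color). The right stimulus always carries the
#'   complementary color and motion.
#' @export
stimulus_features <- function(left_color, left_motion) {
  stopifnot(left_color %in% c(1L, 2L), left_motion %in% c("up", "down"))
  lm <- if (left_motion == "up") 3L else 4L
  lc <- if (left_color == 1L) 5L else 6L
  list(
    left = c(1L, lm, lc),
    right = c(2L, if (lm == 3L) 4L else 3L, if (lc == 5L) 6L else 5L)
  )
}

#' Delta-rule value update
#'
#' Classical prediction-error learning applied to each feature-value
#' combination of the chosen stimulus: `V_i <- V_i + eta * (R - V_i)`. With
#' `eta = 1` the value is set to the reward; beyond `eta = 2` repeated
#' updates are unstable.
#'
#' @param values Length-6 feature-value table.
#' @param chosen Integer indices (the chosen stimulus' three FVCs).
#' @param reward 0 or 1.
#' @param eta Learning rate, `>= 0`.
#' @return Updated value table; unchosen entries untouched.
#' @export
delta_update <- function(values, chosen, reward, eta) {
  if (eta < 0) stop("eta must be >= 0")
  values[chosen] <- values[chosen] + eta * (reward - values[chosen])
  values
}

#' Divisive decay of unchosen feature values
#'
#' Values of the feature-value combinations belonging to the non-chosen
#' stimulus shrink by the decay constant: `V_i <- V_i / omega`. `omega = 1`
#' is the identity; larger `omega` means stronger decay.
#'
#' @param values Length-6 feature-value table.
#' @param unchosen Integer indices of the non-chosen stimulus' FVCs.
#' @param omega Decay constant, `>= 1`.
#' @return Updated value table.
#' @export
decay_update <- function(values, unchosen, omega) {
  if (omega < 1) stop("omega must be >= 1")
  values[unchosen] <- values[unchosen] / omega
  values
}

#' Delta rule with outcome-dependent learning rates
#'
#' Applies the delta rule with rate `eta1` after rewarded choices and `eta0`
#' after unrewarded ones.
#'
#' @inheritParams delta_update
#' @param eta1,eta0 Learning rates for rewarded / unrewarded outcomes.
#' @return Updated value table.
#' @export
two_eta_update <- function(values, chosen, reward, eta1, eta0) {
  if (eta1 < 0 || eta0 < 0) stop("learning rates must be >= 0")
  delta_update(values, chosen, reward, if (reward == 1) eta1 else eta0)
}

#' Softmax (Boltzmann) choice probabilities
#'
#' `P_j` proportional to `exp(beta * V_j)` over the two stimuli, computed
#' with max-subtraction so that large `beta * V` cannot overflow.
#'
#' @param value_left,value_right Stimulus values.
#' @param beta Inverse-noise parameter, `>= 0`; `beta = 0` gives (0.5, 0.5).
#' @return Numeric pair `(P_left, P_right)` summing to 1.
#' @export
softmax_choice <- function(value_left, value_right, beta) {
  z <- beta * c(value_left, value_right)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Bayesian posterior update over candidate targets
#'
#' Multiplies the posterior over the six candidate target features by the
#' outcome likelihood: candidates contained in the chosen stimulus get
#' `p_r * R + (1 - p_r) * (1 - R)`; the others get `p_n * R + (1 - p_n) * (1 - R)`
#' with `p_n = 1 - p_r`; the result is renormalized.
#'
#' @param belief Length-6 posterior (non-negative, sums to 1).
#' @param chosen Indices of the chosen stimulus' three FVCs.
#' @param reward 0 or 1.
#' @param p_r Model-assumed reward probability for the true target
#'   (default 0.99).
#' @return Updated, normalized posterior.
#' @export
bayes_update <- function(belief, chosen, reward, p_r = P_REWARD_MODEL) {
  p_n <- 1 - p_r
  lik <- rep(p_n * reward + (1 - p_n) * (1 - reward), 6)
  lik[chosen] <- p_r * reward + (1 - p_r) * (1 - reward)
  post <- belief * lik
  post / sum(post)
}

#' Predicted reward probability of each stimulus under the belief
#'
#' The Bayesian integrator values a stimulus by the posterior-predictive
#' probability of reward when choosing it:
#' `P(R = 1 | choose j) = sum_f p(R = 1 | j, f) p(f)`. With `p_n = 1 - p_r`
#' the two sides' values sum to 1.
#'
#' @param belief Length-6 posterior.
#' @param left,right Index triples of the two stimuli.
#' @inheritParams bayes_update
#' @return Numeric pair of predicted reward probabilities.
#' @export
bi_choice_value <- function(belief, left, right, p_r = P_REWARD_MODEL) {
  p_n <- 1 - p_r
  m_left <- sum(belief[left])
  m_right <- sum(belief[right])
  c(p_r * m_left + p_n * (1 - m_left),
    p_r * m_right + p_n * (1 - m_right))
}

#' Feature-dimension attention weights
#'
#' The posterior mass that the target lies in dimension `d` is
#' `g_d = sum of p(f)` over that dimension's two feature values; weights are
#' `w_d = g_d^alpha / sum_d' g_d'^alpha`. `alpha = 0` gives uniform weights;
#' large `alpha` concentrates weight on the most probable dimension.
#'
#' @param belief Length-6 posterior.
#' @param alpha Weighting exponent, `>= 0`.
#' @return Numeric weights `(location, motion, color)` summing to 1.
#' @export
dimension_weights <- function(belief, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  g <- c(belief[1] + belief[2], belief[3] + belief[4], belief[5] + belief[6])
  ga <- g^alpha
  ga / sum(ga)
}

#' Dimension-weighted stimulus value
#'
#' `V_stim = sum_d w_d * V(f_d)` over the stimulus' feature value in each of
#' the three dimensions.
#'
#' @param values Length-6 feature-value table.
#' @param weights Length-3 dimension weights (location, motion, color).
#' @param features Index triple of the stimulus, ordered
#'   (location, motion, color).
#' @return Scalar stimulus value.
#' @export
fw_stimulus_value <- function(values, weights, features) {
  sum(weights * values[features])
}

#' Object-level prediction-error update for feature-weighting models
#'
#' All chosen feature values move by the same prediction error computed at
#' the object level: `V_i <- V_i + eta * (R - V_stim_chosen)`, where
#' `V_stim_chosen` is the dimension-weighted value of the chosen stimulus on
#' the same trial.
#'
#' @inheritParams delta_update
#' @param v_stim_chosen The chosen stimulus' weighted value before update.
#' @return Updated value table.
#' @export
fw_update <- function(values, chosen, v_stim_chosen, reward, eta) {
  if (eta < 0) stop("eta must be >= 0")
  values[chosen] <- values[chosen] + eta * (reward - v_stim_chosen)
  values
}

#' Choice-history (color-perseveration) filter on choice probabilities
#'
#' A provisional softmax choice is accepted outright when it repeats the
#' previously chosen color; otherwise it is accepted with probability
#' `gamma` and else switched to the color-matching stimulus. Marginally the
#' color-matching side gains the rejected mass:
#' `P_final(match) = P_match + (1 - gamma) * P_other`,
#' `P_final(other) = gamma * P_other`. With no previous choice the filter is
#' the identity, as it is at `gamma = 1`; `gamma = 0` always repeats the
#' previous color.
#'
#' @param probs Numeric pair of provisional (left, right) probabilities.
#' @param match_side 1 if the left stimulus carries the previously chosen
#'   color, 2 if the right one does, `NA` for no previous choice.
#' @param gamma Acceptance probability in `[0, 1]`.
#' @return Adjusted probability pair summing to 1.
#' @export
choice_history_filter <- function(probs, match_side, gamma) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (is.na(match_side)) return(probs)
  other <- 3L - match_side
  out <- numeric(2)
  out[match_side] <- probs[match_side] + (1 - gamma) * probs[other]
  out[other] <- gamma * probs[other]
  out
}

# choice probabilities (left, right) for any model given current state
model_choice_probs <- function(model, params, state, feats) {
  switch(model,
    "FV" = , "FV+Decay" = , "FV+2Eta" = {
      softmax_choice(sum(state$V[feats$left]), sum(state$V[feats$right]),
                     params[["beta"]])
    },
    "BI" = {
      v <- bi_choice_value(state$belief, feats$left, feats$right)
      softmax_choice(v[1], v[2], params[["beta"]])
    },
    {
      w <- dimension_weights(state$belief, params[["alpha"]])
      vl <- fw_stimulus_value(state$V, w, feats$left)
      vr <- fw_stimulus_value(state$V, w, feats$right)
      p <- softmax_choice(vl, vr, params[["beta"]])
      if (model == "FW+ChoiceHistory" && !is.na(state$prev_color)) {
        colors <- c(feats$left[3], feats$right[3])
        match_side <- which(colors == state$prev_color)
        p <- choice_history_filter(p, match_side, params[["gamma"]])
      }
      p
    }
  )
}

# state transition after observing (choice, reward); choice is 1 or 2
model_update_state <- function(model, params, state, feats, choice, reward) {
  chosen <- if (choice == 1L) feats$left else feats$right
  unchosen <- if (choice == 1L) feats$right else feats$left
  switch(model,
    "FV" = {
      state$V <- delta_update(state$V, chosen, reward, params[["eta"]])
    },
    "FV+Decay" = {
      state$V <- delta_update(state$V, chosen, reward, params[["eta"]])
      state$V <- decay_update(state$V, unchosen, params[["omega"]])
    },
    "FV+2Eta" = {
      state$V <- two_eta_update(state$V, chosen, reward,
                                params[["eta1"]], params[["eta0"]])
    },
    "BI" = {
      state$belief <- bayes_update(state$belief, chosen, reward)
    },
    {
      # hybrid feature-weighting models: object-level PE + Bayes update
      w <- dimension_weights(state$belief, params[["alpha"]])
      v_stim <- fw_stimulus_value(state$V, w, chosen)
      eta <- switch(model,
        "FW+2Eta" = if (reward == 1) params[["eta1"]] else params[["eta0"]],
        params[["eta"]]
      )
      state$V <- fw_update(state$V, chosen, v_stim, reward, eta)
      if (model == "FW+Decay") {
        state$V <- decay_update(state$V, unchosen, params[["omega"]])
      }
      state$belief <- bayes_update(state$belief, chosen, reward)
    }
  )
  state$prev_color <- chosen[3]
  state
}

#' Log-likelihood increment for one trial
#'
#' Scores the observed choice under the model's current state (choice
#' probability computed first), then applies the model's value/belief
#' updates using the observed outcome. Trials without a completed choice
#' contribute zero and leave the state unchanged.
#'
#' @param model Model name.
#' @param params Named parameter vector (see [check_params()]).
#' @param state Model state from [init_state()] or a previous call.
#' @param trial One-row data.frame (or list) with `left_color`,
#'   `left_motion`, `choice` ("left"/"right"/"none"), `reward`.
#' @param floor Per-trial likelihood floor applied before the log
#'   (default `1e-12`) so the log-likelihood stays finite.
#' @return List with `loglik` (scalar) and `state` (updated).
#' @export
trial_loglik <- function(model, params, state, trial, floor = 1e-12) {
  if (trial$choice == "none") return(list(loglik = 0, state = state))
  feats <- stimulus_features(trial$left_color, trial$left_motion)
  p <- model_choice_probs(model, params, state, feats)
  side <- if (trial$choice == "left") 1L else 2L
  ll <- log(max(p[side], floor))
  state <- model_update_state(model, params, state, feats, side, trial$reward)
  list(loglik = ll, state = state)
}

#' Session log-likelihood (reference R implementation)
#'
#' Sums [trial_loglik()] over a trial table, re-initializing the model state
#' at each new `session_id`. This is the slow reference path; the fitter
#' uses a compiled equivalent ([session_nll()]) that must agree with it.
#'
#' @inheritParams trial_loglik
#' @param trials Trial table as produced by [generate_session()] or
#'   [read_trials()].
#' @return Total log-likelihood (scalar).
#' @export
session_loglik_r <- function(model, params, trials, floor = 1e-12) {
  params <- check_params(model, params)
  total <- 0
  state <- NULL
  cur_session <- NULL
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (is.null(cur_session) || tr$session_id != cur_session) {
      state <- init_state(model)
      cur_session <- tr$session_id
    }
    res <- trial_loglik(model, params, state, tr, floor)
    total <- total + res$loglik
    state <- res$state
  }
  total
}

#' Pack a trial table for the compiled likelihood
#'
#' Converts a trial table into the integer representation consumed by the
#' compiled likelihood and simulation routines.
#'
#' @param trials Trial table.
#' @return List of integer vectors (`session`, `left_color`, `left_motion`,
#'   `choice`, `reward`).
#' @keywords internal
pack_trials <- function(trials) {
  list(
    session = as.integer(factor(trials$session_id,
                                levels = unique(trials$session_id))),
    left_color = as.integer(trials$left_color),
    left_motion = as.integer(trials$left_motion == "up"),
    choice = ifelse(trials$choice == "none", 0L,
                    ifelse(trials$choice == "left", 1L, 2L)),
    reward = as.integer(trials$reward)
  )
}

#' Session negative log-likelihood (compiled)
#'
#' Fast path used by the optimizer: identical model equations to
#' [session_loglik_r()], implemented in C++. State is re-initialized at each
#' session boundary.
#'
#' @inheritParams session_loglik_r
#' @param packed Optional pre-packed trials from [pack_trials()]; supply it
#'   when calling repeatedly on the same data.
#' @return The negative log-likelihood (scalar).
#' @export
session_nll <- function(model, params, trials, packed = NULL,
                        floor = 1e-12) {
  params <- check_params(model, params)
  if (is.null(packed)) packed <- pack_trials(trials)
  model_id <- match(model, model_names()) - 1L
  cpp_session_nll(model_id, as.numeric(params[MODEL_PARAMS[[model]]]),
                  packed$session, packed$left_color, packed$left_motion,
                  packed$choice, packed$reward, P_REWARD_MODEL, floor)
}

#' Per-trial model probability of the rewarded-color choice
#'
#' Runs a model through observed trials (same state dynamics as the
#' likelihood) and returns, for each completed trial, the probability the
#' model assigns to choosing the stimulus carrying the currently rewarded
#' color. Used for model-versus-behavior comparison curves.
#'
#' @inheritParams session_loglik_r
#' @return Numeric vector, one entry per row of `trials` (`NA` for
#'   non-choice trials).
#' @export
model_correct_prob <- function(model, params, trials) {
  params <- check_params(model, params)
  packed <- pack_trials(trials)
  model_id <- match(model, model_names()) - 1L
  p <- cpp_correct_prob(model_id, as.numeric(params[MODEL_PARAMS[[model]]]),
                        packed$session, packed$left_color,
                        packed$left_motion, packed$choice, packed$reward,
                        as.integer(trials$rewarded_color), P_REWARD_MODEL)
  p[packed$choice == 0L] <- NA_real_
  p
}
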