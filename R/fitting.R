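# Optimization bounds. Learning rates are capped at 2 (the delta rule is
# unstable beyond that), beta at 20 (effectively deterministic choice),
# omega at 3 (strong decay), alpha at 5 (near winner-take-all weighting).
PARAM_BOUNDS <- list(
  eta   = c(0, 2), eta1 = c(0, 2), eta0 = c(0, 2),
  beta  = c(0, 20),
  omega = c(1, 3),
  alpha = c(0, 5),
  gamma = c(0, 1)
)

param_bounds <- function(model) {
  pars <- MODEL_PARAMS[[model_spec(model)$name]]
  lower <- vapply(pars, function(p) PARAM_BOUNDS[[p]][1], numeric(1))
  upper <- vapply(pars, function(p) PARAM_BOUNDS[[p]][2], numeric(1))
  list(par = pars, lower = lower, upper = upper)
}

#' Fit a learning model by maximum likelihood
#'
#' Minimizes the negative log-likelihood of the observed choices with a
#' two-stage multi-start scheme: from each of `n_starts` random points
#' (uniform within the parameter bounds) a short Nelder-Mead simplex
#' warm-up (at most `simplex_iter` iterations) is followed by a bounded
#' quasi-Newton (`L-BFGS-B`) refinement; the best incumbent across starts
#' is returned. One-parameter models use Brent's method directly.
#'
#' @param model One of [model_names()].
#' @param trials Trial table with at least one block of completed choices.
#' @param n_starts Number of random starts (default 5).
#' @param simplex_iter Simplex warm-up iteration cap (default 20).
#' @param seed Optional integer seed for the start draws.
#' @return A `model_fit` list: `model`, `params` (named best-fit vector),
#'   `nll`, `aic` (`2k + 2 nll`), `k`, `n_trials` (completed choices
#'   scored), `converged`, and `starts` (per-start NLLs).
#' @export
fit_model <- function(model, trials, n_starts = 5L, simplex_iter = 20L,
                      seed = NULL) {
  spec <- model_spec(model)
  if (nrow(trials) == 0) stop("empty trial set")
  packed <- pack_trials(trials)
  n_choice <- sum(packed$choice != 0L)
  if (n_choice == 0) stop("no completed choices to fit")
  if (!is.null(seed)) set.seed(seed)

  b <- param_bounds(model)
  k <- length(b$par)
  fn <- function(x) {
    if (any(x < b$lower) || any(x > b$upper)) {
      return(1e10 + sum(pmax(b$lower - x, 0) + pmax(x - b$upper, 0)) * 1e6)
    }
    cpp_session_nll(match(model, model_names()) - 1L, x,
                    packed$session, packed$left_color, packed$left_motion,
                    packed$choice, packed$reward, P_REWARD_MODEL, 1e-12)
  }

  best <- NULL
  start_nll <- numeric(n_starts)
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    x0 <- runif(k, b$lower, b$upper)
    if (k == 1L) {
      opt <- optim(x0, fn, method = "Brent",
                   lower = b$lower, upper = b$upper)
      conv <- opt$convergence == 0
    } else {
      warm <- optim(x0, fn, method = "Nelder-Mead",
                    control = list(maxit = simplex_iter, warn.1d.NelderMead = FALSE))
      x1 <- pmin(pmax(warm$par, b$lower), b$upper)
      opt <- optim(x1, fn, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 200))
      conv <- opt$convergence == 0
    }
    start_nll[s] <- opt$value
    any_conv <- any_conv || conv
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$converged <- conv
    }
  }
  if (!any_conv) warning("optimizer did not converge at any start; ",
                         "returning best incumbent")

  params <- setNames(best$par, b$par)
  nll <- best$value
  structure(list(
    model = model, params = params, nll = nll,
    aic = 2 * k + 2 * nll, k = k, n_trials = n_choice,
    converged = best$converged, starts = start_nll
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Model %s: NLL = %.2f, AIC = %.2f (k = %d, %d choices)\n",
              x$model, x$nll, x$aic, x$k, x$n_trials))
  print(round(x$params, 4))
  invisible(x)
}

# blocks as the sampling unit: unique (session_id, block_index) pairs
block_ids <- function(trials) {
  unique(paste(trials$session_id, trials$block_index, sep = "\r"))
}

subset_blocks <- function(trials, ids) {
  key <- paste(trials$session_id, trials$block_index, sep = "\r")
  trials[key %in% ids, , drop = FALSE]
}

#' Block-level cross-validation of a learning model
#'
#' Repeats `n_reps` times: draw a random `split` fraction of reversal
#' blocks (the exchangeable unit, not trials) as training set, fit the
#' model on it, and evaluate the log-likelihood of the held-out blocks at
#' the training optimum. Within a subset, model state still resets only at
#' session boundaries; omitted blocks are simply skipped in the sequence.
#'
#' @inheritParams fit_model
#' @param n_reps Number of train/test replicates (default 100).
#' @param split Training fraction of blocks (default 0.8).
#' @param seed Integer seed governing both the splits and the fit starts.
#' @return A `model_cv` list: `model`, `k`, `train_ll` and `test_ll`
#'   (length `n_reps`, log-likelihoods, sign convention: larger is better),
#'   `params` (`n_reps` x `k` matrix of per-replicate training optima),
#'   `n_train_trials`, `n_test_trials`.
#' @export
cross_validate <- function(model, trials, n_reps = 100L, split = 0.8,
                           n_starts = 5L, seed = NULL) {
  ids <- block_ids(trials)
  if (length(ids) < 5) stop("need at least 5 blocks for cross-validation")
  if (!is.null(seed)) set.seed(seed)
  spec <- model_spec(model)
  k <- spec$k
  n_train <- max(1L, round(split * length(ids)))
  train_ll <- test_ll <- numeric(n_reps)
  n_train_tr <- n_test_tr <- integer(n_reps)
  params <- matrix(NA_real_, n_reps, k,
                   dimnames = list(NULL, MODEL_PARAMS[[model]]))
  for (r in seq_len(n_reps)) {
    tr_ids <- sample(ids, n_train)
    train <- subset_blocks(trials, tr_ids)
    test <- subset_blocks(trials, setdiff(ids, tr_ids))
    fit <- fit_model(model, train, n_starts = n_starts)
    params[r, ] <- fit$params
    train_ll[r] <- -fit$nll
    test_ll[r] <- -session_nll(model, fit$params, test)
    n_train_tr[r] <- sum(train$choice != "none")
    n_test_tr[r] <- sum(test$choice != "none")
  }
  structure(list(
    model = model, k = k, train_ll = train_ll, test_ll = test_ll,
    params = params, n_train_trials = n_train_tr,
    n_test_trials = n_test_tr
  ), class = "model_cv")
}

#' Compare fitted models
#'
#' @param fits A list of `model_fit` objects (from [fit_model()]) for the
#'   same trial table; optionally a parallel list of `model_cv` objects.
#' @param cv Optional list of `model_cv` results in the same order.
#' @return A data.frame ranked by AIC (winner first) with columns `model`,
#'   `k`, `nll`, `aic`, and mean train/test log-likelihood when `cv` is
#'   given.
#' @export
compare_models <- function(fits, cv = NULL) {
  n_tr <- vapply(fits, function(f) f$n_trials, integer(1))
  if (length(unique(n_tr)) != 1) {
    stop("fits were not computed on identical data (choice counts differ)")
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f$model, character(1)),
    k = vapply(fits, function(f) f$k, integer(1)),
    nll = vapply(fits, function(f) f$nll, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(cv)) {
    tab$mean_train_ll <- vapply(cv, function(x) mean(x$train_ll), numeric(1))
    tab$mean_test_ll <- vapply(cv, function(x) mean(x$test_ll), numeric(1))
  }
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  tab
}

#' Pairwise parameter correlations across cross-validation replicates
#'
#' Pearson correlations of the per-replicate training optima, the standard
#' summary of how parameters co-vary across block subsamples.
#'
#' @param params Numeric matrix (replicates x parameters), e.g. the
#'   `params` element of [cross_validate()] output.
#' @return A data.frame with one row per parameter pair: `par1`, `par2`,
#'   `r`, `n`, and `degenerate` (TRUE when a parameter was constant across
#'   replicates, where `r` is undefined and returned as `NA`).
#' @export
param_correlations <- function(params) {
  if (nrow(params) < 3) stop("need at least 3 replicates")
  nm <- colnames(params)
  const <- apply(params, 2, function(x) sd(x) == 0 || !is.finite(sd(x)))
  pairs <- utils::combn(seq_along(nm), 2)
  out <- data.frame(
    par1 = nm[pairs[1, ]], par2 = nm[pairs[2, ]],
    r = NA_real_, n = nrow(params),
    degenerate = const[pairs[1, ]] | const[pairs[2, ]],
    stringsAsFactors = FALSE
  )
  for (i in seq_len(ncol(pairs))) {
    if (!out$degenerate[i]) {
      out$r[i] <- cor(params[, pairs[1, i]], params[, pairs[2, i]])
    }
  }
  rownames(out) <- NULL
  out
}

#' Sum of squared deviations between model and observed learning curves
#'
#' Aligns trials on trials-since-reversal (1..`max_trial`), computes the
#' observed proportion of rewarded choices per position across blocks, and
#' the model's mean probability of choosing the rewarded-color stimulus at
#' the same positions (model state driven by the observed history), and
#' returns the sum of squared differences.
#'
#' @param model,params Fitted model specification.
#' @param trials Trial table.
#' @param max_trial Last trial-since-reversal position (default 30).
#' @return List with `ssd` and `curve` (data.frame: `trial`, `observed`,
#'   `model`, `n_blocks`).
#' @export
model_behavior_ssd <- function(model, params, trials, max_trial = 30L) {
  if (nrow(trials) == 0) stop("empty trial table")
  p_model <- model_correct_prob(model, params, trials)
  ok <- trials$choice != "none" & trials$trial_in_block <= max_trial
  pos <- trials$trial_in_block[ok]
  obs <- tapply(trials$reward[ok], pos, mean)
  mod <- tapply(p_model[ok], pos, mean)
  n_b <- tapply(trials$reward[ok], pos, length)
  tr <- as.integer(names(obs))
  curve <- data.frame(trial = tr, observed = as.numeric(obs),
                      model = as.numeric(mod), n_blocks = as.integer(n_b))
  list(ssd = sum((curve$observed - curve$model)^2), curve = curve)
}
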