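# State-space estimation of the trial-wise probability of a rewarded
# choice within a block (the Smith-Brown ideal-observer framework):
# a latent Gaussian random walk x_t = x_{t-1} + e_t, e_t ~ N(0, s2e),
# observed through Bernoulli outcomes with
# p_t = logistic(mu + x_t), mu = logit(chance). The boundary state has a
# fixed prior x_0 ~ N(0, s2_0) anchored at chance and is marginalized by
# the smoother; the state-noise variance s2e is estimated by EM.
#
# Inference runs on a discretized state grid (exact forward filter and
# backward smoother of the discretized model, compiled); the classical
# Gaussian-approximation filter/smoother below is retained as an
# independent reference implementation for cross-checks. The Gaussian
# approximation understates the information carried by long runs of
# correct trials (observation curvature p(1-p) vanishes as p -> 1), which
# inflates the smoothed variance there; the grid smoother does not.

logistic <- function(z) 1 / (1 + exp(-z))

# one forward-backward pass given (s2e, s2_0); returns smoothed
# means/variances (including the t = 0 boundary state) and the
# approximate observed-data log-likelihood (one-step-ahead predictive)
ss_filter_smooth <- function(outcomes, mu, s2e, s2_0) {
  T_ <- length(outcomes)
  x_f <- s_f <- x_p <- s_p <- numeric(T_)
  ll <- 0
  x_prev <- 0
  s_prev <- s2_0  # prior variance of the boundary state
  for (t in seq_len(T_)) {
    xp <- x_prev
    sp <- s_prev + s2e
    # posterior mode by Newton iteration on
    #   x = xp + sp * (n_t - logistic(mu + x))
    x <- xp
    for (it in 1:50) {
      p <- logistic(mu + x)
      f <- x - xp - sp * (outcomes[t] - p)
      fp <- 1 + sp * p * (1 - p)
      step <- f / fp
      x <- x - step
      if (abs(step) < 1e-10) break
    }
    p <- logistic(mu + x)
    s <- 1 / (1 / sp + p * (1 - p))
    # one-step-ahead predictive likelihood of the outcome
    p_pred <- logistic(mu + xp)
    ll <- ll + outcomes[t] * log(max(p_pred, 1e-12)) +
      (1 - outcomes[t]) * log(max(1 - p_pred, 1e-12))
    x_p[t] <- xp; s_p[t] <- sp; x_f[t] <- x; s_f[t] <- s
    x_prev <- x; s_prev <- s
  }
  # fixed-interval (RTS) smoother
  x_s <- x_f; s_s <- s_f
  a <- numeric(T_)
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      a[t] <- s_f[t] / s_p[t + 1]
      x_s[t] <- x_f[t] + a[t] * (x_s[t + 1] - x_p[t + 1])
      s_s[t] <- s_f[t] + a[t]^2 * (s_s[t + 1] - s_p[t + 1])
    }
  }
  # boundary state smoothing (t = 0)
  a0 <- s2_0 / s_p[1]
  x0_s <- a0 * (x_s[1] - x_p[1])
  s0_s <- s2_0 + a0^2 * (s_s[1] - s_p[1])
  # lag-one smoothed covariances cov(x_t, x_{t-1} | data), t = 1 uses x_0
  cov1 <- numeric(T_)
  cov1[1] <- a0 * s_s[1]
  if (T_ > 1) for (t in 2:T_) cov1[t] <- a[t - 1] * s_s[t]
  list(x = x_s, s = s_s, cov1 = cov1, x0 = x0_s, s0 = s0_s, loglik = ll)
}

#' Fit a state-space learning curve to a block of binary outcomes
#'
#' Estimates the trial-wise probability of a rewarded choice from a binary
#' outcome sequence with a latent Gaussian random walk observed through a
#' Bernoulli likelihood. The state-noise variance is estimated by EM; the
#' curve and its confidence bounds are mapped through the logistic link
#' anchored at the chance level.
#'
#' @param outcomes Binary vector (1 = rewarded choice), length `>= 5`.
#' @param chance Chance probability of a rewarded choice (default 0.5 for
#'   the two-alternative task).
#' @param level Confidence level of the bounds (default 0.95).
#' @param max_iter EM iteration cap (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param prior_var Prior variance of the boundary state on the logit
#'   scale (default 1): the curve starts as a weakly informative
#'   distribution centered on chance, and its estimation uncertainty is
#'   carried into the confidence bounds.
#' @return A `learning_curve` list: `pmode`, `lower`, `upper` (per-trial
#'   probability estimate and bounds), `learning_trial` (see
#'   [learning_trial()]), `chance`, `level`, `sigma2e`, `loglik` (per EM
#'   iteration), `n_iter`, `converged`.
#' @export
fit_learning_curve <- function(outcomes, chance = 0.5, level = 0.95,
                               max_iter = 500L, tol = 1e-6,
                               prior_var = 1) {
  outcomes <- as.numeric(outcomes)
  if (length(outcomes) < 5) stop("need at least 5 trials")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary")
  if (chance <= 0 || chance >= 1) stop("chance must be in (0, 1)")
  mu <- log(chance / (1 - chance))
  res <- cpp_ss_curve(as.integer(outcomes), mu, level,
                      0.005, prior_var, as.integer(max_iter), tol,
                      -8, 8, 161L)
  curve <- structure(list(
    pmode = as.numeric(res$pmode), lower = as.numeric(res$lower),
    upper = as.numeric(res$upper),
    learning_trial = NA_integer_, chance = chance, level = level,
    sigma2e = res$sigma2e, loglik = as.numeric(res$loglik),
    n_iter = length(res$loglik), converged = res$converged
  ), class = "learning_curve")
  curve$learning_trial <- learning_trial(curve)
  curve
}

# Gaussian-approximation EM (reference implementation, not exported):
# same model, classical approximate filter/smoother
fit_learning_curve_gauss <- function(outcomes, chance = 0.5, level = 0.95,
                                     max_iter = 500L, tol = 1e-6,
                                     prior_var = 1) {
  mu <- log(chance / (1 - chance))
  T_ <- length(outcomes)
  s2e <- 0.005
  ll_trace <- numeric(0)
  fs <- NULL
  for (iter in seq_len(max_iter)) {
    fs <- ss_filter_smooth(outcomes, mu, s2e, prior_var)
    ll_trace <- c(ll_trace, fs$loglik)
    d <- diff(c(fs$x0, fs$x))
    ev <- fs$s + c(fs$s0, fs$s[-T_]) - 2 * fs$cov1
    s2e_new <- max(sum(d^2 + ev) / T_, 1e-8)
    if (iter > 1) {
      rel <- abs(ll_trace[iter] - ll_trace[iter - 1]) /
        max(abs(ll_trace[iter - 1]), 1e-12)
      if (rel < tol) { s2e <- s2e_new; break }
    }
    s2e <- s2e_new
  }
  z <- -qnorm((1 - level) / 2)
  list(pmode = logistic(mu + fs$x),
       lower = logistic(mu + fs$x - z * sqrt(fs$s)),
       upper = logistic(mu + fs$x + z * sqrt(fs$s)),
       sigma2e = s2e, loglik = ll_trace)
}

#' Learning trial of a fitted curve
#'
#' The first trial from which the lower confidence bound of the
#' probability-correct estimate exceeds chance for all remaining trials of
#' the block; `NA` when the bound never stays above chance.
#'
#' @param curve A `learning_curve` from [fit_learning_curve()].
#' @return Integer trial index or `NA`.
#' @export
learning_trial <- function(curve) {
  above <- curve$lower > curve$chance
  if (!any(above)) return(NA_integer_)
  # last run of TRUEs must extend to the end of the block
  n <- length(above)
  if (!above[n]) return(NA_integer_)
  first <- n
  while (first > 1 && above[first - 1]) first <- first - 1
  as.integer(first)
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf(
    "learning_curve: %d trials, learning trial %s, sigma2e = %.4g (%s)\n",
    length(x$pmode),
    ifelse(is.na(x$learning_trial), "none", x$learning_trial),
    x$sigma2e, if (x$converged) "EM converged" else "EM not converged"))
  invisible(x)
}

#' Learning-curve table for every block of a trial table
#'
#' Fits [fit_learning_curve()] to the completed-choice outcome sequence of
#' each (session, block) and extracts the learning trial.
#'
#' @param trials Trial table.
#' @param level Confidence level for the detection rule.
#' @param min_trials Blocks with fewer completed choices are skipped.
#' @return A data.frame: `session_id`, `condition`, `block_index`,
#'   `n_choices`, `learning_trial` (NA when no learning was detected),
#'   plus a `curves` attribute (list of `learning_curve` objects keyed by
#'   `session_id.block_index`).
#' @export
learning_trials_table <- function(trials, level = 0.95, min_trials = 5L) {
  done <- trials[trials$choice != "none", ]
  key <- paste(done$session_id, done$block_index, sep = ".")
  keys <- unique(key)
  rows <- vector("list", length(keys))
  curves <- vector("list", length(keys))
  names(curves) <- keys
  for (i in seq_along(keys)) {
    blk <- done[key == keys[i], ]
    lt <- NA_integer_
    if (nrow(blk) >= min_trials) {
      cv <- fit_learning_curve(blk$reward, chance = 0.5, level = level)
      curves[[i]] <- cv
      lt <- cv$learning_trial
    }
    rows[[i]] <- data.frame(
      session_id = blk$session_id[1], condition = blk$condition[1],
      block_index = blk$block_index[1], n_choices = nrow(blk),
      learning_trial = lt, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}

#' Distribution of learning trials per condition
#'
#' Blocks without a detected learning trial are excluded (statistics are
#' over blocks that showed learning).
#'
#' @param lt_table Output of [learning_trials_table()] (or any data.frame
#'   with `condition` and `learning_trial` columns).
#' @param fast_cut Upper bound of "fast" learning in trials (default 10).
#' @return A data.frame per condition: `condition`, `n_blocks` (learned),
#'   `median_learning_trial`, `prop_fast` (learning within `fast_cut`
#'   trials), plus a `histograms` attribute (list of trial-count tables).
#' @export
learning_trial_distribution <- function(lt_table, fast_cut = 10L) {
  learned <- lt_table[!is.na(lt_table$learning_trial), ]
  if (nrow(learned) == 0) stop("no blocks with a detected learning trial")
  conds <- unique(learned$condition)
  hist_list <- list()
  rows <- lapply(conds, function(cd) {
    lt <- learned$learning_trial[learned$condition == cd]
    hist_list[[cd]] <<- table(lt)
    data.frame(condition = cd, n_blocks = length(lt),
               median_learning_trial = median(lt),
               prop_fast = mean(lt <= fast_cut),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histograms") <- hist_list
  out
}

#' Export a learning curve as TSV
#'
#' @param curve A `learning_curve`.
#' @param path Output path.
#' @return `path`, invisibly. Columns: `trial`, `mode`, `lo`, `hi`.
#' @export
write_learning_curve <- function(curve, path) {
  df <- data.frame(trial = seq_along(curve$pmode), mode = curve$pmode,
                   lo = curve$lower, hi = curve$upper)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
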