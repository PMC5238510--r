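# Resampling statistics for trial-aligned condition differences plus
# descriptive performance metrics.

#' Trial-aligned probability-correct curves, one row per block
#'
#' Builds the blocks x trials matrix consumed by
#' [trialwise_permutation_test()]: for each block, the state-space
#' probability-correct estimate ([fit_learning_curve()]) at trial positions
#' 1..`max_trial` since the reversal (NA beyond the block length).
#'
#' @param trials Trial table.
#' @param max_trial Number of aligned positions (default 30).
#' @param level Confidence level passed to the curve fit.
#' @return List with `curves` (numeric matrix, blocks x `max_trial`) and
#'   `labels` (condition per block).
#' @export
trial_aligned_curves <- function(trials, max_trial = 30L, level = 0.95) {
  done <- trials[trials$choice != "none", ]
  key <- paste(done$session_id, done$block_index, sep = ".")
  keys <- unique(key)
  curves <- matrix(NA_real_, length(keys), max_trial)
  labels <- character(length(keys))
  for (i in seq_along(keys)) {
    blk <- done[key == keys[i], ]
    labels[i] <- blk$condition[1]
    if (nrow(blk) < 5) next
    cv <- fit_learning_curve(blk$reward, level = level)
    n <- min(length(cv$pmode), max_trial)
    curves[i, seq_len(n)] <- cv$pmode[seq_len(n)]
  }
  list(curves = curves, labels = labels)
}

#' Trial-wise permutation test with pooled-null familywise correction
#'
#' Tests, for each trial position since reversal, whether the median
#' probability of a rewarded choice differs between two conditions. The
#' observed statistic is the per-trial difference of condition medians
#' across blocks. The null is built by `n_perm` random reassignments of
#' the block condition labels; the per-trial null differences are pooled
#' across all trial positions into a single distribution whose `level`
#' quantile is the familywise threshold (one threshold for all trials, so
#' no further multiple-comparison correction is needed). Observed
#' differences exceeding the threshold are flagged at familywise
#' p < 1 - `level`.
#'
#' @param curves Numeric matrix, blocks x trial positions (NA allowed).
#' @param labels Condition label per block (exactly two distinct values;
#'   differences are first minus second in sorted-unique order unless
#'   `positive` names the condition of interest).
#' @param n_perm Number of label permutations (default 1000; a warning is
#'   issued below 100).
#' @param level Familywise confidence level (default 0.95).
#' @param seed Integer seed for the permutation RNG.
#' @param positive Optional condition name whose excess is being tested
#'   (defaults to the first sorted label).
#' @return List: `diff` (observed per-trial median differences),
#'   `threshold` (pooled null `level`-quantile), `significant` (flagged
#'   trial positions), `n_perm`, `level`, `seed`.
#' @export
trialwise_permutation_test <- function(curves, labels, n_perm = 1000L,
                                       level = 0.95, seed = 1L,
                                       positive = NULL) {
  labs <- sort(unique(labels))
  if (length(labs) != 2) stop("need exactly two condition labels")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null")
  if (is.null(positive)) positive <- labs[1]
  if (!positive %in% labs) stop("unknown 'positive' condition")
  if (min(table(labels)) < 5) stop("need at least 5 blocks per condition")
  lab_int <- ifelse(labels == positive, 1L, 2L)
  res <- cpp_perm_median_diff(curves, lab_int, as.integer(n_perm),
                              as.integer(seed))
  obs <- res[1, ]
  null_pool <- as.numeric(res[-1, , drop = FALSE])
  null_pool <- null_pool[!is.na(null_pool)]
  # paper-style order statistic: the level-quantile of the pooled null
  thr <- sort(null_pool)[ceiling(level * length(null_pool))]
  list(diff = obs, threshold = thr,
       significant = which(!is.na(obs) & obs > thr),
       n_perm = n_perm, level = level, seed = seed)
}

# median learning trials over sliding windows of 4 block positions:
# 8 forward-aligned starts (blocks 1..8 of a session) and 7
# backward-aligned starts (last, ..., seventh-to-last), 15 positions total
sliding_position_medians <- function(lt_table, n_forward = 8L,
                                     n_backward = 7L, width = 4L) {
  by_sess <- split(lt_table, lt_table$session_id)
  fwd <- matrix(NA_real_, 0, 0)
  collect <- function(position_of) {
    # position_of(blk_df) -> integer position per block row (NA = skip)
    vals <- list()
    for (s in by_sess) {
      s <- s[order(s$block_index), ]
      pos <- position_of(s)
      for (i in seq_len(nrow(s))) {
        if (!is.na(pos[i]) && !is.na(s$learning_trial[i])) {
          p <- as.character(pos[i])
          vals[[p]] <- c(vals[[p]], s$learning_trial[i])
        }
      }
    }
    vals
  }
  med_at <- function(vals, starts, width) {
    vapply(starts, function(k) {
      x <- unlist(vals[as.character(k:(k + width - 1))])
      if (length(x)) median(x) else NA_real_
    }, numeric(1))
  }
  fwd_vals <- collect(function(s) seq_len(nrow(s)))
  bwd_vals <- collect(function(s) rev(seq_len(nrow(s))))
  c(med_at(fwd_vals, seq_len(n_forward), width),
    med_at(bwd_vals, seq_len(n_backward), width))
}

#' Randomization test for consistency of learning differences
#'
#' Summarizes each condition's learning trials over 15 sliding sets of
#' four successive block positions (8 aligned to session start, 7 aligned
#' to session end) and uses as test statistic the proportion of positions
#' at which the median learning trial is earlier under the `faster`
#' condition (ties count as not earlier). The null distribution reassigns
#' session condition labels `n_perm` times; the p-value is one minus the
#' fraction of null statistics that the observed statistic exceeds.
#'
#' @param lt_table Learning-trial table ([learning_trials_table()]):
#'   columns `session_id`, `condition`, `block_index`, `learning_trial`.
#'   Sessions with fewer than 4 blocks contribute only to positions they
#'   reach.
#' @param faster Condition expected to learn earlier (default first sorted
#'   label).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer RNG seed.
#' @return List: `statistic` (observed proportion of earlier positions),
#'   `p_value`, `position_medians` (15 x 2 matrix), `n_perm`, `seed`.
#' @export
consistency_randomization <- function(lt_table, faster = NULL,
                                      n_perm = 1000L, seed = 1L) {
  labs <- sort(unique(lt_table$condition))
  if (length(labs) != 2) stop("need exactly two condition labels")
  if (is.null(faster)) faster <- labs[1]
  other <- setdiff(labs, faster)
  blocks_per_sess <- table(lt_table$session_id)
  if (any(blocks_per_sess < 4)) {
    warning("session(s) with fewer than 4 blocks contribute only to ",
            "positions they reach")
  }
  stat_of <- function(tab) {
    m1 <- sliding_position_medians(tab[tab$condition == faster, ])
    m2 <- sliding_position_medians(tab[tab$condition == other, ])
    ok <- !is.na(m1) & !is.na(m2)
    if (!any(ok)) return(NA_real_)
    mean(m1[ok] < m2[ok])
  }
  obs_m1 <- sliding_position_medians(lt_table[lt_table$condition == faster, ])
  obs_m2 <- sliding_position_medians(lt_table[lt_table$condition == other, ])
  obs <- stat_of(lt_table)

  sessions <- unique(lt_table[, c("session_id", "condition")])
  set.seed(seed)
  null_stat <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    shuffled <- setNames(sample(sessions$condition), sessions$session_id)
    tab <- lt_table
    tab$condition <- shuffled[tab$session_id]
    null_stat[r] <- stat_of(tab)
  }
  p <- 1 - mean(obs > null_stat, na.rm = TRUE)
  list(statistic = obs, p_value = p,
       position_medians = cbind(faster = obs_m1, other = obs_m2),
       n_perm = n_perm, seed = seed)
}

#' Descriptive performance metrics per session and condition
#'
#' @param trials Trial table.
#' @return List with `per_session` (one row per session: proportion of
#'   rewarded completed choices overall and split by dimming condition,
#'   premature rate, fixation-break rate, blocks and completed choices per
#'   session) and `comparison` (per metric: condition means and the
#'   two-sided Wilcoxon rank-sum p-value across sessions, when both
#'   conditions are present).
#' @export
performance_metrics <- function(trials) {
  if (nrow(trials) == 0) stop("empty trial table")
  sess <- split(trials, trials$session_id)
  per_session <- do.call(rbind, lapply(sess, function(s) {
    done <- s[s$choice != "none", ]
    prop_dim <- vapply(DIMMING_LEVELS, function(dc) {
      d <- done[done$dimming_condition == dc, ]
      if (nrow(d)) mean(d$reward) else NA_real_
    }, numeric(1))
    data.frame(
      session_id = s$session_id[1], condition = s$condition[1],
      prop_rewarded = if (nrow(done)) mean(done$reward) else NA_real_,
      prop_rewarded_simultaneous = prop_dim[1],
      prop_rewarded_rewarded_first = prop_dim[2],
      prop_rewarded_rewarded_second = prop_dim[3],
      premature_rate = mean(s$outcome_class == "premature"),
      fixation_break_rate = mean(s$outcome_class == "fixation_break"),
      n_blocks = length(unique(s$block_index)),
      n_choices = nrow(done),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_session) <- NULL
  comparison <- NULL
  conds <- unique(per_session$condition)
  if (length(conds) == 2) {
    metrics <- setdiff(names(per_session), c("session_id", "condition"))
    comparison <- do.call(rbind, lapply(metrics, function(m) {
      x <- per_session[per_session$condition == conds[1], m]
      y <- per_session[per_session$condition == conds[2], m]
      p <- tryCatch(stats::wilcox.test(x, y, exact = FALSE)$p.value,
                    error = function(e) NA_real_)
      data.frame(metric = m,
                 mean_1 = mean(x, na.rm = TRUE),
                 mean_2 = mean(y, na.rm = TRUE),
                 p_wilcoxon = p, stringsAsFactors = FALSE)
    }))
    names(comparison)[2:3] <- paste0("mean_", conds)
    rownames(comparison) <- NULL
  }
  list(per_session = per_session, comparison = comparison)
}
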