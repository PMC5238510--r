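# Task structure: two peripheral drifting gratings that always carry
# complementary colors (1/2) and motions (up/down); only color predicts
# reward; the color-reward map flips un-cued between blocks of 30-50 trials.

#' Session plan for the reversal-learning task simulator
#'
#' @param n_blocks Number of reversal blocks to run (`>= 1`).
#' @param block_length_min,block_length_max Trial bounds per block
#'   (defaults 30 and 50).
#' @param advance_window,advance_threshold The performance criterion that
#'   ends a block early: a running average of rewarded completed trials over
#'   the last `advance_window` trials reaching `advance_threshold`
#'   (defaults 12 and 0.90), evaluated only once `block_length_min` trials
#'   have been played.
#' @param dimming_proportions Probabilities of the three dimming (go-cue)
#'   conditions `simultaneous`, `rewarded_first`, `rewarded_second`; must
#'   sum to 1 (default 1/3 each).
#' @param lapse_rate Probability of an incomplete trial (fixation break or
#'   premature response, no choice scored); default 0 because the learning
#'   models operate on completed choices only.
#' @param rng_seed Optional integer; when given, [generate_session()] seeds
#'   the RNG so the session is reproducible.
#' @return A `session_plan` list.
#' @export
session_plan <- function(n_blocks,
                         block_length_min = 30L,
                         block_length_max = 50L,
                         advance_window = 12L,
                         advance_threshold = 0.90,
                         dimming_proportions = c(1, 1, 1) / 3,
                         lapse_rate = 0,
                         rng_seed = NULL) {
  if (n_blocks < 1) stop("n_blocks must be a positive integer")
  if (abs(sum(dimming_proportions) - 1) > 1e-8) {
    stop("dimming_proportions must sum to 1")
  }
  if (block_length_min > block_length_max) stop("block length bounds crossed")
  if (lapse_rate < 0 || lapse_rate >= 1) stop("lapse_rate must be in [0, 1)")
  structure(list(
    n_blocks = as.integer(n_blocks),
    block_length_min = as.integer(block_length_min),
    block_length_max = as.integer(block_length_max),
    advance_window = as.integer(advance_window),
    advance_threshold = advance_threshold,
    dimming_proportions = dimming_proportions,
    lapse_rate = lapse_rate,
    rng_seed = rng_seed
  ), class = "session_plan")
}

DIMMING_LEVELS <- c("simultaneous", "rewarded_first", "rewarded_second")

#' Simulate one session of the reversal task
#'
#' Plays `plan$n_blocks` blocks with an agent defined by one of the eight
#' learning models. Each trial the color-to-side and motion-to-side
#' assignments are randomized independently (probability 0.5), so only
#' color carries reward information. The agent's choice is drawn from its
#' model's choice probabilities; reward is delivered deterministically for
#' choosing the stimulus with the currently rewarded color. The rewarded
#' color flips between blocks; the first block's rewarded color is drawn
#' from the RNG. A block ends when the running reward average over the last
#' `advance_window` completed trials reaches `advance_threshold` (evaluated
#' from trial `block_length_min` on), or at the `block_length_max` cap;
#' each block's exit route is tagged.
#'
#' @param plan A [session_plan()].
#' @param model One of [model_names()].
#' @param params Named parameter vector for the agent (see
#'   [check_params()]).
#' @param session_id Session label written to the trial table.
#' @param condition Condition label (`"drug"` or `"control"`, free-form).
#' @return A data.frame of trials with columns `session_id`, `condition`,
#'   `block_index`, `trial_in_block`, `left_color`, `left_motion`,
#'   `rewarded_color`, `dimming_condition`, `choice`, `reward`,
#'   `outcome_class`, carrying a `block_end` attribute (data.frame of
#'   `block_index`, `length`, `reason` = "criterion" or "cap").
#' @export
generate_session <- function(plan, model, params, session_id = "s1",
                             condition = "control") {
  if (!inherits(plan, "session_plan")) plan <- do.call(session_plan, plan)
  params <- check_params(model, params)
  if (!is.null(plan$rng_seed)) set.seed(plan$rng_seed)

  state <- init_state(model)
  rewarded_color <- sample(1:2, 1L)
  rows <- vector("list", plan$n_blocks * plan$block_length_max)
  n_row <- 0L
  block_end <- data.frame(block_index = integer(), length = integer(),
                          reason = character())

  for (b in seq_len(plan$n_blocks)) {
    rewards <- integer(0)  # completed-choice rewards within this block
    t_in_block <- 0L
    repeat {
      t_in_block <- t_in_block + 1L
      left_color <- sample(1:2, 1L)
      left_motion <- sample(c("up", "down"), 1L)
      dimming <- sample(DIMMING_LEVELS, 1L, prob = plan$dimming_proportions)

      if (plan$lapse_rate > 0 && runif(1) < plan$lapse_rate) {
        choice <- "none"
        reward <- 0L
        outcome <- sample(c("fixation_break", "premature"), 1L)
      } else {
        feats <- stimulus_features(left_color, left_motion)
        p <- model_choice_probs(model, params, state, feats)
        side <- if (runif(1) < p[1]) 1L else 2L
        choice <- c("left", "right")[side]
        chosen_color <- if (side == 1L) left_color else 3L - left_color
        reward <- as.integer(chosen_color == rewarded_color)
        state <- model_update_state(model, params, state, feats, side, reward)
        outcome <- if (reward == 1L) "rewarded_choice" else "error_choice"
        rewards <- c(rewards, reward)
      }

      n_row <- n_row + 1L
      rows[[n_row]] <- data.frame(
        session_id = session_id, condition = condition,
        block_index = b, trial_in_block = t_in_block,
        left_color = left_color, left_motion = left_motion,
        rewarded_color = rewarded_color, dimming_condition = dimming,
        choice = choice, reward = reward, outcome_class = outcome,
        stringsAsFactors = FALSE
      )

      crit <- t_in_block >= plan$block_length_min &&
        length(rewards) >= plan$advance_window &&
        mean(tail(rewards, plan$advance_window)) >= plan$advance_threshold
      if (crit || t_in_block >= plan$block_length_max) {
        block_end <- rbind(block_end, data.frame(
          block_index = b, length = t_in_block,
          reason = if (crit) "criterion" else "cap"))
        break
      }
    }
    rewarded_color <- 3L - rewarded_color
  }

  out <- do.call(rbind, rows[seq_len(n_row)])
  attr(out, "block_end") <- block_end
  out
}

#' Simulate a whole condition (multiple sessions)
#'
#' Runs sessions of `blocks_per_session` blocks until `n_blocks_total`
#' blocks have been played (the last session may be shorter), relabeling
#' `block_index` within sessions. Sub-seeds per session are derived from
#' the current RNG state, so a single `set.seed()` before the call makes
#' the whole condition reproducible.
#'
#' @param n_blocks_total Total reversal blocks for the condition.
#' @param model,params Agent specification.
#' @param condition Condition label.
#' @param blocks_per_session Blocks per simulated session (default 8, a
#'   typical daily yield in this task).
#' @param session_prefix Prefix for session ids.
#' @param ... Further arguments passed to [session_plan()].
#' @return A trial table (rowbound sessions) with a combined `block_end`
#'   attribute.
#' @export
simulate_condition <- function(n_blocks_total, model, params,
                               condition = "control",
                               blocks_per_session = 8L,
                               session_prefix = condition, ...) {
  if (n_blocks_total < 1) stop("n_blocks_total must be >= 1")
  sizes <- rep(blocks_per_session,
               n_blocks_total %/% blocks_per_session)
  if (n_blocks_total %% blocks_per_session) {
    sizes <- c(sizes, n_blocks_total %% blocks_per_session)
  }
  pieces <- vector("list", length(sizes))
  ends <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    plan <- session_plan(n_blocks = sizes[i], ...)
    sid <- sprintf("%s_%02d", session_prefix, i)
    pieces[[i]] <- generate_session(plan, model, params,
                                    session_id = sid, condition = condition)
    be <- attr(pieces[[i]], "block_end")
    be$session_id <- sid
    ends[[i]] <- be
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "block_end") <- do.call(rbind, ends)
  out
}

TRIAL_COLUMNS <- c("session_id", "condition", "block_index",
                   "trial_in_block", "left_color", "left_motion",
                   "rewarded_color", "dimming_condition", "choice",
                   "reward", "outcome_class")

#' Validate a trial table
#'
#' Checks the documented column schema and the task invariants: categorical
#' levels, `trial_in_block <= 50`, and `reward = 1` exactly when a
#' completed choice selected the stimulus carrying the rewarded color.
#'
#' @param trials Data.frame to validate.
#' @return The validated data.frame (column-ordered), invisibly an error on
#'   violation.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  trials <- trials[, TRIAL_COLUMNS]
  if (nrow(trials) == 0) return(trials)
  if (!all(trials$left_color %in% 1:2) || !all(trials$rewarded_color %in% 1:2))
    stop("colors must be coded 1 or 2")
  if (!all(trials$left_motion %in% c("up", "down")))
    stop("left_motion must be 'up' or 'down'")
  if (!all(trials$dimming_condition %in% DIMMING_LEVELS))
    stop("illegal dimming_condition value")
  if (!all(trials$choice %in% c("left", "right", "none")))
    stop("choice must be 'left', 'right' or 'none'")
  if (!all(trials$reward %in% 0:1)) stop("reward must be 0 or 1")
  if (any(trials$trial_in_block < 1 | trials$trial_in_block > 50))
    stop("trial_in_block must lie in [1, 50]")
  chosen_color <- ifelse(trials$choice == "left", trials$left_color,
                         ifelse(trials$choice == "right",
                                3L - trials$left_color, NA))
  expect_reward <- as.integer(!is.na(chosen_color) &
                              chosen_color == trials$rewarded_color)
  if (any(trials$reward != expect_reward)) {
    stop("reward inconsistent with choice and rewarded_color at row(s) ",
         paste(head(which(trials$reward != expect_reward), 5), collapse = ", "))
  }
  trials
}

#' Write a trial table to TSV
#'
#' @param trials Trial table (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from TSV
#'
#' Reads and validates a TSV written by [write_trials()] (or produced
#' externally with the same schema); write-then-read round-trips exactly.
#'
#' @param path TSV file with the documented column schema.
#' @return Validated trial data.frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  trials <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       colClasses = list(session_id = "character",
                                         condition = "character"))
  validate_trials(trials)
}

#' Block lengths and exit routes of a simulated trial table
#'
#' @param trials Trial table from [generate_session()] or
#'   [simulate_condition()].
#' @return The `block_end` attribute if present, otherwise a data.frame
#'   recomputed from the table (without exit-reason tags).
#' @export
block_summary <- function(trials) {
  be <- attr(trials, "block_end")
  if (!is.null(be)) return(be)
  agg <- stats::aggregate(trial_in_block ~ session_id + block_index,
                          data = trials, FUN = max)
  names(agg)[names(agg) == "trial_in_block"] <- "length"
  agg$reason <- NA_character_
  agg
}
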