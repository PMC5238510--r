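# Orchestration: YAML run configuration, derived sub-seeds, and the
# simulate / fit / analyze / recover entry points used by the CLI script
# (inst/cli/revlearn).

#' Default run configuration
#'
#' @param seed Master seed; every stochastic stage derives a logged
#'   sub-seed from it.
#' @return Nested configuration list (YAML-serializable).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      conditions = list(
        drug = list(model = "FW+Decay",
                    params = list(eta = 0.648, beta = 2.12,
                                  alpha = 0.41, omega = 1.179),
                    n_blocks = 148L),
        control = list(model = "FW+Decay",
                       params = list(eta = 0.561, beta = 2.18,
                                     alpha = 0.44, omega = 1.043),
                       n_blocks = 148L)
      ),
      blocks_per_session = 8L
    ),
    fit = list(models = model_names(), n_starts = 5L,
               cv_reps = 100L, cv_split = 0.8),
    analyze = list(level = 0.95, n_perm = 1000L, max_trial = 30L),
    recover = list(model = "FW+Decay", n_blocks = 148L,
                   tolerance_sd = list(eta = 0.118, beta = 0.048,
                                       alpha = 0.126, omega = 0.108))
  )
}

#' Load a YAML run configuration
#'
#' Missing fields are filled from [default_config()].
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @param seed Optional seed override.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' Derive a stage sub-seed from the master seed
#'
#' Deterministic, stage-keyed, and kept below 2^31 so it is a valid R
#' integer seed.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character).
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

write_manifest <- function(out_dir, config, stage, extra = list()) {
  manifest <- c(list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("revlearn")),
    config = config
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate the experiment described by a configuration
#'
#' Generates every condition in `config$simulate$conditions` with its own
#' derived sub-seed and writes one combined TSV trial table plus a
#' manifest.
#'
#' @param config Configuration list ([load_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Path of the written trial TSV, invisibly; the trial table is
#'   returned as the `trials` attribute.
#' @export
cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- config$simulate$conditions
  if (is.null(conds) || !length(conds)) stop("no conditions configured")
  pieces <- lapply(names(conds), function(cd) {
    cc <- conds[[cd]]
    if (is.null(cc$n_blocks) || cc$n_blocks < 1) {
      stop("condition ", cd, ": n_blocks must be >= 1")
    }
    set.seed(derive_seed(config$seed, paste0("simulate.", cd)))
    simulate_condition(cc$n_blocks, cc$model, unlist(cc$params),
                       condition = cd,
                       blocks_per_session = config$simulate$blocks_per_session)
  })
  trials <- do.call(rbind, pieces)
  path <- file.path(out_dir, "trials.tsv")
  write_trials(trials, path)
  write_manifest(out_dir, config, "simulate",
                 list(n_trials = nrow(trials),
                      sub_seeds = setNames(
                        lapply(names(conds), function(cd)
                          derive_seed(config$seed, paste0("simulate.", cd))),
                        names(conds))))
  out <- invisible(path)
  attr(out, "trials") <- trials
  out
}

#' Fit and compare the configured models on a trial table
#'
#' Runs [fit_model()] and optionally [cross_validate()] for every model in
#' `config$fit$models`, per condition, and writes the comparison table and
#' per-replicate parameters.
#'
#' @param config Configuration list.
#' @param trials_path Trial TSV path (from [cmd_simulate()] or external).
#' @param out_dir Output directory.
#' @param run_cv Whether to run the cross-validation stage (default TRUE;
#'   the plain fits are always run).
#' @return List per condition: `fits`, `cv`, `comparison`, invisibly;
#'   written as JSON/TSV.
#' @export
cmd_fit <- function(config, trials_path, out_dir, run_cv = TRUE) {
  trials <- read_trials(trials_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- config$fit$models
  results <- list()
  for (cd in unique(trials$condition)) {
    tr <- trials[trials$condition == cd, ]
    fits <- list()
    cvs <- if (run_cv) list() else NULL
    for (m in models) {
      fits[[m]] <- fit_model(m, tr, n_starts = config$fit$n_starts,
                             seed = derive_seed(config$seed,
                                                paste0("fit.", cd, ".", m)))
      if (run_cv) {
        cvs[[m]] <- cross_validate(m, tr, n_reps = config$fit$cv_reps,
                                   split = config$fit$cv_split,
                                   n_starts = config$fit$n_starts,
                                   seed = derive_seed(config$seed,
                                                      paste0("cv.", cd, ".", m)))
        write.table(cvs[[m]]$params,
                    file.path(out_dir, sprintf("cv_params_%s_%s.tsv", cd, m)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    comparison <- compare_models(fits, cv = cvs)
    results[[cd]] <- list(fits = fits, cv = cvs, comparison = comparison)
    jsonlite::write_json(
      list(condition = cd, comparison = comparison,
           best_fit_params = lapply(fits, function(f) as.list(f$params))),
      file.path(out_dir, sprintf("fit_%s.json", cd)),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  write_manifest(out_dir, config, "fit")
  invisible(results)
}

#' Learning-curve and resampling analyses of a trial table
#'
#' Computes per-block learning curves and learning trials, their
#' per-condition distributions, the trial-wise pooled-null permutation
#' test, the sliding-window consistency randomization, and descriptive
#' performance metrics.
#'
#' @inheritParams cmd_fit
#' @return List of results, invisibly; written as JSON/TSV under
#'   `out_dir`.
#' @export
cmd_analyze <- function(config, trials_path, out_dir) {
  trials <- read_trials(trials_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  level <- config$analyze$level
  lt <- learning_trials_table(trials, level = level)
  write.table(lt, file.path(out_dir, "learning_trials.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (all(is.na(lt$learning_trial))) {
    warning("no blocks with detected learning; distribution and ",
            "randomization stages skipped")
    dist <- NULL; consist <- NULL; perm <- NULL
  } else {
    dist <- learning_trial_distribution(lt)
    conds <- unique(trials$condition)
    perm <- NULL; consist <- NULL
    if (length(conds) == 2) {
      tac <- trial_aligned_curves(trials, max_trial = config$analyze$max_trial,
                                  level = level)
      perm <- trialwise_permutation_test(
        tac$curves, tac$labels, n_perm = config$analyze$n_perm,
        level = level, seed = derive_seed(config$seed, "perm"))
      consist <- consistency_randomization(
        lt, n_perm = config$analyze$n_perm,
        seed = derive_seed(config$seed, "consistency"))
    }
  }
  metrics <- performance_metrics(trials)
  res <- list(learning_trials = lt, distribution = dist,
              permutation = perm, consistency = consist,
              metrics = metrics)
  jsonlite::write_json(
    list(distribution = dist,
         permutation = perm[c("diff", "threshold", "significant",
                              "n_perm", "level", "seed")],
         consistency = consist[c("statistic", "p_value", "n_perm", "seed")],
         comparison = metrics$comparison),
    file.path(out_dir, "analysis.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, config, "analyze")
  invisible(res)
}

#' Parameter-recovery experiment
#'
#' Simulates the configured number of blocks from each condition's
#' generative parameter vector, refits the generating model, and reports
#' generative versus recovered values with a pass/fail check at
#' `2 * tolerance_sd` per parameter.
#'
#' @param config Configuration list; uses `config$recover` and the
#'   generative vectors in `config$simulate$conditions`.
#' @param out_dir Output directory.
#' @return Data.frame (one row per condition x parameter): `condition`,
#'   `parameter`, `generative`, `recovered`, `tolerance`, `pass`;
#'   invisibly, also written as TSV + manifest.
#' @export
cmd_recover <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- config$recover$model
  tol_sd <- unlist(config$recover$tolerance_sd)
  rows <- list()
  for (cd in names(config$simulate$conditions)) {
    cc <- config$simulate$conditions[[cd]]
    gen <- unlist(cc$params)[MODEL_PARAMS[[model]]]
    set.seed(derive_seed(config$seed, paste0("recover.sim.", cd)))
    trials <- simulate_condition(config$recover$n_blocks, model, gen,
                                 condition = cd,
                                 blocks_per_session =
                                   config$simulate$blocks_per_session)
    fit <- fit_model(model, trials,
                     n_starts = config$fit$n_starts,
                     seed = derive_seed(config$seed,
                                        paste0("recover.fit.", cd)))
    for (p in names(gen)) {
      tol <- 2 * tol_sd[[p]]
      rows[[paste(cd, p)]] <- data.frame(
        condition = cd, parameter = p, generative = gen[[p]],
        recovered = unname(fit$params[p]), tolerance = tol,
        pass = abs(fit$params[p] - gen[[p]]) <= tol,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.table(out, file.path(out_dir, "recovery.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, config, "recover")
  invisible(out)
}
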