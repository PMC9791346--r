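#' Configuration of a full simulated study run
#'
#' Bundles every setting a run depends on, so a run is reproducible from the
#' config alone. Serialisable to JSON via [write_run_config()].
#'
#' @param experiment `"exp1"` (fixed-intensity) or `"exp2"` (adaptive).
#' @param cohort A [group_config()].
#' @param start_ml Staircase starting morph level (exp2).
#' @param burn_in Burn-in rounds per condition excluded from summaries (exp2).
#' @param rt_cutoff_ms Reaction-time exclusion cutoff, ms.
#' @param min_trials_per_ml Minimum retained trials per morph level for the
#'   caricature-slope score.
#' @param match_strategy Matching strategy, see [match_groups()].
#' @param match_min_size Smallest admissible matched subgroup.
#' @param rng_seed Integer master seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(experiment = c("exp2", "exp1"),
                       cohort = group_config(),
                       start_ml = 100,
                       burn_in = 4L,
                       rt_cutoff_ms = 6000,
                       min_trials_per_ml = 4L,
                       match_strategy = "global",
                       match_min_size = 2L,
                       rng_seed = 1L) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(cohort, "group_config"),
            start_ml %in% ml_grid(),
            is_number(burn_in), burn_in >= 0,
            is_number(rt_cutoff_ms), rt_cutoff_ms > 0,
            is_number(min_trials_per_ml), min_trials_per_ml >= 1,
            is_number(rng_seed))
  structure(
    list(experiment = experiment, cohort = cohort, start_ml = start_ml,
         burn_in = as.integer(burn_in), rt_cutoff_ms = rt_cutoff_ms,
         min_trials_per_ml = as.integer(min_trials_per_ml),
         match_strategy = match_strategy,
         match_min_size = as.integer(match_min_size),
         rng_seed = as.integer(rng_seed)),
    class = "run_config"
  )
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$cohort <- unclass(obj$cohort)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- do.call(group_config, obj$cohort)
  do.call(run_config, c(list(cohort = cohort),
                        obj[setdiff(names(obj), "cohort")]))
}

# derive distinct sub-seeds (< 2^31) from the master seed
sub_seed <- function(seed, k) (seed * 101L + k) %% .Machine$integer.max

#' Run the fixed-intensity experiment end to end
#'
#' Samples a cohort, simulates all 256 trials per observer, applies the
#' reaction-time exclusion, summarises accuracy, computes audiovisual
#' benefit/cost scores, and runs the study's inferential battery: the mixed
#' ANOVA on accuracy (condition x speaker sex within, listener group
#' between), the benefit/cost group ANOVA and group t tests (benefit
#' one-tailed, CI > NH predicted), and the Spearman correlations of CI users'
#' quality-of-life score with overall and auditory-only accuracy.
#'
#' @param config A [run_config()] with `experiment = "exp1"`.
#' @param out_dir Optional directory to write CSV artifacts into.
#' @return List bundle: `cohort`, `trials`, `exclusions`, `summary`,
#'   `summary_by_spsex`, `benefit_cost`, `anova`, `bc_anova`, `tests`,
#'   `correlations`.
#' @export
run_exp1 <- function(config = run_config("exp1"), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$experiment != "exp1") stop("config field 'experiment' must be \"exp1\"", call. = FALSE)
  cohort <- sample_cohort(config$cohort, rng_seed = sub_seed(config$rng_seed, 1L))
  trials <- simulate_experiment1(cohort, rng_seed = sub_seed(config$rng_seed, 2L))
  flt <- filter_rt(trials, config$rt_cutoff_ms)
  summ <- summarize_exp1(flt$trials)
  summ_sp <- summarize_exp1(flt$trials, by_speaker_sex = TRUE)
  bc <- benefit_cost(summ, value = "accuracy")

  anova <- mixed_rm_anova(summ_sp, dv = "accuracy", subject = "participant_id",
                          within = c("condition", "speaker_sex"),
                          between = "group")
  bc_long <- data.frame(
    participant_id = rep(bc$participant_id, 2L),
    group = rep(bc$group, 2L),
    score_type = rep(c("benefit", "cost"), each = nrow(bc)),
    value = c(bc$benefit, bc$cost),
    stringsAsFactors = FALSE
  )
  bc_anova <- mixed_rm_anova(bc_long, dv = "value", subject = "participant_id",
                             within = "score_type", between = "group")

  ci <- bc$group == "CI"
  tests <- list(
    benefit_ci_gt_nh = t_test(bc$benefit[ci], bc$benefit[!ci], welch = TRUE,
                              tail = "greater"),
    cost_ci_vs_nh = t_test(bc$cost[ci], bc$cost[!ci], tail = "two.sided")
  )

  overall <- stats::aggregate(accuracy ~ participant_id + group, data = summ,
                              FUN = mean)
  audio <- summ[summ$condition == "audio_only", ]
  qol <- cohort$qol_env[match(overall$participant_id[overall$group == "CI"],
                              cohort$participant_id)]
  correlations <- list(
    qol_vs_overall_acc = spearman_cor(overall$accuracy[overall$group == "CI"], qol),
    qol_vs_audio_acc = spearman_cor(
      audio$accuracy[audio$group == "CI"],
      cohort$qol_env[match(audio$participant_id[audio$group == "CI"],
                           cohort$participant_id)])
  )

  bundle <- list(cohort = cohort, trials = flt$trials,
                 exclusions = flt[c("n_total", "n_excluded", "prop_excluded")],
                 summary = summ, summary_by_spsex = summ_sp,
                 benefit_cost = bc, anova = anova, bc_anova = bc_anova,
                 tests = tests, correlations = correlations)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, config)
  bundle
}

#' Run the adaptive experiment end to end
#'
#' Samples a cohort, runs every observer through the 384-trial adaptive
#' session, applies the reaction-time exclusion, summarises post-burn-in
#' morph levels and accuracy-by-morph-level, computes benefit/cost scores on
#' the morph-level scale, matches the groups on auditory-only morph level by
#' iterative pair removal, computes caricature-slope scores, and runs the
#' inferential battery (mixed ANOVA on morph level; one-tailed benefit test,
#' CI more negative predicted; matched-subgroup t tests; one-sample slope
#' tests; quality-of-life Spearman correlation).
#'
#' @param config A [run_config()] with `experiment = "exp2"`.
#' @param out_dir Optional directory to write CSV/JSON artifacts into.
#' @return List bundle: `cohort`, `schedule`, `trials`, `rounds`,
#'   `exclusions`, `summary` (`ml` + `accuracy_by_ml`), `benefit_cost`,
#'   `match`, `slopes`, `anova`, `tests`, `slope_tests`, `correlations`.
#' @export
run_exp2 <- function(config = run_config("exp2"), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$experiment != "exp2") stop("config field 'experiment' must be \"exp2\"", call. = FALSE)
  cohort <- sample_cohort(config$cohort, rng_seed = sub_seed(config$rng_seed, 1L))
  schedule <- build_exp2_schedule(rng_seed = sub_seed(config$rng_seed, 2L))
  sim <- run_cohort_staircases(cohort, schedule, start_ml = config$start_ml,
                               rng_seed = sub_seed(config$rng_seed, 3L))
  flt <- filter_rt(sim$trials, config$rt_cutoff_ms)
  summ <- summarize_exp2(sim$rounds, trials = flt$trials,
                         burn_in = config$burn_in)
  bc <- benefit_cost(summ$ml, value = "mean_ml")
  slopes <- caricature_slope(summ$accuracy_by_ml, config$min_trials_per_ml)

  anova <- mixed_rm_anova(summ$ml, dv = "mean_ml", subject = "participant_id",
                          within = "condition", between = "group")

  ci <- bc$group == "CI"
  tests <- list(
    # on the ML scale facilitation is negative: CI benefit predicted lower
    benefit_ci_gt_nh = t_test(bc$benefit[ci], bc$benefit[!ci], welch = TRUE,
                              tail = "less"),
    cost_ci_vs_nh = t_test(bc$cost[ci], bc$cost[!ci], tail = "greater")
  )

  audio <- summ$ml[summ$ml$condition == "audio_only", ]
  a_ci <- audio[audio$group == "CI", ]
  a_nh <- audio[audio$group == "NH", ]
  match <- match_groups(a_ci$mean_ml, a_nh$mean_ml,
                        min_group_size = config$match_min_size,
                        strategy = config$match_strategy,
                        ci_ids = a_ci$participant_id,
                        nh_ids = a_nh$participant_id)
  sub_ml <- function(cond, ids) {
    d <- summ$ml[summ$ml$condition == cond, ]
    d$mean_ml[match(ids, d$participant_id)]
  }
  tests$matched_audio <- t_test(sub_ml("audio_only", match$kept_ci),
                                sub_ml("audio_only", match$kept_nh))
  tests$matched_congruent <- t_test(sub_ml("av_congruent", match$kept_ci),
                                    sub_ml("av_congruent", match$kept_nh),
                                    tail = "less")
  tests$matched_incongruent <- t_test(sub_ml("av_incongruent", match$kept_ci),
                                      sub_ml("av_incongruent", match$kept_nh),
                                      tail = "greater")

  slope_tests <- list()
  for (g in c("CI", "NH")) {
    for (cond in conditions(pooled = TRUE)) {
      s <- slopes$score[slopes$group == g & slopes$condition == cond]
      s <- s[!is.na(s)]
      slope_tests[[paste(g, cond, sep = ".")]] <-
        if (length(s) >= 2) t_test(s, mu = 0, tail = "greater") else NULL
    }
  }

  qol <- cohort$qol_env[match(a_ci$participant_id, cohort$participant_id)]
  correlations <- list(
    qol_vs_audio_ml = spearman_cor(a_ci$mean_ml, qol)
  )

  bundle <- list(cohort = cohort, schedule = schedule, trials = flt$trials,
                 rounds = sim$rounds,
                 exclusions = flt[c("n_total", "n_excluded", "prop_excluded")],
                 summary = summ, benefit_cost = bc, match = match,
                 slopes = slopes, anova = anova, tests = tests,
                 slope_tests = slope_tests, correlations = correlations)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, config)
  bundle
}

#' Write a result bundle to disk
#'
#' Writes every tabular component as CSV, the match result as JSON, and a
#' JSON manifest with the config, exclusion counts and test results, so that
#' every reported number is traceable to an artifact.
#'
#' @param bundle Result of [run_exp1()] or [run_exp2()].
#' @param out_dir Output directory (created if absent).
#' @param config The [run_config()] that produced the bundle.
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  wr(bundle$cohort, "cohort")
  wr(bundle$trials, "trials")
  if (!is.null(bundle$rounds)) wr(bundle$rounds, "rounds")
  if (!is.null(bundle$schedule)) wr(bundle$schedule, "schedule")
  if (is.data.frame(bundle$summary)) {
    wr(bundle$summary, "summary")
  } else {
    wr(bundle$summary$ml, "summary_ml")
    if (!is.null(bundle$summary$accuracy_by_ml)) {
      wr(bundle$summary$accuracy_by_ml, "accuracy_by_ml")
    }
  }
  wr(bundle$benefit_cost, "benefit_cost")
  if (!is.null(bundle$slopes)) wr(bundle$slopes, "slopes")
  wr(bundle$anova, "anova")
  if (!is.null(bundle$bc_anova)) wr(bundle$bc_anova, "bc_anova")
  if (!is.null(bundle$match)) {
    match_result_json(bundle$match, file.path(out_dir, "match_result.json"))
  }
  manifest <- list(
    config = if (!is.null(config)) {
      cfg <- unclass(config); cfg$cohort <- unclass(cfg$cohort); cfg
    },
    exclusions = bundle$exclusions,
    tests = lapply(bundle$tests, unclass),
    slope_tests = lapply(Filter(Negate(is.null), bundle$slope_tests), unclass),
    correlations = bundle$correlations
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Type-I error calibration of the group-difference test
#'
#' Monte-Carlo check that the fixed-intensity experiment's group comparison
#' rejects at the nominal rate under a null configuration in which both
#' groups share the same threshold law. Per replicate, each participant's
#' number of correct responses over the 256 trials is drawn as
#' Binomial(256, p), with p from the participant's psychometric function at
#' the 100% morph level — the exact distribution the trial-level simulation
#' induces on per-participant accuracy — and group mean accuracies are
#' compared with the two-tailed Welch test.
#'
#' @param n_reps Number of Monte-Carlo replicates.
#' @param n_per_group Participants per group.
#' @param theta_mean,theta_sd Shared threshold law of both groups.
#' @param slope,lapse Psychometric parameters.
#' @param alpha Nominal level.
#' @param rng_seed Integer seed or `NULL`.
#' @return List with `rejection_rate`, `n_reps`, `alpha`.
#' @export
calibrate_type1 <- function(n_reps = 10000L, n_per_group = 26L,
                            theta_mean = 100, theta_sd = 15,
                            slope = 10, lapse = 0.02, alpha = 0.05,
                            rng_seed = NULL) {
  n_trials <- nrow(build_exp1_stimuli())
  with_seed(rng_seed, {
    rej <- logical(n_reps)
    for (i in seq_len(n_reps)) {
      theta <- stats::rnorm(2L * n_per_group, theta_mean, theta_sd)
      p <- p_correct(100, theta, slope, lapse)
      acc <- stats::rbinom(length(p), n_trials, p) / n_trials
      res <- t_test(acc[seq_len(n_per_group)], acc[-seq_len(n_per_group)],
                    welch = TRUE)
      rej[i] <- res$p_value < alpha
    }
    list(rejection_rate = mean(rej), n_reps = n_reps, alpha = alpha)
  })
}
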