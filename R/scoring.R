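#' Exclude slow trials
#'
#' Removes trials whose reaction time (measured from voice offset) strictly
#' exceeds the cutoff; a trial at exactly the cutoff is retained.
#'
#' @param trials Trial-record data frame with an `rt_ms` column.
#' @param cutoff_ms Cutoff in milliseconds (default 6000).
#' @return List with `trials` (retained rows), `n_total`, `n_excluded` and
#'   `prop_excluded`.
#' @export
filter_rt <- function(trials, cutoff_ms = 6000) {
  stopifnot("rt_ms" %in% names(trials))
  drop <- trials$rt_ms > cutoff_ms
  list(
    trials = trials[!drop, , drop = FALSE],
    n_total = nrow(trials),
    n_excluded = sum(drop),
    prop_excluded = if (nrow(trials)) sum(drop) / nrow(trials) else NA_real_
  )
}

#' Per-participant accuracy summaries of the fixed-intensity experiment
#'
#' Computes the proportion of correct responses per participant and
#' condition, then pools the two auditory-only variants by averaging their
#' two accuracies (they differ only in nominal timing). With
#' `by_speaker_sex = TRUE` the summary is additionally split by speaker sex,
#' as required by the mixed ANOVA design.
#'
#' @param trials Filtered trial records from [simulate_experiment1()].
#' @param by_speaker_sex Split cells by speaker sex?
#' @return Data frame with `participant_id`, `group`, optionally
#'   `speaker_sex`, `condition` (pooled labels) and `accuracy`. A participant
#'   with no trials in a raw condition gets `NA` there.
#' @export
summarize_exp1 <- function(trials, by_speaker_sex = FALSE) {
  fac <- list(participant_id = trials$participant_id,
              condition = trials$condition)
  if (by_speaker_sex) fac$speaker_sex <- trials$speaker_sex
  agg <- stats::aggregate(trials$correct, by = fac, FUN = mean)
  names(agg)[ncol(agg)] <- "accuracy"

  # complete the participant x condition grid so absent cells become NA
  grid_args <- list(participant_id = unique(trials$participant_id),
                    condition = conditions())
  if (by_speaker_sex) grid_args$speaker_sex <- c("female", "male")
  grid <- do.call(expand.grid,
                  c(grid_args, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  agg <- merge(grid, agg, all.x = TRUE, sort = FALSE)

  # pool the two auditory-only variants by averaging their accuracies;
  # a missing variant propagates NA (flagging the participant)
  agg$condition <- pooled_condition(agg$condition)
  by2 <- list(participant_id = agg$participant_id, condition = agg$condition)
  if (by_speaker_sex) by2$speaker_sex <- agg$speaker_sex
  out <- stats::aggregate(agg["accuracy"], by = by2, FUN = mean,
                          na.action = NULL) # keep NA propagation
  grp <- unique(trials[, c("participant_id", "group")])
  out$group <- grp$group[match(out$participant_id, grp$participant_id)]
  cols <- c("participant_id", "group",
            if (by_speaker_sex) "speaker_sex", "condition", "accuracy")
  out <- out[, cols]
  out[order(out$participant_id, out$condition), , drop = FALSE]
}

#' Per-participant summaries of the adaptive experiment
#'
#' From the round log, computes each participant's mean morph level per
#' pooled condition over the retained (post-burn-in) rounds; the two
#' auditory-only variants are pooled round-by-round before averaging. From
#' the (already reaction-time-filtered) trial log it additionally tabulates
#' post-burn-in accuracy per pooled condition and morph level.
#'
#' @param rounds Round log from [run_cohort_staircases()].
#' @param trials Optional trial log (after [filter_rt()]) for the
#'   accuracy-by-morph-level table.
#' @param burn_in Number of initial rounds per condition to discard.
#' @return List with `ml` (columns `participant_id`, `group`, `condition`,
#'   `mean_ml`) and, when `trials` is given, `accuracy_by_ml` (columns
#'   `participant_id`, `group`, `condition`, `morph_level`, `n_trials`,
#'   `accuracy`).
#' @export
summarize_exp2 <- function(rounds, trials = NULL, burn_in = 4L) {
  keep <- rounds$round_index > burn_in
  if (!any(keep)) stop("no rounds left after burn-in", call. = FALSE)
  r <- rounds[keep, , drop = FALSE]
  grp <- unique(rounds[, c("participant_id", "group")])

  # round-level pooling of the two auditory-only variants
  wide_key <- interaction(r$participant_id, r$round_index, drop = TRUE)
  is_orig <- r$condition == "audio_only_orig"
  is_inc <- r$condition == "audio_only_incong"
  pooled_ml <- pool_audio_only(
    r$morph_level[is_orig][order(wide_key[is_orig])],
    r$morph_level[is_inc][order(wide_key[is_inc])]
  )
  audio <- data.frame(
    participant_id = r$participant_id[is_orig][order(wide_key[is_orig])],
    condition = "audio_only",
    morph_level = pooled_ml,
    stringsAsFactors = FALSE
  )
  av <- r[r$condition %in% c("av_congruent", "av_incongruent"),
          c("participant_id", "condition", "morph_level")]
  all_r <- rbind(audio, av)
  ml <- stats::aggregate(morph_level ~ participant_id + condition, data = all_r,
                         FUN = mean)
  names(ml)[names(ml) == "morph_level"] <- "mean_ml"
  ml$group <- grp$group[match(ml$participant_id, grp$participant_id)]
  ml <- ml[order(ml$participant_id, ml$condition),
           c("participant_id", "group", "condition", "mean_ml")]

  out <- list(ml = ml)
  if (!is.null(trials)) {
    tt <- trials[trials$round_index > burn_in, , drop = FALSE]
    tt$condition <- pooled_condition(tt$condition)
    acc <- stats::aggregate(
      tt$correct,
      by = list(participant_id = tt$participant_id, group = tt$group,
                condition = tt$condition, morph_level = tt$morph_level),
      FUN = function(z) c(n = length(z), acc = mean(z))
    )
    acc <- cbind(acc[, 1:4], n_trials = acc$x[, "n"], accuracy = acc$x[, "acc"])
    out$accuracy_by_ml <- acc[order(acc$participant_id, acc$condition,
                                    acc$morph_level), , drop = FALSE]
  }
  out
}

#' Audiovisual benefit and cost difference scores
#'
#' Benefit is the congruent-audiovisual summary minus the auditory-only
#' summary; cost is incongruent minus auditory-only, on the experiment's
#' native scale. For accuracy, positive benefit means facilitation; for morph
#' levels, facilitation shows as negative benefit (lower level = better).
#' A missing condition summary propagates to a missing score.
#'
#' @param summary Data frame with `participant_id`, `group`, `condition`
#'   (pooled labels) and one value column.
#' @param value Name of the value column (`"accuracy"` or `"mean_ml"`).
#' @return Data frame with `participant_id`, `group`, `benefit`, `cost`.
#' @export
#' @examples
#' s <- data.frame(participant_id = "p1", group = "CI",
#'                 condition = conditions(pooled = TRUE),
#'                 accuracy = c(0.6, 0.8, 0.5))
#' benefit_cost(s) # benefit 0.2, cost -0.1
benefit_cost <- function(summary, value = intersect(c("accuracy", "mean_ml"),
                                                    names(summary))[1]) {
  stopifnot(value %in% names(summary))
  pick <- function(cond) {
    s <- summary[summary$condition == cond, c("participant_id", value)]
    names(s)[2] <- cond
    s
  }
  w <- Reduce(function(a, b) merge(a, b, by = "participant_id", all = TRUE),
              lapply(conditions(pooled = TRUE), pick))
  grp <- unique(summary[, c("participant_id", "group")])
  data.frame(
    participant_id = w$participant_id,
    group = grp$group[match(w$participant_id, grp$participant_id)],
    benefit = w$av_congruent - w$audio_only,
    cost = w$av_incongruent - w$audio_only,
    stringsAsFactors = FALSE
  )
}

#' Caricature-slope score: accuracy gain per morph-level step
#'
#' For each participant and condition, the difference in accuracy between the
#' highest and the lowest morph level the participant performed on, divided
#' by the number of 20% steps between them. Only morph levels with at least
#' `min_trials_per_ml` retained trials qualify; when fewer than two levels
#' qualify (e.g. an observer pinned at the 140% ceiling, so lower levels were
#' never visited) the score is missing — a value, not an error.
#'
#' @param accuracy_by_ml Table from [summarize_exp2()] (`accuracy_by_ml`).
#' @param min_trials_per_ml Minimum retained trials for a level to qualify.
#' @return Data frame with one row per participant x condition:
#'   `participant_id`, `group`, `condition`, `ml_low`, `ml_high`, `acc_low`,
#'   `acc_high`, `n_steps`, `score` (NA when unavailable).
#' @export
caricature_slope <- function(accuracy_by_ml, min_trials_per_ml = 4L) {
  need <- c("participant_id", "group", "condition", "morph_level", "n_trials",
            "accuracy")
  stopifnot(all(need %in% names(accuracy_by_ml)))
  key <- interaction(accuracy_by_ml$participant_id, accuracy_by_ml$condition,
                     drop = TRUE)
  rows <- lapply(split(accuracy_by_ml, key), function(d) {
    q <- d[d$n_trials >= min_trials_per_ml, , drop = FALSE]
    out <- data.frame(
      participant_id = d$participant_id[1], group = d$group[1],
      condition = d$condition[1],
      ml_low = NA_real_, ml_high = NA_real_,
      acc_low = NA_real_, acc_high = NA_real_,
      n_steps = NA_real_, score = NA_real_,
      stringsAsFactors = FALSE
    )
    if (nrow(q) >= 2) {
      lo <- which.min(q$morph_level)
      hi <- which.max(q$morph_level)
      out$ml_low <- q$morph_level[lo]
      out$ml_high <- q$morph_level[hi]
      out$acc_low <- q$accuracy[lo]
      out$acc_high <- q$accuracy[hi]
      out$n_steps <- (out$ml_high - out$ml_low) / ml_step()
      out$score <- (out$acc_high - out$acc_low) / out$n_steps
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$condition), , drop = FALSE]
}
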