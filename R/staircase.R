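#' Transformed up-down rule: next morph level after a four-trial round
#'
#' The staircase targets 75% correct: with 2 or fewer of the round's 4 trials
#' correct the next round uses more diagnostic emotional information (one 20%
#' step up), with exactly 3 correct the level is kept, and with all 4 correct
#' the next round uses less diagnostic information (one step down). Levels
#' saturate at the grid bounds 60 and 140.
#'
#' @param current_ml Current morph level; must lie on [ml_grid()].
#' @param n_correct Number of correct trials in the round, 0-4.
#' @return Next morph level, on the grid. Vectorised.
#' @export
#' @examples
#' next_ml(100, 2) # 120
#' next_ml(100, 3) # 100
#' next_ml(100, 4) # 80
next_ml <- function(current_ml, n_correct) {
  if (!all(current_ml %in% ml_grid())) {
    stop("current_ml must lie on the morph-level grid", call. = FALSE)
  }
  if (!all(n_correct %in% 0:4)) {
    stop("n_correct must be an integer in 0..4", call. = FALSE)
  }
  delta <- ifelse(n_correct <= 2, ml_step(), ifelse(n_correct == 3, 0L, -ml_step()))
  pmin(max(ml_grid()), pmax(min(ml_grid()), current_ml + delta))
}

#' Run the adaptive staircases of one observer
#'
#' Plays the full adaptive session: for each of the four conditions, 24
#' four-trial rounds (96 trials; 384 in total) whose morph level follows
#' [next_ml()] from the observer's performance in the preceding round of the
#' same condition. Within a round all 4 trials share the round's morph level;
#' 2 anger and 2 surprise items are presented in random order, with
#' speaker/pseudoword combinations sampled without replacement within the
#' round. Block and trial indices come from the interleaved `schedule`.
#'
#' @param observer One-row data frame (or list) from [sample_cohort()].
#' @param schedule Data frame from [build_exp2_schedule()], or `NULL` to draw
#'   a schedule on the current RNG stream.
#' @param start_ml Morph level of each condition's first round (default 100,
#'   the unmanipulated original voice).
#' @param rng_seed Integer seed or `NULL`.
#' @return List with `trials` (one row per trial: `participant_id`, `group`,
#'   `trial_index`, `block`, `condition`, `round_index`, `trial_in_round`,
#'   `morph_level`, `emotion`, `speaker_id`, `speaker_sex`, `pseudoword`,
#'   `correct`, `rt_ms`) and `rounds` (one row per condition round:
#'   `participant_id`, `condition`, `round_index`, `morph_level`,
#'   `n_correct`).
#' @export
run_staircases <- function(observer, schedule = NULL, start_ml = 100, rng_seed = NULL) {
  if (!start_ml %in% ml_grid()) stop("start_ml must lie on the grid", call. = FALSE)
  with_seed(rng_seed, {
    if (is.null(schedule)) schedule <- build_exp2_schedule()
    conds <- conditions()
    stopifnot(identical(sort(unique(schedule$condition)), sort(conds)))
    spk <- speaker_table()
    pw <- pseudowords("exp2")
    combos <- expand.grid(speaker_id = spk$speaker_id, pseudoword = pw,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n_total <- nrow(schedule)

    # preallocated trial-level columns, filled per condition stream
    t_cond <- t_emotion <- t_pw <- character(n_total)
    t_round <- t_tir <- t_ml <- t_spk <- integer(n_total)
    t_correct <- logical(n_total)
    t_rt <- numeric(n_total)

    rounds_list <- vector("list", length(conds))
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      slots <- which(schedule$condition == cond)
      n_rounds <- length(slots) %/% 4L
      thr <- observer_threshold(observer, cond)
      ml <- as.integer(start_ml)
      r_ml <- r_nc <- integer(n_rounds)
      for (r in seq_len(n_rounds)) {
        idx <- slots[(4L * (r - 1L) + 1L):(4L * r)]
        pick <- sample.int(nrow(combos), 4L)
        emo <- sample(rep(emotions(), 2L))
        p <- p_correct(ml, thr, observer$slope, observer$lapse)
        corr <- stats::runif(4L) < p
        t_cond[idx] <- cond
        t_round[idx] <- r
        t_tir[idx] <- 1:4
        t_ml[idx] <- ml
        t_emotion[idx] <- emo
        t_spk[idx] <- combos$speaker_id[pick]
        t_pw[idx] <- combos$pseudoword[pick]
        t_correct[idx] <- corr
        t_rt[idx] <- stats::rlnorm(4L, observer$rt_meanlog, observer$rt_sdlog)
        r_ml[r] <- ml
        r_nc[r] <- sum(corr)
        ml <- next_ml(ml, r_nc[r])
      }
      rounds_list[[ci]] <- data.frame(
        participant_id = observer$participant_id, condition = cond,
        round_index = seq_len(n_rounds), morph_level = r_ml, n_correct = r_nc,
        stringsAsFactors = FALSE
      )
    }
    trials <- data.frame(
      participant_id = observer$participant_id,
      group = observer$group,
      trial_index = schedule$trial_index,
      block = schedule$block,
      condition = t_cond,
      round_index = t_round,
      trial_in_round = t_tir,
      morph_level = t_ml,
      emotion = t_emotion,
      speaker_id = t_spk,
      speaker_sex = spk$speaker_sex[t_spk],
      pseudoword = t_pw,
      correct = t_correct,
      rt_ms = t_rt,
      stringsAsFactors = FALSE
    )
    list(trials = trials, rounds = do.call(rbind, rounds_list))
  })
}

#' Run the adaptive experiment for a whole cohort
#'
#' @param cohort Data frame from [sample_cohort()].
#' @param schedule Shared schedule, or `NULL` to draw one per observer.
#' @param start_ml,rng_seed As in [run_staircases()].
#' @return List of stacked `trials` and `rounds` data frames, with a `group`
#'   column added to `rounds`.
#' @export
run_cohort_staircases <- function(cohort, schedule = NULL, start_ml = 100,
                                  rng_seed = NULL) {
  with_seed(rng_seed, {
    res <- lapply(seq_len(nrow(cohort)), function(i) {
      obs <- cohort[i, ]
      r <- run_staircases(obs, schedule = schedule, start_ml = start_ml)
      r$rounds$group <- obs$group
      r
    })
    list(
      trials = do.call(rbind, lapply(res, `[[`, "trials")),
      rounds = do.call(rbind, lapply(res, `[[`, "rounds"))
    )
  })
}

#' Mean morph level of the retained staircase rounds
#'
#' Averages the round morph levels after discarding the initial burn-in
#' rounds, during which the staircase is still approaching its asymptote.
#'
#' @param morph_levels Round morph levels of one condition, in round order.
#' @param burn_in Number of initial rounds to discard (default 4).
#' @return Arithmetic mean of the retained levels.
#' @export
mean_ml <- function(morph_levels, burn_in = 4L) {
  stopifnot(is.numeric(morph_levels))
  if (burn_in >= length(morph_levels)) {
    stop("burn_in must be smaller than the number of rounds", call. = FALSE)
  }
  mean(morph_levels[(burn_in + 1L):length(morph_levels)])
}

#' Pool the two auditory-only summaries
#'
#' The two auditory-only variants differ only in nominal timing; their
#' summaries are combined by the arithmetic mean. Applied round-by-round when
#' round histories are available, the result is identical to pooling the
#' per-condition means (linearity of the mean over equal-length histories).
#'
#' @param ml_orig,ml_incong Summaries (or round vectors) of the two variants.
#' @return Element-wise mean.
#' @export
pool_audio_only <- function(ml_orig, ml_incong) (ml_orig + ml_incong) / 2
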