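make_trials <- function(id, cond, n, acc, rt = 1000, group = "CI") {
  data.frame(participant_id = id, group = group, condition = cond,
             correct = rep(c(TRUE, FALSE), times = c(round(n * acc),
                                                     n - round(n * acc))),
             rt_ms = rt, stringsAsFactors = FALSE)
}

test_that("reaction-time filtering is strict at the cutoff", {
  tr <- data.frame(rt_ms = c(rep(1000, 97), 6000, 6001, 7000))
  f <- filter_rt(tr)
  expect_equal(f$n_excluded, 2)
  expect_equal(f$prop_excluded, 0.02)
  expect_true(6000 %in% f$trials$rt_ms)   # exactly at cutoff: retained
  expect_false(any(f$trials$rt_ms > 6000))
  f0 <- filter_rt(data.frame(rt_ms = rep(1000, 10)))
  expect_equal(f0$n_excluded, 0)
})

test_that("fixed-intensity summaries pool the two auditory-only variants by their mean", {
  tr <- rbind(
    make_trials("p1", "audio_only_orig", 10, 0.6),
    make_trials("p1", "audio_only_incong", 10, 0.8),
    make_trials("p1", "av_congruent", 10, 0.9),
    make_trials("p1", "av_incongruent", 10, 0.5)
  )
  s <- summarize_exp1(tr)
  expect_equal(s$accuracy[s$condition == "audio_only"], 0.7)
  expect_equal(s$accuracy[s$condition == "av_congruent"], 0.9)
  expect_equal(nrow(s), 3)
})

test_that("a participant with no trials in a condition gets a flagged missing value", {
  tr <- rbind(
    make_trials("p1", "audio_only_orig", 10, 0.6),
    make_trials("p1", "av_congruent", 10, 0.9),
    make_trials("p1", "av_incongruent", 10, 0.5)
  )
  s <- summarize_exp1(tr)
  expect_true(is.na(s$accuracy[s$condition == "audio_only"]))
  bc <- benefit_cost(s)
  expect_true(is.na(bc$benefit) && is.na(bc$cost)) # missing propagates
})

test_that("perfect responses give accuracy one everywhere", {
  coh <- observer_profile("p", theta_aud = -1e6, lapse = 0)
  tr <- simulate_experiment1(coh, rng_seed = 21)
  s <- summarize_exp1(filter_rt(tr)$trials)
  expect_true(all(s$accuracy == 1))
})

test_that("pooling commutes with reaction-time filtering", {
  set.seed(22)
  tr <- simulate_experiment1(sample_cohort(group_config(n_per_group = 3)))
  s1 <- summarize_exp1(filter_rt(tr)$trials)
  # filtering first, then per-variant accuracies pooled by hand
  ft <- filter_rt(tr)$trials
  acc <- tapply(ft$correct, list(ft$participant_id, ft$condition), mean)
  pooled <- (acc[, "audio_only_orig"] + acc[, "audio_only_incong"]) / 2
  got <- s1$accuracy[s1$condition == "audio_only"]
  names(got) <- s1$participant_id[s1$condition == "audio_only"]
  expect_equal(got[names(pooled)], pooled)
})

test_that("benefit and cost are the signed condition differences", {
  s <- data.frame(participant_id = "p1", group = "CI",
                  condition = conditions(pooled = TRUE),
                  accuracy = c(0.6, 0.8, 0.5))
  bc <- benefit_cost(s)
  expect_equal(bc$benefit, 0.2)
  expect_equal(bc$cost, -0.1)

  # on the morph-level scale, from the adaptive experiment's group means
  s2 <- data.frame(participant_id = "g", group = "CI",
                   condition = conditions(pooled = TRUE),
                   mean_ml = c(118.9, 97.08, 129.76))
  bc2 <- benefit_cost(s2, value = "mean_ml")
  expect_equal(bc2$benefit, -21.82)
  expect_equal(bc2$cost, 10.86)

  # identical conditions: zero scores
  s3 <- data.frame(participant_id = "z", group = "NH",
                   condition = conditions(pooled = TRUE), accuracy = 0.7)
  expect_equal(benefit_cost(s3)$benefit, 0)
  expect_equal(benefit_cost(s3)$cost, 0)
})

test_that("benefit/cost is antisymmetric under swapping the differenced conditions", {
  s <- data.frame(participant_id = "p1", group = "CI",
                  condition = conditions(pooled = TRUE),
                  accuracy = c(0.55, 0.85, 0.45))
  sw <- s
  sw$condition[sw$condition == "av_congruent"] <- "tmp"
  sw$condition[sw$condition == "audio_only"] <- "av_congruent"
  sw$condition[sw$condition == "tmp"] <- "audio_only"
  expect_equal(benefit_cost(sw)$benefit, -benefit_cost(s)$benefit)
})

test_that("caricature slope follows the per-step formula and availability rule", {
  tab <- rbind(acc_row("p1", "audio_only", 60, 20, 0.5),
               acc_row("p1", "audio_only", 140, 20, 0.9))
  s <- caricature_slope(tab)
  expect_equal(s$n_steps, 4)
  expect_equal(s$score, 0.1)

  # intermediate levels do not enter the score, only the extremes
  tab2 <- rbind(tab, acc_row("p1", "audio_only", 100, 20, 0.2))
  expect_equal(caricature_slope(tab2)$score, 0.1)

  # only one qualifying level: missing, not an error
  one <- acc_row("p2", "av_incongruent", 140, 80, 0.55)
  expect_true(is.na(caricature_slope(one)$score))

  # levels below the trial minimum do not qualify
  thin <- rbind(acc_row("p3", "audio_only", 60, 3, 0.2),
                acc_row("p3", "audio_only", 100, 20, 0.6),
                acc_row("p3", "audio_only", 140, 20, 0.8))
  s3 <- caricature_slope(thin, min_trials_per_ml = 4)
  expect_equal(s3$ml_low, 100)
  expect_equal(s3$score, (0.8 - 0.6) / 2)

  # equal accuracy at both extremes: slope zero
  flat <- rbind(acc_row("p4", "audio_only", 60, 20, 0.7),
                acc_row("p4", "audio_only", 140, 20, 0.7))
  expect_equal(caricature_slope(flat)$score, 0)
})

test_that("slope scores are non-negative in expectation for monotone observers", {
  set.seed(23)
  coh <- sample_cohort(group_config(n_per_group = 8))
  sim <- run_cohort_staircases(coh, fixture_schedule())
  summ <- summarize_exp2(sim$rounds, trials = filter_rt(sim$trials)$trials)
  sl <- caricature_slope(summ$accuracy_by_ml)
  expect_gt(mean(sl$score, na.rm = TRUE), 0)
})

test_that("adaptive summaries pool auditory-only at round level and respect burn-in", {
  # constructed round log: audio variants at 80 and 120 -> pooled 100
  rounds <- expand.grid(participant_id = "p1", condition = conditions(),
                        round_index = 1:24, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  rounds$group <- "CI"
  rounds$morph_level <- ifelse(rounds$condition == "audio_only_orig", 80,
                        ifelse(rounds$condition == "audio_only_incong", 120,
                        ifelse(rounds$condition == "av_congruent", 60, 140)))
  # burn-in rounds get a wild level that must not contaminate the mean
  rounds$morph_level[rounds$round_index <= 4] <- 140
  rounds$n_correct <- 3
  s <- summarize_exp2(rounds, burn_in = 4)
  expect_equal(s$ml$mean_ml[s$ml$condition == "audio_only"], 100)
  expect_equal(s$ml$mean_ml[s$ml$condition == "av_congruent"], 60)
  expect_equal(s$ml$mean_ml[s$ml$condition == "av_incongruent"], 140)
})
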