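# shared fixtures, built in code

# fixed interleaved schedule reused across Monte-Carlo tests
fixture_schedule <- function() build_exp2_schedule(rng_seed = 4242)

# an observer responding at chance (threshold far above the grid)
chance_observer <- function(id = "chance") {
  observer_profile(id, theta_aud = 1e6, lapse = 0.02)
}

# an observer responding correctly on every trial
perfect_observer <- function(id = "perfect") {
  observer_profile(id, theta_aud = -1e6, lapse = 0)
}

# post-burn-in round morph levels of one condition, in round order
round_mls <- function(run, cond, burn_in = 0L) {
  r <- run$rounds[run$rounds$condition == cond, ]
  r <- r[order(r$round_index), ]
  r$morph_level[r$round_index > burn_in]
}

# accuracy-by-ml fixture row
acc_row <- function(id, cond, ml, n, acc, group = "CI") {
  data.frame(participant_id = id, group = group, condition = cond,
             morph_level = ml, n_trials = n, accuracy = acc,
             stringsAsFactors = FALSE)
}
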