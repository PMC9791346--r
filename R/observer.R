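#' Probability of a correct 2-AFC response at a morph level
#'
#' Logistic psychometric function with a guessing floor and a lapse ceiling,
#' parameterised directly by the morph level at which accuracy equals 0.75:
#' \deqn{p(x) = \gamma + (1 - \gamma - \lambda)\, F\!\left(\frac{x - \alpha}{\beta}\right)}
#' with \eqn{F} the standard logistic, \eqn{\gamma} the guess rate (0.5 for
#' 2-AFC), \eqn{\lambda} the lapse rate, \eqn{\beta} the slope scale in
#' morph-level units, and \eqn{\alpha} solved analytically so that
#' `p_correct(threshold75) == 0.75` exactly. The function is monotone
#' non-decreasing in `morph_level` for positive slope and bounded in
#' `[guess, 1 - lapse]`.
#'
#' @param morph_level Morph level(s) in percent; may lie off the grid.
#' @param threshold75 Morph level at which accuracy is 0.75. May lie outside
#'   the presentable \[60, 140\] grid for floor/ceiling observers.
#' @param slope Transition scale in morph-level units (> 0).
#' @param lapse Lapse probability in \[0, 0.1\].
#' @param guess Guessing rate; fixed at 0.5 for the 2-AFC task.
#' @return Vector of correct-response probabilities.
#' @export
#' @examples
#' p_correct(100, threshold75 = 100, slope = 10) # 0.75
p_correct <- function(morph_level, threshold75, slope = 10, lapse = 0.02, guess = 0.5) {
  alpha <- psychometric_alpha(threshold75, slope, lapse, guess)
  guess + (1 - guess - lapse) * stats::plogis((morph_level - alpha) / slope)
}

# location parameter alpha such that accuracy hits 0.75 at threshold75;
# errors when the 0.75 target is unattainable (1 - lapse <= 0.75).
psychometric_alpha <- function(threshold75, slope, lapse, guess = 0.5) {
  stopifnot(is.numeric(threshold75), is_number(slope), slope > 0)
  if (lapse < 0 || guess < 0 || guess >= 1) {
    stop("invalid psychometric parameters", call. = FALSE)
  }
  target <- (0.75 - guess) / (1 - guess - lapse)
  if (!is.finite(target) || target <= 0 || target >= 1) {
    stop("75% correct is not attainable with guess = ", guess,
         " and lapse = ", lapse, call. = FALSE)
  }
  threshold75 - slope * stats::qlogis(target)
}

#' Generative configuration of a simulated cohort
#'
#' Defines the population laws from which simulated cochlear-implant (CI) and
#' normal-hearing (NH) participants are drawn. Per-group auditory-only
#' 75%-correct thresholds theta_aud are normal; audiovisual benefit
#' (threshold reduction under congruent faces) and cost (increase under
#' incongruent faces) are normal truncated at 0. Defaults are calibrated to
#' the adaptive experiment's printed group condition means (CI auditory-only
#' 118.9, congruent 97.08, incongruent 129.76; NH 80.30, 72.04, 96.28) with
#' theta_aud SDs recovered from the printed SEMs at n = 25.
#'
#' @param n_per_group Participants per group (>= 2).
#' @param ci,nh Per-group lists with elements `theta_aud_mean`,
#'   `theta_aud_sd`, `benefit_mean`, `benefit_sd`, `cost_mean`, `cost_sd`.
#' @param slope,lapse Shared psychometric slope (morph-level units) and lapse.
#' @param rho_qol Target Spearman correlation between theta_aud and the
#'   quality-of-life score (negative: better listeners report higher QoL).
#' @param rt_median_ms Median reaction time from voice offset, ms.
#' @param rt_tail_prob Probability of a reaction time exceeding 6000 ms.
#' @return Object of class `group_config`.
#' @export
group_config <- function(n_per_group = 25L,
                         ci = list(theta_aud_mean = 118.9, theta_aud_sd = 22.5,
                                   benefit_mean = 21.82, benefit_sd = 10,
                                   cost_mean = 10.86, cost_sd = 10),
                         nh = list(theta_aud_mean = 80.30, theta_aud_sd = 13.6,
                                   benefit_mean = 8.26, benefit_sd = 10,
                                   cost_mean = 15.98, cost_sd = 10),
                         slope = 10,
                         lapse = 0.02,
                         rho_qol = -0.38,
                         rt_median_ms = 1500,
                         rt_tail_prob = 0.0087) {
  stopifnot(
    is_number(n_per_group), n_per_group >= 2,
    is_number(slope), slope > 0,
    is_number(lapse), lapse >= 0, lapse <= 0.1,
    is_number(rho_qol), rho_qol >= -1, rho_qol <= 1,
    is_number(rt_median_ms), rt_median_ms > 0, rt_median_ms < 6000,
    is_number(rt_tail_prob), rt_tail_prob > 0, rt_tail_prob < 0.5
  )
  for (g in list(ci, nh)) {
    need <- c("theta_aud_mean", "theta_aud_sd", "benefit_mean", "benefit_sd",
              "cost_mean", "cost_sd")
    if (!all(need %in% names(g))) stop("group list missing fields", call. = FALSE)
    if (any(unlist(g[c("theta_aud_sd", "benefit_sd", "cost_sd")]) < 0)) {
      stop("SDs must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(n_per_group = as.integer(n_per_group), ci = ci, nh = nh,
         slope = slope, lapse = lapse, rho_qol = rho_qol,
         rt_median_ms = rt_median_ms, rt_tail_prob = rt_tail_prob),
    class = "group_config"
  )
}

# lognormal RT parameters with exact tail mass beyond 6000 ms:
# P(X > 6000) = tail  <=>  sdlog = (log(6000) - log(median)) / qnorm(1 - tail)
rt_lognormal_params <- function(median_ms, tail_prob) {
  meanlog <- log(median_ms)
  sdlog <- (log(6000) - meanlog) / stats::qnorm(1 - tail_prob)
  list(meanlog = meanlog, sdlog = sdlog)
}

#' Draw a cohort of simulated observers
#'
#' Samples `n_per_group` CI and NH observers from a [group_config()].
#' Auditory-only thresholds are normal; congruent and incongruent thresholds
#' are `theta_aud - benefit` and `theta_aud + cost` with benefit and cost
#' truncated at 0. The quality-of-life score (WHOQOL-BREF environmental
#' health domain, 4-20 scale) is generated jointly with theta_aud through a
#' Gaussian copula whose Pearson parameter is chosen so the population
#' Spearman correlation equals `rho_qol` (rho_pearson = 2 sin(pi rho_s / 6)).
#'
#' @param config A [group_config()].
#' @param rng_seed Integer seed or `NULL`.
#' @return Data frame with one row per observer: `participant_id`, `group`,
#'   `listener_sex`, `theta_aud`, `theta_cong`, `theta_incong`, `slope`,
#'   `lapse`, `rt_meanlog`, `rt_sdlog`, `qol_env`.
#' @export
sample_cohort <- function(config = group_config(), rng_seed = NULL) {
  stopifnot(inherits(config, "group_config"))
  with_seed(rng_seed, {
    rho_p <- 2 * sin(pi * config$rho_qol / 6)
    rt <- rt_lognormal_params(config$rt_median_ms, config$rt_tail_prob)
    one_group <- function(group, pars) {
      n <- config$n_per_group
      z_theta <- stats::rnorm(n)
      theta_aud <- pars$theta_aud_mean + pars$theta_aud_sd * z_theta
      benefit <- pmax(0, stats::rnorm(n, pars$benefit_mean, pars$benefit_sd))
      cost <- pmax(0, stats::rnorm(n, pars$cost_mean, pars$cost_sd))
      z_q <- rho_p * z_theta + sqrt(max(0, 1 - rho_p^2)) * stats::rnorm(n)
      data.frame(
        participant_id = sprintf("%s%02d", group, seq_len(n)),
        group = group,
        listener_sex = rep_len(c("female", "male"), n),
        theta_aud = theta_aud,
        theta_cong = theta_aud - benefit,
        theta_incong = theta_aud + cost,
        slope = config$slope,
        lapse = config$lapse,
        rt_meanlog = rt$meanlog,
        rt_sdlog = rt$sdlog,
        qol_env = 4 + 16 * stats::pnorm(z_q),
        stringsAsFactors = FALSE
      )
    }
    rbind(one_group("CI", config$ci), one_group("NH", config$nh))
  })
}

#' Construct a single observer profile
#'
#' Convenience constructor for one simulated participant, useful for
#' targeted simulations (e.g. a chance-level observer via an arbitrarily
#' high threshold, or a perfect observer via a very low threshold and zero
#' lapse). [sample_cohort()] is the population-level generator.
#'
#' @param participant_id Identifier string.
#' @param group `"CI"` or `"NH"`.
#' @param theta_aud Auditory-only 75%-correct threshold (morph-level percent;
#'   may lie far outside the grid to pin the observer at chance or ceiling).
#' @param theta_cong,theta_incong Congruent / incongruent thresholds
#'   (default: equal to `theta_aud`).
#' @param slope,lapse Psychometric slope and lapse.
#' @param rt_median_ms,rt_tail_prob Reaction-time law: median and tail mass
#'   beyond 6000 ms.
#' @param listener_sex `"female"` or `"male"`.
#' @return One-row data frame in the [sample_cohort()] layout.
#' @export
observer_profile <- function(participant_id = "obs01", group = "NH",
                             theta_aud = 100, theta_cong = theta_aud,
                             theta_incong = theta_aud, slope = 10,
                             lapse = 0.02, rt_median_ms = 1500,
                             rt_tail_prob = 0.0087,
                             listener_sex = "female") {
  rt <- rt_lognormal_params(rt_median_ms, rt_tail_prob)
  data.frame(
    participant_id = participant_id, group = group,
    listener_sex = listener_sex,
    theta_aud = theta_aud, theta_cong = theta_cong,
    theta_incong = theta_incong,
    slope = slope, lapse = lapse,
    rt_meanlog = rt$meanlog, rt_sdlog = rt$sdlog,
    qol_env = NA_real_,
    stringsAsFactors = FALSE
  )
}

# threshold the observer applies to a raw condition label
observer_threshold <- function(observer, condition) {
  thr <- c(
    audio_only_orig = observer$theta_aud,
    audio_only_incong = observer$theta_aud,
    audio_only = observer$theta_aud,
    av_congruent = observer$theta_cong,
    av_incongruent = observer$theta_incong
  )
  unname(thr[condition])
}

#' Simulate one trial response
#'
#' Correctness is a Bernoulli draw from the observer's psychometric function
#' for the stimulus condition; the reaction time (measured from voice offset)
#' is lognormal with the observer's configured tail mass beyond 6000 ms.
#'
#' @param stimulus List or one-row data frame with `condition` and
#'   `morph_level`.
#' @param observer One-row data frame (or list) from [sample_cohort()].
#' @return List with `correct` (logical) and `rt_ms`.
#' @export
simulate_response <- function(stimulus, observer) {
  thr <- observer_threshold(observer, stimulus$condition)
  p <- p_correct(stimulus$morph_level, thr, observer$slope, observer$lapse)
  list(
    correct = stats::runif(1L) < p,
    rt_ms = stats::rlnorm(1L, observer$rt_meanlog, observer$rt_sdlog)
  )
}

#' Simulate the fixed-intensity experiment for a cohort
#'
#' Each observer responds once to all 256 stimuli of the fixed-intensity
#' design (original 100% morph level), presented in random order.
#'
#' @param cohort Data frame from [sample_cohort()].
#' @param rng_seed Integer seed or `NULL`.
#' @return Trial-record data frame: one row per observer x stimulus with
#'   `participant_id`, `group`, `trial_index`, `block`, stimulus columns,
#'   `correct` and `rt_ms`. Blocks are 4 runs of 64 trials.
#' @export
simulate_experiment1 <- function(cohort, rng_seed = NULL) {
  stopifnot(nrow(cohort) >= 1)
  stim <- build_exp1_stimuli()
  n_stim <- nrow(stim)
  with_seed(rng_seed, {
    per_obs <- lapply(seq_len(nrow(cohort)), function(i) {
      obs <- cohort[i, ]
      ord <- sample.int(n_stim)
      s <- stim[ord, ]
      thr <- observer_threshold(obs, s$condition)
      p <- p_correct(s$morph_level, thr, obs$slope, obs$lapse)
      data.frame(
        participant_id = obs$participant_id,
        group = obs$group,
        trial_index = seq_len(n_stim),
        block = rep(1:4, each = n_stim %/% 4L),
        s,
        correct = stats::runif(n_stim) < p,
        rt_ms = stats::rlnorm(n_stim, obs$rt_meanlog, obs$rt_sdlog),
        row.names = NULL,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_obs)
  })
}
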