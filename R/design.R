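#' Morph-level grid of the adaptive experiment
#'
#' The voice continuum runs from emotion anti-caricatures (60%) over the
#' unmanipulated original voice (100%) to emotion caricatures (140%) in 20%
#' steps. Higher levels carry more diagnostic emotional information and are
#' easier to classify.
#'
#' @return Integer vector `c(60, 80, 100, 120, 140)`.
#' @export
ml_grid <- function() seq(60L, 140L, by = 20L)

#' Grid step size in morph-level percent
#' @return 20.
#' @export
ml_step <- function() 20L

#' Presentation conditions
#'
#' Four conditions: congruent audiovisual (voice and face express the same
#' emotion), incongruent audiovisual, and two auditory-only variants that
#' differ only in the nominal timing they inherit (from the congruent or the
#' incongruent video) and are pooled into a single auditory-only condition
#' downstream.
#'
#' @param pooled If `TRUE`, return the three analysis-level condition labels
#'   after pooling the two auditory-only variants.
#' @return Character vector of condition labels.
#' @export
conditions <- function(pooled = FALSE) {
  if (pooled) {
    c("audio_only", "av_congruent", "av_incongruent")
  } else {
    c("audio_only_orig", "audio_only_incong", "av_congruent", "av_incongruent")
  }
}

#' Emotion categories of the 2-AFC task
#' @return `c("anger", "surprise")`.
#' @export
emotions <- function() c("anger", "surprise")

# speaker panel: 8 speakers, balanced 4 female / 4 male
speaker_table <- function() {
  data.frame(
    speaker_id = 1:8,
    speaker_sex = rep(c("female", "male"), each = 4L),
    stringsAsFactors = FALSE
  )
}

pseudowords <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") c("belam", "namil", "molen", "loman") else c("belam", "molen")
}

#' Map a raw condition label to its pooled analysis label
#'
#' @param condition Character vector of raw condition labels.
#' @return Character vector with both auditory-only variants mapped to
#'   `"audio_only"`.
#' @export
pooled_condition <- function(condition) {
  out <- condition
  out[condition %in% c("audio_only_orig", "audio_only_incong")] <- "audio_only"
  out
}

#' Full stimulus set of the fixed-intensity experiment
#'
#' The factorial crossing 2 emotions x 8 speakers x 4 pseudowords x 4
#' conditions at the original (100%) morph level: 256 unique stimuli, each
#' presented exactly once.
#'
#' @return Data frame with one row per stimulus and columns `emotion`,
#'   `speaker_id`, `speaker_sex`, `pseudoword`, `morph_level`, `condition`.
#' @export
#' @examples
#' nrow(build_exp1_stimuli()) # 256
build_exp1_stimuli <- function() {
  spk <- speaker_table()
  g <- expand.grid(
    emotion = emotions(),
    speaker_id = spk$speaker_id,
    pseudoword = pseudowords("exp1"),
    condition = conditions(),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  g$speaker_sex <- spk$speaker_sex[g$speaker_id]
  g$morph_level <- 100L
  g[, c("emotion", "speaker_id", "speaker_sex", "pseudoword", "morph_level", "condition")]
}

#' Full stimulus set of the adaptive experiment
#'
#' The factorial crossing 2 emotions x 8 speakers x 2 pseudowords x 5 morph
#' levels x 4 conditions: 640 unique stimuli. The adaptive procedure samples
#' from this set at the morph level the staircase currently requests.
#'
#' @return Data frame as in [build_exp1_stimuli()], 640 rows.
#' @export
build_exp2_stimuli <- function() {
  spk <- speaker_table()
  g <- expand.grid(
    emotion = emotions(),
    speaker_id = spk$speaker_id,
    pseudoword = pseudowords("exp2"),
    morph_level = ml_grid(),
    condition = conditions(),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  g$speaker_sex <- spk$speaker_sex[g$speaker_id]
  g[, c("emotion", "speaker_id", "speaker_sex", "pseudoword", "morph_level", "condition")]
}

#' Trial schedule for the adaptive experiment
#'
#' 384 trial slots in 8 blocks of 48, with exactly 12 slots per condition in
#' every block and slot order randomised within block. A condition's trial
#' stream is the sequence of its own slots in schedule order; consecutive
#' quadruples of that stream form the 24 four-trial rounds the staircase rule
#' operates on.
#'
#' @param rng_seed Integer seed for reproducible shuffling, or `NULL` to use
#'   the current RNG stream.
#' @return Data frame with columns `trial_index` (1..384), `block` (1..8) and
#'   `condition`.
#' @export
build_exp2_schedule <- function(rng_seed = NULL) {
  with_seed(rng_seed, {
    blocks <- lapply(1:8, function(b) {
      cond <- sample(rep(conditions(), each = 12L))
      data.frame(block = b, condition = cond, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
    out$trial_index <- seq_len(nrow(out))
    out[, c("trial_index", "block", "condition")]
  })
}
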