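utils::globalVariables(c("round_index", "m", "group", "se"))

#' Plot group-mean morph-level trajectories across staircase rounds
#'
#' Mean morph level per round, condition and listener group, with a
#' pointwise 95% confidence ribbon across participants — the standard view of
#' an adaptive session converging on its target level.
#'
#' @param rounds Round log from [run_cohort_staircases()] (needs a `group`
#'   column).
#' @return A ggplot object.
#' @export
plot_ml_trajectories <- function(rounds) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  agg <- stats::aggregate(
    morph_level ~ group + condition + round_index, data = rounds,
    FUN = function(z) c(m = mean(z), se = stats::sd(z) / sqrt(length(z))))
  agg <- cbind(agg[, 1:3], m = agg$morph_level[, "m"],
               se = agg$morph_level[, "se"])
  ggplot2::ggplot(agg, ggplot2::aes(x = round_index, y = m,
                                    colour = group, fill = group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = m - 1.96 * se, ymax = m + 1.96 * se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "round", y = "morph level (%)") +
    ggplot2::theme_minimal()
}
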