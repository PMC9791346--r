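#' Student or Welch t test with configurable tail
#'
#' Thin, contract-stable wrapper around [stats::t.test()] returning a flat
#' result record. With `welch = TRUE` (independent samples only) the
#' Welch-Satterthwaite degrees of freedom are used. Zero variance in both
#' samples with equal means yields an undefined statistic, reported as `NA`
#' rather than an error.
#'
#' @param x,y Numeric samples (`y = NULL` for a one-sample test against `mu`).
#' @param paired Paired test?
#' @param welch Use the Welch test (unequal variances)?
#' @param tail `"two.sided"`, `"greater"` or `"less"` (alternative for x
#'   relative to y or `mu`).
#' @param mu Null value for one-sample/paired tests.
#' @return Object of class `test_result`: list with `statistic`, `df`,
#'   `p_value`, `tail`, `method`, `estimate`, `n`.
#' @export
t_test <- function(x, y = NULL, paired = FALSE, welch = FALSE,
                   tail = c("two.sided", "greater", "less"), mu = 0) {
  tail <- match.arg(tail)
  x <- x[!is.na(x)]
  if (!is.null(y)) y <- y[!is.na(y)]
  res <- tryCatch(
    stats::t.test(x, y, paired = paired, var.equal = !welch,
                  alternative = tail, mu = mu),
    error = function(e) NULL
  )
  if (!is.null(res) && !is.finite(res$statistic)) res <- NULL
  if (is.null(res)) {
    out <- list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                tail = tail, method = "undefined (zero variance)",
                estimate = NA_real_,
                n = c(length(x), if (!is.null(y)) length(y)))
  } else {
    out <- list(
      statistic = unname(res$statistic),
      df = unname(res$parameter),
      p_value = res$p.value,
      tail = tail,
      method = res$method,
      estimate = unname(res$estimate)[1],
      n = c(length(x), if (!is.null(y)) length(y))
    )
  }
  structure(out, class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n  t(", format(x$df, digits = 5), ") = ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$p_value, digits = 4), " (", x$tail, ")\n", sep = "")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties and the asymptotic t
#' approximation for the p value (the same approximation [stats::cor.test()]
#' applies in the presence of ties). Constant input yields an undefined
#' correlation, reported as `NA`.
#'
#' @param x,y Numeric vectors without missing pairs, n >= 3.
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `rho`, `p_value`, `n`, `tail`.
#' @export
spearman_cor <- function(x, y, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x), tail = tail))
  }
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = tail,
                    exact = FALSE)
  )
  list(rho = unname(res$estimate), p_value = res$p.value, n = length(x),
       tail = tail)
}

#' Mixed repeated-measures ANOVA with Huynh-Feldt correction
#'
#' Fits a balanced mixed design with one or two within-subject factors and an
#' optional between-subject factor on a per-cell summary (one observation per
#' participant and cell), via the multivariate linear model route
#' ([car::Anova()], type III, sum-to-zero contrasts). For every within
#' effect the Huynh-Feldt epsilon and the epsilon-corrected degrees of
#' freedom and p value are reported (epsilon capped at 1; a two-level factor
#' has epsilon 1 by construction). Partial eta squared is computed from the
#' effect and error sums of squares.
#'
#' @param data Long-format data frame, one row per participant x cell.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the participant-id column.
#' @param within Character vector of 1 or 2 within-subject factor columns.
#' @param between Optional between-subject factor column.
#' @return Data frame with one row per effect: `effect`, `df_num`, `df_den`,
#'   `F`, `p`, `pes` (partial eta squared), `eps_hf`, `df_num_hf`,
#'   `df_den_hf`, `p_hf` (the last four `NA` for purely between effects).
#' @export
mixed_rm_anova <- function(data, dv, subject, within, between = NULL) {
  stopifnot(length(within) %in% 1:2, all(c(dv, subject, within, between) %in% names(data)))
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])

  # one observation per participant x within-cell, complete and balanced
  cell <- interaction(data[within], drop = FALSE)
  tab <- table(data[[subject]], cell)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("design must have exactly one observation per participant and cell; ",
         "offending cells: ",
         paste(utils::head(paste(rownames(tab)[bad[, 1]],
                                 colnames(tab)[bad[, 2]], sep = ":"), 5),
               collapse = ", "), call. = FALSE)
  }

  idata <- expand.grid(lapply(data[within], levels), KEEP.OUT.ATTRS = FALSE)
  names(idata) <- within
  cell_levels <- do.call(paste, c(idata, list(sep = ".")))

  # wide response matrix, rows = subjects, cols = within cells
  subj_levels <- levels(data[[subject]])
  m <- matrix(NA_real_, nrow = length(subj_levels), ncol = length(cell_levels),
              dimnames = list(subj_levels, cell_levels))
  row_cell <- do.call(paste, c(lapply(within, function(w) data[[w]]),
                               list(sep = ".")))
  m[cbind(as.character(data[[subject]]), row_cell)] <- data[[dv]]

  if (!is.null(between)) {
    btab <- unique(data[, c(subject, between)])
    bfac <- factor(btab[[between]][match(subj_levels, as.character(btab[[subject]]))])
    dfw <- data.frame(bfac = bfac)
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    mod <- stats::lm(m ~ bfac, data = dfw)
  } else {
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    mod <- stats::lm(m ~ 1)
  }
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  # car warns when an HF estimate exceeds 1 or a correction is unavailable;
  # both cases are handled explicitly below
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  adj <- s$pval.adjustments

  eff_names <- rownames(uni)
  keep <- eff_names != "(Intercept)"
  out <- data.frame(
    effect = if (is.null(between)) eff_names[keep] else
      gsub("bfac", between, eff_names[keep], fixed = TRUE),
    df_num = uni[keep, "num Df"],
    df_den = uni[keep, "den Df"],
    F = uni[keep, "F value"],
    p = uni[keep, "Pr(>F)"],
    pes = uni[keep, "Sum Sq"] / (uni[keep, "Sum Sq"] + uni[keep, "Error SS"]),
    eps_hf = NA_real_, df_num_hf = NA_real_, df_den_hf = NA_real_,
    p_hf = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )

  raw_names <- eff_names[keep]
  is_within <- vapply(raw_names, function(nm) {
    any(vapply(within, function(w) grepl(w, nm, fixed = TRUE), logical(1)))
  }, logical(1))
  for (i in which(is_within)) {
    nm <- raw_names[i]
    if (out$df_num[i] == 1) {
      eps <- 1 # sphericity is vacuous for a 2-level factor
    } else if (!is.null(adj) && nm %in% rownames(adj)) {
      eps <- min(1, adj[nm, "HF eps"])
    } else {
      eps <- 1
    }
    out$eps_hf[i] <- eps
    out$df_num_hf[i] <- eps * out$df_num[i]
    out$df_den_hf[i] <- eps * out$df_den[i]
    out$p_hf[i] <- stats::pf(out$F[i], out$df_num_hf[i], out$df_den_hf[i],
                             lower.tail = FALSE)
  }
  out
}
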