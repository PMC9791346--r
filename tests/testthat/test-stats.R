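test_that("t tests reproduce hand-computed statistics", {
  # identical independent samples: t = 0, p = 1
  r <- t_test(c(1, 2, 3), c(1, 2, 3), welch = TRUE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # Welch statistic and Satterthwaite df from the closed form
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  vx <- var(x) / 4; vy <- var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 3 + vy^2 / 3)
  r2 <- t_test(x, y, welch = TRUE)
  expect_equal(r2$statistic, t_hand)
  expect_equal(r2$df, df_hand)
  expect_equal(r2$p_value, 2 * pt(-abs(t_hand), df_hand))

  # one-tailed p halves the two-tailed p on the predicted side
  r_one <- t_test(x, y, welch = TRUE, tail = "less")
  expect_equal(r_one$p_value, r2$p_value / 2)
})

test_that("Welch reduces to Student for equal variances and sample sizes", {
  set.seed(41)
  x <- rnorm(12); y <- rnorm(12)
  w <- t_test(x, y, welch = TRUE)
  s <- t_test(x, y, welch = FALSE)
  expect_equal(w$statistic, s$statistic)
  expect_lte(w$df, s$df) # Satterthwaite df never exceeds pooled df
})

test_that("a fully degenerate t test is reported as undefined, not an error", {
  r <- t_test(rep(1, 5), rep(1, 5), paired = TRUE)
  expect_true(is.na(r$statistic))
  expect_true(is.na(r$p_value))
  expect_match(r$method, "undefined")
})

test_that("Spearman correlation handles monotone data, reversals and ties", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^2)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)

  # midrank oracle: Pearson correlation of midranks
  x2 <- c(1, 2, 2, 3, 4)
  y2 <- c(10, 30, 20, 50, 40)
  oracle <- cor(rank(x2), rank(y2))
  expect_equal(spearman_cor(x2, y2)$rho, oracle)

  # invariance under strictly monotone transformation
  set.seed(42)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_cor(exp(a), b)$rho, spearman_cor(a, b)$rho)

  # constant input: undefined, reported as such
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("a two-level within factor has Huynh-Feldt epsilon one", {
  set.seed(43)
  d <- expand.grid(participant_id = paste0("s", 1:10),
                   condition = c("a", "b"), stringsAsFactors = FALSE)
  d$group <- rep(c("g1", "g2"), 10)
  d$y <- rnorm(20)
  res <- mixed_rm_anova(d, "y", "participant_id", "condition", "group")
  expect_equal(res$eps_hf[res$effect == "condition"], 1)
  expect_equal(res$p_hf[res$effect == "condition"],
               res$p[res$effect == "condition"])
})

test_that("the within-subject ANOVA matches an independent aov and epsilon oracle", {
  # balanced one-way repeated-measures design, no between factor
  set.seed(44)
  n <- 8; k <- 3
  d <- expand.grid(participant_id = paste0("s", 1:n),
                   condition = c("c1", "c2", "c3"), stringsAsFactors = FALSE)
  subj_eff <- rnorm(n, sd = 2)
  d$y <- subj_eff[as.integer(factor(d$participant_id))] +
    c(c1 = 0, c2 = 0.8, c3 = 1.5)[d$condition] + rnorm(nrow(d))

  res <- mixed_rm_anova(d, "y", "participant_id", "condition")

  # F oracle: classical aov error stratification
  a <- summary(aov(y ~ condition + Error(participant_id / condition), data = d))
  ftab <- a[["Error: participant_id:condition"]][[1]]
  expect_equal(res$F[res$effect == "condition"], ftab["condition", "F value"],
               tolerance = 1e-8)
  expect_equal(res$p[res$effect == "condition"], ftab["condition", "Pr(>F)"],
               tolerance = 1e-8)

  # epsilon oracle: Greenhouse-Geisser from the cell covariance matrix,
  # Huynh-Feldt from the standard correction of it
  m <- matrix(d$y[order(d$condition, d$participant_id)], nrow = n)
  S <- cov(m)
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  gg <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  hf <- min(1, (n * (k - 1) * gg - 2) / ((k - 1) * (n - 1 - (k - 1) * gg)))
  expect_equal(res$eps_hf[res$effect == "condition"], hf, tolerance = 1e-8)

  # partial eta squared oracle from the aov sums of squares
  pes <- ftab["condition", "Sum Sq"] /
    (ftab["condition", "Sum Sq"] + ftab["Residuals", "Sum Sq"])
  expect_equal(res$pes[res$effect == "condition"], pes, tolerance = 1e-8)
})

test_that("the mixed ANOVA matches aov F statistics in a two-within-one-between design", {
  set.seed(45)
  d <- expand.grid(participant_id = paste0("s", 1:12),
                   condition = c("c1", "c2", "c3"),
                   speaker_sex = c("f", "m"), stringsAsFactors = FALSE)
  d$group <- rep(c("g1", "g2"), 36)
  d$y <- rnorm(72) + (d$group == "g1") * 0.5 + (d$condition == "c2") * 0.7
  res <- mixed_rm_anova(d, "y", "participant_id",
                        within = c("condition", "speaker_sex"),
                        between = "group")
  a <- summary(aov(y ~ group * condition * speaker_sex +
                     Error(participant_id / (condition * speaker_sex)),
                   data = d))
  f_oracle <- a[["Error: participant_id:condition"]][[1]]["condition", "F value"]
  expect_equal(res$F[res$effect == "condition"], f_oracle, tolerance = 1e-8)
  f_between <- a[["Error: participant_id"]][[1]]["group", "F value"]
  expect_equal(res$F[res$effect == "group"], f_between, tolerance = 1e-8)
  f_int <- a[["Error: participant_id:condition"]][[1]]["group:condition", "F value"]
  expect_equal(res$F[res$effect == "group:condition"], f_int, tolerance = 1e-8)
  expect_true(all(res$eps_hf[res$df_num == 1 & grepl("speaker_sex|condition",
                                                     res$effect)] == 1,
                  na.rm = TRUE))
})

test_that("incomplete designs fail with the offending cells named", {
  d <- expand.grid(participant_id = paste0("s", 1:4),
                   condition = c("a", "b", "c"), stringsAsFactors = FALSE)
  d$y <- rnorm(12)
  d <- d[-1, ] # knock out one cell
  expect_error(mixed_rm_anova(d, "y", "participant_id", "condition"),
               "offending cells")
})

test_that("constant data yield undefined within-subject F ratios, reported not raised", {
  d <- expand.grid(participant_id = paste0("s", 1:6),
                   condition = c("a", "b", "c"), stringsAsFactors = FALSE)
  d$group <- ifelse(d$participant_id %in% paste0("s", 1:3), "g1", "g2")
  d$y <- 1
  res <- mixed_rm_anova(d, "y", "participant_id", "condition", "group")
  expect_true(all(is.na(res$F[res$effect != "group"]) |
                    is.nan(res$F[res$effect != "group"])))
})
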