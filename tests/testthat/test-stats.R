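test_that("Welch t matches the closed-form arithmetic oracle", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  res <- welch_t(a, b)
  # direct Welch formula
  se2 <- var(a) / 4 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p_value, p_hand, tolerance = 1e-10)
  d_hand <- (mean(a) - mean(b)) /
    sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(res$effect, d_hand, tolerance = 1e-10)

  # equal n and equal variances: Satterthwaite df = n_a + n_b - 2 exactly
  x <- c(0, 1, 2, 5); y <- c(10, 11, 12, 15)
  expect_equal(welch_t(x, y)$df, 6, tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  res0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Kendall tau-b matches brute-force pair counting", {
  tau_oracle <- function(x, y) {
    n <- length(x); conc <- 0; disc <- 0; tx <- 0; ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
    n0 <- n * (n - 1) / 2
    (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
  }
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(kendall_tau(x, y)$statistic, tau_oracle(x, y),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:5) {
    xx <- sample(1:6, 7, replace = TRUE)
    yy <- sample(1:6, 7, replace = TRUE)
    if (sd(xx) == 0 || sd(yy) == 0) next
    expect_equal(kendall_tau(xx, yy)$statistic, tau_oracle(xx, yy),
                 tolerance = 1e-12)
  }
  expect_equal(kendall_tau(1:5, 1:5)$statistic, 1)
  expect_equal(kendall_tau(1:5, 5:1)$statistic, -1)
  # tie-corrected tau-b agrees with the standard implementation at larger n
  set.seed(4)
  xx <- sample(1:5, 30, replace = TRUE); yy <- sample(1:5, 30, replace = TRUE)
  expect_equal(kendall_tau(xx, yy)$statistic,
               unname(cor(xx, yy, method = "kendall")), tolerance = 1e-12)
})

test_that("one-sample signed-rank p is exact by enumeration for small n", {
  enum_p <- function(x) {
    # brute force: all 2^n sign assignments of |x| under H0
    x <- x[x != 0]; n <- length(x)
    r <- rank(abs(x))
    v_obs <- sum(r[x > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- signs %*% r
    mean(vs >= v_obs)
  }
  set.seed(5)
  for (i in 1:5) {
    x <- round(rnorm(sample(6:12, 1)), 2)
    x <- x[abs(x) > 0.01]
    if (length(x) < 5 || any(duplicated(abs(x)))) next
    expect_equal(wilcoxon_one_sample(x)$p_value, enum_p(x),
                 tolerance = 1e-12)
  }
  # all-positive n = 10: one-tailed p = 1/2^10
  expect_equal(wilcoxon_one_sample(abs(rnorm(10)) + 0.1)$p_value, 1 / 1024,
               tolerance = 1e-12)
  # antisymmetric sample: p >= 0.5
  x <- c(1.5, -1.5, 2.5, -2.5, 0.5, -0.5, 3.5, -3.5)
  expect_gte(wilcoxon_one_sample(x)$p_value, 0.5)
  expect_error(wilcoxon_one_sample(rep(0, 6)), "zero")
  expect_error(wilcoxon_one_sample(c(1, 2, 3)), "at least 5")
})

test_that("ANCOVA decomposes sums of squares like the matrix oracle", {
  set.seed(6)
  n <- 200
  grp <- factor(rep(c("healthy", "patient"), each = n / 2))
  cov <- rnorm(n, 10, 3)
  y <- 2 * (grp == "patient") + 0.5 * cov + rnorm(n)
  res <- ancova_group_cov(y, grp, cov)

  # independent oracle: explicit least squares via normal equations
  rss_of <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  g <- as.numeric(grp == "patient")
  rss_full <- rss_of(cbind(1, g, cov))
  rss_nog <- rss_of(cbind(1, cov))
  ss_group <- rss_nog - rss_full
  f_hand <- ss_group / (rss_full / (n - 3))
  expect_equal(res$group$statistic, f_hand, tolerance = 1e-8)
  expect_equal(res$group$ges, ss_group / (ss_group + rss_full),
               tolerance = 1e-8)
  expect_equal(res$group$p_value, pf(f_hand, 1, n - 3, lower.tail = FALSE),
               tolerance = 1e-10)
  # SS decomposition closes: covariate-first sequential SS plus the Type-II
  # group SS plus the residual recovers the total SS
  seq_total <- rss_of(cbind(1))
  ss_cov_seq <- seq_total - rss_nog
  expect_equal(ss_cov_seq + res$group$ss + res$group$ss_residual, seq_total,
               tolerance = 1e-8)
  # interaction F from the moderated model
  rss_int <- rss_of(cbind(1, g, cov, g * cov))
  f_int_hand <- (rss_full - rss_int) / (rss_int / (n - 4))
  expect_equal(res$interaction$statistic, f_int_hand, tolerance = 1e-8)
  expect_true(res$group$ges >= 0 && res$group$ges <= 1)

  # adjusted means at the grand covariate mean
  beta <- solve(t(cbind(1, g, cov)) %*% cbind(1, g, cov),
                t(cbind(1, g, cov)) %*% y)
  expect_equal(res$adjusted_means$emmean,
               c(beta[1] + beta[3] * mean(cov),
                 beta[1] + beta[2] + beta[3] * mean(cov)),
               tolerance = 1e-8)
})

test_that("ANCOVA degenerate designs behave sensibly", {
  set.seed(7)
  grp <- factor(rep(c("a", "b"), each = 20))
  y <- rnorm(40)
  # groups identical in y (and in the covariate): F is zero and the
  # adjusted means coincide exactly
  y20 <- rnorm(20); c20 <- rnorm(20)
  res <- ancova_group_cov(rep(y20, 2), grp, rep(c20, 2))
  expect_lt(res$group$statistic, 1e-20)
  expect_equal(res$adjusted_means$emmean[1], res$adjusted_means$emmean[2],
               tolerance = 1e-8)
  # covariate orthogonal to y and balanced: adjusted means = raw means
  cov_orth <- rep(c(-1, 1), 20)
  res2 <- ancova_group_cov(y, grp, cov_orth)
  expect_equal(res2$adjusted_means$emmean,
               c(mean(y[grp == "a"]), mean(y[grp == "b"])),
               tolerance = 0.05)
  expect_warning(res3 <- ancova_group_cov(y, grp, rep(1, 40)), "constant")
  expect_equal(res3$group$df[2], 38)
})

test_that("Pearson correlation reports r with a t-based p", {
  set.seed(8)
  x <- rnorm(20); y <- x + rnorm(20)
  res <- pearson_r(x, y)
  r <- cor(x, y)
  t_hand <- r * sqrt(18 / (1 - r^2))
  expect_equal(res$statistic, r, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 18), tolerance = 1e-10)
  expect_warning(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("mixed-model table and fit do the bookkeeping and recover effects", {
  # 3 patients x 10 windows
  grid <- window_grid(2100, 500, 1.5, 0.3)
  nw <- nrow(grid)
  aligned <- expand.grid(subject = c("P1", "P2", "P3"),
                         window = seq_len(nw), stringsAsFactors = FALSE)
  aligned$start_s <- grid$start_s[aligned$window]
  aligned$end_s <- grid$end_s[aligned$window]
  aligned$label <- factor(rep(c("arm", "neither"), length.out = nrow(aligned)),
                          levels = c("arm", "leg", "both", "neither"))
  set.seed(9)
  aligned$isc <- rnorm(nrow(aligned))
  aligned <- merge(aligned, load_scores_fixture(), by.x = "subject",
                   by.y = "Code")
  tab <- build_mixed_table(aligned, score_cols = c("GMD", "Attention"))
  expect_equal(nrow(tab), 3 * nw)
  expect_equal(nlevels(tab$subject), 3)
  fit <- fit_mixed(tab)
  expect_s4_class(fit$fit, "lmerMod")
  expect_true(all(c("estimate", "se", "t", "p_approx") %in%
                    names(fit$coefficients)))

  # parameter recovery: a known movement effect lands within 2 SE
  set.seed(10)
  n_subj <- 12; n_win <- 40
  sim <- expand.grid(subject = sprintf("S%02d", 1:n_subj),
                     window = 1:n_win, stringsAsFactors = FALSE)
  sim$label <- factor(sample(c("arm", "neither"), nrow(sim), TRUE),
                      levels = c("arm", "leg", "both", "neither"))
  subj_int <- rnorm(n_subj, 0, 0.3)
  beta_mv <- 0.4
  sim$GMD <- rep(sample(1:14, n_subj, TRUE), times = n_win)
  sim$isc <- subj_int[match(sim$subject, sprintf("S%02d", 1:n_subj))] +
    beta_mv * (sim$label == "neither") + rnorm(nrow(sim), 0, 0.2)
  tab2 <- build_mixed_table(sim, score_cols = "GMD")
  fit2 <- fit_mixed(tab2)
  cf <- fit2$coefficients["labelneither", ]
  expect_lt(abs(cf$estimate - beta_mv), 2.5 * cf$se)

  # single-level movement factor drops the term with a warning
  sim1 <- sim; sim1$label[] <- "neither"
  expect_warning(fit_mixed(build_mixed_table(sim1, score_cols = "GMD")),
                 "single movement")
})
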