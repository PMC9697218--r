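# The statistical battery for the group comparison and its covariate
# controls: Welch two-sample t with Cohen's d, one-covariate ANCOVA with
# generalized eta-squared and covariate-adjusted group means, Pearson and
# Kendall (tau-b) correlations, the one-sample one-tailed Wilcoxon
# signed-rank test with effect size r = |Z|/sqrt(n), and assembly/fitting of
# the mixed-effects long table (fitting delegated to lme4).

stat_result <- function(statistic, df = NA_real_, p_value, effect_name = NA,
                        effect = NA_real_, adjustment = "none", extra = NULL) {
  out <- list(statistic = unname(statistic), df = unname(df),
              p_value = unname(p_value), effect_name = effect_name,
              effect = unname(effect), adjustment = adjustment)
  c(out, extra)
}

#' Welch two-sample t-test with Cohen's d
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-sided p;
#' Cohen's d is reported alongside using the pooled-SD convention.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return list with `statistic`, `df`, `p_value`, `effect` (Cohen's d).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  d <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
  stat_result(tt$statistic, tt$parameter, tt$p.value, "cohens_d", d)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `statistic` (r), `df`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length samples of size >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(stat_result(NA_real_, NA_real_, NA_real_, "r", NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  stat_result(ct$estimate, ct$parameter, ct$p.value, "r", ct$estimate)
}

#' Kendall rank correlation (tau-b) with exact or approximate p
#'
#' Tie-corrected tau-b. For n <= 8 the p-value is computed by exact
#' enumeration of all permutations of one margin (valid under ties);
#' otherwise the normal approximation with tie-corrected variance is used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `statistic` (tau-b), `p_value`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length samples of size >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; tau undefined")
    return(stat_result(NA_real_, NA_real_, NA_real_, "tau_b", NA_real_))
  }
  n <- length(x)
  tau <- tau_b(x, y)
  if (n <= 8) {
    perms <- all_permutations(n)
    taus <- apply(perms, 1, function(p) tau_b(x, y[p]))
    p <- mean(abs(taus) >= abs(tau) - 1e-12)
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                           exact = FALSE))
    p <- ct$p.value
  }
  stat_result(tau, NA_real_, p, "tau_b", tau)
}

tau_b <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, `-`)); dy <- sign(outer(y, y, `-`))
  num <- sum(dx * dy) / 2
  t0 <- n * (n - 1) / 2
  tx <- sum(dx == 0) / 2 - n / 2   # tied pairs in x (off-diagonal)
  ty <- sum(dy == 0) / 2 - n / 2
  den <- sqrt((t0 - tx) * (t0 - ty))
  if (den == 0) return(NA_real_)
  num / den
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' One-sample one-tailed Wilcoxon signed-rank test
#'
#' Tests whether the values are shifted above zero. Zeros are dropped; the
#' p-value is exact (signed-rank distribution) for n <= 25 without ties in
#' the absolute values, otherwise a normal approximation with continuity and
#' tie correction. Effect size is r = |Z|/sqrt(n) from the normal
#' approximation.
#'
#' @param x numeric sample with at least 5 non-zero values.
#' @param alternative only `"greater"` is offered (shift above zero).
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `effect` (r).
#' @export
wilcoxon_one_sample <- function(x, alternative = "greater") {
  stopifnot(alternative == "greater")
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) stop("all values are zero")
  if (n < 5) stop("need at least 5 non-zero values")
  r <- rank(abs(x))
  v <- sum(r[x > 0])
  ties <- any(duplicated(abs(x)))
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu) / sqrt(sigma2)
  if (!ties && n <= 25) {
    p <- stats::psignrank(v - 1, n, lower.tail = FALSE)
  } else {
    p <- stats::pnorm((v - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  stat_result(v, NA_real_, p, "r", abs(z) / sqrt(n))
}

rss <- function(fit) sum(stats::residuals(fit)^2)

#' ANCOVA of a two-group outcome with one covariate
#'
#' Fits `y ~ group + cov` and reports the group effect adjusting for the
#' covariate (Type-II sums of squares), its generalized eta-squared, the
#' group x covariate interaction from the moderated model (tested
#' separately), and the covariate-adjusted group means at the grand
#' covariate mean with Bonferroni-adjusted pairwise p-values. A constant
#' covariate degrades to a one-way ANOVA with a warning. Generalized
#' eta-squared treats the covariate as part of the manipulated design
#' (`SS_effect / (SS_effect + SS_error)` for this two-group layout).
#'
#' @param y numeric outcome.
#' @param group two-level factor (or coercible).
#' @param cov numeric covariate.
#' @return list with elements `group` (F, df, p, ges), `interaction`
#'   (F, df, p, ges) and `adjusted_means` (per group, with pairwise
#'   Bonferroni p).
#' @export
ancova_group_cov <- function(y, group, cov) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (length(y) <= 4) stop("need n > 4")
  if (stats::sd(cov) == 0) {
    warning("constant covariate; reducing to one-way ANOVA")
    cov <- NULL
  }
  df0 <- data.frame(y = y, group = group)
  if (!is.null(cov)) df0$cov <- cov
  fit_add <- if (is.null(cov)) stats::lm(y ~ group, data = df0)
             else stats::lm(y ~ group + cov, data = df0)
  n <- length(y)
  df_res <- fit_add$df.residual
  ss_res <- rss(fit_add)
  ss_group <- if (is.null(cov))
    rss(stats::lm(y ~ 1, data = df0)) - ss_res
  else rss(stats::lm(y ~ cov, data = df0)) - ss_res
  f_group <- (ss_group / 1) / (ss_res / df_res)
  p_group <- stats::pf(f_group, 1, df_res, lower.tail = FALSE)
  ges_group <- ss_group / (ss_group + ss_res)
  interaction <- NULL
  if (!is.null(cov)) {
    fit_full <- stats::lm(y ~ group * cov, data = df0)
    ss_int <- ss_res - rss(fit_full)
    df_full <- fit_full$df.residual
    f_int <- (ss_int / 1) / (rss(fit_full) / df_full)
    interaction <- list(statistic = f_int, df = c(1, df_full),
                        p_value = stats::pf(f_int, 1, df_full,
                                            lower.tail = FALSE),
                        ges = ss_int / (ss_int + rss(fit_full)))
  }
  lev <- levels(group)
  newd <- data.frame(group = factor(lev, levels = lev))
  if (!is.null(cov)) newd$cov <- mean(cov)
  emm <- stats::predict(fit_add, newdata = newd, se.fit = TRUE)
  diff_p <- summary(fit_add)$coefficients[paste0("group", lev[2]),
                                          "Pr(>|t|)"]
  n_pairs <- 1L
  adj <- data.frame(group = lev, emmean = emm$fit, se = emm$se.fit)
  list(group = list(statistic = f_group, df = c(1, df_res),
                    p_value = p_group, ges = ges_group, ss = ss_group,
                    ss_residual = ss_res),
       interaction = interaction,
       adjusted_means = adj,
       pairwise_p = min(1, diff_p * n_pairs),
       p_adjustment = "bonferroni")
}

#' Assemble the mixed-model design table
#'
#' Takes the aligned patient x window long table (ISC, movement label,
#' scores) and prepares it for a mixed-effects fit: factors are coerced,
#' rows with missing ISC dropped, and the requested score columns checked.
#'
#' @param aligned output of [align_annotation_isc()].
#' @param score_cols score columns used as fixed effects (and in interaction
#'   with movement).
#' @return data.frame ready for [fit_mixed()], attribute `score_cols`.
#' @export
build_mixed_table <- function(aligned,
                              score_cols = c("Paresis", "CNS_Damage", "DMD",
                                             "GMD", "Attention")) {
  stopifnot(all(c("subject", "isc", "label") %in% names(aligned)))
  miss <- setdiff(score_cols, names(aligned))
  if (length(miss)) stop("missing score columns: ",
                         paste(miss, collapse = ", "))
  out <- aligned[!is.na(aligned$isc), , drop = FALSE]
  out$subject <- factor(out$subject)
  out$label <- droplevels(factor(out$label))
  attr(out, "score_cols") <- score_cols
  out
}

#' Fit the mixed-effects model of windowed ISC
#'
#' Predicts each window's ISC from the dominant movement label, the
#' patient's scores and their interactions with movement (fixed effects),
#' with subject identity and its interaction with movement as random
#' effects: `(1 | subject) + (1 | subject:label)`. Fitting is delegated to
#' [lme4::lmer()] (REML); per-coefficient p-values use the normal
#' approximation on the t statistic, which is what large-window-count
#' designs warrant. A single-level movement factor drops all movement terms
#' with a warning.
#'
#' @param table output of [build_mixed_table()].
#' @return list with `fit` (the lmer object), `coefficients` (estimate, SE,
#'   t, approximate p per fixed effect) and `formula`.
#' @export
fit_mixed <- function(table) {
  score_cols <- attr(table, "score_cols")
  has_movement <- nlevels(table$label) >= 2
  if (!has_movement)
    warning("single movement level; dropping movement terms")
  fixed <- if (has_movement)
    paste("label +", paste(score_cols, collapse = " + "), "+",
          paste(paste0("label:", score_cols), collapse = " + "))
  else paste(score_cols, collapse = " + ")
  rand <- if (has_movement) "(1 | subject) + (1 | subject:label)"
          else "(1 | subject)"
  fml <- stats::as.formula(paste("isc ~", fixed, "+", rand))
  fit <- lme4::lmer(fml, data = table, REML = TRUE)
  cf <- as.data.frame(summary(fit)$coefficients)
  names(cf) <- c("estimate", "se", "t")
  cf$p_approx <- 2 * stats::pnorm(-abs(cf$t))
  list(fit = fit, coefficients = cf, formula = fml)
}
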