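test_that("covariances match the double-loop summation oracle", {
  # small integer tensor, N=3 x D=2 x T=5
  set.seed(1)
  arr <- array(sample(-5:5, 30, replace = TRUE), dim = c(3, 2, 5))
  e <- multisubject_eeg(arr, 10, c("a", "b"), c("s1", "s2", "s3"))
  cp <- compute_covariances(e)
  oracle <- cov_pair_oracle(arr)
  expect_equal(cp$Rw, oracle$Rw, tolerance = 1e-12)
  expect_equal(cp$Rb, oracle$Rb, tolerance = 1e-12)

  # identical subjects: Rb equals Rw (one channel with variance v)
  x <- rnorm(50)
  arr2 <- array(rep(x, each = 2), dim = c(2, 1, 50))
  e2 <- multisubject_eeg(arr2, 10, "a", c("s1", "s2"))
  cp2 <- compute_covariances(e2)
  expect_equal(cp2$Rb, cp2$Rw, tolerance = 1e-12)
  expect_equal(cp2$Rw[1, 1], var(x), tolerance = 1e-12)

  # exactly orthogonal zero-mean subjects: Rb is the zero matrix
  arr3 <- array(0, dim = c(2, 1, 4))
  arr3[1, 1, ] <- c(1, -1, 1, -1)
  arr3[2, 1, ] <- c(1, 1, -1, -1)
  cp3 <- compute_covariances(multisubject_eeg(arr3, 4, "a", c("s1", "s2")))
  expect_equal(cp3$Rb[1, 1], 0, tolerance = 1e-12)

  expect_error(compute_covariances(
    multisubject_eeg(array(1, c(1, 2, 5)), 10, c("a", "b"), "s1")),
    "at least 2")
})

test_that("covariance pooling is the element-wise mean over videos", {
  set.seed(2)
  mk <- function(rb, rw) structure(list(Rb = rb, Rw = rw, n_subjects = 3,
                                        n_samples = 10),
                                   class = "covariance_pair")
  m <- matrix(rnorm(4), 2)
  one <- mk(m, diag(2))
  expect_equal(pool_covariances(list(one))$Rb, m)
  two <- pool_covariances(list(mk(matrix(0, 2, 2), diag(2)), mk(m, diag(2))))
  expect_equal(two$Rb, m / 2)
  four <- lapply(1:4, function(i) mk(matrix(rnorm(4), 2), random_spd(2)))
  pooled <- pool_covariances(four)
  expect_equal(pooled$Rb, Reduce(`+`, lapply(four, `[[`, "Rb")) / 4)
  expect_equal(pooled$Rw, Reduce(`+`, lapply(four, `[[`, "Rw")) / 4)
  expect_error(pool_covariances(list()), "empty")
  expect_error(pool_covariances(list(one, mk(diag(3), diag(3)))), "mismatch")
})

test_that("fit_corrca solves the generalized eigenproblem", {
  mk <- function(rb, rw) structure(list(Rb = rb, Rw = rw, n_subjects = 3,
                                        n_samples = 10),
                                   class = "covariance_pair")
  # identity case: all eigenvalues 1
  idk <- fit_corrca(mk(diag(4), diag(4)), k = 4, shrinkage = 0)
  expect_equal(idk$eigenvalues, rep(1, 4), tolerance = 1e-12)
  # diagonal closed form
  dg <- fit_corrca(mk(diag(c(0.8, 0.2)), diag(2)), k = 2, shrinkage = 0)
  expect_equal(dg$eigenvalues, c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(abs(dg$W), diag(2), tolerance = 1e-9)
  # leading ratio beats 1e4 random directions on random SPD pairs
  set.seed(5)
  for (rep in 1:3) {
    rb <- random_spd(4); rw <- random_spd(4)
    fit <- fit_corrca(mk(rb, rw), k = 4, shrinkage = 0)
    w <- matrix(rnorm(4 * 1e4), 4)
    ratios <- colSums(w * (rb %*% w)) / colSums(w * (rw %*% w))
    expect_gte(fit$eigenvalues[1], max(ratios) - 1e-9)
    # and the eigenvector attains its eigenvalue as a ratio
    w1 <- fit$W[, 1]
    expect_equal(drop(w1 %*% rb %*% w1) / drop(w1 %*% rw %*% w1),
                 fit$eigenvalues[1], tolerance = 1e-9)
  }
  expect_error(fit_corrca(mk(diag(2), diag(2)), k = 5), "channels")
  sing <- mk(diag(2), matrix(c(1, 1, 1, 1), 2))
  expect_error(fit_corrca(sing, k = 2, shrinkage = 0), "shrinkage")
  # forward model identity: A = Rw W (W' Rw W)^-1 and sign convention
  set.seed(6)
  rb <- random_spd(5); rw <- random_spd(5)
  fit <- fit_corrca(mk(rb, rw), k = 3, shrinkage = 0)
  a_direct <- rw %*% fit$W %*% solve(t(fit$W) %*% rw %*% fit$W)
  expect_equal(fit$A, a_direct, tolerance = 1e-9)
  for (j in 1:3) expect_gt(fit$A[which.max(abs(fit$A[, j])), j], 0)
})

test_that("projection applies W channel-wise", {
  g <- tiny_cohort(n_healthy = 2, n_patient = 0, duration = 1, seed = 51)
  e <- g$eeg[[1]]
  model <- structure(list(W = diag(19)[, 1, drop = FALSE],
                          eigenvalues = 1, A = diag(19)[, 1, drop = FALSE],
                          shrinkage = 0), class = "corrca_model")
  p <- project_components(e, model)
  expect_equal(p[1, 1, ], e$data[1, 1, ])
  zero <- e; zero$data[] <- 0
  expect_true(all(project_components(zero, model) == 0))
  bad <- model; bad$W <- diag(5)[, 1, drop = FALSE]
  expect_error(project_components(e, bad), "channel dimension")
})

test_that("leave-one-out ISC matches direct Pearson arithmetic", {
  # identical target and references: isc 1 per component, top-3 sum 3
  x <- matrix(rnorm(3 * 100), 3, 100)
  proj <- proj_array(rep(list(x), 4), fs = 100)
  isc <- loo_isc_table(proj, reference = 1:4)
  expect_equal(isc$isc, rep(1, 12), tolerance = 1e-12)
  expect_equal(unique(isc$topk_sum), 3, tolerance = 1e-12)

  # orthogonal constructed target: isc 0
  s1 <- rep(c(1, -1), 50); s2 <- rep(c(1, 1, -1, -1), 25)
  portho <- proj_array(list(rbind(s1, s1, s1), rbind(s2, s2, s2),
                            rbind(s1, s1, s1)), fs = 100)
  isco <- loo_isc_table(portho, reference = c(1, 3), targets = 2)
  expect_equal(isco$isc, rep(0, 3), tolerance = 1e-12)

  # printed toy vectors, 3 references, T=6: hand Pearson oracle
  tgt <- c(2, 4, 3, 7, 5, 6)
  refs <- list(c(1, 3, 2, 6, 4, 8), c(2, 2, 5, 7, 6, 6), c(9, 4, 1, 7, 5, 3))
  pl <- proj_array(c(list(rbind(tgt, tgt, tgt)),
                     lapply(refs, function(r) rbind(r, r, r))), fs = 10)
  got <- loo_isc_table(pl, reference = 2:4, targets = 1)
  hand <- mean(vapply(refs, function(r) cor(tgt, r), numeric(1)))
  expect_equal(got$isc[got$component == 1], hand, tolerance = 1e-12)

  # averaging order: per-video means then across-video average
  pv1 <- proj_array(list(rbind(tgt), rbind(refs[[1]])), fs = 10)
  pv2 <- proj_array(list(rbind(tgt), rbind(refs[[3]])), fs = 10)
  two <- loo_isc_table(list(pv1, pv2), reference = 2, targets = 1,
                       k_report = 1)
  s <- isc_summary(two)
  expect_equal(s$comp1, mean(c(cor(tgt, refs[[1]]), cor(tgt, refs[[3]]))),
               tolerance = 1e-12)
})

test_that("ISC is invariant to subject order and per-subject scaling", {
  g <- tiny_cohort(n_healthy = 4, n_patient = 2, duration = 2, seed = 52)
  e <- g$eeg[[1]]
  model <- fit_corrca(compute_covariances(e), k = 3)
  proj <- project_components(e, model)
  base <- isc_summary(loo_isc_table(proj, reference = 1:4))

  perm <- c(3, 1, 4, 2, 6, 5)
  ep <- multisubject_eeg(e$data[perm, , ], e$fs, e$channel_labels,
                         e$subject_ids[perm], e$group[perm])
  pp <- project_components(ep, model)
  got <- isc_summary(loo_isc_table(pp, reference = match(1:4, perm)))
  ord <- match(base$subject, got$subject)
  expect_equal(got$isc_topk[ord], base$isc_topk, tolerance = 1e-9)

  es <- e; es$data[2, , ] <- 7.3 * es$data[2, , ]
  ps <- project_components(es, model)
  got2 <- isc_summary(loo_isc_table(ps, reference = 1:4))
  expect_equal(got2$isc_topk, base$isc_topk, tolerance = 1e-9)
})

test_that("within-group ISC refits on the group alone", {
  expect_error(within_group_isc(tiny_cohort(n_healthy = 3, n_patient = 2,
                                            duration = 1,
                                            seed = 53)$eeg,
                                "patient"),
               "at least 3")
  # patients share their own source: within-patient ISC is positive
  g <- generate_cohort(cohort_spec(n_healthy = 4, n_patient = 8,
                                   duration = 10, n_videos = 2,
                                   gain_patient = 0.2,
                                   patient_shared_gain = 0.6, seed = 54))
  wp <- isc_summary(within_group_isc(g$eeg, "patient"))
  expect_true(all(wp$group == "patient"))
  expect_gt(mean(wp$isc_topk), 0)
  wt <- wilcoxon_one_sample(wp$isc_topk)
  expect_lt(wt$p_value, 0.05)
  # independent-noise groups, projections not fitted on the scored data:
  # grand mean ISC within 2 Monte-Carlo SEs of zero (SE over independent
  # replicate cohorts; leave-one-out values inside a cohort share pairs, so
  # a within-cohort SE would be too small)
  axes <- structure(list(W = diag(19)[, 1:3], eigenvalues = rep(1, 3),
                         A = diag(19)[, 1:3], shrinkage = 0),
                    class = "corrca_model")
  null_mean <- function(seed) {
    g0 <- generate_cohort(cohort_spec(n_healthy = 2, n_patient = 10,
                                      duration = 6, n_videos = 1,
                                      gain_patient = 0,
                                      patient_shared_gain = 0, seed = seed))
    e0 <- g0$eeg[[1]]
    idx <- which(e0$group == "patient")
    p0 <- project_components(
      multisubject_eeg(e0$data[idx, , , drop = FALSE], e0$fs,
                       e0$channel_labels, e0$subject_ids[idx],
                       e0$group[idx]), axes)
    mean(isc_summary(loo_isc_table(p0, reference = seq_along(idx),
                                   k_report = 1))$comp1)
  }
  means <- vapply(101:110, null_mean, numeric(1))
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(length(means)))
  # refitting on the scored data itself selects the in-sample maximum and
  # biases the leading component's null ISC slightly upward; the bias stays
  # small and does not affect group contrasts, which share one fit
  g0 <- generate_cohort(cohort_spec(n_healthy = 4, n_patient = 10,
                                    duration = 10, n_videos = 1,
                                    gain_patient = 0, patient_shared_gain = 0,
                                    seed = 55))
  wrefit <- isc_summary(within_group_isc(g0$eeg, "patient", k_report = 1))
  expect_gt(mean(wrefit$comp1), 0)
  expect_lt(mean(wrefit$comp1), 0.06)
})

test_that("window grid follows the stated arithmetic", {
  g <- window_grid(3000, 500, 1.5, 0.3)
  expect_equal(nrow(g), 16)              # floor((6 - 1.5)/0.3) + 1
  expect_equal(g$end_sample - g$start_sample + 1L, rep(750L, 16))
  expect_equal(diff(g$start_sample), rep(150L, 15))
  # formula property across lengths
  for (tt in c(750, 1000, 2950, 7500, 30000)) {
    gg <- window_grid(tt, 500, 1.5, 0.3)
    expect_equal(nrow(gg), floor((tt - 750) / 150) + 1)
  }
  expect_error(window_grid(500, 500, 1.5, 0.3), "longer")
  expect_error(window_grid(3000, 500, 1.5, 0), "positive")
})

test_that("time-resolved ISC is consistent with whole-recording ISC", {
  g <- generate_cohort(cohort_spec(n_healthy = 8, n_patient = 0,
                                   duration = 12, n_videos = 1, seed = 56))
  e <- g$eeg[[1]]
  model <- fit_corrca(compute_covariances(e), k = 3)
  proj <- project_components(e, model)
  whole <- mean(isc_summary(loo_isc_table(proj, reference = 1:8,
                                          k_report = 1))$comp1)
  w <- time_resolved_isc(proj, reference = 1:8, window_length = 1.5,
                         step = 0.3, k_report = 1)
  grid <- attr(w, "grid")
  expect_equal(nrow(grid), floor((12 - 1.5) / 0.3) + 1)
  mean_w <- mean(w$isc[w$component == 1], na.rm = TRUE)
  expect_lt(abs(mean_w - whole), 0.05)
  # windows mostly zero-filled for a subject go missing
  e2 <- e
  e2$data[3, , 1:2000] <- 0
  p2 <- project_components(e2, model)
  w2 <- time_resolved_isc(p2, reference = 1:8, k_report = 1)
  first <- w2[w2$window == 1 & w2$component == 1, ]
  expect_true(is.na(first$isc[first$subject == e$subject_ids[3]]))
  expect_false(anyNA(first$isc[first$subject != e$subject_ids[3]]))
})
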