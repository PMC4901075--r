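# HRF, design matrices, OLS fitting, subject contrasts, group t-maps

test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf()
  t <- attr(h, "t")
  expect_equal(h[1], 0)                       # gamma density at 0, shape > 1
  expect_equal(max(h), 1)                     # peak normalisation
  # argmax near 5 s by dense evaluation of the closed form
  p <- hrf_params()
  tt <- seq(0, 32, by = 0.001)
  dense <- dgamma(tt, shape = 6, scale = 1) - dgamma(tt, shape = 16) / 6
  expect_lt(abs(t[which.max(h)] - tt[which.max(dense)]), p$dt + 1e-9)
  expect_error(hrf_params(peak_dispersion = 0))
})

test_that("design matrices carry the study's regressor counts", {
  sch_v <- generate_schedule(value_task_spec(), seed = 1)
  d_v <- build_design(sch_v[[1]], 200, grouping = condition_grouping("Value"))
  expect_length(d_v$task_columns, 15)
  expect_identical(nrow(d_v$X), 200L)

  sch_e <- generate_schedule(emotion_task_spec(), seed = 1)
  d_e <- build_design(sch_e[[1]], 108, grouping = condition_grouping("Emotion"))
  expect_identical(sort(d_e$task_columns),
                   sort(c("choice", "fb_gain", "fb_nogain")))

  sch_m <- generate_schedule(math_task_spec(), seed = 1)
  d_m <- build_design(sch_m[[1]], 224,
                      grouping = condition_grouping("Mathematical"))
  expect_length(d_m$task_columns, 9)
  expect_true("choice_incorrect" %in% d_m$nuisance_columns)

  # motion columns become nuisance regressors
  m <- matrix(rnorm(108 * 6), ncol = 6)
  d_em <- build_design(sch_e[[1]], 108, motion = m,
                       grouping = condition_grouping("Emotion"))
  expect_identical(ncol(d_em$X), 3L + 6L + 1L)
  expect_error(build_design(sch_e[[1]], 108, motion = m[1:10, ],
                            grouping = condition_grouping("Emotion")),
               "one row per scan")

  # degenerate: empty schedule leaves only nuisance columns, with a warning
  expect_warning(d0 <- build_design(sch_e[[1]][0, ], 108,
                                    grouping = condition_grouping("Emotion")),
                 "empty schedule")
  expect_length(d0$task_columns, 0)
  expect_identical(d0$nuisance_columns, "intercept")
})

test_that("OLS recovers exact coefficients and is a projection", {
  g <- tiny_grid(c(4, 4, 3))
  sch <- generate_schedule(emotion_task_spec(), seed = 2)
  des <- build_design(sch[[1]], 108, grouping = condition_grouping("Emotion"))
  p <- ncol(des$X)
  set.seed(1)
  beta_true <- matrix(rnorm(p * prod(g$dims)), nrow = p)
  series <- fmri_series(t(des$X %*% beta_true), g)
  bm <- fit_run(series, des)
  expect_lt(max(abs(bm$beta - beta_true)), 1e-9)
  # residual orthogonality on noisy data
  noisy <- fmri_series(t(des$X %*% beta_true) +
                         matrix(rnorm(prod(g$dims) * 108), ncol = 108), g)
  bm2 <- fit_run(noisy, des)
  fitted <- des$X %*% bm2$beta
  res <- t(noisy$data) - fitted
  expect_lt(max(abs(crossprod(des$X, res))) /
              (max(abs(des$X)) * max(abs(res)) * 108), 1e-8)
  # refitting fitted values returns identical beta (idempotence)
  bm3 <- fit_run(fmri_series(t(fitted), g), des)
  expect_equal(bm3$beta, bm2$beta, tolerance = 1e-9)
  expect_identical(bm$df, 108L - ncol(des$X))
})

test_that("rank-deficient designs fail naming the collinear columns", {
  sch <- generate_schedule(emotion_task_spec(), seed = 2)
  des <- build_design(sch[[1]], 108, grouping = condition_grouping("Emotion"))
  des$X <- cbind(des$X, dupe = des$X[, "choice"])
  g <- tiny_grid(c(2, 2, 2))
  series <- fmri_series(matrix(rnorm(8 * 108), ncol = 108), g)
  expect_error(fit_run(series, des), "dupe|choice")
})

test_that("white-noise t statistics follow Student t with df_error", {
  g <- acq_grid(c(25, 20, 20), voxel_size = c(3.4375, 3.4375, 4))
  sch <- generate_schedule(emotion_task_spec(), seed = 3)
  des <- build_design(sch[[1]], 108, grouping = condition_grouping("Emotion"))
  set.seed(77)
  series <- fmri_series(matrix(rnorm(prod(g$dims) * 108), ncol = 108), g)
  bm <- fit_run(series, des)
  tt <- contrast_t(bm, c(choice = 1))
  ks <- ks.test(tt, pt, df = bm$df)
  expect_gt(ks$p.value, 0.01)
})

test_that("subject contrasts are run-weighted means", {
  g <- tiny_grid(c(3, 3, 2))
  sch <- generate_schedule(value_task_spec(), seed = 6)
  fits <- lapply(1:2, function(r) {
    des <- build_design(sch[[r]], 200, grouping = condition_grouping("Value"))
    set.seed(r)
    beta <- matrix(rnorm(ncol(des$X) * prod(g$dims)), nrow = ncol(des$X))
    fit_run(fmri_series(t(des$X %*% beta), g), des)
  })
  ct <- c(choice_L1 = 0.5, choice_L2 = 0.5)
  # single run with unit weight equals the run contrast
  single <- subject_contrast(fits[1], ct)
  expect_equal(as.numeric(single$values),
               drop(t(fits[[1]]$beta[names(ct), ]) %*% ct),
               tolerance = 1e-12)
  # hand-computed two-run weighted mean at one voxel
  v1 <- sum(ct * fits[[1]]$beta[names(ct), 5])
  v2 <- sum(ct * fits[[2]]$beta[names(ct), 5])
  got <- subject_contrast(fits, ct, weights = c(0.3, 0.7))
  expect_equal(as.numeric(got$values)[5], 0.3 * v1 + 0.7 * v2,
               tolerance = 1e-12)
  # equal betas make the result weight-invariant
  two_same <- subject_contrast(list(fits[[1]], fits[[1]]), ct,
                               weights = c(0.9, 0.1))
  expect_equal(two_same$values, single$values, tolerance = 1e-12)
  expect_error(subject_contrast(fits, ct, weights = 1), "length")
})

test_that("group t-maps behave like one-sample t statistics", {
  g <- tiny_grid(c(6, 6, 4))
  n <- 20
  set.seed(12)
  vols <- lapply(seq_len(n), function(i)
    fmri_volume(array(rnorm(prod(g$dims), mean = 0.5), g$dims), g))
  tm <- group_tmap(vols, task = "Value", phase = "choice")
  expect_identical(tm$df, 19L)
  expect_equal(mean(tm$values$values), 0.5 * sqrt(20), tolerance = 0.1)
  # antisymmetry
  neg <- group_tmap(lapply(vols, function(v) fmri_volume(-v$values, g)))
  expect_equal(neg$values$values, -tm$values$values, tolerance = 1e-12)
  # zero-variance voxels are flagged non-finite
  const <- lapply(1:5, function(i) fmri_volume(array(1, g$dims), g))
  tc <- group_tmap(const)
  expect_true(all(is.na(tc$values$values)))
  expect_error(group_tmap(vols[1]), "at least 2")
})

test_that("t statistics are invariant to paired rescaling", {
  g <- tiny_grid(c(3, 3, 2))
  sch <- generate_schedule(emotion_task_spec(), seed = 2)
  des <- build_design(sch[[1]], 108, grouping = condition_grouping("Emotion"))
  set.seed(2)
  series <- fmri_series(matrix(rnorm(prod(g$dims) * 108), ncol = 108) + 100, g)
  bm <- fit_run(series, des)
  bm_scaled <- fit_run(fmri_series(series$data * 3.7, g), des)
  expect_equal(contrast_t(bm, c(choice = 1)),
               contrast_t(bm_scaled, c(choice = 1)), tolerance = 1e-9)
})
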