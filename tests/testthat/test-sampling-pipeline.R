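test_that("uniform region-of-interest sampling respects bounds and moments", {
  sp <- default_mmi_space()
  pts <- sample_roi(sp, 1000, seed = 1)
  expect_true(all(pts[, "ca_sr_ini"] >= 300 & pts[, "ca_sr_ini"] <= 700))
  expect_true(all(pts[, "g_k1_sf"] >= 0 & pts[, "g_k1_sf"] <= 1))
  # per-axis mean within 3 SE of the midpoint (uniform SE = range/sqrt(12 n))
  for (j in seq_len(nrow(sp))) {
    mid <- (sp$min[j] + sp$max[j]) / 2
    se <- (sp$max[j] - sp$min[j]) / sqrt(12 * 1000)
    expect_lt(abs(mean(pts[, j]) - mid), 3 * se)
  }
  expect_identical(pts, sample_roi(sp, 1000, seed = 1))
})

test_that("transition sampling accepts only points inside the band", {
  m <- table1_model()
  sp <- m$space
  prelim <- structure(
    list(space = sp, spec = m$spec, intercept = m$intercept,
         weights = m$weights, se = m$se), class = "ebprob_lrm")
  pts <- sample_transition(sp, prelim, 200, band = c(0.025, 0.975), seed = 2)
  expect_identical(nrow(pts), 200L)
  p <- predict_probability(prelim, pts)
  expect_true(all(p > 0.025 & p < 0.975))
  # a (0, 1) band accepts everything, matching plain uniform sampling rates
  pts_all <- sample_transition(sp, prelim, 100, band = c(1e-12, 1 - 1e-12),
                               seed = 3)
  expect_identical(nrow(pts_all), 100L)
})

test_that("steep 1-D transition sampling inverts the band analytically", {
  sp <- mmi_space("x", 0, 1)
  m <- structure(list(space = sp, spec = linear_feature_spec(sp),
                      intercept = -25, weights = c(x = 50),
                      se = c(x = NA_real_)), class = "ebprob_lrm")
  pts <- sample_transition(sp, m, 300, band = c(0.025, 0.975), seed = 4)
  half_width <- qlogis(0.975) / 50  # ~ 0.0733
  expect_true(all(abs(pts[, "x"] - 0.5) < half_width + 1e-12))
})

test_that("an unreachable band errors with advice", {
  sp <- mmi_space("x", 0, 1)
  m <- structure(list(space = sp, spec = linear_feature_spec(sp),
                      intercept = -2000, weights = c(x = 10),
                      se = c(x = NA_real_)), class = "ebprob_lrm")
  expect_error(
    sample_transition(sp, m, 5, band = c(0.4, 0.6), seed = 1,
                      min_rate = 1e-3),
    "widen")
})

test_that("information criteria match their closed forms", {
  expect_equal(caic(0, 0, 10), 0)
  expect_equal(caic(-100, 5, exp(1)), 210)  # ln(e) + 1 = 2 per parameter
  expect_equal(caic(-100, 5, 100, criterion = "aic"), 210)
  expect_equal(caic(-50, 3, 400), 100 + 3 * (log(400) + 1))
})

test_that("a pure-noise feature raises CAIC in most replicates", {
  sp <- mmi_space("x", 0, 1)
  spec_lin <- linear_feature_spec(sp)
  spec_noise <- feature_spec(c("x", "x^2"), sp)
  worse <- vapply(1:20, function(s) {
    obs <- make_synthetic_obs(sp, spec_lin, -2, c(x = 4), n_sets = 60,
                              n_real = 200, seed = 900 + s)
    f0 <- fit_lrm(obs, sp, spec_lin)
    f1 <- fit_lrm(obs, sp, spec_noise)
    N <- sum(obs$n)
    caic(f1$log_likelihood, 3, N) > caic(f0$log_likelihood, 2, N)
  }, logical(1))
  expect_gte(mean(worse), 0.9)
})

test_that("exhaustive selection keeps generating quadratics and drops noise", {
  sp <- toy_space_2d()
  # truth has a strong x^2 term and no other quadratic
  spec_true <- feature_spec(c("x", "y", "x^2"), sp)
  hits_x2 <- logical(10)
  no_noise <- logical(10)
  for (s in 1:10) {
    obs <- make_synthetic_obs(sp, spec_true, -1, c(x = 3, y = -2, `x^2` = 8),
                              n_sets = 80, n_real = 500, seed = 300 + s)
    sel <- select_feature_set(obs, sp)
    hits_x2[s] <- "x^2" %in% sel$terms
    no_noise[s] <- !any(c("y^2", "x*y") %in% sel$terms)
  }
  expect_gte(mean(hits_x2), 0.9)
  expect_gte(mean(no_noise), 0.7)
  # 1-D linear truth: empty quadratic set selected in most replicates
  sp1 <- mmi_space("x", 0, 1)
  empty <- vapply(1:10, function(s) {
    obs <- make_synthetic_obs(sp1, linear_feature_spec(sp1), -2, c(x = 4),
                              n_sets = 60, n_real = 200, seed = 400 + s)
    identical(select_feature_set(obs, sp1)$terms, "x")
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("pipeline runs end to end and satisfies its structural invariants", {
  cfg <- pipeline_config(sets_per_iteration = 40, seed = 21)
  run <- run_two_iteration_pipeline(cfg, toy_model_config())
  expect_s3_class(run$model, "ebprob_lrm")
  # iteration-1 model is linear-only
  expect_identical(run$iterations[[1]]$model$spec$terms, cfg$space$name)
  # pooled size = 2 x sets_per_iteration
  expect_identical(nrow(run$pooled_observations), 80L)
  # all second-iteration points lie in the transition band of the prelim model
  obs2 <- run$iterations[[2]]$observations
  p2 <- predict_probability(run$iterations[[1]]$model,
                            obs2[, cfg$space$name])
  expect_true(all(p2 > cfg$transition_band[1] & p2 < cfg$transition_band[2]))
  # all linear features retained in the final spec
  expect_true(all(cfg$space$name %in% run$model$spec$terms))
  # reproducibility
  run2 <- run_two_iteration_pipeline(cfg, toy_model_config())
  expect_identical(run$model$weights, run2$model$weights)
})

test_that("an under-determined pipeline request fails at the fitting stage", {
  cfg <- pipeline_config(sets_per_iteration = 2, seed = 1)
  expect_error(run_two_iteration_pipeline(cfg, toy_model_config()),
               class = "ebprob_pipeline_error")
})

test_that("pipeline-recovered surrogate predicts held-out synthetic data", {
  cfg <- pipeline_config(sets_per_iteration = 50, seed = 31)
  sim <- toy_model_config()
  run <- run_two_iteration_pipeline(cfg, sim)
  test_pts <- sample_roi(cfg$space, 100, seed = 32)
  test_obs <- simulate_batches(sim, test_pts, n = 100, seed = 33)
  v <- validate_lrm(run$model, test_obs)
  expect_lt(v$mean_abs_error, 0.03)
  expect_gt(v$r2_transition, 0.95)
})
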