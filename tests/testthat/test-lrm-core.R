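test_that("anchor-derived intercept matches the hand-summation oracle", {
  sp <- default_mmi_space()
  spec <- table1_feature_spec(sp)
  w <- setNames(oracle_weights, spec$terms)
  b0 <- derive_intercept_from_anchor(w, sp, spec, set1, 0.5)
  expect_equal(b0, 0 - sum(oracle_weights * oracle_features(set1)),
               tolerance = 1e-12)
  expect_equal(b0, -44.010, tolerance = 1e-3)
  # zero-weight closed forms
  w0 <- setNames(numeric(10), spec$terms)
  expect_equal(derive_intercept_from_anchor(w0, sp, spec, set1, 0.5), 0)
  expect_equal(derive_intercept_from_anchor(w0, sp, spec, set1, 0.73),
               qlogis(0.73))
  expect_error(derive_intercept_from_anchor(w, sp, spec, set1, 1),
               "strictly in")
})

test_that("linear predictor and probability match the oracle on published sets", {
  m <- table1_model()
  expect_equal(linear_predictor(m, set1), 0, tolerance = 1e-12)
  expect_equal(linear_predictor(m, hf_gk1_point), 2.402, tolerance = 1e-3)
  for (pt in list(set2, set3, default_set, normal_gk1_point, hf_gk1_point)) {
    expect_equal(linear_predictor(m, pt), oracle_lp(pt), tolerance = 1e-10)
    expect_equal(predict_probability(m, pt), oracle_prob(pt),
                 tolerance = 1e-12)
  }
})

test_that("prediction is numerically stable and monotone in the predictor", {
  sp <- mmi_space("x", 0, 1)
  m <- structure(list(space = sp, spec = linear_feature_spec(sp),
                      intercept = 0, weights = c(x = 1400),
                      se = c(x = NA_real_), provenance = "synthetic"),
                 class = "ebprob_lrm")
  expect_equal(predict_probability(m, c(x = 0.5)), 1)   # argument 700
  expect_equal(predict_probability(m, c(x = -0.5)), 0)  # argument -700
  eta <- seq(-40, 40, length.out = 400)
  pp <- predict_probability(m, cbind(x = eta / 1400))
  expect_true(all(diff(pp) >= 0))                 # monotone link throughout
  mid <- abs(eta) < 25
  expect_true(all(diff(pp[mid]) > 0))             # strict where unsaturated
})

test_that("fit recovers known generating weights on seeded synthetic designs", {
  sp <- default_mmi_space()
  spec <- table1_feature_spec(sp)
  truth <- setNames(oracle_weights, spec$terms)
  b0 <- -44.010077
  obs <- make_synthetic_obs(sp, spec, b0, truth, n_sets = 200,
                            n_real = 1000, seed = 101)
  fit <- fit_lrm(obs, sp, spec)
  z <- abs(fit$weights - truth) / fit$se
  expect_gte(mean(z <= 3), 0.95)
  expect_identical(fit$provenance, "fitted")
  expect_lte(fit$log_likelihood, 0)
})

test_that("two-point single-covariate fit matches the closed form", {
  sp <- mmi_space("x", 0, 1)
  n <- 1e6
  obs <- data.frame(x = c(0, 1),
                    k = round(c(0.269, 0.731) * n), n = n)
  fit <- fit_lrm(obs, sp, linear_feature_spec(sp))
  # logit(0.731) - logit(0.269) ~ 2, logit(0.269) ~ -1
  expect_equal(unname(fit$weights["x"]), 2.0, tolerance = 0.01)
  expect_equal(fit$intercept, -1.0, tolerance = 0.01)
})

test_that("symmetric half-events data yields a null model", {
  sp <- toy_space_2d()
  set.seed(3)
  obs <- as.data.frame(sample_roi(sp, 30))
  obs$k <- 50L
  obs$n <- 100L
  fit <- fit_lrm(obs, sp,
                 feature_spec(c("x", "y", "x^2", "x*y"), sp))
  expect_equal(unname(fit$weights), rep(0, 4), tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
})

test_that("weight recovery bias shrinks as realizations per set grow", {
  sp <- toy_space_2d()
  spec <- linear_feature_spec(sp)
  truth <- c(x = 4, y = -3)
  err <- vapply(c(100, 1000, 10000), function(n_real) {
    obs <- make_synthetic_obs(sp, spec, -0.5, truth, n_sets = 150,
                              n_real = n_real, seed = 500 + n_real)
    fit <- fit_lrm(obs, sp, spec)
    sqrt(mean((fit$weights - truth)^2))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.1)
})

test_that("separation and under-determined designs raise typed errors", {
  sp <- mmi_space("x", 0, 1)
  # perfectly separated: all-0 then all-1 outcomes
  obs <- data.frame(x = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                    k = c(0, 0, 0, 100, 100, 100), n = 100)
  expect_error(fit_lrm(obs, sp, linear_feature_spec(sp)),
               class = "ebprob_error")
  # fewer observations than parameters
  expect_error(
    fit_lrm(data.frame(x = 0.5, k = 3, n = 10), sp,
            feature_spec(c("x", "x^2"), sp)),
    "at least")
  # malformed counts are reported by row
  expect_error(
    fit_lrm(data.frame(x = c(0.1, 0.5), k = c(2, 12), n = c(10, 10)),
            sp, linear_feature_spec(sp)),
    "row")
})

test_that("predicted probabilities are invariant to affine feature rescaling", {
  # Fitting on a space with rescaled bounds changes the scaled coordinates
  # affinely; the fitted probabilities must agree.
  spec_terms <- c("x", "y", "x^2", "x*y")
  sp1 <- mmi_space(c("x", "y"), min = c(0, 0), max = c(1, 1))
  sp2 <- mmi_space(c("x", "y"), min = c(-2, 0.2), max = c(3, 0.8))
  set.seed(11)
  pts <- sample_roi(sp2, 60)
  X <- expand_features(scale_mmi(pts, sp1), feature_spec(spec_terms, sp1))
  p <- plogis(-0.3 + as.numeric(X %*% c(2.5, -1.5, 1.2, 0.8)))
  obs <- as.data.frame(pts)
  obs$k <- rbinom(60, 500, p)
  obs$n <- 500L
  f1 <- fit_lrm(obs, sp1, feature_spec(spec_terms, sp1))
  f2 <- fit_lrm(obs, sp2, feature_spec(spec_terms, sp2))
  expect_equal(predict_probability(f1, pts), predict_probability(f2, pts),
               tolerance = 1e-8)
})

test_that("feature ranking orders by |weight| with canonical tie-break", {
  m <- table1_model()
  expect_identical(rank_features(m)$feature, m$spec$terms)
  # tie: equal |weights| fall back to spec order
  sp <- toy_space_2d()
  mt <- structure(list(space = sp, spec = feature_spec(c("x", "y"), sp),
                       intercept = 0, weights = c(x = -2, y = 2),
                       se = c(x = 0.1, y = 0.1)),
                  class = "ebprob_lrm")
  expect_identical(rank_features(mt)$feature, c("x", "y"))
})

test_that("sub-models keep the top-ranked features and full refit matches", {
  sp <- default_mmi_space()
  spec <- table1_feature_spec(sp)
  truth <- setNames(oracle_weights, spec$terms)
  obs <- make_synthetic_obs(sp, spec, -44.010077, truth, n_sets = 200,
                            n_real = 200, seed = 77)
  full <- fit_lrm(obs, sp, spec)
  same <- submodel(full, obs, n_features(spec))
  expect_equal(sort(names(same$weights)), sort(names(full$weights)))
  expect_equal(same$weights[full$spec$terms], full$weights, tolerance = 1e-6)
  # published ranking: top 7 is the smallest sub-model with all four MMIs
  m <- table1_model()
  top7 <- rank_features(m)$feature[1:7]
  expect_true(all(sp$name %in% top7))
  expect_false(all(sp$name %in% rank_features(m)$feature[1:6]))
  sub7 <- submodel(full, obs, 7)
  expect_true(all(sp$name %in% names(sub7$weights)))
  expect_error(submodel(full, obs, 0), "between")
  expect_error(submodel(full, obs, 11), "between")
})

test_that("validation metrics match direct arithmetic", {
  sp <- mmi_space("x", 0, 1)
  m <- structure(list(space = sp, spec = linear_feature_spec(sp),
                      intercept = qlogis(0.3), weights = c(x = 0),
                      se = c(x = NA_real_)), class = "ebprob_lrm")
  # predictions are 0.3 and (via a second model) arbitrary; use two sets
  obs <- data.frame(x = c(0.2, 0.8), k = c(2, 8), n = 10)
  v <- validate_lrm(m, obs)
  # phat = (0.2, 0.8); predictions both 0.3 -> errors (0.1, 0.5)
  expect_equal(v$mean_abs_error, 0.3)
  expect_equal(v$n_transition, 2L)
  expect_true(is.na(v$r2_transition))  # fewer than 3 transition sets
  # exact predictions give zero error and unit R^2
  m2 <- structure(list(space = sp, spec = linear_feature_spec(sp),
                       intercept = 0, weights = c(x = 4),
                       se = c(x = NA_real_)), class = "ebprob_lrm")
  xs <- seq(0.05, 0.95, length.out = 9)
  ph <- predict_probability(m2, cbind(x = xs))
  obs2 <- data.frame(x = xs, k = round(ph * 1e6), n = 1e6)
  v2 <- validate_lrm(m2, obs2)
  expect_lt(v2$mean_abs_error, 1e-6)
  expect_equal(v2$r2_transition, 1, tolerance = 1e-6)
})
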