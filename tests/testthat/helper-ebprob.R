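# Shared fixtures: published MMI sets and an independent hand-arithmetic
# oracle for the reconstructed model, kept free of package scaling/feature
# code so it can cross-check that path.

set1 <- c(ca_i_ini = 150, ca_sr_ini = 500, g_k1_sf = 0.338, k_ryr_sf = 1)
set2 <- c(ca_i_ini = 150, ca_sr_ini = 500, g_k1_sf = 0.638, k_ryr_sf = 1)
set3 <- c(ca_i_ini = 150, ca_sr_ini = 500, g_k1_sf = 0.000, k_ryr_sf = 1)
default_set <- c(ca_i_ini = 100, ca_sr_ini = 700, g_k1_sf = 1, k_ryr_sf = 1)
normal_gk1_point <- c(ca_i_ini = 150, ca_sr_ini = 550, g_k1_sf = 1,
                      k_ryr_sf = 1)
hf_gk1_point <- c(ca_i_ini = 150, ca_sr_ini = 550, g_k1_sf = 0.51,
                  k_ryr_sf = 1)

# Published weights in importance order.
oracle_weights <- c(71.27, 44.37, -24.41, -15.36, -13.45,
                    12.77, -7.98, -3.62, -2.68, -2.48)

# Feature vector at a point, by direct arithmetic (importance order:
# sr, k, sr^2, sr*k, k^2, i, g, g^2, i^2, g*k on scaled coordinates).
oracle_features <- function(pt) {
  xi <- (pt[["ca_i_ini"]] - 100) / 200
  xs <- (pt[["ca_sr_ini"]] - 300) / 400
  xg <- pt[["g_k1_sf"]]
  xk <- (pt[["k_ryr_sf"]] - 0.5) / 1
  c(xs, xk, xs^2, xs * xk, xk^2, xi, xg, xg^2, xi^2, xg * xk)
}

# Hand-summation linear predictor with the set-1 anchor intercept.
oracle_lp <- function(pt) {
  b0 <- 0 - sum(oracle_weights * oracle_features(set1))
  b0 + sum(oracle_weights * oracle_features(pt))
}

oracle_prob <- function(pt) 1 / (1 + exp(-oracle_lp(pt)))

# A small 2-axis space for cheap synthetic fits.
toy_space_2d <- function() {
  mmi_space(c("x", "y"), min = c(0, 0), max = c(1, 1))
}

# Synthetic count observations from a known logistic surface over a space.
make_synthetic_obs <- function(space, spec, intercept, weights, n_sets,
                               n_real, seed) {
  set.seed(seed)
  pts <- sample_roi(space, n_sets)
  X <- expand_features(scale_mmi(pts, space), spec)
  p <- plogis(intercept + as.numeric(X %*% weights))
  obs <- as.data.frame(pts)
  obs$k <- rbinom(n_sets, n_real, p)
  obs$n <- n_real
  obs
}
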