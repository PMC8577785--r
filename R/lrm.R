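#' Fit a binomial logistic surrogate model
#'
#' Fits the logistic regression `P(event) = 1 / (1 + exp(-(b0 + B'P)))` by
#' maximum likelihood to per-set event counts, where the features `P` are
#' min-max-scaled MMIs and optional quadratic terms. The likelihood uses the
#' binomial counts `(k, n)` per MMI set directly (identical maximum-likelihood
#' solution to expanded per-realization rows, at a fraction of the cost).
#' Fitting is by iteratively reweighted least squares via [stats::glm.fit].
#'
#' @param observations data frame with one column per axis of `space` (native
#'   units), plus integer columns `k` (events) and `n` (realizations).
#' @param space the [mmi_space] fixing the scaling bounds; these are frozen
#'   into the fitted model and never re-derived from data.
#' @param spec a [feature_spec]; default all linear features.
#' @param max_iter,epsilon IRLS iteration cap and relative deviance
#'   convergence tolerance.
#' @return An object of class `ebprob_lrm`: list with `space`, `spec`,
#'   `intercept`, `weights` (named, spec order), `se` (Wald standard errors
#'   from the observed information, including the intercept's as
#'   `se_intercept`), `log_likelihood` (nats, binomial), `n_obs`,
#'   `provenance = "fitted"`.
#' @examples
#' cfg <- toy_model_config()
#' pts <- sample_roi(cfg$space, 50, seed = 1)
#' obs <- simulate_batches(cfg, pts, n = 100, seed = 2)
#' fit <- fit_lrm(obs, cfg$space)
#' fit
#' @export
fit_lrm <- function(observations, space, spec = linear_feature_spec(space),
                    max_iter = 100L, epsilon = 1e-10) {
  obs <- validate_observations(observations, space)
  if (nrow(obs) < n_features(spec) + 1L) {
    stop_ebprob(paste0("need at least ", n_features(spec) + 1L,
                       " observations to fit ", n_features(spec),
                       " features plus an intercept; got ", nrow(obs)),
                "ebprob_fit_error")
  }
  phat <- obs$k / obs$n
  if (length(unique(phat)) == 1L && nrow(obs) > 1L && stats::var(phat) == 0 &&
      (phat[1] %in% c(0, 1))) {
    stop_ebprob("all observed event frequencies are identically 0 or 1; the model is not identifiable",
                "ebprob_separation_error")
  }
  X <- expand_features(scale_mmi(obs[, space$name, drop = FALSE], space), spec)
  Xd <- cbind(`(intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(
    x = Xd, y = phat, weights = obs$n, family = stats::binomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = max_iter)
  ))
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    stop_ebprob("fit produced aliased (collinear) features; reduce the spec",
                "ebprob_fit_error")
  }
  separated <- all(phat %in% c(0, 1)) &&
    all(abs(fit$fitted.values - phat) < 1e-6) && max(abs(coefs)) > 25
  if (separated || (!fit$converged && max(abs(coefs)) > 1e3)) {
    stop_ebprob(
      paste0("complete separation detected: every fitted probability is 0 ",
             "or 1 and weights are unbounded (max |weight| = ",
             format(max(abs(coefs)), digits = 4), " after ", fit$iter,
             " iterations)"),
      "ebprob_separation_error", iterations = fit$iter)
  }
  if (!fit$converged) {
    stop_ebprob(paste0("IRLS did not converge in ", fit$iter, " iterations"),
                "ebprob_fit_error", iterations = fit$iter)
  }
  mu <- fit$fitted.values
  # Observed = expected information for the canonical logit link.
  W <- obs$n * mu * (1 - mu)
  info <- crossprod(Xd * sqrt(W))
  se <- rep(NA_real_, ncol(Xd))
  cv <- try(chol2inv(chol(info)), silent = TRUE)
  if (!inherits(cv, "try-error")) se <- sqrt(pmax(diag(cv), 0))
  ll <- sum(stats::dbinom(obs$k, obs$n, mu, log = TRUE))
  structure(
    list(space = space, spec = spec,
         intercept = unname(coefs[1]),
         weights = stats::setNames(coefs[-1], spec$terms),
         se = stats::setNames(se[-1], spec$terms),
         se_intercept = se[1],
         log_likelihood = ll,
         n_obs = nrow(obs),
         n_trials = sum(obs$n),
         provenance = "fitted"),
    class = "ebprob_lrm"
  )
}

validate_observations <- function(observations, space) {
  obs <- as.data.frame(observations)
  missing <- setdiff(c(space$name, "k", "n"), colnames(obs))
  if (length(missing)) {
    stop("observations missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(obs) == 0L) stop("no observations")
  bad <- which(obs$k < 0 | obs$k > obs$n | obs$n < 1)
  if (length(bad)) {
    stop("invalid event counts (need 0 <= k <= n, n >= 1) at row(s): ",
         paste(bad, collapse = ", "))
  }
  obs
}

#' @export
print.ebprob_lrm <- function(x, ...) {
  cat("Logistic surrogate model (", x$provenance, "), ",
      n_features(x$spec), " features over ", space_dim(x$space),
      " MMIs\n", sep = "")
  cat("  intercept: ", format(x$intercept, digits = 6), "\n", sep = "")
  tab <- rank_features(x)
  print(tab, row.names = FALSE, digits = 4)
  if (!is.na(x$log_likelihood)) {
    cat("  log-likelihood:", format(x$log_likelihood, digits = 6),
        "on", x$n_obs, "MMI sets\n")
  }
  invisible(x)
}

#' Linear predictor of a fitted surrogate
#'
#' The argument of the logistic function: intercept plus the weighted sum of
#' features at the given MMI point(s).
#'
#' @param model an `ebprob_lrm`.
#' @param point MMI point(s) in native units.
#' @return Numeric vector.
#' @export
linear_predictor <- function(model, point) {
  X <- expand_features(scale_mmi(point, model$space), model$spec)
  as.numeric(model$intercept + X %*% model$weights)
}

#' Predicted event probability
#'
#' Applies the logistic function to [linear_predictor]; numerically stable
#' for arbitrarily large magnitudes of the argument.
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of probabilities.
#' @examples
#' m <- table1_model()
#' predict_probability(m, c(ca_i_ini = 150, ca_sr_ini = 500,
#'                          g_k1_sf = 0.638, k_ryr_sf = 1))
#' @export
predict_probability <- function(model, point) {
  logistic(linear_predictor(model, point))
}

#' @export
predict.ebprob_lrm <- function(object, newdata,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- linear_predictor(object, newdata)
  if (type == "link") eta else logistic(eta)
}

#' Construct a surrogate from published weights and an anchor point
#'
#' When a model's weights are published without its intercept, the intercept
#' can be recovered from any point with a known predicted probability:
#' `intercept = logit(p_anchor) - B' P(anchor)`.
#'
#' @param weights named weight vector (scaled-feature domain).
#' @param space,spec the [mmi_space] and [feature_spec].
#' @param anchor MMI point (native units) with known probability.
#' @param anchor_p the model probability at `anchor`, strictly in (0, 1).
#' @return The intercept (dimensionless).
#' @export
derive_intercept_from_anchor <- function(weights, space, spec, anchor,
                                         anchor_p) {
  if (!is.numeric(anchor_p) || length(anchor_p) != 1L ||
      anchor_p <= 0 || anchor_p >= 1) {
    stop("'anchor_p' must lie strictly in (0, 1)")
  }
  X <- expand_features(scale_mmi(anchor, space), spec)
  w <- stats::setNames(numeric(n_features(spec)), spec$terms)
  w[names(weights)] <- weights
  as.numeric(logit(anchor_p) - X %*% w)
}

#' Rank model features by importance
#'
#' Because all features share the scaled `[0, 1]` domain, the absolute weight
#' is directly comparable across features and serves as the importance
#' measure. Ties are broken by the canonical (spec) term order.
#'
#' @param model an `ebprob_lrm`.
#' @return Data frame with columns `feature`, `weight`, `se`, ordered by
#'   decreasing `|weight|`.
#' @export
rank_features <- function(model) {
  ord <- order(-abs(model$weights), seq_along(model$weights))
  data.frame(feature = model$spec$terms[ord],
             weight = unname(model$weights[ord]),
             se = unname(model$se[ord]),
             stringsAsFactors = FALSE)
}

#' Refit a surrogate on its top-ranked features
#'
#' Builds the sub-model containing only the `top_n` most important features
#' (plus intercept), refitted on the same observations, for assessing how
#' many features the surrogate actually needs.
#'
#' @param model a fitted `ebprob_lrm`.
#' @param observations the training observations.
#' @param top_n number of features to keep, between 1 and the feature count.
#' @return A fitted `ebprob_lrm`.
#' @export
submodel <- function(model, observations, top_n) {
  p <- n_features(model$spec)
  if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1 || top_n > p) {
    stop("'top_n' must be between 1 and ", p)
  }
  keep <- rank_features(model)$feature[seq_len(as.integer(top_n))]
  # preserve canonical order within the reduced spec
  keep <- model$spec$terms[model$spec$terms %in% keep]
  fit_lrm(observations, model$space, feature_spec(keep, model$space))
}

#' Validate a surrogate against observed event frequencies
#'
#' Computes the mean and SD of the absolute prediction error
#' `|phat_i - P_i(model)|` over all observations, and the coefficient of
#' determination of the ordinary least-squares regression of predicted on
#' observed probabilities, both over all sets (`r2_all`) and restricted to
#' the transition domain (`r2_transition`; sets with `0 < k/n < 1`, the only
#' region where the probability is informative).
#'
#' @param model an `ebprob_lrm`.
#' @param observations data frame of batch observations.
#' @return A list of class `ebprob_validation`: `r2_all`, `r2_transition`,
#'   `mean_abs_error`, `sd_abs_error`, `n_transition`, `n_obs`.
#'   `r2_transition` is `NA` when fewer than 3 transition sets exist.
#' @export
validate_lrm <- function(model, observations) {
  obs <- validate_observations(observations, model$space)
  phat <- obs$k / obs$n
  pred <- predict_probability(model, obs[, model$space$name, drop = FALSE])
  abserr <- abs(phat - pred)
  trans <- phat > 0 & phat < 1
  r2 <- function(y, yhat) {
    if (length(y) < 3L || stats::var(y) == 0) return(NA_real_)
    summary(stats::lm(yhat ~ y))$r.squared
  }
  structure(
    list(r2_all = r2(phat, pred),
         r2_transition = r2(phat[trans], pred[trans]),
         mean_abs_error = mean(abserr),
         sd_abs_error = stats::sd(abserr),
         n_transition = sum(trans),
         n_obs = nrow(obs)),
    class = "ebprob_validation"
  )
}

#' @export
print.ebprob_validation <- function(x, ...) {
  cat("Surrogate validation on", x$n_obs, "MMI sets (",
      x$n_transition, "in transition domain)\n")
  cat("  mean |error|:", format(x$mean_abs_error, digits = 4),
      "+/-", format(x$sd_abs_error, digits = 4), "\n")
  cat("  R^2 (all):", format(x$r2_all, digits = 4),
      " R^2 (transition):", format(x$r2_transition, digits = 4), "\n")
  invisible(x)
}
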