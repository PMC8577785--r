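#' Configuration for the two-iteration surrogate-building pipeline
#'
#' @param space the [mmi_space] region of interest.
#' @param sets_per_iteration MMI sets sampled per iteration (default 100).
#' @param realizations_per_set stochastic realizations per MMI set
#'   (default 100).
#' @param transition_band probability interval defining the transition domain
#'   under the preliminary model (default `c(0.025, 0.975)`, the smallest
#'   probabilities resolvable at 100 realizations per set).
#' @param criterion model-selection criterion, `"caic"` (consistent AIC,
#'   default) or `"aic"`.
#' @param sample_size_convention sample size entering the CAIC penalty:
#'   `"total_trials"` (sum of realizations, default) or `"n_sets"`.
#' @param seed integer seed for all pipeline randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(space = default_mmi_space(),
                            sets_per_iteration = 100L,
                            realizations_per_set = 100L,
                            transition_band = c(0.025, 0.975),
                            criterion = c("caic", "aic"),
                            sample_size_convention = c("total_trials", "n_sets"),
                            seed = NULL) {
  criterion <- match.arg(criterion)
  sample_size_convention <- match.arg(sample_size_convention)
  if (sets_per_iteration < 1 || realizations_per_set < 1) {
    stop("counts must be >= 1")
  }
  tb <- as.numeric(transition_band)
  if (length(tb) != 2L || tb[1] <= 0 || tb[2] >= 1 || tb[1] >= tb[2]) {
    stop("'transition_band' must satisfy 0 < low < high < 1")
  }
  structure(
    list(space = space,
         sets_per_iteration = as.integer(sets_per_iteration),
         realizations_per_set = as.integer(realizations_per_set),
         transition_band = tb, criterion = criterion,
         sample_size_convention = sample_size_convention, seed = seed),
    class = "pipeline_config"
  )
}

#' Sample MMI points uniformly over the region of interest
#'
#' Each coordinate is drawn independently and uniformly over its axis bounds.
#'
#' @param space an [mmi_space].
#' @param n number of points.
#' @param seed optional integer seed.
#' @return Numeric matrix, one row per point, columns in axis order.
#' @export
sample_roi <- function(space, n, seed = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  with_seed(seed, {
    m <- vapply(seq_len(space_dim(space)), function(j) {
      stats::runif(n, space$min[j], space$max[j])
    }, numeric(n))
    m <- matrix(m, nrow = n, dimnames = list(NULL, space$name))
    m
  })
}

#' Sample MMI points from the transition domain of a preliminary model
#'
#' Rejection sampling: uniform proposals over the region of interest are
#' accepted when the preliminary model's predicted probability falls inside
#' `band`. The transition domain is an implicit nonlinear region of the MMI
#' space, so rejection is exact and simple. Errors if the acceptance rate
#' over the proposal budget falls below `min_rate` (advice: widen the band).
#'
#' @param space an [mmi_space].
#' @param prelim_model an `ebprob_lrm` from the first iteration.
#' @param n number of accepted points required.
#' @param band probability interval, default `c(0.025, 0.975)`.
#' @param seed optional integer seed.
#' @param min_rate minimum tolerated acceptance rate (default 1e-5).
#' @return Numeric matrix of `n` accepted points.
#' @export
sample_transition <- function(space, prelim_model, n,
                              band = c(0.025, 0.975), seed = NULL,
                              min_rate = 1e-5) {
  if (n < 1) stop("'n' must be >= 1")
  budget <- max(1e5, ceiling(n / min_rate))
  with_seed(seed, {
    accepted <- matrix(numeric(0), ncol = space_dim(space),
                       dimnames = list(NULL, space$name))
    proposed <- 0
    chunk <- max(1000L, 10L * n)
    while (nrow(accepted) < n && proposed < budget) {
      pts <- sample_roi(space, chunk)
      proposed <- proposed + chunk
      p <- predict_probability(prelim_model, pts)
      ok <- p > band[1] & p < band[2]
      if (any(ok)) accepted <- rbind(accepted, pts[ok, , drop = FALSE])
    }
    if (nrow(accepted) < n) {
      stop_ebprob(
        paste0("transition-domain acceptance rate ",
               format(nrow(accepted) / proposed, digits = 3),
               " below ", min_rate, " over ", proposed,
               " proposals; widen the transition band"),
        "ebprob_sampling_error")
    }
    accepted[seq_len(n), , drop = FALSE]
  })
}

#' Akaike-type information criteria for count-based logistic fits
#'
#' Consistent AIC (Bozdogan): `-2 logL + k (ln N + 1)`; ordinary AIC:
#' `-2 logL + 2 k`.
#'
#' @param log_likelihood maximized log-likelihood in nats.
#' @param n_params number of free parameters (features + intercept).
#' @param sample_size sample size `N` entering the CAIC penalty.
#' @param criterion `"caic"` (default) or `"aic"`.
#' @return The criterion value (smaller is better).
#' @export
caic <- function(log_likelihood, n_params, sample_size,
                 criterion = c("caic", "aic")) {
  criterion <- match.arg(criterion)
  if (criterion == "caic" && sample_size < 1) stop("'sample_size' must be >= 1")
  if (criterion == "caic") {
    -2 * log_likelihood + n_params * (log(sample_size) + 1)
  } else {
    -2 * log_likelihood + 2 * n_params
  }
}

#' Exhaustive quadratic-feature selection by information criterion
#'
#' Fits every candidate feature set consisting of all linear features plus
#' one of the `2^q` subsets of quadratic terms (`q = d(d+1)/2`; 1024
#' candidates for four MMIs) and returns the criterion-minimizing
#' specification. Ties are broken deterministically: fewer terms first, then
#' lexicographic order of the term labels. Individual fit failures are
#' skipped with a warning.
#'
#' @param observations training batch observations (both iterations pooled).
#' @param space an [mmi_space] (exhaustive search supported up to 5 axes).
#' @param criterion `"caic"` or `"aic"`.
#' @param sample_size_convention `"total_trials"` or `"n_sets"`.
#' @param return_table if `TRUE`, attach the full selection table (one row
#'   per candidate with its criterion value) as attribute `"selection_table"`.
#' @return The selected [feature_spec].
#' @export
select_feature_set <- function(observations, space,
                               criterion = c("caic", "aic"),
                               sample_size_convention = c("total_trials", "n_sets"),
                               return_table = FALSE) {
  criterion <- match.arg(criterion)
  sample_size_convention <- match.arg(sample_size_convention)
  if (space_dim(space) > 5L) {
    stop("exhaustive selection supported for at most 5 axes (",
         2^(5 * 6 / 2), " fits); reduce the space")
  }
  obs <- validate_observations(observations, space)
  quad <- quadratic_candidates(space)
  nq <- length(quad)
  N <- if (sample_size_convention == "total_trials") sum(obs$n) else nrow(obs)
  rows <- vector("list", 2^nq)
  best <- NULL
  for (s in seq_len(2^nq)) {
    mask <- as.logical(bitwAnd(s - 1L, bitwShiftL(1L, seq_len(nq) - 1L)))
    terms <- c(space$name, quad[mask])
    spec <- feature_spec(terms, space)
    fit <- tryCatch(fit_lrm(obs, space, spec),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("candidate {", paste(quad[mask], collapse = ", "),
              "} skipped: ", conditionMessage(fit))
      next
    }
    crit <- caic(fit$log_likelihood, n_features(spec) + 1L, N, criterion)
    rows[[s]] <- data.frame(
      quadratic = paste(quad[mask], collapse = "+"),
      n_terms = n_features(spec), criterion = crit,
      stringsAsFactors = FALSE)
    better <- is.null(best) ||
      crit < best$crit ||
      (crit == best$crit && (n_features(spec) < n_features(best$spec) ||
        (n_features(spec) == n_features(best$spec) &&
           paste(sort(terms), collapse = "|") <
             paste(sort(best$spec$terms), collapse = "|"))))
    if (better) best <- list(spec = spec, crit = crit)
  }
  if (is.null(best)) {
    stop_ebprob("every candidate feature set failed to fit",
                "ebprob_fit_error")
  }
  out <- best$spec
  if (return_table) {
    attr(out, "selection_table") <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  out
}

#' Run the two-iteration surrogate-building pipeline
#'
#' Iteration 1 samples the region of interest uniformly, simulates event
#' batches, and fits a linear-features-only preliminary model. Iteration 2
#' resamples inside the transition domain of that model (where the event
#' probability is informative), simulates again, pools both iterations'
#' observations, selects the quadratic feature subset by exhaustive
#' information-criterion search, and fits the final model.
#'
#' @param config a [pipeline_config].
#' @param simulator a [toy_model_config] (or any object usable with
#'   [simulate_batches]) standing in for the expensive stochastic model.
#' @return A list of class `ebprob_pipeline`: `model` (final `ebprob_lrm`),
#'   `iterations` (list of two, each with `observations` and `model`),
#'   `selected_spec`, and the `config`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sets_per_iteration = 50, seed = 1)
#' run <- run_two_iteration_pipeline(cfg, toy_model_config())
#' run$model
#' }
#' @export
run_two_iteration_pipeline <- function(config, simulator) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_ebprob(paste0("pipeline stage '", what, "': ",
                         conditionMessage(e)), "ebprob_pipeline_error")
    })
  }
  # iteration 1: uniform design, linear-only preliminary fit
  pts1 <- stage("sample_roi",
                sample_roi(config$space, config$sets_per_iteration,
                           seed = child_seed(seed, 1L)))
  obs1 <- stage("simulate (iteration 1)",
                simulate_batches(simulator, pts1,
                                 n = config$realizations_per_set,
                                 seed = child_seed(seed, 2L)))
  m1 <- stage("fit (iteration 1, linear features)",
              fit_lrm(obs1, config$space, linear_feature_spec(config$space)))
  # iteration 2: transition-domain resampling under the preliminary model
  pts2 <- stage("sample_transition",
                sample_transition(config$space, m1,
                                  config$sets_per_iteration,
                                  band = config$transition_band,
                                  seed = child_seed(seed, 3L)))
  obs2 <- stage("simulate (iteration 2)",
                simulate_batches(simulator, pts2,
                                 n = config$realizations_per_set,
                                 seed = child_seed(seed, 4L)))
  pooled <- rbind(obs1, obs2)
  pooled$iteration <- rep(1:2, c(nrow(obs1), nrow(obs2)))
  spec <- stage("select_feature_set",
                select_feature_set(pooled, config$space,
                                   criterion = config$criterion,
                                   sample_size_convention =
                                     config$sample_size_convention,
                                   return_table = TRUE))
  final <- stage("fit (final)", fit_lrm(pooled, config$space, spec))
  structure(
    list(model = final,
         iterations = list(
           list(iteration = 1L, observations = obs1, model = m1),
           list(iteration = 2L, observations = obs2)),
         selected_spec = spec,
         pooled_observations = pooled,
         config = config),
    class = "ebprob_pipeline"
  )
}

#' @export
print.ebprob_pipeline <- function(x, ...) {
  cat("Two-iteration surrogate pipeline:",
      nrow(x$pooled_observations), "pooled MMI sets x",
      x$config$realizations_per_set, "realizations\n")
  quad <- setdiff(x$selected_spec$terms, x$config$space$name)
  cat("Selected quadratic terms:",
      if (length(quad)) paste(quad, collapse = ", ") else "(none)", "\n")
  print(x$model)
  invisible(x)
}
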