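#' Specify normally distributed uncertainty on MMIs
#'
#' Each axis gets a mean and a standard deviation in native units; axes with
#' `sigma = 0` are held fixed. Draws are independent normals with no
#' truncation at the region-of-interest bounds — the surrogate extrapolates,
#' which is required when a mean sits on a boundary of the region.
#'
#' @param mean named numeric vector, one mean per axis of `space`.
#' @param sigma named numeric vector of standard deviations (>= 0); axes
#'   omitted default to 0 (fixed).
#' @param space an [mmi_space].
#' @return A list of class `uncertainty_spec` with `mean` and `sigma` in
#'   axis order.
#' @examples
#' uncertainty_spec(
#'   mean = c(ca_i_ini = 150, ca_sr_ini = 550, g_k1_sf = 1, k_ryr_sf = 1),
#'   sigma = c(g_k1_sf = 0.1108), space = default_mmi_space())
#' @export
uncertainty_spec <- function(mean, sigma = numeric(0),
                             space = default_mmi_space()) {
  nm <- space$name
  mv <- as.numeric(as_point_matrix(mean, space))
  sv <- stats::setNames(numeric(length(nm)), nm)
  if (length(sigma)) {
    unknown <- setdiff(names(sigma), nm)
    if (is.null(names(sigma)) || length(unknown)) {
      stop("'sigma' must be named by axes; unknown: ",
           paste(unknown, collapse = ", "))
    }
    sv[names(sigma)] <- sigma
  }
  if (any(sv < 0)) stop("'sigma' entries must be >= 0")
  structure(list(mean = stats::setNames(mv, nm), sigma = sv, axes = nm),
            class = "uncertainty_spec")
}

new_probability_distribution <- function(samples, n_bins, analytic = FALSE,
                                         masses = NULL, seed = NULL) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  if (is.null(masses)) {
    idx <- pmin(pmax(ceiling(samples * n_bins), 1L), n_bins)
    masses <- tabulate(idx, nbins = n_bins) / length(samples)
    mean_p <- mean(samples)
    sd_p <- stats::sd(samples)
    n_samples <- length(samples)
  } else {
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    mean_p <- sum(masses * mids)
    sd_p <- sqrt(max(0, sum(masses * mids^2) - mean_p^2))
    n_samples <- NA_integer_
  }
  dist <- structure(
    list(samples = if (analytic) NULL else samples,
         analytic = analytic,
         bin_edges = edges, masses = masses,
         mean = mean_p, sd = sd_p,
         n_samples = n_samples, seed = seed),
    class = "probability_distribution")
  dist$entropy <- dist_entropy(dist)
  dist$modality <- classify_modality(dist)
  dist
}

#' @export
print.probability_distribution <- function(x, ...) {
  cat("P(event) distribution (",
      if (x$analytic) "analytic" else paste0(x$n_samples, " MC samples"),
      "), ", length(x$masses), " bins\n", sep = "")
  cat("  mean ", format(x$mean, digits = 4), ", sd ", format(x$sd, digits = 4),
      ", entropy ", format(x$entropy, digits = 4), " nats, ",
      x$modality, "\n", sep = "")
  invisible(x)
}

#' Monte Carlo propagation of MMI uncertainty through a surrogate
#'
#' Draws each uncertain MMI independently from its normal distribution
#' (no truncation), evaluates the surrogate per draw, and summarizes the
#' resulting distribution of event probabilities: histogram on `[0, 1]`,
#' mean, SD, Shannon entropy of the bin masses, and a modality label.
#'
#' @param model an `ebprob_lrm`.
#' @param uspec an [uncertainty_spec].
#' @param n_samples Monte Carlo sample count (default `1e6`).
#' @param seed optional integer seed.
#' @param n_bins histogram bin count (default 100 equal bins on `[0, 1]`).
#' @return A `probability_distribution`.
#' @examples
#' m <- table1_model()
#' us <- uncertainty_spec(
#'   mean = c(ca_i_ini = 150, ca_sr_ini = 550, g_k1_sf = 1, k_ryr_sf = 1),
#'   sigma = c(g_k1_sf = 0.1108), space = m$space)
#' propagate_mc(m, us, n_samples = 1e5, seed = 1)
#' @export
propagate_mc <- function(model, uspec, n_samples = 1e6, seed = NULL,
                         n_bins = 100L) {
  stopifnot(inherits(uspec, "uncertainty_spec"))
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  n_samples <- as.integer(n_samples)
  nm <- model$space$name
  with_seed(seed, {
    pts <- matrix(rep(uspec$mean[nm], each = n_samples), nrow = n_samples,
                  dimnames = list(NULL, nm))
    for (ax in nm[uspec$sigma[nm] > 0]) {
      pts[, ax] <- stats::rnorm(n_samples, uspec$mean[ax], uspec$sigma[ax])
    }
    p <- predict_probability(model, pts)
    new_probability_distribution(p, n_bins = n_bins, seed = seed)
  })
}

#' Logit-normal probability density
#'
#' Density of `logistic(Y)` with `Y ~ N(mu_y, sigma_y^2)` — the exact
#' distribution of a surrogate probability when the uncertain input enters
#' the linear predictor only linearly.
#'
#' @param p probabilities strictly in (0, 1).
#' @param mu_y,sigma_y mean and SD of the normal linear predictor;
#'   `sigma_y > 0`.
#' @return Density values.
#' @examples
#' logit_normal_pdf(0.5, 0, 1)   # 4 / sqrt(2 * pi)
#' @export
logit_normal_pdf <- function(p, mu_y, sigma_y) {
  if (sigma_y <= 0) stop("'sigma_y' must be positive")
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)")
  stats::dnorm(logit(p), mu_y, sigma_y) / (p * (1 - p))
}

#' Analytic propagated distribution where the logit-normal form applies
#'
#' With exactly one uncertain MMI that appears in no quadratic feature, the
#' linear predictor is normal and the propagated probability is exactly
#' logit-normal with `mu_y` the linear predictor at the mean point and
#' `sigma_y = |weight| * sigma / (max - min)` (the weight acting on the
#' scaled coordinate). Otherwise (several uncertain axes, or the uncertain
#' axis enters a quadratic term) the analytic form does not apply and `NULL`
#' is returned; fall back to [propagate_mc].
#'
#' @param model an `ebprob_lrm`.
#' @param uspec an [uncertainty_spec].
#' @param n_bins histogram bin count for the returned summary.
#' @return A `probability_distribution` with `analytic = TRUE` (and fields
#'   `mu_y`, `sigma_y`), or `NULL` when not applicable.
#' @export
analytic_distribution <- function(model, uspec, n_bins = 100L) {
  stopifnot(inherits(uspec, "uncertainty_spec"))
  nm <- model$space$name
  uncertain <- nm[uspec$sigma[nm] > 0]
  if (length(uncertain) != 1L) return(NULL)
  ax <- uncertain
  in_quad <- vapply(model$spec$parsed, function(tp) {
    tp$type == "quadratic" && ax %in% tp$axes
  }, logical(1))
  if (any(in_quad)) return(NULL)
  if (!(ax %in% model$spec$terms)) return(NULL)
  j <- match(ax, model$space$name)
  scale <- model$space$max[j] - model$space$min[j]
  mu_y <- linear_predictor(model, uspec$mean)
  sigma_y <- abs(model$weights[[ax]]) * uspec$sigma[[ax]] / scale
  if (sigma_y == 0) return(NULL)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  cdf <- stats::pnorm(logit(pmin(pmax(edges, 1e-300), 1 - 1e-16)), mu_y, sigma_y)
  cdf[1] <- 0; cdf[length(cdf)] <- 1
  masses <- diff(cdf)
  dist <- new_probability_distribution(NULL, n_bins = n_bins, analytic = TRUE,
                                       masses = masses)
  # exact moments by quadrature on the logit scale
  mom <- function(k) {
    stats::integrate(function(y) logistic(y)^k * stats::dnorm(y, mu_y, sigma_y),
                     mu_y - 12 * sigma_y, mu_y + 12 * sigma_y,
                     rel.tol = 1e-10)$value
  }
  m1 <- mom(1)
  dist$mean <- m1
  dist$sd <- sqrt(max(0, mom(2) - m1^2))
  dist$mu_y <- mu_y
  dist$sigma_y <- sigma_y
  dist
}

#' Shannon entropy of a propagated probability distribution
#'
#' `H = -sum(m_i log m_i)` in nats over histogram bins with positive mass;
#' 0 for a point mass and `log(n_bins)` for a perfectly uniform histogram.
#'
#' @param dist a `probability_distribution`.
#' @return Entropy in nats.
#' @export
dist_entropy <- function(dist) {
  m <- dist$masses
  m <- m[m > 0]
  -sum(m * log(m))
}

#' Classify the modality of a propagated probability distribution
#'
#' Distinguishes the three patterns the propagated event-probability
#' distribution exhibits as input uncertainty grows: unimodal (mass
#' concentrated around one probability), approximately uniform (mass spread
#' over the whole interval), and bimodal (mass piled at both 0 and 1).
#' The histogram is lightly smoothed (3-bin moving average), local maxima
#' with height at least `prominence` times the tallest bin are treated as
#' peaks, and:
#' \itemize{
#'   \item \strong{bimodal} - peaks present in both edge regions (outermost
#'     `edge_bins` bins at each end);
#'   \item \strong{uniform_like} - otherwise, if no smoothed bin mass exceeds
#'     `uniform_ratio` times the uniform level `1 / n_bins`;
#'   \item \strong{unimodal} - otherwise.
#' }
#'
#' @param dist a `probability_distribution`.
#' @param prominence minimum peak height as a fraction of the tallest
#'   smoothed bin (default 0.2; suppresses sampling noise).
#' @param uniform_ratio flatness threshold on max smoothed mass relative to
#'   the uniform level (default 1.5).
#' @param edge_bins width of each edge region in bins (default 5).
#' @return One of `"unimodal"`, `"uniform_like"`, `"bimodal"`.
#' @export
classify_modality <- function(dist, prominence = 0.2, uniform_ratio = 1.5,
                              edge_bins = 5L) {
  m <- dist$masses
  nb <- length(m)
  # 3-bin moving average; edges averaged over the available neighbours
  sm <- stats::filter(m, rep(1 / 3, 3), sides = 2)
  sm <- as.numeric(sm)
  sm[1] <- mean(m[1:2])
  sm[nb] <- mean(m[(nb - 1):nb])
  peaks <- integer(0)
  d <- diff(sm)
  interior <- which(diff(sign(d)) < 0) + 1L
  if (sm[1] > sm[2]) peaks <- c(peaks, 1L)
  peaks <- c(peaks, interior)
  if (sm[nb] > sm[nb - 1]) peaks <- c(peaks, nb)
  peaks <- peaks[sm[peaks] >= prominence * max(sm)]
  left <- any(peaks <= edge_bins)
  right <- any(peaks > nb - edge_bins)
  if (left && right) return("bimodal")
  if (max(sm) * nb < uniform_ratio) return("uniform_like")
  "unimodal"
}

#' Mean propagated probability as a function of input uncertainty
#'
#' Recomputes the Monte Carlo propagation over a grid of standard deviations
#' for one axis and reports the distribution mean at each; at `sigma = 0`
#' this is the point prediction. As uncertainty grows, mass spills into both
#' plateau domains and the mean converges toward 0.5 whatever the starting
#' point.
#'
#' @param model an `ebprob_lrm`.
#' @param uspec an [uncertainty_spec] supplying the means (its sigma on
#'   `axis` is overridden by the grid).
#' @param axis name of the uncertain axis.
#' @param sigma_grid non-negative increasing vector of SDs (native units).
#' @param n_samples Monte Carlo samples per grid point (default `1e5`).
#' @param seed optional integer seed.
#' @return Data frame with columns `sigma` and `mean_p`.
#' @export
mean_p_vs_sigma <- function(model, uspec, axis, sigma_grid,
                            n_samples = 1e5, seed = NULL) {
  if (any(sigma_grid < 0) || is.unsorted(sigma_grid)) {
    stop("'sigma_grid' must be non-negative and increasing")
  }
  if (!axis %in% model$space$name) stop("unknown axis: ", axis)
  means <- vapply(seq_along(sigma_grid), function(i) {
    s <- sigma_grid[i]
    if (s == 0) return(predict_probability(model, uspec$mean))
    sig <- uspec$sigma
    sig[axis] <- s
    us <- uncertainty_spec(uspec$mean, sig[sig > 0], model$space)
    propagate_mc(model, us, n_samples = n_samples,
                 seed = child_seed(seed, i))$mean
  }, numeric(1))
  data.frame(sigma = sigma_grid, mean_p = means)
}
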