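#' Classify an MMI point into probability domains of a surrogate
#'
#' The region of interest splits into a transition domain, where the event
#' probability responds steeply to the inputs, and lower/upper plateau
#' domains where it is pinned near 0 or 1. A surrogate probability is never
#' exactly 0 or 1, so classification uses a band: `lower_plateau` when
#' `P <= band[1]`, `upper_plateau` when `P >= band[2]`, `transition`
#' otherwise.
#'
#' @param model an `ebprob_lrm`.
#' @param point MMI point(s) in native units.
#' @param band probability band, default `c(0.025, 0.975)`.
#' @return Character vector of labels `"lower_plateau"`, `"transition"`,
#'   `"upper_plateau"`.
#' @export
classify_domain <- function(model, point, band = c(0.025, 0.975)) {
  p <- predict_probability(model, point)
  ifelse(p <= band[1], "lower_plateau",
         ifelse(p >= band[2], "upper_plateau", "transition"))
}

#' Classify observed batches by the strict empirical rule
#'
#' For finite-realization batches the empirical event frequency takes a
#' discrete set of values, so the strict definition applies: a set is in a
#' plateau domain exactly when every realization (or none) produced an event.
#'
#' @param observations data frame with columns `k` and `n`.
#' @return Character vector of domain labels.
#' @export
classify_empirical_domain <- function(observations) {
  k <- observations$k
  n <- observations$n
  ifelse(k == 0, "lower_plateau",
         ifelse(k == n, "upper_plateau", "transition"))
}

#' Model-characteristic (MC) curve along one MMI axis
#'
#' Sweeps the predicted event probability along a grid of one MMI while the
#' other MMIs are held fixed — the one-dimensional characteristic of the
#' surrogate used to reason about uncertainty propagation.
#'
#' @param model an `ebprob_lrm`.
#' @param axis name of the swept axis.
#' @param fixed a full MMI point supplying the fixed values of the other
#'   axes (its value on `axis` is ignored).
#' @param grid_size number of grid points (default 201).
#' @param range 2-vector sweep range in native units; defaults to the
#'   region-of-interest bounds of the axis.
#' @return A data frame of class `mc_curve` with columns `value` (native
#'   units of `axis`) and `probability`; attributes `axis` and `fixed`.
#' @examples
#' m <- table1_model()
#' set1 <- c(ca_i_ini = 150, ca_sr_ini = 500, g_k1_sf = 0.338, k_ryr_sf = 1)
#' head(mc_curve(m, "ca_sr_ini", set1))
#' @export
mc_curve <- function(model, axis, fixed, grid_size = 201L, range = NULL) {
  space <- model$space
  j <- match(axis, space$name)
  if (is.na(j)) stop("unknown axis: ", axis)
  if (is.null(range)) range <- c(space$min[j], space$max[j])
  grid <- seq(range[1], range[2], length.out = grid_size)
  pm <- as_point_matrix(fixed, space)
  pts <- pm[rep(1L, grid_size), , drop = FALSE]
  pts[, j] <- grid
  out <- data.frame(value = grid,
                    probability = predict_probability(model, pts))
  attr(out, "axis") <- axis
  attr(out, "fixed") <- pm
  class(out) <- c("mc_curve", "data.frame")
  out
}
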