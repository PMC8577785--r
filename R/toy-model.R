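#' Configure the synthetic stochastic event simulator
#'
#' A seedable stand-in for an expensive stochastic myocyte model. Each
#' realization draws a binary ectopic-beat outcome from a known logistic
#' probability surface over the MMI space and emits a membrane-potential-like
#' trace: events peak above 0 mV (a triggered action potential), non-events
#' produce a subthreshold delayed-afterdepolarization-like bump that stays
#' below 0 mV. The waveform is a minimal piecewise-linear placeholder with no
#' biophysics; only the 0 mV detection rule is meaningful.
#'
#' @param space an [mmi_space]; default the published region of interest.
#' @param spec a [feature_spec] for the true surface; default the published
#'   10-feature specification.
#' @param true_intercept,true_weights intercept and named weight vector (on
#'   scaled features) of the true logistic surface; defaults reconstruct the
#'   published ectopic-beat model so synthetic experiments live in the same
#'   probability landscape.
#' @param duration trace duration in ms (default 800).
#' @param rest_potential resting membrane potential in mV (default -93.4).
#' @param event_peak trace peak for event realizations in mV (default +35).
#' @param dad_peak_range 2-vector, mV range (entirely below 0) from which
#'   non-event peak amplitudes are drawn uniformly (default c(-80, -40)).
#' @param time_step trace sampling interval in ms (default 1).
#' @return An object of class `toy_model_config`.
#' @examples
#' cfg <- toy_model_config()
#' true_probability(cfg, c(ca_i_ini = 150, ca_sr_ini = 500,
#'                         g_k1_sf = 0.338, k_ryr_sf = 1))
#' @export
toy_model_config <- function(space = NULL, spec = NULL,
                             true_intercept = NULL, true_weights = NULL,
                             duration = 800, rest_potential = -93.4,
                             event_peak = 35, dad_peak_range = c(-80, -40),
                             time_step = 1) {
  if (is.null(space) || is.null(spec) || is.null(true_weights) ||
      is.null(true_intercept)) {
    ref <- table1_model()
    space <- space %||% ref$space
    spec <- spec %||% ref$spec
    true_weights <- true_weights %||% ref$weights
    true_intercept <- true_intercept %||% ref$intercept
  }
  if (duration <= 0) stop("'duration' must be positive")
  if (time_step <= 0 || time_step > duration) stop("invalid 'time_step'")
  if (rest_potential >= 0) stop("'rest_potential' must be below 0 mV")
  if (event_peak <= 0) stop("'event_peak' must be above 0 mV")
  dad_peak_range <- sort(as.numeric(dad_peak_range))
  if (length(dad_peak_range) != 2L || dad_peak_range[2] >= 0) {
    stop("'dad_peak_range' must lie entirely below 0 mV")
  }
  unknown <- setdiff(names(true_weights), spec$terms)
  if (is.null(names(true_weights)) || length(unknown)) {
    stop("'true_weights' must be named by feature terms of the spec; ",
         "unknown: ", paste(unknown, collapse = ", "))
  }
  w <- stats::setNames(numeric(n_features(spec)), spec$terms)
  w[names(true_weights)] <- true_weights
  structure(
    list(space = space, spec = spec, true_intercept = true_intercept,
         true_weights = w, duration = duration,
         rest_potential = rest_potential, event_peak = event_peak,
         dad_peak_range = dad_peak_range, time_step = time_step),
    class = "toy_model_config"
  )
}

#' @export
print.toy_model_config <- function(x, ...) {
  cat("Synthetic event simulator over", space_dim(x$space), "MMIs;",
      n_features(x$spec), "true-surface features\n")
  cat("  duration", x$duration, "ms, rest", x$rest_potential,
      "mV, event peak", x$event_peak, "mV\n")
  invisible(x)
}

#' True event probability of the synthetic simulator
#'
#' Evaluates the configured logistic surface at one or more MMI points
#' (native units). Extrapolation outside the region of interest is allowed.
#'
#' @param config a [toy_model_config].
#' @param point an MMI point (named vector) or matrix/data frame of points.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
true_probability <- function(config, point) {
  X <- expand_features(scale_mmi(point, config$space), config$spec)
  as.numeric(logistic(config$true_intercept +
                        X %*% config$true_weights))
}

#' Detect an ectopic beat in a membrane-potential trace
#'
#' The event rule: a trace records an ectopic beat if and only if any sample
#' strictly exceeds the threshold (0 mV by default); subthreshold delayed
#' afterdepolarizations do not count.
#'
#' @param voltages numeric vector of membrane potentials (mV).
#' @param threshold detection threshold in mV (default 0).
#' @return Logical scalar.
#' @examples
#' detect_event(c(-93.4, -50, -93.4))   # FALSE: a DAD
#' detect_event(c(-93.4, 35, -93.4))    # TRUE: an ectopic beat
#' @export
detect_event <- function(voltages, threshold = 0) {
  if (length(voltages) == 0L) stop("'voltages' must be non-empty")
  max(voltages) > threshold
}

# Piecewise-linear placeholder waveform: rest -> peak at mid-trace -> rest.
make_trace <- function(config, peak) {
  times <- seq(0, config$duration, by = config$time_step)
  n <- length(times)
  v <- rep(config$rest_potential, n)
  if (n >= 3L) {
    i_up <- max(2L, floor(n * 0.3))
    i_peak <- max(i_up + 1L, floor(n * 0.45))
    i_down <- min(n - 1L, floor(n * 0.6))
    ramp_up <- seq(config$rest_potential, peak, length.out = i_peak - i_up + 1L)
    ramp_dn <- seq(peak, config$rest_potential, length.out = i_down - i_peak + 1L)
    v[i_up:i_peak] <- ramp_up
    v[i_peak:i_down] <- ramp_dn
  } else {
    v[n] <- peak
  }
  list(times = times, voltages = v)
}

#' Simulate one stochastic realization
#'
#' Draws the binary event outcome from the true probability at `point` and
#' emits a trace whose peak is `event_peak` mV for events, or a uniform draw
#' from `dad_peak_range` for non-events.
#'
#' @param config a [toy_model_config].
#' @param point a single MMI point in native units.
#' @param seed optional integer seed; identical seeds give identical
#'   realizations. `NULL` uses the current RNG stream.
#' @return A list of class `trace_outcome` with elements `times` (ms),
#'   `voltages` (mV) and `event` (logical).
#' @export
simulate_realization <- function(config, point, seed = NULL) {
  p <- true_probability(config, point)
  if (length(p) != 1L) stop("'point' must be a single MMI point")
  with_seed(seed, {
    event <- stats::runif(1) < p
    peak <- if (event) config$event_peak else
      stats::runif(1, config$dad_peak_range[1], config$dad_peak_range[2])
    tr <- make_trace(config, peak)
    structure(list(times = tr$times, voltages = tr$voltages, event = event),
              class = "trace_outcome")
  })
}

#' Simulate a batch of realizations at one MMI point
#'
#' Runs `n` independent realizations and counts events, the synthetic
#' analogue of estimating the event probability from repeated stochastic
#' myocyte-model runs.
#'
#' @param config a [toy_model_config].
#' @param point a single MMI point in native units.
#' @param n number of realizations (default 100).
#' @param seed optional integer seed for reproducibility.
#' @param return_traces if `TRUE`, attach the individual `trace_outcome`s.
#' @return A one-row data frame (class `batch_observation`): the MMI values,
#'   `k` (event count), `n`, and `seed`; with attribute `traces` when
#'   requested.
#' @export
simulate_batch <- function(config, point, n = 100, seed = NULL,
                           return_traces = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive count")
  }
  n <- as.integer(n)
  p <- true_probability(config, point)
  if (length(p) != 1L) stop("'point' must be a single MMI point")
  pm <- as_point_matrix(point, config$space)
  with_seed(seed, {
    u <- stats::runif(n)
    events <- u < p
    traces <- NULL
    if (return_traces) {
      traces <- lapply(seq_len(n), function(i) {
        peak <- if (events[i]) config$event_peak else
          stats::runif(1, config$dad_peak_range[1], config$dad_peak_range[2])
        tr <- make_trace(config, peak)
        structure(list(times = tr$times, voltages = tr$voltages,
                       event = events[i]), class = "trace_outcome")
      })
    }
    obs <- as.data.frame(pm)
    obs$k <- sum(events)
    obs$n <- n
    obs$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
    class(obs) <- c("batch_observation", "data.frame")
    if (!is.null(traces)) attr(obs, "traces") <- traces
    obs
  })
}

#' Simulate batches at many MMI points
#'
#' @param config a [toy_model_config].
#' @param points matrix or data frame of MMI points (native units).
#' @param n realizations per point.
#' @param seed optional base seed; each point uses a derived child seed.
#' @return A data frame of batch observations, one row per point.
#' @export
simulate_batches <- function(config, points, n = 100, seed = NULL) {
  pm <- as_point_matrix(points, config$space)
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    simulate_batch(config, pm[i, , drop = FALSE], n = n,
                   seed = child_seed(seed, i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
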