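#' Write batch observations to CSV
#'
#' One row per MMI set with the MMI values in native units plus `k`, `n`
#' and (if present) `seed`.
#'
#' @param observations data frame of batch observations.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(as.data.frame(observations), path, row.names = FALSE)
  invisible(path)
}

#' Read batch observations from CSV
#'
#' Validates that every row satisfies `0 <= k <= n`, `n >= 1` and that all
#' axes of `space` are present; malformed rows are reported by number.
#'
#' @param path CSV file as written by [write_observations].
#' @param space the [mmi_space] the observations must cover.
#' @return A data frame of batch observations.
#' @export
read_observations <- function(path, space) {
  obs <- utils::read.csv(path)
  validate_observations(obs, space)
}

#' Serialize a surrogate model to JSON
#'
#' Stores the space bounds, feature specification, intercept, weights,
#' standard errors and provenance; the scaling bounds travel with the model
#' so predictions never depend on external state.
#'
#' @param model an `ebprob_lrm`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lrm <- function(model, path) {
  obj <- list(
    schema = "ebprob_lrm/1",
    space = list(name = model$space$name, min = model$space$min,
                 max = model$space$max, units = model$space$units),
    terms = model$spec$terms,
    intercept = model$intercept,
    weights = as.list(model$weights),
    se = as.list(model$se),
    se_intercept = model$se_intercept,
    log_likelihood = model$log_likelihood,
    n_obs = model$n_obs,
    n_trials = model$n_trials,
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a surrogate model from JSON
#'
#' @param path file written by [write_lrm].
#' @return An `ebprob_lrm`.
#' @export
read_lrm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ebprob_lrm/1")) {
    stop("unrecognized model schema: ", obj$schema %||% "(missing)")
  }
  for (key in c("space", "terms", "intercept", "weights")) {
    if (is.null(obj[[key]])) stop("model file missing field: ", key)
  }
  space <- mmi_space(obj$space$name, obj$space$min, obj$space$max,
                     obj$space$units %||% rep("", length(obj$space$name)))
  spec <- feature_spec(obj$terms, space)
  as_named <- function(x, default = NA_real_) {
    v <- stats::setNames(rep(default, length(spec$terms)), spec$terms)
    if (length(x)) v[names(x)] <- unlist(x)
    v
  }
  structure(
    list(space = space, spec = spec,
         intercept = as.numeric(obj$intercept),
         weights = as_named(obj$weights),
         se = as_named(obj$se),
         se_intercept = obj$se_intercept %||% NA_real_,
         log_likelihood = obj$log_likelihood %||% NA_real_,
         n_obs = obj$n_obs %||% NA_integer_,
         n_trials = obj$n_trials %||% NA_integer_,
         provenance = obj$provenance %||% "unknown"),
    class = "ebprob_lrm"
  )
}

#' Write a membrane-potential trace to CSV
#'
#' @param trace a `trace_outcome` from [simulate_realization].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$times,
                              voltage_mV = trace$voltages),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a propagated probability distribution
#'
#' Exports the histogram (bin edges and masses) to CSV and, alongside it, a
#' JSON summary (mean, sd, entropy, modality, sample count, seed).
#'
#' @param dist a `probability_distribution`.
#' @param path CSV output path; the JSON summary is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  nb <- length(dist$masses)
  utils::write.csv(data.frame(bin_low = dist$bin_edges[-(nb + 1L)],
                              bin_high = dist$bin_edges[-1L],
                              mass = dist$masses),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(mean = dist$mean, sd = dist$sd, entropy = dist$entropy,
         modality = dist$modality, n_samples = dist$n_samples,
         analytic = dist$analytic, seed = dist$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a pipeline or simulator configuration from JSON
#'
#' The file must define `space` (axis `name`, `min`, `max`) and may set any
#' of the [pipeline_config] fields. Missing axis bounds are reported by key.
#'
#' @param path JSON configuration file.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$space)) stop("config missing key: space")
  for (key in c("name", "min", "max")) {
    if (is.null(obj$space[[key]])) stop("config missing key: space$", key)
  }
  space <- mmi_space(obj$space$name, obj$space$min, obj$space$max,
                     obj$space$units %||% rep("", length(obj$space$name)))
  pipeline_config(
    space = space,
    sets_per_iteration = obj$sets_per_iteration %||% 100L,
    realizations_per_set = obj$realizations_per_set %||% 100L,
    transition_band = obj$transition_band %||% c(0.025, 0.975),
    criterion = obj$criterion %||% "caic",
    sample_size_convention = obj$sample_size_convention %||% "total_trials",
    seed = obj$seed
  )
}

#' Snapshot a pipeline run directory
#'
#' Writes the config, per-iteration observations, fitted models and the
#' feature-selection table of a pipeline run to a directory, so the run is
#' fully reproducible from the snapshot plus the recorded seed.
#'
#' @param run an `ebprob_pipeline` from [run_two_iteration_pipeline].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  jsonlite::write_json(
    list(space = list(name = cfg$space$name, min = cfg$space$min,
                      max = cfg$space$max, units = cfg$space$units),
         sets_per_iteration = cfg$sets_per_iteration,
         realizations_per_set = cfg$realizations_per_set,
         transition_band = cfg$transition_band,
         criterion = cfg$criterion,
         sample_size_convention = cfg$sample_size_convention,
         seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  write_observations(run$iterations[[1]]$observations,
                     file.path(dir, "observations_iter1.csv"))
  write_observations(run$iterations[[2]]$observations,
                     file.path(dir, "observations_iter2.csv"))
  write_lrm(run$iterations[[1]]$model, file.path(dir, "model_iter1.json"))
  write_lrm(run$model, file.path(dir, "model_final.json"))
  tab <- attr(run$selected_spec, "selection_table")
  if (!is.null(tab)) {
    utils::write.csv(tab, file.path(dir, "selection_table.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Write a model-characteristic curve to CSV
#'
#' @param curve an `mc_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mc_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
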