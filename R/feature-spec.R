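#' Specify the feature vector of a logistic surrogate
#'
#' A feature specification is an ordered list of terms over the axes of an
#' [mmi_space]. Each term is either a linear axis name (`"ca_sr_ini"`), a
#' square (`"ca_sr_ini^2"`), or a cross product (`"ca_sr_ini*k_ryr_sf"`).
#' All features are evaluated on min-max-scaled coordinates, so quadratic
#' entries are products of linear entries. The term order is preserved
#' throughout fitting, ranking and serialization.
#'
#' @param terms character vector of term labels.
#' @param space the [mmi_space] whose axes the terms may reference.
#' @return An object of class `feature_spec`.
#' @examples
#' sp <- default_mmi_space()
#' feature_spec(c("ca_sr_ini", "k_ryr_sf", "ca_sr_ini^2"), sp)
#' @export
feature_spec <- function(terms, space) {
  terms <- as.character(terms)
  if (length(terms) < 1L) stop("a feature spec needs at least one term")
  parsed <- lapply(terms, parse_term, axes = space$name)
  canon <- vapply(parsed, function(p) p$label, character(1))
  if (anyDuplicated(canon)) {
    stop("duplicate feature terms: ",
         paste(canon[duplicated(canon)], collapse = ", "))
  }
  structure(
    list(terms = canon, parsed = parsed, axes = space$name),
    class = "feature_spec"
  )
}

# A term is "axis", "axis^2" or "axis_a*axis_b"; cross products are
# canonicalized to axis order so "b*a" and "a*b" are the same term.
parse_term <- function(term, axes) {
  term <- gsub(" ", "", term)
  if (grepl("\\^2$", term)) {
    a <- sub("\\^2$", "", term)
    parts <- c(a, a)
  } else if (grepl("\\*", term)) {
    parts <- strsplit(term, "*", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed feature term: ", term)
  } else {
    parts <- term
  }
  unknown <- setdiff(parts, axes)
  if (length(unknown)) {
    stop("feature term '", term, "' references unknown axis: ",
         paste(unknown, collapse = ", "))
  }
  if (length(parts) == 1L) {
    list(type = "linear", axes = parts, label = parts)
  } else {
    parts <- parts[order(match(parts, axes))]
    label <- if (parts[1] == parts[2]) paste0(parts[1], "^2") else
      paste0(parts[1], "*", parts[2])
    list(type = "quadratic", axes = parts, label = label)
  }
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("Feature spec (", length(x$terms), " terms): ",
      paste(x$terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_features <- function(spec) length(spec$terms)

is_linear_term <- function(spec) {
  vapply(spec$parsed, function(p) p$type == "linear", logical(1))
}

#' All linear features of a space, in axis order
#'
#' @param space an [mmi_space].
#' @return A `feature_spec` with one linear term per axis.
#' @export
linear_feature_spec <- function(space) feature_spec(space$name, space)

#' Enumerate all candidate quadratic terms of a space
#'
#' For a `d`-axis space there are `d` squares and `d(d-1)/2` cross products,
#' `d(d+1)/2` in total (10 for the four-MMI ectopic-beat space), returned in
#' a deterministic order: squares in axis order, then cross products in
#' lexicographic axis order.
#'
#' @param space an [mmi_space].
#' @return Character vector of quadratic term labels.
#' @examples
#' quadratic_candidates(default_mmi_space())
#' @export
quadratic_candidates <- function(space) {
  ax <- space$name
  d <- length(ax)
  squares <- paste0(ax, "^2")
  crosses <- character(0)
  if (d >= 2L) {
    idx <- utils::combn(d, 2L)
    crosses <- paste0(ax[idx[1, ]], "*", ax[idx[2, ]])
  }
  c(squares, crosses)
}

#' Evaluate a feature specification on scaled coordinates
#'
#' @param scaled a scaled coordinate vector or matrix as returned by
#'   [scale_mmi] (one row per point, one column per axis).
#' @param spec a [feature_spec].
#' @return A numeric matrix, one row per point, one column per term in spec
#'   order.
#' @examples
#' sp <- default_mmi_space()
#' x <- scale_mmi(c(ca_i_ini = 150, ca_sr_ini = 500, g_k1_sf = 0.338,
#'                  k_ryr_sf = 1), sp)
#' expand_features(x, table1_feature_spec())
#' @export
expand_features <- function(scaled, spec) {
  if (is.null(dim(scaled))) {
    scaled <- matrix(scaled, nrow = 1L,
                     dimnames = list(NULL, names(scaled)))
  }
  if (is.null(colnames(scaled))) {
    if (ncol(scaled) != length(spec$axes)) {
      stop("scaled matrix has ", ncol(scaled), " columns; spec expects ",
           length(spec$axes))
    }
    colnames(scaled) <- spec$axes
  }
  missing <- setdiff(spec$axes, colnames(scaled))
  if (length(missing)) {
    stop("scaled coordinates missing axes: ", paste(missing, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = nrow(scaled), ncol = n_features(spec),
                dimnames = list(NULL, spec$terms))
  for (j in seq_along(spec$parsed)) {
    p <- spec$parsed[[j]]
    out[, j] <- if (p$type == "linear") scaled[, p$axes] else
      scaled[, p$axes[1]] * scaled[, p$axes[2]]
  }
  out
}
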