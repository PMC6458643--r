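#' Fit a principal-component shape model
#'
#' Mean-centred PCA via singular value decomposition of the subject-by-feature
#' matrix. For `kind = "curvature"` the features are the concatenated x, y, z
#' coordinates of the (normalised, registered) centreline points; for
#' `kind = "radius"` they are the (mean-radius-scaled) radius profiles. No
#' per-feature variance scaling is applied, so the components live in the
#' original geometric space. Curvature and calibre are modelled strictly
#' separately.
#'
#' Each component's sign is fixed so that its largest-magnitude loading is
#' positive (the sign of a principal axis is otherwise arbitrary).
#'
#' @param population List of [centreline()]s, all with the same point count,
#'   already normalised (and, for curvature, rigidly registered).
#' @param kind `"curvature"` or `"radius"`.
#' @param n_components Number of components to retain (default 5).
#' @return An object of class `shape_model`: list with `kind`, `n_points`,
#'   `mean_vector`, `components` (feature x component matrix, orthonormal),
#'   `sd` (per-component standard deviation of scores), `variance_fraction`,
#'   and `subject_weights` (subject x component scores in SD units).
#' @export
fit_shape_model <- function(population, kind = c("curvature", "radius"),
                            n_components = 5L) {
  kind <- match.arg(kind)
  n <- length(population)
  if (n < n_components + 1L) {
    stop("need at least n_components + 1 subjects")
  }
  X <- t(vapply(population, feature_vector, kind = kind,
                numeric(length(feature_vector(population[[1]], kind)))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2) / (n - 1)
  if (total_var <= 0) stop("population has zero shape variance")
  sv <- svd(Xc)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  k <- n_components
  if (k > rank) {
    warning(sprintf("requested %d components but rank is %d; truncating",
                    k, rank))
    k <- rank
  }
  V <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  # Sign convention: largest-|loading| entry of each component positive.
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  sds <- d / sqrt(n - 1)
  scores_sd <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k), 2,
                     sds, "/")
  structure(list(
    kind = kind,
    n_points = nrow(population[[1]]$points),
    mean_vector = mu,
    components = V,
    sd = sds,
    variance_fraction = d^2 / sum(sv$d^2),
    subject_weights = scores_sd
  ), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model (%s): %d components over %d subjects>\n",
              x$kind, ncol(x$components), nrow(x$subject_weights)))
  cat("variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

# Feature vector for the PCA: concatenated coordinates or radius profile.
feature_vector <- function(cl, kind) {
  if (kind == "curvature") as.numeric(cl$points) else cl$radius
}

#' Project a shape onto a fitted model
#'
#' Returns per-component scores in standard-deviation units: the inner
#' product of the mean-centred feature vector with each component, divided by
#' that component's score SD. By construction the training population has
#' unit SD on every component.
#'
#' @param model A [fit_shape_model()] result.
#' @param cl A [centreline()] processed identically to the training data, or
#'   a raw feature vector.
#' @return Numeric vector of weights (SD units), one per component.
#' @export
project <- function(model, cl) {
  stopifnot(inherits(model, "shape_model"))
  v <- if (inherits(cl, "centreline")) feature_vector(cl, model$kind)
       else as.numeric(cl)
  if (length(v) != length(model$mean_vector)) {
    stop("dimensionality mismatch with the fitted model")
  }
  as.numeric(crossprod(model$components, v - model$mean_vector)) / model$sd
}

#' Reconstruct a proto-shape at chosen component weights
#'
#' Builds `mean + sum_i w_i * (2 sd_i) * component_i`: a *display* weight of
#' +-1 corresponds to +-2 standard deviations along that component, the
#' convention used for visualising extreme proto-aortas. A weight vector of
#' zeros returns the population mean shape exactly.
#'
#' @param model A [fit_shape_model()] result.
#' @param weights Display-weight vector (recycled entries are not allowed; a
#'   shorter vector is padded with zeros).
#' @return The reconstructed feature vector: length `3 * n_points` for
#'   curvature (use [reconstruct_curve()] for the matrix form), `n_points`
#'   for radius.
#' @export
reconstruct <- function(model, weights) {
  stopifnot(inherits(model, "shape_model"))
  k <- ncol(model$components)
  if (length(weights) > k) stop("more weights than components")
  w <- c(as.numeric(weights), rep(0, k - length(weights)))
  as.numeric(model$mean_vector +
               model$components %*% (w * 2 * model$sd))
}

#' Reconstructed curvature shape as a point matrix
#'
#' @param model A curvature [fit_shape_model()] result.
#' @param weights Display weights as in [reconstruct()].
#' @return `n_points x 3` matrix of coordinates, mm.
#' @export
reconstruct_curve <- function(model, weights) {
  if (model$kind != "curvature") stop("model is not a curvature model")
  matrix(reconstruct(model, weights), ncol = 3)
}

#' Write a shape model to JSON
#'
#' @param model A [fit_shape_model()] result.
#' @param path Output path.
#' @export
write_shape_model <- function(model, path) {
  obj <- list(kind = model$kind, n_points = model$n_points,
              mean_vector = model$mean_vector,
              components = model$components,
              sd = model$sd,
              variance_fraction = model$variance_fraction,
              subject_weights = model$subject_weights)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a shape model from JSON
#'
#' @param path File written by [write_shape_model()].
#' @return A `shape_model` object.
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = obj$kind, n_points = obj$n_points,
                 mean_vector = obj$mean_vector,
                 components = as.matrix(obj$components),
                 sd = obj$sd,
                 variance_fraction = obj$variance_fraction,
                 subject_weights = as.matrix(obj$subject_weights)),
            class = "shape_model")
}

#' Principal angles between two subspaces
#'
#' Utility for validating mode recovery: the principal angles between the
#' column spaces of two basis matrices, from the singular values of
#' `Q1' Q2`.
#'
#' @param A,B Matrices whose columns span the subspaces (same row count).
#' @return Angles in radians, one per dimension of the smaller subspace.
#' @export
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1))
}
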