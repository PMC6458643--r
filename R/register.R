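#' Rigid registration of a centreline to a reference
#'
#' Least-squares rigid alignment (rotation + translation only, no scaling, no
#' reflection) of corresponding points, solved in closed form via the SVD of
#' the cross-covariance matrix with the determinant of the rotation
#' constrained to +1. Correspondence is by point index, which is why
#' centrelines are resampled to a common count first.
#'
#' @param cl A [centreline()].
#' @param reference A [centreline()] with the same number of points.
#' @return The transformed [centreline()] (radii unchanged), with the applied
#'   rotation and translation stored in attribute `"transform"`.
#' @export
rigid_register <- function(cl, reference) {
  stopifnot(inherits(cl, "centreline"), inherits(reference, "centreline"))
  if (nrow(cl$points) != nrow(reference$points)) {
    stop("centrelines must have equal point counts for registration")
  }
  fit <- kabsch(cl$points, reference$points)
  out <- centreline(fit$aligned, cl$radius, cl$landmarks, cl$id)
  attr(out, "transform") <- fit[c("R", "t")]
  out
}

# Kabsch algorithm: proper rotation R (det +1) and translation t minimising
# ||X R' + t - Y||^2 over corresponding rows.
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) {
    warning("degenerate (rank-deficient) point set: registration non-unique")
    d <- 1
  }
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- sweep(Xc %*% t(R), 2, cy, "+")
  list(R = R, t = cy - as.numeric(R %*% cx), aligned = aligned)
}

# Unit normal of the best-fit plane of a point set (3rd right-singular
# vector of the centred coordinates).
plane_normal <- function(points) {
  P <- sweep(points, 2, colMeans(points))
  svd(P, nu = 0, nv = 3)$v[, 3]
}

# Deterministic canonical pose for a mean shape: centroid at the origin,
# best-fit plane normal along +z (sign fixed by curve chirality), chord
# direction first->last along +x within the plane. An externally supplied
# plane normal (e.g. the population-average normal) may override the shape's
# own.
canonical_pose <- function(points, e3 = NULL) {
  ctr <- colMeans(points)
  P <- sweep(points, 2, ctr)
  n <- nrow(P)
  if (is.null(e3)) e3 <- plane_normal(P)
  e3 <- e3 / sqrt(sum(e3^2))
  mid <- P[round(n / 2), ]
  chir <- det(rbind(mid - P[1, ], P[n, ] - mid, e3))
  if (chir < 0) e3 <- -e3
  chord <- P[n, ] - P[1, ]
  e1 <- chord - sum(chord * e3) * e3
  if (sqrt(sum(e1^2)) < 1e-12) e1 <- c(1, 0, 0) - e3[1] * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  P %*% cbind(e1, e2, e3)
}

#' Build a population reference shape by generalised alignment
#'
#' Iteratively registers every centreline to the current mean and recomputes
#' the mean until the mean stops moving (generalised Procrustes, rotation and
#' translation only). The converged mean is then put into a deterministic
#' canonical pose whose z-axis is the average best-fit plane normal of the
#' aligned population, making the result independent of input order.
#'
#' @param population List of [centreline()]s with equal point counts
#'   (normalised beforehand).
#' @param tol RMS mean-shape change at convergence, mm.
#' @param max_iter Maximum alignment sweeps.
#' @return The reference [centreline()]; its radius profile is the population
#'   mean radius.
#' @export
build_reference <- function(population, tol = 1e-12, max_iter = 100L) {
  if (length(population) < 2L) stop("need at least 2 centrelines")
  pts <- lapply(population, function(cl) {
    stopifnot(inherits(cl, "centreline"))
    cl$points
  })
  npts <- nrow(pts[[1]])
  if (any(vapply(pts, nrow, integer(1)) != npts)) {
    stop("all centrelines must have equal point counts")
  }
  mean_shape <- sweep(pts[[1]], 2, colMeans(pts[[1]]))
  for (it in seq_len(max_iter)) {
    aligned <- lapply(pts, function(p) kabsch(p, mean_shape)$aligned)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  if (delta >= tol) stop("generalised alignment did not converge")

  # Orient: average best-fit plane of the aligned examples defines the
  # canonical z-axis (first left singular direction of the stacked,
  # sign-aligned plane normals); the pose rules are order-invariant.
  ref_n <- plane_normal(mean_shape)
  normals <- vapply(aligned, function(p) {
    nv <- plane_normal(p)
    if (sum(nv * ref_n) < 0) nv <- -nv
    nv
  }, numeric(3))
  avg_n <- svd(normals, nu = 3, nv = 0)$u[, 1]
  if (sum(avg_n * ref_n) < 0) avg_n <- -avg_n
  mean_shape <- canonical_pose(mean_shape, e3 = avg_n)
  rad <- Reduce(`+`, lapply(population, `[[`, "radius")) / length(population)
  lm <- population[[1]]$landmarks
  if (!is.null(lm)) {
    all_lm <- lapply(population, `[[`, "landmarks")
    if (all(vapply(all_lm, function(x) identical(names(x), names(lm)),
                   logical(1)))) {
      lm <- stats::setNames(
        as.integer(round(Reduce(`+`, all_lm) / length(all_lm))), names(lm))
    } else {
      lm <- NULL
    }
  }
  centreline(mean_shape, rad, lm, "reference")
}
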