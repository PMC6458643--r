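#' Aortic centreline
#'
#' An ordered polyline of 3D points with a per-point lumen radius (radius of
#' the maximal inscribed sphere), running from the sinotubular junction to the
#' diaphragm. This is the geometric unit of the shape analysis.
#'
#' @param points Numeric matrix `n x 3` of (x, y, z) coordinates in mm.
#' @param radius Numeric vector of length `n`, per-point radius in mm,
#'   strictly positive.
#' @param landmarks Optional named integer vector mapping landmark names
#'   (e.g. `"isthmus"`) to point indices.
#' @param id Optional subject identifier.
#' @return An object of class `centreline`.
#' @export
centreline <- function(points, radius, landmarks = NULL, id = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  n <- nrow(points)
  if (n < 2L) stop("centreline needs at least 2 points")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive centreline points must be distinct")
  radius <- as.numeric(radius)
  if (length(radius) != n) stop("radius must have one value per point")
  if (any(radius <= 0)) stop("radius must be strictly positive everywhere")
  if (!is.null(landmarks)) {
    landmarks <- vapply(landmarks, as.integer, integer(1))
    if (any(landmarks < 1L | landmarks > n)) {
      stop("landmark indices out of range")
    }
  }
  structure(list(points = points, radius = radius, landmarks = landmarks,
                 id = id), class = "centreline")
}

#' @export
print.centreline <- function(x, ...) {
  cat(sprintf("<centreline%s: %d points, length %.1f mm, radius [%.2f, %.2f] mm>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              nrow(x$points), arc_length(x), min(x$radius), max(x$radius)))
  invisible(x)
}

#' Polyline arc length of a centreline
#'
#' @param cl A [centreline()].
#' @return Total chordal arc length in mm.
#' @export
arc_length <- function(cl) {
  p <- cl$points
  n <- nrow(p)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-n, , drop = FALSE])^2)))
}

# Cumulative arc length, starting at 0.
cum_arc_length <- function(points) {
  n <- nrow(points)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' Resample a centreline to equally spaced points
#'
#' Points (and radii) are linearly interpolated at `n_points` positions
#' equally spaced in chordal arc length. Landmarks are mapped to the nearest
#' new index.
#'
#' @param cl A [centreline()].
#' @param n_points Number of output points (default 100, the working
#'   resolution of the shape analysis).
#' @return A resampled [centreline()].
#' @export
resample_centreline <- function(cl, n_points = 100L) {
  stopifnot(inherits(cl, "centreline"))
  if (n_points < 2L) stop("n_points must be at least 2")
  s <- cum_arc_length(cl$points)
  s_new <- seq(0, s[length(s)], length.out = n_points)
  pts <- vapply(1:3, function(j) {
    stats::approx(s, cl$points[, j], xout = s_new)$y
  }, numeric(n_points))
  rad <- stats::approx(s, cl$radius, xout = s_new)$y
  lm_new <- NULL
  if (!is.null(cl$landmarks)) {
    lm_new <- vapply(cl$landmarks, function(i) {
      which.min(abs(s_new - s[i]))
    }, integer(1))
  }
  centreline(pts, rad, lm_new, cl$id)
}

#' Scale a centreline to a target arc length
#'
#' Uniform similarity scaling about the centroid so that the polyline arc
#' length equals `target_length`. The radius profile is deliberately left
#' untouched: calibre is normalised separately by [normalise_radius()].
#'
#' @param cl A [centreline()].
#' @param target_length Target arc length, mm.
#' @return A scaled [centreline()].
#' @export
normalise_length <- function(cl, target_length) {
  stopifnot(inherits(cl, "centreline"), target_length > 0)
  L <- arc_length(cl)
  if (L <= 0) stop("zero-length centreline cannot be scaled")
  ctr <- colMeans(cl$points)
  sc <- target_length / L
  pts <- sweep(sweep(cl$points, 2, ctr, "-") * sc, 2, ctr, "+")
  centreline(pts, cl$radius, cl$landmarks, cl$id)
}

#' Scale a radius profile to a target mean radius
#'
#' Multiplies the per-point radii by `target_mean_radius / mean(radius)`;
#' coordinates are untouched.
#'
#' @param cl A [centreline()].
#' @param target_mean_radius Target mean radius along the length, mm.
#' @return A [centreline()] with scaled radii.
#' @export
normalise_radius <- function(cl, target_mean_radius) {
  stopifnot(inherits(cl, "centreline"), target_mean_radius > 0)
  centreline(cl$points, cl$radius * target_mean_radius / mean(cl$radius),
             cl$landmarks, cl$id)
}

#' Clinical arch geometry indices
#'
#' Computes the two diameter-ratio indices used to quantify residual
#' narrowing and arch hypoplasia, reading diameters as twice the centreline
#' radius at landmark positions:
#' * coarctation index = isthmus diameter / descending (diaphragm) diameter;
#' * arch index = transverse arch diameter (between the innominate and left
#'   common carotid origins) / descending diameter.
#'
#' @param cl A [centreline()] with landmarks `innominate_LCC_midpoint`,
#'   `isthmus` and `diaphragm`.
#' @return A list with `coarctation_index` and `arch_index`.
#' @export
geometry_indices <- function(cl) {
  stopifnot(inherits(cl, "centreline"))
  need <- c("innominate_LCC_midpoint", "isthmus", "diaphragm")
  for (nm in need) {
    if (is.null(cl$landmarks) || !nm %in% names(cl$landmarks)) {
      stop(sprintf("missing landmark '%s'", nm))
    }
  }
  d <- function(nm) 2 * cl$radius[cl$landmarks[[nm]]]
  list(coarctation_index = d("isthmus") / d("diaphragm"),
       arch_index = d("innominate_LCC_midpoint") / d("diaphragm"))
}

#' Write a centreline to CSV
#'
#' Columns: `index, x_mm, y_mm, z_mm, radius_mm`. Landmarks, if present, are
#' stored in a comment-free sidecar convention: an extra column `landmark`
#' holding the landmark name at its index (empty elsewhere).
#'
#' @param cl A [centreline()].
#' @param path Output file path.
#' @export
write_centreline_csv <- function(cl, path) {
  n <- nrow(cl$points)
  lm_col <- rep("", n)
  if (!is.null(cl$landmarks)) lm_col[cl$landmarks] <- names(cl$landmarks)
  df <- data.frame(index = seq_len(n), x_mm = cl$points[, 1],
                   y_mm = cl$points[, 2], z_mm = cl$points[, 3],
                   radius_mm = cl$radius, landmark = lm_col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a centreline from CSV
#'
#' @param path File written by [write_centreline_csv()] (columns `x_mm, y_mm,
#'   z_mm, radius_mm`, optional `landmark`).
#' @param id Optional subject id (defaults to the file name).
#' @return A [centreline()].
#' @export
read_centreline_csv <- function(path, id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lm <- NULL
  if ("landmark" %in% names(df)) {
    has <- !is.na(df$landmark) & nzchar(df$landmark)
    if (any(has)) lm <- stats::setNames(which(has), df$landmark[has])
  }
  if (is.null(id)) id <- sub("\\.csv$", "", basename(path))
  centreline(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), df$radius_mm, lm, id)
}

#' Read a centreline from a VTK XML polyline (.vtp) file
#'
#' Minimal reader for ASCII `.vtp` files as produced by common centreline
#' extraction tools: takes the `Points` array and a point-data array named
#' `MaximumInscribedSphereRadius`. Requires the `xml2` package.
#'
#' @param path Path to an ASCII .vtp file.
#' @param id Optional subject id.
#' @return A [centreline()].
#' @export
read_centreline_vtp <- function(path, id = NULL) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("reading .vtp files requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                            "[[:space:]]+")[[1]])
  pts_node <- xml2::xml_find_first(doc, ".//Points/DataArray")
  if (is.na(pts_node)) stop("no Points array found in .vtp file")
  if (!identical(xml2::xml_attr(pts_node, "format"), "ascii")) {
    stop("only ascii-format .vtp files are supported")
  }
  pts <- matrix(num(pts_node), ncol = 3, byrow = TRUE)
  rad_node <- xml2::xml_find_first(
    doc, ".//PointData/DataArray[@Name='MaximumInscribedSphereRadius']")
  if (is.na(rad_node)) stop("no MaximumInscribedSphereRadius point-data array")
  rad <- num(rad_node)
  if (is.null(id)) id <- sub("\\.vtp$", "", basename(path))
  centreline(pts, rad, NULL, id)
}
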