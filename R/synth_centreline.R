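#' Analytic "candy-cane" base arch curve
#'
#' A planar aortic-arch-like centreline built from a smooth curvature profile:
#' a gentle background curvature along both limbs plus a Gaussian curvature
#' bump at the arch, integrating to a total turning angle of pi (ascending
#' limb pointing cranially, descending limb caudally). A mild sinusoidal
#' out-of-plane component is added for anatomical realism. The curve is
#' arc-length parameterised and returned at `n` equally spaced points.
#'
#' @param n Number of points.
#' @param total_length Arc length, mm.
#' @param arch_centre Arc-length fraction of the arch apex.
#' @param arch_width Gaussian width of the arch curvature bump, mm.
#' @param limb_turning Total turning angle (radians) contributed by the
#'   background curvature of the limbs.
#' @param out_of_plane Amplitude of the out-of-plane bow, mm.
#' @return `n x 3` matrix of coordinates (mm); x spans ascending to
#'   descending, z is cranio-caudal, y is out-of-plane.
#' @export
base_arch_curve <- function(n = 100L, total_length = 250,
                            arch_centre = 0.40, arch_width = 25,
                            limb_turning = 1.2, out_of_plane = 6) {
  L <- total_length
  s_fine <- seq(0, L, length.out = 2000L)
  bump <- exp(-((s_fine - arch_centre * L) / arch_width)^2)
  k0 <- limb_turning / L
  # Scale the arch bump so the tangent turns by exactly pi over the curve.
  ka <- (pi - limb_turning) / (sum(bump) * (s_fine[2] - s_fine[1]))
  kappa <- k0 + ka * bump
  ds <- s_fine[2] - s_fine[1]
  phi <- cumsum(c(0, (kappa[-1] + kappa[-length(kappa)]) / 2 * ds))
  x <- cumsum(c(0, (sin(phi[-1]) + sin(phi[-length(phi)])) / 2 * ds))
  z <- cumsum(c(0, (cos(phi[-1]) + cos(phi[-length(phi)])) / 2 * ds))
  s_out <- seq(0, L, length.out = n)
  cbind(x = stats::approx(s_fine, x, s_out)$y,
        y = out_of_plane * sin(pi * s_out / L),
        z = stats::approx(s_fine, z, s_out)$y)
}

#' Base radius taper of the synthetic aorta
#'
#' Ascending bulge decaying towards a descending plateau, with a mild fixed
#' isthmus waist at the usual repair site: mean calibre geometry consistent
#' with an adult post-repair aorta (ascending diameter about 25 mm,
#' descending about 18 mm, coarctation index just above 0.9).
#'
#' @param n Number of points.
#' @return Radius profile in mm at `n` equally spaced arc-length fractions.
#' @export
base_radius_profile <- function(n = 100L) {
  f <- seq(0, 1, length.out = n)
  9 + 3.5 * exp(-(f / 0.25)^2) - 0.8 * exp(-((f - 0.62) / 0.06)^2)
}

# Named spatial profiles for shape-variation modes. Curvature profiles are
# 3n-vectors (displacements of the n points, x/y/z blocks); radius profiles
# are n-vectors. Raw shapes below are orthonormalised in construction order.
raw_mode_profile <- function(name, kind, n) {
  f <- seq(0, 1, length.out = n)
  zeros <- numeric(n)
  if (kind == "curvature") {
    switch(name,
      arch_angulation = c(zeros, zeros, exp(-((f - 0.40) / 0.10)^2)),
      asc_desc_sweep  = c(sin(2 * pi * f), zeros, zeros),
      out_of_plane_bow = c(zeros, sin(pi * f), zeros),
      asc_length      = c(zeros, zeros, exp(-((f - 0.12) / 0.10)^2)),
      desc_curve      = c(pmax(f - 0.55, 0)^2, zeros, zeros),
      stop(sprintf("unknown curvature mode profile '%s'", name))
    )
  } else {
    switch(name,
      ascending_dilation = exp(-((f - 0.10) / 0.09)^2),
      isthmus_narrowing  = exp(-((f - 0.62) / 0.05)^2),
      arch_hypoplasia    = exp(-((f - 0.42) / 0.07)^2),
      descending_taper   = f - 0.5,
      root_arch_contrast = exp(-((f - 0.10) / 0.09)^2) -
        0.5 * exp(-((f - 0.45) / 0.12)^2),
      stop(sprintf("unknown radius mode profile '%s'", name))
    )
  }
}

# Gram-Schmidt orthonormalisation of profile vectors (columns), in order.
orthonormalise <- function(M) {
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (j > 1) {
      prev <- M[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("mode profiles are linearly dependent")
    M[, j] <- v / nv
  }
  M
}

#' Configuration for the synthetic centreline population
#'
#' Defines the base arch geometry and a set of mutually orthogonal shape
#' variation modes (curvature = point displacements, radius = calibre
#' profiles) with known per-mode weight SDs. Per-mode weights are drawn
#' `Normal(0, sd^2)` and stored as ground truth.
#'
#' @param n_subjects Cohort size (>= 1).
#' @param seed RNG seed; identical seed + config gives a bit-identical
#'   cohort.
#' @param modes List of mode definitions, each
#'   `list(id =, kind = "curvature"|"radius", profile = <name or vector>,
#'   sd = <weight SD, mm>)`. The default is three curvature and three radius
#'   modes emulating arch angulation, ascending/descending sweep,
#'   out-of-plane bow, ascending dilation, isthmus narrowing and transverse
#'   arch hypoplasia.
#' @param noise_sd Independent Gaussian noise SD added to every point
#'   coordinate, mm.
#' @param radius_noise_sd Noise SD added to every radius sample, mm.
#' @param n_points Points per centreline.
#' @param landmark_fractions Named, strictly increasing arc-length fractions
#'   in `[0, 1]` at which landmarks are emitted.
#' @param gothic_rule `list(mode =, slope =, intercept =)`: the gothic-arch
#'   label is drawn `Bernoulli(plogis(intercept + slope * w))` where `w` is
#'   the named curvature-mode weight in SD units.
#' @param base Named list of [base_arch_curve()] arguments overriding its
#'   defaults.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_subjects = 60L, seed = 1L,
                              modes = default_modes(),
                              noise_sd = 0.5, radius_noise_sd = 0.15,
                              n_points = 100L,
                              landmark_fractions = c(
                                sinotubular = 0, innominate_LCC_midpoint = 0.35,
                                isthmus = 0.62, diaphragm = 1),
                              gothic_rule = list(mode = "arch_angulation",
                                                 slope = 1.5,
                                                 intercept = -1.4),
                              base = list()) {
  stopifnot(n_subjects >= 1, noise_sd >= 0, radius_noise_sd >= 0,
            n_points >= 2)
  lf <- landmark_fractions
  if (any(lf < 0 | lf > 1) || any(diff(lf) <= 0)) {
    stop("landmark fractions must be strictly increasing within [0, 1]")
  }
  for (m in modes) {
    stopifnot(is.list(m), !is.null(m$id), m$kind %in% c("curvature", "radius"),
              m$sd >= 0)
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 modes = modes, noise_sd = noise_sd,
                 radius_noise_sd = radius_noise_sd,
                 n_points = as.integer(n_points),
                 landmark_fractions = lf, gothic_rule = gothic_rule,
                 base = base),
            class = "population_config")
}

#' Default shape-variation mode set
#'
#' @return The default `modes` list for [population_config()].
#' @export
default_modes <- function() {
  list(
    list(id = "arch_angulation", kind = "curvature",
         profile = "arch_angulation", sd = 6),
    list(id = "asc_desc_sweep", kind = "curvature",
         profile = "asc_desc_sweep", sd = 3.5),
    list(id = "out_of_plane_bow", kind = "curvature",
         profile = "out_of_plane_bow", sd = 2),
    list(id = "ascending_dilation", kind = "radius",
         profile = "ascending_dilation", sd = 1.2),
    list(id = "isthmus_narrowing", kind = "radius",
         profile = "isthmus_narrowing", sd = 0.8),
    list(id = "arch_hypoplasia", kind = "radius",
         profile = "arch_hypoplasia", sd = 0.6)
  )
}

#' Radius mode set for the proto-aorta 1D experiment
#'
#' Three near-disjoint orthogonal calibre modes in which one direction
#' enlarges the proximal aorta relative to the distal aorta, in different
#' spatial flavours: an isolated ascending dilation, a transverse-arch
#' calibre mode, and a proximal-to-distal taper tilt. These emulate the
#' calibre patterns reported to drive backward compression waves.
#'
#' @return A `modes` list for [population_config()].
#' @export
proto_modes <- function() {
  list(
    list(id = "ascending_dilation", kind = "radius",
         profile = "ascending_dilation", sd = 1.5),
    list(id = "arch_hypoplasia", kind = "radius",
         profile = "arch_hypoplasia", sd = 1.0),
    list(id = "descending_taper", kind = "radius",
         profile = "descending_taper", sd = 0.5)
  )
}

# Resolve + orthonormalise mode profiles of one kind; errors if user-supplied
# numeric profiles are not mutually orthogonal.
resolve_profiles <- function(modes, kind, n) {
  sel <- Filter(function(m) m$kind == kind, modes)
  if (length(sel) == 0) return(NULL)
  p_len <- if (kind == "curvature") 3L * n else n
  M <- vapply(sel, function(m) {
    if (is.character(m$profile)) raw_mode_profile(m$profile, kind, n)
    else as.numeric(m$profile)
  }, numeric(p_len))
  M <- matrix(M, nrow = p_len)
  user_supplied <- vapply(sel, function(m) !is.character(m$profile),
                          logical(1))
  if (any(user_supplied)) {
    Mn <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    G <- crossprod(Mn)
    if (max(abs(G - diag(ncol(G)))) > 1e-8) {
      stop("user-supplied mode profiles must be mutually orthogonal")
    }
    M <- Mn
  } else {
    M <- orthonormalise(M)
  }
  colnames(M) <- vapply(sel, `[[`, "", "id")
  list(profiles = M, sds = vapply(sel, `[[`, numeric(1), "sd"))
}

#' Generate a synthetic centreline population with known modes
#'
#' Each centreline is the base candy-cane curve plus a weighted sum of the
#' orthonormal curvature mode profiles (weights drawn Normal with the
#' configured SDs) plus i.i.d. coordinate noise; the radius profile is the
#' base taper plus radius-mode perturbations plus noise. A subject whose
#' perturbed radius becomes non-positive anywhere is rejected and redrawn
#' (clipping would break mode orthogonality); the redraw count is recorded.
#' Landmarks are emitted at the configured arc-length fractions and the
#' gothic-arch label is drawn from a logistic rule on the arch-angulation
#' mode weight.
#'
#' @param cfg A [population_config()].
#' @return List with `centrelines` (list of [centreline()]), `truth` (data
#'   frame: id, per-mode weights in mm, per-mode weights in SD units
#'   (`*_sd` columns), gothic label) and `profiles` (the orthonormal mode
#'   matrices actually used). Attribute `n_redraws` counts rejected draws.
#' @export
generate_centerline_population <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  set.seed(cfg$seed)
  n <- cfg$n_points
  base_pts <- do.call(base_arch_curve, c(list(n = n), cfg$base))
  base_rad <- base_radius_profile(n)
  curv <- resolve_profiles(cfg$modes, "curvature", n)
  radm <- resolve_profiles(cfg$modes, "radius", n)
  lm_idx <- stats::setNames(
    pmax(1L, pmin(n, as.integer(round(cfg$landmark_fractions * (n - 1) + 1)))),
    names(cfg$landmark_fractions))

  n_redraws <- 0L
  draw_subject <- function() {
    for (attempt in seq_len(100L)) {
      wc <- if (is.null(curv)) numeric(0) else
        stats::rnorm(length(curv$sds), 0, curv$sds)
      wr <- if (is.null(radm)) numeric(0) else
        stats::rnorm(length(radm$sds), 0, radm$sds)
      pts <- base_pts
      if (!is.null(curv)) {
        pts <- pts + matrix(curv$profiles %*% wc, ncol = 3)
      }
      if (cfg$noise_sd > 0) {
        pts <- pts + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd), ncol = 3)
      }
      rad <- base_rad
      if (!is.null(radm)) rad <- rad + as.numeric(radm$profiles %*% wr)
      if (cfg$radius_noise_sd > 0) {
        rad <- rad + stats::rnorm(n, 0, cfg$radius_noise_sd)
      }
      if (all(rad > 0)) return(list(wc = wc, wr = wr, pts = pts, rad = rad))
      n_redraws <<- n_redraws + 1L
    }
    stop("could not draw a subject with positive radii in 100 attempts")
  }

  gothic_of <- function(wc) {
    gr <- cfg$gothic_rule
    w_sd <- 0
    if (!is.null(curv) && gr$mode %in% colnames(curv$profiles)) {
      j <- match(gr$mode, colnames(curv$profiles))
      w_sd <- wc[j] / curv$sds[j]
    }
    stats::rbinom(1L, 1L, stats::plogis(gr$intercept + gr$slope * w_sd)) == 1L
  }

  cls <- vector("list", cfg$n_subjects)
  rows <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    s <- draw_subject()
    id <- sprintf("S%03d", i)
    cls[[i]] <- centreline(s$pts, s$rad, lm_idx, id)
    w_named <- c(
      if (!is.null(curv)) stats::setNames(s$wc, colnames(curv$profiles)),
      if (!is.null(radm)) stats::setNames(s$wr, colnames(radm$profiles)))
    w_sd <- c(
      if (!is.null(curv)) stats::setNames(s$wc / curv$sds,
                                          paste0(colnames(curv$profiles), "_sd")),
      if (!is.null(radm)) stats::setNames(s$wr / radm$sds,
                                          paste0(colnames(radm$profiles), "_sd")))
    vals <- c(as.list(w_named), as.list(w_sd))
    parts <- list(data.frame(id = id))
    if (length(vals)) {
      parts <- c(parts, list(as.data.frame(vals, check.names = FALSE)))
    }
    parts <- c(parts, list(data.frame(gothic = gothic_of(s$wc))))
    rows[[i]] <- do.call(cbind, parts)
  }
  truth <- do.call(rbind, rows)
  out <- list(centrelines = cls, truth = truth,
              profiles = list(curvature = if (!is.null(curv)) curv$profiles,
                              radius = if (!is.null(radm)) radm$profiles,
                              curvature_sds = if (!is.null(curv)) curv$sds,
                              radius_sds = if (!is.null(radm)) radm$sds))
  attr(out, "n_redraws") <- n_redraws
  out
}
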