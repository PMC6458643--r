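MMHG <- 1333.22  # dyn/cm^2 per mmHg

#' Arterial tree configuration for the 1D model
#'
#' Validates a segment list into an arterial tree. Each segment is a list
#' with `id`, `length_cm`, `r_prox_cm`, `r_dist_cm` (linear taper),
#' `c0_cm_s` (reference wave speed defining the wall stiffness
#' `beta = 2 rho c0^2 sqrt(A0)`), optional `children` (character ids, 0-2),
#' optional `terminal` (`list(type = "rcr"|"resistance"|"closed", Zc =, Rp =,
#' Cp =, Pout_mmHg =)`, CGS units for Zc/Rp/Cp), and optional flags
#' `aortic`, `f_start`, `f_end` marking the aortic arc-length range the
#' segment occupies (used by [apply_radius_profile()]).
#'
#' @param segments List of segment definitions.
#' @param Pext_mmHg External (reference) pressure of the tube law, mmHg; the
#'   reference areas `A0` are the lumen areas at this pressure.
#' @param rho Blood density, g/cm^3.
#' @param mu Dynamic viscosity, poise; the friction coefficient is
#'   `Kf = 22 pi mu / rho` (Poiseuille-profile approximation).
#' @return An object of class `arterial_tree`.
#' @export
build_tree <- function(segments, Pext_mmHg = 0, rho = 1.06, mu = 0.04) {
  ids <- vapply(segments, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate segment ids")
  names(segments) <- ids
  child_ids <- unlist(lapply(segments, function(s) s$children))
  if (any(!child_ids %in% ids)) {
    stop("unknown child segment id(s): ",
         paste(setdiff(child_ids, ids), collapse = ", "))
  }
  if (anyDuplicated(child_ids)) stop("a segment has two parents (not a tree)")
  roots <- setdiff(ids, child_ids)
  if (length(roots) != 1L) {
    stop(sprintf("tree must have exactly one root segment (found %d)",
                 length(roots)))
  }
  # reachability from the root (detects cycles/orphans)
  seen <- character(0); stack <- roots
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    if (cur %in% seen) stop("cycle detected in segment connectivity")
    seen <- c(seen, cur)
    stack <- c(stack, segments[[cur]]$children)
  }
  if (length(seen) != length(ids)) {
    stop("orphan segment(s): ", paste(setdiff(ids, seen), collapse = ", "))
  }
  for (s in segments) {
    stopifnot(s$length_cm > 0, s$r_prox_cm > 0, s$r_dist_cm > 0)
    if (is.null(s$children) || length(s$children) == 0) {
      if (is.null(s$terminal)) {
        stop(sprintf("leaf segment '%s' has no terminal closure", s$id))
      }
    } else if (length(s$children) > 2L) {
      stop("junctions support at most two children")
    }
    if (is.null(s$c0_cm_s) && is.null(s$beta)) {
      stop(sprintf("segment '%s' needs c0_cm_s or beta", s$id))
    }
  }
  structure(list(segments = segments, root = roots, rho = rho,
                 Kf = 22 * pi * mu / rho, Pext = Pext_mmHg * MMHG),
            class = "arterial_tree")
}

#' Read an arterial tree from a YAML configuration
#'
#' @param path YAML file with top-level keys `segments` (list as in
#'   [build_tree()]) and optionally `Pext_mmHg`, `rho`, `mu`.
#' @return An `arterial_tree`.
#' @export
read_tree_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  build_tree(cfg$segments,
             Pext_mmHg = cfg$Pext_mmHg %||% 0,
             rho = cfg$rho %||% 1.06, mu = cfg$mu %||% 0.04)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default reduced systemic arterial tree
#'
#' A thoracic aorta discretised into ten segments (sinotubular junction to
#' diaphragm, matched to the 100-point radius-profile grid) with the three
#' head-and-neck branches leaving the arch, RCR windkessel terminals on every
#' leaf tuned to give a mean root pressure near 90 mmHg at a cardiac output
#' of about 5 l/min (peripheral run-off split roughly 65% lower body / 35%
#' head and arms), and reference wave speeds typical of a young adult aorta.
#'
#' @param r_profile_mm Optional 100-point aortic radius profile (mm) used for
#'   the aortic segment radii; defaults to [base_radius_profile()].
#' @return An `arterial_tree`.
#' @export
default_tree <- function(r_profile_mm = base_radius_profile(100L)) {
  rho <- 1.06
  r_at <- function(f) stats::approx(seq(0, 1, length.out =
                                          length(r_profile_mm)),
                                    r_profile_mm, f)$y / 10
  n_ao <- 10L
  f_edges <- seq(0, 1, length.out = n_ao + 1)
  ao <- lapply(seq_len(n_ao), function(i) {
    list(id = paste0("ao", i), length_cm = 2.5,
         r_prox_cm = r_at(f_edges[i]), r_dist_cm = r_at(f_edges[i + 1]),
         c0_cm_s = 470, aortic = TRUE,
         f_start = f_edges[i], f_end = f_edges[i + 1],
         children = if (i < n_ao) paste0("ao", i + 1))
  })
  # head-and-neck branches off the arch
  ao[[3]]$children <- c("ao4", "br_inn")
  ao[[4]]$children <- c("ao5", "br_lcc")
  ao[[5]]$children <- c("ao6", "br_lsa")
  term <- function(R_tot, A_ref, c0, frac) {
    Zc <- rho * c0 / A_ref
    list(type = "rcr", Zc = Zc, Rp = max(R_tot - Zc, 10),
         Cp = 6e-4 * frac, Pout_mmHg = 0)
  }
  R_tot <- 1445  # dyn s/cm^5, MBP ~90 mmHg at ~83 ml/s
  br <- list(
    list(id = "br_inn", length_cm = 4, r_prox_cm = 0.55, r_dist_cm = 0.5,
         c0_cm_s = 600,
         terminal = term(R_tot / 0.15, pi * 0.5^2, 600, 0.15)),
    list(id = "br_lcc", length_cm = 4, r_prox_cm = 0.35, r_dist_cm = 0.32,
         c0_cm_s = 600,
         terminal = term(R_tot / 0.08, pi * 0.32^2, 600, 0.08)),
    list(id = "br_lsa", length_cm = 4, r_prox_cm = 0.45, r_dist_cm = 0.4,
         c0_cm_s = 600,
         terminal = term(R_tot / 0.12, pi * 0.4^2, 600, 0.12))
  )
  ao[[n_ao]]$terminal <- term(R_tot / 0.65, pi * r_at(1)^2, 470, 0.65)
  build_tree(c(ao, br), Pext_mmHg = 70)
}

#' Time-varying elastance heart model
#'
#' Double-Hill normalised elastance (the standard two-sigmoid shape with
#' exponents 1.32 and 21.9 and characteristic times 0.269 T and 0.452 T),
#' scaled between `Emin` and `Emax`. The ventricle couples to the root
#' through an ideal valve with a quadratic (Bernoulli) pressure loss and
#' fills from a constant-pressure source through a mitral resistance.
#'
#' @param Emax,Emin End-systolic and baseline elastance, mmHg/ml.
#' @param period Cardiac period, s.
#' @param V0 Unstressed ventricular volume, ml.
#' @param filling_pressure Constant filling pressure, mmHg.
#' @param R_mitral Filling resistance, mmHg s/ml.
#' @param K_valve Bernoulli loss coefficient, mmHg/(ml/s)^2.
#' @return A list of class `heart_model` with an `E(t)` evaluator (mmHg/ml).
#' @export
heart_model <- function(Emax = 2.5, Emin = 0.07, period = 0.8, V0 = 10,
                        filling_pressure = 9, R_mitral = 0.01,
                        K_valve = 3e-5) {
  stopifnot(Emax > Emin, Emin > 0, period > 0)
  n1 <- 1.32; n2 <- 21.9; tau1 <- 0.269; tau2 <- 0.452
  shape <- function(tn) {
    g1 <- (tn / tau1)^n1
    (g1 / (1 + g1)) / (1 + (tn / tau2)^n2)
  }
  k <- 1 / max(shape(seq(0, 1, length.out = 2001)))
  E <- function(t) {
    tn <- (t %% period) / period
    Emin + (Emax - Emin) * k * shape(tn)
  }
  structure(list(E = E, Emax = Emax, Emin = Emin, period = period, V0 = V0,
                 filling_pressure = filling_pressure, R_mitral = R_mitral,
                 K_valve = K_valve), class = "heart_model")
}

# Discretise the tree into the per-node arrays the C++ solver consumes.
discretise_tree <- function(tree, dx) {
  ids <- names(tree$segments)
  lapply(tree$segments, function(s) {
    n <- max(3L, round(s$length_cm / dx) + 1L)
    seg_dx <- s$length_cm / (n - 1)
    r <- seq(s$r_prox_cm, s$r_dist_cm, length.out = n)
    A0 <- pi * r^2
    beta <- if (!is.null(s$c0_cm_s)) {
      2 * tree$rho * s$c0_cm_s^2 * sqrt(A0)
    } else rep(s$beta, n)
    tt <- 0L
    Zc <- Rp <- Cp <- Pout <- 0
    if (!is.null(s$terminal)) {
      tt <- switch(s$terminal$type, rcr = 1L, resistance = 2L, closed = 3L,
                   stop("unknown terminal type"))
      Zc <- s$terminal$Zc %||% 0
      Rp <- s$terminal$Rp %||% 0
      Cp <- s$terminal$Cp %||% 0
      Pout <- (s$terminal$Pout_mmHg %||% 0) * MMHG
    }
    list(A0 = A0, beta = beta, dx = seg_dx,
         children = as.integer(match(s$children, ids) - 1L),
         term_type = tt, Zc = Zc, Rp = Rp, Cp = Cp, Pout = Pout)
  })
}

#' Run a 1D pulse-wave simulation
#'
#' Integrates the 1D flow equations over `n_beats` cardiac cycles with
#' either a prescribed root inflow or a time-varying elastance heart at the
#' inlet. The time step is chosen from the CFL condition with the given
#' safety factor; a CFL violation or negative area during the run aborts
#' with an error. Convergence to a periodic state is judged from the
#' beat-to-beat change of root pulse pressure.
#'
#' @param tree An [build_tree()] result.
#' @param inlet Either a `heart_model` or a flow [waveform()] (ml/s)
#'   prescribing root inflow.
#' @param n_beats Number of cycles to run.
#' @param dx Target grid spacing, cm.
#' @param cfl CFL safety factor (< 1).
#' @param period Cycle length, s; defaults to the heart period or the
#'   waveform period.
#' @param monitors Data frame with columns `segment` (id) and `fraction`
#'   (0 = proximal, 1 = distal node) selecting output locations; default is
#'   the root inlet plus the distal end of every aortic segment path.
#' @param convergence_tol Relative beat-to-beat root pulse-pressure change
#'   accepted as periodic.
#' @return A list of class `sim_result`: `t` (s), per-monitor matrices `P`
#'   (mmHg), `Q` (ml/s), `A` (cm^2), `beat_pp` (mmHg), mass-balance
#'   summaries, `converged`, `dt`, `steps_per_beat` and the monitor table.
#' @export
simulate_tree <- function(tree, inlet, n_beats = 8L, dx = 0.5, cfl = 0.9,
                          period = NULL, monitors = NULL,
                          convergence_tol = 1e-3) {
  stopifnot(inherits(tree, "arterial_tree"))
  segs <- discretise_tree(tree, dx)
  ids <- names(tree$segments)
  # CFL-limited time step from reference wave speeds with headroom for
  # systolic dilation and advection
  c0max <- max(vapply(segs, function(s) {
    max(sqrt(s$beta / (2 * tree$rho * sqrt(s$A0))))
  }, numeric(1)))
  dxmin <- min(vapply(segs, `[[`, numeric(1), "dx"))
  dt <- cfl * dxmin / (1.35 * c0max + 150)
  if (is.null(period)) {
    period <- if (inherits(inlet, "heart_model")) inlet$period
              else inlet$period
  }
  steps_per_beat <- max(16L, as.integer(round(period / dt)))
  dt <- period / steps_per_beat
  nsteps <- as.integer(n_beats * steps_per_beat)

  tgrid <- (0:nsteps) * dt
  if (inherits(inlet, "heart_model")) {
    inlet_type <- 1L
    inflow <- numeric(1)
    heart <- list(E = inlet$E(tgrid) * MMHG, V0 = inlet$V0,
                  Vinit = inlet$V0 + inlet$filling_pressure / inlet$Emin,
                  Pfill = inlet$filling_pressure * MMHG,
                  Rmit = inlet$R_mitral * MMHG,
                  Kv = inlet$K_valve * MMHG)
  } else if (inherits(inlet, "waveform")) {
    inlet_type <- 0L
    inflow <- stats::approx(inlet$t, inlet$values,
                            xout = tgrid %% inlet$period, rule = 2)$y
    heart <- list(E = 0)
  } else stop("inlet must be a heart_model or a flow waveform")

  if (is.null(monitors)) {
    monitors <- data.frame(segment = ids[1], fraction = 0)
  }
  mon_seg <- match(monitors$segment, ids) - 1L
  if (anyNA(mon_seg)) stop("unknown monitor segment id")
  mon_node <- vapply(seq_len(nrow(monitors)), function(i) {
    n <- length(segs[[mon_seg[i] + 1L]]$A0)
    as.integer(round(monitors$fraction[i] * (n - 1)))
  }, integer(1))

  res <- solve_tree_1d(segs, tree$rho, tree$Kf, tree$Pext, dt, nsteps,
                       steps_per_beat, inlet_type, inflow, heart,
                       mon_seg, mon_node, 1L)
  pp <- res$beat_pp
  nb <- length(pp)
  converged <- nb >= 2 && pp[nb] > 0 &&
    abs(pp[nb] - pp[nb - 1]) / pp[nb] < convergence_tol
  if (!converged) {
    warning("simulation did not reach a periodic state; returning last beat")
  }
  sv <- res$inlet_vol_beat
  mass_err <- abs(res$inlet_vol_beat - res$outlet_vol_beat -
                    diff(res$stored_vol)) / pmax(abs(sv), 1e-12)
  structure(list(
    t = res$t, P = res$P / MMHG, Q = res$Q, A = res$A,
    heart = list(Pv = res$heart_Pv / MMHG, V = res$heart_V,
                 Qin = res$heart_Qin),
    beat_pp = pp / MMHG,
    inlet_vol_beat = res$inlet_vol_beat,
    outlet_vol_beat = res$outlet_vol_beat,
    stored_vol = res$stored_vol,
    mass_error = mass_err,
    converged = converged, dt = dt, steps_per_beat = steps_per_beat,
    monitors = monitors, tree = tree
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result: %d monitors, %d beats, dt = %.3g ms, %s>\n",
              ncol(x$P), length(x$beat_pp), 1000 * x$dt,
              if (x$converged) "periodic" else "NOT converged"))
  invisible(x)
}

#' Extract one monitored signal over the final beat as a waveform
#'
#' @param sim A [simulate_tree()] result.
#' @param monitor Monitor row index.
#' @param quantity `"P"` (mmHg), `"Q"` (ml/s), `"A"` (cm^2) or `"U"`
#'   (= Q/A, cm/s).
#' @return A [waveform()] over the last simulated cycle.
#' @export
sim_waveform <- function(sim, monitor = 1L, quantity = c("P", "Q", "A", "U")) {
  quantity <- match.arg(quantity)
  n <- length(sim$t)
  idx <- seq(n - sim$steps_per_beat, n - 1L)
  v <- switch(quantity,
              P = sim$P[idx, monitor],
              Q = sim$Q[idx, monitor],
              A = sim$A[idx, monitor],
              U = sim$Q[idx, monitor] / sim$A[idx, monitor])
  waveform(sim$t[idx] - sim$t[idx[1]], v,
           period = sim$steps_per_beat * sim$dt)
}

#' Impose a proto-aorta radius profile on the tree
#'
#' Replaces the proximal/distal radii of the aortic segments (those flagged
#' `aortic`, with arc-length fractions `f_start`/`f_end`) by interpolated
#' values of a 100-point radius profile in mm. Non-aortic segments are
#' untouched.
#'
#' @param tree An `arterial_tree` whose aortic segments carry arc-length
#'   fractions.
#' @param profile_mm Radius profile in mm over arc-length fractions
#'   `[0, 1]`.
#' @return The modified `arterial_tree`.
#' @export
apply_radius_profile <- function(tree, profile_mm) {
  if (any(profile_mm <= 0)) stop("radius profile must be strictly positive")
  f <- seq(0, 1, length.out = length(profile_mm))
  r_at <- function(fr) stats::approx(f, profile_mm, fr)$y / 10
  for (nm in names(tree$segments)) {
    s <- tree$segments[[nm]]
    if (isTRUE(s$aortic)) {
      tree$segments[[nm]]$r_prox_cm <- r_at(s$f_start)
      tree$segments[[nm]]$r_dist_cm <- r_at(s$f_end)
    }
  }
  tree
}

#' Pressure-velocity wave intensity analysis
#'
#' Conventional wave separation from pressure and velocity increments:
#' `dI+ = (dP + rho c dU)^2 / (4 rho c)`,
#' `dI- = -(dP - rho c dU)^2 / (4 rho c)`; their sum equals `dP dU`
#' identically. The returned frame is window-compatible with
#' [wave_areas()]: the forward/backward *pressure* increments occupy the
#' compression-discriminator columns.
#'
#' @param P Pressure [waveform()], mmHg (converted to CGS internally).
#' @param U Velocity [waveform()], cm/s.
#' @param rho Blood density, g/cm^3.
#' @param c Local wave speed, cm/s.
#' @return Data frame with `dI_plus`, `dI_minus`, `dI_net`, `dA_fwd`,
#'   `dA_bwd` (the latter two holding dP+/-, in dyn/cm^2).
#' @export
wia_pu <- function(P, U, rho = 1.06, c) {
  if (c <= 0) stop("wave speed must be positive")
  if (length(P$values) != length(U$values)) stop("P and U grids differ")
  dP <- diff(P$values) * MMHG
  dU <- diff(U$values)
  zc <- rho * c
  data.frame(
    dI_plus = (dP + zc * dU)^2 / (4 * zc),
    dI_minus = -(dP - zc * dU)^2 / (4 * zc),
    dI_net = dP * dU,
    dA_fwd = (dP + zc * dU) / 2,
    dA_bwd = (dP - zc * dU) / 2
  )
}

#' Proto-aorta simulation experiment
#'
#' For each selected radius principal component and display weight (+-1,
#' i.e. +-2 SD), reconstructs the proto-aorta radius profile, imposes it on
#' the aortic segments of the tree, simulates with the elastance heart, and
#' quantifies root wave reflection by conventional pressure-velocity wave
#' intensity. A weight-0 (mean shape) control run is included for every
#' component.
#'
#' @param model A radius [fit_shape_model()] result.
#' @param pcs Components to simulate (indices).
#' @param weights Display weights per component (default -1 and +1).
#' @param tree Arterial tree template (default [default_tree()]).
#' @param heart A [heart_model()].
#' @param n_beats,dx Passed to [simulate_tree()].
#' @return Data frame with one row per (pc, weight): `pc`, `weight`,
#'   `FCW_area`, `BCW_area`, `bcw_fcw_ratio`, plus attribute
#'   `"larger_bcw_weight"`: the weight with the larger BCW per component.
#' @export
run_proto_aorta_experiment <- function(model, pcs = 1:3,
                                       weights = c(-1, 1),
                                       tree = default_tree(),
                                       heart = heart_model(),
                                       n_beats = 6L, dx = 0.5) {
  if (model$kind != "radius") stop("a radius shape model is required")
  run_one <- function(pc, w) {
    wv <- numeric(ncol(model$components))
    if (pc > 0) wv[pc] <- w
    profile <- reconstruct(model, wv)
    tr <- apply_radius_profile(tree, profile)
    sim <- simulate_tree(tr, heart, n_beats = n_beats, dx = dx,
                         monitors = data.frame(segment = tr$root,
                                               fraction = 0))
    P <- sim_waveform(sim, 1L, "P")
    U <- sim_waveform(sim, 1L, "U")
    A <- sim_waveform(sim, 1L, "A")
    seg <- discretise_tree(tr, dx)[[tr$root]]
    c0_root <- sqrt(seg$beta[1] / (2 * tree$rho * sqrt(seg$A0[1])))
    c_loc <- c0_root * (mean(A$values) / seg$A0[1])^0.25
    wa <- wave_areas(wia_pu(P, U, rho = tree$rho, c = c_loc))
    data.frame(pc = pc, weight = w, FCW_area = wa$FCW_area,
               BCW_area = wa$BCW_area,
               bcw_fcw_ratio = wa$BCW_area / wa$FCW_area)
  }
  rows <- list(run_one(0, 0))
  for (pc in pcs) for (w in weights) rows <- c(rows, list(run_one(pc, w)))
  out <- do.call(rbind, rows)
  larger <- vapply(pcs, function(pc) {
    sub <- out[out$pc == pc, ]
    sub$weight[which.max(sub$BCW_area)]
  }, numeric(1))
  attr(out, "larger_bcw_weight") <- stats::setNames(larger,
                                                    paste0("pc", pcs))
  out
}
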