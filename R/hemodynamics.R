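#' Central pressure calibration from an area waveform
#'
#' Synthesises a central aortic pressure curve from a lumen area waveform and
#' brachial cuff pressures, using the single-stiffness-parameter exponential
#' pressure-area model `P(t) = P_d exp(alpha (A(t)/A_d - 1))`. The diastolic
#' anchor is `A_d = min(area)` with `P(A_d) = DBP`, resting on the assumption
#' that diastolic and mean pressures are conserved along the arterial tree.
#' The stiffness `alpha` is tuned by bracketed root finding so that the time
#' mean of the synthesised curve equals MBP (the mean is strictly increasing
#' in `alpha`, so the root is unique). Central SBP is the peak of the curve
#' and central pulse pressure is `c_SBP - DBP`.
#'
#' @param area An area [waveform()], cm^2, with non-zero pulsatility.
#' @param DBP Brachial diastolic pressure, mmHg.
#' @param MBP Brachial mean pressure, mmHg; must exceed DBP.
#' @param tol Absolute tolerance on the mean-pressure match, mmHg.
#' @return List of class `pressure_cal`: `alpha`, `P_d`, `A_d`, `c_SBP`,
#'   `c_PP`, and the synthesised `pressure` [waveform()].
#' @export
calibrate_pressure_from_area <- function(area, DBP, MBP, tol = 1e-6) {
  stopifnot(inherits(area, "waveform"), DBP > 0)
  if (MBP <= DBP) stop("MBP must exceed DBP")
  A <- area$values
  A_d <- min(A)
  if (max(A) - A_d <= 0) {
    stop("pulseless area waveform cannot be calibrated to MBP > DBP")
  }
  x <- A / A_d - 1
  f <- function(alpha) mean(DBP * exp(alpha * x)) - MBP
  lo <- 1e-3; hi <- 1e3
  if (f(lo) > 0 || f(hi) < 0) {
    stop("alpha outside the bracket [1e-3, 1e3]: pressures inconsistent with area pulsatility")
  }
  alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  P <- DBP * exp(alpha * x)
  # polish: uniroot tol is on alpha; verify the mean-match tolerance
  if (abs(mean(P) - MBP) > tol) {
    alpha <- stats::uniroot(f, c(alpha * 0.9, alpha * 1.1),
                            tol = .Machine$double.eps^0.75)$root
    P <- DBP * exp(alpha * x)
  }
  structure(list(alpha = alpha, P_d = DBP, A_d = A_d,
                 c_SBP = max(P), c_PP = max(P) - DBP,
                 pressure = waveform(area$t, P, area$period,
                                     kind = "pressure")),
            class = "pressure_cal")
}

#' Vascular resistance from mean pressure and cardiac output
#'
#' @param MBP Mean blood pressure, mmHg.
#' @param CO Cardiac output as mean aortic flow, ml/s.
#' @return R = MBP / CO, mmHg s/ml.
#' @export
vascular_resistance <- function(MBP, CO) {
  if (CO <= 0) stop("cardiac output must be positive")
  MBP / CO
}

#' Total arterial compliance by windkessel tuning
#'
#' Finds the compliance `C` of a 2-element windkessel (resistance `R` fixed
#' at the measured value) whose periodic steady-state pressure, driven by the
#' measured aortic flow, has a pulse pressure equal to the measured central
#' pulse pressure. Model pulse pressure is strictly decreasing in `C`, so a
#' bracketed root search converges to the unique solution.
#'
#' @param flow A flow [waveform()], ml/s.
#' @param R Vascular resistance, mmHg s/ml.
#' @param target_cPP Measured central pulse pressure, mmHg.
#' @param tol Tolerance on the pulse-pressure match, mmHg.
#' @return Compliance `C` in ml/mmHg.
#' @export
fit_tac <- function(flow, R, target_cPP, tol = 1e-4) {
  stopifnot(inherits(flow, "waveform"), R > 0)
  if (target_cPP <= 0) stop("target pulse pressure must be positive")
  if (wf_pulse(flow) <= 0) stop("flow waveform has no pulsatility")
  pp_of <- function(C) wf_pulse(generate_wk2_pressure(flow, R, C))
  C_lo <- 1e-6
  if (target_cPP >= pp_of(C_lo)) {
    stop("target pulse pressure unattainably large for this flow and resistance")
  }
  C_hi <- 1e4
  if (pp_of(C_hi) >= target_cPP) {
    stop("target pulse pressure too small: not attainable within bracket")
  }
  C <- stats::uniroot(function(C) pp_of(C) - target_cPP, c(C_lo, C_hi),
                      tol = 1e-12)$root
  if (abs(pp_of(C) - target_cPP) > tol) {
    stop("windkessel tuning failed to reach the pulse-pressure tolerance")
  }
  C
}

# Default QA-loop window: from flow-upstroke onset (first sample above 5% of
# the pulse above baseline) to the sample reaching 60% of the pulse.
qa_window <- function(flow) {
  q <- flow$values
  q0 <- min(q); qp <- max(q)
  i_pk <- which.max(q)
  start <- which(q > q0 + 0.05 * (qp - q0))
  start <- start[start <= i_pk][1]
  if (is.na(start)) stop("could not locate the flow upstroke")
  end <- start
  while (end < i_pk && q[end] < q0 + 0.60 * (qp - q0)) end <- end + 1L
  if (end - start + 1L < 4L) end <- min(i_pk, start + 3L)
  start:end
}

#' Wave speed from the flow-area (QA) loop
#'
#' Estimates local wave speed as the slope of the linear regression of flow
#' on area over an early-systolic window, where the wave is assumed
#' unidirectional so that `dQ = c dA` holds sample by sample. The default
#' window runs from the flow upstroke onset (5% of the pulse) to 60% of peak
#' flow, ahead of the arrival of reflections.
#'
#' @param flow,area [waveform()]s on the same grid.
#' @param window Optional integer sample indices to use instead of the
#'   automatic early-systolic window.
#' @return Wave speed `c` in cm/s (flow ml/s over area cm^2).
#' @export
wave_speed_qa <- function(flow, area, window = NULL) {
  stopifnot(inherits(flow, "waveform"), inherits(area, "waveform"))
  if (length(flow$values) != length(area$values)) {
    stop("flow and area must share one sampling grid")
  }
  if (is.null(window)) window <- qa_window(flow)
  if (length(window) < 4L) stop("QA window needs at least 4 samples")
  a <- area$values[window]; q <- flow$values[window]
  if (stats::var(a) < 1e-12 * max(1, mean(a))^2) {
    stop("area is constant over the window: QA loop is vertical")
  }
  c_hat <- stats::cov(q, a) / stats::var(a)
  if (c_hat <= 0) stop("non-positive QA slope: window is not an ejection upstroke")
  c_hat
}

#' Separate flow and area waves into forward and backward intensities
#'
#' Wave intensity in the flow-area formulation, computed from per-sample
#' increments (successive differences): `dI+ = (dQ + c dA)^2 / (4c)` and
#' `dI- = -(dQ - c dA)^2 / (4c)`. Their sum equals the net intensity
#' `dQ dA` identically. Forward/backward area increments
#' `dA+- = (dA +- dQ/c)/2` are returned as well; their sign distinguishes
#' compression (area rising) from decompression waves.
#'
#' @param flow,area [waveform()]s on the same grid.
#' @param c Wave speed, cm/s (> 0), e.g. from [wave_speed_qa()].
#' @return A data frame with one row per increment: `dI_plus`, `dI_minus`,
#'   `dI_net`, `dA_fwd`, `dA_bwd`.
#' @export
separate_waves_qa <- function(flow, area, c) {
  stopifnot(c > 0)
  if (length(flow$values) != length(area$values) ||
      abs(flow$dt - area$dt) > 1e-12) {
    stop("flow and area grids do not match")
  }
  dQ <- diff(flow$values); dA <- diff(area$values)
  data.frame(
    dI_plus = (dQ + c * dA)^2 / (4 * c),
    dI_minus = -(dQ - c * dA)^2 / (4 * c),
    dI_net = dQ * dA,
    dA_fwd = (dA + dQ / c) / 2,
    dA_bwd = (dA - dQ / c) / 2
  )
}

#' Areas of the forward and backward compression waves
#'
#' Sums the separated wave-intensity increments over the dominant compression
#' wave windows: the forward compression wave (FCW, ventricular ejection) is
#' the contiguous run around the maximum of `dI+` where the forward area
#' increment is positive; the backward compression wave (BCW, reflection) is
#' the contiguous run around the extremum of `dI-` where the backward area
#' increment is positive. Magnitudes are reported (both >= 0), in the
#' increment-sum convention (see the package vignette for the unit
#' discussion; multiply by `1/dt^2` via `convention = "timederiv"` for
#' time-normalised derivatives).
#'
#' @param sep Separated increments from [separate_waves_qa()] or [wia_pu()].
#' @param dt Sample interval, s (only used for the time-derivative
#'   convention).
#' @param convention `"increments"` (default) or `"timederiv"`.
#' @return List with `FCW_area` and `BCW_area`.
#' @export
wave_areas <- function(sep, dt = NULL, convention = c("increments",
                                                      "timederiv")) {
  convention <- match.arg(convention)
  scale <- 1
  if (convention == "timederiv") {
    if (is.null(dt)) stop("dt required for the time-derivative convention")
    scale <- 1 / dt^2
  }
  if (max(abs(sep$dI_net)) == 0) {
    return(list(FCW_area = 0, BCW_area = 0))
  }
  n <- nrow(sep)
  # Compression/decompression is discriminated on a lightly smoothed copy of
  # the forward/backward increments: on densely sampled (simulated) signals
  # the raw increments flicker in sign near zero, which would fragment the
  # contiguous wave window.
  smooth_w <- max(3L, 2L * (n %/% 128L) + 1L)
  sm <- function(x) stats::filter(x, rep(1 / smooth_w, smooth_w),
                                  sides = 2) |>
    (\(v) { v[is.na(v)] <- x[is.na(v)]; as.numeric(v) })()
  fwd_disc <- sm(sep$dA_fwd) > 0
  bwd_disc <- sm(sep$dA_bwd) > 0
  fwd_ok <- sep$dI_plus > 0 & fwd_disc
  if (!any(fwd_ok)) stop("no forward compression wave found")

  run_around <- function(centre, ok) {
    lo <- centre
    while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- centre
    while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
    lo:hi
  }
  cand <- which(fwd_ok)
  fcw_idx <- run_around(cand[which.max(sep$dI_plus[cand])], fwd_disc)
  FCW <- sum(sep$dI_plus[fcw_idx])
  BCW <- 0
  if (any(sep$dI_minus < 0 & bwd_disc)) {
    cand <- which(bwd_disc)
    centre <- cand[which.min(sep$dI_minus[cand])]
    bcw_idx <- run_around(centre, bwd_disc)
    BCW <- abs(sum(sep$dI_minus[bcw_idx]))
  }
  list(FCW_area = FCW * scale, BCW_area = BCW * scale)
}

#' Per-subject central haemodynamic summary
#'
#' Runs the full non-invasive chain for one subject: cardiac output from the
#' mean flow, resistance MBP/CO, central pressures by area calibration, total
#' arterial compliance by windkessel tuning to the derived central pulse
#' pressure, QA-loop wave speed, and flow-area wave separation with FCW/BCW
#' areas.
#'
#' @param flow,area [waveform()]s for the ascending aorta.
#' @param DBP,MBP,p_SBP Brachial pressures, mmHg.
#' @param BSA Body surface area, m^2 (for TACi).
#' @return One-row data frame: `CO`, `R`, `c_SBP`, `c_PP`, `TAC`, `TACi`,
#'   `wave_speed`, `FCW`, `BCW`.
#' @export
haemo_summary <- function(flow, area, DBP, MBP, p_SBP = NA, BSA = NA) {
  CO <- wf_mean(flow)
  R <- vascular_resistance(MBP, CO)
  cal <- calibrate_pressure_from_area(area, DBP, MBP)
  TAC <- fit_tac(flow, R, cal$c_PP)
  c_hat <- wave_speed_qa(flow, area)
  sep <- separate_waves_qa(flow, area, c_hat)
  wa <- wave_areas(sep)
  data.frame(CO = CO, R = R, c_SBP = cal$c_SBP, c_PP = cal$c_PP,
             TAC = TAC, TACi = TAC / BSA, wave_speed = c_hat,
             FCW = wa$FCW_area, BCW = wa$BCW_area)
}
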