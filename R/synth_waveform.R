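#' Configuration for the linear-wave waveform generator
#'
#' Describes a forward area pulse plus a delayed, scaled reflection under
#' linear wave theory. Flow and area increments of the forward component obey
#' `dQ_f = c dA_f` and of the backward component `dQ_b = -c dA_b`, so the
#' generated pair carries an exactly known forward/backward decomposition.
#'
#' @param period Cardiac cycle length, s.
#' @param dt Sampling interval, s. The default 0.0096 s mirrors a
#'   high-temporal-resolution phase-contrast acquisition (9.6 ms).
#' @param amplitude Peak of the forward area pulse, cm^2.
#' @param onset Pulse onset time, s.
#' @param width Pulse duration, s (raised-cosine support).
#' @param wave_speed_true True wave speed c, cm/s.
#' @param reflection_coeff Reflection coefficient Gamma in `[0, 1)` applied to
#'   the area pulse.
#' @param reflection_delay Two-way travel delay tau of the reflection, s.
#' @param baseline_area Diastolic lumen area, cm^2.
#' @param baseline_flow Diastolic flow offset, ml/s.
#' @return A list of class `wavegen_config`.
#' @export
wavegen_config <- function(period = 0.96, dt = 0.0096,
                           amplitude = 0.8, onset = 0.05, width = 0.42,
                           wave_speed_true = 470,
                           reflection_coeff = 0.15, reflection_delay = 0.15,
                           baseline_area = 4.5, baseline_flow = 15) {
  stopifnot(dt > 0, period > 0, width > 0, baseline_area > 0,
            reflection_delay >= 0, wave_speed_true > 0, amplitude >= 0)
  if (width >= period) stop("pulse width must be shorter than the period")
  if (reflection_coeff < 0 || reflection_coeff >= 1) {
    stop("reflection_coeff must lie in [0, 1)")
  }
  structure(list(period = period, dt = dt, amplitude = amplitude,
                 onset = onset, width = width,
                 wave_speed_true = wave_speed_true,
                 reflection_coeff = reflection_coeff,
                 reflection_delay = reflection_delay,
                 baseline_area = baseline_area, baseline_flow = baseline_flow),
            class = "wavegen_config")
}

# Unit-amplitude systolic pulse on [onset, onset + width], wrapped
# periodically: half-cosine rise (16% of width), plateau (24%) and a slow
# half-cosine fall (60%), mimicking the flat-topped distension of the
# ascending aorta.
hann_pulse <- function(t, onset, width, period) {
  tau <- (t - onset) %% period
  r <- 0.16 * width; p <- 0.24 * width; f <- 0.60 * width
  out <- numeric(length(tau))
  i1 <- tau < r
  out[i1] <- 0.5 * (1 - cos(pi * tau[i1] / r))
  i2 <- tau >= r & tau < r + p
  out[i2] <- 1
  i3 <- tau >= r + p & tau < width
  out[i3] <- 0.5 * (1 + cos(pi * (tau[i3] - r - p) / f))
  out
}

#' Generate flow and area waveforms with a known reflection
#'
#' Builds `A(t) = A_d + A_f(t) + Gamma * A_f(t - tau)` and the matching flow
#' `Q(t) = Q_0 + c A_f(t) - c Gamma A_f(t - tau)`, i.e. incremental wave
#' fronts that satisfy `dQ_f = c dA_f` (forward) and `dQ_b = -c dA_b`
#' (backward). The returned truth table contains the component signals and the
#' exact forward/backward compression-wave areas computed from the components
#' alone, so wave-separation code can be validated against it.
#'
#' @param cfg A [wavegen_config()].
#' @return A list with elements `flow`, `area` (both [waveform()]s) and
#'   `truth` (list: `wave_speed`, `reflection_coeff`, `reflection_delay`,
#'   component signals, `FCW_area`, `BCW_area`).
#' @export
generate_waveforms <- function(cfg) {
  stopifnot(inherits(cfg, "wavegen_config"))
  n <- round(cfg$period / cfg$dt)
  t <- (seq_len(n) - 1) * cfg$dt
  c_true <- cfg$wave_speed_true
  g <- cfg$reflection_coeff
  if (cfg$reflection_delay + cfg$onset + cfg$width > cfg$period) {
    warning("reflected pulse wraps around the cycle end")
  }
  A_f <- cfg$amplitude * hann_pulse(t, cfg$onset, cfg$width, cfg$period)
  A_b <- g * cfg$amplitude *
    hann_pulse(t, cfg$onset + cfg$reflection_delay, cfg$width, cfg$period)
  Q_f <- c_true * A_f
  Q_b <- -c_true * A_b
  area <- waveform(t, cfg$baseline_area + A_f + A_b, cfg$period, kind = "area")
  flow <- waveform(t, cfg$baseline_flow + Q_f + Q_b, cfg$period, kind = "flow")

  # Exact component-wise wave-intensity areas: dI+ = c dA_f^2 over the
  # forward compression window, dI- = -c dA_b^2 over the backward one.
  dAf <- diff(A_f); dAb <- diff(A_b)
  truth <- list(
    wave_speed = c_true,
    reflection_coeff = g,
    reflection_delay = cfg$reflection_delay,
    A_forward = A_f, A_backward = A_b, Q_forward = Q_f, Q_backward = Q_b,
    FCW_area = sum(c_true * dAf[dAf > 0]^2),
    BCW_area = sum(c_true * dAb[dAb > 0]^2)
  )
  list(flow = flow, area = area, truth = truth)
}

#' Area waveform from a pressure waveform (exponential tube law)
#'
#' Inverts the single-stiffness-parameter exponential pressure-area model
#' `P = P_d exp(alpha (A / A_d - 1))`, giving
#' `A(t) = A_d (1 + log(P(t) / P_d) / alpha)`. This is the exact forward
#' counterpart of [calibrate_pressure_from_area()].
#'
#' @param pressure A pressure [waveform()], mmHg, with `min(P) >= P_d`.
#' @param alpha Dimensionless wall stiffness parameter, > 0.
#' @param A_d Diastolic area, cm^2.
#' @param P_d Diastolic pressure, mmHg.
#' @return An area [waveform()] on the same grid.
#' @export
generate_area_from_pressure <- function(pressure, alpha, A_d, P_d) {
  stopifnot(inherits(pressure, "waveform"), alpha > 0, A_d > 0, P_d > 0)
  if (any(pressure$values < P_d - 1e-12 * P_d)) {
    stop("pressure falls below P_d: outside the domain of the exponential model")
  }
  A <- A_d * (1 + log(pressure$values / P_d) / alpha)
  waveform(pressure$t, A, pressure$period, kind = "area")
}

#' Periodic pressure from a flow waveform via a 2-element windkessel
#'
#' Solves `dP/dt = Q(t)/C - P/(RC)` in periodic steady state. Because the
#' equation is linear with periodic forcing, the steady cycle is obtained
#' exactly (for the trigonometric interpolant of the sampled flow) in the
#' frequency domain: `P_k = R Q_k / (1 + i w_k R C)`. The DC term gives
#' `mean(P) = R mean(Q)` identically.
#'
#' @param flow A flow [waveform()], ml/s; must be periodic.
#' @param R Peripheral resistance, mmHg s/ml.
#' @param C Total arterial compliance, ml/mmHg.
#' @return A pressure [waveform()] on the same grid, mmHg.
#' @export
generate_wk2_pressure <- function(flow, R, C) {
  stopifnot(inherits(flow, "waveform"), R > 0, C > 0)
  assert_periodic(flow, "flow")
  q <- flow$values
  n <- length(q)
  qhat <- stats::fft(q) / n
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # signed harmonic numbers
  w <- 2 * pi * k / flow$period
  phat <- R * qhat / (1 + 1i * w * R * C)
  p <- Re(stats::fft(phat, inverse = TRUE))
  waveform(flow$t, p, flow$period)
}
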