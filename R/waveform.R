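#' Periodic haemodynamic waveform
#'
#' A uniformly sampled signal over one cardiac cycle. Samples are taken at
#' `t = 0, dt, ..., period - dt` (the end point is not duplicated), so a
#' waveform of `n` samples covers the full cycle and its time mean is just
#' `mean(values)`.
#'
#' @param t Sample times in seconds (uniform grid starting at 0).
#' @param values Sample values; units depend on the quantity (ml/s for flow,
#'   cm^2 for area, mmHg for pressure, cm/s for velocity).
#' @param period Cycle length in seconds. Defaults to `n * dt`.
#' @param kind Optional label: `"flow"`, `"area"`, `"pressure"` or
#'   `"velocity"`.
#' @return An object of class `waveform`: a list with elements `t`, `values`,
#'   `period`, `dt` and `kind`.
#' @export
waveform <- function(t, values, period = NULL, kind = NULL) {
  t <- as.numeric(t)
  values <- as.numeric(values)
  n <- length(t)
  if (n < 16L) stop("waveform needs at least 16 samples per cycle")
  if (length(values) != n) stop("t and values must have equal length")
  if (anyNA(t) || anyNA(values)) stop("waveform must not contain NA")
  dt <- diff(t)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9 * max(dt)) {
    stop("waveform requires a strictly increasing uniform time grid")
  }
  dt <- mean(dt)
  if (is.null(period)) period <- n * dt
  if (abs(period - n * dt) > 1e-6 * period) {
    stop("period inconsistent with n * dt (no duplicated end point expected)")
  }
  if (!is.null(kind)) {
    kind <- match.arg(kind, c("flow", "area", "pressure", "velocity"))
    if (kind %in% c("area", "pressure") && any(values <= 0)) {
      stop(sprintf("%s waveform must be strictly positive", kind))
    }
  }
  structure(list(t = t, values = values, period = period, dt = dt,
                 kind = kind), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform%s: %d samples, dt = %.4g s, period = %.4g s, range [%.4g, %.4g]>\n",
              if (is.null(x$kind)) "" else paste0(" ", x$kind),
              length(x$t), x$dt, x$period, min(x$values), max(x$values)))
  invisible(x)
}

#' Time average of a periodic waveform
#'
#' @param wf A [waveform()].
#' @return The mean over one full cycle.
#' @export
wf_mean <- function(wf) mean(wf$values)

#' Peak-to-trough amplitude of a waveform
#'
#' @param wf A [waveform()].
#' @return `max(values) - min(values)`.
#' @export
wf_pulse <- function(wf) max(wf$values) - min(wf$values)

# Internal: check a sampled signal is plausibly periodic -- the wrap-around
# jump between the last and first sample should look like any other increment.
assert_periodic <- function(wf, what = "flow") {
  v <- wf$values
  d <- abs(diff(v))
  wrap <- abs(v[1L] - v[length(v)])
  tol <- 3 * max(d) + 1e-9 * (max(abs(v)) + 1)
  if (wrap > tol) {
    stop(sprintf("%s waveform is not periodic: wrap-around jump %.4g exceeds %.4g",
                 what, wrap, tol))
  }
  invisible(TRUE)
}
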