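# Shared fixtures built in code: small geometric shapes, clean waveforms and
# rigid motions used across the test files.

# A centreline along a straight line with constant radius.
straight_centreline <- function(n = 80, length_mm = 100, radius = 10) {
  pts <- cbind(seq(0, length_mm, length.out = n), 0, 0)
  centreline(pts, rep(radius, n))
}

# Quarter circle of given radius in the xy-plane.
quarter_circle_centreline <- function(n = 80, R = 10) {
  th <- seq(0, pi / 2, length.out = n)
  centreline(cbind(R * cos(th), R * sin(th), 0), rep(1, n))
}

# Random smooth 3D centreline (Fourier bumps), reproducible via the caller's
# RNG state.
random_centreline <- function(n = 50) {
  s <- seq(0, 1, length.out = n)
  pts <- cbind(
    100 * s + 5 * sin(2 * pi * s * runif(1, 0.5, 2)),
    30 * sin(pi * s) + 5 * rnorm(1) * sin(2 * pi * s),
    40 * s^2 + 5 * rnorm(1) * cos(pi * s))
  centreline(pts, 5 + 2 * s)
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Apply a rigid motion to a centreline.
move_centreline <- function(cl, R, t) {
  centreline(sweep(cl$points %*% t(R), 2, t, "+"), cl$radius, cl$landmarks,
             cl$id)
}

# Uniform time grid over one cycle (no duplicated end point).
cycle_grid <- function(period = 0.96, dt = 0.0096) {
  seq(0, period - dt, by = dt)
}

# Non-overlapping forward + reflected waveform pair used in the wave
# intensity tests (pulse and its reflection are separated in time:
# delay > width).
clean_reflection_config <- function(gamma = 0.3, c_true = 470) {
  wavegen_config(period = 0.96, dt = 0.0096, amplitude = 0.9, onset = 0.05,
                 width = 0.30, wave_speed_true = c_true,
                 reflection_coeff = gamma, reflection_delay = 0.50,
                 baseline_area = 4.5, baseline_flow = 0)
}

# Coarctation index of the unperturbed base radius profile.
base_coarctation_index <- function() {
  base <- base_radius_profile(100)
  base[63] / base[100]
}
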