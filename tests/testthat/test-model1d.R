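rho <- 1.06

single_tube <- function(L = 50, r = 1, c0 = 400, terminal = NULL) {
  if (is.null(terminal)) {
    terminal <- list(type = "resistance", Zc = rho * c0 / (pi * r^2),
                     Rp = 0, Pout_mmHg = 0)
  }
  build_tree(list(list(id = "tube", length_cm = L, r_prox_cm = r,
                       r_dist_cm = r, c0_cm_s = c0, terminal = terminal)))
}

narrow_pulse <- function(amp = 20, t0 = 0.08, w = 0.02, period = 0.8) {
  t <- seq(0, period - 0.002, by = 0.002)
  waveform(t, amp * exp(-((t - t0) / w)^2))
}

# time of the 5%-of-peak foot crossing, linearly interpolated
foot_time <- function(q, t) {
  th <- 0.05 * max(q)
  i <- which(q > th)[1]
  t[i - 1] + (th - q[i - 1]) / (q[i] - q[i - 1]) * (t[i] - t[i - 1])
}

test_that("tree construction validates connectivity and terminals", {
  tr <- single_tube()
  expect_s3_class(tr, "arterial_tree")
  expect_length(tr$segments, 1)
  # leaf without terminal
  expect_error(build_tree(list(list(id = "a", length_cm = 10,
                                    r_prox_cm = 1, r_dist_cm = 1,
                                    c0_cm_s = 400))), "terminal")
  # two roots
  t2 <- list(
    list(id = "a", length_cm = 10, r_prox_cm = 1, r_dist_cm = 1,
         c0_cm_s = 400,
         terminal = list(type = "closed")),
    list(id = "b", length_cm = 10, r_prox_cm = 1, r_dist_cm = 1,
         c0_cm_s = 400, terminal = list(type = "closed")))
  expect_error(build_tree(t2), "exactly one root")
  # unknown child
  expect_error(build_tree(list(list(id = "a", length_cm = 10,
                                    r_prox_cm = 1, r_dist_cm = 1,
                                    c0_cm_s = 400,
                                    children = "zz"))), "unknown child")
  # default tree: every leaf closed by an RCR terminal, positive path
  # lengths
  dt <- default_tree()
  leaves <- Filter(function(s) length(s$children) == 0, dt$segments)
  expect_true(all(vapply(leaves, function(s) identical(s$terminal$type,
                                                       "rcr"), logical(1))))
  expect_true(all(vapply(dt$segments, `[[`, numeric(1),
                         "length_cm") > 0))
})

test_that("radius profiles map onto aortic segments only", {
  tr <- default_tree()
  uni <- apply_radius_profile(tr, rep(10, 100))
  for (nm in names(uni$segments)) {
    s <- uni$segments[[nm]]
    if (isTRUE(s$aortic)) {
      expect_equal(s$r_prox_cm, 1.0)
      expect_equal(s$r_dist_cm, 1.0)
    } else {
      expect_identical(s$r_prox_cm, tr$segments[[nm]]$r_prox_cm)
    }
  }
  expect_error(apply_radius_profile(tr, c(rep(10, 99), -1)), "positive")
  # mean-shape profile reproduces the default construction
  tr0 <- apply_radius_profile(tr, base_radius_profile(100))
  expect_equal(tr0$segments$ao1$r_prox_cm, tr$segments$ao1$r_prox_cm,
               tolerance = 1e-12)
})

test_that("a small pulse propagates at the tube-law wave speed", {
  sim <- suppressWarnings(simulate_tree(
    single_tube(), narrow_pulse(), n_beats = 1, dx = 0.25, period = 0.8,
    monitors = data.frame(segment = "tube", fraction = c(0.2, 0.7))))
  dtt <- foot_time(sim$Q[, 2], sim$t) - foot_time(sim$Q[, 1], sim$t)
  c_meas <- 0.5 * 50 / dtt
  expect_equal(c_meas, 400, tolerance = 0.03)
})

test_that("per-beat volume balance closes", {
  sim <- suppressWarnings(simulate_tree(
    single_tube(), narrow_pulse(), n_beats = 2, dx = 0.25, period = 0.8))
  expect_lt(max(sim$mass_error), 0.005)
  sim2 <- suppressWarnings(simulate_tree(default_tree(), heart_model(),
                                         n_beats = 4))
  expect_lt(max(sim2$mass_error), 0.005)
})

test_that("reflection at a step radius change follows transmission-line
           theory", {
  c0 <- 400; r1 <- 1; r2 <- 0.7
  Z1 <- rho * c0 / (pi * r1^2); Z2 <- rho * c0 / (pi * r2^2)
  gam <- (Z2 - Z1) / (Z1 + Z2)
  tr <- build_tree(list(
    list(id = "s1", length_cm = 40, r_prox_cm = r1, r_dist_cm = r1,
         c0_cm_s = c0, children = "s2"),
    list(id = "s2", length_cm = 40, r_prox_cm = r2, r_dist_cm = r2,
         c0_cm_s = c0,
         terminal = list(type = "resistance", Zc = Z2, Rp = 0,
                         Pout_mmHg = 0))))
  sim <- suppressWarnings(simulate_tree(
    tr, narrow_pulse(amp = 10), n_beats = 1, dx = 0.25, period = 0.8,
    monitors = data.frame(segment = "s1", fraction = 0.5)))
  p <- sim$P[, 1] - sim$P[1, 1]
  # incident passes x = 20 cm around t = 0.08 + 20/400; reflected returns
  # 2 * 20 / 400 = 0.1 s later
  inc_win <- sim$t > 0.05 & sim$t < 0.18
  ref_win <- sim$t > 0.20 & sim$t < 0.33
  g_meas <- max(p[ref_win]) / max(p[inc_win])
  expect_equal(g_meas, gam, tolerance = 0.02)
})

test_that("a closed end reflects the full incident pressure wave", {
  tr <- single_tube(terminal = list(type = "closed"))
  sim <- suppressWarnings(simulate_tree(
    tr, narrow_pulse(amp = 10), n_beats = 1, dx = 0.25, period = 0.8,
    monitors = data.frame(segment = "tube", fraction = 0.4)))
  p <- sim$P[, 1] - sim$P[1, 1]
  inc_win <- sim$t > 0.05 & sim$t < 0.20   # incident passes 20 cm
  ref_win <- sim$t > 0.22 & sim$t < 0.40   # round trip 2*30/400 = 0.15 s
  expect_equal(max(p[ref_win]) / max(p[inc_win]), 1, tolerance = 0.05)
})

test_that("a matched terminal is nearly reflection-free", {
  sim <- suppressWarnings(simulate_tree(
    single_tube(), narrow_pulse(amp = 15), n_beats = 1, dx = 0.25,
    period = 0.8,
    monitors = data.frame(segment = "tube", fraction = 0.1)))
  P <- sim_waveform(sim, 1, "P"); U <- sim_waveform(sim, 1, "U")
  wa <- wave_areas(wia_pu(P, U, c = 400))
  expect_lt(wa$BCW_area, 0.02 * wa$FCW_area)
})

test_that("pressure-velocity separation is exact for a forward
           characteristic", {
  t <- cycle_grid(0.8, 0.004)
  U <- waveform(t, 40 * aortawave:::hann_pulse(t, 0.05, 0.3, 0.8))
  c0 <- 450
  P <- waveform(t, 75 + rho * c0 * U$values / aortawave:::MMHG,
                kind = "pressure")
  sep <- wia_pu(P, U, rho = rho, c = c0)
  expect_lt(max(abs(sep$dI_minus)), 1e-9 * max(sep$dI_plus))
  resid <- abs(sep$dI_plus + sep$dI_minus - sep$dI_net)
  expect_lt(max(resid), 1e-12 * max(abs(sep$dI_net)))
  expect_error(wia_pu(P, U, c = -1), "positive")
})

test_that("the elastance heart ejects and settles to a periodic state", {
  sim <- suppressWarnings(simulate_tree(default_tree(), heart_model(),
                                        n_beats = 10))
  expect_true(sim$converged)
  sv <- tail(sim$inlet_vol_beat, 1)
  expect_gt(sv, 30)                     # positive stroke volume
  P <- sim_waveform(sim, 1, "P")
  expect_gt(wf_mean(P), 60); expect_lt(wf_mean(P), 130)
  expect_gt(wf_pulse(P), 15)
  # inlet flow is never retrograde through the ideal valve
  expect_gte(min(sim$Q[, 1]), -1e-9)
})

test_that("halving the grid changes root pulse pressure by less than 1%", {
  tr <- single_tube(L = 30, c0 = 450,
                    terminal = list(type = "rcr",
                                    Zc = rho * 450 / pi, Rp = 1300,
                                    Cp = 4e-4, Pout_mmHg = 0))
  t <- seq(0, 0.8 - 0.002, by = 0.002)
  qin <- waveform(t, pmax(0, 300 * sin(pi * (t - 0.05) / 0.3)) *
                    (t > 0.05 & t < 0.35))
  pp <- vapply(c(0.5, 0.25), function(dx) {
    sim <- suppressWarnings(simulate_tree(tr, qin, n_beats = 6, dx = dx,
                                          period = 0.8))
    tail(sim$beat_pp, 1)
  }, numeric(1))
  expect_equal(pp[1], pp[2], tolerance = 0.01)
})

test_that("the proto-aorta experiment orders backward waves by
           proximal-distal calibre contrast", {
  cfg <- population_config(n_subjects = 250, seed = 61,
                           modes = proto_modes(), noise_sd = 0,
                           radius_noise_sd = 0.05)
  pop <- generate_centerline_population(cfg)
  # cohort generated at a common scale: profiles enter the PCA directly
  cls <- lapply(pop$centrelines, resample_centreline, n_points = 100L)
  m <- fit_shape_model(cls, "radius", 3)
  ex <- run_proto_aorta_experiment(m, pcs = 1:3)
  # baseline control present for the mean shape
  expect_true(any(ex$pc == 0 & ex$weight == 0))
  prox_dist <- function(w, pc) {
    v <- numeric(3); if (pc > 0) v[pc] <- w
    p <- reconstruct(m, v)
    mean(p[1:50]) / mean(p[51:100])
  }
  for (pc in 1:3) {
    sub <- ex[ex$pc == pc, ]
    adverse <- sub$weight[which.max(vapply(sub$weight, prox_dist, pc = pc,
                                           numeric(1)))]
    expect_gt(sub$BCW_area[sub$weight == adverse],
              sub$BCW_area[sub$weight == -adverse])
  }
  # swapping the +-1 labels swaps the comparison
  lw <- attr(ex, "larger_bcw_weight")
  ex_sw <- ex
  ex_sw$weight <- -ex_sw$weight
  lw_sw <- vapply(1:3, function(pc) {
    sub <- ex_sw[ex_sw$pc == pc, ]
    sub$weight[which.max(sub$BCW_area)]
  }, numeric(1))
  expect_equal(unname(lw_sw), -unname(lw))
})
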