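test_that("pressure calibration inverts the generator across alpha and HR", {
  for (alpha in c(2, 5, 10)) {
    for (hr in c(50, 75, 100)) {
      period <- 60 / hr
      t <- seq(0, period - 0.008, by = 0.008)
      P <- waveform(t, 72 + 46 * aortawave:::hann_pulse(t, 0.04,
                                                        0.4 * period,
                                                        period),
                    kind = "pressure")
      A <- generate_area_from_pressure(P, alpha, A_d = 4.8, P_d = 72)
      cal <- calibrate_pressure_from_area(A, DBP = 72, MBP = wf_mean(P))
      expect_equal(cal$alpha, alpha, tolerance = 1e-3)
      expect_lt(abs(cal$c_SBP - max(P$values)), 0.01)
      expect_lt(max(abs(cal$pressure$values - P$values)), 1e-4)
    }
  }
})

test_that("central pulse pressure is the SBP-DBP difference and degenerates
           gracefully", {
  t <- cycle_grid()
  A <- waveform(t, 4.5 + 0.8 * aortawave:::hann_pulse(t, 0.05, 0.4, 0.96),
                kind = "area")
  cal <- calibrate_pressure_from_area(A, DBP = 70, MBP = 88)
  expect_equal(cal$c_PP, cal$c_SBP - 70, tolerance = 1e-12)
  expect_equal(min(cal$pressure$values), 70, tolerance = 1e-9)
  expect_equal(wf_mean(cal$pressure), 88, tolerance = 1e-6)
  # MBP just above DBP: alpha and pulse collapse towards zero
  cal0 <- calibrate_pressure_from_area(A, DBP = 70, MBP = 70.01)
  expect_lt(cal0$alpha, 0.01)
  expect_lt(cal0$c_PP, 0.1)
  # pulseless area cannot satisfy MBP > DBP
  flatA <- waveform(t, rep(4.5, length(t)), kind = "area")
  expect_error(calibrate_pressure_from_area(flatA, 70, 88), "[Pp]ulseless")
})

test_that("vascular resistance is MBP over CO", {
  expect_equal(vascular_resistance(90, 90), 1.0)
  expect_equal(vascular_resistance(90, 180), 0.5)
  expect_equal(vascular_resistance(93, 83.3), 1.116, tolerance = 1e-3)
  expect_error(vascular_resistance(90, 0), "positive")
})

test_that("windkessel tuning recovers compliance from the analytic target", {
  t <- cycle_grid()
  w <- 2 * pi / 0.96
  q <- waveform(t, 85 + 30 * sin(w * t))
  R <- 1.1; C_star <- 1.2
  target <- 2 * 30 * R / sqrt(1 + (w * R * C_star)^2)
  expect_equal(fit_tac(q, R, target), C_star, tolerance = 1e-3)
  # halving the target pulse pressure strictly increases compliance
  expect_gt(fit_tac(q, R, target / 2), fit_tac(q, R, target))
  # unattainably large target
  expect_error(fit_tac(q, R, R * 70), "unattainab")
  expect_error(fit_tac(q, R, -1), "positive")
  # TACi is plain division by BSA, landing in the adult plausibility range
  wf <- generate_waveforms(wavegen_config(reflection_coeff = 0.18))
  cal <- calibrate_pressure_from_area(wf$area, 70, 70 + 53 / 3)
  Rm <- vascular_resistance(70 + 53 / 3, wf_mean(wf$flow))
  TAC <- fit_tac(wf$flow, Rm, cal$c_PP)
  TACi <- TAC / 1.9
  expect_equal(TACi, TAC / 1.9)
  expect_gt(TACi, 0.3); expect_lt(TACi, 1.0)
})

test_that("QA-loop wave speed is exact for unidirectional waves", {
  wf0 <- generate_waveforms(clean_reflection_config(gamma = 0))
  expect_equal(wave_speed_qa(wf0$flow, wf0$area), 470, tolerance = 1e-9)
  # any window inside the pulse works when all increments are colinear
  expect_equal(wave_speed_qa(wf0$flow, wf0$area, window = 8:14), 470,
               tolerance = 1e-9)
  # with a delayed reflection, the early-systolic window still recovers c
  wf3 <- generate_waveforms(clean_reflection_config(gamma = 0.3))
  expect_equal(wave_speed_qa(wf3$flow, wf3$area), 470, tolerance = 0.02)
  # degenerate: constant area
  t <- cycle_grid()
  flatA <- waveform(t, rep(4.5, length(t)), kind = "area")
  expect_error(wave_speed_qa(wf3$flow, flatA), "constant|vertical")
})

test_that("wave speed is inversely equivariant to area scaling", {
  wf <- generate_waveforms(clean_reflection_config(gamma = 0.2))
  c1 <- wave_speed_qa(wf$flow, wf$area)
  a2 <- waveform(wf$area$t, wf$area$values * 2, wf$area$period)
  expect_equal(wave_speed_qa(wf$flow, a2), c1 / 2, tolerance = 1e-9)
})

test_that("wave separation obeys its algebraic identity for any c", {
  wf <- generate_waveforms(wavegen_config(reflection_coeff = 0.25))
  for (c in c(150, 470, 900)) {
    sep <- separate_waves_qa(wf$flow, wf$area, c)
    resid <- abs(sep$dI_plus + sep$dI_minus - sep$dI_net)
    expect_lt(max(resid), 1e-12 * max(abs(sep$dI_net)))
  }
})

test_that("pure forward and pure backward waves separate cleanly", {
  wf0 <- generate_waveforms(clean_reflection_config(gamma = 0))
  sep <- separate_waves_qa(wf0$flow, wf0$area, 470)
  expect_lt(max(abs(sep$dI_minus)), 1e-10 * max(sep$dI_plus))
  # pure backward wave: dQ = -c dA
  t <- cycle_grid()
  A <- waveform(t, 4.5 + 0.5 * aortawave:::hann_pulse(t, 0.3, 0.2, 0.96))
  Q <- waveform(t, -470 * (A$values - 4.5))
  sepb <- separate_waves_qa(Q, A, 470)
  expect_equal(max(abs(sepb$dI_plus)), 0, tolerance = 1e-20)
})

test_that("wave areas match component truth and scale quadratically", {
  wf <- generate_waveforms(clean_reflection_config(gamma = 0.3))
  sep <- separate_waves_qa(wf$flow, wf$area, wave_speed_qa(wf$flow,
                                                           wf$area))
  wa <- wave_areas(sep)
  expect_equal(wa$FCW_area, wf$truth$FCW_area, tolerance = 0.05)
  expect_equal(wa$BCW_area, wf$truth$BCW_area, tolerance = 0.05)
  expect_lt(abs(wa$BCW_area / wa$FCW_area - 0.09) / 0.09, 0.05)
  # doubling the forward amplitude quadruples the FCW area
  cfg2 <- clean_reflection_config(gamma = 0)
  wa1 <- wave_areas(separate_waves_qa(
    generate_waveforms(cfg2)$flow, generate_waveforms(cfg2)$area, 470))
  cfg2$amplitude <- cfg2$amplitude * 2
  wf2 <- generate_waveforms(cfg2)
  wa2 <- wave_areas(separate_waves_qa(wf2$flow, wf2$area, 470))
  expect_equal(wa2$FCW_area / wa1$FCW_area, 4, tolerance = 1e-9)
  # time-derivative convention is a pure 1/dt^2 rescaling
  wa_td <- wave_areas(sep, dt = 0.0096, convention = "timederiv")
  expect_equal(wa_td$FCW_area, wa$FCW_area / 0.0096^2)
})

test_that("wave areas depend only on increments, not offsets", {
  wf <- generate_waveforms(clean_reflection_config(gamma = 0.3))
  sep1 <- separate_waves_qa(wf$flow, wf$area, 470)
  fshift <- waveform(wf$flow$t, wf$flow$values + 57)
  ashift <- waveform(wf$area$t, wf$area$values + 2.3)
  sep2 <- separate_waves_qa(fshift, ashift, 470)
  wa1 <- wave_areas(sep1); wa2 <- wave_areas(sep2)
  expect_equal(wa2$BCW_area, wa1$BCW_area, tolerance = 1e-12)
  expect_equal(wa2$FCW_area, wa1$FCW_area, tolerance = 1e-12)
})

test_that("the per-subject summary chains all derivations consistently", {
  wf <- generate_waveforms(wavegen_config(reflection_coeff = 0.2))
  h <- haemo_summary(wf$flow, wf$area, DBP = 70, MBP = 88, p_SBP = 123,
                     BSA = 1.85)
  expect_equal(h$CO, wf_mean(wf$flow))
  expect_equal(h$R, 88 / h$CO)
  expect_equal(h$TACi, h$TAC / 1.85)
  expect_gt(h$c_SBP, 88)
  expect_equal(h$wave_speed, 470, tolerance = 0.05)
  expect_gt(h$FCW, 0); expect_gt(h$BCW, 0)
  expect_lt(h$BCW, h$FCW)
})
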