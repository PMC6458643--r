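#' Generate a complete synthetic study cohort
#'
#' Builds per-subject records combining a synthetic centreline (see
#' [generate_centerline_population()]), flow/area waveforms with a known
#' forward wave and reflection (see [generate_waveforms()]), cuff pressures
#' and covariates. The reflection coefficient of each subject's waveform is
#' linked to its radius-mode weights through a configurable linear predictor,
#' so that associations between calibre modes and backward-wave magnitude
#' exist by construction and can be recovered by the analysis stages.
#'
#' Per-subject waveform baseline area is derived from the subject's own
#' ascending aortic radius; wave speed varies across subjects.
#'
#' @param cfg A [population_config()].
#' @param wave_cfg A [wavegen_config()] providing the cohort-level waveform
#'   defaults (period, sampling, pulse shape).
#' @param reflection_link Named numeric vector of coefficients on the
#'   radius-mode weights (SD units) in the linear predictor of the
#'   reflection coefficient, plus an `(intercept)` term; Gamma =
#'   0.6 * plogis(eta). Names must match radius mode ids.
#' @return List of subject records, each a list with elements `id`,
#'   `centreline`, `flow`, `area`, `p_SBP`, `DBP`, `MBP`, `BSA`, `LVMi`,
#'   `LVEF`, `gothic` and `truth` (generator parameters incl. wave speed and
#'   reflection coefficient). The population truth table and mode profiles
#'   are attached as attributes `truth` and `profiles`.
#' @export
generate_cohort <- function(cfg, wave_cfg = wavegen_config(),
                            reflection_link = c(
                              "(intercept)" = -0.85,
                              ascending_dilation = 0.5,
                              isthmus_narrowing = -0.35,
                              arch_hypoplasia = -0.35)) {
  pop <- generate_centerline_population(cfg)
  n <- cfg$n_subjects
  truth <- pop$truth

  # Covariate draws follow the shape draws in the same RNG stream, so the
  # whole cohort is reproducible from (config, seed).
  DBP <- stats::rnorm(n, 70, 8)
  PPp <- pmax(stats::rnorm(n, 53, 10), 25)
  p_SBP <- DBP + PPp
  MBP <- DBP + PPp / 3
  BSA <- pmax(stats::rnorm(n, 1.85, 0.2), 1.2)
  LVMi <- pmax(stats::rnorm(n, 72, 14), 35)
  LVEF <- pmin(pmax(stats::rnorm(n, 66, 7.5), 40), 85)
  c_true <- pmax(stats::rnorm(n, 470, 40), 300)
  gamma_noise <- stats::rnorm(n, 0, 0.35)

  rad_ids <- if (is.null(pop$profiles$radius)) character(0) else
    colnames(pop$profiles$radius)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- pop$centrelines[[i]]
    eta <- unname(reflection_link["(intercept)"]) + gamma_noise[i]
    for (id in rad_ids) {
      cf <- reflection_link[id]
      if (!is.na(cf)) eta <- eta + cf * truth[[paste0(id, "_sd")]][i]
    }
    gamma <- 0.6 * stats::plogis(eta)
    A_d <- pi * (cl$radius[max(1L, round(0.05 * length(cl$radius)))] / 10)^2
    wcfg <- wave_cfg
    wcfg$baseline_area <- A_d
    wcfg$amplitude <- 0.18 * A_d
    wcfg$wave_speed_true <- c_true[i]
    wcfg$reflection_coeff <- gamma
    wf <- generate_waveforms(wcfg)
    subjects[[i]] <- list(
      id = cl$id, centreline = cl, flow = wf$flow, area = wf$area,
      p_SBP = p_SBP[i], DBP = DBP[i], MBP = MBP[i], BSA = BSA[i],
      LVMi = LVMi[i], LVEF = LVEF[i], gothic = truth$gothic[i],
      truth = c(wf$truth[c("wave_speed", "reflection_coeff",
                           "FCW_area", "BCW_area")],
                list(mode_weights_sd = truth[i, grep("_sd$", names(truth))]))
    )
  }
  attr(subjects, "truth") <- truth
  attr(subjects, "profiles") <- pop$profiles
  attr(subjects, "n_redraws") <- attr(pop, "n_redraws")
  subjects
}

#' Write a synthetic cohort to disk
#'
#' Lays out the cohort in the plain-text exchange format consumed by the
#' analysis stages: `centrelines/<id>.csv`, `waveforms/<id>.csv` (columns
#' `t_s, flow_ml_s, area_cm2`), `subjects.csv` and `truth.json`.
#'
#' @param subjects Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(file.path(dir, "centrelines"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "waveforms"), showWarnings = FALSE)
  for (s in subjects) {
    write_centreline_csv(s$centreline,
                         file.path(dir, "centrelines",
                                   paste0(s$id, ".csv")))
    utils::write.csv(
      data.frame(t_s = s$flow$t, flow_ml_s = s$flow$values,
                 area_cm2 = s$area$values),
      file.path(dir, "waveforms", paste0(s$id, ".csv")), row.names = FALSE)
  }
  subj <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(id = s$id, p_sbp = s$p_SBP, dbp = s$DBP, mbp = s$MBP,
               bsa = s$BSA, lvmi = s$LVMi, lvef = s$LVEF,
               gothic = as.integer(s$gothic))
  }))
  utils::write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE)
  jsonlite::write_json(attr(subjects, "truth"),
                       file.path(dir, "truth.json"), digits = NA,
                       dataframe = "columns")
  invisible(dir)
}

#' Read a flow/area waveform CSV
#'
#' @param path CSV with columns `t_s`, `flow_ml_s`, `area_cm2`.
#' @return List with `flow` and `area` [waveform()]s.
#' @export
read_waveforms_csv <- function(path) {
  df <- utils::read.csv(path)
  list(flow = waveform(df$t_s, df$flow_ml_s, kind = "flow"),
       area = waveform(df$t_s, df$area_cm2, kind = "area"))
}
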