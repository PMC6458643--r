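#' Study configuration
#'
#' Single configuration object for the end-to-end synthetic study replica.
#' All randomness is funnelled through one seed.
#'
#' @param n_subjects Cohort size.
#' @param seed RNG seed.
#' @param n_components Principal components retained per shape model.
#' @param coarctation_exclusion Subjects with coarctation index below this
#'   value are excluded (residual narrowing filter).
#' @param run_model1d Whether to run the proto-aorta 1D experiment stage.
#' @param model1d_pcs Radius components to simulate in that stage.
#' @param population Overrides passed to [population_config()] (list).
#' @param wave Overrides passed to [wavegen_config()] (list).
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_subjects = 60L, seed = 1L, n_components = 5L,
                         coarctation_exclusion = 0.7, run_model1d = TRUE,
                         model1d_pcs = 1:3,
                         population = list(), wave = list()) {
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed),
                 n_components = as.integer(n_components),
                 coarctation_exclusion = coarctation_exclusion,
                 run_model1d = run_model1d, model1d_pcs = model1d_pcs,
                 population = population, wave = wave),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose keys mirror the [study_config()] arguments.
#' @return A `study_config`.
#' @export
read_study_yaml <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw, f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic study
#'
#' Orchestrates the whole analysis end to end on a synthetic cohort:
#' generate centrelines, waveforms and covariates; exclude residual
#' narrowing (coarctation index below the configured threshold); normalise
#' (resample to 100 points, scale to the population mean length and mean
#' radius) and rigidly register to a generalised-alignment reference; fit
#' separate curvature and radius shape models; derive per-subject central
#' haemodynamics; build the univariable association table plus the
#' multivariable (BCW on radius components) and logistic (gothic label on
#' curvature components) models; optionally run the 1D proto-aorta
#' experiment; and assemble a run manifest.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory to write cohort CSVs, model JSON,
#'   association tables and the manifest into.
#' @return A list of class `study_report`: `manifest`, `cohort` (merged
#'   per-subject table), `curvature_model`, `radius_model`,
#'   `variance_fractions`, `assoc` (the [table1()] object), `bcw_multi`,
#'   `gothic_logistic`, `exclusions`, and `proto_experiment` (or `NULL`).
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  pop_args <- utils::modifyList(
    list(n_subjects = config$n_subjects, seed = config$seed),
    config$population)
  cfg <- do.call(population_config, pop_args)
  wcfg <- do.call(wavegen_config, config$wave)
  subjects <- generate_cohort(cfg, wcfg)

  # ---- geometry indices and exclusion filter (on raw centrelines) ----
  idx <- lapply(subjects, function(s) geometry_indices(s$centreline))
  ci <- vapply(idx, `[[`, numeric(1), "coarctation_index")
  ai <- vapply(idx, `[[`, numeric(1), "arch_index")
  excluded <- which(ci < config$coarctation_exclusion)
  exclusions <- data.frame(
    id = vapply(subjects[excluded], `[[`, "", "id"),
    coarctation_index = ci[excluded],
    rule = rep(sprintf("coarctation index < %g",
                       config$coarctation_exclusion), length(excluded)))
  keep <- setdiff(seq_along(subjects), excluded)
  subjects_k <- subjects[keep]
  ci_k <- ci[keep]; ai_k <- ai[keep]

  # ---- shape normalisation and registration ----
  cls <- lapply(subjects_k, function(s) resample_centreline(s$centreline,
                                                            100L))
  mean_len <- mean(vapply(cls, arc_length, numeric(1)))
  cls_len <- lapply(cls, normalise_length, target_length = mean_len)
  mean_rad <- mean(vapply(cls, function(cl) mean(cl$radius), numeric(1)))
  cls_rad <- lapply(cls_len, normalise_radius,
                    target_mean_radius = mean_rad)
  ref <- build_reference(cls_len)
  cls_reg <- lapply(cls_rad, rigid_register, reference = ref)

  curv_model <- fit_shape_model(cls_reg, "curvature", config$n_components)
  rad_model <- fit_shape_model(cls_reg, "radius", config$n_components)

  # ---- haemodynamics ----
  haemo <- do.call(rbind, lapply(subjects_k, function(s) {
    cbind(data.frame(id = s$id),
          haemo_summary(s$flow, s$area, s$DBP, s$MBP, s$p_SBP, s$BSA))
  }))

  # ---- merged cohort table ----
  cw <- curv_model$subject_weights
  rw <- rad_model$subject_weights
  colnames(cw) <- paste0("pc_curv", seq_len(ncol(cw)))
  colnames(rw) <- paste0("pc_rad", seq_len(ncol(rw)))
  cohort <- cbind(
    data.frame(id = vapply(subjects_k, `[[`, "", "id")),
    cw, rw,
    data.frame(coarctation_index = ci_k, arch_index = ai_k,
               p_SBP = vapply(subjects_k, `[[`, numeric(1), "p_SBP"),
               LVMi = vapply(subjects_k, `[[`, numeric(1), "LVMi"),
               LVEF = vapply(subjects_k, `[[`, numeric(1), "LVEF"),
               gothic = vapply(subjects_k, `[[`, logical(1), "gothic")),
    haemo[, setdiff(names(haemo), "id")])

  # ---- association stage ----
  assoc <- table1(cohort)
  rad_cols <- paste0("pc_rad", seq_len(ncol(rw)))
  sig_rad <- rad_cols[assoc$p[rad_cols, "BCW"] < 0.05]
  bcw_multi <- if (length(sig_rad) >= 1) {
    ols_multi(as.matrix(cohort[, sig_rad, drop = FALSE]), cohort$BCW)
  }
  gothic_logit <- if (length(unique(cohort$gothic)) == 2) {
    logistic_assoc(cohort$gothic,
                   as.matrix(cohort[, colnames(cw), drop = FALSE]))
  }

  # ---- 1D proto-aorta experiment ----
  proto <- NULL
  if (isTRUE(config$run_model1d)) {
    proto <- run_proto_aorta_experiment(rad_model, pcs = config$model1d_pcs)
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_subjects = config$n_subjects,
    n_excluded = length(excluded),
    n_analysed = length(keep),
    n_components = config$n_components,
    mean_length_mm = mean_len,
    mean_radius_mm = mean_rad,
    package_version = as.character(utils::packageVersion("aortawave")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  report <- structure(list(
    manifest = manifest, cohort = cohort,
    curvature_model = curv_model, radius_model = rad_model,
    variance_fractions = list(
      curvature = curv_model$variance_fraction,
      radius = rad_model$variance_fraction),
    assoc = assoc, bcw_multi = bcw_multi, gothic_logistic = gothic_logit,
    exclusions = exclusions, proto_experiment = proto,
    reference = ref), class = "study_report")

  if (!is.null(out_dir)) write_study_report(report, subjects, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Study replica: %d subjects analysed (%d excluded), %d PCs\n",
              m$n_analysed, m$n_excluded, m$n_components))
  cat("curvature variance fractions: ",
      paste(sprintf("%.0f%%", 100 * x$variance_fractions$curvature),
            collapse = " "), "\n")
  cat("radius variance fractions:    ",
      paste(sprintf("%.0f%%", 100 * x$variance_fractions$radius),
            collapse = " "), "\n")
  if (!is.null(x$bcw_multi)) {
    cat(sprintf("BCW ~ radius PCs: r^2 = %.2f (p = %.3g)\n",
                x$bcw_multi$r_squared, x$bcw_multi$p_overall))
  }
  if (!is.null(x$proto_experiment)) {
    lw <- attr(x$proto_experiment, "larger_bcw_weight")
    cat("proto-aorta larger-BCW weights:",
        paste(names(lw), lw, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Write the study outputs as plain-text artefacts.
write_study_report <- function(report, subjects, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(subjects, file.path(out_dir, "cohort"))
  utils::write.csv(report$cohort, file.path(out_dir, "merged.csv"),
                   row.names = FALSE)
  write_shape_model(report$curvature_model,
                    file.path(out_dir, "model_curvature.json"))
  write_shape_model(report$radius_model,
                    file.path(out_dir, "model_radius.json"))
  write_assoc_csv(report$assoc, file.path(out_dir, "table1.csv"))
  if (!is.null(report$proto_experiment)) {
    utils::write.csv(report$proto_experiment,
                     file.path(out_dir, "proto_experiment.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
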