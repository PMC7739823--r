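#' Configuration for a full pipeline run
#'
#' Bundles the cohort generating model with the analysis options and the
#' synthetic measurement-noise levels applied when each subject's label
#' volume, range-of-motion trial, and gait trial are simulated.
#'
#' @param cohort a [cohort_config()].
#' @param alpha significance level.
#' @param cap_p cap Holm-adjusted p-values at 1.
#' @param exact_cutoff largest pooled n for the exact Mann-Whitney test.
#' @param force_cutoff_hz,marker_cutoff_hz inverse-dynamics filter
#'   cutoffs.
#' @param tendon_slices axial slices of each subject's free tendon
#'   phantom.
#' @param rom_marker_noise_mm,rom_edge_noise_mm measurement noise in the
#'   range-of-motion trials.
#' @param gait_noise list passed to [generate_gait_trial()] (`grf_sd_n`,
#'   `marker_sd_m`, `torque_cv`).
#' @param n_strides strides per gait trial.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       alpha = 0.05,
                       cap_p = FALSE,
                       exact_cutoff = 25,
                       force_cutoff_hz = 25,
                       marker_cutoff_hz = 6,
                       tendon_slices = 26,
                       rom_marker_noise_mm = 0.5,
                       rom_edge_noise_mm = 0.3,
                       gait_noise = list(grf_sd_n = 5, marker_sd_m = 5e-4,
                                         torque_cv = 0.05),
                       n_strides = 12) {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, alpha = alpha, cap_p = cap_p,
                 exact_cutoff = exact_cutoff,
                 force_cutoff_hz = force_cutoff_hz,
                 marker_cutoff_hz = marker_cutoff_hz,
                 tendon_slices = tendon_slices,
                 rom_marker_noise_mm = rom_marker_noise_mm,
                 rom_edge_noise_mm = rom_edge_noise_mm,
                 gait_noise = gait_noise, n_strides = n_strides),
            class = "run_config")
}

#' Run the full simulate - measure - analyze - report pipeline
#'
#' Stages, in dependency order:
#' \enumerate{
#'   \item \strong{simulate} - generate the cohort and, per subject, a
#'     labeled limb phantom (NIfTI), a range-of-motion trial, and a gait
#'     trial, all from the subject's ground truth;
#'   \item \strong{morphometry} - read each phantom back and measure
#'     muscle volumes, tendon geometry, and ratios;
#'   \item \strong{moment_arm} - read each trial back and estimate the
#'     neutral-posture moment arm;
#'   \item \strong{gait} - inverse dynamics per trial: mean peak
#'     plantarflexion torque, spatiotemporal parameters, tendon force;
#'   \item \strong{stats} - assemble the three cohort tables from the
#'     measured (not true) values.
#' }
#' Writes `measures.csv`, the table reports, and a `manifest.json`
#' recording the seed, configuration, stages, and file checksums. Outputs
#' are a pure function of (config, seed); a rerun with the same seed is
#' byte-identical. On stage failure a `FAILED` marker naming the stage is
#' left in the run directory and the error is re-raised.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created; reused if present).
#' @return invisibly, a list with `measures` (data.frame), `tables`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  stage <- "simulate"
  manifest <- list(seed = config$cohort$seed,
                   r_version = R.version.string,
                   package_version = as.character(
                     utils::packageVersion("tsmorph")),
                   stages = character(0))
  result <- tryCatch({
    ## stage 1: simulate
    cohort <- generate_cohort(config$cohort)
    sim_dir <- file.path(out_dir, "simulated")
    write_cohort(cohort, sim_dir)
    ids <- cohort$subjects$id
    for (i in seq_along(ids)) {
      tru <- cohort$truth[[ids[i]]]
      sseed <- child_seed(config$cohort$seed, 100L, i)
      vol <- generate_label_volume(
        tru$true_volumes_cm3,
        tendon = tendon_spec(tru$true_csa_mm2, config$tendon_slices))
      write_label_volume(vol, file.path(sim_dir,
                                        paste0(ids[i], "_labels.nii.gz")))
      rom <- generate_rom_trial(
        axis = list(point = c(30, 40, 60), direction = c(0.97, 0.17, 0.17)),
        quad_coeffs = c(tru$true_moment_arm_mm, -0.1, -0.01),
        marker_noise_sd = config$rom_marker_noise_mm,
        edge_noise_sd = config$rom_edge_noise_mm,
        seed = child_seed(sseed, 1L))
      write_rom_trial(rom, file.path(sim_dir, paste0(ids[i], "_rom")))
      gait <- generate_gait_trial(
        peak_torque_nm = tru$true_peak_torque_nm,
        n_strides = config$n_strides,
        body_mass_kg = cohort$subjects$mass_kg[i],
        noise = config$gait_noise,
        seed = child_seed(sseed, 2L))
      write_gait_trial(gait, file.path(sim_dir, paste0(ids[i], "_gait")))
    }
    manifest$stages <- c(manifest$stages, "simulate")

    ## stage 2: morphometry
    stage <- "morphometry"
    meas <- cohort$subjects[, c("id", "group", "height_m", "mass_kg",
                                "height_mass_kgm")]
    morph_rows <- lapply(seq_along(ids), function(i) {
      vol <- read_label_volume(file.path(sim_dir,
                                         paste0(ids[i], "_labels.nii.gz")))
      mm <- compute_muscle_volumes(vol, meas$height_m[i], meas$mass_kg[i])
      tg <- tendon_geometry(vol)
      utils::write.csv(tg$profile,
                       file.path(sim_dir, paste0(ids[i], "_csa_profile.csv")),
                       row.names = FALSE)
      c(stats::setNames(mm$volumes_cm3, paste0("vol_", names(mm$volumes_cm3))),
        vol_total_cm3 = mm$total_cm3,
        tendon_csa_mm2 = tg$mid_csa_mm2,
        tendon_length_mm = tg$length_mm,
        tendon_volume_cm3 = tg$volume_cm3)
    })
    meas <- cbind(meas, as.data.frame(do.call(rbind, morph_rows)))
    manifest$stages <- c(manifest$stages, "morphometry")

    ## stage 3: moment arm
    stage <- "moment_arm"
    meas$moment_arm_mm <- vapply(ids, function(id) {
      rom <- read_rom_trial(file.path(sim_dir, paste0(id, "_rom")))
      analyze_rom_trial(rom)$moment_arm_0deg_mm
    }, 1.0)
    manifest$stages <- c(manifest$stages, "moment_arm")

    ## stage 4: gait kinetics
    stage <- "gait"
    gait_rows <- lapply(seq_along(ids), function(i) {
      trial <- read_gait_trial(file.path(sim_dir, paste0(ids[i], "_gait")))
      jk <- ankle_inverse_dynamics(trial,
                                   force_cutoff_hz = config$force_cutoff_hz,
                                   marker_cutoff_hz = config$marker_cutoff_hz)
      st <- jk$spatiotemporal
      c(peak_torque_nm = jk$mean_peak_nm,
        peak_torque_sd_nm = jk$sd_peak_nm,
        stride_time_s = st$stride_time_s,
        stride_length_m = st$stride_length_m,
        step_length_m = st$step_length_m,
        cadence_steps_min = st$cadence_steps_min)
    })
    meas <- cbind(meas, as.data.frame(do.call(rbind, gait_rows)))
    meas$tendon_force_n <- vapply(seq_along(ids), function(i) {
      estimate_tendon_force(meas$peak_torque_nm[i], meas$moment_arm_mm[i])
    }, 1.0)
    utils::write.csv(meas, file.path(out_dir, "measures.csv"),
                     row.names = FALSE)
    manifest$stages <- c(manifest$stages, "gait")

    ## stage 5: statistics
    stage <- "stats"
    if (config$cohort$n_young < 2 || config$cohort$n_older < 2) {
      stop("each sample n >= 2 is required for the group statistics")
    }
    tables <- build_tables(meas, alpha = config$alpha, cap_p = config$cap_p)
    write_tables(tables, file.path(out_dir, "reports"))
    manifest$stages <- c(manifest$stages, "stats")

    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("manifest.json$", files)]
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- substring(names(manifest$checksums),
                                           nchar(out_dir) + 2)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(measures = meas, tables = tables, manifest = manifest)
  }, error = function(e) {
    writeLines(paste("stage:", stage, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(e)
  })
  invisible(result)
}
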