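#' Generate a synthetic two-group cohort with known ground truth
#'
#' Samples subjects per group: bounded-normal height and mass; total
#' triceps surae volume as a zero-intercept linear function of
#' height x mass (group-specific slope) plus Gaussian scatter; per-muscle
#' volumes as perturbed fractions of the total (renormalized so the four
#' muscles sum exactly to the total); Achilles tendon mid-length CSA either
#' coupled to total volume (linear + noise) or drawn independently of it,
#' depending on the group's coupling model; moment arm and peak walking
#' torque from their own group models. The peak tendon force is
#' torque / moment arm.
#'
#' Randomness is split per subject: subject i of group g always sees the
#' same stream for a given config seed, so enlarging a group never changes
#' previously generated subjects.
#'
#' @param config a [cohort_config()].
#' @return list with `subjects`, a data.frame (one row per subject: id,
#'   group, height_m, mass_kg, height_mass_kgm, vol_PS..vol_LG,
#'   vol_total_cm3, tendon_csa_mm2, moment_arm_mm, peak_torque_nm,
#'   tendon_force_n), and `truth`, a list of per-subject ground-truth
#'   records (true volumes, generating slope, coupling flag).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  groups <- c(rep("young", config$n_young), rep("older", config$n_older))
  n <- length(groups)
  subjects <- vector("list", n)
  truth <- vector("list", n)
  idx_in_group <- c(seq_len(config$n_young), seq_len(config$n_older))
  for (i in seq_len(n)) {
    g <- groups[i]
    gcode <- if (g == "young") 1L else 2L
    s <- child_seed(config$seed, gcode, idx_in_group[i])
    rec <- with_seed(s, generate_subject(config, g))
    rec$subject$id <- sprintf("%s%02d", toupper(substr(g, 1, 1)), idx_in_group[i])
    rec$subject <- rec$subject[c("id", setdiff(names(rec$subject), "id"))]
    subjects[[i]] <- as.data.frame(rec$subject, stringsAsFactors = FALSE)
    truth[[i]] <- rec$truth
    names(truth)[i] <- rec$subject$id
  }
  list(subjects = do.call(rbind, subjects), truth = truth)
}

generate_subject <- function(config, group) {
  height <- rnorm_bounded(1, config$height_dist[[group]][1],
                          config$height_dist[[group]][2], lower = 0)
  mass <- rnorm_bounded(1, config$mass_dist[[group]][1],
                        config$mass_dist[[group]][2], lower = 0)
  hm <- height * mass
  slope <- config$volume_slope[[group]]
  vol_total <- slope * hm + stats::rnorm(1, 0, config$volume_noise_sd[[group]])
  vol_total <- max(vol_total, 0.1 * slope * hm)  # physical floor

  fr <- config$muscle_fractions
  if (config$fraction_noise_sd > 0) {
    fr <- fr + stats::rnorm(4, 0, config$fraction_noise_sd)
    fr <- pmax(fr, 0.01)
    fr <- fr / sum(fr)
  }
  vols <- vol_total * fr
  names(vols) <- muscle_names()

  tc <- config$tendon_coupling[[group]]
  csa <- if (isTRUE(tc$coupled)) {
    tc$slope * vol_total + tc$intercept + stats::rnorm(1, 0, tc$resid_sd)
  } else {
    rnorm_bounded(1, tc$mean, tc$sd, lower = 0)
  }
  csa <- max(csa, 1)

  ma <- rnorm_bounded(1, config$moment_arm_mean_sd[[group]][1],
                      config$moment_arm_mean_sd[[group]][2], lower = 0)
  torque <- config$torque_scale[[group]] * hm +
    stats::rnorm(1, 0, config$torque_resid_sd[[group]])
  torque <- max(torque, 1)
  force <- torque / (ma / 1000)

  subject <- c(list(group = group, height_m = height, mass_kg = mass,
                    height_mass_kgm = hm),
               as.list(stats::setNames(vols, paste0("vol_", names(vols)))),
               list(vol_total_cm3 = vol_total, tendon_csa_mm2 = csa,
                    moment_arm_mm = ma, peak_torque_nm = torque,
                    tendon_force_n = force))
  truth <- list(group = group, true_volumes_cm3 = vols,
                true_total_cm3 = vol_total, volume_slope = slope,
                tendon_coupled = isTRUE(tc$coupled),
                true_csa_mm2 = csa, true_moment_arm_mm = ma,
                true_peak_torque_nm = torque)
  list(subject = subject, truth = truth)
}

#' Write a cohort to disk (CSV subject table + JSON ground-truth sidecars)
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "subjects.csv")
  utils::write.csv(cohort$subjects, csv, row.names = FALSE)
  sidecars <- character(0)
  for (id in names(cohort$truth)) {
    p <- file.path(dir, paste0(id, "_truth.json"))
    jsonlite::write_json(cohort$truth[[id]], p, auto_unbox = TRUE, digits = NA)
    sidecars <- c(sidecars, p)
  }
  invisible(c(csv, sidecars))
}
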