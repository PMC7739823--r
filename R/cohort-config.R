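#' Configuration for a synthetic two-group cohort
#'
#' Defines the generating model for a young/older cohort: anthropometry
#' distributions, the allometric scaling of total triceps surae volume with
#' body size (height x mass), the split of total volume over the four
#' muscles (posterior soleus PS, anterior soleus AS, medial gastrocnemius
#' MG, lateral gastrocnemius LG), the muscle-tendon coupling model for
#' Achilles tendon cross-sectional area, and the walking-torque scaling.
#'
#' Defaults reproduce the study conditions of the source cohort: 14 young
#' and 7 older adults; young total volume scales at 7.00 cm^3 per kg*m and
#' older at 5.95; tendon CSA is coupled to total muscle volume in the young
#' group (slope 0.05 mm^2/cm^3, intercept 16.56 mm^2) and drawn
#' independently of volume in the older group (65.54 +/- 6.96 mm^2).
#'
#' @param n_young,n_older subjects per group (each >= 2).
#' @param height_dist,mass_dist list with `young` and `older` entries, each
#'   `c(mean, sd)` in m and kg respectively.
#' @param volume_slope named vector, cm^3 of total triceps surae volume per
#'   kg*m of height x mass, per group.
#' @param volume_noise_sd named vector, residual SD of total volume (cm^3)
#'   about the scaling line, per group.
#' @param muscle_fractions length-4 proportions (PS, AS, MG, LG) summing
#'   to 1.
#' @param fraction_noise_sd SD of the per-muscle perturbation applied to
#'   the volume fractions before renormalization (dimensionless).
#' @param tendon_coupling list with `young = list(coupled = TRUE,
#'   slope, intercept, resid_sd)` (mm^2 per cm^3, mm^2, mm^2) and
#'   `older = list(coupled = FALSE, mean, sd)` (mm^2); either group may use
#'   either form.
#' @param moment_arm_mean_sd list with per-group `c(mean, sd)` in mm.
#' @param torque_scale named vector, peak walking plantarflexion torque in
#'   Nm per kg*m, per group.
#' @param torque_resid_sd named vector, residual SD of peak torque (Nm).
#' @param seed integer seed; all randomness is split per subject from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_young = 14,
                          n_older = 7,
                          height_dist = list(young = c(1.78, 0.10),
                                             older = c(1.76, 0.07)),
                          mass_dist = list(young = c(74.87, 12.11),
                                           older = c(74.57, 15.26)),
                          volume_slope = c(young = 7.00, older = 5.95),
                          volume_noise_sd = c(young = 80, older = 122),
                          muscle_fractions = c(PS = 0.419, AS = 0.088,
                                               MG = 0.309, LG = 0.184),
                          fraction_noise_sd = 0.025,
                          tendon_coupling = list(
                            young = list(coupled = TRUE, slope = 0.05,
                                         intercept = 16.56, resid_sd = 5.5),
                            older = list(coupled = FALSE, mean = 65.54,
                                         sd = 6.96)),
                          moment_arm_mean_sd = list(young = c(46.64, 3.87),
                                                    older = c(43.54, 8.13)),
                          torque_scale = c(young = 0.857, older = 0.808),
                          torque_resid_sd = c(young = 6, older = 6),
                          seed = 1L) {
  cfg <- list(n_young = as.integer(n_young), n_older = as.integer(n_older),
              height_dist = height_dist, mass_dist = mass_dist,
              volume_slope = volume_slope, volume_noise_sd = volume_noise_sd,
              muscle_fractions = muscle_fractions,
              fraction_noise_sd = fraction_noise_sd,
              tendon_coupling = tendon_coupling,
              moment_arm_mean_sd = moment_arm_mean_sd,
              torque_scale = torque_scale,
              torque_resid_sd = torque_resid_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_young < 2 || cfg$n_older < 2) {
    stop("each group needs n >= 2 subjects")
  }
  sds <- c(cfg$height_dist$young[2], cfg$height_dist$older[2],
           cfg$mass_dist$young[2], cfg$mass_dist$older[2],
           cfg$volume_noise_sd, cfg$fraction_noise_sd, cfg$torque_resid_sd,
           cfg$moment_arm_mean_sd$young[2], cfg$moment_arm_mean_sd$older[2])
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (abs(sum(cfg$muscle_fractions) - 1) > 1e-9) {
    stop("muscle_fractions must sum to 1 within 1e-9")
  }
  if (any(cfg$volume_slope <= 0)) stop("volume slopes must be > 0")
  for (g in c("young", "older")) {
    tc <- cfg$tendon_coupling[[g]]
    if (isTRUE(tc$coupled)) {
      if (is.null(tc$slope) || tc$slope <= 0) {
        stop("coupled tendon model needs slope > 0")
      }
    } else {
      if (is.null(tc$mean) || tc$mean <= 0 || tc$sd < 0) {
        stop("uncoupled tendon model needs mean > 0 and sd >= 0")
      }
    }
  }
  invisible(cfg)
}

muscle_names <- function() c("PS", "AS", "MG", "LG")
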