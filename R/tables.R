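#' Derived per-subject measures used by the cohort tables
#'
#' Adds normalized volumes (cm^3 per kg*m), relative volumes (% of
#' total), and tendon CSA / muscle volume ratios (cm^-1) to a subject
#' table with columns `vol_PS..vol_LG`, `vol_total_cm3`,
#' `height_mass_kgm`, `tendon_csa_mm2`.
#'
#' @param subjects per-subject measures data.frame.
#' @return the table with derived columns appended.
#' @export
derive_measures <- function(subjects) {
  for (m in muscle_names()) {
    v <- subjects[[paste0("vol_", m)]]
    subjects[[paste0("nvol_", m)]] <- v / subjects$height_mass_kgm
    subjects[[paste0("rvol_", m)]] <- v / subjects$vol_total_cm3 * 100
    subjects[[paste0("csa_per_vol_", m)]] <-
      (subjects$tendon_csa_mm2 / MM2_PER_CM2) / v
  }
  subjects$nvol_total <- subjects$vol_total_cm3 / subjects$height_mass_kgm
  subjects$csa_per_vol_total <-
    (subjects$tendon_csa_mm2 / MM2_PER_CM2) / subjects$vol_total_cm3
  subjects$csa_per_hm <- subjects$tendon_csa_mm2 / subjects$height_mass_kgm
  subjects
}

row_comparison <- function(subjects, col, label) {
  y <- subjects[[col]][subjects$group == "young"]
  o <- subjects[[col]][subjects$group == "older"]
  mw <- mann_whitney(y, o)
  data.frame(measure = label,
             young_mean = mw$mean_a, young_sd = mw$sd_a,
             older_mean = mw$mean_b, older_sd = mw$sd_b,
             U = mw$U, p = mw$p, stringsAsFactors = FALSE)
}

#' Assemble cohort summary tables
#'
#' Builds the three report tables of the analysis from a per-subject
#' measures table (`group` column plus the measure columns):
#' `table1` - subject characteristics and gait measures, group
#' mean +/- SD with an (unadjusted) Mann-Whitney p per row;
#' `table2` - per-muscle and total volumes, normalized volumes, relative
#' volumes, and tendon CSA/volume ratios, where each block's four
#' per-muscle tests form one Holm family (the total column is a single
#' test, left unadjusted); `table3` - per-group linear regressions of
#' height x mass, tendon CSA, peak torque, and tendon force on each
#' muscle volume and the total. Holm-adjusted p-values are uncapped by
#' default so step-down products above 1 remain visible.
#'
#' @param subjects per-subject measures (see [generate_cohort()]);
#'   derived columns are added automatically.
#' @param alpha significance level for the `significant` flags.
#' @param cap_p cap Holm-adjusted p-values at 1.
#' @return list of data.frames `table1`, `table2`, `table3`.
#' @export
build_tables <- function(subjects, alpha = 0.05, cap_p = FALSE) {
  stopifnot(all(c("group", "height_mass_kgm") %in% names(subjects)))
  subjects <- derive_measures(subjects)
  muscles <- muscle_names()

  t1_rows <- c(height_m = "Height (m)", mass_kg = "Mass (kg)",
               tendon_csa_mm2 = "Tendon CSA (mm^2)",
               moment_arm_mm = "Moment arm (mm)",
               peak_torque_nm = "Peak ankle torque (Nm)",
               stride_length_m = "Stride length (m)",
               step_length_m = "Step length (m)",
               stride_time_s = "Stride time (s)",
               cadence_steps_min = "Cadence (steps/min)")
  t1 <- list()
  for (col in names(t1_rows)) {
    if (!col %in% names(subjects)) next
    if (any(is.na(subjects[[col]]))) {
      warning("measure ", col, " missing for some subjects; row skipped")
      next
    }
    t1[[col]] <- row_comparison(subjects, col, t1_rows[[col]])
  }
  table1 <- do.call(rbind, t1)
  table1$significant <- table1$p < alpha
  rownames(table1) <- NULL

  blocks <- list(`Muscle volume (cm^3)` = c(paste0("vol_", muscles),
                                            "vol_total_cm3"),
                 `Normalized volume (cm^3/kg*m)` = c(paste0("nvol_", muscles),
                                                     "nvol_total"),
                 `Relative volume (%)` = paste0("rvol_", muscles),
                 `Tendon CSA/volume (cm^-1)` = c(paste0("csa_per_vol_",
                                                        muscles),
                                                 "csa_per_vol_total"))
  t2 <- list()
  for (bl in names(blocks)) {
    cols <- blocks[[bl]]
    rows <- lapply(seq_along(cols), function(i) {
      lab <- if (grepl("total", cols[i])) "total" else muscles[i]
      cbind(block = bl, row_comparison(subjects, cols[i], lab))
    })
    rows <- do.call(rbind, rows)
    fam <- rows$measure != "total"
    rows$p_adj <- rows$p
    rows$p_adj[fam] <- holm_bonferroni(rows$p[fam], cap = cap_p)
    t2[[bl]] <- rows
  }
  table2 <- do.call(rbind, t2)
  table2$significant <- table2$p_adj < alpha
  rownames(table2) <- NULL

  responses <- c(height_mass_kgm = "Height * mass (kg*m)",
                 tendon_csa_mm2 = "Achilles tendon CSA (mm^2)",
                 peak_torque_nm = "Peak plantarflexion torque (Nm)",
                 tendon_force_n = "Estimated peak tendon force (N)")
  xcols <- c(stats::setNames(paste0("vol_", muscles), muscles),
             total = "vol_total_cm3")
  t3 <- list()
  for (resp in names(responses)) {
    if (!resp %in% names(subjects)) next
    for (grp in c("young", "older")) {
      sub <- subjects[subjects$group == grp, ]
      if (nrow(sub) < 3) {
        warning("group ", grp, " has n < 3; regression rows skipped")
        next
      }
      for (mus in names(xcols)) {
        fit <- linear_regression(sub[[xcols[[mus]]]], sub[[resp]])
        t3[[length(t3) + 1]] <- data.frame(
          response = responses[[resp]], group = grp, muscle = mus,
          slope = fit$slope, intercept = fit$intercept,
          r_squared = fit$r_squared, p = fit$p, n = fit$n,
          significant = fit$p < alpha, stringsAsFactors = FALSE)
      }
    }
  }
  table3 <- do.call(rbind, t3)
  rownames(table3) <- NULL

  list(table1 = table1, table2 = table2, table3 = table3)
}

#' Write the three cohort tables as CSV plus a JSON of all fits
#' @param tables result of [build_tables()].
#' @param dir output directory.
#' @return paths, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "tables.json")
  jsonlite::write_json(tables, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, jp))
}
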