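#' Muscle volumes, relative volumes, and body-size-normalized volumes
#'
#' Volume of each muscle label is the voxel count times the voxel volume
#' (dx dy dz), reported in cm^3. Relative volume is each muscle as a
#' percentage of the total triceps surae volume (the sum of the four
#' muscles); normalized volume divides by height x mass (cm^3 per kg*m),
#' the body-size correction under which healthy adult lower-limb muscle
#' volumes scale approximately linearly.
#'
#' @param vol a [label_volume()] containing all four muscle labels
#'   (PS, AS, MG, LG).
#' @param height_m,mass_kg subject anthropometry; both required for
#'   normalized volumes (may be NA to skip them).
#' @return object of class `muscle_morphometry`: per-muscle and total
#'   volumes (cm^3), relative volumes (%), normalized volumes
#'   (cm^3/(kg*m)).
#' @export
compute_muscle_volumes <- function(vol, height_m = NA, mass_kg = NA) {
  stopifnot(inherits(vol, "label_volume"))
  voxel_mm3 <- prod(vol$spacing)
  muscles <- muscle_names()
  counts <- vapply(muscles, function(m) {
    sum(vol$data == vol$labels[[m]])
  }, 1.0)
  if (any(counts == 0)) {
    stop("missing muscle label(s): ",
         paste(muscles[counts == 0], collapse = ", "))
  }
  volumes <- counts * voxel_mm3 / MM3_PER_CM3
  total <- sum(volumes)
  if (total == 0) stop("total muscle volume is zero")
  relative <- volumes / total * 100
  hm <- height_m * mass_kg
  normalized <- c(volumes, total = total) / hm
  structure(list(volumes_cm3 = volumes, total_cm3 = total,
                 relative_pct = relative,
                 normalized_cm3_per_kgm = normalized,
                 height_mass_kgm = hm),
            class = "muscle_morphometry")
}

#' @export
print.muscle_morphometry <- function(x, ...) {
  cat("muscle_morphometry: total", round(x$total_cm3, 1), "cm^3\n")
  df <- data.frame(volume_cm3 = round(x$volumes_cm3, 1),
                   relative_pct = round(x$relative_pct, 2))
  print(df)
  invisible(x)
}

#' Achilles free-tendon geometry from a label volume
#'
#' The free tendon spans the slices between the two landmark labels: the
#' most proximal slice where the calcaneus is visible (0% of normalized
#' length) and the soleus muscle-tendon junction (100%). Per-slice CSA is
#' the tendon voxel count in that axial slice times the in-plane voxel
#' area (measured in the imaging plane, not perpendicular to the local
#' tendon direction). Tendon volume is the summed CSA times the slice
#' thickness; tendon length is the summed distance between centroids of
#' adjacent cross sections. The representative CSA is taken at half the
#' free tendon's length: the slice whose cumulative centroid-path length
#' first reaches 50% of the total (for a straight even-count tendon this
#' picks the lower of the two central slices). The CSA profile is also
#' resampled to 101 points on normalized length 0-100%.
#'
#' @param vol a [label_volume()] with a tendon label on every slice
#'   between the landmarks.
#' @param landmarks optional list `list(calcaneus_top = slice,
#'   soleus_mtj = slice)` (1-based axial indices), e.g. from a JSON
#'   sidecar; if NULL they are located from landmark labels 6 and 7 in
#'   the volume. Both paths behave identically downstream.
#' @return object of class `tendon_geometry`: slice indices and
#'   z-positions (mm), per-slice CSA (mm^2), centroids (mm), free-tendon
#'   length (mm), volume (cm^3), mid-length CSA (mm^2), and the 101-point
#'   normalized-length profile.
#' @export
tendon_geometry <- function(vol, landmarks = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  d <- dim(vol$data)
  if (is.null(landmarks)) {
    k6 <- which(apply(vol$data == vol$labels[["calcaneus_top"]], 3, any))
    k7 <- which(apply(vol$data == vol$labels[["soleus_mtj"]], 3, any))
    if (length(k6) == 0 || length(k7) == 0) {
      stop("landmark labels (calcaneus top, soleus MTJ) not found; ",
           "supply `landmarks` explicitly")
    }
    landmarks <- list(calcaneus_top = min(k6), soleus_mtj = max(k7))
  }
  lo <- min(landmarks$calcaneus_top, landmarks$soleus_mtj)
  hi <- max(landmarks$calcaneus_top, landmarks$soleus_mtj)
  ks <- lo:hi
  tl <- vol$labels[["tendon"]]
  counts <- vapply(ks, function(k) sum(vol$data[, , k] == tl), 1.0)
  if (any(counts == 0)) {
    stop("gap in tendon label between landmark slices at slice(s) ",
         paste(ks[counts == 0], collapse = ", "))
  }
  csa <- counts * vol$spacing[1] * vol$spacing[2]

  centroids <- t(vapply(seq_along(ks), function(i) {
    k <- ks[i]
    idx <- which(vol$data[, , k] == tl, arr.ind = TRUE)
    c(vol$origin[1] + (mean(idx[, 1]) - 1) * vol$spacing[1],
      vol$origin[2] + (mean(idx[, 2]) - 1) * vol$spacing[2],
      vol$origin[3] + (k - 1) * vol$spacing[3])
  }, numeric(3)))

  n <- length(ks)
  seglen <- if (n > 1) {
    sqrt(rowSums((centroids[-1, , drop = FALSE] -
                    centroids[-n, , drop = FALSE])^2))
  } else numeric(0)
  len <- sum(seglen)
  cumlen <- c(0, cumsum(seglen))
  volume <- sum(csa) * vol$spacing[3] / MM3_PER_CM3

  mid_idx <- if (n == 1) 1L else which(cumlen >= len / 2)[1]
  mid_csa <- csa[mid_idx]

  pos_pct <- if (len > 0) cumlen / len * 100 else seq(0, 100, length.out = n)
  prof <- resample_linear(pos_pct, csa, 101)

  structure(list(slices = ks, z_mm = centroids[, 3], csa_mm2 = csa,
                 centroids_mm = centroids, length_mm = len,
                 volume_cm3 = volume, mid_slice = ks[mid_idx],
                 mid_csa_mm2 = mid_csa,
                 profile = data.frame(length_pct = prof$x,
                                      csa_mm2 = prof$y)),
            class = "tendon_geometry")
}

#' @export
print.tendon_geometry <- function(x, ...) {
  cat("tendon_geometry:", length(x$slices), "slices, length",
      round(x$length_mm, 1), "mm, volume", round(x$volume_cm3, 2),
      "cm^3, mid-length CSA", round(x$mid_csa_mm2, 1), "mm^2\n")
  invisible(x)
}

#' Tendon-size-per-muscle-size and per-body-size ratios
#'
#' Divides the representative (mid-length) Achilles tendon CSA by the
#' individual and total triceps surae muscle volumes, and by
#' height x mass. Units are made consistent before dividing: CSA is
#' converted from mm^2 to cm^2, so CSA/volume ratios are in cm^-1;
#' CSA/(height x mass) stays in mm^2 per kg*m.
#'
#' @param csa_mid_mm2 representative tendon CSA (mm^2).
#' @param morpho a [compute_muscle_volumes()] result.
#' @return list with `csa_per_volume_cm` (named, per muscle and total,
#'   cm^-1) and `csa_per_height_mass` (mm^2/(kg*m), NA when anthropometry
#'   was not supplied).
#' @export
tendon_muscle_ratios <- function(csa_mid_mm2, morpho) {
  stopifnot(inherits(morpho, "muscle_morphometry"))
  vols <- c(morpho$volumes_cm3, total = morpho$total_cm3)
  if (any(vols <= 0)) stop("muscle volumes must be positive")
  csa_cm2 <- csa_mid_mm2 / MM2_PER_CM2
  list(csa_per_volume_cm = csa_cm2 / vols,
       csa_per_height_mass = csa_mid_mm2 / morpho$height_mass_kgm)
}
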