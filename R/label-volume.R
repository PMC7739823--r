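#' Label dictionary for limb label volumes
#'
#' 0 background, 1-4 the four triceps surae muscles (posterior soleus,
#' anterior soleus, medial gastrocnemius, lateral gastrocnemius), 5 the
#' Achilles free tendon, 6 the most-proximal-calcaneus landmark slice,
#' 7 the soleus muscle-tendon-junction landmark slice.
#' @export
label_dictionary <- function() {
  c(background = 0L, PS = 1L, AS = 2L, MG = 3L, LG = 4L,
    tendon = 5L, calcaneus_top = 6L, soleus_mtj = 7L)
}

#' Construct a label volume
#'
#' A voxelized labeled limb: an integer label grid with voxel spacing in
#' mm. The third array axis is the axial (slice) direction. Voxel indices
#' are 0-based in world terms: the center of array element `[i, j, k]`
#' (1-based in R) is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data integer 3-D array of labels.
#' @param spacing voxel spacing `c(dx, dy, dz)` in mm, strictly positive.
#' @param origin world position (mm) of the first voxel center.
#' @param labels named integer label dictionary.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0),
                         labels = label_dictionary()) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  present <- sort(unique(as.integer(data)))
  if (!all(present %in% labels)) {
    stop("data contains labels outside the declared dictionary: ",
         paste(setdiff(present, labels), collapse = ", "))
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), axial_axis = 3L,
                 labels = labels),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$data), collapse = " x "),
      "voxels at", paste(signif(x$spacing, 3), collapse = " x "), "mm\n")
  tab <- table(factor(x$data, levels = x$labels,
                      labels = names(x$labels)))
  print(tab[tab > 0])
  invisible(x)
}

#' Ellipsoid semi-axes realizing a target volume at fixed aspect ratios
#'
#' @param volume_cm3 target analytic volume.
#' @param ratios relative semi-axis lengths (x, y, z).
#' @return semi-axes in mm with `4/3 pi a b c` equal to the target.
#' @export
ellipsoid_semi_axes <- function(volume_cm3, ratios = c(1, 0.7, 3)) {
  stopifnot(volume_cm3 > 0, all(ratios > 0))
  u <- (volume_cm3 * MM3_PER_CM3 * 3 / (4 * pi * prod(ratios)))^(1 / 3)
  u * ratios
}

# Rasterize one ellipsoid into `arr` (center-inside rule). Returns the
# modified array; errors on collision with an existing label.
rasterize_ellipsoid <- function(arr, spacing, origin, center, semi, value) {
  d <- dim(arr)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(d[a]) - 1) * spacing[a])
  rng <- lapply(1:3, function(a) {
    which(ax[[a]] >= center[a] - semi[a] & ax[[a]] <= center[a] + semi[a])
  })
  if (any(vapply(rng, length, 1L) == 0)) return(arr)
  x2 <- ((ax[[1]][rng[[1]]] - center[1]) / semi[1])^2
  y2 <- ((ax[[2]][rng[[2]]] - center[2]) / semi[2])^2
  z2 <- ((ax[[3]][rng[[3]]] - center[3]) / semi[3])^2
  xy <- outer(x2, y2, "+")
  for (k in seq_along(z2)) {
    mask <- xy <= 1 - z2[k]
    if (!any(mask)) next
    sub <- arr[rng[[1]], rng[[2]], rng[[3]][k], drop = FALSE]
    sub <- array(sub, dim(xy))
    hit <- sub[mask]
    if (any(hit != 0)) {
      stop(sprintf("shape for label %d collides with existing label(s) %s",
                   value, paste(sort(unique(hit[hit != 0])), collapse = ", ")))
    }
    sub[mask] <- value
    arr[rng[[1]], rng[[2]], rng[[3]][k]] <- sub
  }
  arr
}

#' Specification of a synthetic Achilles free-tendon tube
#'
#' @param csa_mm2 per-slice cross-sectional area: scalar (constant tube) or
#'   vector of length `n_slices`.
#' @param n_slices number of axial slices the tendon occupies.
#' @param incline_deg tilt of the centroid path away from the axial axis
#'   (degrees); 0 is a straight vertical tube.
#' @param center_xy_mm in-plane position (mm, world) of the tube center at
#'   its first slice.
#' @return list, consumed by [generate_label_volume()].
#' @export
tendon_spec <- function(csa_mm2, n_slices, incline_deg = 0,
                        center_xy_mm = NULL) {
  stopifnot(n_slices >= 1, all(csa_mm2 > 0))
  csa <- rep_len(csa_mm2, n_slices)
  list(csa_mm2 = csa, n_slices = as.integer(n_slices),
       incline_deg = incline_deg, center_xy_mm = center_xy_mm)
}

#' Rasterize a labeled limb phantom with known analytic ground truth
#'
#' Muscles are rasterized as ellipsoids whose analytic volumes equal the
#' requested true volumes; the Achilles tendon as a tube (optionally
#' inclined against the axial axis) with prescribed per-slice CSA; landmark
#' labels mark the most proximal calcaneus slice (distal end of the free
#' tendon) and the soleus muscle-tendon-junction slice (proximal end).
#' A voxel carries a label iff its center lies inside the analytic shape;
#' no partial-volume weighting, matching the voxel-counting measurement
#' model of the downstream morphometry.
#'
#' @param true_volumes named numeric, cm^3 per muscle (names from the label
#'   dictionary); may be empty for a background-only volume.
#' @param tendon tendon specification from [tendon_spec()], or NULL.
#' @param spacing voxel spacing in mm; default is the acquisition grid of
#'   the study (0.72 x 0.72 mm in plane, 2 mm slices).
#' @param shape_ratios ellipsoid aspect ratios passed to
#'   [ellipsoid_semi_axes()].
#' @param margin_mm empty margin kept around all shapes.
#' @return a [label_volume()] whose `truth` attribute records the analytic
#'   per-muscle volumes, ellipsoid parameters, and tendon ground truth
#'   (per-slice CSA, centroid path, length, volume).
#' @export
generate_label_volume <- function(true_volumes = numeric(0), tendon = NULL,
                                  spacing = c(0.72, 0.72, 2),
                                  shape_ratios = c(1, 0.7, 3),
                                  margin_mm = 5) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  labels <- label_dictionary()
  if (length(true_volumes) > 0) {
    if (is.null(names(true_volumes)) ||
        !all(names(true_volumes) %in% names(labels))) {
      stop("true_volumes must be named with labels from label_dictionary()")
    }
    if (any(true_volumes <= 0)) stop("true volumes must be > 0")
  }

  semis <- lapply(true_volumes, ellipsoid_semi_axes, ratios = shape_ratios)

  # Lay shapes out side by side along x, all centered in y and z.
  slot_w <- vapply(semis, function(s) 2 * s[1] + margin_mm, 1.0)
  tendon_slot <- 0
  tendon_r <- NULL
  if (!is.null(tendon)) {
    tendon_r <- sqrt(tendon$csa_mm2 / pi)
    shift <- (tendon$n_slices - 1) * spacing[3] *
      tan(tendon$incline_deg * pi / 180)
    tendon_slot <- 2 * max(tendon_r) + abs(shift) + margin_mm
  }
  width <- margin_mm + sum(slot_w) + tendon_slot + margin_mm
  max_sy <- max(c(vapply(semis, `[`, 1.0, 2), tendon_r, 1))
  max_sz <- max(c(vapply(semis, `[`, 1.0, 3), 1))
  z_needed <- max(2 * max_sz + 2 * margin_mm,
                  if (!is.null(tendon)) {
                    tendon$n_slices * spacing[3] + 2 * margin_mm
                  } else 0)
  dims <- c(ceiling(width / spacing[1]),
            ceiling((2 * max_sy + 2 * margin_mm) / spacing[2]),
            ceiling(z_needed / spacing[3]))
  arr <- array(0L, dims)
  origin <- c(0, 0, 0)
  cy <- (dims[2] - 1) * spacing[2] / 2
  cz <- (dims[3] - 1) * spacing[3] / 2

  truth <- list(volumes_cm3 = true_volumes, ellipsoids = list(),
                tendon = NULL)
  x_cursor <- margin_mm
  for (nm in names(true_volumes)) {
    s <- semis[[nm]]
    center <- c(x_cursor + s[1], cy, cz)
    arr <- rasterize_ellipsoid(arr, spacing, origin, center, s,
                               labels[[nm]])
    truth$ellipsoids[[nm]] <- list(center = center, semi_axes = s,
                                   analytic_volume_cm3 =
                                     4 / 3 * pi * prod(s) / MM3_PER_CM3)
    x_cursor <- x_cursor + slot_w[[nm]]
  }

  if (!is.null(tendon)) {
    ns <- tendon$n_slices
    if (ns > dims[3]) stop("tendon does not fit inside the grid axially")
    k0 <- max(1L, floor((dims[3] - ns) / 2) + 1L)
    ks <- k0:(k0 + ns - 1L)
    cx0 <- if (!is.null(tendon$center_xy_mm)) tendon$center_xy_mm[1] else {
      x_cursor + max(tendon_r) + abs(min(0, (ns - 1) * spacing[3] *
                                           tan(tendon$incline_deg * pi / 180)))
    }
    cy0 <- if (!is.null(tendon$center_xy_mm)) tendon$center_xy_mm[2] else cy
    xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
    ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
    slope <- tan(tendon$incline_deg * pi / 180)
    centers <- matrix(NA_real_, ns, 3)
    for (s in seq_len(ns)) {
      zc <- origin[3] + (ks[s] - 1) * spacing[3]
      cx <- cx0 + slope * (s - 1) * spacing[3]
      r <- tendon_r[s]
      mask <- outer((xs - cx)^2, (ys - cy0)^2, "+") <= r^2
      if (!any(mask)) {
        stop("tendon radius too small for the voxel grid at slice ", s)
      }
      sl <- arr[, , ks[s]]
      hit <- sl[mask]
      if (any(hit != 0)) {
        stop(sprintf("shape for label %d collides with existing label(s) %s",
                     labels[["tendon"]],
                     paste(sort(unique(hit[hit != 0])), collapse = ", ")))
      }
      sl[mask] <- labels[["tendon"]]
      arr[, , ks[s]] <- sl
      centers[s, ] <- c(cx, cy0, zc)
    }
    # landmark blobs on the end slices, in distinct free corners so a
    # single-slice tendon still carries both landmarks
    for (lm in list(list(k = ks[1], lab = labels[["calcaneus_top"]],
                         cols = 1:2),
                    list(k = ks[ns], lab = labels[["soleus_mtj"]],
                         cols = 4:5))) {
      sl <- arr[, , lm$k]
      sl[1:2, lm$cols] <- lm$lab
      arr[, , lm$k] <- sl
    }
    seglen <- if (ns > 1) {
      sqrt(rowSums((centers[-1, , drop = FALSE] -
                      centers[-ns, , drop = FALSE])^2))
    } else numeric(0)
    truth$tendon <- list(csa_mm2 = tendon$csa_mm2, centroids_mm = centers,
                         length_mm = sum(seglen),
                         volume_cm3 = sum(tendon$csa_mm2) * spacing[3] /
                           MM3_PER_CM3,
                         incline_deg = tendon$incline_deg,
                         slices = ks)
  }

  vol <- label_volume(arr, spacing, origin, labels)
  vol$truth <- truth
  vol
}

#' Write a label volume to NIfTI
#' @param vol a [label_volume()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' Spacing is taken from the header. If `expected_spacing` is supplied
#' (e.g. from a sidecar), a disagreement beyond 1e-4 mm is an error.
#' @param path NIfTI file.
#' @param expected_spacing optional spacing to validate against.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path, expected_spacing = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (!is.null(expected_spacing) && any(abs(sp - expected_spacing) > 1e-4)) {
    stop("NIfTI voxel spacing disagrees with the sidecar: header ",
         paste(signif(sp, 6), collapse = "x"), " vs expected ",
         paste(signif(expected_spacing, 6), collapse = "x"))
  }
  arr <- array(as.integer(round(as.array(img))), dim(img))
  label_volume(arr, sp)
}
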