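#' Specification of a FLAIR-like lesion phantom
#'
#' Concentric-ellipsoid phantom: an ellipsoidal "brain" (intracranial
#' volume) containing a hypointense hematoma core wrapped in a hyperintense
#' edema shell, on a darker background - the FLAIR contrast ordering
#' (edema > normal brain > hematoma > background).
#'
#' @param image_shape voxels per axis (length 3).
#' @param voxel_mm isotropic voxel edge (mm).
#' @param icv_ml target intracranial volume (ml).
#' @param hematoma_ml target hematoma volume (ml).
#' @param edema_ml target edema shell volume (ml); may be 0.
#' @param intensities named mean intensity per tissue class
#'   (`background`, `brain`, `edema`, `hematoma`); edema must be brightest,
#'   hematoma darker than brain.
#' @param noise_sd additive Gaussian noise SD on the rendered image.
#' @param axis_ratios relative ellipsoid semi-axes (anisotropy), length 3.
#' @param lesion_offset_mm centre offset of the lesion relative to the ICV
#'   centre (mm, length 3); the lesion must remain inside the ICV.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(128L, 128L, 128L), voxel_mm = 0.5,
                         icv_ml = 70.3, hematoma_ml = 1.00, edema_ml = 2.38,
                         intensities = c(background = 10, brain = 100,
                                         edema = 180, hematoma = 40),
                         noise_sd = 0, axis_ratios = c(1.15, 1, 0.87),
                         lesion_offset_mm = c(8, 6, 4)) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 3L, all(image_shape > 0))
  assert_scalar_num(voxel_mm, "voxel_mm", positive = TRUE)
  assert_scalar_num(icv_ml, "icv_ml", positive = TRUE)
  assert_scalar_num(hematoma_ml, "hematoma_ml", nonneg = TRUE)
  assert_scalar_num(edema_ml, "edema_ml", nonneg = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  need <- c("background", "brain", "edema", "hematoma")
  if (!all(need %in% names(intensities))) {
    stopf("intensities must name %s", paste(need, collapse = ", "),
          class = "perispect_validation_error")
  }
  if (!(intensities["edema"] > intensities["brain"] &&
        intensities["brain"] > intensities["hematoma"] &&
        intensities["brain"] > intensities["background"])) {
    stopf("FLAIR-like ordering violated: need edema > brain > hematoma and brain > background",
          class = "perispect_validation_error")
  }
  if (hematoma_ml + edema_ml >= icv_ml) {
    stopf("hematoma + edema volume (%.2f ml) must be smaller than the ICV (%.2f ml)",
          hematoma_ml + edema_ml, icv_ml, class = "perispect_validation_error")
  }
  structure(list(image_shape = image_shape, voxel_mm = voxel_mm,
                 icv_ml = icv_ml, hematoma_ml = hematoma_ml,
                 edema_ml = edema_ml, intensities = intensities,
                 noise_sd = noise_sd, axis_ratios = axis_ratios,
                 lesion_offset_mm = lesion_offset_mm),
            class = "phantom_spec")
}

#' Analytic ellipsoid semi-axes for a target volume
#'
#' Semi-axes `a = ratios * s` such that `4/3 * pi * a1 * a2 * a3` equals
#' `volume_ml` exactly.
#'
#' @param volume_ml target volume (ml).
#' @param ratios relative semi-axes (length 3).
#' @return numeric length-3 semi-axes in mm.
#' @export
ellipsoid_semiaxes <- function(volume_ml, ratios = c(1.15, 1, 0.87)) {
  assert_scalar_num(volume_ml, "volume_ml", positive = TRUE)
  s <- (volume_ml * 1000 / (4 / 3 * pi * prod(ratios)))^(1 / 3)
  ratios * s
}

# Normalised quadratic form q(x) = sum(((x - centre) / (ratios))^2) on the
# voxel-centre grid (mm); a voxel is inside the ellipsoid with scale s iff
# q <= s^2.
ellipsoid_qform <- function(shape, voxel_mm, centre_mm, ratios) {
  ax <- (seq_len(shape[1]) - 0.5) * voxel_mm
  ay <- (seq_len(shape[2]) - 0.5) * voxel_mm
  az <- (seq_len(shape[3]) - 0.5) * voxel_mm
  qx <- ((ax - centre_mm[1]) / ratios[1])^2
  qy <- ((ay - centre_mm[2]) / ratios[2])^2
  qz <- ((az - centre_mm[3]) / ratios[3])^2
  outer(outer(qx, qy, `+`), qz, `+`)
}

# Scale s such that the number of voxel centres with q <= s^2 equals
# round(volume_ml / voxel_volume): the discrete rendering then matches the
# target volume to the nearest voxel.
calibrated_scale <- function(q, volume_ml, voxel_mm, structure_name) {
  vv <- voxel_mm^3 / 1000  # ml per voxel
  k <- round(volume_ml / vv)
  if (k < 100) {
    stopf("%s target (%.3f ml) spans only %d voxels at %.2f mm; need >= 100",
          structure_name, volume_ml, k, voxel_mm,
          class = "perispect_validation_error")
  }
  if (k >= length(q)) {
    stopf("%s target (%.3f ml) does not fit in the image at %.2f mm voxels",
          structure_name, volume_ml, voxel_mm,
          class = "perispect_validation_error")
  }
  qk <- sort(q, partial = k + 1L)[k:(k + 1L)]
  sqrt(mean(qk))  # threshold between the k-th and (k+1)-th order statistic
}

#' Render a FLAIR-like lesion phantom
#'
#' Builds the concentric-ellipsoid phantom described by a [phantom_spec()]:
#' intensity volume plus a ground-truth label volume (0 = background,
#' 1 = brain, 2 = edema, 3 = hematoma). By default each ellipsoid scale is
#' calibrated so its discrete voxel count matches the target volume to the
#' nearest voxel; with `calibrate = FALSE` the analytic semi-axes from
#' [ellipsoid_semiaxes()] are used unchanged (discrete volumes then converge
#' to the target as `voxel_mm -> 0`).
#'
#' @param spec a [phantom_spec()].
#' @param seed seed for the additive noise (ignored when `noise_sd = 0`).
#' @param calibrate match discrete voxel counts to the targets?
#' @return list of class `flair_phantom`: `image` (3D numeric array),
#'   `labels` (3D integer array), `voxel_mm`, `spec`, `volumes_ml` (achieved
#'   label volumes), `seeds_mm` (suggested in-structure seed points, voxel
#'   indices).
#' @export
simulate_flair_phantom <- function(spec, seed = NULL, calibrate = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$image_shape
  vmm <- spec$voxel_mm
  vv <- vmm^3 / 1000
  centre <- shp * vmm / 2
  r <- spec$axis_ratios

  q_icv <- ellipsoid_qform(shp, vmm, centre, r)
  s_icv <- if (calibrate) {
    calibrated_scale(q_icv, spec$icv_ml, vmm, "intracranial volume")
  } else {
    ellipsoid_semiaxes(spec$icv_ml, r)[1] / r[1]
  }
  icv <- q_icv <= s_icv^2
  touches_border <- any(icv[1, , ]) || any(icv[shp[1], , ]) ||
    any(icv[, 1, ]) || any(icv[, shp[2], ]) ||
    any(icv[, , 1]) || any(icv[, , shp[3]])
  if (touches_border) {
    stopf("intracranial volume touches the image border; enlarge image_shape",
          class = "perispect_validation_error")
  }

  labels <- array(0L, dim = shp)
  labels[icv] <- 1L

  has_lesion <- spec$hematoma_ml > 0 || spec$edema_ml > 0
  if (has_lesion) {
    lcentre <- centre + spec$lesion_offset_mm
    q_les <- ellipsoid_qform(shp, vmm, lcentre, r)
    if (spec$hematoma_ml > 0) {
      s_h <- if (calibrate) {
        calibrated_scale(q_les, spec$hematoma_ml, vmm, "hematoma")
      } else {
        ellipsoid_semiaxes(spec$hematoma_ml, r)[1] / r[1]
      }
    } else s_h <- 0
    if (spec$edema_ml > 0) {
      outer_ml <- spec$hematoma_ml + spec$edema_ml
      s_o <- if (calibrate) {
        calibrated_scale(q_les, outer_ml, vmm, "edema")
      } else {
        ellipsoid_semiaxes(outer_ml, r)[1] / r[1]
      }
    } else s_o <- s_h
    outer_mask <- q_les <= s_o^2
    if (any(outer_mask & !icv)) {
      stopf("edema shell extends outside the intracranial volume; reduce lesion_offset_mm or volumes",
            class = "perispect_validation_error")
    }
    if (spec$edema_ml > 0) labels[outer_mask] <- 2L
    if (spec$hematoma_ml > 0) labels[q_les <= s_h^2] <- 3L
  }

  img <- array(spec$intensities[["background"]], dim = shp)
  img[labels == 1L] <- spec$intensities[["brain"]]
  img[labels == 2L] <- spec$intensities[["edema"]]
  img[labels == 3L] <- spec$intensities[["hematoma"]]
  if (spec$noise_sd > 0) {
    img <- img + with_seed(seed, array(stats::rnorm(prod(shp), 0, spec$noise_sd),
                                       dim = shp))
  }

  vols <- c(icv_ml = sum(labels > 0L) * vv,
            hematoma_ml = sum(labels == 3L) * vv,
            edema_ml = sum(labels == 2L) * vv)

  seeds <- list()
  to_idx <- function(mm) pmin(pmax(round(mm / vmm + 0.5), 1L), shp)
  if (spec$hematoma_ml > 0) seeds$hematoma <- to_idx(centre + spec$lesion_offset_mm)
  if (spec$edema_ml > 0) {
    # point midway through the shell along +x from the lesion centre
    mid <- centre + spec$lesion_offset_mm +
      c((s_h + s_o) / 2 * r[1], 0, 0)
    seeds$edema <- to_idx(mid)
  }
  seeds$brain <- to_idx(centre - c(0.6, 0, 0) * s_icv * r[1])

  structure(list(image = img, labels = labels, voxel_mm = vmm, spec = spec,
                 volumes_ml = vols, seeds = seeds),
            class = "flair_phantom")
}

#' Write a phantom as a NIfTI image/label pair
#'
#' @param phantom a `flair_phantom`.
#' @param prefix output path prefix; writes `<prefix>_image.nii.gz` and
#'   `<prefix>_labels.nii.gz` with the voxel size in the header.
#' @return named character vector of the two paths, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "flair_phantom"))
  v <- phantom$voxel_mm
  img <- RNifti::asNifti(phantom$image, pixdim = c(v, v, v))
  lab <- RNifti::asNifti(phantom$labels + 0, pixdim = c(v, v, v))
  paths <- c(image = paste0(prefix, "_image.nii.gz"),
             labels = paste0(prefix, "_labels.nii.gz"))
  RNifti::writeNifti(img, paths[["image"]])
  RNifti::writeNifti(lab, paths[["labels"]])
  invisible(paths)
}
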