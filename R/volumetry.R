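# Linear-index neighbour offsets for 6- or 26-connectivity in an array
# padded by one voxel on every face (padding guarantees offsets never wrap).
neighbour_offsets <- function(dim_padded, connectivity) {
  steps <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  steps <- steps[!(steps$dx == 0 & steps$dy == 0 & steps$dz == 0), ]
  if (connectivity == 6) {
    steps <- steps[abs(steps$dx) + abs(steps$dy) + abs(steps$dz) == 1, ]
  } else if (connectivity != 26) {
    stopf("connectivity must be 6 or 26", class = "perispect_validation_error")
  }
  as.integer(steps$dx + steps$dy * dim_padded[1] +
               steps$dz * dim_padded[1] * dim_padded[2])
}

#' Seed-growing segmentation
#'
#' Grows a connected region from a seed voxel: a frontier of candidate
#' voxels is expanded sweep by sweep, and a candidate joins the region when
#' its intensity lies within `tolerance` of the running region mean. The
#' mean is updated after each sweep (not per voxel), which makes the result
#' independent of within-sweep ordering and hence deterministic.
#'
#' @param image 3D numeric array, finite-valued.
#' @param seed `c(x, y, z)` voxel index (1-based) inside the image.
#' @param tolerance absolute intensity half-range around the running region
#'   mean (>= 0).
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @param max_iter cap on growth sweeps.
#' @return list of class `region_mask`: `mask` (logical array), `n_voxels`,
#'   `mean_intensity`, `iterations`, and `flags` (contains
#'   `"touches_border"` when the region reaches the image edge - a possible
#'   leak - and `"max_iter"` when growth was truncated).
#' @export
region_grow <- function(image, seed, tolerance, connectivity = 26,
                        max_iter = 10000L) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  if (!all(is.finite(image))) {
    stopf("image must be finite-valued", class = "perispect_validation_error")
  }
  assert_scalar_num(tolerance, "tolerance", nonneg = TRUE)
  dm <- dim(image)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dm)) {
    stopf("seed (%s) outside image bounds %s",
          paste(seed, collapse = ","), paste(dm, collapse = "x"),
          class = "perispect_validation_error")
  }

  dmp <- dm + 2L
  pad <- array(-Inf, dim = dmp)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- image
  offs <- neighbour_offsets(dmp, connectivity)
  lin <- function(x, y, z) x + (y - 1L) * dmp[1] + (z - 1L) * dmp[1] * dmp[2]
  seed_lin <- lin(seed[1] + 1L, seed[2] + 1L, seed[3] + 1L)

  in_mask <- logical(prod(dmp))
  in_mask[seed_lin] <- TRUE
  region_sum <- pad[seed_lin]
  region_n <- 1L
  frontier <- seed_lin
  iter <- 0L
  flags <- character(0)
  while (length(frontier) && iter < max_iter) {
    iter <- iter + 1L
    cand <- unique(as.vector(outer(frontier, offs, `+`)))
    cand <- cand[!in_mask[cand]]
    if (!length(cand)) break
    mu <- region_sum / region_n
    ok <- abs(pad[cand] - mu) <= tolerance
    accepted <- cand[ok]
    if (!length(accepted)) break
    in_mask[accepted] <- TRUE
    region_sum <- region_sum + sum(pad[accepted])
    region_n <- region_n + length(accepted)
    frontier <- accepted
  }
  if (iter >= max_iter) flags <- c(flags, "max_iter")

  mask_p <- array(in_mask, dim = dmp)
  mask <- mask_p[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)]
  touches <- any(mask[1, , ]) || any(mask[dm[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, dm[2], ]) ||
    any(mask[, , 1]) || any(mask[, , dm[3]])
  if (touches) flags <- c(flags, "touches_border")
  structure(list(mask = mask, n_voxels = region_n,
                 mean_intensity = region_sum / region_n,
                 iterations = iter, flags = flags),
            class = "region_mask")
}

#' Intracranial volume by thresholding and hole filling
#'
#' The ICV is segmented as the connected super-threshold component
#' containing `seed`, with interior holes filled (any sub-threshold pocket
#' not connected to the image border is included). The threshold defaults
#' to halfway between the background and the darkest intracranial class.
#'
#' @param image 3D numeric array.
#' @param threshold intensity separating background from brain classes.
#' @param seed voxel index inside the brain; defaults to the image centre.
#' @return a `region_mask` (see [region_grow()]).
#' @export
segment_icv <- function(image, threshold, seed = round(dim(image) / 2)) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  bin <- array(as.numeric(image > threshold), dim = dim(image))
  if (bin[seed[1], seed[2], seed[3]] != 1) {
    stopf("ICV seed is below the threshold", class = "perispect_validation_error")
  }
  comp <- region_grow(bin, seed, tolerance = 0.5, connectivity = 6)
  # fill holes: grow the background from a corner and take the complement
  inv <- array(as.numeric(!comp$mask), dim = dim(image))
  if (inv[1, 1, 1] == 1) {
    bg <- region_grow(inv, c(1L, 1L, 1L), tolerance = 0.5, connectivity = 6)
    filled <- !bg$mask
  } else {
    filled <- comp$mask
  }
  comp$mask <- filled
  comp$n_voxels <- sum(filled)
  comp
}

#' Segment a phantom (or FLAIR-like image) into ICV, edema and hematoma
#'
#' Runs [region_grow()] from the hematoma and edema seeds and
#' [segment_icv()] for the intracranial volume, and checks the FLAIR
#' intensity ordering (edema brightest, hematoma darkest of the three).
#'
#' @param image 3D numeric array.
#' @param seeds named list with `hematoma`, `edema` (and optionally `brain`)
#'   voxel indices, e.g. `phantom$seeds`.
#' @param tolerance intensity tolerance for region growing.
#' @param connectivity 6 or 26.
#' @param icv_threshold background/brain intensity threshold.
#' @return named list of `region_mask` objects (`icv`, `edema`, `hematoma`)
#'   plus a `qc` character vector.
#' @export
segment_phantom <- function(image, seeds, tolerance = 20, connectivity = 26,
                            icv_threshold = NULL) {
  qc <- character(0)
  hem <- region_grow(image, seeds$hematoma, tolerance, connectivity)
  ede <- region_grow(image, seeds$edema, tolerance, connectivity)
  if (ede$mean_intensity <= hem$mean_intensity) {
    qc <- c(qc, "intensity_ordering: edema not brighter than hematoma")
  }
  if (is.null(icv_threshold)) {
    bgc <- stats::median(c(image[1, 1, 1], image[dim(image)[1], 1, 1],
                           image[1, dim(image)[2], 1]))
    icv_threshold <- (bgc + hem$mean_intensity) / 2
  }
  icv_seed <- seeds$brain %||% round(dim(image) / 2)
  icv <- segment_icv(image, icv_threshold, icv_seed)
  for (nm in c("hematoma", "edema")) {
    m <- list(hematoma = hem, edema = ede)[[nm]]
    if ("touches_border" %in% m$flags) {
      qc <- c(qc, sprintf("%s mask touches image border (possible leak)", nm))
    }
  }
  list(icv = icv, edema = ede, hematoma = hem, qc = qc)
}

#' Volumes from segmentation masks
#'
#' Volume = voxel count x voxel volume, reported in ml.
#'
#' @param masks named list of `region_mask` (or logical arrays) with
#'   elements `icv`, `hematoma`, `edema` (missing entries give `NA`).
#' @param voxel_mm isotropic voxel edge (mm), or length-3 edges.
#' @param animal,day identifiers carried into the record.
#' @return one-row data.frame (`lesion_volumes`): `animal`, `day`,
#'   `icv_ml`, `hematoma_ml`, `edema_ml`.
#' @export
compute_volumes <- function(masks, voxel_mm, animal = NA, day = NA) {
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  vv <- prod(voxel_mm) / 1000
  count <- function(m) {
    if (is.null(m)) return(NA_real_)
    if (inherits(m, "region_mask")) m <- m$mask
    sum(m) * vv
  }
  data.frame(animal = animal, day = day,
             icv_ml = count(masks$icv),
             hematoma_ml = count(masks$hematoma),
             edema_ml = count(masks$edema),
             stringsAsFactors = FALSE)
}

#' Percent volume reduction relative to a baseline day
#'
#' `100 * (V_baseline - V_day) / V_baseline` per outcome and day; positive
#' values are reductions. Undefined (flagged `NA`) when the baseline volume
#' is zero.
#'
#' @param volumes data.frame of per-day volumes (as from
#'   [compute_volumes()], possibly many animals; values are averaged per
#'   day before the change is computed).
#' @param baseline_day day used as baseline.
#' @param outcomes columns to summarise.
#' @return data.frame with `day`, `outcome`, `volume_ml`, `pct_change`.
#' @export
percent_change <- function(volumes, baseline_day = 1,
                           outcomes = c("hematoma_ml", "edema_ml")) {
  stopifnot(baseline_day %in% volumes$day)
  out <- list()
  for (oc in outcomes) {
    mday <- tapply(volumes[[oc]], volumes$day, mean, na.rm = TRUE)
    v0 <- mday[[as.character(baseline_day)]]
    for (d in names(mday)) {
      pc <- if (!is.finite(v0) || v0 == 0) NA_real_ else
        100 * (v0 - mday[[d]]) / v0
      out[[length(out) + 1L]] <- data.frame(
        day = as.numeric(d), outcome = oc, volume_ml = mday[[d]],
        pct_change = pc, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$outcome, res$day), , drop = FALSE]
}
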