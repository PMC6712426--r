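#' Load a pipeline run configuration
#'
#' Reads a YAML run configuration (see `inst/extdata/demo-config.yaml`) and
#' fills defaults: acquisition parameters, priors table, phantom geometry,
#' segmentation settings and cohort design.
#'
#' @param path YAML file; default is the shipped demo configuration.
#' @return list of class `run_config`.
#' @export
load_run_config <- function(path = system.file("extdata", "demo-config.yaml",
                                               package = "perispect")) {
  y <- yaml::read_yaml(path)
  acq_y <- y$acquisition %||% list()
  acq <- acquisition_params(
    tr = acq_y$tr %||% 2000, te = acq_y$te %||% 144,
    bandwidth = acq_y$bandwidth %||% 2000,
    n_points = acq_y$n_points %||% 2048,
    field_ppm_hz = acq_y$field_ppm_hz %||% 127.728,
    grid_shape = unlist(acq_y$grid_shape %||% c(9L, 9L)),
    voxel_size = unlist(acq_y$voxel_size %||% c(15, 15, 15)))
  priors_path <- y$priors %||% system.file("extdata", "priors-3t.yaml",
                                           package = "perispect")
  pri <- load_priors(priors_path)
  ph_y <- y$phantom %||% list()
  seg_y <- y$segmentation %||% list()
  coh_y <- y$cohort %||% list()
  structure(list(
    acquisition = acq,
    priors = pri,
    snr = y$snr %||% 20,
    phase0_max = y$phase0_max %||% 30,
    half_width_ppm = y$half_width_ppm %||% 0.08,
    phantom = list(voxel_mm = ph_y$voxel_mm %||% 1.0,
                   image_shape = unlist(ph_y$image_shape %||% c(96L, 96L, 96L)),
                   icv_ml = ph_y$icv_ml %||% 70.3,
                   noise_sd = ph_y$noise_sd %||% 0),
    segmentation = list(tolerance = seg_y$tolerance %||% 20,
                        connectivity = seg_y$connectivity %||% 26),
    cohort = list(n_animals = coh_y$n_animals %||% 12,
                  sd_animal = coh_y$sd_animal %||% 1.0,
                  sd_animal_region = coh_y$sd_animal_region %||% 0.8,
                  sd_resid = coh_y$sd_resid %||% 2.0),
    config_path = path),
    class = "run_config")
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[perispect] stage: %s", name))
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("perispect_stage_error", "error", "condition"),
      stage = name))
  })
}

#' Run the full simulate - process - quantify - segment - model pipeline
#'
#' End-to-end reproducible run: simulates labelled CSI grids and lesion
#' phantoms for each study day, quantifies the PHE/ATNE/CONTRA voxels,
#' segments and measures lesion volumes, simulates a full cohort and fits
#' the mixed models, and writes summary tables, figures and a JSON manifest
#' (config hash, package version, seed, per-stage QC flags) to `out_dir`.
#' Deterministic given `seed`.
#'
#' @param config a `run_config` from [load_run_config()].
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing).
#' @param verbose print stage progress?
#' @return (invisibly) list with the summary tables and the manifest.
#' @export
run_pipeline <- function(config = load_run_config(), seed = 1,
                         out_dir = tempfile("perispect_run_"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acq <- config$acquisition
  pri <- config$priors
  mets <- pri$metabolites
  water <- pri$water
  days <- c(1, 7, 14)
  qc <- list()

  means <- default_cohort_means()
  vol_means <- default_volume_means()

  # --- simulate + quantify the three analysis voxels per day ------------
  conc <- run_stage("quantify", verbose, {
    rows <- list()
    voxels <- list(PHE = c(4L, 4L), ATNE = c(4L, 6L), CONTRA = c(6L, 6L))
    grids <- list()
    for (di in seq_along(days)) {
      day <- days[di]
      tm <- matrix(list(), acq$grid_shape[1], acq$grid_shape[2])
      for (i in seq_len(acq$grid_shape[1])) {
        for (j in seq_len(acq$grid_shape[2])) {
          tm[[i, j]] <- ground_truth_voxel(
            "CONTRA", c(NAA = 12, Cr = 9, Cho = 2.6),
            phase0 = 0, snr = config$snr)
        }
      }
      for (rg in names(voxels)) {
        mm <- means[means$day == day & means$region == rg, ]
        cm <- stats::setNames(mm$mean_mM, mm$metabolite)
        ph0 <- with_seed(seed + 100L * di, stats::runif(1, -1, 1)) *
          config$phase0_max
        tm[[voxels[[rg]][1], voxels[[rg]][2]]] <- ground_truth_voxel(
          rg, cm, phase0 = ph0, snr = config$snr)
      }
      g <- simulate_csi_grid(tm, mets, water, acq, seed = seed + di)
      # keep region labels only on the analysis voxels
      lab <- matrix(NA_character_, acq$grid_shape[1], acq$grid_shape[2])
      for (rg in names(voxels)) lab[voxels[[rg]][1], voxels[[rg]][2]] <- rg
      g$regions <- lab
      grids[[as.character(day)]] <- g
      q <- quantify_grid(g, mets, water, acq,
                         half_width_ppm = config$half_width_ppm,
                         regions_only = TRUE)
      q$day <- day
      rows[[di]] <- q
    }
    wqc <- water_ratio_qc(grids, voxels)
    qc$water_ratio <- wqc
    utils::write.csv(wqc, file.path(out_dir, "water_ratio_qc.csv"),
                     row.names = FALSE)
    do.call(rbind, rows)
  })
  utils::write.csv(conc, file.path(out_dir, "concentrations.csv"),
                   row.names = FALSE)

  # --- phantoms and volumetry -------------------------------------------
  volumes <- run_stage("segment", verbose, {
    rows <- list()
    for (di in seq_along(days)) {
      day <- days[di]
      vm <- vol_means[vol_means$day == day, ]
      ph <- simulate_flair_phantom(
        phantom_spec(image_shape = config$phantom$image_shape,
                     voxel_mm = config$phantom$voxel_mm,
                     icv_ml = config$phantom$icv_ml,
                     hematoma_ml = vm$hematoma_ml, edema_ml = vm$edema_ml,
                     noise_sd = config$phantom$noise_sd),
        seed = seed + 50L + di)
      seg <- segment_phantom(ph$image, ph$seeds,
                             tolerance = config$segmentation$tolerance,
                             connectivity = config$segmentation$connectivity)
      if (length(seg$qc)) qc[[paste0("segment_day", day)]] <- seg$qc
      rows[[di]] <- compute_volumes(seg, ph$voxel_mm, animal = "phantom",
                                    day = day)
    }
    do.call(rbind, rows)
  })
  utils::write.csv(volumes, file.path(out_dir, "volumes.csv"),
                   row.names = FALSE)
  pc <- percent_change(volumes)
  utils::write.csv(pc, file.path(out_dir, "volume_percent_change.csv"),
                   row.names = FALSE)

  # --- cohort simulation and mixed models -------------------------------
  results <- run_stage("model", verbose, {
    design <- cohort_design(n_animals = config$cohort$n_animals,
                            sd_animal = config$cohort$sd_animal,
                            sd_animal_region = config$cohort$sd_animal_region,
                            sd_resid = config$cohort$sd_resid)
    coh <- simulate_cohort(design, seed = seed + 1000L)
    utils::write.csv(coh, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    ctr <- list()
    for (met in unique(coh$metabolite)) {
      fit <- fit_lmm(coh[coh$metabolite == met, ])
      if (fit$singular) qc[[paste0("lmm_", met)]] <- fit$flags
      tab <- region_time_contrasts(fit)
      tab$metabolite <- met
      ctr[[met]] <- tab
    }
    contrasts <- do.call(rbind, ctr)
    vols <- simulate_volume_cohort(n_animals = config$cohort$n_animals,
                                   seed = seed + 2000L)
    utils::write.csv(vols, file.path(out_dir, "volume_cohort.csv"),
                     row.names = FALSE)
    veff <- list()
    for (oc in c("hematoma_ml", "edema_ml")) {
      vfit <- fit_volume_model(vols, outcome = oc)
      de <- vfit$day_effects
      de$outcome <- oc
      veff[[oc]] <- de
    }
    list(contrasts = contrasts, volume_effects = do.call(rbind, veff),
         cohort = coh)
  })
  utils::write.csv(results$contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(results$volume_effects,
                   file.path(out_dir, "volume_effects.csv"), row.names = FALSE)

  # --- figures -----------------------------------------------------------
  run_stage("figures", verbose, {
    agg <- stats::aggregate(value_mM ~ region + day + metabolite,
                            results$cohort, mean)
    p1 <- ggplot2::ggplot(agg, ggplot2::aes(x = day, y = value_mM,
                                            colour = region)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~metabolite, scales = "free_y") +
      ggplot2::labs(x = "day after ICH", y = "concentration (mM)")
    ggplot2::ggsave(file.path(out_dir, "concentrations_by_day.png"), p1,
                    width = 8, height = 3.2, dpi = 120)
    vl <- utils::stack(volumes[, c("hematoma_ml", "edema_ml")])
    vl$day <- rep(volumes$day, 2)
    p2 <- ggplot2::ggplot(vl, ggplot2::aes(x = day, y = values,
                                           colour = ind)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "day after ICH", y = "volume (ml)", colour = NULL)
    ggplot2::ggsave(file.path(out_dir, "volumes_by_day.png"), p2,
                    width = 5, height = 3.2, dpi = 120)
  })

  # --- manifest -----------------------------------------------------------
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(config[setdiff(names(config), "priors")], cfg_json,
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  manifest <- list(
    package = "perispect",
    version = as.character(utils::packageVersion("perispect")),
    seed = seed,
    config_path = config$config_path,
    config_md5 = unname(tools::md5sum(cfg_json)),
    outputs = list.files(out_dir),
    qc = qc,
    timestamp_free = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  if (verbose) message(sprintf("[perispect] run complete: %s", out_dir))
  invisible(list(concentrations = conc, volumes = volumes,
                 percent_change = pc, contrasts = results$contrasts,
                 volume_effects = results$volume_effects,
                 manifest = manifest, out_dir = out_dir))
}
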