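#' Design of a longitudinal metabolite cohort
#'
#' Cell means and variance components for simulating a 3-region x 3-day
#' cohort with animal-level random effects. The generating model per
#' metabolite is
#' `value = mean(region, day) + a_animal + b_(animal x region) + e`,
#' with independent Gaussian effects; the animal and animal-by-region
#' intercepts induce the nested covariance the analysis model assumes.
#'
#' @param n_animals number of animals.
#' @param days ordered measurement days.
#' @param region_time_means data.frame with columns `region`, `day`,
#'   `metabolite`, `mean_mM`, covering every (region, day) cell for every
#'   metabolite.
#' @param sd_animal SD of the animal random intercept (mM).
#' @param sd_animal_region SD of the animal-by-region intercept (mM).
#' @param sd_resid residual SD (mM).
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_animals = 12, days = c(1, 7, 14),
                          region_time_means = default_cohort_means(),
                          sd_animal = 1.0, sd_animal_region = 0.8,
                          sd_resid = 2.0) {
  assert_scalar_num(n_animals, "n_animals", positive = TRUE)
  assert_scalar_num(sd_animal, "sd_animal", nonneg = TRUE)
  assert_scalar_num(sd_animal_region, "sd_animal_region", nonneg = TRUE)
  assert_scalar_num(sd_resid, "sd_resid", nonneg = TRUE)
  need <- c("region", "day", "metabolite", "mean_mM")
  if (!all(need %in% names(region_time_means))) {
    stopf("region_time_means must have columns %s", paste(need, collapse = ", "),
          class = "perispect_validation_error")
  }
  m <- region_time_means
  cells <- expand.grid(region = unique(m$region), day = days,
                       metabolite = unique(m$metabolite))
  key <- function(df) paste(df$region, df$day, df$metabolite)
  missing_cells <- setdiff(key(cells), key(m))
  if (length(missing_cells)) {
    stopf("region_time_means is missing cells: %s",
          paste(utils::head(missing_cells, 5), collapse = "; "),
          class = "perispect_validation_error")
  }
  structure(list(n_animals = as.integer(n_animals), days = days,
                 region_time_means = m, sd_animal = sd_animal,
                 sd_animal_region = sd_animal_region, sd_resid = sd_resid),
            class = "cohort_design")
}

#' Default cohort cell means (mM)
#'
#' Region-by-day means for NAA, Cr and Cho in the PHE, ATNE and
#' contralesional voxels at days 1, 7 and 14. Day-1 and day-14 NAA and Cr
#' means are the published group means for this design; day-7 values and all
#' Cho values are stand-ins chosen to reproduce the qualitative trajectory
#' (early loss in both perilesional regions, day-14 restoration in PHE only,
#' stable contralesional values).
#'
#' @return data.frame with columns `region`, `day`, `metabolite`, `mean_mM`.
#' @export
default_cohort_means <- function() {
  tab <- rbind(
    # metabolite, region, day1, day7, day14
    data.frame(metabolite = "NAA", region = "PHE",    d1 = 9.70, d7 = 11.5, d14 = 14.79),
    data.frame(metabolite = "NAA", region = "ATNE",   d1 = 9.45, d7 = 9.20, d14 = 9.99),
    data.frame(metabolite = "NAA", region = "CONTRA", d1 = 13.7, d7 = 14.0, d14 = 14.5),
    data.frame(metabolite = "Cr",  region = "PHE",    d1 = 3.62, d7 = 4.50, d14 = 6.23),
    data.frame(metabolite = "Cr",  region = "ATNE",   d1 = 3.46, d7 = 4.00, d14 = 5.15),
    data.frame(metabolite = "Cr",  region = "CONTRA", d1 = 9.43, d7 = 10.0, d14 = 10.7),
    data.frame(metabolite = "Cho", region = "PHE",    d1 = 1.60, d7 = 1.90, d14 = 2.70),
    data.frame(metabolite = "Cho", region = "ATNE",   d1 = 1.50, d7 = 1.70, d14 = 1.80),
    data.frame(metabolite = "Cho", region = "CONTRA", d1 = 2.80, d7 = 2.90, d14 = 2.90))
  out <- data.frame(
    region = rep(tab$region, 3),
    day = rep(c(1, 7, 14), each = nrow(tab)),
    metabolite = rep(tab$metabolite, 3),
    mean_mM = c(tab$d1, tab$d7, tab$d14),
    stringsAsFactors = FALSE)
  out[order(out$metabolite, out$region, out$day), ]
}

#' Simulate a longitudinal cohort table
#'
#' One row per animal x region x day x metabolite, drawn from the
#' [cohort_design()] generating model. Random effects are drawn
#' independently per metabolite (each metabolite is modelled separately
#' downstream). Regeneration with the same seed is bit-identical.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return data.frame with columns `animal`, `region`, `day`, `metabolite`,
#'   `value_mM`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_design(n_animals = 4), seed = 1)
#' head(coh)
simulate_cohort <- function(design, seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  m <- design$region_time_means
  regions <- unique(m$region)
  mets <- unique(m$metabolite)
  n <- design$n_animals
  grid <- expand.grid(animal = seq_len(n), region = regions,
                      day = design$days, metabolite = mets,
                      stringsAsFactors = FALSE)
  key <- paste(m$region, m$day, m$metabolite)
  mu <- stats::setNames(m$mean_mM, key)
  grid$mean <- mu[paste(grid$region, grid$day, grid$metabolite)]
  grid$value_mM <- NA_real_

  with_seed(seed, {
    for (met in mets) {
      a <- stats::rnorm(n, 0, design$sd_animal)
      ar <- matrix(stats::rnorm(n * length(regions), 0,
                                design$sd_animal_region),
                   n, length(regions), dimnames = list(NULL, regions))
      sel <- grid$metabolite == met
      idx_a <- grid$animal[sel]
      idx_r <- match(grid$region[sel], regions)
      e <- stats::rnorm(sum(sel), 0, design$sd_resid)
      grid$value_mM[sel] <- grid$mean[sel] + a[idx_a] +
        ar[cbind(idx_a, idx_r)] + e
    }
    grid
  })
  grid$animal <- paste0("A", formatC(grid$animal, width = 2, flag = "0"))
  out <- grid[, c("animal", "region", "day", "metabolite", "value_mM")]
  out[order(out$metabolite, out$animal, out$region, out$day), ]
}

#' Simulate a longitudinal lesion-volume table
#'
#' Per-animal ICV, hematoma and edema volumes over days with an animal
#' random intercept and residual noise; draws are truncated at zero since
#' volumes cannot be negative. Default day means follow the published group
#' trajectory (edema 2.38 ml resolving by 82.7% at day 14, hematoma 1.00 ml
#' clearing by 38.3%, stable ICV).
#'
#' @param n_animals number of animals.
#' @param days measurement days.
#' @param day_means data.frame with columns `day`, `icv_ml`, `hematoma_ml`,
#'   `edema_ml`.
#' @param sd_animal,sd_resid variance components (ml), recycled per outcome
#'   in the order icv, hematoma, edema.
#' @param seed integer seed.
#' @return data.frame with columns `animal`, `day`, `icv_ml`,
#'   `hematoma_ml`, `edema_ml`.
#' @export
simulate_volume_cohort <- function(n_animals = 12, days = c(1, 7, 14),
                                   day_means = default_volume_means(),
                                   sd_animal = c(5, 0.5, 0.7),
                                   sd_resid = c(1.5, 0.2, 0.3),
                                   seed = 1) {
  stopifnot(all(days %in% day_means$day))
  outcomes <- c("icv_ml", "hematoma_ml", "edema_ml")
  sd_animal <- rep_len(sd_animal, 3)
  sd_resid <- rep_len(sd_resid, 3)
  grid <- expand.grid(animal = seq_len(n_animals), day = days)
  with_seed(seed, {
    for (k in seq_along(outcomes)) {
      oc <- outcomes[k]
      mu <- stats::setNames(day_means[[oc]], day_means$day)
      a <- stats::rnorm(n_animals, 0, sd_animal[k])
      e <- stats::rnorm(nrow(grid), 0, sd_resid[k])
      grid[[oc]] <- pmax(0, mu[as.character(grid$day)] + a[grid$animal] + e)
    }
    grid
  })
  grid$animal <- paste0("A", formatC(grid$animal, width = 2, flag = "0"))
  grid[order(grid$animal, grid$day), c("animal", "day", outcomes)]
}

#' @rdname simulate_volume_cohort
#' @export
default_volume_means <- function() {
  data.frame(day = c(1, 7, 14),
             icv_ml = c(70.3, 72.9, 74.2),
             hematoma_ml = c(1.00, 1.00 * (1 - 0.157), 1.00 * (1 - 0.383)),
             edema_ml = c(2.38, 2.38 * (1 - 0.231), 2.38 * (1 - 0.827)))
}

#' Write a cohort table to CSV
#'
#' @param cohort data.frame from [simulate_cohort()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
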