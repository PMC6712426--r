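test_that("a zero-noise cohort yields fixed effects equal to cell-mean differences", {
  d0 <- cohort_design(n_animals = 4, sd_animal = 0, sd_animal_region = 0,
                      sd_resid = 0)
  coh <- simulate_cohort(d0, seed = 1)
  fit <- suppressWarnings(suppressMessages(
    fit_lmm(coh[coh$metabolite == "NAA", ])))
  expect_true(fit$singular || any(fit$flags == "fallback_ols"))
  ct <- region_time_contrasts(fit)
  get <- function(nm) ct$estimate[ct$contrast == nm]
  expect_equal(get("ATNE - CONTRA @ day 1"), 9.45 - 13.7, tolerance = 1e-8)
  expect_equal(get("PHE - CONTRA @ day 14"), 14.79 - 14.5, tolerance = 1e-8)
  expect_equal(get("PHE: day 14 - day 1"), 14.79 - 9.70, tolerance = 1e-8)
  expect_equal(get("CONTRA: day 14 - day 1"), 14.5 - 13.7, tolerance = 1e-8)
  expect_lt(sum(fit$varcomp), 1e-8)
})

test_that("balanced designs reproduce ordinary cell means under the mixed model", {
  coh <- simulate_cohort(cohort_design(n_animals = 8), seed = 5)
  naa <- coh[coh$metabolite == "NAA", ]
  fit <- fit_lmm(naa)
  ct <- region_time_contrasts(fit)
  cell <- function(rg, dy) mean(naa$value_mM[naa$region == rg & naa$day == dy])
  expect_equal(ct$estimate[ct$contrast == "PHE - CONTRA @ day 7"],
               cell("PHE", 7) - cell("CONTRA", 7), tolerance = 1e-6)
  expect_equal(ct$estimate[ct$contrast == "ATNE: day 14 - day 1"],
               cell("ATNE", 14) - cell("ATNE", 1), tolerance = 1e-6)
})

test_that("symmetric regions produce identical contrasts against the reference", {
  m <- default_cohort_means()
  m$mean_mM[m$region == "ATNE"] <- m$mean_mM[m$region == "PHE"]
  d <- cohort_design(n_animals = 400, region_time_means = m)
  coh <- simulate_cohort(d, seed = 9)
  fit <- fit_lmm(coh[coh$metabolite == "NAA", ])
  ct <- region_time_contrasts(fit)
  e_phe <- ct$estimate[ct$contrast == "PHE - CONTRA @ day 1"]
  e_atne <- ct$estimate[ct$contrast == "ATNE - CONTRA @ day 1"]
  se <- ct$se[ct$contrast == "PHE - CONTRA @ day 1"]
  expect_lt(abs(e_phe - e_atne), 4 * se)
})

test_that("fixed-effect estimates are unbiased over repeated cohorts", {
  # parameter recovery: mean estimate of the PHE day-14 - day-1 contrast
  # over replicates stays within half a standard error of the truth
  truth <- 14.79 - 9.70
  n_rep <- 200
  est <- se <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    coh <- simulate_cohort(cohort_design(), seed = 5000 + k)
    fit <- suppressMessages(suppressWarnings(
      fit_lmm(coh[coh$metabolite == "NAA", ])))
    ct <- region_time_contrasts(fit)
    i <- ct$contrast == "PHE: day 14 - day 1"
    est[k] <- ct$estimate[i]; se[k] <- ct$se[i]
  }
  bias <- mean(est) - truth
  expect_lt(abs(bias), 0.5 * mean(se))
})

test_that("volume models recover day effects and flag degenerate fits", {
  # constant volumes -> zero day effects
  vols <- data.frame(animal = rep(sprintf("A%d", 1:6), each = 3),
                     day = rep(c(1, 7, 14), 6), edema_ml = 2)
  fit <- suppressWarnings(suppressMessages(fit_volume_model(vols)))
  expect_true(all(abs(fit$day_effects$estimate) < 1e-10))
  # zero-noise declining series -> day effects equal the differences exactly
  decl <- data.frame(animal = rep(sprintf("A%d", 1:6), each = 3),
                     day = rep(c(1, 7, 14), 6),
                     edema_ml = rep(c(2.38, 1.83, 0.41), 6))
  fit2 <- suppressWarnings(suppressMessages(fit_volume_model(decl)))
  eff <- fit2$day_effects
  expect_equal(eff$estimate[eff$contrast == "day 14 - day 1"], 0.41 - 2.38,
               tolerance = 1e-8)
  expect_equal(eff$estimate[eff$contrast == "day 7 - day 1"], 1.83 - 2.38,
               tolerance = 1e-8)
  # stochastic cohort at the design means
  vols3 <- simulate_volume_cohort(n_animals = 12, seed = 4)
  fit3 <- fit_volume_model(vols3, outcome = "edema_ml")
  eff3 <- fit3$day_effects
  e14 <- eff3$estimate[eff3$contrast == "day 14 - day 1"]
  se14 <- eff3$se[eff3$contrast == "day 14 - day 1"]
  expect_lt(abs(e14 - (0.41 - 2.38)), 4 * se14)
})

test_that("model preconditions are enforced", {
  coh <- simulate_cohort(cohort_design(n_animals = 3), seed = 1)
  one <- coh[coh$animal == "A01" & coh$metabolite == "NAA", ]
  expect_error(fit_lmm(one), class = "perispect_validation_error")
  empty_cell <- coh[!(coh$region == "PHE" & coh$day == 14) &
                      coh$metabolite == "NAA", ]
  expect_error(fit_lmm(empty_cell), class = "perispect_validation_error")
})

test_that("correlation tables are descriptive and complete", {
  coh <- simulate_cohort(cohort_design(), seed = 11)
  conc <- coh
  vols <- simulate_volume_cohort(n_animals = 12, seed = 11)
  tab <- correlate_volumes(conc, vols)
  expect_equal(nrow(tab), 3 * 3 * 2)
  expect_true(all(is.na(tab$r) | abs(tab$r) <= 1))
  expect_true(all(is.na(tab$p_value) | (tab$p_value >= 0 & tab$p_value <= 1)))
})
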