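#' Fit the longitudinal mixed model for metabolite concentrations
#'
#' REML linear mixed model with fixed effects for brain region, categorical
#' (polychotomous) day and their interaction, and random intercepts for
#' animal and for the animal-by-region interaction - the nested covariance
#' structure that accounts for correlation of repeated measurements within
#' an animal and the stronger correlation within a region of that animal.
#' Degrees of freedom and p-values use the Satterthwaite approximation.
#'
#' If the REML fit is singular (one or more variance components estimated at
#' the zero boundary) the result is flagged, never silently accepted; if the
#' mixed-model fit fails outright (e.g. a zero-residual degenerate cohort),
#' an ordinary least-squares fit of the fixed effects is returned, flagged
#' `fallback_ols`.
#'
#' @param cohort long-format data.frame with columns `animal`, `region`,
#'   `day` and the response.
#' @param response response column name (default `value_mM`).
#' @param reference_region region used as the fixed-effect reference level.
#' @return object of class `mm_fit`: `model`, `fixed` (coefficient table),
#'   `varcomp` (named variances for animal, animal:region, residual),
#'   `singular`, `flags`, plus the factor levels used.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_design(), seed = 1)
#' fit <- fit_lmm(subset(coh, metabolite == "NAA"))
#' fit$varcomp
fit_lmm <- function(cohort, response = "value_mM",
                    reference_region = "CONTRA") {
  need <- c("animal", "region", "day", response)
  if (!all(need %in% names(cohort))) {
    stopf("cohort must have columns %s", paste(need, collapse = ", "),
          class = "perispect_validation_error")
  }
  d <- cohort
  if (length(unique(d$animal)) < 2L) {
    stopf("need at least 2 animals", class = "perispect_validation_error")
  }
  regions <- unique(as.character(d$region))
  if (reference_region %in% regions) {
    regions <- c(reference_region, setdiff(regions, reference_region))
  }
  d$region <- factor(d$region, levels = regions)
  d$day <- factor(d$day, levels = sort(unique(as.numeric(as.character(d$day)))))
  d$animal <- factor(d$animal)
  if (any(table(d$region, d$day) == 0L)) {
    stopf("every region x day cell must be non-empty",
          class = "perispect_validation_error")
  }
  d$.y <- d[[response]]

  flags <- character(0)
  model <- tryCatch(
    lmerTest::lmer(.y ~ region * day + (1 | animal) + (1 | animal:region),
                   data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) e)
  if (inherits(model, "error")) {
    flags <- c(flags, "fallback_ols")
    model <- stats::lm(.y ~ region * day, data = d)
    fixed <- as.data.frame(summary(model)$coefficients)
    varcomp <- c(animal = 0, `animal:region` = 0,
                 residual = stats::sigma(model)^2)
    singular <- TRUE
  } else {
    singular <- lme4::isSingular(model)
    if (singular) flags <- c(flags, "singular_fit")
    fixed <- as.data.frame(stats::coef(summary(model)))
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- stats::setNames(vc$vcov, vc$grp)
    names(varcomp)[names(varcomp) == "Residual"] <- "residual"
  }
  structure(list(model = model, fixed = fixed, varcomp = varcomp,
                 singular = singular, flags = flags,
                 region_levels = levels(d$region),
                 day_levels = levels(d$day), data = d,
                 response = response),
            class = "mm_fit")
}

# Row of the fixed-effect design matrix for one (region, day) cell.
cell_design_row <- function(fit, region, day) {
  nd <- data.frame(region = factor(region, levels = fit$region_levels),
                   day = factor(day, levels = fit$day_levels))
  stats::model.matrix(~ region * day, nd,
                      contrasts.arg = NULL)[1, , drop = TRUE]
}

# Estimate/SE/df/p for a single linear combination of fixed effects.
estimate_contrast <- function(fit, L) {
  if (inherits(fit$model, "lmerModLmerTest")) {
    ct <- lmerTest::contest1D(fit$model, L, confint = FALSE)
    data.frame(estimate = ct$Estimate, se = ct$`Std. Error`, df = ct$df,
               statistic = ct$`t value`, p_value = ct$`Pr(>|t|)`)
  } else {
    # OLS fallback
    b <- stats::coef(fit$model)
    V <- stats::vcov(fit$model)
    est <- sum(L * b)
    se <- sqrt(drop(t(L) %*% V %*% L))
    df <- stats::df.residual(fit$model)
    tv <- if (se > 0) est / se else NA_real_
    data.frame(estimate = est, se = se, df = df, statistic = tv,
               p_value = if (is.na(tv)) NA_real_ else
                 2 * stats::pt(-abs(tv), df))
  }
}

#' Region-by-time contrast table
#'
#' The comparison set of the study design: each lesional region versus the
#' contralesional reference at each day (hemispheric differences), and the
#' last-versus-first day change within each region (temporal differences).
#' Two-sided p-values; no multiplicity correction by default (set
#' `adjust = "holm"` to apply one).
#'
#' @param fit an `mm_fit` from [fit_lmm()].
#' @param alpha significance threshold used for the `significant` column.
#' @param adjust p-value adjustment method (`"none"` or any
#'   [stats::p.adjust()] method).
#' @return data.frame with columns `contrast`, `estimate`, `se`, `df`,
#'   `statistic`, `p_value`, `significant`.
#' @export
region_time_contrasts <- function(fit, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(fit, "mm_fit"))
  ref <- fit$region_levels[1]
  others <- setdiff(fit$region_levels, ref)
  d1 <- fit$day_levels[1]
  dK <- fit$day_levels[length(fit$day_levels)]
  rows <- list()
  for (day in fit$day_levels) {
    for (rg in others) {
      L <- cell_design_row(fit, rg, day) - cell_design_row(fit, ref, day)
      est <- estimate_contrast(fit, L)
      est$contrast <- sprintf("%s - %s @ day %s", rg, ref, day)
      rows[[length(rows) + 1L]] <- est
    }
  }
  for (rg in fit$region_levels) {
    L <- cell_design_row(fit, rg, dK) - cell_design_row(fit, rg, d1)
    est <- estimate_contrast(fit, L)
    est$contrast <- sprintf("%s: day %s - day %s", rg, dK, d1)
    rows[[length(rows) + 1L]] <- est
  }
  out <- do.call(rbind, rows)
  out <- out[, c("contrast", "estimate", "se", "df", "statistic", "p_value")]
  if (!identical(adjust, "none")) {
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Fit the longitudinal mixed model for lesion volumes
#'
#' Per-outcome model with categorical day as the fixed effect and a random
#' intercept per animal; day effects are expressed relative to the first
#' day.
#'
#' @param volumes data.frame with columns `animal`, `day` and the outcome.
#' @param outcome outcome column (e.g. `"edema_ml"`).
#' @return an `mm_fit`; its `day_effects` element tabulates each later day
#'   versus the first (estimate, SE, df, p).
#' @export
fit_volume_model <- function(volumes, outcome = "edema_ml") {
  need <- c("animal", "day", outcome)
  if (!all(need %in% names(volumes))) {
    stopf("volumes must have columns %s", paste(need, collapse = ", "),
          class = "perispect_validation_error")
  }
  d <- volumes
  d$day <- factor(d$day, levels = sort(unique(as.numeric(as.character(d$day)))))
  d$animal <- factor(d$animal)
  d$.y <- d[[outcome]]
  flags <- character(0)
  model <- tryCatch(
    lmerTest::lmer(.y ~ day + (1 | animal), data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) e)
  if (inherits(model, "error")) {
    flags <- c(flags, "fallback_ols")
    model <- stats::lm(.y ~ day, data = d)
    singular <- TRUE
    varcomp <- c(animal = 0, residual = stats::sigma(model)^2)
    fixed <- as.data.frame(summary(model)$coefficients)
  } else {
    singular <- lme4::isSingular(model)
    if (singular) flags <- c(flags, "singular_fit")
    fixed <- as.data.frame(stats::coef(summary(model)))
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- stats::setNames(vc$vcov, vc$grp)
    names(varcomp)[names(varcomp) == "Residual"] <- "residual"
  }
  fit <- structure(list(model = model, fixed = fixed, varcomp = varcomp,
                        singular = singular, flags = flags,
                        day_levels = levels(d$day), data = d,
                        response = outcome),
                   class = "mm_fit")
  days <- levels(d$day)
  eff <- list()
  for (dk in days[-1]) {
    nd1 <- data.frame(day = factor(days[1], levels = days))
    ndk <- data.frame(day = factor(dk, levels = days))
    L <- stats::model.matrix(~day, ndk)[1, ] - stats::model.matrix(~day, nd1)[1, ]
    est <- estimate_contrast(fit, L)
    est$contrast <- sprintf("day %s - day %s", dk, days[1])
    eff[[length(eff) + 1L]] <- est
  }
  fit$day_effects <- do.call(rbind, eff)[, c("contrast", "estimate", "se",
                                             "df", "statistic", "p_value")]
  fit
}

#' Descriptive correlation of lesion volumes with metabolite concentrations
#'
#' Plain Pearson correlation (with unadjusted p-values) between per-animal
#' lesion volumes and voxel concentrations, per region, metabolite and
#' outcome. Reported descriptively only.
#'
#' @param concentrations data.frame with `animal`, `day`, `region`,
#'   `metabolite`, `value_mM`.
#' @param volumes data.frame with `animal`, `day`, `hematoma_ml`,
#'   `edema_ml`.
#' @return data.frame of `region`, `metabolite`, `outcome`, `r`, `p_value`,
#'   `n`.
#' @export
correlate_volumes <- function(concentrations, volumes) {
  merged <- merge(concentrations, volumes, by = c("animal", "day"))
  out <- list()
  for (rg in unique(merged$region)) {
    for (met in unique(merged$metabolite)) {
      sub <- merged[merged$region == rg & merged$metabolite == met, ]
      for (oc in c("hematoma_ml", "edema_ml")) {
        if (nrow(sub) < 4 || stats::sd(sub[[oc]]) == 0 ||
            stats::sd(sub$value_mM) == 0) {
          r <- NA_real_; p <- NA_real_
        } else {
          ct <- stats::cor.test(sub$value_mM, sub[[oc]])
          r <- unname(ct$estimate); p <- ct$p.value
        }
        out[[length(out) + 1L]] <- data.frame(
          region = rg, metabolite = met, outcome = oc, r = r, p_value = p,
          n = nrow(sub), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>", if (x$singular) "(singular)" else "", "\n")
  cat("variance components:\n")
  print(x$varcomp)
  cat("fixed effects:\n")
  print(utils::head(x$fixed, 12))
  invisible(x)
}
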