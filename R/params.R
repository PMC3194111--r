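#' Radon concentration model parameters
#'
#' Fixed effects of the log-linear indoor radon model (log pCi/L scale) plus
#' the variance components of its four-level nesting
#' (house within census tract (SSU) within county (PSU) within state).
#' Reference levels -- Midwest region, Low geological potential, detached
#' house with basement -- carry coefficient exactly 0.
#'
#' @param intercept Intercept on the log(pCi/L) scale.
#' @param region_coefs Named numeric over all of [region_levels()].
#' @param geo_coefs Named numeric over all of [geo_potential_levels()].
#' @param hdd_coef Log units per heating-infiltration degree-day.
#' @param diurnal_coef Log units per degree of average diurnal swing.
#' @param housetype_coefs Named numeric over all of [house_type_levels()].
#' @param variance_components Named numeric with entries `state`, `psu`,
#'   `ssu`, `residual` (variances on the log scale).
#' @param se Optional named numeric of standard errors.
#' @param loglik Optional log-likelihood of the fit that produced the values.
#' @return An object of class `radon_params`.
#' @export
radon_params <- function(intercept, region_coefs, geo_coefs, hdd_coef,
                         diurnal_coef, housetype_coefs, variance_components,
                         se = NULL, loglik = NULL) {
  obj <- structure(
    list(intercept = as.numeric(intercept),
         region_coefs = region_coefs,
         geo_coefs = geo_coefs,
         hdd_coef = as.numeric(hdd_coef),
         diurnal_coef = as.numeric(diurnal_coef),
         housetype_coefs = housetype_coefs,
         variance_components = variance_components,
         se = se, loglik = loglik),
    class = "radon_params")
  validate_radon_params(obj)
}

#' @rdname radon_params
#' @param x Object to validate.
#' @export
validate_radon_params <- function(x) {
  stopifnot(inherits(x, "radon_params"))
  .need_names <- function(v, nm, what) {
    if (!all(nm %in% names(v)))
      stop(sprintf("radon_params: %s must cover: %s", what,
                   paste(setdiff(nm, names(v)), collapse = ", ")),
           call. = FALSE)
  }
  .need_names(x$region_coefs, region_levels(), "region_coefs")
  .need_names(x$geo_coefs, geo_potential_levels(), "geo_coefs")
  .need_names(x$housetype_coefs, house_type_levels(), "housetype_coefs")
  .need_names(x$variance_components, c("state", "psu", "ssu", "residual"),
              "variance_components")
  if (x$region_coefs[["Midwest"]] != 0)
    stop("radon_params: reference region Midwest must carry coefficient 0",
         call. = FALSE)
  if (x$geo_coefs[["Low"]] != 0)
    stop("radon_params: reference geological potential Low must carry 0",
         call. = FALSE)
  if (x$housetype_coefs[["detached_with_basement"]] != 0)
    stop("radon_params: reference house type must carry coefficient 0",
         call. = FALSE)
  if (any(x$variance_components < 0))
    stop("radon_params: variance components must be >= 0", call. = FALSE)
  if (!all(is.finite(c(x$intercept, x$hdd_coef, x$diurnal_coef,
                       x$region_coefs, x$geo_coefs, x$housetype_coefs))))
    stop("radon_params: non-finite coefficient", call. = FALSE)
  x
}

#' @export
print.radon_params <- function(x, ...) {
  cat("Log-linear radon concentration model (log pCi/L scale)\n")
  cat(sprintf("  intercept: %g\n", x$intercept))
  cat("  region:", paste(sprintf("%s=%g", names(x$region_coefs),
                                 x$region_coefs), collapse = " "), "\n")
  cat("  geological potential:",
      paste(sprintf("%s=%g", names(x$geo_coefs), x$geo_coefs),
            collapse = " "), "\n")
  cat(sprintf("  HDD: %g per degree-day, diurnal swing: %g per degree\n",
              x$hdd_coef, x$diurnal_coef))
  cat("  house type:", paste(sprintf("%s=%g", names(x$housetype_coefs),
                                     x$housetype_coefs), collapse = " "), "\n")
  cat("  variance components:",
      paste(sprintf("%s=%g", names(x$variance_components),
                    x$variance_components), collapse = " "), "\n")
  invisible(x)
}

#' Multinomial housing model parameters
#'
#' Log-odds of living in each non-reference house type (reference: single
#' detached house with basement), as a function of poverty, sex, race, Census
#' region and age group. Stored on the natural-log scale; the published table
#' prints odds ratios, so `coefs` holds `log(OR)`.
#'
#' @param intercepts Named numeric over [house_type_outcomes()] (log-odds).
#' @param coefs Numeric matrix, rows keyed `"term:level"` (e.g.
#'   `"poverty:below"`), columns [house_type_outcomes()], entries log-odds.
#' @param se Optional list with elements `intercepts` and `coefs` mirroring
#'   the shapes above.
#' @param loglik Optional log-likelihood.
#' @param islander_map Race level used in place of `islander` (absent from
#'   the housing model); default `"other"`.
#' @return An object of class `housing_params`.
#' @export
housing_params <- function(intercepts, coefs, se = NULL, loglik = NULL,
                           islander_map = "other") {
  obj <- structure(
    list(outcomes = house_type_outcomes(),
         reference = "detached_with_basement",
         intercepts = intercepts, coefs = coefs,
         se = se, loglik = loglik, islander_map = islander_map),
    class = "housing_params")
  validate_housing_params(obj)
}

#' @rdname housing_params
#' @param x Object to validate.
#' @export
validate_housing_params <- function(x) {
  stopifnot(inherits(x, "housing_params"))
  if (!all(house_type_outcomes() %in% names(x$intercepts)))
    stop("housing_params: intercepts must cover all non-reference outcomes",
         call. = FALSE)
  if (!is.matrix(x$coefs) ||
      !all(house_type_outcomes() %in% colnames(x$coefs)))
    stop("housing_params: coefs must be a matrix with one column per outcome",
         call. = FALSE)
  if (!all(is.finite(x$intercepts)) || !all(is.finite(x$coefs)))
    stop("housing_params: non-finite coefficient", call. = FALSE)
  if (!x$islander_map %in% race_levels_housing())
    stop("housing_params: islander_map must be a housing-model race level",
         call. = FALSE)
  x
}

#' @export
print.housing_params <- function(x, ...) {
  cat("Multinomial house-type model (reference: detached with basement)\n")
  cat("  intercepts (log-odds):",
      paste(sprintf("%s=%g", names(x$intercepts), x$intercepts),
            collapse = " "), "\n")
  cat(sprintf("  %d covariate-level coefficients per outcome (log OR)\n",
              nrow(x$coefs)))
  invisible(x)
}

#' Multilevel ever-smoking model parameters
#'
#' Fixed effects (logit scale) and random-parameter variances of the
#' multilevel logistic model of ever-smoking: random intercepts for state and
#' CBSA, a state-level random slope for Black race (jointly normal with the
#' state intercept), and a household random intercept.
#'
#' @param intercept Logit-scale intercept (reference: female, 45-54, above
#'   poverty, white, all state/CBSA covariates and residuals 0).
#' @param coefs Named numeric of fixed effects keyed `"term:level"` for
#'   categorical terms (e.g. `"sex:male"`, `"race_male:black"`) and bare term
#'   names for continuous/flag terms (`"state_tax"`, `"prev_state_prevalence"`,
#'   `"indoor_restrictions"`, `"cbsa_poverty_above_median"`,
#'   `"cbsa_nonmetropolitan"`, `"income_not_reported"`).
#' @param var_state,var_state_black_slope,cov_state_blackslope Variances of
#'   the state random intercept and Black-race random slope, and their
#'   covariance (logit^2).
#' @param var_cbsa,var_household CBSA and household random-intercept
#'   variances (logit^2).
#' @param se Optional named numeric of standard errors.
#' @param loglik Optional log-likelihood.
#' @return An object of class `smoking_params`.
#' @export
smoking_params <- function(intercept, coefs, var_state, var_state_black_slope,
                           cov_state_blackslope, var_cbsa, var_household,
                           se = NULL, loglik = NULL) {
  obj <- structure(
    list(intercept = as.numeric(intercept), coefs = coefs,
         var_state = as.numeric(var_state),
         var_state_black_slope = as.numeric(var_state_black_slope),
         cov_state_blackslope = as.numeric(cov_state_blackslope),
         var_cbsa = as.numeric(var_cbsa),
         var_household = as.numeric(var_household),
         se = se, loglik = loglik),
    class = "smoking_params")
  validate_smoking_params(obj)
}

#' @rdname smoking_params
#' @param x Object to validate.
#' @export
validate_smoking_params <- function(x) {
  stopifnot(inherits(x, "smoking_params"))
  needed <- c("sex:male", "poverty:below", "income_not_reported",
    paste0("age_group:", setdiff(age_groups_adult(), "45-54")),
    paste0("race:", setdiff(race_levels(), "white")),
    paste0("race_male:", setdiff(race_levels(), "white")),
    "state_tax", "prev_state_prevalence", "indoor_restrictions",
    "cbsa_poverty_above_median", "cbsa_nonmetropolitan")
  miss <- setdiff(needed, names(x$coefs))
  if (length(miss) > 0L)
    stop(sprintf("smoking_params: missing fixed effect(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  vars <- c(x$var_state, x$var_state_black_slope, x$var_cbsa, x$var_household)
  if (any(vars < 0))
    stop("smoking_params: variances must be >= 0", call. = FALSE)
  bound <- sqrt(x$var_state * x$var_state_black_slope)
  if (abs(x$cov_state_blackslope) > bound + 1e-12)
    stop("smoking_params: |cov(state, black slope)| exceeds Cauchy-Schwarz bound",
         call. = FALSE)
  if (!all(is.finite(c(x$intercept, x$coefs))))
    stop("smoking_params: non-finite coefficient", call. = FALSE)
  x
}

#' @export
print.smoking_params <- function(x, ...) {
  cat("Multilevel logistic ever-smoking model (logit scale)\n")
  cat(sprintf("  intercept: %g, %d fixed effects\n",
              x$intercept, length(x$coefs)))
  cat(sprintf("  random parameters: var(state)=%g, var(black slope)=%g, cov=%g, var(CBSA)=%g, var(household)=%g\n",
              x$var_state, x$var_state_black_slope, x$cov_state_blackslope,
              x$var_cbsa, x$var_household))
  invisible(x)
}

#' Exposure constants of the risk algorithm
#'
#' Physical constants converting an indoor radon gas concentration into a
#' cumulative progeny exposure in working level months (WLM). At the default
#' 40% equilibrium fraction, 1 pCi/L of radon gas corresponds to 0.004 WL of
#' progeny; one WL-year is 51.6 WLM; occupants are assumed home 70% of the
#' time. The derived exposure rate is
#' `wl_per_pci * wlm_per_wl_year * occupancy_fraction` WLM/yr per pCi/L
#' (0.14448 at the defaults, conventionally quoted as 0.144).
#'
#' @param wl_per_pci Working levels of progeny per pCi/L of radon gas.
#' @param wlm_per_wl_year WLM per WL-year.
#' @param occupancy_fraction Fraction of time spent at home, in (0, 1].
#' @param equilibrium_fraction Progeny equilibrium fraction (documentation
#'   only; its effect is already embodied in `wl_per_pci`).
#' @param exposure_duration_years Exposure duration used for lifetime risk.
#' @return An object of class `exposure_constants`.
#' @export
exposure_constants <- function(wl_per_pci = 0.004, wlm_per_wl_year = 51.6,
                               occupancy_fraction = 0.70,
                               equilibrium_fraction = 0.40,
                               exposure_duration_years = 75) {
  obj <- structure(
    list(wl_per_pci = wl_per_pci, wlm_per_wl_year = wlm_per_wl_year,
         occupancy_fraction = occupancy_fraction,
         equilibrium_fraction = equilibrium_fraction,
         exposure_duration_years = exposure_duration_years),
    class = "exposure_constants")
  validate_exposure_constants(obj)
}

#' @rdname exposure_constants
#' @param x Object to validate.
#' @export
validate_exposure_constants <- function(x) {
  stopifnot(inherits(x, "exposure_constants"))
  vals <- unlist(x)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("exposure_constants: all constants must be positive and finite",
         call. = FALSE)
  if (x$occupancy_fraction > 1)
    stop("exposure_constants: occupancy_fraction must be in (0, 1]",
         call. = FALSE)
  x
}

#' @export
print.exposure_constants <- function(x, ...) {
  cat("Exposure constants\n")
  cat(sprintf("  %g WL/(pCi/L) x %g WLM/WL-yr x %g occupancy = %g WLM/yr per pCi/L\n",
              x$wl_per_pci, x$wlm_per_wl_year, x$occupancy_fraction,
              exposure_rate(x)))
  cat(sprintf("  exposure duration: %g years (equilibrium fraction %g, informational)\n",
              x$exposure_duration_years, x$equilibrium_fraction))
  invisible(x)
}

#' Unit risk factors per WLM
#'
#' Lifetime excess probability of fatal lung cancer per WLM of radon-progeny
#' exposure, stratified by sex and ever/never smoking (the effect-modifying
#' stratum). The general-population value is used only to reproduce the EPA
#' calibration benchmark, never inside the bin-level chain.
#'
#' @param male_ever,female_ever,male_never,female_never Per-WLM lifetime
#'   fatal lung-cancer risks.
#' @param general_population Population-average per-WLM risk (calibration).
#' @return An object of class `unit_risk_factors`.
#' @export
unit_risk_factors <- function(male_ever = 0.00106, female_ever = 0.000851,
                              male_never = 0.000174, female_never = 0.000161,
                              general_population = 0.00054) {
  obj <- structure(
    list(male_ever = male_ever, female_ever = female_ever,
         male_never = male_never, female_never = female_never,
         general_population = general_population),
    class = "unit_risk_factors")
  validate_unit_risk_factors(obj)
}

#' @rdname unit_risk_factors
#' @param x Object to validate.
#' @export
validate_unit_risk_factors <- function(x) {
  stopifnot(inherits(x, "unit_risk_factors"))
  vals <- unlist(x)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals >= 0.01))
    stop("unit_risk_factors: values must lie in (0, 0.01)", call. = FALSE)
  if (x$male_ever <= x$male_never || x$female_ever <= x$female_never)
    stop("unit_risk_factors: ever-smoker risk must exceed never-smoker risk within sex",
         call. = FALSE)
  x
}

#' @export
print.unit_risk_factors <- function(x, ...) {
  cat("Unit risk factors (lifetime fatal lung cancer per WLM)\n")
  cat(sprintf("  ever-smokers:  male %g, female %g\n",
              x$male_ever, x$female_ever))
  cat(sprintf("  never-smokers: male %g, female %g\n",
              x$male_never, x$female_never))
  cat(sprintf("  general population (calibration): %g\n",
              x$general_population))
  invisible(x)
}
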