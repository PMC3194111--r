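#' Floor-clamp raw radon measurements
#'
#' Survey instruments can record non-positive concentrations; before
#' log-scale modelling these are clamped to a small positive floor
#' (default 0.1 pCi/L, about the minimal outdoor concentration).
#'
#' @param raw Numeric vector of raw measurements (pCi/L, possibly <= 0).
#' @param floor Positive clamp floor in pCi/L.
#' @return `pmax(raw, floor)`, strictly positive and log-safe.
#' @examples
#' preprocess_concentration(c(-0.3, 0, 2.5))  # 0.1 0.1 2.5
#' @export
preprocess_concentration <- function(raw, floor = 0.1) {
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor <= 0)
    stop("floor must be a single positive number", call. = FALSE)
  if (any(!is.finite(raw)))
    stop("raw concentrations must be finite", call. = FALSE)
  pmax(raw, floor)
}

# vectorised fixed-effect linear predictor on the log(pCi/L) scale
.radon_lp <- function(region, geo_potential, hdd, diurnal_swing, house_type,
                      params) {
  .check_levels(region, region_levels(), "region")
  .check_levels(geo_potential, geo_potential_levels(), "geo_potential")
  .check_levels(house_type, house_type_levels(), "house_type")
  params$intercept +
    unname(params$region_coefs[as.character(region)]) +
    unname(params$geo_coefs[as.character(geo_potential)]) +
    params$hdd_coef * hdd +
    params$diurnal_coef * diurnal_swing +
    unname(params$housetype_coefs[as.character(house_type)])
}

#' Radon-model linear predictor for a county context
#'
#' Sums the fixed effects of the log-linear radon model -- intercept, Census
#' region, geological potential class, heating degree-days, diurnal swing and
#' house type -- optionally adding the county's state (and, when present,
#' county) residuals on the log scale.
#'
#' @param context One county row: a list or one-row data.frame with fields
#'   `region`, `geo_potential`, `hdd`, `diurnal_swing` and optionally
#'   `radon_state_residual`, `radon_county_residual` (default 0, the rule for
#'   unsampled states/counties).
#' @param house_type One of [house_type_levels()].
#' @param params A [radon_params()] object.
#' @param include_residuals Add the context's radon residuals?
#' @return Linear predictor on the log(pCi/L) scale.
#' @examples
#' p <- load_coefficients("radon")
#' ctx <- list(region = "Midwest", geo_potential = "Low", hdd = 0,
#'             diurnal_swing = 0)
#' radon_linear_predictor(ctx, "detached_with_basement", p)  # -0.02
#' @export
radon_linear_predictor <- function(context, house_type, params,
                                   include_residuals = FALSE) {
  lp <- .radon_lp(context$region, context$geo_potential, context$hdd,
                  context$diurnal_swing, house_type, params)
  if (include_residuals) {
    rs <- context$radon_state_residual
    rc <- context$radon_county_residual
    lp <- lp + (if (is.null(rs)) 0 else rs) + (if (is.null(rc)) 0 else rc)
  }
  lp
}

#' Predicted radon concentration
#'
#' Exponentiates the linear predictor: a geometric-scale (median-type)
#' prediction with no lognormal mean correction, matching the convention of
#' summing fixed effects and using the result directly as the concentration.
#' Set `mean_correction = TRUE` to add half the residual-and-nesting variance
#' before exponentiating (arithmetic-mean convention) instead.
#'
#' @inheritParams radon_linear_predictor
#' @param mean_correction Apply the +sigma^2/2 lognormal retransformation?
#'   Default `FALSE`.
#' @return Concentration in pCi/L.
#' @examples
#' p <- load_coefficients("radon")
#' ctx <- list(region = "Midwest", geo_potential = "Low", hdd = 0,
#'             diurnal_swing = 0)
#' predict_concentration(ctx, "detached_with_basement", p)  # exp(-0.02)
#' @export
predict_concentration <- function(context, house_type, params,
                                  include_residuals = FALSE,
                                  mean_correction = FALSE) {
  lp <- radon_linear_predictor(context, house_type, params,
                               include_residuals)
  if (mean_correction) lp <- lp + sum(params$variance_components) / 2
  exp(lp)
}

#' Fit the four-level radon concentration model
#'
#' Restricted-maximum-likelihood fit (via [lme4::lmer()]) of the log-linear
#' nested random-intercept model: log concentration on region, geological
#' potential, meteorology and house type, with random intercepts for state,
#' PSU (county) and SSU (census tract), houses at level one.
#'
#' @param records Data.frame of measurement records with columns `house_id`,
#'   `ssu_id`, `psu_id`, `state_id`, `house_type`, `region`, `geo_potential`,
#'   `hdd`, `diurnal_swing`, `concentration` (strictly positive pCi/L;
#'   run [preprocess_concentration()] first if needed).
#' @param REML Use REML (default) or ML.
#' @param adjust_se Report Kenward-Roger small-sample adjusted standard
#'   errors (default, REML only): with moderate numbers of states and PSUs
#'   the model-based SEs of cluster-level covariates are slightly
#'   anticonservative, and the Kenward-Roger adjustment is the standard
#'   correction.
#' @return A [radon_params()] object carrying estimates, standard errors,
#'   variance components and the fit log-likelihood; the fitted `merMod` is
#'   attached as attribute `"fit"`.
#' @export
fit_radon_model <- function(records, REML = TRUE, adjust_se = REML) {
  need <- c("house_id", "ssu_id", "psu_id", "state_id", "house_type",
            "region", "geo_potential", "hdd", "diurnal_swing",
            "concentration")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(records$concentration <= 0))
    stop("concentrations must be strictly positive; apply preprocess_concentration() first",
         call. = FALSE)
  .check_nesting(records, c("ssu_id", "psu_id", "state_id"))
  for (lv in c("ssu_id", "psu_id", "state_id")) {
    if (length(unique(records[[lv]])) < 2L)
      stop("need at least 2 distinct ", lv, " groups", call. = FALSE)
  }
  .check_design_levels(records$region, region_levels(), "region")
  .check_design_levels(records$geo_potential, geo_potential_levels(),
                       "geo_potential")
  .check_design_levels(records$house_type, house_type_levels(), "house_type")

  d <- records
  d$log_conc <- log(d$concentration)
  d$region <- factor(d$region, levels = region_levels())
  d$region <- stats::relevel(d$region, ref = "Midwest")
  d$geo_potential <- factor(d$geo_potential, levels = geo_potential_levels())
  d$house_type <- factor(d$house_type, levels = house_type_levels())
  fit <- suppressWarnings(suppressMessages(lme4::lmer(
    log_conc ~ region + geo_potential + hdd + diurnal_swing + house_type +
      (1 | state_id) + (1 | psu_id) + (1 | ssu_id),
    data = d, REML = REML)))

  fe <- lme4::fixef(fit)
  if (adjust_se && REML) {
    se <- sqrt(diag(as.matrix(pbkrtest::vcovAdj(fit))))
  } else {
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(grp) {
    i <- which(vc$grp == grp)
    if (length(i) == 0L) 0 else vc$vcov[i]
  }
  pick <- function(nm) if (nm %in% names(fe)) unname(fe[[nm]]) else 0
  region_coefs <- stats::setNames(
    vapply(region_levels(), function(l) pick(paste0("region", l)),
           numeric(1)), region_levels())
  geo_coefs <- stats::setNames(
    vapply(geo_potential_levels(),
           function(l) pick(paste0("geo_potential", l)), numeric(1)),
    geo_potential_levels())
  ht_coefs <- stats::setNames(
    vapply(house_type_levels(), function(l) pick(paste0("house_type", l)),
           numeric(1)), house_type_levels())
  out <- radon_params(
    intercept = unname(fe[["(Intercept)"]]),
    region_coefs = region_coefs, geo_coefs = geo_coefs,
    hdd_coef = pick("hdd"), diurnal_coef = pick("diurnal_swing"),
    housetype_coefs = ht_coefs,
    variance_components = c(state = getvar("state_id"),
                            psu = getvar("psu_id"), ssu = getvar("ssu_id"),
                            residual = getvar("Residual")),
    se = stats::setNames(se, names(fe)),
    loglik = as.numeric(stats::logLik(fit)))
  attr(out, "fit") <- fit
  out
}

# every child id must map to exactly one parent id, all the way up
.check_nesting <- function(d, id_cols) {
  for (i in seq_len(length(id_cols) - 1L)) {
    child <- id_cols[i]; parent <- id_cols[i + 1L]
    n_parents <- tapply(d[[parent]], d[[child]],
                        function(x) length(unique(x)))
    if (any(n_parents > 1L))
      stop(sprintf("identifiers not strictly nested: %s spans multiple %s",
                   child, parent), call. = FALSE)
  }
  invisible(TRUE)
}

.check_design_levels <- function(x, allowed, what) {
  .check_levels(x, allowed, what)
  absent <- setdiff(allowed, unique(as.character(x)))
  if (length(absent) > 0L)
    stop(sprintf("singular design: %s level(s) absent from the data: %s",
                 what, paste(absent, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
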