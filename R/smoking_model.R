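# vectorised fixed+residual logit for bins joined with contexts
.smoking_lp <- function(sex, age_group, poverty, race, params,
                        state_tax = 0, prev_state_prevalence = 0,
                        indoor_restrictions = 0,
                        cbsa_poverty_above_median = 0,
                        cbsa_nonmetropolitan = 0,
                        state_residual = 0, cbsa_residual = 0,
                        state_black_slope = 0,
                        income_not_reported = FALSE) {
  .check_levels(sex, sex_levels(), "sex")
  .check_levels(age_group, age_groups_adult(), "age_group")
  .check_levels(poverty, poverty_levels(), "poverty")
  .check_levels(race, race_levels(), "race")
  cf <- c(params$coefs, "__ref__" = 0)
  pick <- function(keys) unname(cf[keys])
  male <- sex == "male"
  black <- race == "black"
  params$intercept +
    ifelse(male, cf[["sex:male"]], 0) +
    pick(ifelse(age_group == "45-54", "__ref__",
                paste0("age_group:", age_group))) +
    ifelse(poverty == "below", cf[["poverty:below"]], 0) +
    pick(ifelse(race == "white", "__ref__", paste0("race:", race))) +
    pick(ifelse(race == "white" | !male, "__ref__",
                paste0("race_male:", race))) +
    ifelse(income_not_reported, cf[["income_not_reported"]], 0) +
    cf[["state_tax"]] * state_tax +
    cf[["prev_state_prevalence"]] * prev_state_prevalence +
    cf[["indoor_restrictions"]] * indoor_restrictions +
    cf[["cbsa_poverty_above_median"]] * cbsa_poverty_above_median +
    cf[["cbsa_nonmetropolitan"]] * cbsa_nonmetropolitan +
    state_residual + cbsa_residual +
    ifelse(black, state_black_slope, 0)
}

#' Ever-smoking linear predictor for a bin
#'
#' Sums the fixed effects of the multilevel ever-smoking model -- sex, age,
#' poverty, race and race-by-male interaction, state cigarette tax, previous
#' state smoking prevalence, indoor-smoking legislation and CBSA flags --
#' plus the context's state and CBSA residuals, and the state-specific
#' Black-race slope residual when the bin is Black. The household random
#' effect is never included: predictions are conditional on an average
#' household. The `income_not_reported` coefficient applies only when a bin
#' is explicitly so flagged (never, for Census-derived bins).
#'
#' @param bin List or one-row data.frame with `sex`, `age_group`, `poverty`,
#'   `race`, optionally `income_not_reported` (logical, default FALSE).
#' @param context List or one-row data.frame with `state_tax`,
#'   `prev_state_prevalence`, `indoor_restrictions`,
#'   `cbsa_poverty_above_median`, `cbsa_nonmetropolitan` and residual fields
#'   `smoking_state_residual`, `smoking_cbsa_residual`,
#'   `smoking_state_black_slope` (each defaulting to 0 when absent).
#' @param params A [smoking_params()] object.
#' @return Logit-scale linear predictor.
#' @examples
#' sp <- load_coefficients("smoking")
#' ref <- list(sex = "female", age_group = "45-54", poverty = "above",
#'             race = "white")
#' ctx <- list(state_tax = 0, prev_state_prevalence = 0,
#'             indoor_restrictions = 0, cbsa_poverty_above_median = 0,
#'             cbsa_nonmetropolitan = 0)
#' smoking_linear_predictor(ref, ctx, sp)  # -0.43, the printed intercept
#' @export
smoking_linear_predictor <- function(bin, context, params) {
  g0 <- function(x) if (is.null(x)) 0 else x
  .smoking_lp(bin$sex, bin$age_group, bin$poverty, bin$race, params,
              state_tax = g0(context$state_tax),
              prev_state_prevalence = g0(context$prev_state_prevalence),
              indoor_restrictions = g0(context$indoor_restrictions),
              cbsa_poverty_above_median = g0(context$cbsa_poverty_above_median),
              cbsa_nonmetropolitan = g0(context$cbsa_nonmetropolitan),
              state_residual = g0(context$smoking_state_residual),
              cbsa_residual = g0(context$smoking_cbsa_residual),
              state_black_slope = g0(context$smoking_state_black_slope),
              income_not_reported = isTRUE(bin$income_not_reported))
}

#' Predicted ever-smoking probability for a bin
#'
#' Inverse logit of [smoking_linear_predictor()]. Because the household
#' random effect is omitted without a marginalisation correction, this is a
#' conditional (median-household) probability; see
#' [smoking_attenuation_diagnostic()] for the gap to the population-average
#' prevalence.
#'
#' @inheritParams smoking_linear_predictor
#' @return Probability in (0, 1).
#' @export
predict_ever_smoking <- function(bin, context, params) {
  stats::plogis(smoking_linear_predictor(bin, context, params))
}

#' Conditional-vs-marginal smoking prevalence gap
#'
#' The prediction chain uses the inverse logit of the fixed+residual linear
#' predictor, omitting the household random effect. Averaging over household
#' effects would give a population-average (marginal) prevalence pulled
#' toward 0.5. This diagnostic quantifies the attenuation by Monte Carlo:
#' it reports the conditional probability, the marginal probability under
#' `N(0, var_household)` household effects, and their difference.
#'
#' @param lp Logit-scale linear predictor(s) to evaluate at.
#' @param params A [smoking_params()] object (source of `var_household`).
#' @param n_mc Monte Carlo draws.
#' @param seed Seed for the draws.
#' @return Data.frame with columns `lp`, `conditional`, `marginal`, `gap`.
#' @export
smoking_attenuation_diagnostic <- function(lp, params, n_mc = 1e5,
                                           seed = 1L) {
  b <- withr_seed_rnorm(n_mc, sd = sqrt(params$var_household), seed = seed)
  marg <- vapply(lp, function(x) mean(stats::plogis(x + b)), numeric(1))
  cond <- stats::plogis(lp)
  data.frame(lp = lp, conditional = cond, marginal = marg,
             gap = cond - marg)
}

# draw rnorm under a local RNG state, leaving the caller's stream untouched
withr_seed_rnorm <- function(n, sd, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Fit the multilevel ever-smoking model
#'
#' Laplace-approximation maximum-likelihood fit (via [glmmTMB::glmmTMB()])
#' of ever-smoking on the fixed effects of the published model, with a joint
#' random intercept and Black-race slope by state, a CBSA random intercept,
#' and a household random intercept. Context covariates that are constant in
#' the data (e.g. `income_not_reported` for Census-style inputs) are dropped
#' from the fixed part and reported as 0.
#'
#' The Laplace approximation is known to underestimate the variance of
#' random intercepts over very small binary clusters (here: households of
#' two persons); expect the household variance, and with it the
#' state/Black-slope covariance, to be biased toward zero. Fixed effects and
#' the state/CBSA variances are much less affected.
#'
#' @param records Person-level data.frame with columns `person_id`,
#'   `household_id`, `cbsa_id`, `state_id`, `sex`, `age_group`, `poverty`,
#'   `race`, `state_tax`, `prev_state_prevalence`, `indoor_restrictions`,
#'   `cbsa_poverty_above_median`, `cbsa_nonmetropolitan`, optionally
#'   `income_not_reported`, and binary `ever_smoker`. Households must nest in
#'   CBSAs, CBSAs in states.
#' @return A [smoking_params()] object with estimates, standard errors,
#'   random-parameter estimates and the fit log-likelihood; the `glmmTMB`
#'   fit is attached as attribute `"fit"`.
#' @export
fit_smoking_model <- function(records) {
  need <- c("household_id", "cbsa_id", "state_id", "sex", "age_group",
            "poverty", "race", "state_tax", "prev_state_prevalence",
            "indoor_restrictions", "cbsa_poverty_above_median",
            "cbsa_nonmetropolitan", "ever_smoker")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(records$ever_smoker %in% c(0, 1)))
    stop("ever_smoker must be 0/1", call. = FALSE)
  if (length(unique(records$ever_smoker)) < 2L)
    stop("degenerate outcome: ever_smoker is constant", call. = FALSE)
  if (length(unique(records$state_id)) < 2L)
    stop("need at least 2 states", call. = FALSE)
  .check_nesting(records, c("household_id", "cbsa_id", "state_id"))

  d <- records
  d$sex <- stats::relevel(factor(d$sex, levels = sex_levels()),
                          ref = "female")
  d$age_group <- factor(d$age_group, levels = age_groups_adult())
  d$poverty <- factor(d$poverty, levels = poverty_levels())
  d$race <- factor(d$race, levels = race_levels())
  d$black <- as.numeric(d$race == "black")
  if (is.null(d$income_not_reported)) d$income_not_reported <- 0

  cont <- c("income_not_reported", "state_tax", "prev_state_prevalence",
            "indoor_restrictions", "cbsa_poverty_above_median",
            "cbsa_nonmetropolitan")
  keep <- cont[vapply(cont, function(v) stats::var(d[[v]]) > 0, logical(1))]
  fixed <- paste(c("sex", "age_group", "poverty", "race", "race:sex", keep),
                 collapse = " + ")
  form <- stats::as.formula(paste(
    "ever_smoker ~", fixed,
    "+ (1 + black | state_id) + (1 | cbsa_id) + (1 | household_id)"))
  fit <- suppressWarnings(suppressMessages(glmmTMB::glmmTMB(
    form, data = d, family = stats::binomial())))
  # a boundary variance (common when a true variance is near 0) reports
  # "singular convergence" but leaves the estimates usable; only abandon
  # the fit if it produced non-finite coefficients
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0)
    warning("smoking model optimizer reported: ", fit$fit$message,
            call. = FALSE)
  fe <- glmmTMB::fixef(fit)$cond
  if (any(!is.finite(fe)))
    stop("smoking model fit failed: non-finite fixed effects",
         call. = FALSE)
  se <- sqrt(diag(as.matrix(stats::vcov(fit)$cond)))
  pick <- function(nm) if (nm %in% names(fe)) unname(fe[[nm]]) else 0
  nonwhite <- setdiff(race_levels(), "white")
  coefs <- c(
    "sex:male" = pick("sexmale"),
    stats::setNames(vapply(setdiff(age_groups_adult(), "45-54"),
                           function(a) pick(paste0("age_group", a)),
                           numeric(1)),
                    paste0("age_group:",
                           setdiff(age_groups_adult(), "45-54"))),
    "poverty:below" = pick("povertybelow"),
    "income_not_reported" = pick("income_not_reported"),
    stats::setNames(vapply(nonwhite, function(r) pick(paste0("race", r)),
                           numeric(1)), paste0("race:", nonwhite)),
    # interaction term naming differs by fitter; exactly one order is present
    stats::setNames(vapply(nonwhite, function(r) {
      pick(paste0("race", r, ":sexmale")) + pick(paste0("sexmale:race", r))
    }, numeric(1)), paste0("race_male:", nonwhite)),
    "state_tax" = pick("state_tax"),
    "prev_state_prevalence" = pick("prev_state_prevalence"),
    "indoor_restrictions" = pick("indoor_restrictions"),
    "cbsa_poverty_above_median" = pick("cbsa_poverty_above_median"),
    "cbsa_nonmetropolitan" = pick("cbsa_nonmetropolitan"))
  vc <- glmmTMB::VarCorr(fit)$cond
  st <- vc$state_id
  out <- smoking_params(
    intercept = unname(fe[["(Intercept)"]]),
    coefs = coefs,
    var_state = st["(Intercept)", "(Intercept)"],
    var_state_black_slope = st["black", "black"],
    cov_state_blackslope = st["(Intercept)", "black"],
    var_cbsa = as.numeric(vc$cbsa_id),
    var_household = as.numeric(vc$household_id),
    se = stats::setNames(se, names(fe)),
    loglik = as.numeric(stats::logLik(fit)))
  attr(out, "fit") <- fit
  out
}
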