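# n x 4 matrix of log-odds (columns = non-reference outcomes) for vectors of
# demographics; reference levels contribute 0 via the padded "__ref__" row
.housing_eta <- function(poverty, sex, race, region, age_group, params) {
  .check_levels(poverty, poverty_levels(), "poverty")
  .check_levels(sex, sex_levels(), "sex")
  .check_levels(race, race_levels(), "race")
  .check_levels(region, region_levels(), "region")
  .check_levels(age_group, age_groups_all(), "age_group")
  race <- ifelse(race == "islander", params$islander_map, race)

  cm <- rbind(params$coefs, "__ref__" = 0)
  key_or_ref <- function(term, level, ref) {
    k <- ifelse(level == ref, "__ref__", paste(term, level, sep = ":"))
    unknown <- setdiff(unique(k), rownames(cm))
    if (length(unknown) > 0L)
      stop("no housing coefficient for ", paste(unknown, collapse = ", "),
           call. = FALSE)
    k
  }
  n <- max(length(poverty), length(sex), length(race), length(region),
           length(age_group))
  eta <- matrix(rep(params$intercepts[house_type_outcomes()], each = n),
                nrow = n, dimnames = list(NULL, house_type_outcomes()))
  eta <- eta +
    cm[key_or_ref("poverty", rep_len(poverty, n), "above"), , drop = FALSE] +
    cm[key_or_ref("sex", rep_len(sex, n), "female"), , drop = FALSE] +
    cm[key_or_ref("race", rep_len(race, n), "white"), , drop = FALSE] +
    cm[key_or_ref("region", rep_len(region, n), "South"), , drop = FALSE] +
    cm[key_or_ref("age_group", rep_len(age_group, n), "45-54"), ,
       drop = FALSE]
  rownames(eta) <- NULL
  eta
}

#' House-type log-odds for one demographic profile
#'
#' Linear predictors of the multinomial housing model: for each non-reference
#' house type, the intercept plus the log odds ratios of the active covariate
#' levels (poverty below threshold, male sex, non-white race, non-South
#' region, non-45-54 age group). The reference outcome (detached with
#' basement) implicitly carries 0. The Pacific-Islander race level, absent
#' from the housing model, is mapped to the level in `params$islander_map`
#' (default `"other"`).
#'
#' @param bin A list or one-row data.frame with `poverty`, `sex`, `race`,
#'   `age_group`.
#' @param region Census region of the bin's county.
#' @param params A [housing_params()] object.
#' @return Named numeric of log-odds over [house_type_outcomes()].
#' @examples
#' hp <- load_coefficients("housing")
#' ref <- list(poverty = "above", sex = "female", race = "white",
#'             age_group = "45-54")
#' housing_linear_predictors(ref, "South", hp)  # the printed intercepts
#' @export
housing_linear_predictors <- function(bin, region, params) {
  eta <- .housing_eta(bin$poverty, bin$sex, bin$race, region, bin$age_group,
                      params)
  stats::setNames(as.numeric(eta[1L, ]), colnames(eta))
}

#' House-type probabilities for one demographic profile
#'
#' Softmax over the five house types, the reference outcome entering with
#' linear predictor 0. Probabilities are strictly positive and sum to 1.
#'
#' @inheritParams housing_linear_predictors
#' @return Named numeric of probabilities over [house_type_levels()].
#' @export
housing_probabilities <- function(bin, region, params) {
  eta <- housing_linear_predictors(bin, region, params)
  .softmax5(matrix(eta, nrow = 1, dimnames = list(NULL, names(eta))))[1L, ]
}

# softmax over {0, eta}: n x 4 log-odds matrix -> n x 5 probability matrix
.softmax5 <- function(eta) {
  full <- cbind(detached_with_basement = 0, eta)
  m <- apply(full, 1L, max)
  ex <- exp(full - m)
  probs <- ex / rowSums(ex)
  colnames(probs) <- c("detached_with_basement", colnames(eta))
  probs[, house_type_levels(), drop = FALSE]
}

#' Fit the multinomial house-type model
#'
#' Single-level multinomial logistic MLE (via [nnet::multinom()]) of house
#' type on poverty, sex, race, Census region and age group. The outcome is a
#' household characteristic shared by everyone in a home, so no multilevel
#' structure is used.
#'
#' @param records Person-level data.frame with columns `house_type`,
#'   `poverty`, `sex`, `race`, `region`, `age_group` (race vocabulary of the
#'   housing model: no `islander`).
#' @param maxit Maximum optimizer iterations.
#' @return A [housing_params()] object with estimates, standard errors and
#'   the fit log-likelihood; the `multinom` fit is attached as attribute
#'   `"fit"`.
#' @export
fit_housing_model <- function(records, maxit = 400L) {
  need <- c("house_type", "poverty", "sex", "race", "region", "age_group")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  .check_levels(records$house_type, house_type_levels(), "house_type")
  absent <- setdiff(house_type_levels(), unique(records$house_type))
  if (length(absent) > 0L)
    stop("degenerate outcome: house type(s) absent from the data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  .check_levels(records$race, race_levels_housing(), "race")

  d <- records
  d$house_type <- factor(d$house_type, levels = house_type_levels())
  d$poverty <- factor(d$poverty, levels = poverty_levels())
  d$sex <- factor(d$sex, levels = sex_levels())
  d$race <- factor(d$race, levels = race_levels_housing())
  d$region <- stats::relevel(factor(d$region, levels = region_levels()),
                             ref = "South")
  age_lv <- intersect(age_groups_all(), unique(d$age_group))
  d$age_group <- factor(d$age_group,
                        levels = c("45-54", setdiff(age_lv, "45-54")))
  # covariates constant in the data are dropped (their effects report as 0)
  covars <- c("poverty", "sex", "race", "region", "age_group")
  covars <- covars[vapply(covars,
                          function(v) length(unique(d[[v]])) > 1L,
                          logical(1))]
  form <- stats::as.formula(paste(
    "house_type ~", if (length(covars) > 0L)
      paste(covars, collapse = " + ") else "1"))
  fit <- nnet::multinom(form, data = d, maxit = maxit, trace = FALSE,
                        Hess = TRUE, reltol = 1e-12)
  if (fit$convergence != 0)
    stop("multinomial fit did not converge (possible separation); ",
         "final value ", format(fit$value), call. = FALSE)

  B <- stats::coef(fit)            # outcomes x model terms
  SE <- summary(fit)$standard.errors
  term_key <- function(cn) {
    for (tm in c("poverty", "sex", "race", "region", "age_group")) {
      if (startsWith(cn, tm))
        return(paste(tm, sub(paste0("^", tm), "", cn), sep = ":"))
    }
    cn
  }
  keys <- vapply(setdiff(colnames(B), "(Intercept)"), term_key, character(1))
  outs <- house_type_outcomes()
  coefs <- matrix(0, nrow = length(keys), ncol = length(outs),
                  dimnames = list(unname(keys), outs))
  se_coefs <- coefs
  for (o in outs) {
    coefs[, o] <- B[o, setdiff(colnames(B), "(Intercept)")]
    se_coefs[, o] <- SE[o, setdiff(colnames(B), "(Intercept)")]
  }
  out <- housing_params(
    intercepts = stats::setNames(B[outs, "(Intercept)"], outs),
    coefs = coefs,
    se = list(intercepts = stats::setNames(SE[outs, "(Intercept)"], outs),
              coefs = se_coefs),
    loglik = -fit$value)
  attr(out, "fit") <- fit
  out
}
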