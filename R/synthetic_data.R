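# joint draw of (intercept, slope) random effects from a 2x2 covariance
.rmvn2 <- function(n, v1, v2, cv) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  a <- sqrt(v1)
  b <- if (a > 0) cv / a else 0
  c2 <- v2 - b^2
  if (c2 < 0) c2 <- 0   # numerical guard at the Cauchy-Schwarz boundary
  cbind(a * z1, b * z1 + sqrt(c2) * z2)
}

# documented default covariate mixes for synthetic persons; they only need
# to span the design space, not match real US margins
.race_mix <- function() c(white = 0.70, black = 0.12, asian = 0.05,
                          native = 0.01, islander = 0.005, other = 0.115)
.race_mix_housing <- function() c(white = 0.72, black = 0.12, asian = 0.05,
                                  native = 0.01, other = 0.10)
.adult_age_mix <- function() c("45-54" = 0.18, "18-24" = 0.13,
                               "25-34" = 0.18, "35-44" = 0.20,
                               "55-64" = 0.13, "65-74" = 0.10, "75+" = 0.08)
.all_age_mix <- function() c("45-54" = 0.14, "18-24" = 0.12, "25-34" = 0.13,
                             "35-44" = 0.14, "55-64" = 0.12, "65-74" = 0.08,
                             "75+" = 0.07, "<18" = 0.20)
.region_mix <- function() c(Northeast = 0.18, Midwest = 0.22, South = 0.37,
                            West = 0.23)
.geo_mix <- function() c(Low = 0.4, Medium = 0.4, High = 0.2)
.housetype_mix <- function() c(detached_with_basement = 0.45,
                               attached = 0.25, crawl_space = 0.12,
                               slab = 0.12, other_detached = 0.06)

.sample_mix <- function(n, mix) sample(names(mix), n, replace = TRUE,
                                       prob = mix)

# row-wise categorical draw from an n x k probability matrix
.sample_rows <- function(probs) {
  cum <- t(apply(probs, 1L, cumsum))
  u <- stats::runif(nrow(probs))
  colnames(probs)[rowSums(cum < u) + 1L]
}

#' Generate a synthetic geography of states, counties and CBSAs
#'
#' Builds a county-context table with the nesting the risk chain assumes:
#' counties in states (regions cycling over the four Census regions), CBSAs
#' in states, geological potential classes and meteorology drawn from
#' documented ranges, and all residuals drawn from the normal distributions
#' implied by the parameter bundles' variance components. State tobacco
#' covariates (tax, previous prevalence) are drawn as deviations from
#' national norms, centered at 0, so the published intercept keeps its
#' reference-bin meaning.
#'
#' @param n_states,n_counties,n_cbsas Frame sizes; `n_counties >= n_states`
#'   and `n_cbsas >= n_states` required.
#' @param seed Integer seed; output is byte-identical across reruns.
#' @param radon_params,smoking_params Parameter bundles supplying the
#'   residual variances (defaults: the packaged published values).
#' @param hdd_range,swing_range Uniform ranges for heating-infiltration
#'   degree-days per year and average diurnal swing in degrees.
#' @return Context data.frame (one row per county) consumable by
#'   [predict_bin_risks()] with zero modification.
#' @export
generate_geography <- function(n_states = 44L, n_counties = 125L,
                               n_cbsas = 60L, seed = 1L,
                               radon_params = load_coefficients("radon"),
                               smoking_params = load_coefficients("smoking"),
                               hdd_range = c(0, 9000),
                               swing_range = c(10, 35)) {
  if (n_counties < n_states)
    stop("n_counties must be >= n_states", call. = FALSE)
  if (n_cbsas < n_states)
    stop("n_cbsas must be >= n_states", call. = FALSE)
  set.seed(seed)
  states <- sprintf("S%02d", seq_len(n_states))
  state_region <- rep_len(region_levels(), n_states)
  vc <- radon_params$variance_components
  radon_state <- stats::rnorm(n_states, sd = sqrt(vc[["state"]]))
  sm <- .rmvn2(n_states, smoking_params$var_state,
               smoking_params$var_state_black_slope,
               smoking_params$cov_state_blackslope)
  state_tax <- stats::runif(n_states, -0.5, 0.5)
  state_prev <- stats::runif(n_states, -5, 5)
  state_restrict <- stats::rbinom(n_states, 1L, 0.5)

  cbsa_state_idx <- rep_len(seq_len(n_states), n_cbsas)
  cbsas <- sprintf("B%03d", seq_len(n_cbsas))
  cbsa_resid <- stats::rnorm(n_cbsas, sd = sqrt(smoking_params$var_cbsa))
  cbsa_pov <- stats::rbinom(n_cbsas, 1L, 0.5)
  cbsa_nonmetro <- stats::rbinom(n_cbsas, 1L, 0.5)

  county_state_idx <- rep_len(seq_len(n_states), n_counties)
  county_cbsa_idx <- vapply(county_state_idx, function(s) {
    cands <- which(cbsa_state_idx == s)
    if (length(cands) == 1L) cands else sample(cands, 1L)
  }, integer(1))

  data.frame(
    county_id = sprintf("C%03d", seq_len(n_counties)),
    state_id = states[county_state_idx],
    cbsa_id = cbsas[county_cbsa_idx],
    region = state_region[county_state_idx],
    geo_potential = .sample_mix(n_counties, .geo_mix()),
    hdd = stats::runif(n_counties, hdd_range[1L], hdd_range[2L]),
    diurnal_swing = stats::runif(n_counties, swing_range[1L],
                                 swing_range[2L]),
    radon_state_residual = radon_state[county_state_idx],
    radon_county_residual = stats::rnorm(n_counties,
                                         sd = sqrt(vc[["psu"]])),
    smoking_state_residual = sm[county_state_idx, 1L],
    smoking_state_black_slope = sm[county_state_idx, 2L],
    smoking_cbsa_residual = cbsa_resid[county_cbsa_idx],
    state_tax = state_tax[county_state_idx],
    prev_state_prevalence = state_prev[county_state_idx],
    indoor_restrictions = state_restrict[county_state_idx],
    cbsa_poverty_above_median = cbsa_pov[county_cbsa_idx],
    cbsa_nonmetropolitan = cbsa_nonmetro[county_cbsa_idx],
    stringsAsFactors = FALSE)
}

#' Generate Census-like demographic bin counts
#'
#' For every county, emits all 7 x 2 x 6 x 2 adult cells (age x sex x race x
#' poverty) with counts drawn `Poisson(mean_pop * w)`, where the cell weight
#' `w` is the product of documented marginal mixes. Every cell is present,
#' possibly with count 0; expected county population is `mean_pop`.
#'
#' @param contexts Context table from [generate_geography()].
#' @param mean_pop Expected adult population per county.
#' @param seed Integer seed.
#' @return Bin data.frame consumable by [predict_bin_risks()].
#' @export
generate_census_bins <- function(contexts, mean_pop = 2000, seed = 1L) {
  if (mean_pop <= 0) stop("mean_pop must be > 0", call. = FALSE)
  set.seed(seed)
  cells <- expand.grid(age_group = age_groups_adult(), sex = sex_levels(),
                       race = race_levels(), poverty = poverty_levels(),
                       stringsAsFactors = FALSE)
  age_w <- .adult_age_mix() / sum(.adult_age_mix())
  race_w <- .race_mix()
  pov_w <- c(above = 0.87, below = 0.13)
  w <- age_w[cells$age_group] * 0.5 * race_w[cells$race] *
    pov_w[cells$poverty]
  n_c <- nrow(contexts)
  out <- cells[rep(seq_len(nrow(cells)), times = n_c), ]
  out$county_id <- rep(contexts$county_id, each = nrow(cells))
  out$state_id <- rep(contexts$state_id, each = nrow(cells))
  out$count <- stats::rpois(nrow(out), rep(w, times = n_c) * mean_pop)
  rownames(out) <- NULL
  out[c("county_id", "state_id", "age_group", "sex", "race", "poverty",
        "count")]
}

#' Simulate nested radon measurement records
#'
#' Draws a four-level survey-like sample -- houses in census tracts (SSUs)
#' in counties (PSUs) in states -- with log concentrations generated exactly
#' from the radon model: fixed effects plus normal random intercepts at
#' state, PSU and SSU level plus lognormal residual noise.
#'
#' @param params A [radon_params()] object (fixed effects and variance
#'   components of the generating model).
#' @param n_houses,n_ssus,n_psus,n_states Frame sizes; must be weakly
#'   decreasing.
#' @param seed Integer seed.
#' @param hdd_range,swing_range Uniform ranges for the PSU-level meteorology.
#' @return Measurement-record data.frame consumable by [fit_radon_model()].
#' @export
generate_nrrs_like <- function(params, n_houses = 5336L, n_ssus = 977L,
                               n_psus = 125L, n_states = 44L, seed = 1L,
                               hdd_range = c(0, 9000),
                               swing_range = c(10, 35)) {
  if (!(n_houses >= n_ssus && n_ssus >= n_psus && n_psus >= n_states))
    stop("frame sizes must nest: n_houses >= n_ssus >= n_psus >= n_states",
         call. = FALSE)
  set.seed(seed)
  vc <- params$variance_components
  state_region <- rep_len(region_levels(), n_states)
  state_eff <- stats::rnorm(n_states, sd = sqrt(vc[["state"]]))
  psu_state <- rep_len(seq_len(n_states), n_psus)
  psu_eff <- stats::rnorm(n_psus, sd = sqrt(vc[["psu"]]))
  psu_geo <- .sample_mix(n_psus, .geo_mix())
  psu_hdd <- stats::runif(n_psus, hdd_range[1L], hdd_range[2L])
  psu_swing <- stats::runif(n_psus, swing_range[1L], swing_range[2L])
  ssu_psu <- rep_len(seq_len(n_psus), n_ssus)
  ssu_eff <- stats::rnorm(n_ssus, sd = sqrt(vc[["ssu"]]))
  house_ssu <- rep_len(seq_len(n_ssus), n_houses)

  psu_of_house <- ssu_psu[house_ssu]
  state_of_house <- psu_state[psu_of_house]
  house_type <- .sample_mix(n_houses, .housetype_mix())
  lp <- .radon_lp(state_region[state_of_house], psu_geo[psu_of_house],
                  psu_hdd[psu_of_house], psu_swing[psu_of_house],
                  house_type, params)
  log_c <- lp + state_eff[state_of_house] + psu_eff[psu_of_house] +
    ssu_eff[house_ssu] +
    stats::rnorm(n_houses, sd = sqrt(vc[["residual"]]))
  data.frame(
    house_id = sprintf("H%05d", seq_len(n_houses)),
    ssu_id = sprintf("T%04d", house_ssu),
    psu_id = sprintf("P%03d", psu_of_house),
    state_id = sprintf("S%02d", state_of_house),
    house_type = house_type,
    region = state_region[state_of_house],
    geo_potential = psu_geo[psu_of_house],
    hdd = psu_hdd[psu_of_house],
    diurnal_swing = psu_swing[psu_of_house],
    concentration = exp(log_c),
    stringsAsFactors = FALSE)
}

#' Simulate person-level house-type records
#'
#' Draws demographics from documented mixes and samples house type from the
#' softmax of the multinomial model's linear predictors -- the exact
#' generating process [fit_housing_model()] assumes.
#'
#' @param params A [housing_params()] object.
#' @param n Number of persons.
#' @param seed Integer seed.
#' @return Person-level data.frame consumable by [fit_housing_model()].
#' @export
generate_ahs_like <- function(params, n = 50000L, seed = 1L) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  set.seed(seed)
  d <- data.frame(
    person_id = sprintf("A%06d", seq_len(n)),
    poverty = .sample_mix(n, c(above = 0.87, below = 0.13)),
    sex = .sample_mix(n, c(female = 0.51, male = 0.49)),
    race = .sample_mix(n, .race_mix_housing()),
    region = .sample_mix(n, .region_mix()),
    age_group = .sample_mix(n, .all_age_mix()),
    stringsAsFactors = FALSE)
  eta <- .housing_eta(d$poverty, d$sex, d$race, d$region, d$age_group,
                      params)
  d$house_type <- .sample_rows(.softmax5(eta))
  d
}

#' Simulate person-level ever-smoking records
#'
#' Draws a nested frame of households in CBSAs in states, with state
#' tobacco covariates as centered deviations, then generates Bernoulli
#' ever-smoking outcomes exactly from the multilevel model: fixed effects
#' plus a joint state intercept/Black-slope draw (with the published
#' covariance), a CBSA intercept, and a household intercept.
#'
#' @param params A [smoking_params()] object.
#' @param n_states,n_cbsas,n_households Frame sizes; `n_cbsas >= n_states`,
#'   `n_households >= n_cbsas`.
#' @param household_size Persons per household.
#' @param seed Integer seed.
#' @return Person-level data.frame consumable by [fit_smoking_model()].
#' @export
generate_cps_like <- function(params, n_states = 40L, n_cbsas = 400L,
                              n_households = 30000L, household_size = 2L,
                              seed = 1L) {
  if (n_cbsas < n_states)
    stop("n_cbsas must be >= n_states", call. = FALSE)
  if (n_households < n_cbsas)
    stop("n_households must be >= n_cbsas", call. = FALSE)
  set.seed(seed)
  sm <- .rmvn2(n_states, params$var_state, params$var_state_black_slope,
               params$cov_state_blackslope)
  state_tax <- stats::runif(n_states, -0.5, 0.5)
  state_prev <- stats::runif(n_states, -5, 5)
  state_restrict <- stats::rbinom(n_states, 1L, 0.5)
  cbsa_state <- rep_len(seq_len(n_states), n_cbsas)
  cbsa_eff <- stats::rnorm(n_cbsas, sd = sqrt(params$var_cbsa))
  cbsa_pov <- stats::rbinom(n_cbsas, 1L, 0.5)
  cbsa_nonmetro <- stats::rbinom(n_cbsas, 1L, 0.5)
  hh_cbsa <- rep_len(seq_len(n_cbsas), n_households)
  hh_eff <- stats::rnorm(n_households, sd = sqrt(params$var_household))

  n <- n_households * household_size
  hh <- rep(seq_len(n_households), each = household_size)
  cb <- hh_cbsa[hh]
  st <- cbsa_state[cb]
  d <- data.frame(
    person_id = sprintf("Q%07d", seq_len(n)),
    household_id = sprintf("HH%06d", hh),
    cbsa_id = sprintf("B%04d", cb),
    state_id = sprintf("S%02d", st),
    sex = .sample_mix(n, c(female = 0.51, male = 0.49)),
    age_group = .sample_mix(n, .adult_age_mix()),
    poverty = .sample_mix(n, c(above = 0.87, below = 0.13)),
    race = .sample_mix(n, .race_mix()),
    income_not_reported = 0,
    state_tax = state_tax[st],
    prev_state_prevalence = state_prev[st],
    indoor_restrictions = state_restrict[st],
    cbsa_poverty_above_median = cbsa_pov[cb],
    cbsa_nonmetropolitan = cbsa_nonmetro[cb],
    stringsAsFactors = FALSE)
  lp <- .smoking_lp(d$sex, d$age_group, d$poverty, d$race, params,
                    state_tax = d$state_tax,
                    prev_state_prevalence = d$prev_state_prevalence,
                    indoor_restrictions = d$indoor_restrictions,
                    cbsa_poverty_above_median = d$cbsa_poverty_above_median,
                    cbsa_nonmetropolitan = d$cbsa_nonmetropolitan,
                    state_residual = sm[st, 1L],
                    cbsa_residual = cbsa_eff[cb],
                    state_black_slope = sm[st, 2L]) +
    hh_eff[hh]
  d$ever_smoker <- stats::rbinom(n, 1L, stats::plogis(lp))
  d
}
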