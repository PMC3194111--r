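test_that("all generators are seed-deterministic", {
  g1 <- generate_geography(n_states = 6, n_counties = 15, n_cbsas = 8,
                           seed = 42)
  g2 <- generate_geography(n_states = 6, n_counties = 15, n_cbsas = 8,
                           seed = 42)
  expect_identical(g1, g2)
  b1 <- generate_census_bins(g1, mean_pop = 300, seed = 43)
  expect_identical(b1, generate_census_bins(g2, mean_pop = 300, seed = 43))
  r1 <- generate_nrrs_like(pkg_radon, 200, 50, 20, 8, seed = 44)
  expect_identical(r1, generate_nrrs_like(pkg_radon, 200, 50, 20, 8,
                                          seed = 44))
  a1 <- generate_ahs_like(pkg_housing, n = 500, seed = 45)
  expect_identical(a1, generate_ahs_like(pkg_housing, n = 500, seed = 45))
  c1 <- generate_cps_like(pkg_smoking, 5, 10, 200, seed = 46)
  expect_identical(c1, generate_cps_like(pkg_smoking, 5, 10, 200,
                                         seed = 46))
  # and a different seed gives different draws
  expect_false(identical(g1$hdd,
                         generate_geography(n_states = 6, n_counties = 15,
                                            n_cbsas = 8, seed = 43)$hdd))
})

test_that("geography respects frame-size validation and zero variances", {
  expect_error(generate_geography(n_states = 10, n_counties = 5, seed = 1),
               "n_counties")
  rp0 <- pkg_radon; rp0$variance_components[] <- 0
  sp0 <- pkg_smoking
  sp0$var_state <- 0; sp0$var_state_black_slope <- 0
  sp0$cov_state_blackslope <- 0; sp0$var_cbsa <- 0
  g <- generate_geography(n_states = 5, n_counties = 12, n_cbsas = 6,
                          seed = 2, radon_params = rp0, smoking_params = sp0)
  expect_true(all(g$radon_state_residual == 0))
  expect_true(all(g$radon_county_residual == 0))
  expect_true(all(g$smoking_state_residual == 0))
  expect_true(all(g$smoking_state_black_slope == 0))
  expect_true(all(g$smoking_cbsa_residual == 0))
  expect_silent(validate_contexts(g))
})

test_that("census bins emit all 168 adult cells per county", {
  g <- generate_geography(n_states = 4, n_counties = 10, n_cbsas = 5,
                          seed = 3)
  bins <- generate_census_bins(g, mean_pop = 800, seed = 4)
  expect_equal(nrow(bins), 10 * 7 * 2 * 6 * 2)
  counts <- table(bins$county_id)
  expect_true(all(counts == 168))
  expect_silent(validate_bins(bins))
  # Poisson total: within 3 sd of n_counties * mean_pop
  expected <- 10 * 800
  expect_lt(abs(sum(bins$count) - expected), 3 * sqrt(expected))
})

test_that("degenerate radon simulation equals the fixed-effect prediction", {
  rp0 <- pkg_radon; rp0$variance_components[] <- 0
  rec <- generate_nrrs_like(rp0, 300, 60, 20, 8, seed = 5)
  lp <- vapply(seq_len(nrow(rec)), function(i) {
    radon_linear_predictor(
      list(region = rec$region[i], geo_potential = rec$geo_potential[i],
           hdd = rec$hdd[i], diurnal_swing = rec$diurnal_swing[i]),
      rec$house_type[i], rp0)
  }, numeric(1))
  expect_equal(rec$concentration, exp(lp), tolerance = 1e-12)
  expect_error(generate_nrrs_like(pkg_radon, 100, 200, 20, 8, seed = 5),
               "nest")
})

test_that("housing draws converge to the softmax of printed intercepts", {
  d <- generate_ahs_like(pkg_housing, n = 100000L, seed = 6L)
  ref <- d$poverty == "above" & d$sex == "female" & d$race == "white" &
    d$region == "South" & d$age_group == "45-54"
  expect_gt(sum(ref), 500)
  share <- mean(d$house_type[ref] == "detached_with_basement")
  p_ref <- 1 / (1 + exp(1.14) + exp(-0.51) + exp(-0.30) + exp(-2.80))
  expect_lt(abs(share - p_ref), 3 * sqrt(p_ref * (1 - p_ref) / sum(ref)))
})

test_that("smoking prevalence matches the model under zero random effects", {
  sp0 <- pkg_smoking
  sp0$var_state <- 0; sp0$var_state_black_slope <- 0
  sp0$cov_state_blackslope <- 0; sp0$var_cbsa <- 0; sp0$var_household <- 0
  d <- generate_cps_like(sp0, n_states = 8, n_cbsas = 30,
                         n_households = 20000, seed = 7)
  # overall prevalence equals the average model probability within MC error
  p_overall <- mean(d$ever_smoker)
  p_model <- vapply(seq_len(500), function(i) {
    predict_ever_smoking(
      list(sex = d$sex[i], age_group = d$age_group[i],
           poverty = d$poverty[i], race = d$race[i]),
      d[i, c("state_tax", "prev_state_prevalence", "indoor_restrictions",
             "cbsa_poverty_above_median", "cbsa_nonmetropolitan")], sp0)
  }, numeric(1))
  # first 500 persons are an unbiased subsample of the covariate mix
  se <- sqrt(stats::var(p_model) / 500 +
               p_overall * (1 - p_overall) / nrow(d))
  expect_lt(abs(p_overall - mean(p_model)), 4 * se)
  # and at the reference covariate profile the rate is plogis(-0.43)
  ref <- d$sex == "female" & d$age_group == "45-54" & d$race == "white" &
    d$poverty == "above"
  lp_ref <- vapply(which(ref)[1:200], function(i) {
    smoking_linear_predictor(
      list(sex = "female", age_group = "45-54", poverty = "above",
           race = "white"),
      d[i, c("state_tax", "prev_state_prevalence", "indoor_restrictions",
             "cbsa_poverty_above_median", "cbsa_nonmetropolitan")], sp0)
  }, numeric(1))
  expect_true(all(is.finite(lp_ref)))
  expect_error(generate_cps_like(pkg_smoking, n_states = 10, n_cbsas = 5,
                                 n_households = 100, seed = 1), "n_cbsas")
})

test_that("generated tables feed every fitter and predictor unmodified", {
  g <- generate_geography(n_states = 5, n_counties = 12, n_cbsas = 6,
                          seed = 8)
  bins <- generate_census_bins(g, mean_pop = 200, seed = 9)
  res <- predict_bin_risks(bins, g, pkg_radon, pkg_housing, pkg_smoking)
  expect_equal(nrow(res), nrow(bins))
  expect_true(all(res$lifetime_risk >= 0 & res$lifetime_risk < 1))
  expect_true(all(abs(rowSums(as.matrix(
    res[paste0("p_", house_type_levels())])) - 1) < 1e-9))
})
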