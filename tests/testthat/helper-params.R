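# shared fixtures: the packaged parameter bundles and a few reference
# profiles used across test files
pkg_radon <- load_coefficients("radon")
pkg_housing <- load_coefficients("housing")
pkg_smoking <- load_coefficients("smoking")
pkg_constants <- load_risk_constants()

ref_bin <- list(age_group = "45-54", sex = "female", race = "white",
                poverty = "above", count = 100L)

ref_context <- list(county_id = "C1", state_id = "S1", region = "Midwest",
                    geo_potential = "Low", hdd = 0, diurnal_swing = 0,
                    state_tax = 0, prev_state_prevalence = 0,
                    indoor_restrictions = 0, cbsa_poverty_above_median = 0,
                    cbsa_nonmetropolitan = 0, radon_state_residual = 0,
                    radon_county_residual = 0, smoking_state_residual = 0,
                    smoking_state_black_slope = 0, smoking_cbsa_residual = 0)

# a small but structurally complete synthetic universe, reused read-only
small_contexts <- generate_geography(n_states = 8L, n_counties = 20L,
                                     n_cbsas = 12L, seed = 2024L)
small_bins <- generate_census_bins(small_contexts, mean_pop = 500,
                                   seed = 2024L)

# draw a table of random valid bins + contexts for property-style loops
random_bins <- function(n, seed) {
  set.seed(seed)
  county <- sample(small_contexts$county_id, n, replace = TRUE)
  data.frame(
    county_id = county,
    state_id = small_contexts$state_id[match(county,
                                             small_contexts$county_id)],
    age_group = sample(age_groups_adult(), n, replace = TRUE),
    sex = sample(sex_levels(), n, replace = TRUE),
    race = sample(race_levels(), n, replace = TRUE),
    poverty = sample(poverty_levels(), n, replace = TRUE),
    count = sample.int(1000L, n, replace = TRUE),
    stringsAsFactors = FALSE)
}
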