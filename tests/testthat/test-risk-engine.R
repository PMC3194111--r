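test_that("exposure rate is the product of its conversion factors", {
  expect_equal(exposure_rate(), 0.004 * 51.6 * 0.70, tolerance = 1e-15)
  expect_equal(round(exposure_rate(), 3), 0.144)
  full_time <- exposure_constants(occupancy_fraction = 1.0)
  expect_equal(exposure_rate(full_time), 0.2064, tolerance = 1e-12)
  expect_error(exposure_constants(wl_per_pci = 0), "positive")
})

test_that("lifetime risk multiplies concentration, rate, duration and UR", {
  const <- pkg_constants$exposure
  ur <- pkg_constants$unit_risks
  rate <- exposure_rate(const)
  expect_equal(lifetime_risk_for_status(1.0, "male", "ever", const, ur),
               1.0 * rate * 75 * 0.00106, tolerance = 1e-12)
  # the conventionally quoted value with the rounded 0.144 rate
  expect_equal(lifetime_risk_for_status(1.0, "male", "ever", const, ur),
               0.011448, tolerance = 5e-3)
  expect_equal(lifetime_risk_for_status(0, "female", "never", const, ur), 0)
  expect_error(lifetime_risk_for_status(-1, "male", "ever", const, ur),
               ">= 0")
  # ever/never ratio within sex equals the unit-risk ratio
  expect_equal(lifetime_risk_for_status(2.3, "male", "ever", const, ur) /
                 lifetime_risk_for_status(2.3, "male", "never", const, ur),
               0.00106 / 0.000174, tolerance = 1e-12)
})

test_that("the EPA general-population benchmark is reproduced", {
  risk <- lifetime_risk_general(1.25, pkg_constants$exposure,
                                pkg_constants$unit_risks)
  expect_equal(round(100 * risk, 2), 0.73)
})

test_that("risk is linear in concentration and duration and clips at 1", {
  const <- pkg_constants$exposure
  ur <- pkg_constants$unit_risks
  r1 <- lifetime_risk_for_status(1.7, "female", "ever", const, ur)
  expect_equal(lifetime_risk_for_status(3.4, "female", "ever", const, ur),
               2 * r1, tolerance = 1e-12)
  const35 <- exposure_constants(exposure_duration_years = 37.5)
  expect_equal(lifetime_risk_for_status(1.7, "female", "ever", const35, ur),
               r1 / 2, tolerance = 1e-12)
  expect_warning(huge <- lifetime_risk_general(1e9, const, ur), "clipped")
  expect_lt(huge, 1)
})

test_that("bin risk factorises the sex-specific ever/never blend", {
  ctx <- ref_context
  res <- bin_risk(ref_bin, ctx, pkg_radon, pkg_housing, pkg_smoking,
                  pkg_constants$exposure, pkg_constants$unit_risks)
  expect_s3_class(res, "bin_risk_result")
  expect_equal(sum(res$housetype_probs), 1, tolerance = 1e-9)
  expect_equal(res$expected_concentration,
               sum(res$housetype_probs *
                     res$concentration_by_type[names(res$housetype_probs)]),
               tolerance = 1e-12)
  rate <- exposure_rate(pkg_constants$exposure)
  ur <- pkg_constants$unit_risks
  p <- res$p_ever_smoking
  expect_equal(res$lifetime_risk,
               res$expected_concentration * rate * 75 *
                 (p * ur$female_ever + (1 - p) * ur$female_never),
               tolerance = 1e-15)
})

test_that("factorised bin risk equals exhaustive enumeration", {
  bins <- random_bins(200L, seed = 55L)
  res <- predict_bin_risks(bins, small_contexts, pkg_radon, pkg_housing,
                           pkg_smoking, pkg_constants$exposure,
                           pkg_constants$unit_risks)
  rate <- exposure_rate(pkg_constants$exposure)
  D <- pkg_constants$exposure$exposure_duration_years
  ur <- unlist(pkg_constants$unit_risks)
  for (i in seq_len(nrow(res))) {
    p <- res$p_ever_smoking[i]
    enum <- 0
    for (ht in house_type_levels()) {
      for (status in c("ever", "never")) {
        p_joint <- res[[paste0("p_", ht)]][i] *
          (if (status == "ever") p else 1 - p)
        enum <- enum + p_joint * res[[paste0("conc_", ht)]][i] * rate * D *
          ur[[paste(res$sex[i], status, sep = "_")]]
      }
    }
    expect_lt(abs(enum - res$lifetime_risk[i]), 1e-12)
  }
})

test_that("aggregation is a population-weighted mean with exclusions", {
  res <- data.frame(county_id = c("C1", "C1"), state_id = c("S1", "S1"),
                    age_group = "45-54", sex = "female", race = "white",
                    poverty = "above", count = c(100, 300),
                    p_ever_smoking = c(0.3, 0.5),
                    expected_concentration = c(1, 2),
                    lifetime_risk = c(0.004, 0.008))
  agg <- aggregate_risk(res, "county")
  expect_equal(agg$mean_risk, 0.007)
  expect_equal(agg$mean_concentration, 1.75)
  expect_equal(agg$mean_ever_smoking, 0.45)
  # single bin: group average equals the bin's values
  one <- aggregate_risk(res[1, ], "national")
  expect_equal(one$mean_risk, 0.004)
  # zero-count group is excluded with a warning
  z <- res; z$count <- c(0, 0)
  z$county_id <- "C9"
  expect_warning(agg2 <- aggregate_risk(rbind(res, z), "county"),
                 "zero population")
  expect_equal(nrow(agg2), 1L)
})

test_that("aggregates are split-invariant and bounded by member extremes", {
  bins <- random_bins(300L, seed = 66L)
  res <- predict_bin_risks(bins, small_contexts, pkg_radon, pkg_housing,
                           pkg_smoking)
  for (level in c("county", "state", "national")) {
    agg <- aggregate_risk(res, level)
    expect_true(all(agg$mean_risk >= min(res$lifetime_risk) - 1e-15))
    expect_true(all(agg$mean_risk <= max(res$lifetime_risk) + 1e-15))
  }
  # splitting every bin into two identical halves changes nothing
  half <- res; half$count <- res$count / 2
  doubled <- rbind(half, half)
  for (level in c("county", "state", "national")) {
    a <- aggregate_risk(res, level)
    b <- aggregate_risk(doubled, level)
    expect_equal(a$mean_risk, b$mean_risk, tolerance = 1e-12)
    expect_equal(a$population, b$population)
  }
  # the national average lies within the county-average range
  co <- aggregate_risk(res, "county")
  nat <- aggregate_risk(res, "national")
  expect_gte(nat$mean_risk, min(co$mean_risk))
  expect_lte(nat$mean_risk, max(co$mean_risk))
  smry <- county_summary(co)
  expect_equal(smry$mean[smry$variable == "mean_risk"], mean(co$mean_risk))
})
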