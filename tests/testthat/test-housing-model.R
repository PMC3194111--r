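test_that("linear predictors reproduce the published intercepts and sums", {
  eta <- housing_linear_predictors(ref_bin, "South", pkg_housing)
  expect_equal(unname(eta[c("attached", "crawl_space", "slab",
                            "other_detached")]),
               c(1.14, -0.51, -0.30, -2.80))
  pov <- ref_bin; pov$poverty <- "below"
  expect_equal(unname(housing_linear_predictors(pov, "South",
                                                pkg_housing)["attached"]),
               1.14 + log(4.40), tolerance = 1e-12)
  expect_equal(unname(housing_linear_predictors(ref_bin, "Midwest",
                                                pkg_housing)["attached"]),
               1.14 + log(0.21), tolerance = 1e-12)
  bad <- ref_bin; bad$age_group <- "200+"
  expect_error(housing_linear_predictors(bad, "South", pkg_housing),
               "age_group")
})

test_that("probabilities are a softmax of the printed intercepts", {
  p <- housing_probabilities(ref_bin, "South", pkg_housing)
  denom <- 1 + exp(1.14) + exp(-0.51) + exp(-0.30) + exp(-2.80)
  expect_equal(unname(p["detached_with_basement"]), 1 / denom,
               tolerance = 1e-12)
  expect_lt(abs(p[["detached_with_basement"]] - 0.1809), 1e-4)
  expect_lt(abs(p[["attached"]] - 0.5656), 1e-4)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("softmax is uniform at zero log-odds and shift invariant", {
  flat <- pkg_housing
  flat$intercepts[] <- 0
  flat$coefs[] <- 0
  p <- housing_probabilities(ref_bin, "South", flat)
  expect_equal(unname(p), rep(0.2, 5), tolerance = 1e-12)
  # softmax shift invariance is over ALL five outcomes incl. the reference;
  # shifting only the four modelled intercepts must instead change things
  shifted <- pkg_housing
  shifted$intercepts <- shifted$intercepts + 1
  p0 <- housing_probabilities(ref_bin, "South", pkg_housing)
  p1 <- housing_probabilities(ref_bin, "South", shifted)
  expect_false(isTRUE(all.equal(p0, p1)))
  # direct check on the softmax: adding c to every eta (reference included)
  eta <- housing_linear_predictors(ref_bin, "South", pkg_housing)
  soft <- function(full) exp(full) / sum(exp(full))
  expect_equal(soft(c(0, eta) + 3.7), soft(c(0, eta)), tolerance = 1e-12)
})

test_that("probabilities are valid and poverty favours non-basement types", {
  set.seed(99)
  for (i in 1:50) {
    bin <- list(age_group = sample(age_groups_all(), 1),
                sex = sample(sex_levels(), 1),
                race = sample(race_levels(), 1),
                poverty = sample(poverty_levels(), 1))
    p <- housing_probabilities(bin, sample(region_levels(), 1), pkg_housing)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
  # all printed poverty ORs exceed 1, so above-poverty maximises basement
  for (region in region_levels()) {
    above <- ref_bin; above$poverty <- "above"
    below <- ref_bin; below$poverty <- "below"
    expect_gt(
      housing_probabilities(above, region,
                            pkg_housing)["detached_with_basement"],
      housing_probabilities(below, region,
                            pkg_housing)["detached_with_basement"])
  }
})

test_that("islander race maps to the configured residual category", {
  isl <- ref_bin; isl$race <- "islander"
  oth <- ref_bin; oth$race <- "other"
  expect_equal(housing_probabilities(isl, "West", pkg_housing),
               housing_probabilities(oth, "West", pkg_housing))
})

test_that("two-outcome binary-covariate fit matches the 2x2 closed form", {
  # collapse to 2 outcomes: the multinomial MLE for a saturated one-covariate
  # model equals the contingency-table log-odds
  set.seed(11)
  n <- 4000L
  pov <- sample(c("above", "below"), n, replace = TRUE)
  p_att <- ifelse(pov == "below", 0.65, 0.35)
  ht <- ifelse(runif(n) < p_att, "attached", "detached_with_basement")
  d <- data.frame(house_type = ht, poverty = pov, sex = "female",
                  race = "white", region = "South", age_group = "45-54",
                  stringsAsFactors = FALSE)
  # pad a few rows of each unused outcome so the design is non-degenerate,
  # then fit and compare against the closed form of the padded table
  pad <- d[1:6, ]
  pad$house_type <- rep(c("crawl_space", "slab", "other_detached"), 2)
  pad$poverty <- rep(c("above", "below"), 3)
  dd <- rbind(d, pad)
  fit <- suppressWarnings(fit_housing_model(dd))
  tab <- table(dd$poverty, dd$house_type)
  closed_int <- log(tab["above", "attached"] /
                      tab["above", "detached_with_basement"])
  closed_beta <- log(tab["below", "attached"] /
                       tab["below", "detached_with_basement"]) - closed_int
  expect_equal(unname(fit$intercepts["attached"]), closed_int,
               tolerance = 1e-3)
  expect_equal(fit$coefs["poverty:below", "attached"], closed_beta,
               tolerance = 1e-3)
})

test_that("fits with a missing outcome are rejected as degenerate", {
  d <- data.frame(house_type = "detached_with_basement",
                  poverty = sample(poverty_levels(), 50, replace = TRUE),
                  sex = "female", race = "white", region = "South",
                  age_group = "45-54", stringsAsFactors = FALSE)
  expect_error(fit_housing_model(d), "degenerate")
})

test_that("parameters are recovered from a moderate simulated sample", {
  d <- generate_ahs_like(pkg_housing, n = 12000L, seed = 13L)
  fit <- fit_housing_model(d)
  z_int <- (fit$intercepts - pkg_housing$intercepts) / fit$se$intercepts
  common <- intersect(rownames(fit$coefs), rownames(pkg_housing$coefs))
  # cells with no events give infinite MLEs (complete separation); those
  # log-odds are excluded from the coverage check as is standard
  ok <- abs(fit$coefs[common, ]) < 8
  z_cf <- ((fit$coefs[common, ] - pkg_housing$coefs[common, ]) /
             fit$se$coefs[common, ])[ok]
  z <- c(z_int, z_cf)
  # nominal coverage of a +-2 SE interval, pooled over all parameters
  expect_gte(mean(abs(z) <= 2), 0.92)
  expect_lt(max(abs(z)), 4)
})
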