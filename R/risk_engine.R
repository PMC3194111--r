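#' Radon-progeny exposure rate
#'
#' WLM accumulated per year of residence per pCi/L of radon gas:
#' `wl_per_pci * wlm_per_wl_year * occupancy_fraction`. At the default
#' constants this is 0.14448, the conventionally quoted 0.144 WLM/yr per
#' pCi/L.
#'
#' @param constants An [exposure_constants()] object.
#' @return Exposure rate in WLM per year per pCi/L.
#' @export
exposure_rate <- function(constants = exposure_constants()) {
  constants$wl_per_pci * constants$wlm_per_wl_year *
    constants$occupancy_fraction
}

.clip_risk <- function(risk) {
  if (any(risk >= 1)) {
    warning("lifetime risk clipped to [0, 1): linear excess-risk formula ",
            "exceeded 1 for extreme inputs", call. = FALSE)
    risk <- pmin(risk, 1 - 1e-12)
  }
  pmax(risk, 0)
}

#' Lifetime fatal lung-cancer risk at a fixed concentration
#'
#' Linear excess-risk formula: concentration x exposure rate x exposure
#' duration x per-WLM unit risk for the given sex and smoking stratum,
#' clipped to [0, 1).
#'
#' @param concentration Radon concentration in pCi/L (>= 0).
#' @param sex `"male"` or `"female"`.
#' @param smoking_status `"ever"` or `"never"`.
#' @param constants An [exposure_constants()] object.
#' @param unit_risks A [unit_risk_factors()] object.
#' @return Lifetime fatal lung-cancer probability.
#' @examples
#' lifetime_risk_for_status(1.0, "male", "ever")  # ~0.0115
#' @export
lifetime_risk_for_status <- function(concentration, sex, smoking_status,
                                     constants = exposure_constants(),
                                     unit_risks = unit_risk_factors()) {
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  .check_levels(sex, sex_levels(), "sex")
  .check_levels(smoking_status, c("ever", "never"), "smoking_status")
  ur <- unlist(unit_risks)[paste(sex, smoking_status, sep = "_")]
  .clip_risk(concentration * exposure_rate(constants) *
               constants$exposure_duration_years * unname(ur))
}

#' Lifetime risk with the general-population unit risk
#'
#' Same formula as [lifetime_risk_for_status()] but using the
#' population-average per-WLM unit risk; used only to reproduce the EPA
#' calibration benchmark (0.73% lifetime risk at 1.25 pCi/L).
#'
#' @inheritParams lifetime_risk_for_status
#' @return Lifetime fatal lung-cancer probability.
#' @export
lifetime_risk_general <- function(concentration,
                                  constants = exposure_constants(),
                                  unit_risks = unit_risk_factors()) {
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  .clip_risk(concentration * exposure_rate(constants) *
               constants$exposure_duration_years *
               unit_risks$general_population)
}

#' Risk-chain prediction for one demographic bin
#'
#' Runs the full three-model chain for a single bin: ever-smoking
#' probability from the smoking model, house-type mix from the housing
#' model, per-type radon concentration from the radon model (state and
#' county residuals included), the mix-weighted expected concentration, and
#' the lifetime fatal lung-cancer risk
#' \deqn{R = E[C] \cdot r \cdot D \cdot (p\,UR_{ever} + (1-p)\,UR_{never})}
#' where `r` is the exposure rate and `D` the exposure duration. The
#' factorisation is exact under the assumption that smoking status and house
#' type are independent within a bin (no differential distribution of
#' smokers among house types).
#'
#' @param bin One demographic bin (list or one-row data.frame with
#'   `age_group`, `sex`, `race`, `poverty`, `count`, and optionally ids).
#' @param context The bin's county context (see [read_contexts()]).
#' @param radon_params,housing_params,smoking_params Parameter bundles from
#'   [load_coefficients()] or the fitting functions.
#' @param constants,unit_risks Constant bundles from
#'   [load_risk_constants()].
#' @return An object of class `bin_risk_result`: a list with `bin`,
#'   `p_ever_smoking`, `housetype_probs`, `concentration_by_type`,
#'   `expected_concentration`, `lifetime_risk`.
#' @export
bin_risk <- function(bin, context, radon_params, housing_params,
                     smoking_params, constants = exposure_constants(),
                     unit_risks = unit_risk_factors()) {
  p_smoke <- predict_ever_smoking(bin, context, smoking_params)
  ht_probs <- housing_probabilities(bin, context$region, housing_params)
  conc <- vapply(house_type_levels(), function(ht) {
    predict_concentration(context, ht, radon_params,
                          include_residuals = TRUE)
  }, numeric(1))
  expected_c <- sum(ht_probs * conc[names(ht_probs)])
  ur <- unlist(unit_risks)
  blended_ur <- p_smoke * ur[[paste0(bin$sex, "_ever")]] +
    (1 - p_smoke) * ur[[paste0(bin$sex, "_never")]]
  risk <- .clip_risk(expected_c * exposure_rate(constants) *
                       constants$exposure_duration_years * blended_ur)
  structure(list(bin = bin, p_ever_smoking = p_smoke,
                 housetype_probs = ht_probs,
                 concentration_by_type = conc,
                 expected_concentration = expected_c,
                 lifetime_risk = risk),
            class = "bin_risk_result")
}

#' @export
print.bin_risk_result <- function(x, ...) {
  cat(sprintf("Bin risk: %s %s %s, poverty %s\n", x$bin$sex,
              x$bin$age_group, x$bin$race, x$bin$poverty))
  cat(sprintf("  P(ever-smoking) = %.4f\n", x$p_ever_smoking))
  cat(sprintf("  expected concentration = %.3f pCi/L\n",
              x$expected_concentration))
  cat(sprintf("  lifetime fatal lung-cancer risk = %.5f (%.3f%%)\n",
              x$lifetime_risk, 100 * x$lifetime_risk))
  invisible(x)
}

#' Vectorised risk-chain prediction over a bin table
#'
#' Joins bins to their county contexts and runs the full chain for every
#' bin. The flat result table carries the smoking probability, the five
#' house-type probabilities and concentrations, the expected concentration
#' and the lifetime risk per bin.
#'
#' @param bins Bin table (see [read_bins()]).
#' @param contexts Context table (see [read_contexts()]).
#' @inheritParams bin_risk
#' @return Data.frame with one row per bin.
#' @export
predict_bin_risks <- function(bins, contexts, radon_params, housing_params,
                              smoking_params,
                              constants = exposure_constants(),
                              unit_risks = unit_risk_factors()) {
  bins <- validate_bins(bins)
  contexts <- validate_contexts(contexts)
  missing_counties <- setdiff(bins$county_id, contexts$county_id)
  if (length(missing_counties) > 0L)
    stop("no context for county id(s): ",
         paste(utils::head(missing_counties, 5L), collapse = ", "),
         call. = FALSE)
  ctx <- contexts[match(bins$county_id, contexts$county_id), ]

  p_smoke <- stats::plogis(.smoking_lp(
    bins$sex, bins$age_group, bins$poverty, bins$race, smoking_params,
    state_tax = ctx$state_tax,
    prev_state_prevalence = ctx$prev_state_prevalence,
    indoor_restrictions = ctx$indoor_restrictions,
    cbsa_poverty_above_median = ctx$cbsa_poverty_above_median,
    cbsa_nonmetropolitan = ctx$cbsa_nonmetropolitan,
    state_residual = ctx$smoking_state_residual,
    cbsa_residual = ctx$smoking_cbsa_residual,
    state_black_slope = ctx$smoking_state_black_slope))
  eta <- .housing_eta(bins$poverty, bins$sex, bins$race, ctx$region,
                      bins$age_group, housing_params)
  ht_probs <- .softmax5(eta)
  conc <- vapply(house_type_levels(), function(ht) {
    exp(.radon_lp(ctx$region, ctx$geo_potential, ctx$hdd, ctx$diurnal_swing,
                  rep(ht, nrow(bins)), radon_params) +
          ctx$radon_state_residual + ctx$radon_county_residual)
  }, numeric(nrow(bins)))
  if (nrow(bins) == 1L) conc <- matrix(conc, nrow = 1,
                                       dimnames = list(NULL,
                                                       house_type_levels()))
  expected_c <- rowSums(ht_probs * conc[, colnames(ht_probs), drop = FALSE])
  ur <- unlist(unit_risks)
  blended_ur <- p_smoke * ur[paste0(bins$sex, "_ever")] +
    (1 - p_smoke) * ur[paste0(bins$sex, "_never")]
  risk <- .clip_risk(expected_c * exposure_rate(constants) *
                       constants$exposure_duration_years *
                       unname(blended_ur))

  out <- bins[c("county_id", "state_id", "age_group", "sex", "race",
                "poverty", "count")]
  out$p_ever_smoking <- p_smoke
  for (ht in house_type_levels()) out[[paste0("p_", ht)]] <- ht_probs[, ht]
  for (ht in house_type_levels()) out[[paste0("conc_", ht)]] <- conc[, ht]
  out$expected_concentration <- expected_c
  out$lifetime_risk <- risk
  out
}

#' Population-weighted aggregation of bin risks
#'
#' Aggregates bin-level results to county, state or national
#' population-weighted averages of lifetime risk, expected concentration and
#' ever-smoking prevalence, with weights equal to bin population counts.
#' Groups whose total count is 0 are excluded with a warning.
#'
#' @param results Bin-level result table from [predict_bin_risks()].
#' @param level `"county"`, `"state"` or `"national"`.
#' @return Data.frame with grouping columns, `population`, `mean_risk`,
#'   `mean_concentration`, `mean_ever_smoking`.
#' @export
aggregate_risk <- function(results,
                           level = c("county", "state", "national")) {
  level <- match.arg(level)
  key <- switch(level,
                county = interaction(results$state_id, results$county_id,
                                     drop = TRUE, sep = "\r"),
                state = factor(results$state_id),
                national = factor(rep("national", nrow(results))))
  tot <- tapply(results$count, key, sum)
  empty <- names(tot)[tot == 0]
  if (length(empty) > 0L) {
    warning("excluding group(s) with zero population: ",
            paste(gsub("\r", "/", empty), collapse = ", "), call. = FALSE)
  }
  wmean <- function(v) {
    s <- tapply(v * results$count, key, sum)
    as.numeric(s / tot)
  }
  out <- data.frame(group = names(tot), population = as.numeric(tot),
                    mean_risk = wmean(results$lifetime_risk),
                    mean_concentration = wmean(results$expected_concentration),
                    mean_ever_smoking = wmean(results$p_ever_smoking),
                    stringsAsFactors = FALSE)
  if (level == "county") {
    parts <- strsplit(out$group, "\r", fixed = TRUE)
    out <- cbind(state_id = vapply(parts, `[`, "", 1L),
                 county_id = vapply(parts, `[`, "", 2L),
                 out[-1L])
  } else if (level == "state") {
    names(out)[names(out) == "group"] <- "state_id"
  } else {
    out$group <- NULL
  }
  out[is.finite(out$mean_risk), , drop = FALSE]
}

#' Unweighted summary across county averages
#'
#' Mean, median, standard deviation and range of the county-average values
#' (each county counting once, regardless of population), the companion
#' summary to the population-weighted aggregates.
#'
#' @param county_table Output of `aggregate_risk(results, "county")`.
#' @return Data.frame with one row per summarised variable.
#' @export
county_summary <- function(county_table) {
  smry <- function(v) c(mean = mean(v), median = stats::median(v),
                        sd = stats::sd(v), min = min(v), max = max(v))
  vars <- c("mean_risk", "mean_concentration", "mean_ever_smoking")
  out <- as.data.frame(t(vapply(vars, function(v) smry(county_table[[v]]),
                                numeric(5))))
  cbind(variable = vars, out, row.names = NULL)
}
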