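#' Load a packaged (or user-supplied) coefficient table
#'
#' The three regression models of the risk chain are parameter-driven: their
#' published coefficients ship as delimited files under `inst/extdata` so
#' users can substitute refitted parameter bundles. Tables are long format
#' with columns `term`, `level`, `estimate`, `se`, `scale` (housing adds an
#' `outcome` column). Housing covariate effects are printed as odds ratios
#' and converted here to log-odds via the natural log; reference categories
#' are materialised with coefficient exactly 0.
#'
#' @param model One of `"radon"`, `"housing"`, `"smoking"`: which parameter
#'   bundle to build.
#' @param path Optional path to a user table following the packaged schema;
#'   default uses the file shipped with the package.
#' @return A [radon_params()], [housing_params()] or [smoking_params()]
#'   object.
#' @examples
#' rp <- load_coefficients("radon")
#' rp$intercept                      # -0.02 log(pCi/L)
#' hp <- load_coefficients("housing")
#' hp$coefs["poverty:below", "attached"]  # log(4.40)
#' @export
load_coefficients <- function(model = c("radon", "housing", "smoking"),
                              path = NULL) {
  model <- match.arg(model)
  if (is.null(path)) {
    path <- system.file("extdata", paste0(model, "_coefs.csv"),
                        package = "radonrisk", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("coefficient table not found: ", path,
                               call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("term", "level", "estimate", "scale")
  if (model == "housing") need <- c(need, "outcome")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("coefficient table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  est <- suppressWarnings(as.numeric(tab$estimate))
  bad <- which(is.na(est) & nzchar(tab$estimate))
  if (length(bad) > 0L)
    stop(sprintf("non-numeric estimate in row %d of %s", bad[1L], path),
         call. = FALSE)
  if (anyNA(est))
    stop("empty estimate in coefficient table: ", path, call. = FALSE)
  tab$estimate <- est
  tab$se <- suppressWarnings(as.numeric(tab$se))
  switch(model,
         radon = .build_radon_params(tab),
         housing = .build_housing_params(tab),
         smoking = .build_smoking_params(tab))
}

.require_terms <- function(tab, keys, what) {
  have <- paste(tab$term, tab$level, sep = ":")
  miss <- setdiff(keys, have)
  if (length(miss) > 0L)
    stop(sprintf("%s coefficient table missing required term(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
}

.pick <- function(tab, term, level = "") {
  i <- which(tab$term == term & tab$level == level)
  tab$estimate[i]
}

.build_radon_params <- function(tab) {
  .require_terms(tab, c("intercept:", "region:Northeast", "region:South",
                        "region:West", "geo_potential:Medium",
                        "geo_potential:High", "hdd:", "diurnal_swing:",
                        "house_type:attached", "house_type:crawl_space",
                        "house_type:slab", "house_type:other_detached",
                        "variance:state", "variance:psu", "variance:ssu",
                        "variance:residual"), "radon")
  region <- c(Midwest = 0,
              vapply(c("Northeast", "South", "West"),
                     function(l) .pick(tab, "region", l), numeric(1)))
  geo <- c(Low = 0,
           vapply(c("Medium", "High"),
                  function(l) .pick(tab, "geo_potential", l), numeric(1)))
  ht <- c(detached_with_basement = 0,
          vapply(house_type_outcomes(),
                 function(l) .pick(tab, "house_type", l), numeric(1)))
  vc <- vapply(c("state", "psu", "ssu", "residual"),
               function(l) .pick(tab, "variance", l), numeric(1))
  se <- stats::setNames(tab$se, paste(tab$term, tab$level, sep = ":"))
  radon_params(intercept = .pick(tab, "intercept"),
               region_coefs = region[region_levels()],
               geo_coefs = geo[geo_potential_levels()],
               hdd_coef = .pick(tab, "hdd"),
               diurnal_coef = .pick(tab, "diurnal_swing"),
               housetype_coefs = ht[house_type_levels()],
               variance_components = vc, se = se)
}

.build_housing_params <- function(tab) {
  outs <- house_type_outcomes()
  ints <- tab[tab$term == "intercept", , drop = FALSE]
  if (!all(outs %in% ints$outcome))
    stop("housing coefficient table missing required term(s): intercept for ",
         paste(setdiff(outs, ints$outcome), collapse = ", "), call. = FALSE)
  intercepts <- stats::setNames(ints$estimate, ints$outcome)[outs]
  keys <- c("poverty:below", "sex:male",
            paste0("race:", setdiff(race_levels_housing(), "white")),
            paste0("region:", setdiff(region_levels(), "South")),
            paste0("age_group:", setdiff(age_groups_all(), "45-54")))
  cf <- tab[tab$term != "intercept", , drop = FALSE]
  .require_terms(cf, keys, "housing")
  coefs <- matrix(0, nrow = length(keys), ncol = length(outs),
                  dimnames = list(keys, outs))
  for (i in seq_len(nrow(cf))) {
    key <- paste(cf$term[i], cf$level[i], sep = ":")
    out <- cf$outcome[i]
    if (!key %in% keys || !out %in% outs) next
    val <- cf$estimate[i]
    if (identical(cf$scale[i], "odds_ratio")) {
      if (val <= 0) stop("odds ratio must be positive in row ", i,
                         call. = FALSE)
      val <- log(val)
    }
    coefs[key, out] <- val
  }
  se_int <- stats::setNames(ints$se, ints$outcome)[outs]
  housing_params(intercepts = intercepts, coefs = coefs,
                 se = list(intercepts = se_int))
}

.build_smoking_params <- function(tab) {
  fixed_keys <- c("sex:male",
                  paste0("age_group:", setdiff(age_groups_adult(), "45-54")),
                  "poverty:below", "income_not_reported:",
                  paste0("race:", setdiff(race_levels(), "white")),
                  paste0("race_male:", setdiff(race_levels(), "white")),
                  "state_tax:", "prev_state_prevalence:",
                  "indoor_restrictions:", "cbsa_poverty_above_median:",
                  "cbsa_nonmetropolitan:")
  .require_terms(tab, c("intercept:", fixed_keys, "variance:state",
                        "variance:state_black_slope",
                        "covariance:state_blackslope", "variance:cbsa",
                        "variance:household"), "smoking")
  fixed <- tab[!tab$term %in% c("intercept", "variance", "covariance"), ,
               drop = FALSE]
  keys <- ifelse(nzchar(fixed$level),
                 paste(fixed$term, fixed$level, sep = ":"), fixed$term)
  coefs <- stats::setNames(fixed$estimate, keys)
  se <- stats::setNames(tab$se,
                        ifelse(nzchar(tab$level),
                               paste(tab$term, tab$level, sep = ":"),
                               tab$term))
  smoking_params(intercept = .pick(tab, "intercept"),
                 coefs = coefs,
                 var_state = .pick(tab, "variance", "state"),
                 var_state_black_slope = .pick(tab, "variance",
                                               "state_black_slope"),
                 cov_state_blackslope = .pick(tab, "covariance",
                                              "state_blackslope"),
                 var_cbsa = .pick(tab, "variance", "cbsa"),
                 var_household = .pick(tab, "variance", "household"),
                 se = se)
}

#' Load the physical and epidemiological risk constants
#'
#' Reads the packaged YAML file (or a user override following the same
#' layout) holding the WLM conversion constants and the per-WLM unit risk
#' factors. Any field can be overridden via `overrides`, e.g.
#' `list(exposure = list(exposure_duration_years = 70))`.
#'
#' @param path Optional path to a YAML constants file.
#' @param overrides Optional nested list merged over the file contents.
#' @param quiet Suppress the log line reporting the effective constants.
#' @return List with elements `exposure` ([exposure_constants()]) and
#'   `unit_risks` ([unit_risk_factors()]).
#' @export
load_risk_constants <- function(path = NULL, overrides = NULL, quiet = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "risk_constants.yaml",
                        package = "radonrisk", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(overrides)) {
    for (blk in names(overrides)) {
      raw[[blk]][names(overrides[[blk]])] <- overrides[[blk]]
    }
  }
  out <- list(exposure = do.call(exposure_constants, raw$exposure),
              unit_risks = do.call(unit_risk_factors, raw$unit_risks))
  if (!quiet) {
    message(sprintf(
      "risk constants: exposure rate %.5f WLM/yr per pCi/L, duration %g yr, URs (M/F ever, M/F never) %g/%g, %g/%g",
      exposure_rate(out$exposure), out$exposure$exposure_duration_years,
      out$unit_risks$male_ever, out$unit_risks$female_ever,
      out$unit_risks$male_never, out$unit_risks$female_never))
  }
  out
}
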