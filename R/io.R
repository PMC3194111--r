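#' Read and validate a demographic-bin table
#'
#' A bin is one county x age x sex x race x poverty cell with an adult
#' population count: the atomic unit of prediction and aggregation.
#' The file is comma-delimited UTF-8 with a header row and columns
#' `county_id, state_id, age_group, sex, race, poverty, count`.
#' Minors (`"<18"`) are rejected: the smoking model, and therefore the risk
#' chain, applies to adults only.
#'
#' @param path CSV file path.
#' @return A validated data.frame of bins.
#' @export
read_bins <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(county_id = "character",
                                       state_id = "character"))
  validate_bins(df)
}

#' @rdname read_bins
#' @param bins Data.frame to validate in place.
#' @export
validate_bins <- function(bins) {
  need <- c("county_id", "state_id", "age_group", "sex", "race", "poverty",
            "count")
  miss <- setdiff(need, names(bins))
  if (length(miss) > 0L)
    stop("bins table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  .check_levels(bins$age_group, age_groups_adult(), "age_group")
  .check_levels(bins$sex, sex_levels(), "sex")
  .check_levels(bins$race, race_levels(), "race")
  .check_levels(bins$poverty, poverty_levels(), "poverty")
  if (any(!is.finite(bins$count)) || any(bins$count < 0))
    stop("bins table: count must be a non-negative number", call. = FALSE)
  if (any(bins$count != floor(bins$count)))
    stop("bins table: count must be integer-valued", call. = FALSE)
  bins
}

.context_residual_cols <- function() {
  c("radon_state_residual", "radon_county_residual",
    "smoking_state_residual", "smoking_state_black_slope",
    "smoking_cbsa_residual")
}

#' Read and validate a county-context table
#'
#' One row per county holding everything geographic a bin inherits: Census
#' region, USGS geological radon potential class, meteorology (heating
#' infiltration degree-days, average diurnal temperature swing), state and
#' county radon residuals, state/CBSA smoking residuals, and state tobacco
#' covariates. Residual columns absent from the file default to 0 -- the rule
#' applied to states and CBSAs never sampled by the source surveys.
#'
#' @param path CSV file path.
#' @return A validated data.frame keyed by `county_id`.
#' @export
read_contexts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(county_id = "character",
                                       state_id = "character"))
  validate_contexts(df)
}

#' @rdname read_contexts
#' @param contexts Data.frame to validate in place.
#' @export
validate_contexts <- function(contexts) {
  need <- c("county_id", "state_id", "region", "geo_potential", "hdd",
            "diurnal_swing", "state_tax", "prev_state_prevalence",
            "indoor_restrictions", "cbsa_poverty_above_median",
            "cbsa_nonmetropolitan")
  miss <- setdiff(need, names(contexts))
  if (length(miss) > 0L)
    stop("contexts table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in .context_residual_cols()) {
    if (is.null(contexts[[col]])) contexts[[col]] <- 0
  }
  if (anyDuplicated(contexts$county_id))
    stop("contexts table: duplicate county_id", call. = FALSE)
  .check_levels(contexts$region, region_levels(), "region")
  .check_levels(contexts$geo_potential, geo_potential_levels(),
                "geo_potential")
  if (any(!is.finite(contexts$hdd)) || any(contexts$hdd < 0))
    stop("contexts table: hdd must be non-negative", call. = FALSE)
  if (any(!is.finite(as.matrix(contexts[.context_residual_cols()]))))
    stop("contexts table: residuals must be finite", call. = FALSE)
  for (col in c("indoor_restrictions", "cbsa_poverty_above_median",
                "cbsa_nonmetropolitan")) {
    if (!all(contexts[[col]] %in% c(0, 1)))
      stop("contexts table: ", col, " must be 0/1", call. = FALSE)
  }
  contexts
}

#' Write and re-read bin-level risk results
#'
#' Results are written as flat CSV (UTF-8, '.' decimal, full precision) so a
#' write/read round trip reproduces every value exactly.
#'
#' @param results Data.frame as produced by [predict_bin_risks()].
#' @param path Output CSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()` the
#'   data.frame.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  utils::write.csv(format(results, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(county_id = "character",
                                 state_id = "character"))
}
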