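#' Closed categorical vocabularies
#'
#' The prediction chain operates on demographic bins and county contexts whose
#' categorical fields come from fixed vocabularies. Reference levels (the ones
#' carrying coefficient 0 in the published tables) are listed first.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
age_groups_adult <- function() {
  c("45-54", "18-24", "25-34", "35-44", "55-64", "65-74", "75+")
}

#' @rdname vocabularies
#' @export
age_groups_all <- function() c(age_groups_adult(), "<18")

#' @rdname vocabularies
#' @export
sex_levels <- function() c("female", "male")

#' @rdname vocabularies
#' @export
race_levels <- function() {
  c("white", "black", "asian", "native", "islander", "other")
}

# the housing model was fit without a Pacific-Islander category
race_levels_housing <- function() c("white", "black", "asian", "native", "other")

#' @rdname vocabularies
#' @export
poverty_levels <- function() c("above", "below")

#' @rdname vocabularies
#' @export
region_levels <- function() c("Northeast", "Midwest", "South", "West")

#' @rdname vocabularies
#' @export
geo_potential_levels <- function() c("Low", "Medium", "High")

#' @rdname vocabularies
#' @export
house_type_levels <- function() {
  c("detached_with_basement", "attached", "crawl_space", "slab",
    "other_detached")
}

# non-reference house types, in the order the multinomial model indexes them
house_type_outcomes <- function() {
  c("attached", "crawl_space", "slab", "other_detached")
}

.check_levels <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s level(s): %s (allowed: %s)",
                 what, paste(bad, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
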