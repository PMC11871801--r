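# Canonical category levels of the diary schema. Contact attributes admit an
# explicit "unknown" level; nothing is dropped at read time — each analysis
# stage applies its own exclusion rule.

#' Schema category levels
#'
#' Canonical levels for the categorical fields of the diary schema.
#' `unknown_label()` is the explicit level used when a participant could not
#' report an attribute of the contacted person.
#'
#' @return Character vector of levels.
#' @name schema_levels
NULL

#' @rdname schema_levels
#' @export
sex_levels <- function() c("female", "male")

#' @rdname schema_levels
#' @export
relation_levels <- function() {
  c("cohabiting", "extended_family", "brethren", "coworker",
    "educational", "other")
}

#' @rdname schema_levels
#' @export
location_levels <- function() {
  c("home", "workplace", "educational_facility", "other")
}

#' @rdname schema_levels
#' @export
duration_levels <- function() {
  c("<5min", "5-15min", "15min-1h", "1-4h", ">4h")
}

#' @rdname schema_levels
#' @export
frequency_levels <- function() {
  c("daily", "3-6/week", "1-2/week", "1-3/month", "<1/month", "first_time")
}

#' @rdname schema_levels
#' @export
unknown_label <- function() "unknown"

#' Province-to-major-region lookup
#'
#' South Korea's 17 provincial-level regions grouped into the five major
#' regions used for stratified contact matrices (Metropolitan, Chungcheong,
#' Gangwon, Youngnam, Honam). Jeju is grouped with Honam, its nearest major
#' region.
#'
#' @return Tibble with columns `region17` and `region5`.
#' @export
region_map <- function() {
  path <- system.file("extdata", "region5_map.csv", package = "contactdiaries")
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname region_map
#' @export
region17_levels <- function() region_map()$region17

#' @rdname region_map
#' @export
region5_levels <- function() unique(region_map()$region5)

#' Map provincial regions to major regions
#'
#' @param region17 Character vector of provincial-level region labels
#'   (the `unknown` label passes through).
#' @return Character vector of major-region labels.
#' @export
region5_of <- function(region17) {
  map <- region_map()
  out <- map$region5[match(region17, map$region17)]
  out[region17 == unknown_label()] <- unknown_label()
  if (anyNA(out)) {
    bad <- unique(region17[is.na(out)])
    rlang::abort(paste0("unknown region17 label(s): ",
                        paste(bad, collapse = ", ")),
                 class = "contactdiaries_validation_error")
  }
  out
}
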