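#' WHO world standard population weights
#'
#' Age-group weights of the WHO world standard population (18 five-year
#' groups up to 85+). The shipped table stores the published percentage
#' shares; they are renormalized to sum exactly to 1 on load. Any other
#' standard can be supplied wherever a standard population is accepted, as
#' a data frame with columns `age_group` and `weight`.
#'
#' @return Tibble with columns `age_group` and `weight` (summing to 1).
#' @export
#' @examples
#' sum(world_standard_population()$weight)  # 1
world_standard_population <- function() {
  path <- system.file("extdata", "who_world_standard.csv",
                      package = "stoichdiet", mustWork = TRUE)
  std <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble(age_group = std$age_group, weight = std$percent / sum(std$percent))
}

validate_standard <- function(std) {
  assert_cols(std, c("age_group", "weight"), "standard population")
  if (abs(sum(std$weight) - 1) > 1e-9) {
    stopf("standard population weights must sum to 1 (got %.12f)",
          sum(std$weight))
  }
  if (any(std$weight < 0 | std$weight > 1)) {
    stopf("standard population weights must lie in [0, 1]")
  }
  invisible(std)
}

#' Crude death rate per 100,000
#'
#' @param deaths,population Non-negative counts (vectorized).
#' @param context Optional label included in error messages (e.g.
#'   "country_01/1995").
#' @return `1e5 * deaths / population`.
#' @export
#' @examples
#' crude_rate(1000, 1e6)  # 100
crude_rate <- function(deaths, population, context = NULL) {
  ctx <- if (is.null(context)) "" else paste0(" [", context, "]")
  if (any(population <= 0)) {
    stopf("population must be positive to compute a rate%s", ctx)
  }
  if (any(deaths < 0)) stopf("deaths must be non-negative%s", ctx)
  1e5 * deaths / population
}

#' Age-standardized rate per 100,000
#'
#' Weighted average of age-group-specific crude rates, with weights from a
#' standard population — the direct-standardization estimator that removes
#' age-structure differences between countries. The same computation is
#' applied unchanged to prevalence counts.
#'
#' Strata with zero population and zero deaths contribute a rate of 0 (with
#' a warning); zero population with positive deaths is an error.
#'
#' @param slice Data frame with columns `age_group`, `deaths`, `population`
#'   for a single country-year-cause.
#' @param std Standard population (`age_group`, `weight`); defaults to
#'   [world_standard_population()].
#' @return The standardized rate (scalar, per 100,000).
#' @export
#' @examples
#' slice <- tibble::tibble(age_group = c("young", "old"),
#'                         deaths = c(10, 40), population = c(1e4, 2e4))
#' std <- tibble::tibble(age_group = c("young", "old"), weight = c(0.6, 0.4))
#' age_standardized_rate(slice, std)  # 0.6*100 + 0.4*200 = 140
age_standardized_rate <- function(slice, std = world_standard_population()) {
  validate_standard(std)
  assert_cols(slice, c("age_group", "deaths", "population"), "'slice'")
  if (anyDuplicated(slice$age_group)) {
    stopf("duplicate age groups in slice; pass a single country-year-cause")
  }
  missing <- setdiff(std$age_group, slice$age_group)
  if (length(missing) > 0L) {
    stopf("age group(s) missing from the data: %s",
          paste(missing, collapse = ", "))
  }
  extra <- setdiff(slice$age_group, std$age_group)
  if (length(extra) > 0L) {
    warnf("ignoring age group(s) absent from the standard: %s",
          paste(extra, collapse = ", "))
  }
  slice <- slice[match(std$age_group, slice$age_group), , drop = FALSE]
  zero <- slice$population == 0
  if (any(zero & slice$deaths > 0)) {
    stopf("zero population with positive deaths in age group(s): %s",
          paste(slice$age_group[zero & slice$deaths > 0], collapse = ", "))
  }
  rate <- numeric(nrow(slice))
  if (any(zero)) {
    warnf("age group(s) with zero population treated as rate 0: %s",
          paste(slice$age_group[zero], collapse = ", "))
  }
  rate[!zero] <- crude_rate(slice$deaths[!zero], slice$population[!zero])
  sum(std$weight * rate)
}

#' Standardize a full mortality (or prevalence) table
#'
#' Applies [age_standardized_rate()] per country, year and cause, and also
#' reports the crude all-ages rate.
#'
#' @param mortality Table with columns `country`, `year`, `cause`,
#'   `age_group`, `deaths`, `population`.
#' @param std Standard population; defaults to
#'   [world_standard_population()].
#' @return Tibble: `country`, `year`, `cause`, `standardized_rate`,
#'   `crude_rate`.
#' @export
standardize_rates <- function(mortality, std = world_standard_population()) {
  assert_cols(mortality, c("country", "year", "cause", "age_group",
                           "deaths", "population"), "'mortality'")
  grouped <- dplyr::group_by(mortality, .data$country, .data$year, .data$cause)
  out <- dplyr::group_modify(grouped, function(df, key) {
    tibble(
      standardized_rate = age_standardized_rate(df, std),
      crude_rate = 1e5 * sum(df$deaths) / sum(df$population)
    )
  })
  dplyr::ungroup(out)
}
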