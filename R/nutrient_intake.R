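#' Average nutrient concentrations across databases
#'
#' When two or more nutrient-composition databases report values for the
#' same food group, the per-nutrient arithmetic mean across databases is
#' used as the final concentration; groups covered by a single database
#' pass through unchanged.
#'
#' @param food_group Label of the food group to look up.
#' @param tables List of concentration tables, each with columns
#'   `food_group`, `n_g_per_kg`, `p_g_per_kg`, `protein_g_per_kg`,
#'   `kcal_per_kg` and a `database_id`.
#' @return One-row tibble with the averaged concentrations.
#' @export
#' @examples
#' t1 <- tibble::tibble(food_group = "beef", n_g_per_kg = 20, p_g_per_kg = 2,
#'                      protein_g_per_kg = 125, kcal_per_kg = 2000,
#'                      database_id = "a")
#' t2 <- dplyr::mutate(t1, n_g_per_kg = 24, database_id = "b")
#' mean_concentration("beef", list(t1, t2))$n_g_per_kg  # 22
mean_concentration <- function(food_group, tables) {
  merged <- merge_concentrations(tables)
  row <- merged[merged$food_group == food_group, , drop = FALSE]
  if (nrow(row) == 0L) {
    stopf("food group '%s' is absent from all concentration tables", food_group)
  }
  row
}

conc_cols <- c("n_g_per_kg", "p_g_per_kg", "protein_g_per_kg", "kcal_per_kg")

#' Merge concentration tables into one averaged lookup
#'
#' @param tables List of concentration tables (see [mean_concentration()]).
#' @return Tibble with one row per food group and database-averaged
#'   concentration columns.
#' @export
merge_concentrations <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  if (length(tables) == 0L) stopf("no concentration tables supplied")
  all <- dplyr::bind_rows(tables)
  assert_cols(all, c("food_group", conc_cols), "concentration table")
  if (any(as.matrix(all[conc_cols]) < 0, na.rm = TRUE)) {
    stopf("negative concentration values are not allowed")
  }
  dplyr::summarise(
    dplyr::group_by(all, .data$food_group),
    dplyr::across(dplyr::all_of(conc_cols), mean),
    .groups = "drop"
  )
}

validate_intake_table <- function(intake) {
  assert_cols(intake, c("country", "year", "food_group", "source_category",
                        "intake_kg"), "intake table")
  if (any(intake$intake_kg < 0, na.rm = TRUE)) {
    stopf("negative intake values are not allowed")
  }
  dup <- duplicated(intake[c("country", "year", "food_group")])
  if (any(dup)) {
    stopf("duplicate (country, year, food_group) keys in intake table")
  }
  bad <- setdiff(unique(intake$source_category), intake_sources)
  if (length(bad) > 0L) {
    stopf("unknown source categor%s: %s", if (length(bad) > 1) "ies" else "y",
          paste(bad, collapse = ", "))
  }
  invisible(intake)
}

#' Per-capita nutrient intake profile by country, year and source
#'
#' Converts food-group intakes (kg/capita/yr) and nutrient concentrations
#' (g/kg; kcal/kg for energy) into per-source totals: each nutrient is the
#' sum over the source's food groups of intake times concentration, with
#' g-to-kg conversion, so N, P and protein come out in kg/capita/yr and
#' energy in kcal/capita/yr. The N:P mass ratio is the ratio of the summed
#' N to the summed P (not a mean of per-food ratios) and is `NA` (flagged
#' undefined) when the source's P intake is zero.
#'
#' @param intake A food-intake table (see [generate_food_panel()] for the
#'   schema).
#' @param conc A merged concentration lookup from [merge_concentrations()],
#'   or a list of concentration tables to merge.
#' @return Tibble keyed by (country, year, source_category) with columns
#'   `n_kg`, `p_kg`, `np_ratio`, `protein_kg`, `kcal`, `total_kg`.
#' @export
compute_intake_profile <- function(intake, conc) {
  validate_intake_table(intake)
  if (!inherits(conc, "data.frame")) conc <- merge_concentrations(conc)
  assert_cols(conc, c("food_group", conc_cols), "'conc'")
  if (any(as.matrix(conc[conc_cols]) < 0, na.rm = TRUE)) {
    stopf("negative concentration values are not allowed")
  }
  missing <- setdiff(unique(intake$food_group), conc$food_group)
  if (length(missing) > 0L) {
    stopf("no concentration data for food group(s): %s",
          paste(missing, collapse = ", "))
  }
  joined <- dplyr::left_join(intake, conc, by = "food_group")
  prof <- dplyr::summarise(
    dplyr::group_by(joined, .data$country, .data$year, .data$source_category),
    n_kg = sum(.data$intake_kg * .data$n_g_per_kg) / 1000,
    p_kg = sum(.data$intake_kg * .data$p_g_per_kg) / 1000,
    protein_kg = sum(.data$intake_kg * .data$protein_g_per_kg) / 1000,
    kcal = sum(.data$intake_kg * .data$kcal_per_kg),
    total_kg = sum(.data$intake_kg),
    .groups = "drop"
  )
  prof$np_ratio <- ifelse(prof$p_kg > 0, prof$n_kg / prof$p_kg, NA_real_)
  dplyr::select(prof, "country", "year", "source_category",
                "n_kg", "p_kg", "np_ratio", "protein_kg", "kcal", "total_kg")
}

#' Aggregate country-year series over a study period
#'
#' Two aggregation modes are supported: `"mean"` averages each country's
#' values over the period; `"change"` contrasts the period's last decade
#' against its first (mean over the final 10 years minus mean over the
#' initial 10 years), the convention for "2000s relative to the 1960s"
#' style contrasts. Countries without at least one observation in each
#' referenced window are dropped with a message.
#'
#' @param data Data frame with `country`, `year` and one or more value
#'   columns.
#' @param cols Character vector of value columns to aggregate (default: all
#'   numeric columns other than `year`).
#' @param period Integer vector of years delimiting the period (only its
#'   range is used).
#' @param mode `"mean"` or `"change"`.
#' @return Tibble with `country` and the aggregated columns.
#' @export
period_aggregate <- function(data, cols = NULL, period, mode = c("mean", "change")) {
  mode <- match.arg(mode)
  assert_cols(data, c("country", "year"), "'data'")
  if (is.null(cols)) {
    cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "year")
  }
  lo <- min(period); hi <- max(period)
  in_period <- data[data$year >= lo & data$year <= hi, , drop = FALSE]
  if (nrow(in_period) == 0L) stopf("no observations fall inside the period %d-%d", lo, hi)

  if (mode == "mean") {
    return(dplyr::summarise(
      dplyr::group_by(in_period, .data$country),
      dplyr::across(dplyr::all_of(cols), ~ mean(.x)),
      .groups = "drop"
    ))
  }

  first_dec <- in_period[in_period$year <= lo + 9L, , drop = FALSE]
  last_dec <- in_period[in_period$year >= hi - 9L, , drop = FALSE]
  complete <- intersect(unique(first_dec$country), unique(last_dec$country))
  dropped <- setdiff(unique(in_period$country), complete)
  if (length(complete) == 0L) {
    stopf("no country has observations in both the first and last decade of %d-%d", lo, hi)
  }
  if (length(dropped) > 0L) {
    msgf("period_aggregate: dropping %d countr%s without data in both decades: %s",
         length(dropped), if (length(dropped) > 1) "ies" else "y",
         paste(dropped, collapse = ", "))
  }
  agg <- function(d) dplyr::summarise(
    dplyr::group_by(d[d$country %in% complete, , drop = FALSE], .data$country),
    dplyr::across(dplyr::all_of(cols), ~ mean(.x)),
    .groups = "drop"
  )
  a_first <- agg(first_dec)
  a_last <- agg(last_dec)
  a_first <- a_first[match(a_last$country, a_first$country), , drop = FALSE]
  out <- a_last
  out[cols] <- a_last[cols] - a_first[cols]
  out
}

#' Assemble the 33-column country covariate panel
#'
#' Builds the explanatory matrix for the regression stage: the six dietary
#' measures (N, P, N:P, kcal, protein, total kg) for the four intake
#' sources, the terrestrial-animal/vegetable quotient of those six measures
#' (computed per country-year before aggregation), and the three
#' socioeconomic controls — 33 columns in all. Countries missing any
#' covariate after aggregation are dropped (complete-case) with a message.
#'
#' @param profiles Output of [compute_intake_profile()].
#' @param socio Socioeconomic table with columns `country`, `year`,
#'   `gdp_per_capita`, `median_age`, `hdi`.
#' @param period Integer vector of years delimiting the study period.
#' @param mode `"mean"` or `"change"` (see [period_aggregate()]).
#' @return A `covariate_panel`: a tibble with `country` plus the 33
#'   explanatory columns, and attributes `period`, `mode`,
#'   `nutritional_cols`, `control_cols`.
#' @export
assemble_covariates <- function(profiles, socio, period, mode = c("mean", "change")) {
  mode <- match.arg(mode)
  assert_cols(profiles, c("country", "year", "source_category",
                          "n_kg", "p_kg", "np_ratio", "protein_kg",
                          "kcal", "total_kg"), "'profiles'")
  assert_cols(socio, c("country", "year", "gdp_per_capita", "median_age",
                       "hdi"), "'socio'")

  measure_map <- c(n_kg = "N", p_kg = "P", np_ratio = "NP", kcal = "kcal",
                   protein_kg = "protein", total_kg = "total_kg")
  long <- tidyr::pivot_longer(profiles, dplyr::all_of(names(measure_map)),
                              names_to = "measure", values_to = "value")
  long$measure <- measure_map[long$measure]
  wide <- tidyr::pivot_wider(
    long,
    id_cols = c("country", "year"),
    names_from = c("measure", "source_category"),
    names_sep = "_",
    values_from = "value"
  )

  # terrestrial-animal / vegetable quotient, per country-year, then
  # aggregated like any other column; division by zero yields NA and the
  # country falls out in the complete-case step
  for (m in diet_measures) {
    ta <- wide[[paste(m, "terrestrial_animal", sep = "_")]]
    veg <- wide[[paste(m, "vegetable", sep = "_")]]
    wide[[paste(m, "ta_veg_ratio", sep = "_")]] <-
      ifelse(is.finite(veg) & veg != 0, ta / veg, NA_real_)
  }

  nutr_cols <- covariate_names("nutritional")
  missing_cols <- setdiff(nutr_cols, names(wide))
  if (length(missing_cols) > 0L) {
    stopf("intake profile lacks source categories needed for column(s): %s",
          paste(missing_cols, collapse = ", "))
  }

  nutr <- period_aggregate(wide, nutr_cols, period, mode)
  ctrl <- period_aggregate(socio, control_names, period, mode)

  shared <- intersect(nutr$country, ctrl$country)
  if (length(shared) == 0L) {
    stopf("no countries shared between intake and socioeconomic tables")
  }
  panel <- dplyr::inner_join(nutr, ctrl, by = "country")
  panel <- panel[c("country", covariate_names())]

  complete <- stats::complete.cases(panel)
  if (any(!complete)) {
    msgf("assemble_covariates: dropping %d countr%s with incomplete covariates: %s",
         sum(!complete), if (sum(!complete) > 1) "ies" else "y",
         paste(panel$country[!complete], collapse = ", "))
    panel <- panel[complete, , drop = FALSE]
  }
  if (nrow(panel) == 0L) stopf("no complete-case countries remain")

  structure(
    as_tibble(panel),
    period = range(period),
    mode = mode,
    nutritional_cols = nutr_cols,
    control_cols = control_names,
    class = c("covariate_panel", class(as_tibble(panel)))
  )
}

#' One-call synthetic covariate panel
#'
#' Convenience wrapper chaining [generate_food_panel()],
#' [merge_concentrations()], [compute_intake_profile()] and
#' [assemble_covariates()] over the full configured year range.
#'
#' @param config A [synthetic_config()].
#' @param mode Aggregation mode passed to [assemble_covariates()].
#' @return A `covariate_panel`.
#' @export
simulate_panel <- function(config, mode = "mean") {
  gen <- generate_food_panel(config)
  conc <- merge_concentrations(gen$concentrations)
  prof <- compute_intake_profile(gen$intake, conc)
  assemble_covariates(prof, gen$socio, config$years, mode)
}
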