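#' Configuration for the synthetic country-panel generator
#'
#' Defines the study conditions a generated panel emulates: how many
#' countries and years, how many food groups each source category carries,
#' how strongly the dietary covariates of one source co-vary across
#' countries (`block_correlation`), which covariates carry true effects on
#' the simulated outcome, and the outcome noise level.
#'
#' Within each source category, per-country food-group intakes follow a
#' latent-factor model: one standard-normal "diet expansion" factor per
#' country and source drives all groups of that source (with group-specific
#' loadings), on top of idiosyncratic country-by-group and year-by-year
#' log-normal noise and a country-specific time trend. Groups whose intake
#' responds most to the expansion factor are parameterized as the most
#' N-rich and P-poor of their source, so the N:P intake ratio co-varies
#' with the other five measures of its source rather than being pure noise.
#' The alcoholic source is a single beverage group (litres taken as kg 1:1),
#' mirroring analyses that treat total alcohol consumption as one quantity.
#'
#' @param n_countries Number of countries (positive integer).
#' @param years Inclusive integer vector of years, e.g. `1960:2010`.
#' @param n_food_groups_per_source Food groups per multi-group source
#'   (terrestrial-animal, vegetable, aquatic-animal); the alcoholic source
#'   always has one group.
#' @param block_correlation Real in `[0, 1)`: the share of cross-country
#'   log-intake variance carried by the per-source latent factor, hence the
#'   approximate pairwise correlation of the six covariates within a source.
#' @param true_effects Named numeric vector of true outcome effects, in SD
#'   units of the named covariates (see [covariate_names()]); sparse.
#' @param noise_sd Standard deviation of the Gaussian outcome noise
#'   (non-negative).
#' @param age_groups Data frame with columns `age_group` and `share`
#'   (population shares summing to 1); defaults to the shares of the WHO
#'   world standard population.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   tables.
#' @param intake_log_sd Total cross-country SD of log intake per food group.
#' @param loading_spread Relative spread of factor loadings across the food
#'   groups of a source (0 = identical loadings).
#' @param year_sd SD of the year-to-year log-intake noise.
#' @param trend_mean,trend_sd Mean and SD (across country-source pairs) of
#'   the full-period log-intake trend, so intakes drift over the decades and
#'   period-change analyses have signal.
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_food_panel()], [generate_responses()]
#' @export
synthetic_config <- function(n_countries = 40,
                             years = 1960:2010,
                             n_food_groups_per_source = 6,
                             block_correlation = 0.85,
                             true_effects = c(N_terrestrial_animal = 0),
                             noise_sd = 1,
                             age_groups = NULL,
                             seed = 1L,
                             intake_log_sd = 0.5,
                             loading_spread = 1.05,
                             year_sd = 0.08,
                             trend_mean = 0.3,
                             trend_sd = 0.12) {
  if (!is_count(n_countries)) {
    stopf("configuration error: 'n_countries' must be a positive integer")
  }
  if (length(years) == 0L || !is.numeric(years) || any(years != trunc(years))) {
    stopf("configuration error: 'years' must be a non-empty integer range")
  }
  if (!is_count(n_food_groups_per_source)) {
    stopf("configuration error: 'n_food_groups_per_source' must be a positive integer")
  }
  if (!is.numeric(block_correlation) || length(block_correlation) != 1L ||
      block_correlation < 0 || block_correlation >= 1) {
    stopf("configuration error: 'block_correlation' must lie in [0, 1)")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stopf("configuration error: 'noise_sd' must be non-negative")
  }
  if (length(true_effects) > 0L) {
    if (is.null(names(true_effects)) || any(!nzchar(names(true_effects)))) {
      stopf("configuration error: 'true_effects' must be a named numeric vector")
    }
    unknown <- setdiff(names(true_effects), covariate_names())
    if (length(unknown) > 0L) {
      stopf("configuration error: 'true_effects' names not in the covariate set: %s",
            paste(unknown, collapse = ", "))
    }
  }
  if (is.null(age_groups)) {
    std <- world_standard_population()
    age_groups <- tibble(age_group = std$age_group, share = std$weight)
  }
  assert_cols(age_groups, c("age_group", "share"), "'age_groups'")
  if (abs(sum(age_groups$share) - 1) > 1e-9) {
    stopf("configuration error: 'age_groups' shares must sum to 1")
  }
  structure(
    list(
      n_countries = as.integer(n_countries),
      years = as.integer(sort(years)),
      n_food_groups_per_source = as.integer(n_food_groups_per_source),
      source_categories = intake_sources,
      block_correlation = block_correlation,
      true_effects = true_effects,
      noise_sd = noise_sd,
      age_groups = as_tibble(age_groups),
      seed = as.integer(seed),
      intake_log_sd = intake_log_sd,
      loading_spread = loading_spread,
      year_sd = year_sd,
      trend_mean = trend_mean,
      trend_sd = trend_sd
    ),
    class = "synthetic_config"
  )
}

# food-group parameters (base intake, factor loading, nutrient content)
# deterministic given the RNG state in force when called
group_parameters <- function(config) {
  G <- config$n_food_groups_per_source
  rho <- config$block_correlation
  v <- config$intake_log_sd
  spread <- config$loading_spread

  one_source <- function(source, mu_log, n_lo, n_hi, p_hi, p_lo,
                         kcal_lo, kcal_hi, ng) {
    u <- if (ng > 1L) seq(-1, 1, length.out = ng) else 0
    half <- (u + 1) / 2
    tibble(
      source_category = source,
      food_group = sprintf("%s_g%02d", source, seq_len(ng)),
      u = u,
      # heavy-tailed base intakes: a few groups dominate each aggregate, so
      # group-level noise does not average out of the six source totals
      mu = exp(mu_log + 0.25 * rnorm(ng)),
      alpha = v * sqrt(rho) * (1 + spread * u),
      sigma = v * sqrt((1 - rho) * 1.2),
      # N rises and P falls along the loading axis: expansion-sensitive
      # groups are protein/N-rich and P-poor, which couples N:P to the factor
      n_conc = n_lo + (n_hi - n_lo) * half + runif(ng, -0.02, 0.02) * (n_hi - n_lo),
      p_conc = p_hi + (p_lo - p_hi) * half + runif(ng, -0.02, 0.02) * (p_hi - p_lo),
      kcal_conc = runif(ng, kcal_lo, kcal_hi)
    )
  }

  pars <- dplyr::bind_rows(
    one_source("terrestrial_animal", log(18), 12, 45, 7.0, 0.5, 800, 3500, G),
    one_source("vegetable", log(55), 1.0, 12, 3.5, 0.2, 250, 2500, G),
    one_source("aquatic_animal", log(8), 15, 40, 8.0, 0.8, 700, 2200, G),
    one_source("alcoholic", log(55), 0.7, 0.7, 0.14, 0.14, 500, 700, 1L)
  )
  pars$protein_conc <- pars$n_conc * 6.25 * runif(nrow(pars), 0.98, 1.02)
  pars
}

#' Generate a synthetic food-intake panel with companion tables
#'
#' Produces the three tables the intake pipeline consumes: a long
#' food-intake table (country x year x food group), two
#' nutrient-concentration tables whose group-level values are jittered
#' around a common mean (to exercise multi-database averaging), and a
#' socioeconomic table (GDP per capita, HDI, median age, life expectancy
#' per country-year). Output is bit-identical for identical configurations.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `intake`, `concentrations` (list of two
#'   tibbles tagged by `database_id`), `socio`, and `config`.
#' @export
#' @examples
#' panel <- generate_food_panel(synthetic_config(n_countries = 10, years = 2000:2005))
#' head(panel$intake)
generate_food_panel <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stopf("'config' must be created by synthetic_config()")
  }
  C <- config$n_countries
  years <- config$years
  Y <- length(years)

  withr::with_seed(config$seed, {
    pars <- group_parameters(config)
    G <- nrow(pars)
    countries <- sprintf("country_%02d", seq_len(C))
    src_idx <- match(pars$source_category, intake_sources)

    f <- matrix(rnorm(C * 4L), C, 4L)                       # latent factors
    trend <- matrix(rnorm(C * 4L, config$trend_mean, config$trend_sd), C, 4L)
    e_cg <- matrix(rnorm(C * G), C, G)                      # country x group

    tt <- if (Y > 1L) (years - years[1L]) / (years[Y] - years[1L]) - 0.5 else 0

    # index order: country fastest, then group, then year
    ci <- rep(seq_len(C), times = G * Y)
    gi <- rep(rep(seq_len(G), each = C), times = Y)
    yi <- rep(seq_len(Y), each = C * G)
    si <- src_idx[gi]

    log_intake <- log(pars$mu[gi]) +
      pars$alpha[gi] * f[cbind(ci, si)] +
      pars$sigma[gi] * e_cg[cbind(ci, gi)] +
      trend[cbind(ci, si)] * tt[yi] +
      config$year_sd * rnorm(length(ci))

    intake <- tibble(
      country = countries[ci],
      year = years[yi],
      food_group = pars$food_group[gi],
      source_category = pars$source_category[gi],
      intake_kg = exp(log_intake)
    )

    jitter_tab <- function(db) {
      n <- nrow(pars)
      tibble(
        food_group = pars$food_group,
        n_g_per_kg = pars$n_conc * (1 + runif(n, -0.05, 0.05)),
        p_g_per_kg = pars$p_conc * (1 + runif(n, -0.05, 0.05)),
        protein_g_per_kg = pars$protein_conc * (1 + runif(n, -0.05, 0.05)),
        kcal_per_kg = pars$kcal_conc * (1 + runif(n, -0.05, 0.05)),
        database_id = db
      )
    }
    concentrations <- list(jitter_tab("db_A"), jitter_tab("db_B"))

    d <- rowMeans(f)                                        # development score
    gdp_base <- exp(log(12000) + 0.5 * d + 0.6 * rnorm(C))
    hdi_base <- 0.7 + 0.9 * d + 0.5 * rnorm(C)
    age_base <- 24 + 3 * d + 2 * rnorm(C)
    le_base <- 52 + 18 * plogis(0.5 * d + 0.5 * rnorm(C))

    sci <- rep(seq_len(C), times = Y)
    syi <- rep(seq_len(Y), each = C)
    t01 <- tt[syi] + 0.5
    socio <- tibble(
      country = countries[sci],
      year = years[syi],
      gdp_per_capita = gdp_base[sci] * exp(1.0 * t01 + 0.02 * rnorm(C * Y)),
      hdi = plogis(hdi_base[sci] + 1.2 * t01 + 0.03 * rnorm(C * Y)),
      median_age = age_base[sci] + 8 * t01 + 0.3 * rnorm(C * Y),
      life_expectancy = pmin(86, le_base[sci] + 14 * t01 + 0.5 * rnorm(C * Y))
    )

    list(intake = intake, concentrations = concentrations,
         socio = socio, config = config)
  })
}

#' Generate synthetic responses with a known sparse linear truth
#'
#' Draws a country-level response as `intercept + sum(beta_j * z_j) +
#' N(0, noise_sd)` where `z_j` are the standardized covariate columns named
#' in `config$true_effects`. Effects are therefore in SD units and recovery
#' thresholds are scale-free.
#'
#' @param panel A covariate panel from [assemble_covariates()].
#' @param config The [synthetic_config()] holding `true_effects`, `noise_sd`
#'   and the seed (the response stream is offset from the intake stream so
#'   the two are independent).
#' @param response_name Column name for the response, also used as its label
#'   (e.g. `"prevalence_total"`, `"mortality_breast"`, `"le_increase"`).
#' @param intercept Baseline level of the response.
#' @return A list: `responses` (tibble `country`, `<response_name>`) and
#'   `truth` (class `synthetic_truth`: the exact coefficients, the per-country
#'   linear predictor and the seed used).
#' @export
generate_responses <- function(panel, config, response_name = "response",
                               intercept = 100) {
  if (!inherits(config, "synthetic_config")) {
    stopf("'config' must be created by synthetic_config()")
  }
  effects <- config$true_effects
  unmatched <- setdiff(names(effects), names(panel))
  if (length(unmatched) > 0L) {
    stopf("true_effects name covariates absent from the panel: %s",
          paste(unmatched, collapse = ", "))
  }
  lp <- rep(intercept, nrow(panel))
  for (nm in names(effects)) {
    x <- panel[[nm]]
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      stopf("covariate '%s' has zero variance; cannot carry an effect", nm)
    }
    lp <- lp + effects[[nm]] * (x - mean(x)) / s
  }
  y <- withr::with_seed(config$seed + 1L,
                        lp + rnorm(nrow(panel), 0, config$noise_sd))
  responses <- tibble(country = panel$country, !!response_name := y)
  truth <- structure(
    list(true_effects = effects, linear_predictor = setNames(lp, panel$country),
         response_name = response_name, seed = config$seed),
    class = "synthetic_truth"
  )
  list(responses = responses, truth = truth)
}

#' Draw Poisson death counts from age-specific rates
#'
#' Emulates a raw mortality database: given age-specific rates per 100,000
#' and population sizes, deaths are drawn independently as
#' `Poisson(rate * population / 1e5)` per row.
#'
#' @param rates_by_age Data frame with an `age_group` column, a `rate`
#'   column (per 100,000), and any identifying columns (country, year,
#'   cause) shared with `population_by_age`.
#' @param population_by_age Data frame with the same keys and a
#'   `population` column.
#' @param seed Integer seed for the draws.
#' @return A mortality tibble: the shared keys plus `age_group`, `deaths`
#'   and `population`.
#' @export
generate_mortality_counts <- function(rates_by_age, population_by_age, seed) {
  assert_cols(rates_by_age, c("age_group", "rate"), "'rates_by_age'")
  assert_cols(population_by_age, c("age_group", "population"),
              "'population_by_age'")
  if (any(rates_by_age$rate < 0)) {
    stopf("negative rate(s) in 'rates_by_age'")
  }
  if (any(population_by_age$population <= 0)) {
    stopf("non-positive population(s) in 'population_by_age'")
  }
  mism <- union(setdiff(unique(rates_by_age$age_group),
                        unique(population_by_age$age_group)),
                setdiff(unique(population_by_age$age_group),
                        unique(rates_by_age$age_group)))
  if (length(mism) > 0L) {
    stopf("age group(s) present in only one table: %s",
          paste(mism, collapse = ", "))
  }
  keys <- intersect(names(rates_by_age), names(population_by_age))
  joined <- dplyr::inner_join(rates_by_age, population_by_age, by = keys)
  if (nrow(joined) == 0L) {
    stopf("no rows shared between rate and population tables")
  }
  joined$deaths <- withr::with_seed(
    seed, rpois(nrow(joined), joined$rate * joined$population / 1e5)
  )
  dplyr::select(joined, dplyr::all_of(keys), "deaths", "population")
}
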