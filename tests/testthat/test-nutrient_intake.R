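test_that("concentrations are averaged across databases, per nutrient", {
  t1 <- tibble::tibble(food_group = "beef", n_g_per_kg = 20, p_g_per_kg = 2,
                       protein_g_per_kg = 120, kcal_per_kg = 2000,
                       database_id = "a")
  t2 <- dplyr::mutate(t1, n_g_per_kg = 24, database_id = "b")
  expect_equal(mean_concentration("beef", list(t1, t2))$n_g_per_kg, 22)
  expect_equal(mean_concentration("beef", list(t1, t2))$p_g_per_kg, 2)

  # single-database group passes through unchanged
  expect_equal(mean_concentration("beef", list(t1))$n_g_per_kg, 20)
  expect_error(mean_concentration("pork", list(t1, t2)), "pork")
})

test_that("multi-database averaging matches an independent sum/count oracle", {
  groups <- c("g1", "g2", "g3", "g4")
  tables <- lapply(1:5, function(i) rand_conc_table(groups, paste0("db", i),
                                                    seed = 100 + i))
  merged <- merge_concentrations(tables)
  for (g in groups) {
    for (col in c("n_g_per_kg", "p_g_per_kg", "protein_g_per_kg",
                  "kcal_per_kg")) {
      acc <- 0; cnt <- 0
      for (tb in tables) {
        for (i in seq_len(nrow(tb))) {
          if (tb$food_group[i] == g) { acc <- acc + tb[[col]][i]; cnt <- cnt + 1 }
        }
      }
      expect_equal(merged[[col]][merged$food_group == g], acc / cnt,
                   tolerance = 1e-12)
    }
  }
})

test_that("intake profile applies the intake x concentration formula", {
  intake <- tibble::tibble(country = "A", year = 2000, food_group = "beef",
                           source_category = "terrestrial_animal",
                           intake_kg = 50)
  conc <- tibble::tibble(food_group = "beef", n_g_per_kg = 30, p_g_per_kg = 3,
                         protein_g_per_kg = 180, kcal_per_kg = 2500,
                         database_id = "a")
  prof <- compute_intake_profile(intake, conc)
  expect_equal(prof$n_kg, 1.5)       # 50 kg * 30 g/kg / 1000
  expect_equal(prof$p_kg, 0.15)
  expect_equal(prof$np_ratio, 10)
  expect_equal(prof$protein_kg, 9)
  expect_equal(prof$kcal, 125000)
  expect_equal(prof$total_kg, 50)

  zero <- compute_intake_profile(dplyr::mutate(intake, intake_kg = 0), conc)
  expect_equal(zero$n_kg, 0)
  expect_equal(zero$total_kg, 0)
  expect_true(is.na(zero$np_ratio))  # undefined N:P at zero P
})

test_that("profile accumulation matches a per-row loop oracle", {
  groups <- c("g1", "g2", "g3", "g4", "g5", "g6")
  sources <- rep(c("terrestrial_animal", "vegetable"), each = 3)
  intake <- rand_intake_table(c("A", "B"), 2000:2001, groups, sources,
                              seed = 42)
  conc <- rand_conc_table(groups, "db", seed = 43)
  prof <- compute_intake_profile(intake, conc)
  for (i in seq_len(nrow(prof))) {
    rows <- intake[intake$country == prof$country[i] &
                     intake$year == prof$year[i] &
                     intake$source_category == prof$source_category[i], ]
    n <- p <- pr <- kc <- tot <- 0
    for (j in seq_len(nrow(rows))) {
      cc <- conc[conc$food_group == rows$food_group[j], ]
      n <- n + rows$intake_kg[j] * cc$n_g_per_kg / 1000
      p <- p + rows$intake_kg[j] * cc$p_g_per_kg / 1000
      pr <- pr + rows$intake_kg[j] * cc$protein_g_per_kg / 1000
      kc <- kc + rows$intake_kg[j] * cc$kcal_per_kg
      tot <- tot + rows$intake_kg[j]
    }
    expect_equal(prof$n_kg[i], n, tolerance = 1e-12)
    expect_equal(prof$p_kg[i], p, tolerance = 1e-12)
    expect_equal(prof$protein_kg[i], pr, tolerance = 1e-12)
    expect_equal(prof$kcal[i], kc, tolerance = 1e-12)
    expect_equal(prof$total_kg[i], tot, tolerance = 1e-12)
    expect_equal(prof$np_ratio[i] * prof$p_kg[i], prof$n_kg[i],
                 tolerance = 1e-9)
  }
})

test_that("profile validation rejects malformed inputs", {
  intake <- tibble::tibble(country = "A", year = 2000, food_group = "beef",
                           source_category = "terrestrial_animal",
                           intake_kg = 50)
  conc <- rand_conc_table("fish", "db", seed = 1)
  expect_error(compute_intake_profile(intake, conc), "beef")
  expect_error(
    compute_intake_profile(dplyr::mutate(intake, intake_kg = -1),
                           rand_conc_table("beef", "db", 1)),
    "negative"
  )
  dup <- dplyr::bind_rows(intake, intake)
  expect_error(compute_intake_profile(dup, rand_conc_table("beef", "db", 1)),
               "duplicate")
})

test_that("profiles are additive over disjoint tables and scale-equivariant", {
  groups <- paste0("g", 1:6)
  sources <- rep(c("terrestrial_animal", "vegetable", "aquatic_animal"), 2)
  conc <- rand_conc_table(groups, "db", seed = 9)
  tab1 <- rand_intake_table("A", 2000, groups[1:3], sources[1:3], seed = 10)
  tab2 <- rand_intake_table("A", 2000, groups[4:6], sources[4:6], seed = 11)
  both <- compute_intake_profile(dplyr::bind_rows(tab1, tab2), conc)
  p1 <- compute_intake_profile(tab1, conc)
  p2 <- compute_intake_profile(tab2, conc)
  added <- dplyr::full_join(p1, p2, by = c("country", "year", "source_category"))
  for (col in c("n_kg", "p_kg", "protein_kg", "kcal", "total_kg")) {
    sum2 <- rowSums(cbind(added[[paste0(col, ".x")]],
                          added[[paste0(col, ".y")]]), na.rm = TRUE)
    merged <- both[[col]][match(paste(added$country, added$source_category),
                                paste(both$country, both$source_category))]
    expect_equal(merged, sum2, tolerance = 1e-12)
  }

  doubled <- compute_intake_profile(
    dplyr::mutate(tab1, intake_kg = 2 * intake_kg), conc)
  expect_equal(doubled$n_kg, 2 * p1$n_kg, tolerance = 1e-12)
  expect_equal(doubled$kcal, 2 * p1$kcal, tolerance = 1e-12)
  expect_equal(doubled$np_ratio, p1$np_ratio, tolerance = 1e-12)
})

test_that("period aggregation has exact mean and decade-change semantics", {
  const <- tidyr::expand_grid(country = c("A", "B"), year = 1960:2010)
  const$v <- 7
  m <- period_aggregate(const, "v", 1960:2010, "mean")
  expect_equal(m$v, c(7, 7))
  ch <- period_aggregate(const, "v", 1960:2010, "change")
  expect_equal(ch$v, c(0, 0))

  # 1960s mean 10, 2000s mean 25 -> change 15
  steps <- tibble::tibble(country = "A", year = 1960:2010,
                          v = ifelse(1960:2010 <= 1969, 10,
                                     ifelse(1960:2010 >= 2001, 25, 99)))
  expect_equal(period_aggregate(steps, "v", 1960:2010, "change")$v, 15)
})

test_that("period aggregation matches a brute-force groupby oracle", {
  set.seed(21)
  df <- tidyr::expand_grid(country = c("A", "B", "C"), year = 1960:2010)
  df$v <- rnorm(nrow(df))
  m <- period_aggregate(df, "v", 1970:2000, "mean")
  ch <- period_aggregate(df, "v", 1960:2010, "change")
  for (cn in c("A", "B", "C")) {
    sub <- df[df$country == cn, ]
    expect_equal(m$v[m$country == cn],
                 mean(sub$v[sub$year >= 1970 & sub$year <= 2000]),
                 tolerance = 1e-12)
    expect_equal(ch$v[ch$country == cn],
                 mean(sub$v[sub$year >= 2001]) -
                   mean(sub$v[sub$year <= 1969]),
                 tolerance = 1e-12)
  }
  # a country absent from a referenced decade is dropped with a message
  gap <- df[!(df$country == "A" & df$year <= 1975), ]
  expect_message(out <- period_aggregate(gap, "v", 1960:2010, "change"), "A")
  expect_setequal(out$country, c("B", "C"))
})

test_that("the assembled panel always carries the 33 explanatory columns", {
  cfg <- synthetic_config(n_countries = 15, years = 1960:2010, seed = 4)
  for (mode in c("mean", "change")) {
    panel <- simulate_panel(cfg, mode = mode)
    expect_identical(setdiff(names(panel), "country"), covariate_names())
    expect_length(setdiff(names(panel), "country"), 33L)
    expect_false(anyNA(panel))
  }
})

test_that("ratio columns are elementwise terrestrial-animal over vegetable", {
  prof <- tibble::tibble(
    country = "A", year = 2000,
    source_category = c("terrestrial_animal", "vegetable", "aquatic_animal",
                        "alcoholic"),
    n_kg = c(2, 1, 0.5, 0.01), p_kg = c(0.4, 0.2, 0.1, 0.002),
    np_ratio = c(5, 5, 5, 5), protein_kg = c(12, 6, 3, 0.06),
    kcal = c(1e5, 8e5, 5e4, 3e4), total_kg = c(80, 300, 20, 50)
  )
  socio <- tibble::tibble(country = "A", year = 2000, gdp_per_capita = 2e4,
                          median_age = 38, hdi = 0.9, life_expectancy = 80)
  panel <- assemble_covariates(prof, socio, 2000, "mean")
  expect_equal(panel$N_ta_veg_ratio, 2)
  expect_equal(panel$total_kg_ta_veg_ratio, 80 / 300)
  expect_equal(panel$gdp_per_capita, 2e4)
})

test_that("constant-in-time inputs give all-zero nutritional changes", {
  cfg <- synthetic_config(n_countries = 6, years = 1960:2010, seed = 30,
                          year_sd = 0, trend_mean = 0, trend_sd = 0)
  panel <- simulate_panel(cfg, mode = "change")
  nutr <- as.matrix(as.data.frame(panel)[covariate_names("nutritional")])
  expect_lt(max(abs(nutr)), 1e-10)
})

test_that("countries with a zero vegetable denominator are dropped loudly", {
  prof <- tidyr::expand_grid(
    country = c("A", "B"), year = 2000,
    source_category = c("terrestrial_animal", "vegetable", "aquatic_animal",
                        "alcoholic")
  )
  prof <- dplyr::mutate(prof, n_kg = 1, p_kg = 0.2, np_ratio = 5,
                        protein_kg = 6, kcal = 1e5, total_kg = 100)
  prof$total_kg[prof$country == "B" & prof$source_category == "vegetable"] <- 0
  prof$n_kg[prof$country == "B" & prof$source_category == "vegetable"] <- 0
  prof$p_kg[prof$country == "B" & prof$source_category == "vegetable"] <- 0
  prof$np_ratio[prof$country == "B" & prof$source_category == "vegetable"] <- NA
  prof$protein_kg[prof$country == "B" & prof$source_category == "vegetable"] <- 0
  prof$kcal[prof$country == "B" & prof$source_category == "vegetable"] <- 0
  socio <- tibble::tibble(country = c("A", "B"), year = 2000,
                          gdp_per_capita = 2e4, median_age = 38, hdi = 0.9)
  expect_message(panel <- assemble_covariates(prof, socio, 2000, "mean"), "B")
  expect_identical(panel$country, "A")
})
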