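# programmatic fixtures and small independent oracles shared across tests

rand_conc_table <- function(groups, db, seed) {
  withr::with_seed(seed, tibble::tibble(
    food_group = groups,
    n_g_per_kg = runif(length(groups), 1, 40),
    p_g_per_kg = runif(length(groups), 0.2, 8),
    protein_g_per_kg = runif(length(groups), 10, 250),
    kcal_per_kg = runif(length(groups), 300, 3000),
    database_id = db
  ))
}

rand_intake_table <- function(countries, years, groups, sources, seed) {
  grid <- expand.grid(country = countries, year = years, food_group = groups,
                      stringsAsFactors = FALSE)
  grid$source_category <- sources[match(grid$food_group, groups)]
  withr::with_seed(seed, {
    grid$intake_kg <- runif(nrow(grid), 0, 80)
  })
  tibble::as_tibble(grid)
}

# adjusted Rand index between two labelings (contingency-table formula)
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  e <- si * sj / n2
  (sij - e) / ((si + sj) / 2 - e)
}

# ground-truth block of each panel covariate = its source suffix
true_block <- function(covariates) {
  sub("^(N|P|NP|kcal|protein|total_kg)_", "", covariates)
}

# panel columns of one source, dropping degenerate ones
source_cols <- function(panel, source) {
  cols <- grep(paste0("_", source, "$"), covariate_names("nutritional"),
               value = TRUE)
  X <- as.matrix(as.data.frame(panel)[cols])
  X[, apply(X, 2L, stats::sd) > 1e-10, drop = FALSE]
}

cluster_panel <- function(panel) {
  nutr <- covariate_names("nutritional")
  X <- as.matrix(as.data.frame(panel)[nutr])
  X <- X[, apply(X, 2L, stats::sd) > 1e-10, drop = FALSE]
  cluster_covariates(covariate_distance(X))
}

# block-structured covariate matrix with a shared latent per block
make_block_matrix <- function(n, blocks, r_within, seed) {
  # blocks: named list block -> number of variables
  withr::with_seed(seed, {
    cols <- list()
    for (b in names(blocks)) {
      f <- rnorm(n)
      for (i in seq_len(blocks[[b]])) {
        cols[[paste0(b, "_v", i)]] <-
          sqrt(r_within) * f + sqrt(1 - r_within) * rnorm(n)
      }
    }
    do.call(cbind, cols)
  })
}
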