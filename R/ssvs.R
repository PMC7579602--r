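#' Configuration of the spike-and-slab (SSVS) sampler
#'
#' Hyperparameters of the two-component Gaussian mixture prior of
#' stochastic search variable selection: each coefficient is a priori
#' `N(0, spike_sd^2)` when excluded and `N(0, slab_sd^2)` when included,
#' with a Bernoulli(`prior_inclusion`) indicator per regressor and an
#' inverse-gamma prior on the residual variance. Defaults are set for
#' standardized regressors and a standardized response: a spike of 0.01
#' (effectively zero on the SD scale), a diffuse slab of 10, even prior
#' inclusion odds, and a vague variance prior.
#'
#' @param spike_sd Prior SD of an excluded coefficient (small, > 0).
#' @param slab_sd Prior SD of an included coefficient (must exceed
#'   `spike_sd`).
#' @param prior_inclusion Prior inclusion probability in (0, 1).
#' @param sigma_shape,sigma_rate Shape and rate of the inverse-gamma prior
#'   on the residual variance.
#' @param n_draws Total Gibbs iterations (including burn-in).
#' @param n_burn Burn-in iterations discarded (< `n_draws`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param level Credible level for the reported equal-tailed intervals.
#' @param seed Integer seed; fixed seed gives identical draws.
#' @return An object of class `ssvs_config`.
#' @export
ssvs_config <- function(spike_sd = 0.01, slab_sd = 10, prior_inclusion = 0.5,
                        sigma_shape = 0.01, sigma_rate = 0.01,
                        n_draws = 20000L, n_burn = 5000L, thin = 5L,
                        level = 0.95, seed = 1L) {
  if (!(spike_sd > 0 && slab_sd > spike_sd)) {
    stopf("configuration error: need slab_sd > spike_sd > 0")
  }
  if (!(prior_inclusion > 0 && prior_inclusion < 1)) {
    stopf("configuration error: 'prior_inclusion' must lie in (0, 1)")
  }
  if (!(sigma_shape > 0 && sigma_rate > 0)) {
    stopf("configuration error: variance prior shape/rate must be positive")
  }
  if (!is_count(n_draws) || !is_count(thin) ||
      !(is_count(n_burn) || n_burn == 0) || n_burn >= n_draws) {
    stopf("configuration error: need positive integer draws with n_draws > n_burn")
  }
  if (!(level > 0 && level < 1)) stopf("configuration error: 'level' must lie in (0, 1)")
  structure(
    list(spike_sd = spike_sd, slab_sd = slab_sd,
         prior_inclusion = prior_inclusion, sigma_shape = sigma_shape,
         sigma_rate = sigma_rate, n_draws = as.integer(n_draws),
         n_burn = as.integer(n_burn), thin = as.integer(thin),
         level = level, seed = as.integer(seed)),
    class = "ssvs_config"
  )
}

#' Fit a regression with the SSVS spike-and-slab prior
#'
#' Gibbs sampler for `y = X beta + e`, `e ~ N(0, sigma2 I)`, with the
#' George–McCulloch two-component normal mixture prior on each
#' coefficient. One sweep draws (a) `beta` jointly from its conjugate
#' Gaussian full conditional given the inclusion indicators and `sigma2`,
#' (b) each indicator from its Bernoulli full conditional given `beta`
#' (computed in log space for numerical safety), and (c) `sigma2` from its
#' inverse-gamma full conditional. Regressors are standardized and the
#' response centered internally by default, so coefficients are on the
#' per-SD scale.
#'
#' @param X Numeric regressor matrix (rows >= 10; named columns
#'   recommended).
#' @param y Numeric response vector.
#' @param config An [ssvs_config()].
#' @param standardize Standardize columns of `X` and center `y` before
#'   sampling (default `TRUE`).
#' @param force_include Fix all inclusion indicators at 1 (no spike); with
#'   `fix_sigma2` this makes the sampler draw from the exact ridge
#'   posterior, which is useful for validation.
#' @param fix_sigma2 Optional fixed residual variance (disables step (c)).
#' @return An object of class `ssvs_posterior`: `draws` (list of `beta`
#'   matrix, `gamma` matrix, `sigma2` vector over kept iterations),
#'   `summary` tibble (term, median, lower, upper, inclusion, significant),
#'   the config and the standardization constants.
#' @export
fit_ssvs <- function(X, y, config = ssvs_config(), standardize = TRUE,
                     force_include = FALSE, fix_sigma2 = NULL) {
  if (!inherits(config, "ssvs_config")) stopf("'config' must be an ssvs_config()")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stopf("length(y) must equal nrow(X)")
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stopf("non-finite values in X or y")
  }
  n <- nrow(X); p <- ncol(X)
  if (n < 10L) stopf("at least 10 observations are required")

  x_center <- rep(0, p); x_scale <- rep(1, p); y_center <- 0
  if (standardize) {
    std <- standardize_matrix(X)
    X <- std$x; x_center <- std$center; x_scale <- std$scale
    y_center <- mean(y); y <- y - y_center
  }

  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  tau0sq <- config$spike_sd^2
  tau1sq <- config$slab_sd^2
  log_prior_odds <- log(config$prior_inclusion) - log(1 - config$prior_inclusion)

  keep_iters <- seq.int(config$n_burn + 1L, config$n_draws, by = config$thin)
  n_keep <- length(keep_iters)
  beta_draws <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  gamma_draws <- matrix(NA_integer_, n_keep, p, dimnames = list(NULL, colnames(X)))
  sigma2_draws <- numeric(n_keep)

  withr::with_seed(config$seed, {
    gamma <- rep(1L, p)
    sigma2 <- fix_sigma2 %||% max(stats::var(y), 1e-6)
    beta <- rep(0, p)
    slot <- 1L
    for (it in seq_len(config$n_draws)) {
      # (a) beta | gamma, sigma2
      prior_prec <- ifelse(gamma == 1L, 1 / tau1sq, 1 / tau0sq)
      A <- XtX / sigma2 + diag(prior_prec, p)
      R <- chol(A)
      m <- backsolve(R, forwardsolve(t(R), Xty / sigma2))
      beta <- drop(m + backsolve(R, rnorm(p)))
      # (b) gamma | beta  (log-space Bernoulli posterior)
      if (!force_include) {
        logit <- log_prior_odds +
          dnorm(beta, 0, config$slab_sd, log = TRUE) -
          dnorm(beta, 0, config$spike_sd, log = TRUE)
        gamma <- rbinom(p, 1L, plogis(logit))
      }
      # (c) sigma2 | beta
      if (is.null(fix_sigma2)) {
        rss <- sum((y - drop(X %*% beta))^2)
        sigma2 <- 1 / rgamma(1, config$sigma_shape + n / 2,
                             rate = config$sigma_rate + rss / 2)
      }
      if (slot <= n_keep && it == keep_iters[slot]) {
        beta_draws[slot, ] <- beta
        gamma_draws[slot, ] <- gamma
        sigma2_draws[slot] <- sigma2
        slot <- slot + 1L
      }
    }
  })

  structure(
    list(
      draws = list(beta = beta_draws, gamma = gamma_draws,
                   sigma2 = sigma2_draws),
      summary = summarize_draws(beta_draws, gamma_draws, config$level),
      config = config, n = n,
      x_center = x_center, x_scale = setNames(x_scale, colnames(X)),
      y_center = y_center
    ),
    class = "ssvs_posterior"
  )
}

summarize_draws <- function(beta_draws, gamma_draws, level) {
  alpha <- (1 - level) / 2
  qs <- apply(beta_draws, 2L, stats::quantile, probs = c(alpha, 0.5, 1 - alpha),
              names = FALSE)
  tibble(
    term = colnames(beta_draws),
    median = unname(qs[2L, ]),
    lower = unname(qs[1L, ]),
    upper = unname(qs[3L, ]),
    inclusion = if (is.null(gamma_draws)) NA_real_ else unname(colMeans(gamma_draws)),
    significant = unname(qs[1L, ] > 0 | qs[3L, ] < 0)
  )
}

#' @export
print.ssvs_posterior <- function(x, ...) {
  cat(sprintf("SSVS posterior: %d regressors, %d kept draws (n = %d)\n",
              ncol(x$draws$beta), nrow(x$draws$beta), x$n))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Map factor-level posteriors back to covariates
#'
#' For every kept MCMC draw, the effect of each original covariate is the
#' sum over its cluster's retained factors of loading times factor
#' coefficient; summaries (median, equal-tailed interval, significance) are
#' computed on these mapped draws, so back-mapped uncertainty reflects the
#' joint factor posterior. When the sampler standardized the factor scores,
#' coefficients are rescaled by the stored score SDs so mapped effects are
#' per SD of the original (standardized) covariate. A covariate's
#' `inclusion` is the fraction of draws in which at least one factor of its
#' cluster is included. Control regressors (posterior terms not named in
#' the loadings) pass through unmapped.
#'
#' @param posterior An [fit_ssvs()] result whose regressors include the
#'   factor columns of `factors`.
#' @param factors A `factor_set` from [extract_factors()].
#' @return Tibble: `covariate`, `median`, `lower`, `upper`, `inclusion`,
#'   `significant`, and `mapped` (`FALSE` for pass-through controls).
#' @export
backmap_coefficients <- function(posterior, factors) {
  if (!inherits(posterior, "ssvs_posterior")) stopf("'posterior' must come from fit_ssvs()")
  if (!inherits(factors, "factor_set")) stopf("'factors' must come from extract_factors()")
  terms <- colnames(posterior$draws$beta)
  fac_names <- colnames(factors$loadings)
  missing <- setdiff(fac_names, terms)
  if (length(missing) > 0L) {
    stopf("factor regressor(s) absent from the posterior: %s",
          paste(missing, collapse = ", "))
  }
  level <- posterior$config$level
  alpha <- (1 - level) / 2

  # per-unit-score coefficients (undo the sampler's standardization of scores)
  beta_fac <- sweep(posterior$draws$beta[, fac_names, drop = FALSE], 2L,
                    posterior$x_scale[fac_names], "/")
  mapped <- beta_fac %*% t(factors$loadings)    # draws x covariates

  gamma_fac <- posterior$draws$gamma[, fac_names, drop = FALSE]
  member <- factors$membership
  cov_names <- rownames(factors$loadings)
  cov_inclusion <- vapply(cov_names, function(nm) {
    fset <- fac_names[startsWith(fac_names, sprintf("C%d_", member[[nm]]))]
    mean(apply(gamma_fac[, fset, drop = FALSE] == 1L, 1L, any))
  }, numeric(1))

  qs <- apply(mapped, 2L, stats::quantile, probs = c(alpha, 0.5, 1 - alpha),
              names = FALSE)
  out <- tibble(
    covariate = cov_names,
    median = unname(qs[2L, ]),
    lower = unname(qs[1L, ]),
    upper = unname(qs[3L, ]),
    inclusion = unname(cov_inclusion),
    significant = unname(qs[1L, ] > 0 | qs[3L, ] < 0),
    mapped = TRUE
  )

  controls <- setdiff(terms, fac_names)
  if (length(controls) > 0L) {
    ctrl <- posterior$summary[posterior$summary$term %in% controls, , drop = FALSE]
    out <- dplyr::bind_rows(out, tibble(
      covariate = ctrl$term, median = ctrl$median, lower = ctrl$lower,
      upper = ctrl$upper, inclusion = ctrl$inclusion,
      significant = ctrl$significant, mapped = FALSE
    ))
  }
  out
}

#' Cluster, reduce and fit every response: the full model
#'
#' Runs the whole regression stage on an assembled covariate panel: the
#' nutritional covariates are clustered from their correlation structure
#' ([cluster_covariates()]), summarized by per-cluster principal components
#' ([extract_factors()]), and each response column is regressed on the
#' factor scores plus the socioeconomic controls under the SSVS prior; the
#' factor coefficients are then mapped back to the covariates. Responses
#' are standardized internally, so cell values are per-SD effects.
#' Zero-variance covariates (e.g. a constant N:P column from a
#' single-beverage alcoholic source) are excluded from clustering with a
#' warning and reported as `NA` rows.
#'
#' @param panel A `covariate_panel` from [assemble_covariates()].
#' @param responses Tibble with `country` and one column per response
#'   (e.g. the 6 prevalence, 6 mortality and LE-increase outcomes).
#' @param config An [ssvs_config()]; the seed is advanced by one per
#'   response so response fits are independent but jointly reproducible.
#' @param n_eig Eigenvectors retained per cluster.
#' @return An object of class `ssvs_grid`: tibble with one row per
#'   (covariate, response) holding `median`, `lower`, `upper`, `inclusion`,
#'   `significant`; attributes `partition` and `factors`.
#' @export
run_full_model <- function(panel, responses, config = ssvs_config(),
                           n_eig = 3L) {
  if (!inherits(panel, "covariate_panel")) {
    stopf("'panel' must come from assemble_covariates()")
  }
  assert_cols(responses, "country", "'responses'")
  shared <- intersect(panel$country, responses$country)
  if (length(shared) < 10L) {
    stopf("need at least 10 shared countries (got %d)", length(shared))
  }
  panel <- panel[match(shared, panel$country), , drop = FALSE]
  responses <- responses[match(shared, responses$country), , drop = FALSE]

  nutr_cols <- attr(panel, "nutritional_cols") %||% covariate_names("nutritional")
  ctrl_cols <- attr(panel, "control_cols") %||% covariate_names("controls")
  X_nutr <- as.matrix(as.data.frame(panel)[nutr_cols])
  constant <- constant_columns(X_nutr)
  if (any(constant)) {
    warnf("excluding zero-variance covariate(s) from clustering: %s",
          paste(nutr_cols[constant], collapse = ", "))
  }
  active <- nutr_cols[!constant]

  d <- covariate_distance(X_nutr[, active, drop = FALSE])
  partition <- cluster_covariates(d)
  factors <- extract_factors(X_nutr[, active, drop = FALSE], partition, n_eig)

  X <- cbind(factors$scores, as.matrix(as.data.frame(panel)[ctrl_cols]))
  resp_cols <- setdiff(names(responses), "country")

  grid <- dplyr::bind_rows(lapply(seq_along(resp_cols), function(i) {
    y <- responses[[resp_cols[i]]]
    sy <- stats::sd(y)
    if (!is.finite(sy) || sy <= 0) stopf("response '%s' has zero variance", resp_cols[i])
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    post <- fit_ssvs(X, (y - mean(y)) / sy, cfg_i)
    mapped <- backmap_coefficients(post, factors)
    mapped$response <- resp_cols[i]
    mapped
  }))

  # re-emit excluded covariates as NA rows so the grid always has 33 rows
  if (any(constant)) {
    na_rows <- tidyr::expand_grid(
      covariate = nutr_cols[constant], response = resp_cols
    )
    na_rows$median <- NA_real_; na_rows$lower <- NA_real_
    na_rows$upper <- NA_real_; na_rows$inclusion <- NA_real_
    na_rows$significant <- FALSE; na_rows$mapped <- TRUE
    grid <- dplyr::bind_rows(grid, na_rows)
  }
  all_rows <- c(nutr_cols, ctrl_cols)
  grid$covariate <- factor(grid$covariate, levels = all_rows)
  grid <- dplyr::arrange(grid, .data$response, .data$covariate)
  grid$covariate <- as.character(grid$covariate)

  structure(as_tibble(grid), partition = partition, factors = factors,
            class = c("ssvs_grid", class(as_tibble(grid))))
}

#' Shaded coefficient-grid figure
#'
#' Tile plot of the back-mapped median effects (covariate rows, response
#' columns); cells whose 95% credible interval covers zero are shaded
#' white, so color marks only the significant effects.
#'
#' @param grid An `ssvs_grid` from [run_full_model()].
#' @return A ggplot object.
#' @export
plot_coefficient_grid <- function(grid) {
  assert_cols(grid, c("covariate", "response", "median", "significant"),
              "'grid'")
  df <- as_tibble(grid)
  df$shown <- ifelse(df$significant & !is.na(df$median), df$median, NA_real_)
  df$covariate <- factor(df$covariate, levels = rev(unique(df$covariate)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$covariate,
                                   fill = .data$shown)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "white",
                                  name = "median effect\n(per SD)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
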