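# stoichdiet

Country-level analyses that relate the elemental composition of national
diets — nitrogen (N), phosphorus (P), their N:P mass ratio, protein,
kilocalories and total intake, split by food source (terrestrial animal,
vegetable, aquatic animal, alcoholic beverages) — to cancer prevalence,
cancer mortality and life expectancy. The package is aimed at
epidemiologists and ecologists working with food-balance-sheet style data
who need the whole chain from raw tables to a coefficient grid:

1. **Covariate construction** — per-capita nutrient intakes from a
   food-intake table and one or more nutrient-concentration databases
   (`compute_intake_profile()`), assembled into a country panel of 33
   explanatory columns: {N, P, N:P, kcal, protein, total kg} × {terrestrial
   animal, vegetable, terrestrial-animal/vegetable ratio, aquatic animal,
   alcoholic} plus GDP per capita, median age and HDI
   (`assemble_covariates()`), period-averaged or as first-to-last-decade
   changes.
2. **Rate standardization** — age-standardized rates per 100,000 against a
   standard population (`age_standardized_rate()`, WHO world standard
   shipped).
3. **Collinearity-aware dimension reduction** — hierarchical clustering of
   the covariates on `1 - |r|` distances with the cluster count chosen by
   the Kelley criterion (`cluster_covariates()`), then a per-cluster PCA
   keeping the three leading eigenvectors (`extract_factors()`), which
   capture well over 90% of each cluster's variance; `compute_vif()` for
   multicollinearity diagnostics.
4. **Sparse Bayesian regression** — stochastic search variable selection
   (SSVS): a Gibbs sampler with a spike-and-slab prior on each coefficient
   (`fit_ssvs()`), and back-mapping of factor coefficients to the original
   covariates through the PCA loadings (`backmap_coefficients()`).
   `run_full_model()` chains 3 + 4 over many responses and renders the
   shaded coefficient grid (`plot_coefficient_grid()`).
5. **Bivariate views** — reduced major-axis fits (`rma_fit()`).
6. **Synthetic panels with known truth** — `synthetic_config()`,
   `generate_food_panel()`, `generate_responses()`,
   `generate_mortality_counts()` emulate the whole data layer with
   block-collinear diet covariates and sparse linear effects, so the full
   pipeline is testable by parameter recovery without any external data.

## The model in brief

For a response `y` (standardized) and regressors `x_j` (cluster PCA factor
scores plus controls, standardized), SSVS places on each coefficient the
two-component mixture prior

```
beta_j | gamma_j ~ (1 - gamma_j) N(0, tau0^2) + gamma_j N(0, tau1^2),
gamma_j ~ Bernoulli(p),     sigma^2 ~ InvGamma(a, b)
```

with spike `tau0 = 0.01`, slab `tau1 = 10`, `p = 0.5`, `a = b = 0.01` by
default. The Gibbs sampler cycles the conjugate full conditionals of
`beta`, `gamma` and `sigma^2`; a coefficient's posterior inclusion
frequency is its selection evidence, and covariate-level effects are
recovered as `sum_f loading[j, f] * beta_f` per draw. Significance is a
95% equal-tailed credible interval excluding zero — the white-vs-shaded
rule of the coefficient grid.

Age standardization is the direct method, `sum_g w_g * 100000 * d_g / n_g`
with standard-population weights `w_g`; the reduced major axis has slope
`sign(r) * sd(y) / sd(x)` through the centroid.

## Worked example

Simulate a 40-country, 1960–2010 panel in which only terrestrial-animal
nitrogen truly drives mortality (+1.5 SD per SD), then see whether the
pipeline finds that — and nothing else:

```r
library(stoichdiet)

cfg <- synthetic_config(
  n_countries = 40, years = 1960:2010, seed = 1,
  true_effects = c(N_terrestrial_animal = 1.5), noise_sd = 1
)
panel <- simulate_panel(cfg)                      # 40 x (1 + 33)
resp  <- generate_responses(panel, cfg, "mortality_total")$responses

grid <- run_full_model(panel, resp,
                       ssvs_config(n_draws = 10000, n_burn = 2000,
                                   thin = 4, seed = 1))
attr(grid, "partition")
#> Covariate partition: 29 covariates in 5 clusters (Kelley criterion)
#> cluster sizes: 6, 6, 6, 6, 5
round(attr(grid, "factors")$variance_fraction, 3)
#>    C1    C2    C3    C4    C5
#> 0.999 1.000 0.999 1.000 1.000

subset(as.data.frame(grid), significant,
       select = c(covariate, median, lower, upper, inclusion))
#>                     covariate median   lower upper inclusion
#> 1        N_terrestrial_animal  0.126 0.06076 0.196         1
#> 2        P_terrestrial_animal  0.129 0.00953 0.380         1
#> 3     kcal_terrestrial_animal  0.127 0.07332 0.195         1
#> 4  protein_terrestrial_animal  0.126 0.06034 0.196         1
#> 5 total_kg_terrestrial_animal  0.126 0.08320 0.207         1
```

The five clusters are exactly the five source blocks (the constant
alcoholic N:P column is excluded with a warning), three eigenvectors per
cluster carry ≥ 99.9% of within-cluster variance here, and the only
significant cells sit in the terrestrial-animal rows, all positive. The
six terrestrial-animal covariates are nearly collinear by construction, so
the effect is shared across the block rather than attributed to N alone —
that is what back-mapping of a cluster-level factor looks like.
`plot_coefficient_grid(grid)` draws the shaded tile figure.

A bivariate look at the same relationship:

```r
rma_fit(panel$N_terrestrial_animal, resp$mortality_total)
#> Reduced major-axis fit (n = 40)
#>   slope = 0.481339, intercept = 97.967
#>   r = 0.7247, p = 1.239e-07 (correlation test)
```

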