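# dynoccam

Dynamic (multi-season) occupancy analysis for camera-trap surveys of
elusive wildlife — built for the common mesocarnivore-monitoring design
in which paired trail cameras sample a grid of sites over alternating
summer and winter field seasons, and the questions are where a species
occurs, how quickly sites turn over, and whether the distribution is
heading toward decline.

The package takes raw timestamped photo records and deployment logs
through the full workflow:

1. **Independence filtering** — photos of a species at a site are
   clustered greedily; a photo counts as a new detection only if at
   least 20 minutes (configurable) have passed since the last kept
   photo, pooling the site's paired cameras.
2. **Detection histories** — deployment windows are tiled into weekly
   occasions, yielding the site × season × occasion array
   `y ∈ {0, 1, NA}`, plus naive occupancy and trap-night summaries.
3. **Design assembly** — covariates are mean-centered/scaled (specs
   stored for prediction-time replay) and assembled into the four
   submodel design blocks, including the ten-term colonization and
   extirpation structure with `precip×season`, `zone×cover` and
   `moth×TSD` interactions.
4. **Bayesian fitting** — the latent occupancy chain is marginalized by
   the forward algorithm (never sampled); Hamiltonian Monte Carlo with
   analytic gradients samples the coefficients of initial occupancy
   `ψ₁`, colonization `γ`, extirpation `ε`, detection `p`, and a
   site-level detection random effect `η_i ~ N(0, σ_η²)`. Diagnostics:
   split rank-normalized R-hat, `p_pos` (posterior probability a
   coefficient is positive), and strong/moderate support grading at
   0.90/0.70.
5. **Derived dynamics** — occupancy trajectories
   `ψ_{t+1} = ψ_t(1−ε_t) + (1−ψ_t)γ_t`, turnover
   `τ′_t = ψ_t ε_t + (1−ψ_t)γ_t`, per-season rates of change
   `λ = ψ_last/ψ_first`, decline proportions `c_s`/`c_w`, and the
   stable state `ψ^eq = γ/(γ+ε)`, all computed draw-wise over a masked
   prediction grid (cells >40% high development or water removed).

A synthetic-data generator (`scenario()`, `simulate_dataset()`)
produces covariate tables, latent occupancy, detection histories and
clustered photo bursts with the statistical structure the model
assumes, together with the stored truth, so the whole pipeline is
testable end-to-end and parameter recovery can be measured.

## Worked example

```r
library(dynoccam)

sc  <- scenario(n_sites = 60, n_periods = 6, n_occasions = 8)
dat <- simulate_dataset(sc, 42, photos = TRUE)

ev <- filter_independent(dat$records, 20)
h  <- build_history(ev, dat$deployments, 7, species = sc$label,
                    season_levels = dat$season_cov$primary_period)
h
#> detection history: 60 sites x 6 periods x 8 occasions ( default )
#>   detections: 756  surveyed occasions: 2880

round(naive_occupancy(h), 2)
#> S2019 W2020 S2020 W2021 S2021 W2022
#>  0.55  0.67  0.48  0.60  0.50  0.33

cfg <- run_config(mcmc = list(chains = 3, warmup = 500, draws = 1000, seed = 1))
fit <- fit_occupancy(h, dat$site_cov, dat$season_cov, cfg)
fit
#> occupancy model fit: 3 chains x 1000 post-warmup draws, 88 parameters
#>   mean acceptance: 0.93  max split R-hat (coefficients): 1.004

head(summarize_fit(fit)[, c("parameter", "median", "rhat", "p_pos", "support")], 7)
#>          parameter median rhat  p_pos   support
#> 1 psi1_(Intercept)  0.344    1 0.8750 moderate+
#> 2        psi1_moth -0.476    1 0.0647   strong-
#> 3       psi1_cover  0.321    1 0.8473 moderate+
#> 4   psi1_road_dist -0.051    1 0.4370      none
#> 5    p_(Intercept) -0.012    1 0.4503      none
#> 6          p_cover  0.536    1 1.0000   strong+
#> 7      p_zone_area -0.300    1 0.0017   strong-

predict_grid(fit, dat$grid)
#> derived occupancy dynamics over 136 grid cells
#>   decline proportions (median-based): summer 0.669 , winter 1
```

Reading the output: naive occupancy is the raw detected share of
surveyed sites per season; the coefficient table reports posterior
medians on the standardized scale with their support grade (here
detection rises with cover, `p_pos = 1.00`, and falls with zone area);
and the grid summary gives the share of retained 1-km² cells whose
posterior-median occupancy declined between the first and last year of
each season.

`run_pipeline()` wraps these stages per species and writes the
per-species artifacts (history, naive table, fit summary, posterior
archive, support report, derived-dynamics CSVs) plus a reproducibility
manifest; `run_recovery_experiment()` repeats simulate→fit cycles and
tabulates interval coverage against the stored truth.

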