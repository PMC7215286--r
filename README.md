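# ndimap — Bayesian neighborhood-disadvantage-index mapping of areal outlet rates

`ndimap` is for epidemiologists and spatial analysts who ask two questions
of per-tract counts of some amenity — tobacco retailers, vape shops, alcohol
outlets: *is the rate associated with neighborhood socioeconomic
disadvantage*, and *where is risk significantly elevated*?  Answering these
with separate covariates fails because tract-level socioeconomic variables
are strongly correlated, and ignoring spatial structure misstates
uncertainty.  `ndimap` estimates a single **neighborhood disadvantage
index** — a weighted sum of decile-scored covariates whose simplex weights
are learned from the data — inside a Bayesian Poisson relative-risk model
with spatially structured residuals.

## The model

For tract *i* with count *y<sub>i</sub>* and *h<sub>i</sub>* households:

```
y_i ~ Poisson(theta_i * E_i),    E_i = r * h_i,    r = sum(y) / sum(h)

log(theta_i) = beta0 + beta1 * sum_j w_j q_ij  +  { u_i            (variant 1)
                                                  { v_i            (variant 2)
                                                  { u_i + v_i      (variant 3)
                                                  { a_i u_i + (1-a_i) v_i   (4)
```

*q<sub>ij</sub>* ∈ {0,…,9} are decile scores of the oriented covariates
(`max(x) − x` for amounts like income, `1 − x` for proportions like
%-with-degree, so every variable points toward disadvantage);
*w* ~ Dirichlet(α) on the simplex, so *w<sub>j</sub>* is the relative
importance of variable *j* and any weight above 1/C (0.083 for the default
12 variables) marks an over-contributing variable.  `u` is exchangeable
Normal heterogeneity; `v` is an intrinsic CAR (ICAR) field on binary queen
contiguity; variant 4 mixes the two with per-tract Beta(1,1) mixing.
Models are fitted by an adaptive Metropolis-within-Gibbs sampler, compared
by DIC (a drop of ≥ 10 is meaningful), checked with Geweke diagnostics
(|z| < 2) and Moran's I screening, and summarized by exceedance
probabilities `q_ic = mean(theta_i draws > c)`: tracts with `q_ic > 0.90`
at `c = 1` are flagged as significantly elevated.

## Worked example

```r
library(ndimap)
cfg <- sim_config(rows = 10, cols = 10, C = 6, beta1_true = 0.2,
                  variant = 3, sigma_v_true = 0.5, seed = 1)
sim <- simulate_tracts(cfg)          # lattice, covariates, households, counts
dat <- filter_missing(sim$data)      # drop tracts with missing covariates
fit <- ndi_fit(dat, graph = sim$graph, variant = 3, seed = 2)
summary(fit)
```

```
Variant 3 fit over 100 tracts (6-variable index)

   parameter      mean       sd      lower    upper geweke_z
       beta0  -1.11700  0.16860  -1.494000  -0.7702   -1.002
       beta1   0.19120  0.03281   0.120400   0.2664    1.537
 RR_per_unit   1.21100  0.03972   1.128000   1.3050    1.465
     ...

RR per index unit: 1.211 (1.128, 1.305) -- significant

Index weights (importance threshold 0.167):
 variable  mean    sd lower upper important
   ses_03 0.283 0.113 0.071 0.509      TRUE
   ses_01 0.231 0.102 0.034 0.423      TRUE
   ses_06 0.161 0.093 0.012 0.368     FALSE
   ...

DIC = 489.8 (pD = 45.9, mean deviance = 443.8)
21 tract(s) with significantly elevated risk
WARNING: some monitored parameters have |Geweke z| >= 2
```

Reading the output: the data were generated with a true index effect of
0.2, and the fitted relative risk per index unit is exp(0.191) ≈ 1.21 with
a 95% credible interval excluding 1 — a 21% increase in outlet risk per
decile-unit of disadvantage.  Two variables exceed the equal-contribution
threshold 1/6 ≈ 0.167 and drive the index.  21 tracts have exceedance
probability above 0.90.  The convergence warning is the desk profile
(6,000 iterations) being honest; rerun with
`control = paper_protocol()` (60,000 iterations, 30,000 burn-in) for
publication-grade chains.

Model choice across the four variants, and hotspot export:

```r
fits <- lapply(1:4, function(v)
  ndi_fit(dat, graph = sim$graph, variant = v, seed = 2 + v))
compare_dic(fits)                       # DIC/pD table, best variant flagged
export_results(fits[[4]], "out/", polygons = sim$polygons)  # CSV + GeoJSON
```

Real data enter through `read_tract_table()` (CSV), `read_gal()` /
`build_queen_adjacency()` + `read_geojson_polygons()` (spatial structure)
and `assign_points_to_tracts()` (outlet longitude/latitude to tract
counts).  A thin command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/ndimap.R simulate --out data/ --rows 10 --cols 10 --seed 7
Rscript inst/cli/ndimap.R fit --data data/tracts.csv --gal data/adjacency.gal \
        --out fits/ --variants all --seed 7
Rscript inst/cli/ndimap.R hotspots --archive fits/samples_variant4.rds --out hot/
```

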