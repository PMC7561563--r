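# woodsucc

Succession analysis for insect communities on dead wood.

When a tree dies, the wood becomes an ephemeral resource: beetles and other
saproxylic insects colonize it within a season, the community reshuffles as
the wood decays, and within a few years many early colonists are gone.
`woodsucc` is a toolkit for the statistics of that process, built for
longitudinal trap-by-year-by-species count data from designed field
experiments (fixed traps on experimentally killed trees, annual censuses,
environments such as sun-exposed clear-cuts versus closed-canopy shade). It
is aimed at community ecologists who want to quantify *how fast* succession
runs in different environments, not just where it ends.

## What it computes

**Permanent species gain and loss rates.** Richness change is partitioned
into colonizations and extinctions. For a trap with richness S_t1 and S_t2
at the ends of a one-year interval,

    Gp = G / ((S_t1 + S_t2) / 2),    Lp = L / ((S_t1 + S_t2) / 2),

where G counts species gained *permanently* (absent in all previous study
years) and L species lost *permanently* (absent in all following years); a
temporary disappearance counts as neither. The rates are per-interval
turnover relative to the size of the existing community, in [0, 2].

**Functional-group trajectory models.** Negative-binomial (richness,
abundance) and Gaussian (Gp, Lp) mixed models with categorical time x
environment fixed effects and landscape/trap random intercepts, a
likelihood-ratio test of the time x environment interaction (the signature
of environment-dependent successional speed), unadjusted Wald contrasts of
exposed vs shaded within each year, and a three-way year x environment x
group model comparing host-tree specialists with generalists over the first
two years, including predicted year-2/year-1 fold changes.

**Community structure.** Hellinger transformation, partial redundancy
analysis (RDA) with year, environment and their interaction conditioned on
landscape, Freedman-Lane marginal permutation tests with pseudo-F
statistics, type-II-scaled ordination scores with factor-level centroids
and species flagging, and three-set variance partitioning (environment,
year, fungal diversity) into unique and shared adjusted-R² fractions.

**A colonization-extinction simulator.** `simulate_study()` draws
study-shaped data (60 traps, 4 years, 184 host-associated species plus
non-host bycatch) from an explicit latent model — environment- and
guild-specific arrival profiles, geometric persistence, imperfect detection,
overdispersed counts — and `true_turnover()` computes the exactly
enumerated expected rates, so every stage of the pipeline can be tested
against known ground truth.

## A worked example

```r
library(woodsucc)

study <- simulate_study(sim_params(), seed = 42)
aspen <- filter_aspen(study$community, study$traits)
aspen
#> Community matrix: 60 traps x 4 years x 184 species
#> Total individuals: 16598

to <- turnover_rates(aspen, study$traits, "specialist")
summary(to, study$sites)
#>       env t1        Gp        Lp  n
#> 1 exposed  1 1.6124603 0.2542063 30
#> 2 exposed  2 0.2403382 0.8110488 30
#> 3 exposed  3 0.2534127 0.8489683 30
#> 4  shaded  1 1.1269841 0.4444444 21
#> 5  shaded  2 0.7914286 0.5114286 25
#> 6  shaded  3 0.8739796 0.4768707 28
```

Specialist gain rates at exposed sites are high in the first interval
(1.61: colonizations exceeding the mean standing richness) and collapse
afterwards, while shaded sites stay near 0.8-0.9 throughout — fast
early succession in the favourable environment, gradual accumulation in the
shade. The `n` column counts traps with defined rates: early shaded
communities are sometimes empty, and those records are excluded rather than
imputed. Fitting the rate model:

```r
fit <- fit_trajectory(to, study$sites, response = "Gp")
#> landscape random intercept degenerate; using structure 'landscape_fixed'

interaction_lrt(fit)[c("chi2", "df", "p")]
#> $chi2  25.93808
#> $df    2
#> $p     2.331409e-06

within_time_contrasts(fit)
#>   time   estimate        se         z            p
#> 1    1  0.4769761 0.1677905  2.842688 4.473484e-03
#> 2    2 -0.5534704 0.1595871 -3.468140 5.240735e-04
#> 3    3 -0.6205669 0.1548433 -4.007709 6.131062e-05
```

The interaction LRT rejects decisively: the temporal patterning of gains
differs between environments. The within-interval contrasts (exposed minus
shaded, link scale) show why — exposed sites gain *faster* in interval 1-2
(+0.48) and *slower* afterwards (-0.55, -0.62). The message about the
landscape intercept is the documented fallback: with two landscapes the
variance component usually collapses, and the model keeps landscape as a
fixed effect instead.

`run_pipeline(config)` performs the whole analysis (filtering, per-group
turnover and models, the specialist/generalist comparison, ordination with
permutation tests, variance partitioning) and writes a reproducible report
bundle — `turnover_*.csv`, `model_report_*.json`, `rda_summary.json`,
`ordination_scores.csv`, `varpart.json`, figures and a `run.log` — that is
bit-identical across reruns with the same config and seed.

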