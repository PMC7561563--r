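---
title: "Models and methods in woodsucc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in woodsucc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`woodsucc` analyses early succession of insect communities on ephemeral
dead-wood resources: standing dead trees are colonized rapidly after death,
the resource degrades within a few years, and the community assembles and
disassembles on that timescale. The motivating design is a balanced field
experiment — trees killed at a fixed date, flight-interception traps on each
trunk, annual species-level counts over four seasons, trees split between
sun-exposed and shaded sites in two landscapes — and the central scientific
question is whether the *rate* of succession differs between favourable
(exposed) and less favourable (shaded) environments.

This vignette documents the statistical machinery, the choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate. It states no empirical results beyond what the package's tests and
acceptance script compute themselves.

## Data model

The raw observational unit is a count of individuals per (trap, year,
species). `community_matrix()` stores these as a dense integer array with an
explicit trap-year design: absence of a species row is an implicit zero, but
every (trap, year) sample must exist, distinguishing "nothing caught" from
"trap not operated". Long (tidy) CSV is the canonical interchange format;
wide species-by-sample matrices are accepted on import. Calendar years are
recoded to successional years 1..T.

Species carry two classifications: host-tree affinity (specialist on the
host, generalist, or not associated with the host tree — the last are
excluded from all analyses by `filter_aspen()`) and a single trophic guild
(wood-feeder, fungivore, predator, omnivore/saprophage). Guild membership is
exclusive, so guild-level abundances partition the community total — a
property the test suite checks.

## Permanent gain and loss rates

Changes in richness are partitioned into colonizations and extinctions. For
a trap with endpoint richness $S_{t1}$ and $S_{t2}$ over a one-year
interval,

$$G_p = \frac{G}{\tfrac12 (S_{t1}+S_{t2})}, \qquad
  L_p = \frac{L}{\tfrac12 (S_{t1}+S_{t2})},$$

where $G$ and $L$ count *permanent* gains and losses: a species is gained in
a year only if it was absent in **all** previous study years, and lost only
if it is absent in **all** subsequent study years. A species that
disappears and later reappears contributes to neither count. Both rates are
dimensionless, lie in $[0, 2]$ when defined, and measure turnover relative
to the size of the existing community.

Three boundary decisions:

* Permanence is assessed inside the observation window only. A year-T
  presence cannot be falsified later, so final-interval losses are
  right-censored; this mirrors the finite study frame.
* Rates are computed per trap and never pooled before model fitting; the
  trap is the replicate.
* When $S_{t1} + S_{t2} = 0$ the rate is undefined (`NA`) and the record is
  excluded from model fits rather than imputed as zero — imputing zeros
  would bias early shaded-site intervals, where empty communities are
  common, toward spuriously low turnover.

`permanent_gains_losses()` is verified against an independent brute-force
scan of the permanence rule on thousands of random presence histories.

## Trajectory models

Per functional group, richness and abundance (per trap-year) and the gain
and loss rates (per trap-interval) are modelled with time and environment as
crossed categorical fixed effects:

* counts: negative binomial (NB2, $\mathrm{Var} = \mu + \mu^2/\theta$) with
  log link, via `glmmTMB`, fitted by maximum likelihood (Laplace
  approximation);
* rates: Gaussian, also by ML so that likelihood-ratio tests are valid.

The random-effect structure follows the design: a landscape intercept and a
trap intercept nested in landscape. With only two landscapes the landscape
variance is weakly identified and routinely collapses to zero; `fit_trajectory()`
therefore walks a fallback ladder — full structure, then landscape as a
fixed effect with a trap intercept, then fixed effects only — and records
which structure was used. A converged full-structure fit whose landscape
variance has collapsed is kept as a last resort rather than failing. A
second boundary arises with equidispersed counts: the NB dispersion
$\theta \to \infty$, the Hessian loses rank, and the NB2 likelihood's
supremum is the Poisson likelihood; the fitter then fits that Poisson limit
explicitly and says so. The interaction test always refits full and reduced
models under one common family and random structure, because a likelihood
ratio across different random structures is meaningless.

Inference follows the design's logic:

* the time-by-environment interaction — the quantity of scientific interest,
  since it encodes *different successional trajectories* — is tested by
  likelihood ratio between the full and additive models
  (`interaction_lrt()`), with df = (T−1)(E−1);
* exposed-vs-shaded differences within each year or interval are unadjusted
  Wald z contrasts assembled from model-matrix rows
  (`within_time_contrasts()`), so they are invariant to factor coding;
  multiplicity adjustment is available but off by default, matching the
  common reporting convention for per-year comparisons;
* the specialist-versus-generalist comparison over the first two years adds
  functional group as a third crossed factor
  (`specialist_generalist_model()`); the three-way interaction is reported
  as a Wald test on the coding-invariant double difference of cell linear
  predictors, together with each group's predicted year-2/year-1 fold
  change, averaged over environments on the link scale.

Temporal autocorrelation is handled diagnostically, not by modelling:
`residual_time_diagnostics()` returns per-trap residual sequences ordered by
time and their lag-1 autocorrelations. The estimator is the acf-style ratio
$\sum r_t r_{t+1} / \sum r_t^2$ *without* per-trap re-centering: residuals
are already centred by the model, and re-centering series of length 4-6
biases the correlation toward $-1/(T-1)$, which would mask genuine positive
autocorrelation.

## Ordination

Community structure — the relative abundances of species — is analysed by
partial redundancy analysis on Hellinger-transformed counts
($y'_{ij} = \sqrt{y_{ij}/y_{i+}}$; zero-sum rows map to zero rows). The
Hellinger transform bounds entries in $[0,1]$, gives nonzero rows unit norm,
and makes Euclidean distances ecologically sensible for sparse count data.

`partial_rda()` implements the textbook algorithm directly with QR/SVD
linear algebra: centre the response, residualize response and constraining
design on the conditioning design (here: landscape), regress, and decompose
the fitted values. Eigenvalues are reported on the variance scale (divided
by $n-1$); eigenvalues below $10^{-10}\times$ total variance are treated as
numerically zero. Constraint columns wholly absorbed by the conditioning
design are dropped (conditioning on the constraints themselves correctly
yields $R^2 = 0$); any remaining rank deficiency is an error naming the
aliased columns, because silently dropping confounded terms invites
misreading. The implementation is checked to $10^{-8}$ against a
brute-force oracle built from explicit projection matrices, and against
`vegan::rda` — both are cross-checks, neither is the implementation.

Marginal significance of each term uses a permutation test
(`marginal_permutation_test()`): the marginal SS is the difference in fitted
SS between the full constraining design and the design without the term
(type-III-like, with the interaction tested in the presence of main
effects), the statistic is pseudo-F, and the null distribution comes from
Freedman-Lane permutation of reduced-model residuals, permuting whole rows.
Trap-years are permuted freely by default; a `within` argument supports
restricted (repeated-measures) schemes for users who prefer to exchange
rows only within traps. The p-value carries the +1 small-sample correction,
so the smallest attainable p with 999 permutations is 1/1000. The test's
size is verified by a 200-replicate null calibration in the acceptance
suite.

Scores for display use type-II (correlation) scaling: species scores are
eigenvector columns scaled by $\sqrt{\lambda_k/\text{total}}$ and the
display constant $((n-1)\,\text{total})^{1/4}$, site scores are unscaled by
the eigenvalues (scaling 1 reverses the roles). Factor-level and cell
centroids are means of site scores per level, computed on the original
factor levels so they do not depend on the dummy coding. Species with an
absolute score above 0.2 on either of the first two axes are flagged for
labelling, the conventional display threshold for this kind of triplot.

## Variance partitioning

`varpart3()` partitions the variance of the Hellinger matrix among
environment (E), year (Y) and fungal diversity (F, a per-trap count of
fungal/slime-mold taxa entering as a single numeric predictor, df = 1).
All seven non-empty predictor subsets are fitted as unconditioned RDAs; each
raw $R^2$ is Ezekiel-adjusted, $1-(1-R^2)(n-1)/(n-m-1)$, and the seven
elementary fractions (three unique, three pairwise shared, one triple
shared) are recovered by solving the inclusion-exclusion system exactly.
Landscape is omitted from the partition, consistent with its negligible
marginal contribution in this design. Individual shared fractions can be
negative — a well-known property of adjusted-$R^2$ partitioning — and are
reported as computed; only the Venn display truncates at zero. The fractions
are verified to $10^{-10}$ against the inclusion-exclusion identity and
against `vegan::varpart`.

## The synthetic-data generator

`simulate_study()` generates study-shaped data with known ground truth:

* design: 15 traps per environment per landscape, 2 landscapes, 4 years;
* species pool: 17 host-tree specialists and 167 generalists split across
  guilds in the proportions of the motivating tallies (22 wood-feeders, 73
  fungivores, 75 predators, 14 omnivores/saprophages), plus 30 non-host
  species that the filtering step must remove;
* latent dynamics per species and trap: a first-arrival year drawn from an
  environment-, affinity- and guild-specific profile (exposed profiles
  front-loaded, most sharply for specialists and wood-feeders; shaded
  profiles flat, with fungivores rising through time), geometric survival
  with annual persistence 0.5, Bernoulli detection 0.8 per trap-year;
* counts, conditional on presence and detection: zero-truncated negative
  binomial with $\theta = 1$, species-specific lognormal base abundance
  (sd 1.5 on the log scale, emulating the right-skewed species abundance
  distribution of real assemblages), a 2x exposed multiplier, and a
  reciprocal per-species environment affinity (lognormal sd 0.8) so some
  species lean sunny and some shady;
* fungal diversity: Poisson per trap with environment-specific means
  (1.5 exposed, 2.5 shaded).

Parameter values were chosen once to land the simulated tallies and rate
magnitudes in the range of the motivating study (about 15,000 retained
individuals across 184 species; early gain rates near 1 and loss rates near
0.5) and encode the hypothesized dynamics: favourable sites accumulate
species and individuals quickly and then plateau, less favourable sites
accumulate gradually.

`true_turnover()` computes the expected gain/loss rates implied by a
parameter set. The distribution of one species' observed presence history
is enumerated exactly over arrival year, survival duration and per-year
detection outcomes (durations reaching past year T pooled, i.e.
right-censored); because the trap-level rates are ratios of sums across the
pool, their expectations are then averaged over Monte Carlo traps whose
species histories are drawn from that exact distribution. Keeping the
colonization profiles at stratum level (rather than per species) is what
keeps this enumeration exact.

**What the generator does not emulate.** Detection is independent across
years and species; there is no species-level sorting of *occupancy* by
environment (only guild-level profile differences and species-level
abundance sorting); fungal diversity influences nothing downstream (it is a
static covariate, as in the analysis); and there is no spatial structure
beyond the landscape label. The practical consequence: simulated data
reproduce the turnover-rate contrasts, the trajectory-model interactions
and the specialist fold-change pattern at realistic strength, but the
compositional (ordination) signal is much weaker than in real assemblages,
where individual common species are strongly and consistently sorted
between environments. Passing tests therefore demonstrate the correctness
and calibration of the ordination machinery, not that the simulator
reproduces field-strength community structure.

## Problem sizes and numerical choices

The test suite runs each component at sizes chosen to make the statistical
checks meaningful while keeping the suite fast: the turnover oracle on 1000
random 50-species histories plus a 60-trap community; ordination oracles on
40x12 matrices; permutation calibration with 200 replicates of 999
permutations; the gain-rate interaction power check on 100 replicates at
the full field design size; cell-mean recovery averaged over 5 replicate
simulations of 30 traps per environment. Convergence of per-trap rates to
their enumerated expectations is checked at 500 traps within 3 combined
Monte-Carlo standard errors.

Other numerical decisions: duplicate (trap, year, species) keys are an
error, never summed; eigenvalue tie-breaking is left to the SVD (random
matrices in tests have distinct eigenvalues; score comparisons are made up
to axis sign); permutation streams are seeded explicitly and reported in
the output objects, so every pipeline run is bit-reproducible given its
config and seed.

## Known limitations

* The landscape variance component is rarely estimable with two levels; the
  fallback ladder is principled but means "landscape as random effect" is
  often an aspiration, not a fit.
* Gaussian models for rates bounded in $[0, 2]$ are an approximation
  inherited from the field's practice; residual diagnostics are provided,
  but a beta-type model is out of scope.
* The permutation test permutes trap-years freely by default; with strong
  within-trap correlation a restricted scheme (`within = trap`) is more
  conservative and is left to the user.
* Fold changes are predicted ratios averaged over environments on the link
  scale; other marginalizations are possible and will differ slightly.
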