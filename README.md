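# richGP

Species richness estimation from abundance frequency counts under a
Gamma–Poisson mixture model.

## The problem

Surveys of diverse communities (plants, insects, microbiomes) never
detect every species, so the observed richness `S_obs` underestimates the
true richness `S`. Nonparametric corrections such as Chao1
(`S_obs + f1^2/(2 f2)`, built from the numbers of singletons `f1` and
doubletons `f2`) are lower bounds and can be badly negatively biased when
species detection rates are heterogeneous; classical parametric fits
(maximum likelihood under a mixture model) are unstable or undefined on
sparse samples.

This package implements a moment-based estimator that models species
detection rates as Gamma(α, β) — so counts are marginally negative
binomial — and corrects Chao1's bias using only the singleton, doubleton
and tripleton counts:

    S_GP = S_obs + f0.Chao1 * (2 - (2 f2^2 / (3 f1 f3))^-)

where `f0.Chao1 = f1^2/(2 f2)` (or `f1 (f1-1)/2` when `f2 = 0`) and
`(A)^-` clamps the ratio to `[1/2, 1]`, confining the correction
multiplier to `[1, 1.5]`. The estimator is always defined (`f1` or `f3`
is replaced by 1 inside the ratio when zero), never falls below Chao1,
collapses onto Chao1 for homogeneous communities, and in heterogeneous
communities recovers much of Chao1's missing mass while staying far more
stable than full-likelihood fits.

Alongside it: Chao1, first-order jackknife, Chao–Bunge and the
negative-binomial lower-bound (LB) estimator; asymptotic standard errors
via the multinomial delta method; log-normal confidence intervals whose
lower bound cannot drop below `S_obs`; seven classical species-abundance
models for ground-truth simulation; and a Monte Carlo harness reporting
average estimate, bias, sample s.e., average estimated s.e., RMSE and
95% CI coverage.

## Worked example

Three published frequency-count data sets ship with the package. The
vascular-plant survey has 188 observed species among 1,008 individuals,
with `f1 = 61`, `f2 = 35`, `f3 = 18`:

```r
library(richGP)
fc <- fixture_freq_counts(richness_fixture("vascular"))
estimate_richness(fc)
```

```
  estimator S_obs    n point f0_hat   se ci_lower ci_upper             flags
      chao1   188 1008 241.2   53.2 17.9    216.0    288.9
 jackknife1   188 1008 249.0   61.0 11.0    230.9    274.7
 chao_bunge   188 1008    NA     NA   NA       NA       NA theta_nonpositive
         lb   188 1008 259.5   71.5 49.2    209.1    430.3
         gp   188 1008 254.8   66.8 35.4    213.2    365.1
```

Chao1 bounds the richness from below at 241 species; the Gamma–Poisson
estimator judges the community heterogeneous (ratio A ≈ 0.74) and adds
26% more unseen mass, for ≈ 255 species with 95% CI [213, 365]. The
Chao–Bunge estimator is undefined here (its `theta` statistic goes
negative on this heavy-tailed spectrum) and is reported as a flagged row
rather than a number.

Benchmarking estimators against a known truth:

```r
asm <- make_assemblage("zipf_mandelbrot", S = 1000)   # CV = 1.88
run_simulation(asm, n_grid = c(1000, 4000), reps = 200,
               estimators = c("chao1", "gp"), seed = 42)
```

```
   n estimator mean_obs_richness average_estimate   bias coverage
1000     chao1             438.9            806.5 -193.5     0.25
1000        gp             438.9            950.6  -49.4     0.94
4000     chao1             817.0            975.3  -24.7     0.89
4000        gp             817.0           1006.2    6.2     0.92
```

At n = 1000 a sample detects fewer than half of the 1,000 species; Chao1
is 194 species short with 25% interval coverage, while the GP estimator
recovers to within 50 species with near-nominal coverage.

A command-line front end is installed as `exec/richgp` with subcommands
`estimate`, `simulate`, `curve` and `fixtures`:

```sh
richgp estimate --input counts.csv --format frequency
richgp simulate --model broken_stick --S 1000 --n 2000 --reps 1000 --seed 7
```

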