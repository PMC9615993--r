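# sympatr

Quantifies how two co-occurring predators — a dominant species A and a
subordinate species B — partition space, time and food, from camera-trap
records and genetically assigned scats. It was built for high-altitude
carnivore systems (snow leopard vs woolly wolf or common leopard), but the
methods are general to any asymmetric predator pair.

Three analysis axes, each with its own module:

- **Space** — a Bayesian conditional two-species occupancy model:
  `zA ~ Bern(ψA)`, `zB|zA ~ Bern(ψBA)` where A is present and `Bern(ψBa)`
  where absent, with per-occasion Bernoulli detection (`pA`, `pB`) and
  Uniform(0,1) priors, fitted by an exact data-augmented Gibbs sampler
  (`fit_cooccupancy()`). The spatial verdict is the **species interaction
  factor** `SIF = ψBA / (ψA·ψBA + (1−ψA)·ψBa)` (1 = independence, <1 =
  avoidance), summarised per posterior draw with a 95% highest-density
  interval and split-chain Gelman–Rubin diagnostics.
- **Time** — von Mises kernel density estimates of diel activity on the
  circle with a plug-in bandwidth (`estimate_kappa()`, `vonmises_kde()`),
  compared by the coefficient of overlap
  `Δ1 = ∫ min(f̂A, f̂B) dθ` (`delta1()`, `activity_overlap()`).
- **Food** — scat frequency of occurrence `F = 100·n/N` with
  bias-corrected bootstrap 95% CIs (`bootstrap_fo()`), conversion to
  relative biomass through predator-specific `Y = f(X)` regressions
  (`biomass_factor()`), and Pianka's niche overlap
  `O_jk = Σ p_ij p_ik / √(Σ p_ij² Σ p_ik²)` (`pianka()`).

Seeded generators (`simulate_two_species()`, `simulate_activity()`,
`simulate_scats()`) produce data with exactly the structure each stage
assumes, so the whole pipeline is testable without field data. The
`run_*()` functions (and the thin CLI at `inst/cli/sympatr.R`) tie the
stages into a file-based workflow. See the vignette
`vignettes/predator-interactions.Rmd` for the full methods account.

## Worked example

```r
library(sympatr)

# a 120-station, 10-occasion survey with moderate avoidance (true SIF 0.667)
sim <- simulate_two_species(n_sites = 120, K = 10, psiA = 0.5, psiBA = 0.3,
                            psiBa = 0.6, pA = 0.4, pB = 0.4, seed = 11)
fit <- fit_cooccupancy(sim$pair, seed = 11)
fit
#> Two-species occupancy fit: 3 chains x 1000 kept (burn-in 10000)
#>  parameter  mean     sd hdi_low hdi_high  rhat
#>       psiA 0.369 0.0429   0.290    0.457 1.001
#>      psiBA 0.349 0.0699   0.209    0.482 1.000
#>      psiBa 0.542 0.0562   0.428    0.647 1.000
#>         pA 0.412 0.0241   0.369    0.463 0.999
#>         pB 0.407 0.0206   0.367    0.447 1.000
#>        sif 0.740 0.1225   0.490    0.973 1.000
#> SIF = 0.74 (HDI: 0.49 to 0.97); HDI excludes 1: yes
```

The posterior tracks the realized simulation (38% of sites actually ended
up occupied by A in this draw; `mean(sim$zA)` is 0.375), and the SIF below
1 with an HDI excluding 1 correctly flags the built-in avoidance.

```r
# temporal overlap between a crepuscular and a shifted bimodal species
a <- simulate_activity(200, means = c(pi/2, 3*pi/2), kappas = c(3, 3), seed = 1)
b <- simulate_activity(150, means = c(2, 5), kappas = c(2, 2), seed = 2)
delta1(vonmises_kde(a, estimate_kappa(a)), vonmises_kde(b, estimate_kappa(b)))
#> [1] 0.9940994

# dietary overlap from a packaged frequency-of-occurrence table
fo <- read.csv(system.file("extdata", "fo_greater_himalaya.csv", package = "sympatr"))
pianka(fo$snow_leopard, fo$common_leopard)
#> [1] 0.7544829
```

Δ1 near 1 says the two activity patterns are nearly interchangeable;
Pianka 0.75 says three quarters of the two predators' dietary use
overlaps.

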