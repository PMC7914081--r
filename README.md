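# oralca

Stochastic cellular-automaton simulation of oral microbial community
succession, with a delay-logistic toolkit for identifying microbial delay
responses from abundance time series.

## The problem

Only a few substrates are available to microbes in the oral cavity, so
competitive exclusion predicts that only a few species should coexist
there — yet oral communities are diverse, and their abundances fluctuate
asynchronously instead of converging on a dominant winner. `oralca`
implements a mechanistic model of why: decomposition-product feedback plus
delayed responses.

Species come in two behavioural roles. *Collaborators* adapt to the oral
environment with enhanced decomposition of large organic molecules (LMOMs),
producing small organic molecules (SMOMs) — a public good. *Scammers*
consume SMOMs without paying the decomposition cost. When scammers displace
collaborators, the SMOM supply collapses and throttles the scammers in
turn: a negative feedback on population size. Cells buffer such adversity
by entering a lag (dormant) phase backed by intracellular energy stores,
which at the population scale appears as a reproductive delay τ₁ and a
reaction delay τ₂ in the delay logistic equation

    dx/dt = μ x(t − τ₁) (1 − x(t − τ₂) / K)

The package provides, as tested modules:

* `integrate_dde()`, `classify_response()`, `specific_growth_rate()`,
  `identify_delays()` — delay-logistic simulation, regime classification
  (asymptotic stabilization / convergent fluctuation / sustained), the
  discrete growth-rate estimator μ = Δx/(xΔt), and least-squares delay
  identification with residual-bootstrap 95% intervals;
* `sample_community()`, `seed_lattice()` — Monte-Carlo species generation
  from the published parameter intervals (lag-probability tiers
  α₁>α₂>α₃ for collaborators, β₁<β₂<β₃ for scammers, move probability m,
  death probabilities d < p, lag time Lat, overrun factor n) and random
  seeding of a torus lattice;
* `ca_step()`, `run_ca()` — the cellular automaton: neighbour-dependent
  lag induction via the opposite-role Moore count (MLL tiers 6–8 / 3–5 /
  0–2), lag aging with overrun mortality, natural death, and radius-3
  proliferation into vacancies (48 candidate sites), advanced in
  synchronous phases with full event logging;
* `simpson_alpha()`, `population_series()`, `spatial_aggregation()`,
  `cluster_climax()` — Simpson (Gini–Simpson) α diversity dynamics,
  per-species population series, a permutation z-score for spatial
  aggregation of similar species, and hierarchical clustering of the
  climax community with cophenetic-correlation model selection;
* `run_simulation()`, `run_delay_comparison()`,
  `run_delay_identification()` and a thin command-line driver
  (`exec/oralca`) with `simulate`, `compare-delay`, `identify-delays`,
  `analyze` and `fixtures` subcommands.

## Worked example

Recover the delays of a Haemophilus-like population from a trajectory the
integrator itself generated (a self-consistency check — the point estimates
return the generating values):

```r
library(oralca)
p  <- delay_logistic_params(mu = 0.5, K = 1, tau1 = 4.02, tau2 = 8.53, x0 = 0.1)
tr <- integrate_dde(p, horizon = 100, dt = 0.01)
identify_delays(tr, mu = 0.5, K = 1,
                bounds = list(tau1 = c(0, 6), tau2 = c(0, 12)))
#> Reproductive delay tau1: 4.020 h  [4.020, 4.020]
#> Reaction delay     tau2: 8.530 h  [8.530, 8.530]
#> RSS: 7.345e-13   (mu = 0.5, K = 1, bootstrap n = 0)
```

Run the headline lag-on vs lag-off comparison (same species draw, same
initial lattice, lag probabilities zeroed in the second arm):

```r
cfg <- community_config(N = 20, N_p = 0.5, M = 500, M_p = 0.5,
                        lattice_rows = 100, lattice_cols = 100,
                        steps = 400, seed = 42)
run_delay_comparison(cfg)$comparison
#>   condition final_richness late_simpson n_multi_peak_species
#> 1    lag_on              4 1.877632e-01                    3
#> 2   lag_off              1 5.741426e-05                    1
```

With the lag rules active, four species persist to step 400 with a
late-window mean Simpson α of 0.19 and three species showing repeated
post-transient population peaks (asynchronous oscillation); without them a
single species sweeps and diversity collapses. The same contrast holds
across the 10-seed experiment in `tests/testthat/test-acceptance.R` and is
the model's account of how delayed responses keep oral communities
diverse.

From the shell, the same pipeline is:

```sh
./exec/oralca compare-delay --out out/ --seed 42 --steps 400 --n-species 20
./exec/oralca simulate --out out/run1 --seed 1 --steps 200
./exec/oralca analyze --dir out/run1
```

See `vignettes/oral-community-succession.Rmd` for the model's assumptions,
the parameter intervals and their meaning, numerical choices, and the
known scale limitation of the reduced-lattice experiments.

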