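# descurve

Estimating the total — and remaining undescribed — number of species in a
taxon from its history of species descriptions.

## The problem

The catalogue of life is incomplete, and for most groups the only
systematic evidence about how incomplete is the historical record of
species descriptions itself. Raw species-accumulation curves extrapolate
poorly when they are not clearly asymptotic, because the description rate
confounds how many species are left with how hard and how effectively
taxonomists are looking. `descurve` implements an effort-based
pool-depletion model of the description process: the number of species
described in 5-year interval *i* is treated as a Poisson count with
intensity

```
lambda_i = T_i * (S_T - D_i) * a * exp(b * Y_i)
```

where `T_i` is the *taxonomic effort* (number of distinct authorship
strings publishing descriptions in the interval), `S_T` is the unknown
total species pool, `D_i` is the number of species already described
strictly before the interval (so `S_T - D_i` is the undescribed
remainder), `Y_i` is the interval's year offset, and `a * exp(b * Y_i)` is
the *taxonomic efficiency* — species described per taxonomist per
remaining species — which may only stay constant or increase (`a > 0`,
`b >= 0`) as technique and accumulated knowledge improve.

All parameters, including `S_T` itself, are estimated by maximum
likelihood (Nelder–Mead on log-scaled coefficients, restarted from its own
optimum until every estimate changes by less than 9e-6), with Wald
confidence intervals from the numerical Hessian. `S_T` minus the described
total is the estimated number of species still awaiting description.

The package also provides:

* a **Gaussian comparator** (`S_i ~ Normal(T_i (S_T - D_i)(a + b Y_i), z)`),
  the earlier effort-based formulation, fitted the same way for
  side-by-side comparison;
* a **Gillespie direct-method simulator** of description histories as a
  continuous-time pure-death process, with four preset scenarios
  (constant or exponentially increasing efficiency, with or without
  gamma-distributed per-bin efficiency noise);
* a **simulation-study harness** (`run_study()`) reporting per-model mean
  estimate, bias, mean absolute deviation and Wald-interval coverage;
* **per-realm batch fitting** (`fit_by_realm()`) for records labelled with
  biogeographic realms, with no species counted in more than one realm;
* data plumbing: record and series CSV readers/writers, half-open 5-year
  binning, and authorship-string taxonomist counting.

## Worked example

Simulate a description history for a pool of 800 species observed by a
constant effort of 50 taxonomists over twelve 5-year bins, then fit the
Poisson-exponential model:

```r
library(descurve)

sc  <- scenario(2, true_S_T = 800,
                taxonomist_trajectory = rep(50L, 12), seed = 1)
sim <- simulate_history(sc)
fit(sim$binned, model_spec("poisson"))
#> poisson-exponential fit to 'simulated scenario 2'
#>   NLL 36.7975 after 2 restart(s)
#>   a      0.00439413  [0.00397591, 0.00485634]
#>   b     1.35462e-08  [NA, NA]
#>   S_T       819.424  [798.422, 840.426]
#>   described 778; estimated pool 819; undescribed 41 (5.1%), interval [20, 62]
#>   fitted/observed Pearson correlation 0.995
```

Reading the output: 778 of the true 800 species were "described" in the
simulated history; the model estimates a total pool of 819 species
(interval 798–840, covering the truth), hence 41 species (5.1% of the
pool) still undescribed. The efficiency slope `b` collapsed to numerical
zero — over a 55-year window the exponential trend is weakly identified —
so its log-scale interval is unavailable, flagged rather than fabricated.
The fitted per-bin counts correlate with the simulated ones at r = 0.995.

The same workflow runs from the shell via the thin CLI wrapper
(`inst/cli/descurve` after installation):

```sh
descurve simulate --scenario 2 --seed 1 --out series.csv
descurve fit --in series.csv --out fit.json --pred-out predictions.csv
descurve study --scenario 3 --seed 7 --reps 200 --out summary.json
```

Real data enter as a CSV of description records (columns `binomial`,
`year`, `authorship`, optional `realm`) through `bin_records()` or the
`bin` subcommand, or as a pre-binned series CSV (columns `year_start`,
`Y`, `S`, `T`, optional `D`).

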