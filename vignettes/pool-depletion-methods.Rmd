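---
title: "Pool-depletion models of species description: methods and design"
author: "descurve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-depletion models of species description: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(descurve)
```

## The model

`descurve` treats the formal description of species as removals from a
finite unknown pool. Within a 5-year interval $i$, the number of species
described, $S_i$, is modelled as Poisson with intensity

$$\lambda_i = T_i \,(S_T - D_i)\, a e^{bY_i},$$

the product of three interpretable factors:

* **taxonomic effort** $T_i$: how many taxonomists (distinct authorship
  strings) published descriptions in the interval;
* **the undescribed remainder** $S_T - D_i$: the unknown total pool $S_T$
  minus $D_i$, the cumulative count described *strictly before* the
  interval (a bin's own descriptions do not deplete its own pool — the
  alternative convention changes $\lambda_i$ only at second order but
  makes the likelihood awkwardly self-referential);
* **taxonomic efficiency** $a e^{bY_i}$: species described per taxonomist
  per remaining species, where $Y_i$ is the interval's offset in years
  from the window origin. The exponential form is everywhere nonnegative,
  approximately linear over short spans, and with $a > 0$, $b \ge 0$
  encodes the assumption that taxonomists only get better over time as
  methods and collections accumulate.

The likelihood is the product of Poisson probabilities over bins,
evaluated through `lgamma` rather than factorials. Conventions at the
edges: a bin with $\lambda_i = 0$ contributes nothing if $S_i = 0$ and
$+\infty$ if $S_i > 0$; parameter values outside the valid domain
($a \le 0$, $b < 0$, $S_T$ below the described total, non-finite
intensities from overflow) return $+\infty$ rather than raising errors,
so a derivative-free optimiser can probe freely.

The Poisson family ties the variance of the per-bin counts to their mean.
The package's comparator — the earlier effort-based formulation it is
evaluated against — instead takes
$S_i \sim \mathrm{Normal}(T_i (S_T - D_i)(a + bY_i),\ z)$ with a single
dispersion scale $z$ estimated jointly. That original model's likelihood
was never written down explicitly in print; constant-$z$ Gaussian is the
simplest form consistent with describing $z$ as a scaling coefficient
fitted as a free parameter (starting value 5), and we define the
comparator this way rather than asserting it is the historical
implementation. Whether the original scaled its variance with the mean is
unknowable from the published record; the contrast drawn here — Poisson
variance grows with the rate, Gaussian variance does not — is the
substantive difference either way.

A diagnostic companion is the *calculated efficiency*
$CE_i = S_i / ((S_T - D_i) T_i)$, the empirical per-bin efficiency implied
by the data at a given pool size; plotted against $a e^{bY_i}$ it shows
where the efficiency submodel fits and where (wars, revisions,
monographs) it does not.

## Estimation

`fit()` minimises the negative log-likelihood with Nelder–Mead over
$(\ln a, \ln b, S_T)$, plus $\ln z$ for the comparator. Logging $a$ and
$b$ enforces positivity; $S_T$ stays on its natural scale with an
$+\infty$ penalty below the described total (a pool smaller than what has
already been described is impossible). Because $b = 0$ is unreachable on
the log scale, estimates below $10^{-8}$ should be read as numerically
zero.

**Restarts.** The optimiser is restarted from its own optimum until no
natural-scale estimate changes by $9 \times 10^{-6}$ or more, capped at
100 restarts (`converged = FALSE` beyond that). The criterion is applied
on the natural scale deliberately: when the true $b$ is 0, $\ln b$
diverges and a fitting-scale criterion would never trigger.

**Multi-start.** Nelder–Mead from a single far-away start can strand on
sparse series. Three starts are used: (1) the `model_spec()` defaults
($S_T = 5970$, $a = 8\times10^{-4}$, $b = 2\times10^{-3}$, $z = 5$), with
the starting pool raised to $1.02\times$ the described total when the
series has described more than the default; (2) a data-driven start — pool
at $1.05\times$ the described total, efficiency coefficients from a
least-squares line through the (log) calculated efficiencies, falling
back to an aggregate moment match when fewer than three bins are active;
(3) a boundary-profile start — pool fixed at $1.02\times$ the described
total, remaining parameters optimised there, then everything released.
The third start matters on burst-dominated series, where the likelihood
is nearly flat in $S_T$ and searches started far from the boundary stall
above the boundary-region optimum. The lowest optimum wins; among optima
tied within $10^{-6}$ likelihood units, the smallest pool estimate is
preferred — a parsimony tie-break for series that do not identify $S_T$.

**Intervals.** Wald intervals come from the inverse finite-difference
Hessian at the optimum, computed on the fitting scale and back-transformed
for logged parameters (hence slightly asymmetric intervals for $a$, $b$,
$z$). A direction that is flat or indefinite — typically $\ln b$ when
$b \to 0$, or $S_T$ when the estimate sits on the described-total boundary
— yields `NA` bounds for that parameter only, with a warning, instead of
voiding every interval. Reported summaries follow field conventions:
species counts rounded to integers, percentages to one decimal.

The per-bin predicted counts carry central Poisson quantile intervals at
$\hat\lambda_i$ (or $\hat\mu_i \pm q\hat z$ for the comparator). Parameter
uncertainty is *not* propagated into these per-bin bands; they describe
sampling noise around the fitted curve, not uncertainty in the curve.

## The simulator

`simulate_history()` generates description histories by Gillespie's
direct method for a pure-death process: with $D(t)$ species described so
far, the hazard of the next description is
$h(t) = T_{\mathrm{bin}} (S_T - D(t)) E_{\mathrm{bin}}$ per year,
piecewise constant between events. Waiting times are exponential at the
current hazard; a draw that crosses a bin boundary is discarded and the
clock advances to the boundary where the hazard is refreshed — exact for
piecewise-constant rates by the memoryless property, and directly
checkable against the closed form: with constant effort $T$ and
efficiency $a$, the expected first-bin count is
$S_T(1 - e^{-aTw})$ for bin width $w$ (the acceptance suite verifies
$1000(1 - e^{-0.001 \cdot 50 \cdot 5}) = 221.2$ over 2,000 replicates).
Hazards below the smallest normal double are treated as zero (they imply
essentially zero expected events, and `rexp` rejects subnormal rates).

Four preset scenarios vary the efficiency process, all with a true pool
of 5,860 species by default: (1) constant, noiseless ($a = 0.001$,
$b = 0$); (2) exponentially increasing, noiseless ($a = 0.001$,
$b = 0.005$); (3) and (4) the same two with per-bin gamma noise,
$E_i \sim \Gamma(\mathrm{shape} = a e^{bY_i}, \mathrm{scale} = 1)$, whose
mean equals the noiseless efficiency. Efficiency is redrawn once per bin,
not per event, matching the model's per-bin efficiency concept. With
shapes near $10^{-3}$ the gamma is extremely right-skewed: most bins draw
efficiencies indistinguishable from zero and rare bins draw large spikes,
so noise-scenario histories are bursts separated by silence. This is the
literal consequence of the stated noise law and we keep it, but it means
scenarios 3–4 probe the estimators under near-degenerate data, not under
mild overdispersion.

**The packaged taxonomist trajectory** (`mammal_like_taxonomists()`,
`inst/extdata/taxonomist_counts_synthetic.csv`) is a synthetic stand-in,
not observed data: 51 five-year bins with mammal-like *shape* (roughly
exponential growth, dips at the world-war bins). Its *level* is
calibrated in effective units: combined with the scenario efficiencies
and the per-year hazard above, the per-species cumulative hazard reaches
about 3 by the final bin under scenario 2, so simulated histories end
roughly 95% described — matching the completeness of the real mammal
description curve. A trajectory at raw head-count level (hundreds of
taxonomists per bin) would, under this hazard convention, describe 100%
of any pool and make every simulation degenerate.

**Seeding.** A scenario carries one root seed; study replicate $r$ uses
the documented derivation $(\mathrm{seed} + 179r) \bmod (2^{31}-1)$, so
studies are exactly reproducible and replicates independently
re-runnable.

## The simulation study

`run_study()` simulates, fits each candidate model, and summarises
per-model: replicate pool estimates, mean and median, bias, mean absolute
deviation, and the coverage of the nominal 95% Wald interval. Replicates
are grouped in three bookkeeping classes, all reported: outright failures
(error or non-convergence, `n_failed`) are excluded everywhere; converged
fits whose $S_T$ interval is unavailable (`n_no_interval`) contribute
their estimate to the location summaries but cannot contribute to
coverage. The second class is essential under the gamma-noise scenarios,
where the Poisson estimate frequently sits exactly on the described-total
boundary (a burst described the whole pool) with a one-sided likelihood:
excluding those fits outright would discard most noise-scenario
replicates and leave the bias comparison undefined over a handful of
unrepresentative survivors.

**Problem sizes.** The packaged studies and the acceptance suite run at a
reduced scale chosen from closed-form calculations: true pool 800,
constant effort of 50 taxonomists. The noiseless scenarios use a 12-bin
(60-year) horizon, at which per-species survival
$e^{-aTH} \approx 5\%$ matches real-data completeness — a longer horizon
depletes the pool completely and makes estimation trivial, a shorter one
leaves $S_T$ unidentified. The gamma-noise scenarios use the full 51-bin
horizon because their activity is spike-gated (each bin is "active" with
probability around 1%), and a 12-bin horizon would leave most replicates
with no data at all. Replicate counts: 100 for the recovery checks, 200
for the model comparisons, 2,000 for the single-bin closed-form check —
sizes at which each check resolves while the whole suite runs in a few
minutes.

At these conditions the study reproduces the substantive findings:
pool recovery within a few percent under the noiseless scenarios; severe
downward bias for both models under burst noise, with the Gaussian
comparator additionally prone to occasional runaway estimates (its
likelihood genuinely prefers enormous pools on some sparse series); and
nominal-95% interval coverage well below nominal at mammal scale. One
caveat is recorded rather than hidden: under the constant-shape noise
scenario the two models' mean estimates are statistically
indistinguishable (both essentially return the described total on
single-burst series), so a strict better/worse ordering of means is not
resolvable there, while the increasing-shape scenario separates them
decisively.

## Per-realm fitting

`fit_by_realm()` splits labelled records by biogeographic realm, builds
each realm's own series (realm-specific $S$, $T$, $D$), and fits
independently. The interface is a `realm` column on the input records:
each species carries exactly one realm, so realm pools sum comparably to
a global fit without double counting. GIS range-overlap assignment is
deliberately out of scope — labels are an input contract. Realms whose
series cannot be built or fitted are flagged (`note` column), never
silently dropped.

## Data conventions and degenerate inputs

* Binning is half-open, $(\mathrm{start}, \mathrm{start}+w]$, with the
  window origin configurable (default 1755, width 5): a species described
  in 1760 falls in bin $Y = 0$ (1755–1760). The convention reconciles
  interval indexing from 1755 with data windows quoted from 1760, and a
  description dated exactly at the origin folds into $D_0$. Where a
  boundary-year description (e.g. 1758) belongs is genuinely ambiguous in
  the historical record; moving the origin resolves it either way.
* Descriptions predating the window accumulate into $D_0$ rather than
  being dropped, keeping the depletion term correct for late windows.
* Taxonomist counting is purely lexical: trim, collapse whitespace,
  case-fold, count distinct strings. Different author orders are distinct
  "taxonomists"; identical strings collapse. Estimates are known to be
  robust to the assignment rule, so no name parsing is attempted.
* Only exact duplicate binomials are collapsed (earliest year kept);
  synonymy resolution against taxonomic authorities is out of scope.
* Degenerate inputs error early and descriptively: empty windows, all-zero
  counts, fewer than 4 bins, non-uniform bin widths, negative counts,
  records after the window end (named), missing authorship.

## What the synthetic studies do and do not show

The simulator emulates demographic stochasticity of discovery, effort
trajectories, efficiency trends and heavy-tailed efficiency noise. It
does not emulate synonymy and later revision, per-event taxonomist
attribution, spatially structured effort, or reporting lags — so passing
tests demonstrate correct and robust inference *under the model family
and its stated perturbations*, not that the model is true of any real
taxon. Real-data conclusions inherit the usual caveats of effort-based
accumulation models, most importantly that $S_T$ is identified by the
curvature of a depletion signal: a series with no decline in sight
supplies little information about the pool, and the fitted intervals say
so.

## Known limitations

* Wald intervals at a boundary optimum ($\hat S_T$ at the described
  total) are unavailable by construction; a profile-likelihood interval
  would be one-sided and informative, but is out of scope here (bootstrap
  appears only as a test oracle).
* The restart criterion bounds estimate movement, not likelihood
  improvement; on near-flat likelihoods "converged" means "stationary to
  $9\times10^{-6}$", not "uniquely identified" — the interval width, not
  the convergence flag, carries the identifiability information.
* No overdispersed count family (e.g. negative binomial), no alternative
  efficiency forms, no model-selection machinery: the package implements
  one model and its designated comparator.
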