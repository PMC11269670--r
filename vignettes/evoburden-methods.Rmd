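---
title: "Models and methods behind evoburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evoburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoburden)
```

evoburden does two connected things. First, it simulates the
*evolutionary failure* of a burdensome engineered DNA construct: mutants
whose construct is broken grow faster than their engineered ancestors and
take over the culture. Second, it implements the microplate pipeline that
*measures* burden — the percentage reduction in host growth rate — and
attributes it to consumption of the host's gene-expression capacity or to
other causes. A seeded synthetic-data generator with known ground truth
closes the loop so that every statistic the package reports can be
validated end to end without external data.

## The failure model

Two cell types share a culture: engineered cells $E$ with relative growth
rate $1 - b$ (the burden $b$ is the fractional growth-rate reduction) and
failed cells $F$ with relative rate 1. A division of an engineered cell
yields a failed daughter with probability $\mu$, the failure mutation rate
per division. Time is measured in e-folding units of failed-cell growth,
and results are reported against population doublings
$D(t) = \log_2[E(t) + F(t)]$ (shifted so a single founding cell starts at
$D = 0$), because batch growth is resource-limited: a culture of a given
size represents a fixed number of doublings no matter how fast they
happened.

$$\frac{dE}{dt} = (1 - b)(1 - \mu)\,E, \qquad
  \frac{dF}{dt} = F + \mu (1 - b)\,E.$$

`solve_deterministic()` integrates this linear system with `deSolve`, in
transformed coordinates ($\log E$, which is linear in $t$, and
$F e^{-t}$, which stays bounded) so that the solver's relative tolerance
applies directly to well-scaled quantities; the trajectory matches the
closed-form solution to better than $10^{-8}$ relative error in the test
suite. Trajectories are stored on a fixed grid of doubling increments
(default 0.25) so deterministic and stochastic runs are directly
comparable.

The deterministic model seeds mutants continuously from $t = 0$ and
therefore overstates how quickly real cultures fail; the interesting
dynamics are the *waiting time* for the first mutant and occasional
jackpot events. `simulate_stochastic()` therefore simulates the underlying
birth process: an engineered cell divides with propensity $(1-b)E$ into
$2E$ (probability $1-\mu$) or $E + F$ (probability $\mu$); a failed cell
divides with propensity $F$ into $2F$. This is the unique minimal scheme
whose expectation recovers the ODEs. Three methods are provided:

* `exact` — the Gillespie algorithm, refused above a configurable
  population cap (default $10^6$) because event counts scale with the
  population;
* `tau_leap` — fixed steps (default $\tau = 0.01$) in which each
  subpopulation's growth is drawn *exactly* from the Yule (linear birth)
  distribution, a negative binomial, rather than an Euler–Poisson
  approximation; mutant arrivals are Poisson-coupled to the number of
  engineered divisions, so only their within-step timing is approximate.
  At populations beyond integer range, matched normal approximations take
  over and counts are carried as rounded doubles (guarded to $2^{60}$);
* `hybrid` (default) — exact SSA below $10^4$ cells, which is where the
  first-mutant waiting time and jackpots are decided, then leaping.

`ensemble_failure_curve()` runs seeded independent replicates and returns
each run's doublings to 50% failure and the empirical cumulative failure
curve. The published form of this summary uses 10,000 runs; the package
supports that scale (it is minutes of CPU), while tests and examples use
hundreds of runs. The culture calculators convert the model's doubling
axis into laboratory scales: one cell to a colony of $8\times10^6$ cells
is $\log_2 8\times10^6 \approx 22.9$ (~23) divisions, that colony to a
saturated 4-ml tube at $5\times10^9$ cells/ml is ~11 more. Presets for
fermenter-scale densities are deliberately left as arguments, since
saturation density depends on medium and organism.

## The microplate burden pipeline

**Corrections.** `subtract_blanks()` removes the media background (the
mean over the plate's blank wells per timepoint and channel);
`align_baselines()` shifts each replicate well so its first-hour mean
matches the strain's grand mean, removing well-to-well background offsets
without touching strain means. Alignment is applied to both density and
fluorescence channels; the underlying protocol phrase covers both
readings, and the choice is flagged here because it is an interpretation.
Note what alignment cannot do: an offset component shared by all of a
strain's replicates survives it, and such residual offsets — not
photometric noise — dominate the error budget of the exponential window
fits when they are present (see *Synthetic data* below).

**Growth rates.** For every window of 9 consecutive points whose first
corrected OD exceeds 0.03, `fit_max_growth_rate()` fits
$C(t) = C_0 e^{rt}$ by Levenberg–Marquardt least squares (initialised from
a log-linear regression, rate bounded in $(0, 1]$ per minute) and reports
the largest fitted rate. At 10-minute sampling, 9 points span 80 minutes;
"9 consecutive measurements" is taken as the operative definition. OD is
used as a direct proxy for cell count, with no calibration curve. Two
estimator properties deserve note, both visible in the tests and both
shared with any implementation of this procedure: taking the *maximum*
over noisy windows biases the estimate upward by roughly the per-window
noise (about +1.5% at the default noise level, growing for slow-growing
wells whose windows span less fold-change); and windows that straddle the
onset of saturation mis-model the OD, which is why recovery is quantified
on wells with at least ~100 fitted wells pooled.

**Production rates.** Integrating $dF/dt = p\,C(t)$ gives
$F(t) = F_0 + C_0 (p/r)(e^{rt} - 1)$, which is *linear* in $(F_0, p)$ once
$(C_0, r)$ are frozen from the same window's OD fit, so each window's
production fit is an exact least-squares solve ($g(t) = C_0 t$ in the
$r \to 0$ limit). The largest $p$ across windows is reported. Windows
overlapping saturation can inflate the maximum by a few percent — the
frozen exponential under-tracks the flattening OD — which stays well
inside the 5% recovery target.

**Quality control.** The original protocol removed outlier wells by
manual inspection of fits, which is not reproducible; the package instead
flags winning fits with $R^2 < 0.95$ (`flag_low_r2`) and accepts an
explicit exclusion list (`exclude`), never removing anything silently.

## Plate normalization and burden statistics

Most strains on a plate carry negligible burden, so the plate's
"no-burden" reference rate is estimated from the distribution of rate
estimates of non-control strains: a Gaussian-kernel density (exact
summation, evaluated on a 2048-point grid padded by 4 bandwidths) is
scanned for strict local maxima, and among peaks at least 50% as tall as
the tallest, the one at the *highest rate* is the reference
(`no_burden_reference()`). This keeps a shoulder of mildly burdened
strains from dragging the reference down. Replicate-level values are used
(a strain-mean option would put less mass at the mode). All measurements
on the plate, controls included, are divided by the reference.

Bandwidths are instrument- and unit-dependent. The published growth-rate
bandwidth of 0.014 presumes per-hour rates; this package's fits are per
minute (rates around 0.02), so the default is 0.014/60, with the
bandwidth an explicit argument everywhere. The production-rate default of
300 fluorescence units matches the synthetic generator's instrument
scale (no-burden production near 3000 units/OD/min) and must be rescaled
for other instruments.

Burden is $100(1 - \text{normalized growth rate})$ per measurement,
summarised per part. One-sample one-tailed t-tests ("burden > threshold")
are run against 0, 10, 20, 30 and 45% — the last being the bound above
which the failure model predicts a construct cannot even be cloned — with
Benjamini–Hochberg correction across parts at 5% FDR for the test against
zero. Confidence limits are t-based; with zero variance the p-value is 0
above the threshold and 1 otherwise, a documented convention.
`sem_burden_trend()` regresses per-part SEM on mean burden (OLS,
two-tailed slope test): replicate variance inflation at high burden is
the measurable signature of mutant takeover already underway in replicate
cultures.

## Expression capacity and other burden

The host strain carries a constitutive chromosomal GFP cassette whose
production rate reports the remaining shared gene-expression capacity.
On normalized axes (no-burden = 1 on both), control strains expressing a
graded series of a neutral fluorescent protein trace the trade-off line
between growth and expression capacity. `fit_anchored_deming()` fits that
line by Deming regression — errors in both variables, variance ratio
$\lambda$ (default 1 on the normalized axes) — constrained through the
anchor $(1, 1)$: only the slope is free, and it has a closed form from
the second moments about the anchor, verified against brute-force 1-D
minimisation to $10^{-6}$. Control points enter as per-plate strain
means.

For an eligible part (burden BH-significant, mean burden > 10%, no
fluorophore interfering with the GFP channel — GFP, YFP and the amilCP
chromoprotein are excluded, unknown annotations conservatively excluded),
`other_burden_test()` asks whether the part's growth rate is lower than
the line predicts from its GFP footprint. Location-scale t distributions
are fitted by maximum likelihood to the part's growth and GFP
measurements; because the hypothesis concerns the part's *location*, the
2-D distribution used for the decision is the sampling distribution of
the mean — the fitted t rescaled by $\sqrt{n/(n-1)}/\sqrt{n}$ with
$n - 1$ degrees of freedom, which reduces to an exact t-test for
Gaussian data and keeps the null p-values uniform (verified by simulation
in the test suite). Degrees of freedom are fitted freely (floored at 3)
only for $n \ge 30$; assay-scale replicate sets use $n - 1$, because
free-df ML fits at $n \approx 12$ underestimate the scale and break
calibration. The one-tailed p-value is the Monte Carlo mass on the
null-consistent side (growth at or above the line); a documented
compatibility mode (`halve_above`) instead halves the mass on the other
side, the literal reading of the source protocol, which we do not use by
default because it cannot reject for points deep on the other-burden
side. The decomposition is $b_{GE} = 100(1 - \hat y(\bar x))$ and
$b_O = b - b_{GE}$; the interval on $b_O/b$ is a parametric bootstrap
from the fitted t distributions and is deliberately not truncated, so
ratios above 1 (GFP production above the no-burden level) are possible.
`classify_burden_sources()` applies the eligibility rules, runs the test
per part, and BH-adjusts across the eligible set.

## Synthetic data: what it emulates and what it does not

`generate_plate()` emulates the standard assay: 96 wells — 23 test and 5
control strains in triplicate plus 12 blanks — read every 10 minutes for
6 hours. Growth curves are exactly exponential below 30% of the carrying
OD and relax smoothly into saturation (the window fits only ever see the
exponential region; a plain logistic decelerates measurably inside the
fitting windows, which real early-phase curves do not). Fluorescence is
the trapezoid-integrated $\int p\,C\,dt$ on a 1-minute internal grid plus
baseline. Noise has four components, each a config field: additive
measurement noise (OD sd 0.003, fluorescence sd 30), per-well baseline
offsets (sd 0.01 OD), and a per-plate multiplicative rate effect
(±15%).

Defaults that are choices rather than measurements: the no-burden growth
rate 0.021/min (a ~33-minute doubling, consistent with rich-medium
microplate cultures and with a ~1% bandwidth-to-rate ratio for the
published KDE bandwidth); production scale 3000 units/OD/min; and the
true capacity-line slope 1 (pure expression burden lies on the identity
line; injected "other burden" reduces growth at unchanged GFP). The
test-strain burden mixture follows the composition printed for the
301-part survey this assay comes from: ~60% of parts with no measurable
burden, a shoulder below 10%, and a tail with ~11% above 10%, ~6% above
20%, ~2% above 30%, nothing above 45%.

Takeover wells (`generate_takeover_well()`, or `takeover_mu > 0` in a
config) run the stochastic failure model through a seeded preculture —
default 23 doublings, the expansion of a single founding cell into a
colony — and observe the resulting engineered/failed mixture in the
well, so the apparent growth rate drifts from $(1-b)r_0$ toward $r_0$
and replicate wells diverge with the timing of their first mutants. The
default depth is chosen from the model's own failure-time distribution:
at the reference parameters ($b = 0.4$, $\mu = 10^{-4}$) deeper
histories put nearly every replicate past complete takeover, which
erases the variability the generator exists to emulate. With the
realistic burden mixture, only a few percent of parts are takeover-prone
at plausible mutation rates, so the SEM-vs-burden demonstration uses a
designed dose-response cohort (burdens spanning 0–0.45 evenly, 299
parts) rather than the default mixture.

What the generator does *not* emulate: reader optics (gain, path length),
evaporation and edge effects, growth-phase-dependent production,
correlated replicates from a shared preculture (replicate takeover wells
are independent), and multiplicative fluorescence noise (an additive
model is the default; real noise is likely mixed). Passing tests
therefore validate the algorithms and their calibration, not the full
error structure of any particular plate reader.

## Numerical choices and degenerate inputs

* ODE tolerances: `rtol = 1e-12` with scale-aware absolute tolerances;
  trajectory grid 0.25 doublings.
* Window NLS: log-linear initialisation, `ftol = ptol = 1e-12`, rate
  bounded in $(0, 1]$; windows with non-positive fitted rates are skipped
  for the maximum but counted in diagnostics; a well with no eligible
  window is `no_growth`, one where every fit diverges is `fit_failed`.
* KDE grid: 2048 points over the data range padded by 4 bandwidths;
  a peak is a strict local maximum on the grid; a monotone density falls
  back to the global maximum.
* Zero-variance t-tests: p is 0 or 1 by the sign of (mean − threshold).
* `effective_plasmid_rate()` is capped at 1, since $\mu$ is a
  probability per division.
* Interpolation of the 50%-failure time is linear in failed fraction
  between stored points, making the summary independent of the reporting
  grid.

## Problem sizes used in validation

The shipped tests and the acceptance script size their simulations for a
single CPU: deterministic–analytic comparisons on a 12-point parameter
grid; 100–200 stochastic runs per ensemble comparison; three 96-well
plates (252 fitted wells) for rate-recovery medians; a 23-part cohort on
four plates for plate-effect removal; a 46-part, nine-replicate cohort
for the end-to-end ordering check; 200 null and 100 alternative
simulations for the other-burden calibration and power; and the 299-part
dose-response cohort for the takeover trend. Published-scale runs
(10,000-run ensembles, 301-part cohorts) use the same code paths with
larger arguments.
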