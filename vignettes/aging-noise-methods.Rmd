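---
title: "Modeling and measuring gene-expression noise over the replicative lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring gene-expression noise over the replicative lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agenoise)
```

## The scientific problem

Single yeast mother cells tracked in a microfluidic device over their whole
replicative lifespan show a striking pattern: the cell-intrinsic noise of a
reporter driven by the GAL1 promoter *decreases* over the first ~16
generations of life, plateaus, and then rises sharply in a terminal
"catastrophe" phase covering roughly the last four generations.  A
parsimonious mechanistic explanation is that aging speeds up chromatin-state
transitions at the promoter: if the opening rate $r_{on}$ and the closing
rate $r_{off}$ both increase *in the same proportion*, the mean expression
level stays constant while the switching noise falls.

`agenoise` implements everything needed to study this quantitatively:

1. an exact stochastic simulator and an exact moment solver for the
   two-state (telegraph) promoter model with mRNA and protein stages,
2. moment-matching inference of $(r_{on}, r_{off})$ from a measured
   mean and CV,
3. the parameter sweeps that contrast the chromatin mechanism against
   changes in transcription/degradation rates,
4. the trajectory-analysis pipeline (background subtraction, ON/OFF
   classification, lifespan filters, two-generation windows, death-aligned
   catastrophe analysis), and
5. a synthetic cohort generator that emulates the statistical structure of
   microfluidic mother-cell data with full ground truth, so the pipeline is
   testable end to end without access to any experimental recording.

## The stochastic model

The core model is the canonical eukaryotic gene-expression scheme:

$$
\mathrm{OFF} \xrightarrow{r_{on}} \mathrm{ON},\quad
\mathrm{ON} \xrightarrow{r_{off}} \mathrm{OFF},\quad
\mathrm{ON} \xrightarrow{k_m} \mathrm{ON} + M,\quad
M \xrightarrow{\gamma_m} \varnothing,\quad
M \xrightarrow{k_p} M + P,\quad
P \xrightarrow{\gamma_p} \varnothing .
$$

`simulate_ssa()` performs an exact event-by-event Gillespie simulation of
this network.  Randomness comes from a dedicated xoshiro256++ generator
seeded from the user's integer seed, so identical inputs give bit-identical
trajectories and the session RNG is never touched.  Ensemble replicates use
substreams derived from the master seed through a splitmix64 chain
(replicate $r$ is seeded by the $r$-th output), which gives deterministic,
effectively independent streams.

Because every propensity is linear in the state, the first and second
moments of the stationary law obey a closed $8\times8$ linear system (in
$E[G], E[m], E[p], E[Gm], E[Gp], E[m^2], E[mp], E[p^2]$, with $G$ the ON
indicator).  `moment_oracle()` solves that system exactly and is the
independent oracle used throughout the test suite: the simulator must agree
with it within Monte-Carlo error, and it in turn must agree with the
textbook closed forms

$$
p_{on} = \frac{r_{on}}{r_{on}+r_{off}},\qquad
\langle m\rangle = \frac{k_m\,p_{on}}{\gamma_m},\qquad
F_m = 1 + \frac{k_m\,r_{off}}{(r_{on}+r_{off})(r_{on}+r_{off}+\gamma_m)},\qquad
\langle p\rangle = \frac{k_p \langle m\rangle}{\gamma_p}.
$$

```{r oracle}
moment_oracle(promoter_rates(0.0229, 0.0348), kinetic_rates())
```

### Default parameters and why

The promoter defaults are the fitted young-cell rates of the native GAL1
promoter, $r_{off} = 0.0348\,\mathrm{min}^{-1}$ and
$r_{on} = 0.0229\,\mathrm{min}^{-1}$.  The downstream kinetic rates are not
published alongside them, so the package declares its own defaults, chosen
to be ordinary yeast values and exposed in every interface:

| parameter  | default                      | rationale                                    |
|------------|------------------------------|----------------------------------------------|
| $k_m$      | 1 mRNA/min (ON state)        | typical active-promoter transcription rate   |
| $\gamma_m$ | 0.05 /min                    | ~14 min mRNA half-life                       |
| $k_p$      | 2 protein/mRNA/min           | ordinary translation efficiency              |
| $\gamma_p$ | $\ln 2/90$ /min              | stable fluorescent reporter: loss is purely dilution at a 90-min generation time |

Protein removal is continuous first-order dilution in the core model; the
explicit-division alternative (binomial partitioning at division) lives in
the cohort generator, where generation boundaries exist.  The steady-state
sweeps need the dilution reduction, which is the standard equivalence.

`ensemble_stats()` measures at a single endpoint $t_{end}$ rather than
time-averaging; the default $t_{end} = 10/\min(\gamma_m, \gamma_p,
r_{on}+r_{off})$ guarantees relaxation from any initial condition.  The
default initial condition draws the promoter from its stationary law and
puts $m$ and $p$ at their state-conditional means (rounded), which removes
most of the burn-in transient.

### Fitting promoter rates

`fit_promoter_rates()` inverts the moment relations: the target mean fixes
the occupancy $p_{on}$ exactly, and the total switching rate
$s = r_{on} + r_{off}$ is found by root finding on the strictly decreasing
map $s \mapsto \mathrm{CV}_p(s)$ at fixed occupancy (bisection on
$\log_{10} s$, default range $10^{-7}$–$10^{4}$ per min, tolerance
$10^{-12}$).  The CV cannot be pushed below the fast-switching floor
$\mathrm{CV}^2_{floor} = (1 + k_p/(\gamma_m+\gamma_p))/\mu_p$; infeasible
targets raise an error that reports the floor.  At full occupancy the
boundary solution $r_{off} = 0$ is returned.

## The parameter sweeps

`diagonal_sweep()` scales both switching rates by common factors and is the
quantitative statement of the "equal proportions" mechanism: the oracle
mean is conserved to machine precision while CV and Fano fall monotonically.
`vertical_sweep()` holds $r_{off}$ fixed and raises $r_{on}$ — the
alternative route, on which noise also falls but the mean must rise.
`nonchromatin_sweep()` asks how much noise reduction is achievable *without*
touching the promoter: it varies $k_m$ and $\gamma_m$ by up to ten-fold in
both directions on a log grid and rescales the translation rate
($k_p' = k_p \gamma_m' k_m / (\gamma_m k_m')$) so the mean is unchanged,
then reports the largest relative CV decrease on the grid.  The full
published-scale exploration (a ~40×40 grid, >1,600 parameter sets) runs
through the same code path; the test suite uses a 9×9 grid, which already
brackets the extremes of the accessible noise range since the CV response
is monotone along each grid axis.

```{r sweeps}
di <- diagonal_sweep(promoter_rates(), scale_factors = c(1, 2, 4, 8))
di[, c("scale", "mean_p", "cv_p", "fano_p")]
nc <- nonchromatin_sweep(fold = 10, n_grid = 9)
attr(nc, "max_cv_decrease")
```

## The trajectory-analysis pipeline

The pipeline starts from three plain tables — per-cell fluorescence
snapshots, per-cell division times, per-frame pixel samples — and follows
the experimental analysis protocol, with every convention fixed explicitly:

* **Background**: the frame background is the nearest-rank bottom
  10th-percentile pixel (`ceiling(0.1 n)`-th order statistic) of the frame;
  corrected intensities may go negative and are retained, because clamping
  would bias window means upward.
* **ON/OFF**: a cell is OFF when its lifespan-average corrected intensity
  is below 1000 a.u.; the comparison is inclusive (exactly 1000 is ON).
* **Generations** are 1-based half-open intervals
  $[b_{g-1}, b_g)$ between recorded division boundaries; a snapshot exactly
  on a boundary belongs to the generation that starts there.  Snapshots
  outside all intervals are dropped and counted.
* **Filters**: ON cells with lifespan ≥ 10 generations are kept; all
  snapshots from each cell's last 4 generations are removed from the
  normal-aging statistics (they return in the death-aligned analysis).
* **Windows** are non-overlapping two-generation blocks aligned from each
  cell's first generation (window $w$ = generations $2w-1, 2w$); a window
  is emitted only if both generations survive the filters, each carries at
  least 4 snapshots, and the window at least 8.  The trailing odd
  generation is discarded.  A window straddling the last-4 cutoff loses a
  generation and is therefore dropped by the both-generations rule, which
  is the intended behavior.
* **Per-cell first**: CV and Fano are computed per cell within a window and
  only then averaged across cells.  This ordering is what makes the
  statistic *cell-intrinsic*; pooling all cells' snapshots first would
  re-introduce cell-to-cell (extrinsic) variability, and a regression test
  asserts the two give different answers on heterogeneous cohorts.
* **Population summaries** report mean ± SD of per-cell window means and
  mean ± SEM of per-cell CVs/Fanos; windows with fewer than 10 cells are
  flagged and excluded from summary use rather than silently dropped.
* **Death alignment**: the catastrophe analysis indexes generations
  backwards from death and forms two-generation windows from the last
  generation inward, pooling cells on a generations-before-death axis
  (cells are not stratified by their exact final generation — with
  desk-scale cohorts per-stratum counts would fall below the 10-cell
  reporting rule almost everywhere).
* **Statistics conventions**: sample (n−1) variance everywhere, SEM =
  $\sigma/\sqrt{n}$, CV as a ratio (not %), Pearson correlation for the
  expression/division-time check.  Correlations are omitted (with a
  reason) for generations with fewer than 3 cells or zero variance.

## The synthetic cohort generator

`generate_cohort()` produces the three input tables plus ground truth.  It
emulates, per cell: a replicative lifespan from a discretised gamma
distribution (mean 23, shape 5) truncated to [4, 53]; baseline generation
durations uniform on 40–90 min, which at the 10-min snapshot interval
yields 4–9 snapshots per generation; telegraph-model expression simulated
exactly with promoter rates updated at each division according to the
aging schedule; binomial partitioning (retention 0.5) of mRNA and protein
at division with no active protein degradation inside a generation (the
reporter is stable — dilution happens through division); a terminal
catastrophe phase in which the mean and SD of generation durations are
inflated (defaults ×1.8 and ×2.5 at the last generation) and an extrinsic
lognormal multiplier (log-SD 0.3 at the last generation) widens the
intensity distribution; a configurable fraction of OFF cells simulated
with a 50-fold reduced transcription rate; and per-frame background
offsets (normal, mean 300 a.u., SD 30) plus Gaussian measurement noise
(SD 25 a.u.) on every snapshot.

Three design choices deserve explanation:

* **Intensity is a concentration, not a copy number.**  The recorded
  signal is `intensity_scale × protein / volume` with the cell volume
  growing linearly from 1 to 2 over each generation.  Imaging reports
  average pixel intensity inside a fixed region, i.e. concentration.  A raw
  copy-number signal would double deterministically every cycle, and that
  sawtooth — identical in young and old cells — would dominate the
  within-window variance and mask exactly the promoter-noise signal the
  windowed statistics are designed to expose.  With the volume
  normalization the generation-mean profile is flat and within-window
  fluctuations reflect expression stochasticity.
* **Warm-up generations.**  Three unrecorded generations are simulated
  before generation 1 so that recorded traces start at the stationary
  explicit-division state, mirroring cultures grown to steady state before
  loading.  Without them the first windows carry a systematic transient.
* **The catastrophe is a ramp, not a step.**  Duration inflation and the
  extrinsic noise multiplier scale linearly over the last four
  generations, peaking at death.  Observed terminal dynamics are
  graded — noise and durations are highest in the very last generation —
  and a flat step would make the two final death-aligned windows
  statistically identical, leaving the final-window contrast undetectable
  by construction.

The proportional aging schedule defaults to a three-fold rate increase
reached at generation 16.  The magnitude of the true aging-associated rate
change is not identifiable from published summary numbers, so this value
is a declared assumption chosen to give a clearly detectable windowed CV
decrease at cohort sizes near 60 cells; the generator makes no attempt to
reproduce the experimentally reported ~35 % CV / ~57 % Fano decreases, and
the package's tests treat those only as qualitative calibration.

What the generator does *not* emulate: cell-cycle-phase expression
structure, segmentation or tracking artifacts, focus drift, photobleaching,
mother-bud misassignment, and correlated (frame-to-frame) background
drift.  A pipeline that passes the round-trip tests is therefore validated
for its statistical logic, not for robustness to imaging pathology.

```{r cohort}
coh <- generate_cohort(cohort_config(n_cells = 12, off_fraction = 0),
                       seed = 1)
res <- run_pipeline(coh$traces, coh$divisions, coh$pixels)
res
```

The five `scenario_preset()` configurations vary the young-cell rates, the
schedule strength and the lifespan distribution to reproduce the
qualitative ordering of the five characterized strains (noisier and
brighter without the upstream repressor; weakest aging response and longest
lifespans without the global remodeling regulator; higher occupancy with
nucleosome-disfavoring promoter edits; noise already at floor when both
modifications combine, modeled as `constant` mode).

## Problem sizes and numerical tolerances

The oracle/closed-form comparisons run on 5×5 rate grids around the fitted
values at a relative tolerance of $10^{-10}$ (the linear solve is exact up
to conditioning).  Simulator/oracle agreement is asserted within 3
Monte-Carlo SEM on ensembles of 2000 replicates, the published ensemble
size.  Fitting round-trips demand $10^{-6}$ relative accuracy from exact
moments and 15 % from 2000-replicate ensembles (the propagation of a ~1 %
SEM on mean and CV through the inversion).  Pipeline round-trips use
cohorts of 60 ON cells, the scale of the experimental cohorts (52–102
cells); majority-vote properties (catastrophe contrasts, absence of trend
in constant mode) are evaluated over 10 seeds.

## Known limitations

* The model omits upstream GAL-network regulation (the repressor feedback
  and inducer cascade), mRNA export, protein maturation and
  cell-cycle-gated transcription; it is the minimal scheme consistent with
  mean/CV/Fano phenomenology at the promoter level.
* The fitted rates are adopted verbatim, but the non-promoter rates used
  in the original fit are unknown; absolute protein numbers are therefore
  not comparable to fluorescence units, and only noise ratios and trends
  should be interpreted.
* The moment oracle requires positive degradation/dilution rates; pure
  accumulation regimes have no stationary law and must be studied with the
  simulator.
* Death-aligned pooling on a generations-before-death axis is one reading
  of "grouping cells by their last generation"; per-stratum analysis is
  possible from the per-cell output (`catastrophe_analysis()$per_cell`)
  if cohorts are large enough.
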