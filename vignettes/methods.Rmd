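---
title: "Model and methods: the hybrid lymph node-blood T cell simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the hybrid lymph node-blood T cell simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lnblood` simulates the generation of effector and memory T cells across two
coupled physiological compartments: a spatially explicit, agent-based lymph
node (LN) paracortex where antigen presentation, T cell priming and clonal
expansion happen cell by cell, and a well-mixed blood compartment described
by ordinary differential equations. This vignette explains the model, its
assumptions, the parameters that matter, the numerical choices, and what the
synthetic scenarios do and do not say about real immune responses.

## The two compartments

### Lymph node (agent-based)

The LN paracortex is a truncated-cone mask over a cubic lattice with 10 um
spacing (about one T cell diameter). The cone holds ~170,000 T cells at the
empirically observed density of 4.0e6 cells/mm3 when run at full scale; a
`scale` factor shrinks the lattice volume and the target population
proportionally for desk-scale work, and the LN-to-blood conversion factor is
adjusted inversely so that blood concentrations are scale-invariant in
expectation. Each lattice site can hold up to `site_capacity` (8) cells;
mean steady-state occupancy is 4.

Agents are CD4+ and CD8+ T cells in five states - naive (N), activated (A),
effector (E), central memory (CM), effector memory (EM) - and dendritic
cells, either antigen-bearing (Ag-DC) or licensed (LDC). Naive and CM cells
enter through high endothelial venule (HEV) sites placed in the mid-cone
band, at rates proportional to their blood concentrations (multiplied by
`extra_recruitment` while DCs are present, reflecting inflamed-LN
recruitment). Unbound cells perform an unbiased random walk at ~10 um/min
with volume exclusion.

Egress is modelled as a uniform per-step hazard for unbound N/E/CM/EM cells:
efferent sinus access is distributed throughout the paracortex rather than
concentrated on one face, so every in-cone site is an efferent-lymphatic
(EL) site and the per-step exit probability is derived at construction as
`dt / transit`. This makes the mean naive transit time equal the calibrated
16 h at any scale factor, and the steady-state flow ~1000 cells per million
LN cells per minute follows from population/transit balance. (A strictly
basal exit plane was tried first; pure diffusion to a single absorbing face
adds a density gradient whose size grows with cone height, which makes
transit scale-dependent - a known artifact of single-sink geometries, not a
feature of LN physiology.) Activated and DC-bound cells never exit,
mirroring the retention of recently stimulated cells.

### Blood (ODE)

The blood holds eight concentrations (N/E/CM/EM for each lineage) governed
by linear turnover: thymic naive output declining 5% per year (compounded
continuously), naive loss closed by quasi-equilibrium (`delta_N =
S(0)/N(0)`), short-lived effectors lost by death and recruitment to sites of
infection (a pure sink - infection-site dynamics are out of scope), EM cells
dying, being recruited, or converting to CM, and CM cells decaying slowly
(CD8 CM half-life 20 years). LN net output enters not as an ODE term but as
a state increment before each blood step: net (exited - recruited) for the
recirculating N/CM pools, exits only for E/EM. The system is integrated with
forward Euler; first-order convergence is verified in the tests.

Blood turnover constants were calibrated once against the long-run and
response-level behavior the model is meant to reproduce: `delta_N4 = 6.0e-4`
and `delta_N8 = 3.8e-4` per day were solved so a 20-year blood-only run
declines from 450 to ~210 (CD4) and 320 to ~170 (CD8) cells/mm3 under the
5%-per-year thymic decline; EM turnover and EM->CM conversion were set so
post-contraction memory sits near 5% of the response peak with CD8 memory
dominated by EM->CM conversion.

## Priming and the signal-strength differentiation model

Cognate T cells (frequency `cognate_frequency = 1e-4` of naive recruits)
binding an Ag-DC or LDC do so with probability `pMHC / (pMHC + k_bind)` in
the class-matched pMHC (pMHC-II for CD4, pMHC-I for CD8): smooth, monotone
and bounded. Each DC draws its antigen load once at entry from a lognormal
around the scenario's pMHC level (`dc_pmhc_sdlog = 0.55`) - DC-to-DC
heterogeneity in antigen capture is expected biologically, and it is what
makes threshold checkpoints graded rather than all-or-none. Bonds last a
fixed `bind_time` (480 min; 240 min for CM cells), during which the cell
accumulates signal at pMHC x time (x `cm_signal_efficiency` for CM), only
until its first division.

At unbinding the accumulated signal is compared (inclusively) against
thresholds:

* below `priming_threshold`: the cell reverts (N stays N, CM stays CM) and
  forgets its stimulation;
* at or above it: the cell activates and divides;
* at or above `aicd_threshold`: activation-induced cell death. This upper
  cutoff ships enabled: it is part of the signal-strength picture (both
  insufficient and excessive stimulation are lethal) and it caps the
  expansion of the most strongly stimulated clones.

The number of division rounds follows the signal-strength premise that
stronger stimulation drives greater clonal expansion: `rounds = base +
floor(div_signal_slope * log2(signal / priming_threshold))`, capped at
`div_max_extra` extra rounds, with `div_signal_slope = 0` recovering a fixed
program. With the baseline slope (3.4 rounds per doubling of signal excess)
the per-DC antigen-load spread maps into clone sizes spanning ~10 to several
thousand cells, which is what produces the observed heavy-tailed progeny
distribution (disparity index ~0.8, ~50-fold max/median spread) without any
explicit per-clone randomness in the program length. After the activation
rounds the signal is checked again: cells at or above `effector_threshold`
become effectors (two further division rounds); cells below become CM with
probability `prob_cm` if their memory branch is open, and otherwise remain
on the effector track as short-lived effectors (death by neglect, realized
in blood). Completed effectors with signal at or above `em_threshold` and an
open memory branch convert to EM with probability `prob_em = 0.25` (the
midpoint of the 0.1-0.4 literature estimate).

CD4 effectors license Ag-DCs on contact (probability `dc_licensing_prob`
per minute of contact), irreversibly multiplying both pMHC displays by
`licensing_boost`. Under the default rule set (`cd8_requires_ldc`), CD8
cells may be primed by unlicensed Ag-DCs but their memory branch is closed
unless the priming DC was licensed - this is what delays CD8 memory relative
to CD4 and what couples CD8 memory output to CD4 help. The DC-ablation
protocol disables this rule, matching the LPS/Listeria-activated DCs used in
the experiments it mimics.

Newly formed CM cells are refractory for `cm_refractory_days` (7 days,
memory maturation) before they can re-engage a DC. This matters: without
the maturation delay, CM produced early in a primary response re-bind DCs
and re-expand within the same response - a positive feedback that produces
unbounded clone growth. With it, within-response re-activation is
impossible, and recall amplification comes from the recirculating blood CM
pool built during the primary. Re-activated CM run a signal-graded program
from a shorter base (`divisions_activated_cm = 2`), and CM recirculating
through an uninfected LN simply transit and exit like naive cells.

## Scheduling and tunable resolution

Each step processes the LN first (recruitment, motility, binding/signal/
unbinding, checkpoints and proliferation, licensing, egress and death, in
that order, over a freshly shuffled agent order to avoid scan bias), then
injects the LN net output into blood, then advances the blood ODEs across
the same interval. Every scenario starts with a 3-day LN-only
pre-simulation with blood frozen (naive 450/320 cells/mm3) to settle the
spatial distribution.

When the LN holds no DCs, no bound cells, and no A/E/EM cells, it is
suspended and only the blood advances, with a coarse step (0.01 day); one
day before the next scheduled DC recruitment the LN is re-activated and
re-equilibrated against current blood concentrations before antigen
arrives. This is what makes 600-day recall experiments tractable: the LN
runs only during the two response windows.

## Numerical choices

* ABM step `abm_dt` defaults to 25 s; the experiment drivers and tests run
  at 60 s, under which every process is still finely resolved (shortest
  binding time 240 min = 240 steps; cell cycle 5 h = 300 steps; egress
  hazard ~1e-3/step) and whole scenarios fit desk-scale runtimes.
* Blood sub-stepping defaults to 100 Euler substeps per ABM step; blood-only
  epochs use 0.01-day steps. The fastest blood rate (0.8/day) makes both
  regimes deeply stable; accuracy is checked against closed forms.
* Threshold comparisons are inclusive (>=), fixed once and tested at the
  boundary.
* All randomness derives from R's RNG: the compiled core seeds an internal
  xoshiro256+ stream from R's generator at construction, so `set.seed()`
  makes whole simulations bit-reproducible, which the tests assert.
* Division placement requires a free neighboring site; if none exists the
  division is deferred, never lost. Recruitment retries a bounded number of
  HEV sites and skips (untallied) if the lattice is locally full.

## Scales and problem sizes used by the tests

The default test and acceptance runs use one tenth of the full LN (~17,000
T cells, 5 replicates) for the steady-state, acute and lineage analyses,
7.5% (3 replicates) for the 630-day recall runs, and 2.5-3% (5 replicates)
for the DC-ablation and DC/pMHC sweep protocols, always with the full-scale
DC numbers scaled consistently. These sizes keep the scenario suites in the
minutes range while leaving enough cognate precursors per run (tens per
lineage, pooled across replicates) for stable statistics. Because the
pronounced clone-size disparity makes single-run totals heavy-tailed,
replicate peaks and concentrations are summarised by their median rather
than their mean; even so, quantities carried by a handful of CD4 precursors
(the CD4 recall trace especially) retain substantial spread at these
scales.

## What the scenarios emulate - and what they do not

The acute scenario (Ag-DCs recruited over days 0-2 at pMHC 200, dying after
5 days) is a hypothetical acute infection, not a fit to any specific
pathogen; comparisons to real infection data are qualitative, at the level
of peak timing, contraction, memory maintenance and recall amplification.
Single antigen, single LN (standing in for all ~700, via the compartment
scaling), no DC subsets, no TCR affinity spectrum, no site-of-infection
compartment (recruitment there is a sink), no chemokine guidance, and no
explicit stromal network. Passing tests therefore show that the mechanism
set reproduces the characteristic population dynamics and clonal statistics
at desk scale - not that any particular parameter value is physiologically
identified.

## Parameter provenance

Values stated directly by the literature the model builds on: cognate
frequency 1e-4, EM conversion probability 0.1-0.4 (0.25 used), DC lifespan
~5 days, naive blood concentrations 450/320 cells/mm3, thymic decline
5%/year, CD8 CM half-life 20 years, DC recruitment window 2 days, sweep
ranges 50-300 DCs and 100-300 pMHC. Everything else - thresholds, division
mapping, licensing boost, EM/CM turnover, the LN-to-blood conversion - was
calibrated once against the published steady-state values (170,000 cells,
16 h transit, ~1000/1e6/min flow), the 20-year naive endpoints, the primary
peaks (0.91 and 2.49 cells/mm3 near days 6 and 8), the ~5% memory plateau,
the day-600 CM levels, and the clonal-heterogeneity statistics (disparity
~0.81, ~50-fold spread, largest progenies ~2000/~8000), and then frozen.
The baseline configuration ships as
`system.file("extdata", "baseline_params.yaml", package = "lnblood")`.

## Sensitivity analysis

`lhs_sample()` builds stratified (Latin hypercube) designs over the declared
parameter ranges (`usa_ranges()`), `prcc()` computes partial rank
correlation coefficients with t-based significance (tiers +/++/+++ for
p < 0.05/0.01/0.001, uncorrected and documented as such; no multiple-testing
correction is applied because the analysis is used as a screening ranking),
and `run_sensitivity()` chains design -> replicate-averaged scenario runs ->
PRCC tables for LN production and blood concentration readouts. The full
published design sizes (408 LN / 100 blood experiments x 5 replicates) are
supported and runnable through the CLI (`lnsim sensitivity --set ln --n
408`), but take hours; they are meant as batch jobs, not test-suite
content. The machinery itself is validated on constructed cases: exact
monotone dependence (PRCC = 1), rank invariance under monotone transforms,
stratification invariants, and false-positive calibration on independent
noise.

## Known limitations

* **No lymph-node swelling.** The lattice is fixed; during a response the
  population can approach the site-capacity ceiling, so recruitment boosts
  much above 2x saturate the grid rather than expanding it. Real LNs swell
  severalfold.
* **Desk-scale volatility of CD4 memory quantities.** CD4 central memory in
  a scaled run is carried by a handful of precursor clones; its blood trace
  (and everything downstream of it, such as the recall:primary ratio) shows
  large seed-to-seed spread that medians over a few replicates only partly
  tame. Larger scale factors are the remedy when these quantities matter.
* **Clonal disparity versus pMHC optima.** With signal-graded expansion,
  lymph-node output rises with pMHC display up to the activation-induced
  death cutoff and then saturates. At the calibration that reproduces the
  heavy-tailed progeny distribution, the sweep therefore shows saturation in
  pMHC for CD4 effector and CD8 CM output rather than a pronounced interior
  optimum: lowering the death cutoff restores the optimum but collapses the
  clone-size disparity. The two observations pull the upper cutoff in
  opposite directions and are not jointly reproduced by this rule set.
* **One antigen, one lymph node, sessile DCs, no infection-site dynamics**,
  as set out above; comparisons to infection data are qualitative.
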