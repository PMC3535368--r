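---
title: "Modelling and fitting slow cyanide binding to hexacoordinate neuroglobin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and fitting slow cyanide binding to hexacoordinate neuroglobin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngbkin)
```

## The system and the model

Human neuroglobin (Ngb) is a hexacoordinate globin: in the resting met
(Fe^3+^) state the heme iron is axially ligated by both the proximal
His96 and the distal His64, so an external ligand such as CN^-^ can only
bind after the distal histidine transiently dissociates. The package
models this internal competition as the two-step mass-action scheme

$$\mathrm{Ngb_{hexa}}
  \;\underset{k_H}{\overset{k_{-H}}{\rightleftharpoons}}\;
  \mathrm{Ngb_{penta}}
  \;\underset{k_{off,L}}{\overset{k_{on,L}[L]}{\rightleftharpoons}}\;
  \mathrm{Ngb_{penta}}{\cdot}L$$

with first-order histidine dissociation ($k_{-H}$) and rebinding
($k_H$), bimolecular ligand capture by the pentacoordinate iron
($k_{on,L}$, M^-1^ s^-1^), and first-order release ($k_{off,L}$).
Heme *b* additionally sits in the pocket in two stable orientations, A
and B (related by a 180° rotation about the α–γ *meso* axis), populated
roughly 1:2 in human Ngb. The two orientation isomers are chemically
distinct, interconvert far more slowly than any binding experiment, and
bind ligand at different rates, so the model treats each isomer (and
each cysteine redox state) as an independent protein species; all
species share a single finite ligand pool, which couples them through
depletion.

When histidine exchange is fast compared with ligand capture
($k_{on,L}[L] \ll k_H, k_{-H}$), the scheme collapses to a single
apparent bimolecular step,

$$k_{obs} = \frac{k_{on,L}}{1 + K_H}, \qquad K_H = \frac{k_H}{k_{-H}},$$

so the observed kinetics reports on the His–iron bond stability ($K_H$)
and the capture rate. `effective_kobs()` implements this formula and
`rates_from_kobs()` its inverse: given an apparent rate it manufactures
microscopic rates deep inside the rapid pre-equilibrium regime
($k_{-H} = 1\ \mathrm{s^{-1}}$ by default, orders of magnitude above the
capture flux $k_{on,L}[L] \sim 10^{-3}\,\mathrm{s^{-1}}$ at the
concentrations of interest). The published experiments give only
apparent rates, never microscopic His-exchange rates, so the default
$K_H = 9$ (90% hexacoordinate at rest) is a representative placement,
not a measured value; every result computed here depends only on
$k_{obs}$, which tests confirm by comparing the full ODE against the
collapsed closed form (agreement within 5% in the regime above, and
0.1% equilibrium agreement with the depletion solver).

## Observed time courses and the two rate conventions

The reference experiment mixes 100 µM protein (≈2:1 B:A) with 500 µM
KCN at $t = 0$ and follows ^1^H NMR peak intensities: met (high-spin)
marker methyls decay, cyanomet (low-spin) resonances grow, each
monoexponentially with time constant $T$ per isomer. Two conventions
connect $T$ to rate constants:

* **paper mode** — the published convention: $1/T = k_{obs}[L]$ with
  $[L]$ the *total* ligand concentration, and any equilibrium plateau
  handled separately. `kobs_from_time_constant(T, L)` returns
  $1/(T \cdot 60 \cdot L)$ (T in minutes).
* **reversible mode** — the exact pseudo-first-order relaxation:
  $1/T = k_{obs}[L] + k_{off}$, so the observed rate is split using the
  equilibrium free fraction. Both modes coincide when binding goes to
  completion ($k_{off} \approx 0$).

The package computes both and labels every report row with the mode that
produced it. The paper convention also ignores ligand depletion — with
100 µM protein binding to completion, 500 µM total ligand loses up to
20% of its free concentration over the reaction, which lengthens the
fitted $T$ by several percent relative to $1/(k_{obs}[L]_{tot})$. For
this reason the synthetic-data generator's default kinetics
(`kinetics = "paper"` in `generate_experiment()`) renders concentrations
from the same closed form the analysis assumes, so that recovery tests
measure the fidelity of the *pipeline* (quantification + fitting) rather
than the size of an approximation the published analysis deliberately
makes. The full mass-action alternative (`kinetics = "ode"`, integrated
with `deSolve::lsoda` at rtol 1e-8 / atol 1e-12 M) is first-class and is
what the conservation and equilibrium tests exercise; comparing the two
modes quantifies the approximation error itself.

## Equilibrium with ligand depletion

Where binding is incomplete at equilibrium, the dissociation constant
follows from the free protein fraction $f$:
$K_d = \frac{f}{1-f}\,[L]$ (`kd_from_free_fraction()`), and
$k_{off} = K_d\,k_{obs}$ (`koff_from()`). Two ligand conventions are
provided: `mode = "total"` (free ligand ≈ total, the excess-ligand
convention; the default, because it reproduces the published 2.0 mM
value for the triple mutant exactly) and `mode = "depleted"`
(subtracting protein-bound ligand). For forward simulation the coupled
multi-species equilibrium

$$L + \sum_i \frac{tot_i\,L}{L + K_{d,i}} = L_{total}$$

is solved by `solve_equilibrium()` with plain bisection to a relative
tolerance of 1e-10; the left-hand side is strictly increasing in $L$, so
the root is unique and no tie-breaking is needed. The test suite checks
the solver against an independent bisection-free grid scan (coarse pass
plus local refinement) to four significant figures over randomized
specifications.

A note on a published inconsistency: the source analysis states that at
equilibrium about 42% of the A isomer and 24% of the B isomer of the
disulfide-reduced protein remained unbound, yet also reports
$K_{d,A} = 153\ \mu M < K_{d,B} = 316\ \mu M$ — a *less* bound species
cannot have the *higher* affinity. Inverting 42%/24% under either ligand
convention gives ≈311/≈136 µM, i.e. values close to the printed pair
with the isomer labels swapped. The package documents this and takes no
side: the printed $K_d$ values are used as inputs where needed, and no
computation inverts those two percentages.

## The synthetic spectrum generator

`render_spectrum()` builds a 1D spectrum as a sum of Lorentzians,
$I(x) = \sum_p V_p\,\frac{2/(\pi w_p)}{1 + ((x - x_p)/(w_p/2))^2}$, with
each volume $V_p$ proportional to the concentration of the species
carrying the resonance, plus i.i.d. Gaussian noise. Defaults, chosen
once and configurable:

| parameter | default | rationale |
|---|---|---|
| lineshape | pure Lorentzian | natural NMR absorption profile |
| fwhm | 0.15 ppm | paramagnetically broadened lines; no linewidths are published |
| noise SD | 2% of the tallest initial peak | no SNR is published; visually consistent with the published spectra |
| ppm axis | 40 → 10 ppm, 0.01 ppm step | covers both diagnostic regions; the acquisition's full 80 ppm width adds nothing |
| acquisition | one spectrum per 20 min | the published schedule |
| met peaks | 35.4/34.5 ppm (oxidised), 36.7/35.4 ppm (reduced, triple mutant) | published assignments of the M8B/M5A methyls |
| cyanomet peaks | 19.5 (A), 18.5 (B) ppm | invented placements inside the 18–20 ppm window that is free of met resonances; only the labels matter to the pipeline |
| follow-up | 360 min (oxidised states), 900 min (reduced/triple mutant) | ≥ 3 time constants, matching "hardly finished after 5 h" for the slower oxidised isomer and equilibrium-reached statements for the others |

Note the deliberate collision reproduced by the defaults: the oxidised
B-isomer met methyl and the reduced A-isomer met methyl both sit at
35.4 ppm, so quantification windows must be chosen per protein state —
the package documents this rather than auto-resolving it.

What the generator emulates: volumes tracking species concentrations,
monoexponential decays/buildups with possibly incomplete plateaus,
Gaussian noise, the 2:1 populations, and (optionally) slow first-order
air reoxidation of the reduced protein with a 60 h time constant,
modelled as a ligation-state-preserving transfer to the matching
oxidised species (off by default — it is a confound of long
experiments, not part of the binding model). What it does not emulate:
pulse-sequence effects, relaxation and chemical exchange, baseline roll,
solvent-suppression artifacts, field drift, or paramagnetic shift
prediction. Passing recovery tests therefore demonstrate that the
quantification-and-fitting chain is unbiased under the stated noise
model, not that it is robust to every artifact of real spectra.

## Quantification and fitting

`quantify_peak()` fits a single Lorentzian plus constant baseline inside
a window (default 0.4 ppm, about 2.7 linewidths) by Levenberg–Marquardt
(`minpack.lm::nlsLM`), returning the analytic volume; if the fit fails
it falls back to flagged baseline-corrected trapezoidal integration.
The window default matters: at 1.0 ppm the tail of a neighbouring peak
0.9 ppm away biases a 2:1 volume ratio to ≈2.05, at 0.4 ppm the bias is
below 1%. For *series* quantification
(`timecourses_from_spectra()`) the lineshape is determined once on a
reference spectrum (first spectrum for decaying resonances, last for
growing ones) and then held fixed, leaving volume and baseline as linear
unknowns per spectrum — a free nonlinear fit is ill-posed once the
resonance has decayed into the noise, whereas the fixed-shape estimator
stays unbiased and fast.

`fit_monoexponential()` fits
$I(t) = \text{plateau} + (I_0 - \text{plateau})\,e^{-t/T}$ with starting
values from a log-linear regression on plateau-subtracted intensities
(plateau initialised from the last 10% of points, regression restricted
to points above 5% of the maximum excursion so a decayed tail cannot
flatten the slope). Decay intensities are normalised to their $t = 0$
value before fitting. Degenerate series are rejected rather than fitted:
constant input, or a fitted amplitude within two standard errors of
zero, raises an error. Uncertainties come from a residual-resampling
bootstrap (`bootstrap_uncertainty()`), with residuals inflated by
$\sqrt{n/(n-3)}$ to undo the variance absorbed by the three fitted
parameters; without that correction the nominal 95% percentile interval
covers the truth only ~86% of the time in simulation, with it ~93%.

`build_table()` chains the whole analysis — quantification, fitting,
$T \to k_{obs}$, plateau $\to f \to K_d \to k_{off}$ — into one report
row per state/orientation, with A/B ratios (`ratio_report()`) rounded to
one decimal and fold-differences to integers for display only; full
precision is kept internally. A decay whose fitted plateau is below 5%
of the initial intensity is treated as complete binding and gets no
$K_d$/$k_{off}$ entries. Decay and buildup resonances of the same isomer
are fitted independently (as in the source analysis); the headline $T$
comes from the decay resonance.

## Reproducible runs

All user-facing times are minutes and all concentrations molar
internally; configuration strings carry explicit `uM`/`mM`/`M` suffixes
(`parse_conc()`). A single master seed derives per-stage seeds
deterministically (`derive_seed()`), so `cmd_simulate()` /
`cmd_fit()` / `cmd_table1()` / `cmd_recover()` are bit-reproducible and
each stage can be rerun alone. The recovery study (`cmd_recover()`)
simulates all five protein states at the published kinetic parameters —
10 state/orientation series of 19–46 spectra each, 25 noise seeds by
default, about 3001-point spectra — and completes in a few seconds
because series quantification is linear per spectrum.

```{r example, eval = FALSE}
cfg <- reference_simulation_config("WT_ox", duration_min = 360)
sch <- acquisition_schedule(duration = 360, interval = 20,
                            noise_sd = 0.02, seed = 1)
ex  <- generate_experiment(cfg, schedule = sch)
build_table(ex, mode = "paper")
```

## Known limitations

* The microscopic His-exchange rates are not identifiable from the data
  the model targets; only $k_{obs}$ is. The $K_H$ default is a
  placement, and the literature estimate of the pentacoordinate capture
  rate is deliberately excluded as underdetermined.
* The published rate table rounds inconsistently in places (e.g.
  $T = 262$ min gives 0.127 M^-1^ s^-1^, printed as 0.12);
  `table1_arithmetic()` reports a `matches_printed` flag instead of
  forcing agreement.
* No multi-exponential model selection beyond the two-isomer
  decomposition, no global fitting across ligand concentrations (only
  one concentration is in scope), no stochastic simulation, and no
  HCN/CN^-^ ionisation or pH dependence.
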