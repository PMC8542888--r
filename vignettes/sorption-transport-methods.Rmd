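---
title: "Methods: batch sorption screening and sorption-retarded filter transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch sorption screening and sorption-retarded filter transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorbfate)
```

`sorbfate` evaluates biochar sorbents for micropollutant removal from
water, from laboratory batch screening through pilot-scale filter
modelling. This vignette documents the models, the assumptions behind
them, the tunable parameters, and the design decisions taken where the
design was genuinely open.

## Batch sorption and the single-point coefficient

A batch vial mixes a sorbent mass $m$ (kg) with a volume $V$ (L) of
solution spiked at $C_0$ (mg/L). After equilibration the aqueous phase is
at $C_e$ and the sorbed concentration follows by mass balance,

$$q = \frac{(C_0 - C_e)\,V}{m}, \qquad
K_{bc} = \frac{q}{C_e}, \qquad
\text{removal} = 100\,\frac{C_0 - C_e}{C_0}.$$

All concentrations are carried in mg/L, volumes in L and masses in kg, so
$K_{bc}$ comes out in L/kg with no conversion factors. Mass conservation
$C_0 V = C_e V + q m$ holds by construction and is asserted on every
computed point.

Three conventions matter:

* **Intake tolerance.** Records with $C_e > 1.05\,C_0$ are rejected:
  equilibrium cannot exceed the initial concentration beyond analytical
  scatter. The 5% relative band absorbs triplicate quantification noise
  near zero removal; accepted records with $C_e$ marginally above $C_0$
  clip to $q = 0$.
* **Complete removal.** When $C_e = 0$ no finite coefficient exists. The
  point is flagged and reported as a censored lower bound
  $K_{bc} \ge C_0 V / (m \cdot \mathrm{LOQ})$ — the coefficient that would
  put the equilibrium concentration exactly at the limit of
  quantification (default LOQ 0.001 mg/L, configurable). Censored cells
  are never averaged with finite replicates and are excluded from
  clustering by default.
* **Replicates.** Cells of the compounds × sorbents matrix are arithmetic
  means of replicate $K_{bc}$ values at a declared loading (within a 2%
  relative match), with the spread kept as the sample SD. No outlier rule
  is applied.

Salinity series are classified from successive ratios
$r_i = K_{bc,i+1}/K_{bc,i}$ with a relative dead band $\delta = 0.05$:
*decrease* if every $r_i \le 1-\delta$, *increase* if every
$r_i \ge 1+\delta$, *flat* if all ratios sit inside the band, otherwise
*non-monotone*. The dead band reflects that direction calls on such
series are qualitative; 4% wiggles should not flip a label.

## Isotherm models and fitting

Four equilibrium relations $q(C_e)$ are supported: linear, Freundlich,
Langmuir, and an aqueous-phase BET form,

$$q = \frac{q_m K_B C_e}{(C_s - C_e)\left(1 + (K_B - 1)C_e/C_s\right)},$$

in which the aqueous saturation concentration $C_s$ plays the role vapour
pressure plays for gas-phase BET adsorption. This is the standard
adaptation for solution sorption; $C_s$ can be fitted or fixed from
solubility. A Freundlich exponent $1/n > 1$, or an acceptable BET fit
($R^2 \ge 0.9$ by default), raises the multilayer-sorption flag.

Fitting choices:

* **Eligibility.** A series qualifies only with at least five points
  (after excluding complete-removal points) spanning at least a factor of
  five in $C_e$; anything less is refused with the reason, and can only
  be fitted under an explicit `force` flag that marks the result
  ineligible.
* **Natural-space least squares.** Parameters are estimated by
  Levenberg–Marquardt on $(C_e, q)$ directly, not on linearised
  transforms, which would distort the error structure. Positivity is kept
  by box constraints; a parameter ending on a bound is reported in
  `clipped`.
* **Deterministic multi-start.** Initial values come from data-driven
  heuristics (log–log regression for Freundlich, the Henry-limit slope
  for Langmuir) expanded into a fixed multiplicative grid, so repeated
  fits are bit-identical without any random draws.
* **Ranking.** $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ is reported, but
  model ranking uses small-sample AICc (RSS penalised by parameter
  count), and models within 2 AICc units are returned as a tie set rather
  than a single winner — with 6–18 points, RSS alone cannot separate
  two- and three-parameter models honestly.

With 5% noise on $q$ at $n = 8$ points, Langmuir's $q_{max}$ and $b$ are
strongly correlated; individual parameters then carry substantially more
relative error than the fitted curve itself. The tests therefore assert a
median parameter-error bound across seeds rather than a per-seed
guarantee.

## Clustering of sorption profiles

Sorption profiles are compared across sorbents (which biochars behave
alike?) and across compounds (which pollutants see similar surfaces?).
Because $K_{bc}$ spans more than an order of magnitude across cells,
values are log10-transformed and then z-scored per feature before
Euclidean average-linkage agglomeration. All three choices are
config-switchable and recorded in the dendrogram's preprocessing
descriptor; the statistical engine is `stats::hclust`/`cutree`, with
Newick export via `ape`. The log/z-score default makes the tree invariant
to a global rescaling of the matrix, which is the right behaviour when
the interesting signal is the *pattern* of affinities rather than their
absolute magnitude. Sorbents containing censored (complete-removal) cells
are dropped with a notice by default, or imputed at the censoring bound
by flag.

## Column transport

The pilot filter is a vertical sequence of layers (gravel, sand–biochar
10:1 w/w, sand, gravel in flow direction) in a 50 L bucket. Each layer
retards a linearly sorbing solute by

$$R = 1 + \frac{\rho_b}{\theta}\,K_d, \qquad
K_d = f_{sand} K_s + f_{biochar} K_{bc},$$

with the gravel remainder assumed non-sorbing. Two closures are
implemented: instantaneous local sorption equilibrium, and one-site
first-order kinetic exchange $\partial S/\partial t = k(K_d C - S)$. The
kinetic form is the simplest closure that produces the fronting (early
first arrival) and tailing (slow approach to $C/C_{in} = 1$) seen in
field breakthrough data; two-region and intraparticle-diffusion variants
are deliberately out of scope.

**Numerical scheme.** Finite-volume, operator-split per time step:

1. explicit upwind advection, Courant-limited (the step size is chosen so
   the retarded Courant number is at most 0.9 by default, in (0, 1]);
2. implicit (backward Euler) dispersion with harmonic-mean interface
   conductances, solved by a sparse LU factorisation computed once per
   simulation — conservative and unconditionally stable;
3. the kinetic exchange integrated *exactly* over the step: the
   disequilibrium $e = K_d C - S$ decays at rate
   $\lambda = k(1 + \rho_b K_d/\theta)$ while $\theta C + \rho_b S$ is
   conserved, so stiff (large $k$) cases cost nothing and cannot
   destabilise.

The inlet is a third-type (flux) condition, the outlet a zero-dispersive-
gradient condition — the standard pair for column experiments. Grids
refine automatically (up to 4000 cells) until the grid Peclet number
$v\,\Delta x/D \le 2$; the upwind scheme remains monotone beyond that but
accrues numerical dispersion, so a warning is issued at the cap. Global
mass balance (influent + initial storage = effluent + aqueous + sorbed
storage) is audited on every run and closes to machine precision by
construction; the acceptance checks enforce 0.5% as an outer bound.

**Verification.** For a homogeneous column with constant influent the
classical closed-form solution is built in, in both its first-type
(concentration-inlet) and third-type (flux-inlet) variants, evaluated
with scaled complementary error functions so large $vL/D$ cannot
overflow. One subtlety deserves a note: the simulator's effluent — the
resident concentration of the last cell under a Danckwerts outlet — is
effectively a *flux-averaged* concentration, and by the classical
resident/flux duality it converges to the first-type closed form, not to
the semi-infinite third-type resident profile. Solver verification
therefore compares against the concentration-form solution; at a column
Peclet number of 40 the agreement is within 0.005 of $C/C_{in}$ on a
400-cell grid.

**Conditioning.** The pilot protocol fills the bed with influent and
lets it stand before flow starts. With conditioning enabled, pore water
initialises at $C_{in}$ with $S = 0$; the equilibrium closure
re-partitions instantly to $C = C_{in}/R$, the kinetic closure applies
the exact exchange over the conditioning period. This is why weakly
sorbing beds break through essentially instantly in the field setting.
Cumulative volume is counted from the onset of flow, not including the
conditioning fill.

**Inverse estimation.** `fit_column_params()` minimises the sum of
squared $C/C_{in}$ residuals over any subset of $\{K_s, K_{bc}, k\}$ in
log-parameter space — Brent line search for one free parameter, seeded
multi-start L-BFGS-B otherwise. The default protocol is two-stage: fit
$K_s$ on the sand control, then fix it and fit $K_{bc}$ per biochar
filter. Requests that cannot be identified (e.g. $K_{bc}$ on a bed with
no biochar, or an identically zero observed curve) are refused with an
explanation. Composite observations (grab samples that integrate the
effluent over 1 L intervals) are matched by integrating the simulated
effluent over the same intervals, not by point sampling. Both closures
can be fitted to the same curve (`mode = "both"`) to compare their
objectives.

**Default geometry assumptions.** Bucket inner diameter 0.34 m, bulk
densities 1.5 kg/L (gravel) and 1.6 kg/L (sand, sand–biochar), porosity
0.4, dispersivity 0.01 × layer depth, molecular diffusion
$10^{-9}$ m²/s. None of these were measured in the field setting the
defaults emulate; all are overridable and reported with every fit. Under
these defaults the bed's pore volume is about 6 L, so a conservative
tracer at 1 L/min is essentially fully broken through well before the
24 L monitoring window ends.

## Batch-versus-field comparison

The packaged coefficient table pairs field-fitted $K_s$/$K_{bc}$ values
with their batch-screening counterparts for tetracycline, enrofloxacin,
atrazine and diuron on plain and chitosan-impregnated coconut-husk
biochar. Ratios are computed exactly; a left-censored field value
$<\!x$ yields a right-censored ratio $>\!K_{batch}/x$ that is listed but
excluded from the min/max summary, and every exclusion is itemised —
nothing is silently dropped. The finite ratios on the packaged table span
11.9 to 509, i.e. batch screening overestimates field sorption by one to
two orders of magnitude. The qualitative band "about 10–500×" is
operationalised as min ≥ 10 and max ≤ 510 (2% slack for rounding). Which
batch loading the batch column corresponds to is not recorded in the
table; it is treated as the 200 mg/L screening value, as an assumption.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of (truth, seed), with `withr` scoping
so the global RNG stream is untouched.

* **Batch.** For each mass and replicate, the implicit equilibrium
  $C_0 V = C_e V + q(C_e)\,m$ is solved for $C_e$ by root bisection on
  the monotone isotherm (tolerance $10^{-14}$), then multiplicative
  lognormal noise (mean 1, CV 5% by default) is applied to $C_e$ and
  truncated to $[0, C_0]$. Defaults mirror the screening design: 1 mg/L,
  50 mL, masses 5–250 mg, triplicates. The noise CV is a plausible
  figure for UV quantification, not an estimate of any particular
  laboratory's precision.
* **Salinity.** $K_{bc}$ is multiplied by a fixed factor per decade of
  NaCl molarity. The 0 M level has no decade position, so it is placed
  one decade below the lowest positive level; this keeps a factor < 1
  series strictly decreasing across $\{0, 0.01, 0.1, 1\}$ M, matching
  the behaviour the trend classifier is meant to detect. No mechanistic
  salinity model is implied.
* **Planted matrices.** Sorbent blocks with distinct mean coefficients
  (default 2000 vs 200 L/kg), a shared lognormal per-compound affinity
  profile (SD 0.3 log10 units), and 10% per-cell noise.
* **Breakthrough.** The truth parameters are simulated forward, the
  effluent is integrated over each 1 L inter-sample interval to mimic
  composite grab samples, and lognormal noise (CV 5%) is applied.

What passing tests on these data do **not** show: the generators share
the solver and the isotherm code with the fitters (noiseless recovery is
an internal-consistency check, not field validation); no competition
between co-occurring compounds, no natural organic matter, no sorbent
fouling, and no preferential flow is simulated — precisely the phenomena
believed to cause the large batch-versus-field gap. The synthetic tests
establish that the *machinery* is correct, not that the field system is
as simple as the model.

## Problem sizes and tolerances

The verification suite runs at sizes chosen to make the checks sharp yet
quick: 400-cell grids for solver-versus-closed-form comparisons
(agreement within 0.01 of $C/C_{in}$ across $R \in \{1, 2, 10\}$),
200-cell grids for mass audits (0.5% bound; observed errors are at
rounding level), 50 seeded replicates for noisy $K_{bc}$ recovery (within
20% required in ≥ 90% of seeds) and 20 for clustering recovery. Halving
the grid spacing and step of a 400-cell run moves the effluent curve by
less than 0.002, so these resolutions sit well inside the converged
regime.

## Known limitations

* Single-solute transport and isotherms only; the screening mixture's
  competitive effects are carried in the data, not modelled.
* One-site first-order kinetics is the only non-equilibrium closure;
  fronting/tailing can equally arise from preferential flow, which this
  1-D model cannot distinguish.
* Saturated, constant-rate flow; no fouling dynamics, biodegradation, or
  temperature dependence (biodegradation is deliberately set to zero for
  the short, high-rate filtration window the defaults emulate).
* pH is carried as metadata but never used mechanistically; buffering by
  the sorbent makes pH effects secondary in the emulated setting.
* Exact reproduction of any particular laboratory's dendrograms is not a
  goal: linkage, metric and standardisation conventions differ between
  software packages, and only structure that survives those choices (the
  planted-block recovery the tests enforce) is claimed.
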