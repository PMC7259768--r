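---
title: "Kt metrics for dialysis solute removal: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kt metrics for dialysis solute removal: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktdial)
```

## The problem

Dialysis dose is traditionally quantified by blood-side urea kinetics,
but removal efficiency for non-urea solutes — creatinine, phosphorus and
especially middle molecules such as β2-microglobulin — is not
proportional to urea removal and differs sharply between membranes and
treatment schedules. The Kt factor generalizes dose measurement: it is
the volume of plasma completely cleared of a given solute in one
session, an "absolute dose" that characterizes the technology rather
than the patient.

`ktdial` computes Kt by two routes and cross-validates them:

* the **balance route**, from the solute mass recovered in all spent
  dialysate divided by the time-averaged plasma-water concentration
  (TAC), and
* the **instant route**, from one or a few simultaneous
  dialysate/plasma concentration ratios multiplied by the session's
  effluent volume, which avoids dialysate collection entirely.

## The correction chain

All blood-side concentrations enter calculations as plasma-water
levels: measured plasma concentration divided by the Colton water
fraction $1 - 0.0107\,TP$ ($TP$ total protein, g/dl). Solute exchange
across the membrane is governed by water-phase concentrations, so D/P
ratios built from plasma-water values are the physically meaningful
ones.

The end-of-session sample is additionally corrected for

1. **hemoconcentration** (Bergström–Wehle):
   $P_{cor} = P_{post} / (1 + UF/(0.2\,BW_{post}))$, removing the
   concentrating effect of ultrafiltration referenced to an
   extracellular volume of $0.2\,BW$; and
2. **post-dialysis rebound** (Tattersall):
   $P_{eq} = P_{pre}\,(P_{cor}/P_{pre})^{t/(t+t_x)}$, with fixed
   equilibration times $t_x$ of 35 (urea), 50 (creatinine),
   60 (phosphorus) and 110 min (β2-microglobulin).

The balance TAC is the logarithmic mean of the pre-dialysis
plasma-water level and $P_{eq}$ — exact for exponential decay, and
within 0.5% of the true time average for the two-pool trajectories the
simulator produces. `tac_balance()` accepts a `tx_min` override for
systems known to have no compartment disequilibrium (used in the
single-pool analytic check, where the physiological equilibration time
is genuinely zero).

Instant samples receive no correction beyond the plasma-water
conversion: the instant TAC is the log-mean of the 60- and 180-min
values. For short-daily low-dialysate (NSO) sessions only the 60-min
draw exists; the instant D/P is that single value and the mass estimate
references the 60-min plasma-water level instead of a TAC.

The blood-side urea chain deliberately consumes *uncorrected* plasma
urea (no plasma-water conversion): the Daugirdas second-generation
spKt/V and its rate-equation eKt/V were calibrated on raw plasma
values, and the distribution volume solved from the dialysate balance
($V = (Q - P_{pre}\,UF)/(P_{pre} - P_{eq,post})$) uses raw pre and
rebound-equilibrated raw post levels for the same reason. The
arteriovenous (+0.03) form of the rate equation is used; a
venous-catheter variant is not implemented.

## What the simulator emulates

`simulate_session()` integrates a variable-volume two-pool model with a
cardiopulmonary mixing step by fixed-step explicit Euler
(dt = 0.05 min):

* perfused pool (`c1`, the concentration systemic venous blood
  reports) exchanging with a remote pool (`c2`) through an
  intercompartmental clearance $K_c$;
* arterial-inlet concentration
  $c_{art} = c_1 (CO - Q_b)/(CO - Q_b + K_d)$: freshly cleared dialyzer
  outflow remixes at the heart, so during high-efficiency dialysis the
  arterial line runs below systemic concentration (cardiopulmonary
  disequilibrium). $CO = \infty$ disables the effect;
* removal only through the dialyzer ($K_d c_{art}$, with $K_d$ the
  total diffusive+convective clearance); ultrafiltration removes
  solvent, shrinking both pools pro-rata and linearly in time;
* dialysate outlet concentration $K_d c_{art}/(Q_d + Q_{uf})$, with
  each collection bag accumulating the exact time-integral of removed
  mass — conservation therefore holds to machine precision by
  construction, which is why the integrator is a hand-written fixed
  Euler loop rather than an adaptive ODE solver;
* blood samples reported as plasma values (plasma-water times the
  Colton factor, with total protein rising linearly from its pre- to
  its post-dialysis value); pre/post samples report `c1` (the post
  draw following the 5-min low-flow convention that dissipates
  recirculation), instant samples report `c_art` at the arterial line;
* unbiased multiplicative lognormal assay noise (default CV 3%) on
  every reported concentration, under a per-session seed; ground truth
  always comes from the noiseless trajectories.

The infinite-$K_c$ (perfectly mixed) limit is supported exactly by
instantaneous mass redistribution; finite $K_c$ beyond the Euler
stability bound raises an error rather than silently diverging.

### Calibration — and what it does and does not represent

Parameters were fixed once, from the study conditions the package
emulates, and the generator never sees the formulas it is used to test:

* $K_c = V/t_x$ per solute (~1000 ml/min for urea at $V$ = 35 L), the
  regional-blood-flow literature scale, so that rebound *emerges* from
  pool exchange rather than being imposed;
* perfused fraction 0.15 of total volume: together with $K_c$ this
  yields an emergent post-dialysis rebound of 12–16% at standard dose —
  the clinically observed magnitude, and the magnitude the fixed-$t_x$
  Tattersall correction expects. Larger fractions (e.g. 1/3) produce
  an implausibly small rebound that the correction would then
  systematically over-correct;
* dialyzer clearances from the reported instant D/P ratios times
  effluent flow (urea ~220 ml/min at $Q_d$ 500 ml/min on high-flux
  membranes; β2M ~3 ml/min on low-flux, 60–85 ml/min on high-flux and
  hemodiafiltration); the short-daily NSO system runs near dialysate
  saturation, so its clearances are parameterized directly as outlet
  saturation (0.90/0.83/0.77/0.24) — a clearance cannot exceed the
  effluent flow;
* initial concentrations on the scale of the study cohort's reported
  time-averaged levels; cohort generation draws patient anthropometry
  (Watson TBW sets the pool volume), jitters concentrations (18%) and
  clearances (5%) log-normally, and uses 4-h thrice-weekly sessions at
  $Q_d$ 500/600 ml/min (~125–150 L effluent) versus 6×/week NSO
  sessions with dialysate volume $0.5\,TBW/0.85$ (~20–25 L).

The simulator does **not** emulate: access recirculation, intra-plasma
(ECV-referenced) hemoconcentration transients, phosphorus's
multi-compartment mobilization, protein-bound solute behavior, or
intradialytic generation variability. Passing recovery tests therefore
demonstrate the correctness and internal consistency of the metric
chain under two-pool kinetics with cardiopulmonary disequilibrium — not
the clinical accuracy of the corrections in a real patient.

## Validation studies and their problem sizes

All studies run inside the test suite and `scripts/acceptance.R`:

* **Single-pool analytic limit** (1 session): $K_c = \infty$,
  $CO = \infty$, no UF/noise/generation; both Kt routes must equal
  $K_d T$ (48.0 L at 200 ml/min × 240 min) and the decay must match
  $c_0 e^{-K_d t/V}$.
* **Conservation** (1 noiseless session at study conditions): bag
  masses equal ground-truth removal to $10^{-6}$ relative; the
  whole-session mass balance closes.
* **Parameter recovery** (50 noiseless + 50 noisy sessions, varied
  patients): the instant route recovers the dialyzer-referenced
  $K_d T$ to machine precision; the balance route recovers the
  whole-body Kt (removed mass over the true mass-equilibrated TAC)
  with a per-solute mean bias of −1.4% to −2.2%. The residual is the
  fixed-$t_x$ Tattersall correction over-predicting the model's true
  equilibrated endpoint by ~3% at high dose; it is a property of the
  published correction confronted with an independent kinetic model,
  and is left as measured rather than calibrated away. With 3% assay
  noise the additional bias is under 0.4%. This study runs without
  ultrafiltration: the ECV-referenced hemoconcentration correction
  assumes physiology the pro-rata volume-shrink model intentionally
  lacks, and with UF 3 L it shifts the balance route by about +5%.
* **Disequilibrium direction** (1 noiseless session, $CO$ = 5 L/min,
  UF 3 L): the instant Kt exceeds the balance Kt for every solute
  (ratios 1.06–1.13), while the two removed-mass estimates agree to
  1–4.5% — the instant TAC's 60–180-min window slightly
  under-represents the steep early-session decay, most visibly for
  urea, mirroring the small Q differences the original cohort data
  also show.
* **Two-route urea agreement** (16 sessions, 4+3+2+7 across arms):
  regressing eKt/V × V (blood-side chain) on the balance Kt gives
  slope ≈ 1.04 and r ≈ 0.998.
* **Cohort table pattern** (16 sessions): group means of D/P, urea Kt
  (both routes), weekly Kt and stdKt/V reproduce the reported
  group-level values within stochastic tolerance, plus the qualitative
  flux patterns (near-zero β2M removal on low-flux membranes, raised
  middle-molecule fractional clearances on convective and short-daily
  therapies).

## Numerical and design choices

* Fixed explicit Euler (dt = 0.05 min) for bitwise reproducibility;
  per-session seeds derived deterministically from a master seed; RNG
  state is restored after simulation.
* Log-mean TAC returns its continuous limit (the common value) when
  endpoints differ by < 1e−9 relative.
* Effluent volume for the instant route prefers the monitor reading
  (delivered + UF) — the collection-free reading the instant method is
  built on — falling back to the bag-volume sum; both are reported and
  a >3% discrepancy is flagged.
* Zero dialysate concentration (low-flux β2M) yields Kt 0, not an
  error; fractional clearance of urea against itself is exactly 1.
* Per-session metrics are computed per session and only then averaged;
  the report builder never pools inputs before forming a metric.
* Missing per-sample total protein falls back to the session-level
  pre/post value with a warning.
* Validation findings are data (severity, field, message), not
  exceptions; the CLI maps them to exit code 2.
* NSO session duration is a required input (the prescription fixes the
  dialysate volume, not the duration); simulated NSO sessions use
  180 min.
* Statistical tests are two-tailed at 0.05; no multiplicity correction
  beyond Scheffé, matching the reporting conventions the package
  mirrors; ANOVA across arms is plain one-way (sessions as units).

## Known limitations

* The balance route carries the documented ~2% systematic bias of the
  fixed-$t_x$ rebound correction under two-pool kinetics, and the
  ECV-referenced hemoconcentration correction is only as good as the
  $0.2\,BW$ extracellular approximation.
* The instant-route mass estimate inherits the 60–180-min window bias
  (~2–5% low for rapidly cleared solutes).
* Simulated β2-microglobulin uses the same two-pool template as small
  solutes; real β2M kinetics (vascular/interstitial exchange,
  adsorption) are richer, and the balance/instant contrast for β2M in
  the simulated cohort is correspondingly milder than observed
  clinically.
* Spreadsheet ingestion is a thin, mapping-driven reader; it makes no
  attempt to guess unknown study layouts.
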