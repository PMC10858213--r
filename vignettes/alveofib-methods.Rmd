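---
title: "Modeling radiation-induced lung fibrosis in an alveolar segment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling radiation-induced lung fibrosis in an alveolar segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alveofib)
```

## The model

`alveofib` simulates the onset of radiation-induced lung fibrosis (RILF) in
a three-dimensional alveolar segment. The segment is three stacked rings of
six alveoli — hollow spheres of 260 µm diameter inside a 900 µm envelope box,
itself centered in a closed 2000 µm world cube. Each alveolus is lined by
three concentric cell shells: mesenchymal cells (fibroblasts and
myofibroblasts) on the outer shell, alveolar epithelial cells (AEC1, AEC2) on
the middle shell, and macrophages (M1, M2) on the inner shell. Cells are
agents: they migrate on their shell, secrete and sense extracellular
substances, proliferate, differentiate, phagocytose and die, advanced in
20 s steps. A voxel grid overlapping the world carries ten extracellular
substances (MCP-1, MMP, TIMP, ECM, the M2-derived growth factor, and five
further inflammatory/senescence-associated cytokines) solved by an explicit
forward-in-time central-in-space (FTCS) scheme with zero-flux (Neumann)
walls, first-order decay and mass-action depletion couplings
(TIMP neutralizes MMP; MMP degrades ECM).

Irradiation is resolved at the single-cell level. A dose module produces a
per-cell absorbed dose for every epithelial cell, either from parametric
distribution presets that reproduce the characteristic relative-dose
histogram shapes of different source setups (an approximately Gaussian peak
for low-energy 4-field photon beams; a narrow peak at ~80% of the maximum
dose for plateau protons; multiple peaks, a long right tail and a large
zero-dose mass for an isotropic source), or from a toy straight-line
attenuation transport over the explicit geometry. Full track-structure
physics is deliberately out of scope: the agent engine consumes only the
per-cell dose vector, so outcome differences between radiation qualities are
carried entirely by the *shape* of the dose distribution. Doses are sampled
in relative units and aligned to the prescribed mean epithelial dose with a
single multiplicative scale factor.

Cell fate at delivery follows the linear-quadratic (LQ) model. Only AEC2 are
radiation targets; for each one a uniform random number is compared with
`exp(-alpha*D - beta*D^2)` at its scaled dose. Hit cells split between an
apoptotic branch (removal delay drawn from a Poisson law; no movement) and a
damaged branch that converts to senescent with an exponential waiting time.
Senescent AEC2 drive the two damage loops:

* **Bystander spread.** A healthy AEC2 whose neighborhood contains at least
  `bystander_threshold` senescent cells accumulates exposure; its per-step
  conversion probability is `min(1, k * exposure * dt)`. Exposure fades
  slowly when the neighborhood condition lapses, so sustained senescent
  neighborhoods — not isolated encounters — propagate indirect damage.
* **Immune clearance.** Damaged and senescent AEC2 secrete MCP-1; macrophage
  influx onto the inner shell rises with the local MCP-1 concentration (and
  is zero at the homeostatic baseline of zero). A phagocytic macrophage
  within contact range removes up to `phagocytic_index` senescent cells and
  then leaves; recruited (monocyte-derived) macrophages also have a finite
  mean residence time, while the resident population is permanent.

Epithelial loss up-regulates AEC2 proliferation and AEC2→AEC1
differentiation; disruption and the M2-derived growth factor activate
fibroblasts into myofibroblasts, which deposit ECM into the grid up to a
per-voxel saturation concentration. An alveolus — the functional subunit
(FSU) — dies when it no longer contains a healthy AEC2; death is absorbing
because repopulation requires a healthy progenitor.

## Outcome statistics

* `delta_ecm`: increase of the grid-mean ECM concentration over the
  homeostatic baseline (g/cm³), read at an early day and at the end of the
  run.
* `fsu_survival`: fraction of alveoli still containing a healthy AEC2.
* `rsi`: fibrosis severity index `sqrt(dECM_late * V_total * (1 - SF))`
  (g^1/2), with `V_total` the summed spherical alveolar volume. The volume
  factor is implemented as the *lost* surviving volume: only that reading
  makes the index zero for an intact segment, monotone in damage and
  consistent with its saturating erf-shaped dose response; a
  `literal_volume` switch provides the alternative verbal reading
  (volume × surviving fraction).
* Dose-response fits: a sigmoid
  `dECM_max / (1 + exp(4*gamma*(1 - D/D50)))` for both ECM components, an
  erf sigmoid `A/2 * (1 - erf(sqrt(pi)*gamma*(1 - D/ED50)))` for the RSI and
  the LQ/critical-volume survival `1 - (1 - exp(-alpha*D - beta*D^2))^N` for
  the FSU survival. Fits use Levenberg–Marquardt with a small multi-start
  grid (half-saturation started at the dose quantiles, saturation at the
  maximum observed response) to avoid local minima.
* `rbe_fsu`: the FSU-level relative biological effectiveness — the ratio of
  photon to proton dose at equal fitted FSU survival, obtained by numerical
  inversion (bisection to 1e-6 Gy) of the two fitted curves.
* SEM of the RSI by first-order (delta-method) propagation of the ΔECM and
  FSU-survival standard errors.

## Parameters and defaults

Lengths are µm, rates per day, concentrations g/cm³ for ECM and arbitrary
units otherwise. Parameters fall into three groups.

**Published structure.** Alveolus diameter (260 µm), envelope (900 µm),
world (2000 µm), 3×6 alveoli, the 20 s step, the 1200-day full horizon, the
reference damage configuration (phagocytic fraction 1, phagocytic index 1,
apoptotic-to-senescent ratio 0, bystander threshold 2), the 24 h
inter-fraction interval, and the fractionation dose grid (total doses
2.5–42.5 Gy).

**Documented package choices.** Values the source literature keeps in
companion material are shipped as config defaults:

* LQ radiosensitivity `alpha = 0.2 / Gy`, `beta = 0.02 / Gy^2`
  (alpha/beta = 10 Gy, an early-responding epithelial population). With
  N AEC2 per alveolus this puts the critical-volume survival plateau and
  ED50 inside the studied 2.5–42.5 Gy range. A `sensitivity` multiplier
  implements the 10%-lower-radiosensitivity perturbation.
* Homeostatic counts per alveolus: 100 AEC2, 60 AEC1, 20 fibroblasts,
  5 myofibroblasts, 6+6 macrophages (order 10² epithelial cells). Shell
  offsets: one nominal cell diameter (10 µm) on either side of the 130 µm
  epithelial shell.
* Epithelial turnover 0.01/day with the homeostatic balance
  `diff * N_AEC2 = death * N_AEC1` and `prolif = death + diff`; regulation
  is a signed saturating response of the count deficit `d`: births carry
  `m = 1 + gain*d/(K + |d|)` and deaths the mirror `2 - m` (both clamped at
  0), so the restoring force is symmetric around the target and count noise
  is not rectified into a bias. Fibroblasts compose the same regulation
  additively with their growth-factor/disruption gains, so the homeostatic
  count is centered without suppressing the fibrotic expansion. The mesenchymal compartment reacts to epithelial
  disruption only beyond a 10% dead zone, because the terminal
  fibroblast→myofibroblast switch must not fire on homeostatic noise.
* Substance transport: diffusion coefficients 30–60 µm²/s, decay ~2/day
  (ECM: no diffusion, 0.2/day turnover). The ECM field starts at its
  analytic steady state (total deposition / decay), making the grid-mean
  concentration stationary from the first step.
* Bystander neighborhood: the shells are *not* confluent at order-10² cells
  per alveolus — the mean epithelial spacing is tens of µm — so the
  neighborhood radius is set to cover that spacing (40 µm at the default
  density, 45 µm in the scaled profile) rather than a cell-contact
  distance. The exposure fade (0.05/step) makes the threshold an effective
  switch: neighborhoods that satisfy the threshold more often than the fade
  accumulate hazard and the indirect-damage chain becomes self-sustaining,
  which is what distinguishes threshold 1 from threshold 2 at low dose.

**Free qualitative knobs** (secretion rates, recruitment gain, macrophage
residence, activation weights) were calibrated once against two gates: the
20-day homeostasis check (all per-type counts and substance means within
±5%) and the requirement that the damage machinery functions — macrophages
gather within days of irradiation, senescent cells are cleared over one to
two weeks, and depleted alveoli repopulate at low dose.

## Simulation profiles and problem sizes

`default_profile()` is the full study scale: 18 alveoli, ~3500 cells, a
20³-voxel grid and a 1200-day horizon with the early ECM component at day
90. `scaled_profile()` is the package's test scale, used by the test suite
and the acceptance script: 3 alveoli with reduced counts (40 AEC2, 24 AEC1,
10 fibroblasts, 3 myofibroblasts, 4+4 macrophages per alveolus), an
8³-voxel grid and a 30–90-day horizon with the early component at day 10.
One 30-day replicate runs in a few seconds, so multi-seed dose-response
campaigns complete in minutes. Dose-response and fractionation campaigns
use the 30-day horizon; the bystander-threshold experiment uses the 90-day
end of the range, because the low-dose threshold-1 smolder needs weeks to
fully deplete an alveolus.

What the scaled profile preserves: every mechanism (per-cell dose
heterogeneity, LQ fates, bystander spread, clearance, repopulation,
mesenchymal expansion), the homeostatic balance, and the directional
phenomenology — sigmoidal ΔECM and FSU dose responses, fractionation
sparing, the bystander-threshold sensitivity and the quality dependence on
dose-distribution width. What it does not preserve: absolute dose-response
positions (ED50 scales with the AEC2 count per alveolus), the late-phase
plateau values, and any claim about real tissue — passing tests show
internal consistency of the model at this scale, not clinical validity.

## Numerical choices

* FTCS stability: `D*dt/h² ≤ 1/6` per substance and `decay*dt ≤ 1`,
  enforced before every grid step; the default grids satisfy the bound at
  dt = 20 s with margin.
* Couplings use a clamped update (equal-amount depletion for annihilating
  pairs, implicit-in-sink division for catalytic degradation) so no voxel
  can go negative at any rate constant.
* Behavior order within a step is fixed: secretion → diffusion → bystander
  → senescence → apoptotic removal → phagocytosis → recruitment →
  repopulation → mesenchymal dynamics → migration → shell projection.
* Movement is an exact great-circle rotation; positions are radially
  re-projected after every move, so the shell-distance error stays at
  floating-point rounding.
* The engine uses a counter-style splitmix64 random stream seeded from the
  run seed: runs are bit-reproducible for a fixed seed, independently of R's
  session RNG. Sampling and fate draws use R's RNG, controlled by
  `set.seed` inside the orchestration layer; campaign replicates derive
  per-stage seeds deterministically from the master seed.
* Degenerate inputs are first-class: all-equal dose vectors are flagged
  (`sd = 0`) instead of fitted; empty geometries export a manifest only;
  alveoli without epithelial cells score `NA` means; a fully depleted
  alveolus never repopulates.

## Design decisions on genuinely open points

* **RSI volume factor.** Implemented as lost volume `V*(1-SF)` (switchable),
  as discussed above.
* **Re-irradiation of damaged cells.** In multi-fraction schemes, damaged
  (pre-senescent) AEC2 are re-drawn through the LQ lottery in later
  fractions alongside healthy cells; senescent and apoptotic cells are not.
* **Identical source per fraction.** Every fraction uses the same
  distribution preset; only the evolved structure changes between
  deliveries.
* **Fraction bookkeeping.** A multi-fraction scheme simulates 24 h after
  each of its fractions (5 fractions add 5 days before the long run); a
  single fraction is instantaneous.
* **Substance network placeholders.** Only part of the ten-substance
  network is named by the underlying biology (MCP-1, MMP/TIMP/ECM, growth
  factors); the remaining cytokines are carried with diffusion/decay but no
  behavioral coupling, preserving the network topology without inventing
  mechanisms.
* **Macrophage exit.** The clearance loop needs a sink: a phagocytic
  macrophage that has spent its capacity leaves the simulation, and
  recruited macrophages have a finite residence time. Resident macrophages
  are permanent so that homeostasis holds without a baseline influx.

## Known limitations

* DNA damage and sub-lethal repair kinetics are not modeled; fractionation
  sparing arises from the LQ dose-squared term, staggered senescence and
  inter-fraction clearance/repopulation only.
* Immune weakening by radiation is not modeled (only AEC2 are targets).
* The scaled profile's small per-alveolus counts make FSU survival a
  3-alveolus binomial — individual replicates are coarse (0, 1/3, 2/3, 1)
  and conclusions should always be drawn from multi-seed means or fitted
  curves.
* The toy transport is an attenuation model on straight rays; it reproduces
  fluence geometry (field symmetry, 1/r² falloff, chord-length weighting),
  not physical spectra.

## A minimal workflow

```{r example, eval = FALSE}
prep <- prepare_homeostatic_world(scaled_profile(), seed = 1)
cfg  <- run_config(n_fractions = 1, seed = 1, n_replicates = 5,
                   profile = scaled_profile())
camp <- run_campaign(doses_per_fraction = c(2.5, 5, 7.5, 10, 15, 20), cfg)
camp$table

fit <- fit_fsu_survival(camp$table$total_dose, camp$table$fsu_survival,
                        n_aec2 = 40)
fit$parameters
```
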