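# alveofib

Mechanistic simulation of the onset of radiation-induced lung fibrosis
(RILF) in a 3D alveolar segment, coupling per-cell dose deposition to an
agent-based tissue model.

Radiotherapy of thoracic tumours injures the distal airways: damaged type-2
alveolar epithelial cells (AEC2) turn senescent, spread damage to healthy
neighbours (the bystander effect), recruit macrophages via MCP-1, and — when
clearance and repopulation lose the race — drive myofibroblast expansion and
extracellular-matrix (ECM) deposition, i.e. fibrosis. Phenomenological
normal-tissue complication probability (NTCP) models see only the dose
distribution; this package is for researchers who want the mechanism: an
explicit alveolar segment (3 × 6 alveoli, 260 µm hollow spheres lined by
mesenchymal, epithelial and macrophage shells in a 900 µm envelope) evolved
in 20 s steps over simulated months, with a reaction–diffusion grid for ten
extracellular substances.

The quantitative core:

* per-cell survival follows the linear-quadratic law
  `S(D) = exp(-αD - βD²)`;
* an alveolus is a functional subunit (FSU); its survival follows the
  critical-volume form `P(D) = 1 - (1 - e^{-αD-βD²})^{N_AEC2}`;
* fibrosis severity is summarized by
  `RSI = sqrt(ΔECM_late · V_total · (1 - SF))` (g^½),
  fitted against dose with an erf sigmoid
  `RSI(D) = A/2 · {1 - erf(√π·γ·(1 - D/ED50))}`, and the ECM increase with
  `ΔECM(D) = ΔECM_max / (1 + e^{4γ(1 - D/D50)})`;
* radiation qualities are compared through
  `RBE_FSU = D_photon / D_proton` at equal fitted FSU survival.

Per-cell doses come from parametric samplers reproducing the characteristic
relative-dose histograms of different sources (Gaussian for a 4-field
low-energy photon beam, a narrow high peak for plateau protons, multi-peaked
with a zero-dose spike for an isotropic source) or from a toy attenuation
beam transport over the explicit geometry; distribution *shape* — not track
structure — is what the tissue model responds to.

## Worked example

Five-seed single-fraction campaign on the scaled test profile (3 alveoli,
30-day horizon):

```r
library(alveofib)

prep <- prepare_homeostatic_world(scaled_profile(), seed = 1)
cfg  <- run_config(n_fractions = 1, seed = 1, n_replicates = 5,
                   profile = scaled_profile())
camp <- run_campaign(doses_per_fraction = c(2.5, 5, 7.5, 10, 15, 20),
                     cfg, prepared = prep)
camp$table[, c("total_dose", "fsu_survival", "delta_ecm_late", "rsi")]
#>   total_dose fsu_survival delta_ecm_late          rsi
#> 1        2.5    1.0000000   0.0006929728 0.000000e+00
#> 2        5.0    1.0000000   0.0019732280 0.000000e+00
#> 3        7.5    0.8666667   0.0029058518 6.414235e-05
#> 4       10.0    0.8000000   0.0038367113 1.106844e-04
#> 5       15.0    0.2666667   0.0038802203 2.787879e-04
#> 6       20.0    0.0000000   0.0040528985 3.342987e-04
```

Reading the table: FSU survival is complete up to 5 Gy, falls through 50%
near 12 Gy and reaches zero by 20 Gy; the late ECM increase rises
sigmoidally from its homeostatic baseline (here 1.77 mg/cm³ mean over the
world) toward saturation; the severity index combines both. Fit the
dose–response curves and locate the half-survival dose:

```r
fit <- fit_fsu_survival(c(0, camp$table$total_dose),
                        c(1, camp$table$fsu_survival), n_aec2 = 40)
uniroot(function(D) predict(fit, D) - 0.5, c(0, 50))$root
#> [1] 12.31601
```

The same machinery compares fractionation schemes (`n_fractions = 5`
delivers the total in five daily fractions and right-shifts the curves),
bystander thresholds (`sensitivity_suite()`), and radiation qualities
(`preset = "proton_60MeV"` vs `"photon_10keV"`, then `rbe_fsu()`).

A thin command-line wrapper ships at `inst/cli/alveofib.R`
(`prepare` / `irradiate` / `campaign`).

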