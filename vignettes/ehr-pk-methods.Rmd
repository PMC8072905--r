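---
title: "Modelling enterohepatic recycling of mycophenolic acid across three routes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling enterohepatic recycling of mycophenolic acid across three routes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrpk)
```

## The problem

Mycophenolic acid (MPA) is glucuronidated in the rat liver, exported into
bile, stored in the gallbladder/biliary tree, emptied into the gut,
deconjugated by gut bacteria, and re-absorbed. The plasma profile
therefore shows secondary peaks after every route of administration, and
a model without the bile–gut loop cannot reproduce them. `ehrpk`
implements the three route-specific enterohepatic-recycling (EHR) models
used to compare an intravenous bolus, an oral gavage dose, and a 4-h
supralingual mucoadhesive patch, all at 0.5 mg/kg in male
Sprague–Dawley rats, together with the estimation, selection, NCA and
dose-accounting machinery around them.

## Model structure and assumptions

All amounts are carried per kg body weight (ng/kg), so a 0.5 mg/kg dose
enters as 500,000 ng/kg and plasma concentration is `A_central/V` in
ng/mL with `V` in mL/kg. Every process is first order except two:

* **Bile emptying** is parameterised by a duration `Tau` (h) with
  transfer coefficient `GBr = 1/Tau`. Only the coefficient is fully
  determined by the reported parameters, so the default implementation is
  the continuous transfer `R_bile(t) = A_bile(t)/Tau`, which needs no
  unstated trigger time and reproduces the multiple peaks. A *windowed*
  mode — constant-rate discharge of the bile amount present at a
  configurable start time, spread over `Tau` and clamped at zero — is
  available (`solver_config(bile_mode = "windowed")`) for sensitivity
  analysis, since a gallbladder-window construct with an unreported
  trigger cannot be ruled out.
* **Patch input** is a zero-order release of the released fraction of the
  nominal dose into the absorption depot over `[t_lag, patch_duration]`,
  i.e. 0.5 h to 4 h by default. This matches the observed onset (first
  detectable plasma at ~1 h) and the first peak right at patch removal.

Absorption (oral and supralingual) uses one depot with two parallel
first-order outflows: `Ka1` directly into plasma and `Ka2` into a chain
of `n_transit = 5` identical transit compartments traversed at `K_tr`.
No dose-split fraction is introduced — the implied fast fraction is
`Ka1/(Ka1+Ka2)` — because the study reports none. The supralingual model
has no peripheral compartment; with `CL2 > CL` for the other routes,
distribution is fast relative to elimination and the peripheral pool adds
nothing for the flat patch profile.

Parameter counts for AIC (`-2LL + 2p`) include every estimated structural
parameter plus the residual `sigma`: 8 (IV), 11 (oral), 9
(supralingual). Fixed design constants — `n_transit`, `t_lag`,
`patch_duration`, `released_fraction`, dose — are not counted. `K_cb = 0`
is allowed as the recycling-off limit so that the nested non-EHR model
can be fitted and compared.

## Defaults that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_transit` | 5 | – | chain length the structure scan selects |
| `t_lag` (patch) | 0.5 | h | first detectable plasma concentration |
| `patch_duration` | 4 | h | patch removal time |
| `released_fraction` (patch) | 0.794 | – | 20.6% of dose recovered in worn patches |
| `sigma` | 0.15 | – | typical bioanalytical CV inside the ±15% assay acceptance band; the study does not print its estimate |
| LLOQ | 0.5 | ng/mL | lower end of the validated assay range |
| solver | lsoda, rtol 1e-8, atol 1e-10 ng/kg | – | keeps mass balance to ~1e-9 despite on/off inputs |

The integration is segmented at the release start/stop (and at the
emptying window in windowed mode) because zero-order inputs make the
right-hand side discontinuous; `lsoda` restarts cleanly at each
breakpoint.

## The synthetic cohort

No concentration data are deposited, so `generate_cohort()` emulates the
design: 5 IV, 3 oral, 3 patch animals at 0.5 mg/kg on the study's
sampling schedules (minute-scale early draws for IV/oral; hourly sampling
through patch wear; both out to 48 h). Between-animal parameters are
drawn lognormally with moments matched to the published mean ± SD (all
parameters have positive support; a zero-truncated normal is available),
body weights normally around 379.8 ± 44.3 g, residuals multiplicatively
with SD `sigma`, and records below 0.5 ng/mL are flagged BLQ (retained in
files, excluded from likelihoods — the study's own BLQ rule is
unreported). The pre-dose record at t = 0 is emitted as a BLQ zero and
never fitted.

What the generator does *not* emulate: assay drift or run effects,
correlated within-animal parameter structure (draws are independent
across parameters), circadian effects on absorption, and tongue-tissue
kinetics (the study measures only two destructive tongue time points, so
that arithmetic lives in the dose-accounting functions). Tests passing on
synthetic cohorts therefore demonstrate the estimation machinery, not the
biology of any particular rat.

## Estimation

Per-animal maximum likelihood under the proportional error model, with
`sigma` profiled analytically (`sigma^2 = mean(((C_obs-C_pred)/C_pred)^2)`),
which reduces the search dimension and is exact. The study's text calls
the approach a "naïve pool estimate" yet reports per-animal standard
deviations of AIC and parameters; only per-subject fitting produces
those, so per-subject fitting is the default here and pooling is left to
the caller (fit the concatenated records of several animals as one
subject if desired).

The profiled objective is multimodal: recycling timing (`K_cb`, `Tau`,
`K_gc`) trades off against distribution (`CL2`, `V2`) along long curved
valleys, and plain quasi-Newton runs from perturbed starts stall with
"false convergence". The fitter therefore works in two stages:

1. **Warm starts** — bounded Levenberg–Marquardt on the residual vector
   `log(C_obs/C_pred)` from `multi_start` seeded log-uniform
   perturbations of the initial guess (the LM normal equations follow
   these valleys cheaply);
2. **Polish** — the best warm starts are refined on the true profiled
   `-2LL` by alternating Nelder–Mead simplex restarts with bounded
   quasi-Newton until the objective stops improving.

All parameters are estimated on the log scale (positivity plus
conditioning) inside broad boxes (`1e-4`–`1e4` on the natural scale).
The procedure is deterministic given the data, the start, and the
configured seed.

### Identifiability

With the study's 15–16-point schedules, noise-free refits pin down the
well-determined constants — clearances, volumes, `K_tr`, IV `K_cb` — to
much better than 1%. The gut re-absorption rate `K_gc` is only
one-sidedly identified: beyond a few multiples of the emptying rate the
gut empties effectively instantly and the likelihood flattens, so
near-equivalent solutions with very different `K_gc` (and, for the patch
route, proportionally co-drifting `Ka1`/`Ka2`, whose sum exceeds
50 /h against a 3.5-h release window) exist. `fit_subject()` probes each
direction (±10% perturbation; an objective change below 0.01 flags the
profile as flat) and reports the flags; downstream summaries should treat
flagged parameters as order-of-magnitude only. This mirrors the in-vivo
situation, where the corresponding reported SDs exceed the means.

## NCA and derived quantities

`AUC(0-48)` uses linear trapezoids — the most literal reading of a
"manual trapezoidal rule" — with BLQ values counted as zero before the
peak and dropped after it, and linear interpolation to the endpoint if it
is not sampled. The terminal half-life is `ln 2 / |slope|` from a
log-linear OLS on the last three quantifiable points, flagged unreliable
when the slope is nonnegative or R² < 0.8; with strong recycling the
tail still fluctuates, so this NCA half-life understates the true
terminal phase (the supralingual tail is flagged for exactly that
reason — flip-flop kinetics, with absorption slower than elimination).

Bioavailability follows the dose-normalised mean-AUC ratio. Note a
recorded inconsistency in the source tables: the supralingual `F_abs` is
described as residue-adjusted, yet the printed 7.60% equals the
*unadjusted* ratio `165/2170` (adjustment would give ≈9.6%). The
function implements the stated ratio verbatim and leaves the discrepancy
to the caller. Similarly, the printed IV/oral EHR percentages (54.1,
69.2) are means of unavailable per-animal ratios; the ratio of published
means gives 53.5/69.1, so only the supralingual value (96.6, which
matches exactly) is treated as exact.

## Numerical choices and limitations

* Problem sizes used by the shipped tests and acceptance script: one
  synthetic animal per route for noise-free refits, 50 replicate IV
  animals for the bias study, 240–500-point dense profiles for residual
  coverage — sizes chosen so the full analysis re-runs comfortably on a
  single CPU while keeping Monte-Carlo error well inside the asserted
  tolerances.
* Ties in model selection resolve to the more parsimonious candidate
  whenever the AIC gap is below 2.
* The solver clamps nothing: a negativity worse than 1e-6 of the dose
  would surface in the invariant tests rather than being hidden.
* Out of scope, deliberately: metabolite (MPAG) concentrations — the
  loop lumps conversion and deconjugation into the bile/gut transit —
  mixed-effects population estimation, censored-likelihood (M3) BLQ
  handling, and PBPK extensions.
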