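---
title: "A partitioned survival cost-effectiveness model for first-line sugemalimab plus chemotherapy in advanced ESCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned survival cost-effectiveness model for first-line sugemalimab plus chemotherapy in advanced ESCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

Sugemalimab is a PD-L1 monoclonal antibody whose addition to first-line
cisplatin/5-FU chemotherapy prolongs progression-free survival (PFS) and
overall survival (OS) in unresectable advanced oesophageal squamous cell
carcinoma (ESCC). The clinical benefit comes at a high acquisition price,
so the package asks the health-economic question: per quality-adjusted
life year (QALY) gained, what does the combination cost the Chinese
health system relative to chemotherapy alone, and at what price would it
become cost-effective against a willingness-to-pay (WTP) threshold of
\$23,901.90/QALY (1.94 times 2024 per-capita GDP)?

## Model structure

The model is a three-state partitioned survival model (PSM). Unlike a
Markov cohort model it carries no transition matrix: state occupancy at
any time $t$ is read directly off the two marginal survival curves,

$$p_{\mathrm{PFS}}(t) = \min\{S_{\mathrm{PFS}}(t),\, S_{\mathrm{OS}}(t)\},\qquad
  p_{\mathrm{PD}}(t) = \max\{0,\, S_{\mathrm{OS}}(t) - S_{\mathrm{PFS}}(t)\},\qquad
  p_{\mathrm{death}}(t) = 1 - S_{\mathrm{OS}}(t).$$

The `min`/`max` clamp handles the region where an extrapolated PFS curve
crosses above OS — a mathematical artifact of independent parametric
fits, not a clinical state. `occupancy_trace()` counts clamped
boundaries and reports the count as a diagnostic rather than silently
absorbing it.

The cycle length is 21 days, matching the q3w dosing interval, and the
horizon is 10 years (174 cycles), long enough that fewer than 2% of the
modelled cohort remains alive at the end under every scenario. Costs and
QALYs are discounted at 5% per year, compounded continuously in cycle
time: the factor at cycle boundary $j$ is $(1.05)^{-21j/365.25}$.

### Cycle accounting

The engine books each cycle at its opening boundary: cycle $m$
contributes the occupancy and the discount factor of boundary $m-1$
(a left-endpoint rule with no half-cycle correction). This was a
genuinely open design choice — the published table does not state its
convention — and we fixed it by reproduction: against the printed
base-case QALYs, start-of-cycle accounting agrees within ±0.8% on all
six arm×population values, whereas a trapezoid half-cycle rule sits
systematically 1.8–2.3% low and an end-of-cycle rule 4–5% low. The
left-endpoint rule slightly overstates absolute QALYs relative to the
continuous-time integral (by at most half a cycle's occupancy), but the
bias largely cancels in the increments that drive every decision
quantity.

`restricted_mean_survival()` deliberately uses a finer trapezoid
quadrature instead: it estimates the continuous-time area under a curve,
and the tests pin it to closed forms (exponential;
$\theta\arctan(h/\theta)$ for the log-logistic with shape 2) at
$10^{-3}$-cycle accuracy.

## Survival inputs

Six parametric families are supported for extrapolation — exponential,
Weibull (proportional-hazards form $S(t)=e^{-\lambda t^{\gamma}}$),
log-logistic, log-normal, Gompertz and generalized gamma in the Prentice
$(\mu,\sigma,Q)$ form, which keeps the log-normal ($Q=0$) and Weibull
($Q=1$) as interior points. The shipped configuration encodes the
fitted log-logistic/log-normal/Weibull parameters for each arm,
endpoint and PD-L1 subgroup, **in cycle units**: the log-logistic scale
equals the median, and the whole-population combination-arm PFS scale
of 9.06 cycles × 21 days ≈ 6.25 months matches the trial's median PFS
of 6.2 months, which is what fixes the unit interpretation.

`fit_mle()` maximizes the right-censored log-likelihood
$\sum_i \delta_i\ln f(t_i) + (1-\delta_i)\ln S(t_i)$ by multi-start
BFGS on transformed parameters (log scale for positive ones), with
deterministic moment-based starts. The tests cross-check the optimum
against `flexsurv::flexsurvreg` and the closed-form exponential MLE,
and verify 5% parameter recovery at $n = 5000$ uncensored draws per
family. Model ranking (`select_best()`) minimizes AIC with BIC and
parameter count as tie-breaks.

One input resists interpretation: the CPS < 1 combination-arm OS row is
printed as "Weibull 0.01 / 1.32" with inconsistent labels. We read it
as $S(t)=\exp(-0.01\,t^{1.32})$ — the only reading with a plausible
median — but under it (and every alternative reading we tried) the
published CPS < 1 costs, QALYs and ICER are not reproducible; the
implied OS would be *better* than the whole-population curve. The
scenario ships for completeness, and the subgroup-ordering check in the
tests is restricted to the two subgroups whose inputs are coherent
(CPS ≥ 10 cheaper per QALY than 1 ≤ CPS < 10).

## Reconstruction of pseudo-IPD

Published trials expose survival only as plotted curves plus
numbers-at-risk rows. `km_estimate()` is a from-scratch product-limit
estimator (validated against `survival::survfit`), and
`reconstruct_ipd()` inverts it: within each risk-table interval it
allocates integer event and censoring counts — censoring spread
uniformly, counts iteratively adjusted — until the reconstructed curve
and risk set match the digitized inputs. Digitized coordinates are
treated as exact; `digitize_km(jitter_sd = ...)` exists to stress-test
robustness to extraction noise. Round-trip accuracy (simulate → curve →
reconstruct → re-estimate) is held to a 0.02 sup-norm in the tests.

## Synthetic trial data

`trial_sim_spec()`/`simulate_ipd()` generate endpoint-level IPD by
inverse-CDF sampling from true parametric models, censored at the
earlier of an administrative cutoff and a uniform dropout time. The
defaults mirror the study conditions: arm sizes 358 and 182, the
whole-population log-logistic parameters as truth, a 26-cycle
(≈18-month) cutoff matching the span of the published curves, and a 10%
uniform dropout fraction — a typical attrition level for this setting,
chosen once as a realistic default. PFS and OS cohorts are drawn
independently, which is exactly the information a PSM uses (marginal
curves only); patient-level PFS ≤ OS coupling is deliberately out of
scope. What passing the recovery tests shows is therefore that the
fitting/reconstruction/accumulation chain is faithful — not that a real
trial's joint endpoint structure, recruitment pattern or dependent
censoring are captured.

## Costing

All costs are 2023 USD, taken as printed, for a 65 kg / 1.72 m²
reference patient.

* **Drug acquisition.** Doses: sugemalimab 1200 mg flat q3w; cisplatin
  80 mg/m² day 1; 5-FU 800 mg/m²/day, days 1–4. Partial vials are
  billed whole, per administration day (no sharing): 2×600 mg
  sugemalimab packages (\$1732.50 each), 5×30 mg cisplatin vials, and
  6×250 mg 5-FU vials per day × 4 days, i.e. \$3465.00 + \$13.40 +
  \$490.56 per full cycle.
* **Treatment duration.** The chemotherapy backbone is costed for at
  most 4 induction cycles, and sugemalimab across PFS occupancy up to a
  24-month maintenance cap (35 q3w administrations). A literal
  treat-to-progression rule for all components overshoots the published
  arm costs by ~18%, far outside their tolerance, while the capped
  schedule — which mirrors how platinum doublets and checkpoint
  maintenance are actually administered and trialled — reproduces every
  published cost and ICER within 6%. This is the package's costing
  convention; the caps are per-drug config fields (`max_cycles`), so a
  no-cap analysis is one override away.
* **Hospitalization** (\$142.10/cycle) applies to all alive cycles; the
  published bounds for this row (15.89/23.83) contradict its baseline
  and are replaced by ±20% in the sensitivity ranges.
* **Post-progression care** (\$753.49/cycle, the irinotecan + S-1
  second line as a lump rate) applies to every PD cycle until death.
* **Adverse events.** Grade ≥ 3 events with ≥ 3% incidence enter as a
  one-off expected cost at model entry (incidence × unit cost summed;
  \$158.29 for the combination arm, \$136.58 for chemotherapy) —
  trial-level proportions, so per-cycle application would double-count.
* **Assistance program (PAP).** Payment for sugemalimab is gated by a
  three-tier donation ladder — buy 2 get 2, buy 2 get 25, buy 1 get 3 —
  after which supply is free. Within the 35-administration cap exactly
  five cycles (1, 2, 5, 6, 32) are purchased. Behaviour after the third
  tier is unstated in the source; "free thereafter" is adopted and is
  immaterial because the cap ends payment at cycle 35 regardless.

## Decision outputs

`run_all()` produces the comparison table (costs, QALYs, increments,
ICER) for the whole population, the three PD-L1 subgroups and the PAP
scenario. ICERs are computed from unrounded increments.
`price_threshold()` bisects on the sugemalimab package price (bounds
\$0–\$1732.50, 60 iterations, \$0.01 price tolerance, efficacy held
fixed) until the scenario ICER meets the WTP threshold, reporting the
viable price and its percent reduction; non-bracketing thresholds
return labelled boundary verdicts instead of errors.

## Sensitivity analysis

* **One-way (tornado).** Each parameter in the sensitivity table moves
  to its bounds (±20% where no published range exists) with everything
  else at base; rows are ranked by ICER span. The ranking is dominated
  by the sugemalimab package price, with the two state utilities next —
  the qualitative fingerprint reported for this model.
* **Probabilistic.** Ranges are read as 95% intervals,
  $SE = (\text{high}-\text{low})/3.92$; costs draw from gamma
  distributions (shape $b^2/SE^2$, scale $SE^2/b$), probabilities,
  utilities and the discount rate from mean/variance-matched betas.
  Draws are independent across parameters; survival parameters are not
  resampled (no published ranges exist), which understates structural
  uncertainty and is flagged as a limitation. Because the two utilities
  are drawn independently they cross in a few percent of draws; the
  accumulation arithmetic is well defined there, so such draws are kept
  rather than discarded — the ordering constraint binds only the
  base-case configuration. 1000 draws and the CEAC grid are the
  defaults; seeds make every run byte-reproducible.

## Problem sizes and numerical choices

Test and default problem sizes were chosen to keep the full suite fast
while leaving each statistical check well inside its band: parameter
recovery at $n = 5000$ (5% band ≈ 2–4 sampling SDs for the
well-conditioned truths used), marginal convergence and sampler moments
at $n = 10^4$–$10^5$, the reconstruction round trip at $n = 300$ with a
200-point digitization grid, and the pipeline-recovery check at
$n = 2000$ per arm so that reconstruction error, not Monte-Carlo noise,
is what the 3% QALY band measures. Bisection tolerances, optimizer
settings (BFGS, relative tolerance $10^{-12}$, multi-start) and the
clamping rule are all fixed constants, not tuned per dataset.

## Known limitations

* The CPS < 1 subgroup inputs are internally inconsistent in the source
  (see above); its outputs should not be quoted.
* Costing conventions (treatment caps, hospitalization state, vial
  rounding) are reproductions of an under-documented model, stated here
  explicitly so they can be varied; they carry the widest tolerance of
  any reproduced quantity.
* The PSM assumes the two arms' curves can be extrapolated
  independently to 10 years from ≈18 months of follow-up; no external
  calibration (registry survival) is applied.
* Utilities come from international ESCC sources; alternative utility
  sets are a config override (`utilities.pfs` / `utilities.pd`), not a
  packaged scenario.
* Only direct medical costs from the health-system perspective are
  modelled; societal costs are excluded by design.
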