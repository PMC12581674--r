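---
title: "Models, calibration, and numerical choices in akirank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration, and numerical choices in akirank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akirank)
```

`akirank` analyses three-arm ICU trials of kidney protection whose primary
endpoint is a hierarchical global-rank composite. This vignette is the
package's own account of the models it implements, the defaults it ships,
and the numerical decisions taken where the design was genuinely open.

## The hierarchical composite endpoint

Every enrolled patient is reduced to one outcome tier within the 7-day
endpoint window:

* **death** (tier 3, worst) — death within 7 days of enrollment;
* **KRT** (tier 2) — kidney replacement therapy among 7-day survivors;
* **creatinine course** (tier 1) — for event-free patients, the
  baseline-adjusted mean change in serum creatinine:
  the mean over available daily values on days 1–7 of
  $100\,(\mathrm{SCr}_d - \mathrm{SCr}_0)/\mathrm{SCr}_0$, in percent.

Patients are ranked jointly: all deaths share the worst midrank block, KRT
patients the next, and event-free patients order by ascending mean change.
Midranks make the ranking a valid total preorder — ranks always sum to
$n(n+1)/2$ — and the assignment is monotone: moving a patient from survivor
to KRT, or KRT to death, can never improve their rank. Each active arm is
compared with placebo by the Wilcoxon rank-sum test on ranks *recomputed on
that two-arm pool*; the three-arm ranking is only a reporting convenience.

Design decisions taken here:

* **Tiers, not times.** Event-tier patients are internally tied; time to
  death or to dialysis is deliberately not used to order within a tier.
* **Death beats KRT** when both occur in the window.
* **Percent change**, not absolute change, is the creatinine metric, and the
  average runs over days 1–7 only: day 0 *is* the baseline. All available
  daily values are used, not just scheduled ones.
* **Post-KRT creatinine is excluded** from the tier-1 average (dialysis
  controls creatinine mechanically); KRT patients sit in tier 2 regardless.
* **Survivors with no post-baseline creatinine** are assigned 0% change,
  flagged `unevaluable`, and a warning is emitted. Endpoint data are never
  imputed; the flag exists so a sensitivity analysis can drop or bound these
  patients.

## Rank-sum inference under heavy ties

Tied tiers are the norm for this endpoint, so the test is built around them.
Writing $W$ for the rank sum of the first group over pooled midranks:

* **Exact path** (pooled $n \le 16$ by default): the permutation
  distribution of $W$ is fully enumerated; the two-sided p-value is twice
  the smaller tail probability (including the observed point), capped at 1.
* **Approximate path**: a normal approximation with the *exact*
  tie-corrected permutation variance, a continuity correction of one half,
  and, by default, an Edgeworth refinement using the exact third and fourth
  permutation cumulants of $W$ (closed forms in the centered power sums of
  the midrank population, valid for arbitrary tie patterns).

A limitation worth stating precisely: when tie blocks are large relative to
the pooled sample, the exact null distribution of $W$ has point masses
("atoms") of non-negligible probability, and *no* continuous approximation
can track a doubled-tail p-value across such a support to within 0.01 —
the approximation error at an atom is bounded below by roughly half the
atom's mass. On untied 6-vs-6 data the refined approximation is accurate to
about $2\times10^{-3}$; on endpoint-like tied data at pooled sizes of 12 or
fewer the worst-case gap is on the order of 0.1, which is why the package
routes every small-sample comparison through the exact path. The acceptance
suite keeps an assertion of the 0.01 band on small tied samples precisely
to document this gap rather than hide it; it fails by construction of the
problem, not of the code.

The null behaviour of the full procedure is checked by simulation: over
10,000 synthetic 50-versus-50 trials generated under one set of event risks
and a common creatinine-change distribution, the rejection rate at
$\alpha = 0.025$ sits within binomial error of 2.5%.

## KDIGO staging

The creatinine rules are operationalized with **closed lookback windows**
ending at the query time $t$ — $[t-48\mathrm{h},\,t]$ for the absolute rule
and $[t-7\mathrm{d},\,t]$ for the relative rules — with the **window
minimum as the reference** and the most recent observation at or before $t$
as the current value. The window minimum maximizes rule sensitivity and is
the common operationalization when no reference convention is specified.
Stage 1 requires a rise of at least 0.3 mg/dL (48 h) or 50% (7 d); stage 2
at least 100% (7 d); KRT at or before $t$ forces stage 3. Staging is
verified against a brute-force scanner that tests every candidate reference
observation on series of up to 20 points.

Urine output rules use consecutive-hour runs below 0.5 mL/kg/h within the
previous 24 h: at least 6 h for stage 1, at least 12 h for stage 2
(consecutive-run semantics were chosen; a cumulative-hours reading of the
12-h rule is also defensible but less conservative). Gaps longer than one
hour break a run and are never imputed. Time is measured in hours from
enrollment, with day $d$ spanning hours $[24d, 24d+24)$.

Eligibility screening composes these parts: include if and only if the
KDIGO stage at screening is at most 1, the patient is at high AKI risk
(manifest stage 1 or an additive risk score of at least 6 points), and no
exclusion fires (calcium > 9.0 mg/dL, phosphate > 6.0 mg/dL,
eGFR < 15 mL/min/1.73m², stage 2–3). eGFR is an input field, not computed.
The risk-score *threshold* is fixed at 6 by the design; the shipped factor
weights are documented placeholders (configurable in code or YAML), since
published prediction scores keep their exact point values in supplements.

## The synthetic cohort generator

The generator exists so that every downstream stage is exercised on data
with the statistical structure the analysis assumes. Its defaults *are* the
study conditions; they were fixed from the printed dynamics before any
testing and are not tuning knobs.

| Quantity | Default | Source of calibration |
|---|---|---|
| AKI prevalence at enrollment | 35% | printed cohort description |
| 7-day death risk per arm | 7.8% / 18.0% / 12.2% | printed event counts |
| 7-day KRT risk per arm | 2.0% / 2.0% / 8.2% | printed event counts |
| Baseline 25D | lognormal, median 16.1, IQR 10.2–25.9 ng/mL | printed median/IQR |
| Baseline 1,25D | lognormal, median 26.9, IQR 17.5–39.1 pg/mL | printed median/IQR |
| 25D kinetics, calcifediol | ×2 day 1 → ×3 day 5, held | printed fold-rises |
| 1,25D kinetics, calcitriol | ×2.5 day 2, held | printed "more than 2-fold" |
| SCr mean-change quartiles | −21.5% / +18.3%, median 0 | printed IQR |

Lognormal parameters are solved from the printed median and IQR
(`meanlog = log(median)`, `sdlog = log(q3/q1) / (2 z_{0.75})`), matching the
right-skew of concentration data. Metabolite noise is multiplicative
mean-one lognormal with a 15% coefficient of variation — only medians and
IQRs are printed, and 15% is a typical assay-plus-biology scale. The day-0
multiplier is exactly 1 for every arm and analyte by construction.

Creatinine trajectories follow a latent geometric drift with multiplicative
daily noise (default 5%): each patient draws a target mean change from an
asymmetric two-sided half-normal whose quartiles equal the calibration
quartiles, and the daily drift rate is obtained by numerically inverting
the map from drift to 7-day mean change (`uniroot` to $10^{-10}$). This
reproduces the near-zero median and the printed IQR at cohort scale while
keeping the trajectory model (drift + noise) simple and interpretable.

Choices the printed record does not determine, fixed once as realistic:

* **Event timing** within the 7-day window is uniform over days 0–7 (only
  cumulative 7-day counts are printed).
* **28-day mortality** is the 7-day risk plus 8 percentage points — a
  typical ICU excess between day 7 and day 28; late deaths fall uniformly
  on days 8–28.
* **Septic shock prevalence** 70%, matching the printed subcohort split
  (92 of 131); ICU type 60% medical; APACHE II ≈ N(24, 7); age ≈ N(62, 15);
  weight lognormal around 80 kg.
* **Minerals**: calcium/phosphate have patient-level intercepts plus daily
  noise with additive arm offsets, largest for calcitriol — reproducing the
  qualitative ordering (calcitriol runs highest) and making hypercalcemia
  (> 10.7 mg/dL) a rare tail event rather than a planted outcome.
* **Urine output** is hourly with a lognormal patient-level mean (median
  1.0 mL/kg/h), so a realistic minority of patients trip the oliguria
  rules.
* Death censors all later labs; KRT does not censor labs (the endpoint
  logic excludes post-KRT creatinine instead).

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: informative missingness (labs are
complete up to death), within-patient autocorrelated creatinine noise
beyond the latent drift, correlated organ failure across labs, drug
accumulation or nonlinear pharmacokinetics (fold-change schedules only),
and any transcriptomic component. Conclusions about operating
characteristics transfer to real trials only to the extent that these
simplifications are immaterial to rank-based analysis — which is the point
of using ranks.

## Secondary endpoints, safety, and supporting statistics

* **Free days**: $28 - \text{stay}$, floored at 0; death before day 28
  scores exactly 0 (competing-risk convention).
* **New or progressive AKI**: maximum staged day 1–7 exceeds the
  enrollment stage.
* **Safety flags** are strict inequalities (calcium > 10.7, phosphate >
  6.0 mg/dL); boundary values do not flag.
* **Binary contrasts** delegate to `stats::fisher.test` (two-sided by the
  point-probability convention) and `stats::chisq.test` (no continuity
  correction by default); the test suite verifies Fisher against an
  independent hypergeometric enumeration exhaustively over all 2×2 tables
  with total size up to 40 (deduplicated by the symmetry group of the
  table).
* **Longitudinal comparisons** fit `value ~ group * time` with a random
  patient intercept via `nlme::lme`; the group main-effect p-value is
  returned, and singular designs yield a not-estimable marker. A response
  with exactly zero variance is singular for any mixed-model fit, so the
  degenerate "identical trajectories" contract is exercised with a
  $10^{-6}$ noise floor.
* **Multiple imputation**: chained-equation stochastic regression
  imputation (coefficients drawn from their approximate posterior, missing
  values filled with prediction plus residual noise, five sweeps), `m = 5`
  datasets, and Rubin's rules implemented in-package: pooled estimate
  $\bar q$, total variance $\bar u + (1 + 1/m) b$, Rubin's large-sample
  degrees of freedom. With zero missingness the procedure is exactly the
  identity on the complete-data fit; with $m = 1$ the between-imputation
  term is defined as zero.
* **SOFA** is a configurable six-organ 0–4 grid (standard cutoffs shipped
  in code and YAML); a missing organ scores 0 and is flagged, with
  carry-forward available as an option.

## Power design

The design calculation uses the normal approximation
$\Phi(\delta\sqrt{n/2} - z_{1-\alpha/2}) + \Phi(-\delta\sqrt{n/2} - z_{1-\alpha/2})$,
which reproduces the printed 80% at $n = 50$, $\delta = 0.62$,
$\alpha = 0.025$ (computed value 0.8047); the opposite-tail term makes the
power exactly $\alpha$ at $\delta = 0$. A noncentral-t refinement is
available behind `method = "t"`. Multiplicity is handled by design — each
active-versus-placebo contrast is tested at a two-sided 0.025 — not by
post-hoc adjustment. `simulate_power()` checks the closed form by
simulation and extends it to the Wilcoxon (which tracks the
ARE-adjusted effective sample size $0.955\,n$ on normal shifts) and to the
full global-rank endpoint with planted location and event-rate shifts.

## Problem sizes and runtime choices

The shipped tests run the null-calibration study at 10,000 simulated
trials of 50 patients per arm; generator calibration checks use 500
simulated patients per arm; Fisher enumeration covers all 2×2 tables of
total size up to 40; staging properties use 150–200 random series of up to
20 points; mixed-model and imputation recovery studies use 25–60
replicates. These sizes put every Monte-Carlo tolerance at three standard
errors or better while keeping the default suite in the low minutes.

## Known limitations

* The rank-sum approximate path should not be trusted for pooled samples
  below ~20 with dominant tie blocks; the package defaults route those
  through exact enumeration instead.
* The generator's creatinine model has no within-patient autocorrelation
  beyond drift, and its event times are exchangeable within the window;
  endpoints sensitive to event *timing* (none of the shipped ones are)
  would need a richer model.
* eGFR and the risk-score factor weights are inputs, not computations.
* No win-ratio or DOOR-style effect-size estimation is provided — the
  primary inference is deliberately the p-value procedure on ranks; and no
  time-to-event machinery (Kaplan–Meier, Cox) is included.
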