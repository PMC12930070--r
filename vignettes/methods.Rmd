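---
title: "Model and methods: semi-Markov cost-effectiveness of perioperative durvalumab plus FLOT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

`flotcea` implements a cohort-level cost-effectiveness analysis of
perioperative durvalumab added to FLOT chemotherapy (DFLOT) versus FLOT
alone for resectable gastric/gastroesophageal-junction adenocarcinoma,
from a U.S. healthcare payer perspective. The decision statistic is the
incremental cost-effectiveness ratio (ICER), interpreted against
willingness-to-pay (WTP) thresholds of \$100,000–150,000 per QALY.

The model is a four-state semi-Markov structure:

* **EFS** — event-free after randomization (first-line perioperative
  treatment and surveillance);
* **PD1** — first progression (second-line ramucirumab + paclitaxel);
* **PD2** — subsequent progression (best supportive care);
* **Death** — absorbing, with a single hospice episode charged on entry.

Cycles are 4 weeks (28 days = `28/30.4375` months; months are the single
canonical time unit throughout, avoiding calendar drift). The horizon is
10 years, i.e. `floor(10 * 365.25 / 28) = 130` cycles. Both costs and
QALYs are discounted at 3%/year using mid-cycle weights
`(1 + r)^(-t/12)`, and a trapezoid half-cycle correction is applied:
the occupancy credited to cycle *u* is the mean of the start-of-cycle
*u* and *u + 1* occupancies.

### Semi-Markov mechanics

Exit hazards from PD1 and PD2 depend on time since *entering* the state,
not on model time. The engine therefore keeps an entry-cohort ("tunnel")
ledger: occupancy in PD1/PD2 is a vector indexed by residence cycle, the
residence clock resets on entry, and exits are computed per residence bin
from the second-line survival fits. When the exit probabilities are
residence-independent the engine provably coincides with a plain Markov
chain (this is a unit test, checked against a matrix-product oracle), and
the full residence-dependent engine is cross-checked against a
200,000-walker individual-level microsimulation (maximum occupancy gap
below 0.005).

### The EFS exit split

First-line evidence gives marginal EFS and OS curves, but not how EFS
events divide between progression and pre-progression death. The default
split sends, in each cycle, a share `min(1, h_OS(t) / h_EFS(t))` of EFS
exits directly to death (hazards evaluated at the cycle midpoint from the
first-line OS and EFS fits) and the remainder to PD1. This is a modelling
assumption, not an estimate: it treats the marginal OS hazard as an upper
bound on the pre-progression death hazard and will overstate early deaths
when most early OS events occur after progression. A constant split
(`efs_split = "constant"`, any fixed share including 0) is available as
an alternative. Similarly, PD1 exits follow the second-line PFS fit with
the death share `min(1, h_OS2 / h_PFS2)` on the residence clock, and
PD2→Death follows the second-line OS fit evaluated on the PD2 residence
clock — the latter is again an assumption, since no third-line evidence
is modelled. No background general-population mortality is added.

## Evidence synthesis

### Synthetic trial generator

No patient-level or digitized trial data ship with the package; a
generator produces two-arm evidence with the statistical structure the
analysis assumes, so the whole pipeline is testable end to end. Its
defaults are the study conditions of the motivating trial summaries:

* control-arm EFS exponential, calibrated so `S(24 months) = 0.585`
  (rate `-log(0.585)/24` per month);
* treatment-arm EFS by proportional hazards with HR 0.71 applied to the
  control hazard (implying a 2-year landmark of `0.585^0.71 ≈ 0.684`;
  the published treatment-arm landmark 0.674 differs slightly because
  the real trial is not exactly proportional-hazards — only marginal
  summaries are printed, so the reference arm is calibrated and the HR
  applied);
* OS per arm calibrated marginally to its own 2-year landmark
  (0.757 vs 0.704);
* 474 subjects per arm, administrative censoring at 36 months (roughly
  the reported follow-up maturity).

Second-line (post-progression) PFS and OS stand in for an external
second-line trial as Weibull curves with configurable medians. The
defaults (median PFS 4.5 months, median OS 10 months, shape 1.2) are
explicitly synthetic placeholders chosen to be clinically plausible for
second-line ramucirumab + paclitaxel; the original second-line fits live
in unavailable supplementary material, so no claim of equivalence is
made.

What the generator deliberately does **not** emulate: patient covariates,
PD-L1 subgroups, surgery rates, non-proportional hazards, informative
censoring, or digitizer noise (the reconstruction layer has its own
monotonization/clipping repair for that). Passing tests therefore show
the pipeline is correct *under its own assumptions*, not that the
published trial curves are reproduced.

### Kaplan–Meier reconstruction

Published curves are consumed as digitized coordinates plus
number-at-risk tables. Pseudo individual patient data are rebuilt by the
standard iterative interval-solving approach: within each interval
between risk-table times, censorings are assumed uniform, the censoring
count is adjusted until the implied number at risk matches the next
table entry, and event counts at each digitized drop follow from the
product-limit relation. Events are emitted at their click times,
censorings at interval midpoints, survivors at end of follow-up. If a
reported total event count is supplied, final-interval censoring is
tuned to match it; otherwise interval event counts come solely from the
drop-and-risk-table system. Survival coordinates are monotonized by a
running minimum and clipped to [0, 1] with a warning before solving
(digitizer output is noisy), and risk-table boundaries lacking a
digitized point are linearly interpolated. The round trip
(simulate → coordinates → reconstruct → Kaplan–Meier) agrees with the
source curve within 0.02 survival at n = 500 in the test suite, and
reconstruction is idempotent on its own output.

## Survival extrapolation

Seven standard families (exponential, Weibull, Gompertz, log-normal,
log-logistic, gamma, generalized gamma) are fitted by maximum likelihood
with right censoring via `flexsurv`, plus flexible families:

* **Royston–Parmar splines** on the log-cumulative-hazard ("hazard"),
  log-cumulative-odds ("odds") and probit ("normal") scales. Interior
  knots default to 1, placed at quantiles of log event time (the median
  for one knot) with boundary knots at the extreme event times. With 0
  interior knots the hazard scale is exactly Weibull — the test suite
  checks agreement within 10⁻³ nats.
* **Fractional polynomials** on the log hazard, order 1 or 2, powers
  from {−2, −1, −0.5, 0, 0.5, 1, 2, 3} (0 ≡ log t, repeated powers use
  `t^p` and `t^p log t`), selected by deviance. The cumulative hazard is
  integrated by 30-node Gauss–Legendre quadrature per observation.
* **Mixture cure**: `S(t) = π + (1 − π) S_u(t)` with π estimated on the
  logit scale and a standard-family latency; multi-start optimization
  (plateau of the KM tail, 0.1, 0.3 as π starts). A fit driven to the
  π → 0 boundary is reported in the diagnostics rather than hidden.
* **GAM**: registered in the interface but deliberately not available —
  no parameterization is defined for it here, and the registry is
  extensible.

Non-convergence anywhere is flagged on the returned object (and retried
once from perturbed initials for the standard families, or with a
derivative-free optimizer for the spline scales) — never silently
dropped. Model comparison reports log-likelihood, AIC, BIC and 2/5/10-year
landmark survival. Two selection policies exist: `"aic"` (best AIC) and
the default-documented `"conservative"` policy, which among converged
fits within ΔAIC ≤ 3 of the best picks the lowest extrapolated 10-year
survival — a guard against over-optimistic tails when trial data are
immature. Ties break by BIC, then input order.

The base-case family map follows the reference analysis: Weibull for
DFLOT EFS, exponential for FLOT EFS, gamma for second-line OS,
RP-hazard for second-line PFS. First-line OS (which only enters the EFS
exit split) uses exponential for both arms. All assignments are
overridable.

Per-cycle transition probabilities are `p_u = 1 − S(t_{u+1}) / S(t_u)`;
if a curve has already reached zero at a cycle start the probability is
1 with a warning.

## Costs and QALYs

Costs (2025 USD) fall into four categories: drug (acquisition +
infusion administration + the resection fee), adverse-event management,
follow-up surveillance, and end-of-life (best supportive care plus one
hospice episode per incident death). The treatment calendar is 2
neoadjuvant model cycles, surgery at cycle 2, 2 adjuvant cycles, then 10
durvalumab monotherapy cycles (combination arm only) — 14
durvalumab-bearing cycles in all. Receipt is gated by EFS occupancy:
patients who progress stop perioperative therapy.

Decisions worth making explicit:

* The published "drug cost per cycle" for the FLOT components is read as
  per 4-week **model** cycle (the declared model cycle), although two
  2-week chemotherapy cycles occur per model cycle; the per-chemo-cycle
  reading (doubling the component cost) is a configuration switch.
* Infusion fees: each 2-week chemotherapy administration is charged two
  short (≤1 h: docetaxel, leucovorin) and two long (>1 h: oxaliplatin and
  the 24-hour fluorouracil) infusion fees; durvalumab one short fee per
  cycle; second line five short fees (two ramucirumab, three weekly
  paclitaxel) per 28-day cycle.
* Body-surface area uses the Mosteller formula **with** the square root:
  `sqrt(168.3 × 84.7 / 3600) = 1.99 m²` reproduces the published
  reference BSA, the non-root form does not. Because all drug prices are
  per cycle, weight/BSA do not otherwise enter the base case (they are
  retained as sampled parameters with zero structural effect, which the
  tornado correctly reports as zero swing).
* The adverse-event burden (grade ≥3, incidence ≥5%: diarrhea, anemia,
  neutropenia, thrombocytopenia) is expected cost `Σ pᵢcᵢ` and utility
  decrement `Σ pᵢdᵢ`, charged once, undiscounted, at treatment start;
  the decrement lasts one cycle.
* Utilities: EFS 0.797, progressed disease 0.577, death 0; the
  gastrectomy utility 0.773 replaces the EFS utility for 13 cycles after
  surgery.
* Best supportive care is charged per PD2 cycle by default (per-episode
  on PD2 entry is a switch) and is booked in the end-of-life category
  with hospice. The published base-case table's end-of-life magnitudes
  are consistent with hospice alone, so this mapping is a declared
  package convention rather than a reproduction claim.
* The published best-supportive-care range has its minimum above the
  base value (an apparent typo); the constructor repairs it to ±25%
  around the base with a warning.

Life-years and QALYs are half-cycle-corrected, discounted sums of
occupancy (×utility) × cycle length (28/365.25 years). The ICER labels
dominance (cost and QALY differences of opposite sign) and the
zero-ΔQALY degenerate case instead of reporting a ratio.

## Uncertainty analyses

* **OWSA**: every parameter with a range is set to each bound with all
  else at base; fitted curves stay at their estimates, so only the
  economic layer responds. Both the ICER and the incremental NMB are
  reported at each bound (the ICER is unstable near ΔQALY = 0), sorted
  by NMB swing. Bounds are the published ranges (±25% where no sd was
  published; discount rate 0–5%). Utility bounds above 1 are clipped
  with a warning.
* **PSA**: Monte Carlo with common random parameter draws across both
  strategies. Costs are gamma, utilities/probabilities beta,
  anthropometrics normal, all by method of moments with
  `sd = (max − min)/(2 × 1.96)`; draws are independent across
  parameters (only marginal distributions are specified). Survival-model
  parameter uncertainty is included by default via a multivariate normal
  on each fit's estimation scale using its observed information
  (freezing the curves is a toggle — the source analysis is silent on
  whether curves were resampled). Draws violating model invariants are
  rejected, logged and resampled. The reference iteration count is
  5,000; the test suite uses 8–60 draws to stay fast, which is
  sufficient for the exact properties it checks (reproducibility under a
  seed, probability normalization, non-negativity).
* **CEAC / EVPI**: probability each strategy maximizes NMB per
  threshold, and `E[max_s NMB] − max_s E[NMB]` per patient. EVPI is
  non-negative by construction and approaches zero wherever one strategy
  wins almost surely; the two-draw hand example (NMB pairs (10, 0) and
  (0, 10) → EVPI 5) is tested exactly.
* **Scenario — adjuvant completion**: a fraction (0.523) completes all
  10 postoperative monotherapy cycles; non-completers average
  m ∈ {2, 4, 6, 8, 10} cycles, so expected exposure is
  `0.523·10 + (1 − 0.523)·m`, scaling only the monotherapy drug cost
  (the four perioperative cycles are held fixed and efficacy is
  unchanged). The source text says "remaining 48.3%" although
  100 − 52.3 = 47.7; the default uses the complement, and passing the
  literal 0.483 is accepted with a warning that the fractions do not
  sum to 1.

## Numerical choices and degenerate inputs

* Optimizers: `flexsurv` defaults (BFGS) with one restart from jittered
  initials on failure; Nelder–Mead fallback for spline scales; the FP
  and mixture-cure objectives return a large penalty on NaN excursions.
* Quadrature: 30-node Gauss–Legendre for FP cumulative hazards.
* Engine tolerances: row-stochasticity enforced at construction; mass
  conservation asserted per cycle at 10⁻⁹; probabilities clamped to
  [0, 1] after floating-point arithmetic.
* Ties at equal event/censoring times follow the product-limit
  convention (events first).
* All-censored input: the KM is flat, reconstruction returns all
  censored, but fitting requires at least one event and says so.
* `S(t) = 0` inside the horizon: transition probability 1 with a
  warning (can occur for resampled second-line curves at long residence
  times).

## Problem sizes used by the checks

The test suite runs the generator at 474/arm (the trial-like size) for
hazard-ratio recovery, 500 for the reconstruction round trip, 2,000 per
family for parameter recovery, 200,000 walkers for the microsimulation
cross-check, and 8–60 PSA draws for the decision-analytic properties;
the full-analysis smoke test uses 120/arm and 10 draws. These sizes were
chosen so each check is statistically informative at its stated
tolerance while the whole suite stays quick on a laptop.

## Known limitations

* The EFS exit split and the PD2 exit hazard are structural assumptions,
  not estimates; alternatives are configurable but equally unvalidated.
* Second-line defaults are synthetic placeholders, so absolute base-case
  outputs depend on them; the package's claim is correctness of the
  machinery under declared conditions, not reproduction of any single
  published number.
* No covariate-adjusted survival models; arms are fitted separately.
* No societal-perspective costs, no inflation engine, no EVPPI, and no
  individual-level production engine (the microsimulation exists only as
  a test oracle).
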