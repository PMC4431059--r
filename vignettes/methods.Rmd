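---
title: "Model structure, parameterisation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameterisation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namdcea)
```

## The decision problem

Neovascular age-related macular degeneration is treated with intravitreal
anti-VEGF injections (ranibizumab in this model). UK guidance funds
treatment only once acuity in the affected eye has fallen below 6/12.
`namdcea` compares two strategies for a patient whose better seeing eye
presents with nAMD and vision better than 6/12:

* **immediate**: treat on diagnosis — three monthly loading injections,
  then pro re nata (PRN) injections with monthly review;
* **delayed**: monitor untreated until acuity crosses the 6/12 gate, then
  treat with the same loading + PRN protocol.

Outcomes are QALYs and UK NHS costs (GBP, cost year 2012), with no
discounting — defensible at a 2-year horizon and retained, deliberately
and explicitly, for the 5-year scenario as well.

## State space and dynamics

The model is a patient-level state-transition (Markov) microsimulation
over five acuity bands in the better seeing eye — 6/6 to >6/12, 6/12 to
6/24, 6/24 to 6/60, 6/60 to 3/60, <3/60 — plus absorbing death. A single
3-month loading cycle is followed by monthly cycles. Two published
transition structures drive treated eyes: one 3-month loading row (from
the best state) and a full 5×5 monthly matrix. Published rows sum to
0.9999–1.0001 because of printing precision; the loader renormalises each
row proportionally, preserving the printed ratios, and validates
row-stochasticity to 1e-12.

Two points in the published description are under-determined and were
resolved as follows:

* **Loading entries from states 2–5.** Only the best-state loading row is
  published. Delayed-arm patients re-enter treatment in states 2–5, so
  for those rows the loading-cycle kernel applies the monthly matrix
  three times (`M³`) — the only transition information available for
  those states that is consistent with the published data.
* **Delayed-arm pre-treatment period.** Patients wait in the best state
  (accruing its utility, no treatment or monitoring costs) for a time
  drawn from a survival distribution; on crossing the gate they jump to a
  state drawn from the published re-entry distribution (0, 0.4345,
  0.3892, 0.1456, 0.0308 after renormalisation — the printed values sum
  to 1.0000357). The natural-history transition matrix is *not* used by
  the simulation arm; it exists only in the synthetic-EMR module. This
  follows the stated mechanism of the original model literally.

## Background mortality

No mortality source is published. The package embeds a gender-specific
Gompertz model `q(a) = A·exp(B·a)` with (A, B) solved from two anchors
per gender — male q(65) = 0.0143, q(85) = 0.0998; female q(65) = 0.0087,
q(85) = 0.0726 — reproducing UK 2010–12 interim life-table values, the
era-appropriate national source for this cohort. The annual probability
is capped at 0.7 and ages are clamped to [55, 110]; both matter only
beyond age ~105. Annual-to-cycle conversion assumes constant hazard
within the year: `q_c = 1 − (1 − q)^(m/12)`.

Cohort demographics follow the published table: 36.57% male; ages are
drawn per gender from a normal distribution (means 78.8/80.1 years,
SD 7.41 years derived from the published IQRs under normality) truncated
to the published ranges (55–103 male, 55–108 female) and discretised to
whole years. Discretisation lets the deterministic expectation engine
integrate over exactly the same age mixture the sampler draws from.

## Costs and the PRN rate

Unit costs are published: £742.17 per ranibizumab injection, £255.00 per
assessment, £60.00 per monitoring visit. The event mapping is: every
injection costs drug + assessment; every non-injection monthly visit
costs monitoring; loading delivers one injection per month for three
months. The drug-only scenario zeroes assessment and monitoring.

The PRN injection frequency is *not* published (only that it was
estimated from the source records). The packaged default of **0.240
injections per post-loading month** is calibrated so that the
deterministic immediate-arm 2-year cost equals the published immediate-arm
total (£8,469.79). We chose this anchor over the alternative — matching
the published "about one more injection" differential between arms —
because the differential depends on the unpublished delay survival curve,
whereas the immediate-arm total depends only on published quantities.
With this default the simulated immediate arm receives ≈7.6 injections
over two years versus ≈5.4 in the delayed arm.

## Accrual conventions and numerical choices

* Mortality is applied at each cycle start, before the acuity
  transition; patients who die in a cycle accrue nothing for it (no
  half-cycle correction, matching the absence of one in the source
  description). A `half_cycle = TRUE` toggle credits the dying with half
  a cycle's utility; at these hazards it shifts 2-year QALYs by under
  0.02.
* The state at cycle start accrues for the whole cycle.
* If the horizon truncates the loading cycle (delayed patients crossing
  the gate near the end), the cycle shortens and injections scale with
  its length.
* The delay time is continuous exponential, discretised by `ceiling()`
  to whole months; the expectation engine uses the identical monthly
  probability mass function.
* One root seed drives each run; sub-seeds for PSA iterations are
  derived deterministically (kept below 2³¹). Runs are bitwise
  reproducible given the seed, which the suite asserts.

## The deterministic oracle

`cohort_expectation()` propagates the 5-state occupancy vector through
the loading kernel and monthly matrix with per-cycle survival factors,
summing exactly over the gender × integer-age × delay-month mixture. It
is the microsimulation's expectation by construction, so Monte-Carlo
means must (and do, in the tests) land within 3 standard errors of it for
costs and QALYs in both arms. Occupancy mass plus cumulative deaths is
conserved to 1e-12 at every cycle.

## Probabilistic sensitivity analysis

Second-order uncertainty follows standard health-economics practice:

* **Utilities** — beta distributions, method-of-moments from the
  published mean (SD) pairs: 0.89 (0.16), 0.81 (0.20), 0.57 (0.17),
  0.52 (0.24), 0.40 (0.12).
* **Unit costs** — gamma distributions with SD = 10% of the mean (the
  conventional assumption when cost SDs are unreported).
* **Transition rows** — Dirichlet with concentration `row ×
  effective_n`. The underlying transition counts are not recoverable
  from the publication, so the spread is genuinely unidentifiable;
  `effective_n` (default 100 per row) is an explicit, tunable pseudo-count
  rather than a hidden constant. Zero entries are floored at 1e-6
  pseudo-counts to keep the density proper.

Draws are independent across parameters (no published correlation
structure). Within an iteration both arms run under **common random
numbers**, which removes patient-level noise from the increments. The
default design is one patient path per iteration at many iterations —
reading each Monte-Carlo simulation as one parameter draw plus one
patient — with `n_patients` available for nested designs, since the
published description does not separate the two sampling levels. The
acceptability-curve grid defaults to £0–£50,000 in £500 steps, covering
the conventional £20,000 threshold. Setting every SD to zero and
`effective_n = Inf` collapses each sampled parameter set to the base
case exactly; the suite verifies the PSA then reproduces the plain
base-case run identically.

## The synthetic-EMR generator

The original parameterisation came from a national treatment register
(~93,000 injections; ~317,000 visits) that is not available. The
generator emulates the *statistical structure* that the estimators
assume: a long-format monthly visit table per eye (patient id, eye role,
month index, acuity state or ETDRS letters, injection flag), with
treated-eye states Markov under a known matrix, fellow-eye states Markov
under a natural-history matrix, loading injections at months 0–2 and
Bernoulli PRN injections thereafter.

Because a Markov chain's first-passage time is fixed by its matrix, the
time-to-threshold law cannot be set independently of the fellow matrix.
The generator therefore has two modes: `"markov"` (default; the
threshold-crossing law is whatever the chain implies) and
`"exponential"`, which overrides the first dwell in the best state with
an exponential time of configurable median so the Kaplan–Meier estimator
can be validated against a known curve. The default natural-history
matrix is itself a documented synthetic construction (exit from the best
state doubled relative to the treated matrix; recovery mass halved and
shifted to worse states) standing in for the unpublished fellow-eye
dynamics.

What the generator does **not** emulate: irregular visit spacing, missing
data and the original two-stop-service baseline quirk, centre effects,
bilateral treatment, and measurement error in acuity. Passing recovery
tests therefore demonstrates that the estimators are correct for cleanly
sampled Markov data, not that they are robust to real-register messiness.

Estimators: transition matrices by pair counting at the requested
spacing (unobserved rows fall back to identity with a warning);
Kaplan–Meier via `survival::survfit`, with an independent brute-force
product-limit oracle in the tests; injection rate as the post-loading
injection fraction with Wilson intervals. The recovery study runs 20
cohorts of 5,000 patients and achieves ≥90% nominal-interval coverage.

## Known limitations

* **Delayed-arm absolutes are stand-ins.** Under the published mechanism
  (wait in the best state, re-enter via the published distribution, then
  the published monthly matrix), attainable 2-year delayed-arm QALYs lie
  in roughly [1.51, 1.67] *regardless* of the delay distribution,
  because waiting time is spent in the highest-utility state. The
  published delayed-arm value (1.35 QALYs) is therefore unreachable from
  published inputs alone — it must reflect unpublished fellow-eye
  dynamics. Consequently the incremental QALY gap here (≈0.05 at the
  default 6-month median delay) is smaller than the published 0.24, and
  the ICER correspondingly larger; only immediate-arm absolutes and
  directional/one-way results should be compared against the
  publication. The one-way scenarios reproduce every published
  direction: drug-only, 5-year horizon and age-60 cohorts all lower the
  ICER.
* Mortality anchors are approximations to the national life tables, not
  the (unnamed) source the original used; the immediate-arm 2-year QALY
  moves by well under 0.05 across reasonable alternatives, which is why
  results at that tolerance are considered reproduced.
* Both eyes are reduced to the better seeing eye; bilateral treatment
  (16.3% of the source cohort) is out of scope, as are treatment
  discontinuation rules other than death.

## Problem sizes

Default runs simulate 10,000 patients per arm (seconds on one core).
The test suite uses 200–4,000 patients for distributional checks, 20
replicate synthetic cohorts of 5,000 patients for recovery, and
1e5 draws for distribution-moment checks; these sizes give Monte-Carlo
standard errors comfortably below the tolerances they are tested
against.
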