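---
title: "Methods: registry survival modelling and the semi-Markov cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registry survival modelling and the semi-Markov cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipcea)
```

`hipcea` evaluates whether metal-on-metal hip resurfacing (RS) — or, more
precisely, the best-performing RS device–patient subgroups — has been
cost-effective relative to total hip replacement (THR). This vignette is the
package's own account of its methods: the models, every tunable parameter
that matters, the conventions adopted where the design was genuinely open,
and what the tests do and do not establish.

## 1. The synthetic registry: a stated world

Real joint-registry extracts are confidential, so the package ships a
generator whose defaults *are* the analysis conditions, fixed once:

* **Registry window** 9.75 years (an April-2003-to-December-2012 style
  enrolment span), accrual uniform over the window. Censoring is purely
  administrative: a patient entering at time $e \sim U(0, W)$ is censored at
  $W - e$. An optional exponential loss-to-follow-up rate exists but
  defaults to 0, because registry follow-up of implants is near-complete and
  a purely administrative scheme keeps the ground truth analytic.
* **Covariate mixes.** Six RS manufacturers with the market's skew (the
  most-used device takes 55% of RS records, six together >95%); ASA grades
  1–2 dominate (97%); even head sizes 38–58 mm, centred near 50 mm in men
  and 44 mm in women; ages drawn uniformly within 5-year bands spanning
  35–70 with a mean in the mid-50s, echoing published cohort means (e.g.
  55.5 y for the most-used device). Sex split 74/26 male/female, matching
  the relative sizes of published male/female RS cohorts (18,720 vs 6,646).
* **True hazards.** Each record's revision time is drawn by
  inverse-transform sampling from a parametric hazard chosen by the first
  matching rule on (device class, sex, head size). The default world is
  Weibull with shape 1.3 (mildly increasing hazard, as registry revision
  curves show after the early period) and scales solved so that 10-year
  cumulative revision is **3%** for men with heads ≥ 50 mm, **10%** for men
  below 50 mm, **14%** for women, and **3.5%** for THR. Under the default
  male head-size mix, exactly 60% of male RS records therefore sit in
  subgroups truly within the <5% benchmark — the known truth the benchmark
  classifier is tested against. These values were fixed when the world was
  designed, not adjusted afterwards.
* **Life tables** are Gompertz–Makeham,
  $q_x = 1 - \exp(-(a + b e^{c\,\mathrm{age}}))$, with parameters chosen to
  echo recent UK period tables (male $q_{60} \approx 0.005$); the female
  hazard is about 40% lower. The generator guarantees $q_x$ non-decreasing
  above age 40.

What the generator does **not** emulate: calendar-time trends in device use
or surgical technique, surgeon experience and volume effects, patient
activity levels, correlated covariates (head size is independent of age
given sex), death before revision (downstream analyses treat death as
censoring — the cause-specific convention — so the generator omits it by
default), and real registry counts. A green test therefore establishes that
the machinery is correct on a world with these simplifications, not that the
published estimates are reproduced.

## 2. Time-to-revision models

**Kaplan–Meier** estimates (Greenwood variance, log–log confidence
intervals) are delegated to `survival::survfit` behind the package's own
interface; tests verify them against a hand-rolled product-limit oracle.

**Royston–Parmar flexible parametric models** place a restricted cubic
spline on the log cumulative hazard:
$$\log H(t \mid x) = s(\log t;\ \gamma) + x^\top\beta .$$
With `df = 1` the spline is a straight line and the model is *exactly*
Weibull (shape $\gamma_1$, scale $e^{-\gamma_0/\gamma_1}$) — the equivalence
the test suite checks to $10^{-4}$ in log-likelihood. Internal knots
(`df − 1` of them) sit at equally spaced centiles of the *uncensored* log
event times, boundary knots at their extremes: the conventional default, the
source analysis stating no knot scheme. Because the basis is restricted to
be linear beyond the boundary knots, extrapolation to the lifetime horizon
is log-linear in log-time (Weibull-like tails), which keeps $S(t)$ monotone
and in $(0,1]$ out to 65+ years — a property the suite asserts for every
family. The default `df` for lifetime modelling is 3; sensitivity analyses
re-run with `df` ∈ {1, 2, 4} or a parametric family.

**Parametric families** (Weibull, Gompertz, log-logistic, generalised gamma,
exponential) are fitted by direct maximum likelihood of the right-censored
log-likelihood $\sum_i d_i \log h(t_i) + \log S(t_i)$. The **bathtub**
family is an additive two-Weibull hazard, $h(t) = h_1(t) + h_2(t)$ with
$h_1$ decreasing (shape < 1; early, surgery-related failures) and $h_2$
increasing (shape > 1; late wear-out). The supplement that motivated it
never defines its "bath tub fit", so this additive form is a declared
stand-in, not a reconstruction.

Covariates act proportionally on the cumulative hazard for every family
(for the spline model, additively on $\log H$); age enters linearly, and
device strata are handled by separate fits. Covariates are centred at their
sample means for numerical stability. Optimisation is BFGS on unconstrained
transforms (log shapes/scales; logit for the bathtub's early shape; the
late shape as $1 + e^\theta$) with up to 5 jittered restarts from
Weibull-based initial values before a fit is flagged non-convergent;
non-convergent fits refuse to predict. Standard errors come from the
inverse Hessian at the optimum; Weibull-scale SEs for `df = 1` spline fits
use the delta method (`rp_as_weibull()`).

## 3. Benchmark classification

A subgroup (manufacturer × sex × head size × 5-year age band) is **within
benchmark** when its *point* prediction of 10-year cumulative revision is
strictly below 0.05 — point estimate, not a confidence bound, because the
published subgroup rules are stated as point rules. `dichotomize()`
partitions the registry by those decisions and reports per-manufacturer
proportions.

One design decision deserves emphasis. Independent per-cell fits proved
unstable: a cell with a handful of events cannot support a stable 10-year
extrapolation, and a single unlucky cell can flip a fifth of the cohort
across the 5% line. The driver `benchmark_registry()` therefore fits **one
model per manufacturer × sex with head size as a categorical covariate**
(merging sizes with fewer than `min_events = 5` revisions into the
neighbouring size group) **plus linear age**. The baseline time-shape is
pooled across sizes while each size keeps its own level — the classical
proportional-hazards treatment of a stratum effect — and subgroups whose
size group was merged are flagged as borrowed. This realises the
"sparse subgroups inherit the parent decision, flagged" behaviour through
the parent model's covariates instead of a hard copy.

## 4. The four-state semi-Markov cohort model

States: *successful primary*, *revision surgery* (occupied for exactly one
annual cycle; re-entry allowed), *successful revision*, *dead*. Cycle length
one year; horizons 10 years or lifetime (to age 100, i.e. cycles
$0..100-\mathrm{age}_0$). Discounting at 3.5%/year for both costs and QALYs,
cycle-0 accruals undiscounted.

Conventions, each switchable or documented where the sources are silent:

* **Cycle 0** is the primary operation: the whole cohort incurs prosthesis +
  surgery + inpatient costs (operations are paid for even when the patient
  dies on the table); operative mortality (0.0050) applies; survivors spend
  the year in successful-primary. Background (life-table) mortality starts
  at cycle 1, matching the convention that the death transition "after cycle
  one" comes from national statistics.
* **Within-cycle competing risks**: background death and revision are
  combined as independent, with death acting first; patients dying within a
  cycle accrue no utility and no follow-up cost for that cycle.
* **Revision** moves a patient into the one-cycle revision state (operative
  mortality applies on entry, and again at every re-revision); survivors
  graduate to successful-revision and face a constant annual re-revision
  risk of 0.0518 indefinitely — the single constant the input table
  supplies.
* **Costs** (2014 GBP): prosthesis 2,808 (RS) / 1,575–3,911 (THR bearings),
  surgery 1,738, inpatient 1,628 (RS) / 1,687 (THR), annual follow-up 509
  (RS) / 400 (THR) while in successful-primary (from cycle 1), revision
  surgery 16,794 per operation, post-revision follow-up 400/year. The
  source text also quotes pre-inflation values (16,517 / 394); the shipped
  configuration uses the table values and records both.
* **Utilities**: EQ-5D by sex and age band (40–50, 50–60, 60–70) for the
  successful states and a per-sex revision-cycle utility; boundary bands
  carry outward for ages the table does not cover (lifetime horizons need
  ages beyond 70). No half-cycle correction by default (`half_cycle` flag
  available), matching the lineage of this model structure.
* A per-cycle `utility_bonus` hook implements the scenario in which RS
  carries a short-lived quality-of-life advantage for the first two
  post-surgery years; the source table for its magnitude is not reproduced
  here, so the configuration slot ships as a documented placeholder.

The model is verified against an exhaustive path-enumeration oracle (every
state path over 3–4 cycles, tolerance $10^{-12}$) and a closed-form annuity
in the zero-hazard case ($10^{-10}$).

## 5. Probabilistic sensitivity analysis

Each uncertain input carries a distribution: **Beta** for probabilities and
utilities, **Gamma** (shape/scale) for costs, fixed otherwise. Printed
Beta pairs are used where they reproduce the printed mean to 3 decimal
places; one male 60–70 row does not (its pair implies 0.792 against a
printed 0.762), so the method-of-moments pair wins there, and the printed
Gamma pairs for costs are internally inconsistent under either convention,
so all Gamma parameters are moment-matched:
$\alpha = (\mu/\sigma)^2,\ \theta = \sigma^2/\mu$. `beta_from_moments()`
rejects standard errors too large for a Beta and near-degenerate inputs
(cap on $\alpha + \beta$) rather than silently producing spikes.

Per iteration all uncertain inputs are drawn independently (no correlation
structure is published — a documented limitation), both strategies are run
with **one shared draw for parameters common to both arms** (revision cost,
post-revision follow-up, surgical mortality, utilities), and incremental
cost and QALYs are recorded. The re-revision probability has no published
SE and stays fixed. The CEAC reports, at each willingness-to-pay value
$\lambda$ on a £0–£50,000 grid (£500 steps, £20,000 always included), the
fraction of iterations with $\lambda\,\Delta Q - \Delta C > 0$; exact ties
count as not cost-effective, so as $\lambda \to \infty$ the curve tends to
the fraction of iterations with $\Delta Q > 0$. Runs are seed-reproducible
bit-for-bit.

## 6. Numerical choices and degenerate inputs

* All-censored data refuse a parametric fit (informative error) but give a
  Kaplan–Meier of $S \equiv 1$ with a warning.
* A revision schedule is truncated with a warning if fitted survival
  reaches 0 before the horizon; schedules shorter than the horizon are
  refused.
* `classify_subgroup` with threshold 0 classifies any positive prediction
  as outside the benchmark; ties at the threshold are outside (strict
  inequality).
* ICERs are reported only in the proper quadrant; dominance and
  $\Delta Q = 0$ cases carry labels, never silent infinities.
* The generalised gamma uses the Prentice parameterisation with the
  lognormal limit at $|Q| < 10^{-7}$.

## 7. Known limitations

Synthetic data only (see §1); proportional hazards is assumed for every
covariate; no time-dependent covariates, frailty, interval censoring or
competing-risk cumulative incidence; parameters are sampled independently in
the PSA; the 50-replicate parameter-recovery property is run at reduced
replicate counts for the slower families in the routine suite to keep test
time modest, with the full 50-seed check reserved for the spline/Weibull
acceptance criterion; and the acceptance suite checks internal consistency
of the published input/result tables, not reproduction of the confidential
registry analysis itself.
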