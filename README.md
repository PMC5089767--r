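# hipcea

Lifetime cost-utility analysis of metal-on-metal hip resurfacing (RS) versus
total hip replacement (THR), in the style of registry-based health-economic
evaluations of joint implants.

Hip resurfacing was once promoted for young, active patients, but registry
data show revision (re-operation) rates far above those of conventional THR:
as a class RS revises at roughly 13% by 10 years against under 4–5% for the
common THR bearings, and current NICE guidance asks any implant to stay
**below 5% revision at 10 years**. The economic question is whether the
*best* RS device–patient combinations — large head sizes in younger men —
were ever a cost-effective use of health-service money at a willingness to
pay of £20,000/QALY. `hipcea` packages everything needed to study that
question end-to-end on synthetic registry data with known ground truth.

## What is inside

| Stage | Functions | Method |
|---|---|---|
| Synthetic registry | `cohort_spec()`, `generate_registry()`, `filter_registry()`, `make_life_table()` | Individual patient records (age, sex, ASA grade, manufacturer, head size, device class) with revision times drawn from stated parametric hazards and administrative censoring from staggered accrual over a 9.75-year window |
| Time-to-revision | `kaplan_meier()`, `fit_royston_parmar()`, `fit_parametric()`, `annual_transition_probs()` | Product-limit estimates; Royston–Parmar restricted-cubic-spline models on the log cumulative hazard, log H(t\|x) = s(log t; γ) + xβ; Weibull, Gompertz, log-logistic, generalised gamma and an additive two-Weibull "bathtub" family; conversion of S(t) to annual transition probabilities p_t = (S(t−1) − S(t))/S(t−1) |
| Benchmark | `benchmark_registry()`, `classify_subgroup()`, `dichotomize()` | Predicted 10-year cumulative revision per manufacturer × sex × head-size × age-band subgroup, dichotomised at the <5% NICE benchmark |
| Cohort model | `model_inputs()`, `run_cohort()`, `compare_strategies()` | Four-state semi-Markov model (successful primary → revision surgery → successful revision → dead), annual cycles, 3.5% discounting, 10-year and lifetime (to age 100) horizons; ICERs and dominance |
| PSA | `run_psa()`, `ceac()`, `beta_from_moments()`, `gamma_from_moments()` | 1,000-iteration probabilistic sensitivity analysis with Beta-distributed utilities/probabilities and Gamma-distributed costs; cost-effectiveness acceptability curves |
| Reporting | `run_config()`, `run_pipeline()`, `render_table2()` | One-call orchestration with CSV/JSON artifacts and a formatted results table |

The base-case model inputs (costs in 2014 GBP, EQ-5D utilities by sex and
age band with Beta parameters, surgical mortality 0.0050, annual re-revision
risk 0.0518) ship in `inst/extdata/model_inputs.json` and load with
`load_model_config()`.

## Worked example

The base case compares the within-benchmark pool of the most-used RS device
against the most-used cemented metal-on-polyethylene THR (CeMoP) in men:

```r
library(hipcea)

cfg <- run_config(registry = cohort_spec(n_patients = 10000, seed = 1),
                  family = "weibull", start_ages = 50,
                  psa_n = 200, psa_seed = 1)
res <- run_pipeline(cfg)
render_table2(res)
```

```
                                      quantity    age_50
1                        -- 10-year horizon --
2  Total mean costs £ ( BirminghamHip_within )    10,306
3                 Total mean costs £ ( CeMoP )     8,361
4    Total mean QALYs ( BirminghamHip_within )    6.4267
5                   Total mean QALYs ( CeMoP )    6.4264
6                           Incremental cost £     1,945
7                            Incremental QALYs    0.0003
8                                ICER (£/QALY) 6,655,094
9                     P(cost-effective at WTP)         -
10                      -- Lifetime horizon --
11 Total mean costs £ ( BirminghamHip_within )    16,352
12                Total mean costs £ ( CeMoP )    13,742
13   Total mean QALYs ( BirminghamHip_within )   14.0041
14                  Total mean QALYs ( CeMoP )   13.9988
15                          Incremental cost £     2,610
16                           Incremental QALYs    0.0052
17                               ICER (£/QALY)   499,612
18                    P(cost-effective at WTP)    0.0000
```

Reading the output: resurfacing costs ~£1,900–£2,600 more per patient
(pricier prosthesis, more follow-up, more revisions) while gaining at most a
few thousandths of a QALY, so the incremental cost-effectiveness ratio is
two orders of magnitude above the £20,000/QALY threshold and the
probabilistic sensitivity analysis assigns it essentially zero probability
of being cost-effective — the qualitative conclusion registry-based
evaluations of resurfacing reach.

A command-line interface covers the same stages:

```sh
exec/hipcea simulate --n 20000 --seed 1 --out run/
exec/hipcea run --seed 1 --out run/
```

## Scope notes

The package consumes registry-*style* data; real National Joint Registry
extracts are confidential and no attempt is made to reproduce their exact
counts. Utilities are taken as given (no EQ-5D raw-data analysis), costs are
taken as already inflated to 2014 GBP, and cobalt-monitoring costs are
excluded. See `vignettes/hipcea-methods.Rmd` for the model's assumptions,
conventions and limitations.
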