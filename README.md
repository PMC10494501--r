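# owncontrol

An R package for **own-control (self-controlled) effectiveness analyses
of osteoporosis medications in longitudinal claims data**. It takes raw
claims — persons, drug dispensings, hospital stays — and produces
treatment cohorts, fracture events, period-wise person-time and
incidence rate ratios, together with a synthetic claims generator with
known ground truth so that every stage can be exercised and validated
without access to restricted claims databases such as national health
insurance systems.

## Who it is for

Pharmacoepidemiologists analysing fracture outcomes after initiation of
osteoporosis therapy (denosumab, zoledronic acid, teriparatide, oral
bisphosphonates, raloxifene) in dispensing-claims databases, and
methodologists who want a fully testable reference implementation of the
self-controlled design.

## The design in one paragraph

Each woman serves as her own control. After a new-user index (first
dispensing with a 12-month washout, class-level for oral
bisphosphonates), fracture incidence in risk windows 3–12, 3–18 and
3–24 months after initiation is compared with the incidence in the
first 3 months (the **baseline**, when pharmacological benefit is
assumed minimal), within each treatment cohort. The effect measure is
the incidence rate ratio

IRR = (x₁ / PY₁) / (x₀ / PY₀),

with an exact conditional 95% CI obtained by inverting the
Clopper–Pearson interval for the binomial proportion
p = PY₁·IRR/(PY₁·IRR + PY₀) of window events among all events; rates
carry exact Poisson (Garwood) intervals and are reported per 1000
person-years. Censoring is as-treated (discontinuation, switch, death,
end of data), with intent-to-treat and virtual-exposure (carry-over)
sensitivity modes, a post-discontinuation window, stratified subgroup
runs, and a post hoc analysis of early discontinuers. See the methods
vignette (`vignettes/owncontrol-methods.Rmd`) for every convention and
design choice.

## Worked example

Simulate one cohort of 5,000 denosumab initiators with a vertebral
baseline hazard of 35 per 1000 person-years, a true on-treatment
vertebral IRR of 0.5 and a true post-discontinuation IRR of 2.0, then
run the full as-treated pipeline:

```r
library(owncontrol)
library(dplyr)

hz   <- replace(default_baseline_hazards(), "vertebral", 35)
mult <- function(v) replace(setNames(rep(1, length(hz)), names(hz)), "vertebral", v)

cfg <- sim_config(
  n_women_per_drug = c(denosumab = 5000),
  baseline_hazards = hz,
  on_treatment_irr = mult(0.5),
  post_disc_irr    = mult(2),
  seed = 42
)
ds  <- simulate_claims(cfg)
res <- run_pipeline(ds, study_config(modes = "as_treated"))

res$incidence %>%
  filter(site_group == "vertebral", window %in% c("baseline", "m3_24"))
res$irr %>%
  filter(site_group == "vertebral",
         comparison %in% c("m3_24_vs_baseline", "post_disc_vs_baseline"))
```

Output (abridged):

```
vertebral incidence:
    window events person_years  rate             ci
1 baseline     36       1245.7 28.90 [20.24, 40.01]
2    m3_24     95       5585.1 17.01 [13.76, 20.79]

vertebral IRRs:
             comparison  irr           ci
1     m3_24_vs_baseline 0.59 [0.40, 0.89]
2 post_disc_vs_baseline 2.35 [1.68, 3.38]
```

Reading it: the estimated on-treatment IRR 0.59 (95% CI 0.40–0.89) and
post-discontinuation IRR 2.35 (1.68–3.38) recover the planted 0.5 and
2.0 within their intervals — the baseline rate estimate (28.9 from 36
events) fluctuates around the configured 35, and both ratios share that
denominator. `res$flow`, `res$characteristics`, `res$exposure`,
`res$cells` and `forest_data(res$irr)` expose the remaining output
surfaces; `write_claims()` / `read_claims()` round-trip the claims
tables as CSV, and `write_sim_config()` stores generator settings as
JSON or YAML.

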