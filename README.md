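# phenocad

Rules-based phenotyping of coronary artery disease (CAD) from linked
electronic health records, for epidemiologists and statistical geneticists
working with biobank-style cohorts (a baseline questionnaire linked to
hospital admissions, procedures and death registration).

Ascertaining disease from linked EHR is not a lookup: the same person
appears in several sources, codes differ in specificity, events pre- or
post-date enrolment, and self-report is noisier than coded hospital data.
`phenocad` implements a deterministic hierarchical classifier that assigns
every participant exactly one of six mutually exclusive CAD sub-phenotypes
or one of two control labels, driven entirely by replaceable code lists:

1. **EHR-coded MI** (ICD-10/ICD-9 hospital diagnoses, death-registry
   causes) → `prevalent_MI` / `incident_MI`, split on whether the first
   qualifying event falls on-or-before vs after the enrolment date;
2. **EHR-coded CAD without MI** (diagnoses, OPCS-4 revascularisation
   procedures, death causes, self-reported revascularisation) →
   `prevalent_CAD_noMI` / `incident_CAD_noMI`;
3. **self-reported heart attack** → `sr_MI`;
4. **self-reported angina** → `sr_CAD_noMI`;
5. otherwise control: `never_CAD` (died) / `no_CAD` (alive).

A participant is censored from further classification at the first step
that claims them, all sources are administratively censored at a fixed
date (default 2016-11-01), and code matching is longest-prefix-wins within
a coding system (which is also how exclusions such as "I25 is CAD unless
I252, which is old MI" are expressed).

Because chart-review validation is impossible at biobank scale, the
package ships the two standard fidelity evaluations for such phenotypes —
age/sex-adjusted Cox mortality hazard ratios per phenotype versus CAD-free
controls (`Surv(time, event) ~ case + age + sex`, Efron ties, Schoenfeld
checks reported) and per-SD polygenic risk score (PRS) odds ratios from
logistic models after greedy LD clumping (p < 5×10⁻⁶, r² = 0.2, 250 kb) —
plus a synthetic linked-biobank generator with planted labels, a planted
mortality hazard gradient and a planted PRS effect gradient, so every
stage is testable against ground truth with no restricted data.

## Worked example

Simulate a 50,000-participant linked biobank under the default study
conditions (published label fractions, hazard-ratio gradient 6.66 → 1.31,
PRS odds-ratio gradient 1.50 → 1.08), with adversarial distractor records,
then run the full pipeline:

```r
library(phenocad)

cfg <- simulation_config(n = 50000, seed = 2024, adversarial = TRUE)
sim <- simulate_cohort(cfg)

assign <- run_algorithm(sim$cohort)      # code lists -> 8-way partition
run_log(assign)
#>  step                                         description     n
#>     1                 participants entering the algorithm 50000
#>     2                             EHR-coded MI identified   965
#>     3                               assigned prevalent_MI   489
#>     4                                assigned incident_MI   476
#>     5 EHR/self-report-procedure CAD without MI identified  1899
#>     6                         assigned prevalent_CAD_noMI  1029
#>     7                          assigned incident_CAD_noMI   870
#>     8         assigned sr_MI (self-reported heart attack)   259
#>     9         assigned sr_CAD_noMI (self-reported angina)   582
#>    10                  assigned never_CAD (control, died)  1098
#>    11                    assigned no_CAD (control, alive) 45197

mean(assign$label == sim$ground_truth$true_label)   # classifier vs truth
#> [1] 1
```

Every participant lands on exactly one label (489 + 476 + … + 45197 =
50,000) and the classifier reproduces the planted truth exactly, including
the distractor records. Mortality evaluation against CAD-free controls:

```r
rec <- build_survival_records(assign, sim$cohort)
hazard_table(rec)[, 1:6]
#>                 group     n n_events       hr   ci_low  ci_high
#> 1:       prevalent_MI   489     1128 2.456734 1.707676 3.534361
#> 2:        incident_MI   476     1138 6.887814 5.009325 9.470732
#> 3: prevalent_CAD_noMI  1029     1143 1.725468 1.279017 2.327757
#> 4:  incident_CAD_noMI   870     1158 5.996130 4.606177 7.805513
#> 5:              sr_MI   259     1111 2.027439 1.172563 3.505578
#> 6:        sr_CAD_noMI   582     1116 1.272670 0.798803 2.027646
#> 7:            all_CAD  3705     1304 2.752188 2.367524 3.199350
```

Each 95% CI covers its planted hazard ratio (6.66, 5.65, 2.52, 1.75,
1.77, 1.31) and the estimated gradient preserves the planted ordering:
incident MI carries the highest short-term mortality, self-reported CAD
without MI the lowest. The PRS association gradient:

```r
prs <- build_prs(sim$dosages, sim$variants)   # clump + score + standardize
#> 20 variants after clumping (p < 5e-06, r2 = 0.2, 250 kb)
z <- setNames(prs$z, rownames(sim$dosages))
association_table(z, assign, sim$cohort)
#>                 group n_cases       or    ci_low  ci_high flagged
#> 1:       prevalent_MI     489 1.476636 1.3480106 1.617534   FALSE
#> 2:        incident_MI     476 1.493384 1.3615019 1.638040   FALSE
#> 3: prevalent_CAD_noMI    1029 1.394969 1.3096110 1.485891   FALSE
#> 4:  incident_CAD_noMI     870 1.262238 1.1790548 1.351290   FALSE
#> 5:              sr_MI     259 1.147148 1.0140209 1.297754   FALSE
#> 6:        sr_CAD_noMI     582 1.039347 0.9574851 1.128207   FALSE
#> 7:            all_CAD    3705 1.303009 1.2590660 1.348486   FALSE
```

Clumping retains exactly the 20 planted causal variants, and the per-SD
odds ratios recover the planted gradient endpoints (1.50 strongest for
prevalent MI, 1.08 weakest for self-reported CAD) within their CIs.

Real cohorts enter through `read_cohort()` (five delimited tables, YAML
column-name mapping, rejects report for malformed rows) and
`read_code_list()` / `read_prs_inputs()`; thin command-line wrappers for
simulation, phenotyping and both evaluations live in `inst/scripts/`.

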