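---
title: "Rules-based CAD phenotyping from linked EHR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rules-based CAD phenotyping from linked EHR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocad)
library(data.table)
```

## The problem

Population biobanks link a baseline questionnaire to hospital admission
records (ICD-10/ICD-9 diagnoses, OPCS-4 procedures) and national death
registries. Ascertaining who has coronary artery disease (CAD) — and which
clinically distinct form — from these sources is not a lookup: the same
person may appear in several sources, codes differ in specificity, events
may pre- or post-date enrolment, and self-reported illness is noisier than
coded hospital data. Ad-hoc aggregation of "any CAD code anywhere" mixes
sub-populations with very different prognosis and genetic architecture,
which can dilute association estimates even while inflating case counts.

`phenocad` implements a deterministic, rules-based classifier that assigns
every participant exactly one of eight labels:

| step | evidence | labels |
|------|----------|--------|
| 1 | EHR-coded myocardial infarction (hospital diagnoses, death-registry causes) | `prevalent_MI`, `incident_MI` |
| 2 | EHR-coded CAD without MI (diagnoses, revascularisation procedures, death causes) or self-reported revascularisation | `prevalent_CAD_noMI`, `incident_CAD_noMI` |
| 3 | self-reported heart attack | `sr_MI` |
| 4 | self-reported angina | `sr_CAD_noMI` |
| 5 | nothing above | `never_CAD` (died), `no_CAD` (alive) |

A participant is censored from further classification at the first step
that claims them, so the labels are mutually exclusive and the MI step
dominates: a CAD code before enrolment plus an MI code after enrolment is
`incident_MI`, full stop. Steps split prevalent from incident by comparing
the qualifying event date to the enrolment date. The six disease labels sum
to an aggregated *all-CAD* phenotype; the two control labels form the
CAD-free comparison pool.

Because such phenotypes cannot be validated by chart review at biobank
scale, the package also ships the two standard fidelity evaluations:
age/sex-adjusted Cox mortality gradients and per-SD polygenic risk score
(PRS) association gradients, plus a synthetic linked-biobank generator that
makes every stage testable against planted ground truth.

## Code lists and matching

Phenotypes are operationalized entirely by replaceable code lists
(`cad_code_list()`, CSV-loadable). Each entry is a *prefix* in a coding
system tagged `MI` or `CAD_noMI`. Matching is longest-prefix-wins within a
code system, and an entry never matches a code shorter than itself. This is
also how exclusions are expressed: the shipped defaults tag `I25` as
`CAD_noMI` and `I252` (old MI) as `MI`, so `I252x` codes resolve to MI while
every other `I25x` code resolves to CAD without MI.

```{r}
dft <- default_code_list()
match_code(c("I214", "I259", "I252", "I21"), dft, "ICD10")
```

Two design points are deliberate:

* **Ambiguity guard.** Two entries with the *identical* (system, prefix)
  but different tags are rejected at load time. Cross-tag strict-prefix
  overlaps, by contrast, are legal — they are the exclusion mechanism — and
  are resolved by prefix length, with MI winning hypothetical equal-length
  ties. A guard that also banned strict-prefix overlaps would make the
  `I25`/`I252` exclusion inexpressible.
* **Source eligibility is per tag.** By default MI evidence comes from
  hospital diagnoses (both positions) and death-registry causes (underlying
  and contributing); CAD-without-MI evidence additionally from OPCS-4
  procedures and self-reported revascularisation tokens. Every source x tag
  pair is switchable in `algorithm_config()`, since the balance of evidence
  on whether, say, death-registry CAD codes should case-find is a study
  decision, not a package decision.

## Temporal conventions

* **Censor date.** All hospital and mortality data are truncated at a fixed
  administrative censor date (default 2016-11-01, `default_censor_date()`),
  the last date of guaranteed complete linkage. The censor filter runs
  *before* classification, so a participant whose only qualifying event is
  post-censor is a control.
* **Prevalent vs incident.** An event on or before enrolment is prevalent;
  strictly after, incident. The boundary day defaults to prevalent
  (`on_enrolment_date_is`), configurable, since "prior to enrolment" does
  not by itself fix the boundary.
* **Both-sides resolution.** When one tag has qualifying events on both
  sides of enrolment, the default classifies by the more recent (incident)
  event — whose date and diagnosis are the more certain — dated at the
  *earliest post-enrolment* event. `resolution = "prevalent"` flips this
  globally.
* **Undated evidence.** Self-reported revascularisation procedures carry no
  usable date and are treated as prevalent CAD-without-MI evidence. A
  participant whose only evidence is such a token gets
  `prevalent_CAD_noMI` with an absent qualifying date and source
  `selfreport_proc`; this is the one disease label that may lack a date.
* **Deaths.** Death-registry MI causes after enrolment produce
  `incident_MI` dated at death. Controls split into `never_CAD` /
  `no_CAD` by whether death occurred on or before the censor date.

Rows that fail parsing (bad dates, empty codes, unknown categorical values,
orphan participant ids) are never silently dropped: `read_cohort()` routes
them to a rejects report, and classification operates on the clean tables.
Events with missing dates cannot be placed on the prevalent/incident axis
and are therefore rejected rather than guessed.

## Mortality evaluation

`build_survival_records()` starts follow-up at enrolment for prevalent,
self-reported and control labels and at the qualifying event date for
incident labels, ending at death or the censor date. `cox_fit()` compares
one phenotype with the pooled CAD-free controls under
`Surv(time, event) ~ case + age + sex` (the `survival` package, Efron tie
handling — the standard default; the paper-scale data have heavily tied
day-resolution times). Age enters linearly in years at enrolment, for
incident cases too: age at event is not generally available at baseline,
and the difference is absorbed by the group coefficient. The
proportional-hazards assumption is summarized by the correlation of the
group term's scaled Schoenfeld residuals with time plus the score-test
p-value; it is *reported, never used to auto-reject a fit*, because a
flagged PH violation is a finding about the phenotype, not an estimation
failure. Kaplan-Meier curves (`km_curve()`) use the product-limit
estimator with a log-scale confidence band.

## PRS evaluation

`ld_clump()` implements greedy clumping: repeatedly take the remaining
variant with the smallest p-value (ties by chromosome, position, id) below
the significance filter (default `p < 5e-6`), and remove all remaining
variants on the same chromosome within 250 kb whose squared dosage
correlation with it exceeds 0.2. Correlations are computed on the scored
sample's own dosages — an in-sample LD estimate avoids shipping an external
reference panel; with biobank-scale n the difference is negligible. A
zero-variance dosage column has undefined correlation, which is defined as
0 (it cannot be clumped away) and counted.

`compute_prs()` scores participants as the beta-weighted dosage sum,
imputing missing dosages as twice the column's effect-allele frequency
(the observed column mean), and standardizes to mean 0, SD 1 (enforced to
1e-8). Allele harmonization is exact-match of effect alleles; mismatches
are dropped with a count, not strand-flipped. `logistic_association()`
fits case-vs-control logistic models with age and sex covariates and
reports Wald CIs per SD of score; fits with under two cases or signs of
complete separation are flagged rather than suppressed.

## The synthetic biobank generator

`simulate_cohort()` draws, per participant: an enrolment date uniform on
2006-01-01 to 2010-12-31, an integer age uniform on 40-69, a genotype
vector, a phenotype label, a sex, event dates, and a death date; it then
emits the five linked tables containing, for each label, a record pattern
that the classifier provably maps back to that label. Defaults *are* the
study conditions:

* **Label fractions** are the published sub-phenotype counts over 502,631
  participants (e.g. prevalent MI 4,900/502,631). The two control
  fractions are planted as a combined control mass; the realized
  never/no split is an *outcome* of the simulated mortality, as it is in
  real data.
* **Mortality** is exponential from each participant's follow-up origin
  with rate `baseline x HR(label) x exp(0.08 (age - 54.5) + 0.3 male)`
  per year. The planted HR gradient is the published one: 6.66 (incident
  MI), 5.65 (incident CAD), 2.52 (prevalent MI), 1.77 (self-report MI),
  1.75 (prevalent CAD), 1.31 (self-report CAD). The baseline rate 0.002/yr
  was chosen so control mortality over the ~8-year follow-up lands near
  the published ~2.3%; the age and sex coefficients are ordinary
  epidemiological magnitudes and, because male fraction differs by label
  (70.1% in disease groups, 46.7% in self-reported CAD, 45% in controls),
  they create genuine confounding that the adjusted Cox model must
  remove — mirroring why the real analysis adjusts.
* **Genotypes** are sums of two latent-Gaussian gametes thresholded at
  Hardy-Weinberg frequencies. Within an LD block the latent correlation is
  calibrated through the bivariate-normal orthant probability so that the
  *dosage* correlation matches the target (default r² = 0.5, a tight LD
  block); allele frequencies are drawn per block with small per-variant
  jitter so one calibration holds block-wide. Blocks are spaced beyond the
  clumping window. Each causal block carries a causal variant (smallest
  p-value) plus a correlated sub-threshold decoy, so clumping has real work
  to do and, when correct, recovers exactly the causal set.
* **PRS-phenotype link.** Labels are assigned by a multinomial logit with
  the control class as reference: case label g has weight
  `f_g exp(b_g z - b_g^2/2)` where z is the standardized true score and
  `b_g` the configured per-SD log-odds. Because the case:control odds are
  then exactly `exp(const + b_g z)`, a case-control logistic fit recovers
  the planted slope without rare-disease approximations, while marginal
  fractions stay at `f_g` to first order. The planted OR gradient is
  anchored at the published endpoints — 1.50 (prevalent MI) and 1.08
  (self-reported CAD) — with 1.44 (prevalent CAD, also published) and
  interpolated middle values (1.35, 1.30, 1.20) chosen once to preserve
  the published ordering prevalent > incident > self-report.
* **Adversarial mode** adds distractor records whose resolution is still
  uniquely forced by the hierarchy: cross-tag codes on the other side of
  enrolment, self-reported items for EHR-confirmed cases, MI
  death-registry causes for incident-MI deaths, and background non-CAD
  diagnoses for a random tenth of the cohort. Distractors that would make
  the correct label depend on the configurable both-sides resolution are
  deliberately excluded — ground truth must be config-independent.

What the generator does *not* emulate: hospital episode/spell structure
and transfers, realistic marginal code frequencies, real LD maps, secular
trends in coding, non-exponential hazards, competing risks, or
genotype-mortality confounding (a switch exists for label-mediated effects
only). Passing tests therefore demonstrate that the algorithmic machinery
is correct — the hierarchy, date logic, matching, estimation — not that any
particular real cohort is free of linkage artefacts the generator does not
model.

```{r}
sim <- simulate_cohort(simulation_config(n = 5000, seed = 1,
                                         adversarial = TRUE))
a <- run_algorithm(sim$cohort)
mean(a$label == sim$ground_truth$true_label)
```

## Numerical and testing choices

* Dates are day-precision `Date`s; tables are canonically sorted so cohort
  equality is row-order-free and write/read round-trips are byte-stable.
* Ties in Cox event times: Efron approximation. Degenerate designs (no
  events, empty groups) error with the group named; separation flags the
  estimate instead of failing.
* The test suite checks the classifier against planted truth on
  100,000-participant cohorts in both generator modes, the partition
  invariant on 200 randomized configurations, Cox coverage of the planted
  HR gradient over 10 replicate 100,000-participant cohorts, clumping
  against a brute-force reference on 500 random instances, and the
  published count algebra exactly. These sizes were chosen to give each
  per-group estimate enough events (tens to hundreds) for its 95% CI to be
  informative while a full run stays comfortably interactive. Ordering
  recovery is asserted for planted HR pairs at least 10% apart: the
  1.77/1.75 pair differs by ~1%, which is below Monte-Carlo resolution at
  ~550 and ~2,200 cases respectively and is not a decidable comparison at
  this scale — by design, not by measurement.

## Known limitations

* No primary-care (GP) sources; the algorithm covers hospital, death and
  questionnaire data only, which also keeps it portable across cohorts.
* No SNOMED/Read-code or ICD-10-CM dialects; code lists are UK ICD-10,
  ICD-9, OPCS-4 plus questionnaire tokens.
* PRS inputs are dosage matrices plus summary-statistics CSVs; VCF/BGEN
  parsing is an extension point, not a feature.
* The self-report step cannot distinguish "angina plus a self-reported
  procedure" from procedure-confirmed CAD; the procedure rule (the higher
  step) wins.
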