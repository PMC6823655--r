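---
title: "Measuring biopsychosocial complexity from linked client records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring biopsychosocial complexity from linked client records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpscore)
```

## The measurement problem

Community health centers serve clients whose needs are poorly captured by any
single clinical database: people who are unattached to a regular primary-care
provider, use many poorly coordinated services, live with housing instability,
substance use, mental illness and chronic disease at once, and cycle through
emergency departments. `bpscore` operationalises a *profile* view of this
complexity: rather than one disease-oriented index, a client is described by
nine domain scores, each on a 0--4 scale, derived from routinely collected
records across several source systems:

| Domain | Meaning | Main data elements |
|---|---|---|
| Q1 attachment | lack of a regular care relationship | encounters |
| Q2 service density | spread across many programs, access problems | encounters per program, no-shows |
| Q3 social/environmental | housing, occupation barriers | HoNOS items 11--12, PWD forms, SHX codes |
| Q4 psychosocial | cognitive / behavioral / functional impairment | HoNOS items 1, 4, 5, 8 |
| Q5 relationships | inability to maintain relationships | HoNOS items 9, 11, 12; SHX codes |
| Q6 ADLs | difficulty with daily living without supports | HoNOS items 5, 10, 11, 12; InterRAI-MDS, mobility assessments |
| Q7 medical complexity | chronic/concurrent/uncontrolled conditions | problem list, code lists, HoNOS, BP, BMI, Extended Leave |
| Q8 acute utilization | ED and inpatient burden | CTAS-graded ED visits, admission length of stay |
| Q9 risk of harm | risk to self or others | HoNOS items 1--2, violence alerts, Extended Leave, PHQ-9 |

The unit of computation is the **virtual patient record (VPR)**: all of one
client's rows across the eight source tables, linked by exact client id
(`link_records()`). Utilization tables are restricted to a lookback window
before scoring; the problem list and administrative flags are treated as
current-state information and are never window-filtered.

## The analysis window

The default window is the **18 calendar months** ending at the as-of date,
half-open at the start and inclusive of the as-of date. We compute the
lookback in calendar months rather than a fixed day count because the
domain rules are phrased clinically ("in the past 18 months"); day-of-month
clipping follows the usual calendar convention (one month before March 31 is
February 28/29). Admissions are kept when the *stay* intersects the window;
an admission without a discharge date is open and accrues length of stay up
to the as-of date, on the reasoning that a client currently in hospital is
maximally acute. A recorded discharge after the as-of date is likewise
truncated at the as-of date: days beyond the reference time have not been
observed.

## Domain scoring rules and their interpretation

A handful of reading decisions were genuinely open and are fixed as follows.

**Maximum over listed HoNOS items.** Rules of the form "score = k for item A
and/or item B" are implemented as the maximum over the listed items of the
latest in-window assessment. This is the only reading that produces a single
0--4 value per domain and preserves monotonicity in every item.

**Visits are attended encounters.** Q1 counts *attended* encounters; a
booked appointment the client missed is not a visit. Missed booked
appointments (NSBA) instead feed the Q2 elevation: more than 10 in the
window raise service density by 1. Note one structural consequence: Q1 = 4
(no visits) and Q2 = 4 (seen in more than four programs) are mutually
exclusive, because both are driven by attended encounters. The instrument's
maximal composite is therefore attained by a hypothetical all-4 *vector*,
not by any single realisable record.

**Encounter collapse.** Encounters under a week apart collapse into one
visit (greedy forward scan; a date is dropped when it falls fewer than
`encounter_collapse_days` after the last retained date). This
operationalises "equally dispersed" visits: six encounters in one crisis
week count as one visit, not six.

**Presence triggers dominate.** PWD forms and SHX codes (Q3), SHX codes
(Q5), InterRAI-MDS or mobility assessments (Q6), violence alerts, Extended
Leave or a latest PHQ-9 above 9 (Q9) set their domain to exactly 4,
whatever the HoNOS items say. The scoring cells state these as "score = 4"
conditions and the tests enforce the dominance property.

**Q7 tiers and modifiers.** The medical-complexity base tier is the highest
matching of: 4 (any complex-care code, 6+ diagnoses, SU/MH diagnosis while
on Extended Leave, any neurodegenerative diagnosis, or any HoNOS item at 4);
3 (2+ diagnoses and any SU/MH diagnosis); 2 (any SU/MH diagnosis, not on
Extended Leave); 1 (4+ diagnoses); 0 (otherwise, including an empty problem
list). The tiers are deliberately non-monotone in the raw diagnosis
count; they are implemented literally with highest-tier precedence.
Modifiers then add on top: +1 for more than 5 diagnoses, +0.5 for blood
pressure above 140/90 (systolic above 140 *or* diastolic above 90, latest
observation carrying both readings), and a mutually exclusive BMI increment
(+0.25 above 25, +0.5 above 30, +0.75 above 35, highest applicable). The
result clamps to [0, 4], which is why Q7 alone can be fractional.

**Q8 burden and bins.** The hospitalization complexity score is
`sum(6 - CTAS)` over in-window ED visits plus total admission days: the
simplest formula with the required monotone behaviour (more visits, more
acute visits, longer stays all increase it); it is exposed through the
configuration so alternatives can be plugged in. The rule table's score
bands overlap at their edges; they are resolved deterministically as 0, (0,15),
[15,25), [25,50] and >50, giving higher-score precedence at the anchors 15,
25 and 50.

**Missing data never errors.** A domain with no contributing data scores 0
and has its completeness flag cleared — marginalised clients often lack
assessments, and the tool must still score them, with the completeness
vector making the evidence base explicit. Attachment is the one exception:
having no visit records *is* the attachment signal, so Q1 is always
considered computable.

**Ties.** When two assessments share the latest date, the one with the
higher severity (HoNOS item sum; PHQ-9 total) wins: deterministic and
complexity-preserving.

## The composite

Each Q-score is divided by 4, giving an adjusted value $p_i \in [0,1]$, and
the composite complexity score is the root sum squared

$$\mathrm{CCS} = \sqrt{\sum_{i=1}^{9} p_i^2} \in [0, 3].$$

Weighted composites multiply each $p_i$ by a per-domain factor *inside* the
root sum square: $\mathrm{CCS}_w = \sqrt{\sum_i (w_i p_i)^2}$. With the
default three-tier factors (1.20 for Q3, Q4, Q7; 1.00 for Q1, Q6, Q9; 0.75
for Q2, Q5, Q8) the attainable maximum is
$\sqrt{3(1.2^2 + 1^2 + 0.75^2)} \approx 3.00125$, so the designed 0-to-3
range is preserved up to a 0.04% overshoot; we deliberately do not
re-normalise to exactly 3, and every output carries both the weighted and
the unweighted form, since weights encode one site's values at one time.

Weights come from a staff importance survey: per domain, the fraction of
respondents rating it Important or Very Important. The tier thresholds are
not themselves dictated by the survey design, so they are configuration:
the defaults classify a fraction of at least 0.8 as over-weighted (1.20),
below 0.5 as under-weighted (0.75), and anything between as neutral (1.00);
setting `low = high` recovers a two-tier scheme. The shipped
`survey_example.csv` is a synthetic illustration with 29 respondents whose
derived tiers equal the default weight configuration.

## Population reporting

`population_report()` emits the tabular data behind the standard charts:
composite interval counts over the bands [0,1), [1,2) and [2, max] (the
bands partition the range; the final band absorbs the small weighted
overshoot), per-domain distributions of both the raw Q-score and the
weighted domain score, and the per-client delta between weighted and
unweighted composites. Every table conserves the client count, a property
the tests check on every cohort.

## The synthetic cohort generator

No client-level data are published for this scoring system, so the
generator is the package's test bed. Three built-in archetypes caricature
recognisable CHC subpopulations:

* `low` — youth-clinic-style users: one or two programs, roughly 0.15
  attended encounters per month, mostly zero HoNOS items, under one
  recorded problem on average, rare ED use;
* `high` — the complex-care mandate population: three to six programs,
  0.8 encounters and 0.7 no-shows per month, elevated HoNOS (extra mass on
  the housing/occupation items), ~5 problems with an 85% chance of an
  SU/MH code, frequent mid-acuity ED visits, and material prevalences of
  PWD forms, SHX codes, violence alerts and Extended Leave;
* `frail_senior` — ADL-heavy clients: home-health programs, overridden
  HoNOS items 5 and 10, large problem lists with complex-care and
  neurodegenerative codes, InterRAI-MDS and mobility assessments, and
  long admissions (mean 12 days).

These parameters are illustrative: they were chosen once, on clinical
plausibility, to make the low and high archetypes clearly separable under
the scoring rules — not calibrated to any real cohort's distribution.
Passing tests on these cohorts therefore demonstrates the *mechanics*
(linkage, windowing, rule evaluation, aggregation, conservation), not
agreement with any particular site's case mix. Features of real data the
generator does not emulate include cross-source id mismatches (linkage is
exact-id by design), coding drift and free-text noise, correlated
within-client trajectories over time, and missingness that is informative
rather than random.

Reproducibility: each client draws from a stream seeded by
`(seed, client index)`, so cohorts are byte-identical across runs and
client *i* is unchanged when `n` grows. A client whose draws produce no
records at all receives a single registration-era encounter dated before
the window — keeping the cohort at exactly `n` linkable clients without
touching any score.

## Worked example

```{r example}
window <- analysis_window("2019-01-01", 18)
fixtures <- make_worked_fixtures("2019-01-01")
scores <- composite_cohort(score_cohort(fixtures, window))
scores[, c("client_id", "q1", "q2", "q7", "q9", "ccs_unweighted", "ccs_weighted")]
```

The deterministic fixture clients land exactly on the rule-table anchors:
`no_visits` has Q1 = 4, `five_dispersed_visits` Q1 = 0, `five_programs`
Q2 = 4, `empty_problem_list` Q7 = 0 and `phq9_ten` Q9 = 4.

```{r cohort}
spec <- cohort_spec(200, c(low = 0.45, high = 0.4, frail_senior = 0.15),
                    seed = 42)
report <- population_report(generate_cohort(spec), window)
report$interval_counts
round(report$delta$summary, 3)
```

## Numerical and testing choices

* Problem sizes: unit tests use cohorts of 25--100 clients; the deeper
  property suites use 400--10,000 randomized single-client records against
  an independently written rule-table oracle, 100,000 random q-vectors
  against direct formula evaluation, and a 5,000-client cohort for mixture
  recovery — sizes at which the binomial error bounds are tight while the
  whole suite stays fast.
* All comparisons of the composite against the direct formula use a 1e-12
  tolerance; scores themselves are exact rational arithmetic on quarters
  plus the documented modifier fractions.
* Degenerate inputs: empty bundles score to an empty table; an empty VPR
  scores (4, 0, ..., 0) with only Q1 complete; zero survey respondents for
  any domain is an error (there is no defensible default weight).

## Known limitations

* Exact-id linkage only; clients with different identifiers across source
  systems appear as separate records.
* The Q2 rationale's "simultaneously open referrals" is not separately
  modelled; programs are counted through attended encounters.
* Medication counts and PSW forms appear in source systems as plausible
  medical-complexity inputs but have no scoring rule here and are excluded.
* The shipped code lists are placeholders; deployments must supply the
  locally maintained SU/MH, complex-care and neurodegenerative lists.
* Domain weights reflect one site's staff perceptions; both weighted and
  unweighted outputs are always reported so the weighting is never silently
  load-bearing.
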