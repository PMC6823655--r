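# bpscore

Person-oriented biopsychosocial complexity profiles from linked
multi-source client records.

Community health centers are mandated to serve clients whose complexity no
single database captures: poor attachment to primary care, heavy use of many
poorly coordinated programs, housing instability, substance use and mental
illness, chronic disease, and high acute-care utilization. `bpscore` links a
client's records across primary-care and community mental-health EMR
extracts, ED and acute-care data marts into a **virtual patient record**, and
scores nine complexity domains on a 0–4 scale:

Q1 attachment · Q2 service density · Q3 social/environmental ·
Q4 psychosocial · Q5 relationships · Q6 activities of daily living ·
Q7 medical complexity · Q8 acute utilization · Q9 risk of harm

Each domain score is driven by explicit rule tables over encounters (with
sub-week encounters collapsed into single visits), no-shows with booked
appointments, the latest HoNOS assessment, the problem list categorised
against SU/MH / complex-care / neurodegenerative code lists, blood pressure
and BMI, CTAS-graded ED visits and admission length of stay, PHQ-9 totals,
and administrative flags (PWD forms, SHX codes, InterRAI-MDS and mobility
assessments, violence alerts, Extended Leave). Domain scores combine into a
**composite complexity score** by dividing each Q-score by 4 and taking the
root sum squared,

```
CCS = sqrt( p1² + p2² + … + p9² ),   p_i = Q_i / 4,   CCS ∈ [0, 3]
```

reported both unweighted and weighted (factors w_i multiply p_i inside the
root sum square; the default three-tier weighting is 1.20 for Q3/Q4/Q7, 1.00
for Q1/Q6/Q9, 0.75 for Q2/Q5/Q8, derivable from a staff importance survey
with `derive_weights_from_survey()`). Because no client-level data are
published for this instrument, the package ships a seeded synthetic
multi-source cohort generator (`generate_cohort()`) with low-complexity,
high-complexity and frail-senior archetypes, so the whole pipeline is
testable without patient data.

## Worked example

```r
library(bpscore)

window   <- analysis_window("2019-01-01", 18)   # 18-calendar-month lookback
fixtures <- make_worked_fixtures("2019-01-01")  # deterministic rule-table clients
scores   <- composite_cohort(score_cohort(fixtures, window))
scores[, c("client_id", "q1", "q2", "q7", "q9", "ccs_unweighted", "ccs_weighted")]
#>               client_id q1 q2 q7 q9 ccs_unweighted ccs_weighted
#> 1    empty_problem_list  3  0  0  0           0.75         0.75
#> 2 five_dispersed_visits  0  0  0  0           0.00         0.00
#> 3         five_programs  0  4  0  0           1.00         0.75
#> 4          max_triggers  0  4  4  4           2.83         2.83
#> 5             no_visits  4  0  0  0           1.00         1.00
#> 6              phq9_ten  3  0  0  4           1.25         1.25
```

Reading the anchors: `no_visits` has no encounters in the window, so
attachment is maximal (Q1 = 4) and its composite is sqrt((4/4)²) = 1;
`five_dispersed_visits` has five visits spread a month apart (Q1 = 0, and
nothing else, so CCS = 0); `five_programs` was seen in five distinct
programs (Q2 = 4; the 0.75 under-weight pulls its weighted composite down to
0.75); `phq9_ten` scores Q9 = 4 purely from a latest PHQ-9 of 10.

Population-level reporting on a simulated mixed cohort:

```r
spec   <- cohort_spec(200, c(low = 0.45, high = 0.4, frail_senior = 0.15), seed = 42)
report <- population_report(generate_cohort(spec), window)
report$interval_counts
#>   kind       band      n
#> 1 unweighted 0-1      73
#> 2 unweighted 1-2      37
#> 3 unweighted 2+       90
#> 4 weighted   0-1      73
#> 5 weighted   1-2      33
#> 6 weighted   2+       94
round(report$delta$summary, 3)
#>   mean    min    max
#>  0.017 -0.166  0.232
```

The band counts are the disaggregation used operationally: clients at CCS
0–1 likely do not meet a complex-care mandate, while the 2+ band holds the
highly complex clients the mandate targets. The delta table shows the
(low-to-moderate) impact of the weighting.

A command-line front end is installed with the package
(`exec/bpscore`), with subcommands `score`, `report`, `simulate` and
`weights` over bundle files; see the script header for flags.

## Package layout

- `R/record-model.R` — bundle I/O (JSON / per-table CSV), row-level
  validation, exact-id linkage, analysis-window filtering
- `R/domain-scoring.R` — the nine domain scorers and the hospitalization
  complexity score
- `R/composite.R` — composites, weight configs, survey-derived weighting
- `R/reporting.R` — interval histograms, domain breakdowns, delta report,
  export
- `R/synthetic-data.R` — archetypes, cohort generator, worked fixtures
- `R/cli.R`, `exec/bpscore` — command-line entry points
- `inst/extdata/` — bundle JSON Schema, default weights, synthetic code
  lists, example survey and cohort spec
- `vignettes/complexity-scoring.Rmd` — the methods vignette: rules,
  interpretation decisions, generator design, limitations
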