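# riskdays

Time-area exploitation risk for acoustically tagged migratory fish.

Fish that migrate across the boundaries of spatial management units (SMUs)
experience exploitation risk that changes through the year: a stock can sit
under an intense seasonal fishery one month and in a de facto refuge the
next. `riskdays` turns raw acoustic-telemetry detection records, commercial
catch reports, and bottom dissolved-oxygen (DO) monitoring into a
month-by-SMU map of that risk, and quantifies how seasonal hypoxia modifies
it. The motivating system is a large, seasonally stratified lake whose
central basin develops summer hypoxia and whose demersal whitefish stock is
taken mostly as bycatch, but every stage is generic.

## What it computes

**Detection QC.** False detections are flagged by the minimum-lag criterion:
a detection is kept only if another detection of the same tag on the same
receiver falls within a window (default 3600 s). Tags never detected, or
with a valid-detection span under 35 days, are classified as mortalities and
excluded.

**Monthly residency.** Each tag's days between first and last valid
detection are allocated to month × SMU cells. For consecutive detections at
times t₁ (SMU A) and t₂ (SMU B), the gap is split at its temporal midpoint —
[t₁, m] accrues to A and [m, t₂] to B, with m = (t₁+t₂)/2 — then partitioned
across calendar-month boundaries, so every day of the at-large period is
accounted for without bias toward any SMU ordering. Cell days are averaged
over at-large tag-years into mean days d(m, s) and proportions.

**Catch rank percentiles.** Reported catch (lb) is summed per
year × month × SMU and averaged over years. Among the nonzero cells of the
resulting matrix, each cell gets its cumulative percent rank

&nbsp;&nbsp;&nbsp;&nbsp;P(c) = 100 · #{nonzero cells ≤ c} / #{nonzero cells},

with zeros excluded (they are refuges, not low percentiles).

**Risk days.** The core statistic per month × SMU cell:

&nbsp;&nbsp;&nbsp;&nbsp;risk_days(m, s) = d(m, s) × P(m, s)/100,

a proxy for probability of capture: high residency in a high-catch time-area
scores high; any residency in a zero-catch cell scores zero.

**Hypoxia and movement.** Between-SMU transitions during the stratified
season (June–October) with gaps under 21 days are coded by the district
rank difference (east = +1 per district, latitudinal = 0) and by the DO
category of the origin SMU on the start date (hypoxic < 2.0 mg/L).
Detections at logger-equipped receivers are matched day-wise to bottom-DO
readings, producing four metrics (receiver-minus-tag depth, change in tag
depth, change in DO, moved yes/no) compared between categories with a
Gaussian mixed model (tag random intercepts, Kenward–Roger intervals).

**Synthetic studies.** A seeded agent-based generator builds a complete
study — 8-SMU lake, receiver grid, DO field, migrating fish with hypoxia
avoidance, noisy depth-sensing detections, catch records — with ground truth
for every stage, so the whole pipeline is testable against known answers.

## Worked example

```r
library(riskdays)

b     <- simulate_scenario(scenario_config(), seed = 1)
det   <- filter_false_detections(b$detections)
fates <- classify_tag_fates(det, b$tag_meta)
table(fates$fate)
#> excluded retained
#>       35       64

valid <- det[det$is_valid & det$tag_id %in%
               fates$tag_id[fates$fate == "retained"], ]
summ  <- summarize_residency(allocate_residency(valid, b$receivers))
pmat  <- percentile_ranks(mean_catch_matrix(
  b$catch, year_range = b$config$catch_years, smu_ids = b$smus$table$smu_id))
risk  <- compute_risk_days(summ, pmat, b$smus)
head(risk[order(-risk$risk_days)], 3)
#>    smu_id month mean_days percentile risk_days
#> 1:    1 S    11 19.861815  1.0000000 19.861815
#> 2:    3 S     5 21.360714  0.5932203 12.671610
#> 3:    1 N    11  7.912366  0.9830508  7.778258
```

The top cell says fish spent on average ~19.9 of November's 30 days in the
south unit of district 1, where catch ranks at the 100th percentile — the
spawning-season trap-net overlap. The May district-3 cell is the second
mode: long residency against moderate catch.

```r
tr <- extract_transitions(valid, b$receivers, b$smus, b$do)
rank_diff_quantiles(tr)
#>    initial_condition    n min q25 median q75 max
#> 1:           hypoxic  274  -1   1      1   1   1
#> 2:          normoxic 2290  -1  -1      0   1   1
```

Transitions that started in hypoxic water have a median district rank
difference of +1 (eastward displacement); normoxic-origin moves are
unbiased — the generator's avoidance behaviour, recovered by the analysis.

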