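---
title: "Methods: time-area exploitation risk from acoustic telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-area exploitation risk from acoustic telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(riskdays)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage assumes, which parameters matter and why they
default as they do, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open.

## Detection quality control

Acoustic receivers log occasional spurious pings (code collisions,
environmental noise). The package uses the minimum-lag family of filters:
a detection is valid iff another detection of the same tag on the same
receiver lies within `min_lag_max_s` of it. The window defaults to 3600 s,
the conventional one-hour setting for this filter family; it is a parameter
of `filter_false_detections()` because the appropriate window scales with a
tag's nominal transmission delay. Flagged rows are retained, never dropped,
so the filter is auditable and idempotent.

Fates are classified *after* filtering, on valid detections only: tags never
validly detected are excluded as `never_detected`, and tags whose
first-to-last valid span is under `min_days` (default 35 days) as
`short_span` — short spans are indistinguishable from early mortality or tag
failure. Known harvests cannot be inferred from detections alone, so they
enter through an explicit `fate_override` column in the tag metadata rather
than a heuristic.

Receivers are assigned to SMU polygons by point-in-polygon
(`mgcv::in.out()` plus an explicit edge test). A receiver on a shared
boundary goes to the SMU with the smaller district ordinal (the westward
unit), ties broken by lexicographic `smu_id` — an arbitrary but
deterministic and logged rule; with realistic coordinates it essentially
never fires.

All timestamps are UTC and calendar months are evaluated in UTC by default
(`tz` argument of `allocate_residency()`); a study straddling a local
midnight boundary can pass its own zone.

## Residency allocation

The allocation rule is the heart of the pipeline. For consecutive valid
detections at t₁ in SMU A and t₂ in SMU B, the gap is split at its
*temporal midpoint*: [t₁, (t₁+t₂)/2] accrues to A, the rest to B (all to A
when A = B). Each accrued sub-interval is then cut at calendar-month
boundaries. Two properties follow, and are enforced by tests:

* **Day conservation.** Per tag, allocated days sum exactly (to 1e-6 d) to
  the first-to-last detection span: every at-large day is accounted for,
  with no bias toward any SMU ordering.
* **Oracle equivalence.** The midpoint rule equals assigning every instant
  to the temporally nearest bounding detection. The test suite checks this
  against an independent fine-grid discretization on random tracks.

We deliberately implement "divided evenly" as a midpoint split in time
rather than a post-hoc halving of the gap duration: the two coincide when no
month boundary crosses the gap, but only the midpoint formulation keeps the
month partition and the SMU attribution mutually consistent when one does.

Gaps are split regardless of length here; the 21-day censor belongs to the
transition analysis only, where long gaps would dilute the link between a
move and the conditions that triggered it.

Monthly summaries average over *(tag, year)* pairs at large in each month —
a tag contributes to a month iff its detection history overlaps it, so
months before tagging or after loss contribute nothing. When a tag spans
several years its tag-years enter separately (pooling across years was the
main open alternative; tag-year averaging keeps the denominator honest when
the fleet of active tags changes between years). Proportions rescale mean
days to sum to one within month, absorbing unequal month lengths.

The descriptive seasonal trend models the ordinal SMU code of detections as
a function of month with tag random intercepts and detection-count weights
(changing numbers of fish at large make raw detection counts
non-comparable). Because annual migration is cyclic, the default month terms
are the first two annual harmonics; a `"linear"` form (single slope on a
continuous month index) is available for drift-style analyses and is what
the parameter-recovery test exercises. A singular or failed weighted mixed
fit falls back to an unweighted fixed-effects fit, flagged in the result.

## Catch percentiles and risk days

Catch is summed per year × month × SMU and averaged across the year range,
counting absent year-cells as zero — the mean is over the full period, not
over years with fishing. Percent ranks use ≤-counting over *nonzero* cells
only: `P(c) = #{nonzero ≤ c} / #nonzero`. Ties share the maximal cumulative
rank, so the all-equal case degenerates to 1.0 and the matrix maximum is
always 100%. Zeros are excluded and carry `NA` rather than a small
percentile: a time-area that recorded no catch is a refuge, and
`compute_risk_days()` maps it to exactly zero risk regardless of residency.
Percentiles are kept as fractions internally so that
`risk_days = mean_days × percentile` stays in day units, bounded by month
length.

One caveat discovered while validating against the bundled reported catch
matrix (`lake_erie_catch_matrix()`): the interior percent ranks printed in
the original reporting are not reproducible from the printed means under
any single rank convention (e.g. the second-largest of 59 nonzero cells
prints as 99% where ≤-counting on the printed means gives 58/59 ≈ 98.3%),
which indicates they were computed on a finer unpublished matrix. Only the
100% endpoint and the monotone ordering are therefore treated as checkable,
and the acceptance machinery asserts exactly those.

## Hypoxia-conditioned movement

Bottom DO below 2.0 mg/L is hypoxic, strictly: 2.0 itself is normoxic.
Transitions are consecutive valid detections in *different* SMUs within the
stratified window (June–October, when a thermocline isolates bottom water)
separated by less than 21 days; the censor is strict (< 21) and the window,
threshold and censor are all configurable. Rank difference is destination
minus origin district, so east is positive and latitudinal moves within a
district are zero; reversing a transition negates it. Transitions whose
origin SMU lacks a DO value for the start date are labelled `unknown`,
excluded from category contrasts but counted in a coverage attribute.

The logger analysis works at tag-day resolution: the day's *first*
detection at a logger receiver anchors the day (the printed metric is a
proportion of *days* moved, and first-of-day is the least selective
deterministic anchor). Receiver-minus-tag depth is retained even when
negative — apparent sub-bottom readings are real artifacts of
detection-at-a-distance, lake-level change and ±0.9 m sensor accuracy, and
clamping them would bias the demersal-offset contrast. Successive tag-days
on different receivers contribute depth and DO deltas (later minus earlier,
category from the earlier receiver); same-receiver pairs are non-moves.

Each of the four metrics is compared between categories with a Gaussian
random-intercept model (tag as the grouping factor), least-squares means,
and 95% intervals with Kenward–Roger degrees of freedom. The 0/1 moved
metric is fitted on the same Gaussian contract — a linear probability
model — so all four rows share one inferential treatment. Kenward–Roger is
O(n²)-expensive; above 10,000 observations the function switches to
Satterthwaite and records the method used in the output. A singular tag
variance triggers a flagged fixed-effects fallback, and fully degenerate
input (all values identical) short-circuits to a zero difference with a
[0, 0] interval.

## The synthetic study generator

`simulate_scenario()` builds a complete seeded study whose ground truth is
known at every stage. The defaults are the study conditions, chosen once:

* **Geometry**: four 60 × 80 km districts split at mid-height into south
  and north SMUs (8 units, ordinal-coded west→east); receivers on a 15 km
  systematic grid; DO loggers on all central-basin (districts 2–3)
  receivers. District mean depths 7.4 / 18.5 / 18.5 / 24.4 m — a shallow
  western basin, a mid-depth central basin that can go hypoxic, a deep
  eastern basin that cannot.
* **Fish**: 99 tags released at the district-1 spawning grounds on
  1 November, simulated for 12 months (one full migration cycle). Daily
  district Markov walk: directed toward a monthly target in
  November–May (spawning in district 1, post-spawn return to district 2,
  spring residence in district 3), undirected during the stratified months
  so that any summer eastward shift emerges from hypoxia avoidance alone —
  the eastward step probability from a hypoxic SMU is multiplied by
  (1 + `avoidance_strength`), default 5. Latitudinal N/S moves occur at a
  small daily rate pulled toward each fish's home row (72% south), giving
  rank-zero transitions. Districts change by at most one per day.
* **DO field**: central-basin bottom DO follows a half-sine dip scaled by
  `severity` (default reaches ~1 mg/L) between onset month 7 and end month
  9, plus noise; outer districts stay normoxic; logger readings are the SMU
  value plus 0.3 mg/L sensor noise. `severity = 0` disables hypoxia
  entirely.
* **Detections**: 12 transmissions/day detected with probability 0.5 at the
  SMU receiver nearest the fish's persistent latent position, clustered
  into a within-day bout (real detections arrive minutes apart while a fish
  is in range — without clustering a minimum-lag filter would flag genuine
  detections). Recorded depth adds N(0, 0.9 m) sensor noise. 8% of tags are
  never detected and 21% fall silent before 35 days, so fate classification
  has work to do; 1% of fish-days add an isolated spurious ping at a random
  receiver for the false-detection filter to catch.
* **Catch**: yearly Poisson-lognormal draws (σ = 0.5) around the bundled
  reported mean catch matrix mapped west→east onto the synthetic SMUs, so
  the November district-1-south spike and the structural-zero refuges are
  present by construction.

Space is abstracted to SMU-level positions: no 2-D kinematics, no detection
range model beyond "the nearest receiver of the current SMU", no clock
drift, no receiver outages, no temperature-dependent habitat choice, and
DO is homogeneous within an SMU-day. Passing tests therefore demonstrate
that the *estimators* recover known truth under a faithful abstraction of
the sampling process — not that any field dataset meets these assumptions.

One master seed drives independent per-component streams (DO, tracks,
detections, catch), so components can be regenerated independently and the
whole bundle is reproducible bit-for-bit.

## Verification at scale

The test suite's heavier experiments use these problem sizes, chosen as the
smallest that make the checks statistically meaningful: residency recovery
against ground truth with perfect detection uses 50 fish for 12 months
(maximum error below 1 day/month per SMU); the avoidance-recovery contrast
uses 200 fish with avoidance on versus off (hypoxic-origin median rank
difference positive versus both medians zero); interval calibration of the
category mixed model uses 200 simulated replicates of 50 tags × 2
categories × 10 observations (coverage within 93–97%, estimates unbiased
within two Monte-Carlo standard errors); and the headline phenomenon — the
November district-1-south cell being the largest risk-days cell — is checked
across 100 full pipeline runs on the default scenario.

## Known limitations

* Residency is receiver-based: time between detections in different SMUs is
  split at the midpoint, which is exact on average but cannot see excursions
  between detections.
* The percentile treats catch as a proxy for risk without effort
  standardization across gears; comparing areas fished with different gears
  inherits that assumption, and cells with effort but zero catch are
  indistinguishable from cells never fished.
* The moved/not-moved metric is defined at day resolution and depends on the
  first-of-day anchoring rule; sub-daily movement between logger receivers
  is invisible.
* The mixed models assume Gaussian errors; for the 0/1 moved metric this is
  a linear probability model, adequate for mean contrasts away from the
  {0, 1} boundaries but not a substitute for a logistic model if calibrated
  probabilities are needed.
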