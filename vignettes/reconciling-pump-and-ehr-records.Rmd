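---
title: "Reconciling smart pump records with EHR medication orders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling smart pump records with EHR medication orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpconcord)
```

## The reconciliation problem

Continuous intravenous infusions — vasopressors, narcotics, parenteral
nutrition — are titrated over days, across nursing shifts, with the dose
adjusted by structured order modifications and occasionally by verbal
orders transcribed after the fact. Two independent electronic traces
describe what was administered: the medication administration record
(MAR) that clinicians key into the EHR, and the smart pump record (SPR)
the infusion pump logs each time it is programmed. Neither is authoritative.
MARs are documentation and can lag or misstate what the pump is doing;
pump programming is manual and can diverge from the order. Without a
closed-loop interface there is no key joining an SPR to the order it
executes — only the hand-keyed patient ID, the drug-library medication
name, and the timestamp.

`pumpconcord` implements the full reconciliation pipeline as composable
functions plus a synthetic data generator, so that every stage — and the
pipeline end to end — is testable against a known ground truth.

## Pipeline stages and their rules

### Validity screening

An SPR is usable only if its raw patient-ID string maps to the patient
registry and its medication name is present in the drug library (an
infusion programmed in generic "basic" mode has no medication name).
`screen_sprs()` places each record in one quadrant of the 2×2 validity
table; `quadrant_table()` tabulates counts and percentages.

Invalid IDs are assigned to one of nine failure modes by
`classify_invalid_id()`. The patterns overlap — a string with a dropped
digit may also be one substitution away from another patient's ID — so
classification is a fixed precedence chain, most specific first:

1. empty/missing;
2. exact match to a registered patient-name string;
3. exact match to an encounter ID;
4. exact match to a retired (merged-chart) ID;
5. an 8-digit string parseable as `YYYYMMDD` or `MMDDYYYY` whose year
   falls outside the plausible birth-year range (1965–2014 by default);
6. contains non-digit characters;
7. fewer digits than a registry ID (missing digits);
8. more digits (extra digits);
9. substitution distance 1 from some valid ID (typographical);
10. otherwise a random number.

Two choices here are deliberately narrower than the label suggests. The
date test accepts only 8-digit strings: registry IDs are 7 digits wide, so
6–7 digit date-like strings would collide with the missing-digits
category and make the taxonomy ambiguous. Typo detection uses
substitution-only distance 1, keeping it disjoint from the two
length-based categories. With these conventions every category is
recoverable: `corrupt_patient_id()` (the generator's corruption operator)
rejection-samples until its output classifies back to the intended
category, and the test suite round-trips 1,000 random corruptions at
100%.

### Alignment

Only `started`/`restarted` pump records are analyzed — they mark the
initiation of delivery, the moment an erroneous infusion could be
intercepted. Records are grouped by (patient, medication); each SPR links
to the order with the smallest gap between the SPR timestamp and the
order's nearest *activity* event (placement, modification, free-text
communication, or MAR documentation), provided that gap is within 24
hours. The window is symmetric around the SPR timestamp; a look-back-only
variant would differ only for records documented before any order
activity, and symmetry matches the grace-window logic below. Ties break
to the earlier-initiated order, then lexicographic order ID, so linkage
is a deterministic function of the inputs.

MAR entries carry no order key in this data model, so within a group the
active prescription and event-block boundaries are taken from the
chronologically merged order events of all the group's orders, each block
attributed to the order owning its opening event. For orders of the same
patient and medication separated by more than 48 hours (which the
generator guarantees and ICU practice approximates), this is exactly
per-order semantics.

At equal timestamps order events sort before MARs, and MARs before SPRs:
a modification documented at the same minute as an administration
legitimizes it, which is the conservative reading (fewer false
discrepancies).

### Discrepancy detection and the grace window

For each MAR and each linked SPR, the reference is the dose/rate of the
latest order event at or before the administration time. Dose equality is
relative, tolerance `1e-6`: these are machine-entered values, not
measurements, and the tolerance only needs to absorb floating-point and
serialization noise (it is configurable for data that round-trips through
coarser formats).

A mismatching administration is then tested against the *first*
value-matching order event after it, looking ahead at most 24 hours (the
linkage window):

* lead ≤ 30 min — a verbal order transcribed within the institutional
  window; the administration is legitimized, no discrepancy;
* lead > 30 min — the dose was right but the order trailed the
  administration: a *documentation* discrepancy, magnitude 0%, flagged
  `documentation_only`;
* no matching event — a dose discrepancy against the active
  prescription, with signed magnitude
  `(administered − prescribed)/prescribed × 100`.

The first-match rule and the 24-hour look-ahead horizon are the package's
determinism choices; the 30-minute constant is the institutional policy
the method encodes, exposed as `grace_minutes`. Widening the grace window
can only convert documentation discrepancies into matches, never create
new discrepancies — the suite asserts this monotonicity on generated
cohorts. An administration preceding every order event is referenced
against the first order value and flagged `preceded_orders`.

Magnitudes are binned into the ten reporting intervals
`<−50%, [−50%,−20%), [−20%,−10%), [−10%,0%), 0%, (0%,10%], (10%,20%],
(20%,50%], (50%,100%], >100%`, which partition the line exactly; the 0%
bin holds precisely the documentation discrepancies, and `>100%` holds
substantial overdoses. Rates are rounded half-up to one decimal and
quadrant percentages to two, matching clinical reporting convention
(base R `round()` rounds half to even, hence `round_half_up()`).

### Event blocks and concordance

Order timelines are segmented at order initiations, modifications, and
audits (free-text communications set no boundary: they carry no dose).
An inter-event interval with no member administration emits no block — a
block's category is defined by its members' discrepancy flags, so an
empty interval has no defined category. Orders enter the concordance
analysis only when both sources document them (≥ 1 MAR and ≥ 1 linked
SPR). Each analysis block is classified `none` / `MAR_only` / `SPR_only`
/ `both`, and Cohen's kappa is computed from the 2×2 agreement counts:
κ = (pₒ − pₑ)/(1 − pₑ), pₒ = (both + none)/N, pₑ from the marginal
products. Degenerate marginals (pₑ = 1, e.g. every block discrepant in
both sources) make kappa undefined; `cohen_kappa()` returns `NA` with a
`degenerate` attribute rather than ±1 or 0. Reported kappas are rounded
to two decimals; full precision is kept internally.

Discrepancies are counted once per source throughout: a MAR and an SPR
documenting the same physical administration contribute one MAR and one
SPR discrepancy, because the two sources are being compared as detectors.

## What the generator emulates — and what it does not

`generate_cohort()` draws, per patient, a Poisson number of orders
assigned to the nine study medications with an ICU-like order mix, then
builds each order as an initiation followed by Poisson-many dose
modifications at 4–16 hour spacings, with multiplicative titration steps
(0.8×, 1.25×, 1.5× — never 1, so every modification changes the dose).
MARs are documented every 4 h and pump restarts every 2 h within each
block, at minute resolution in a single timezone, stopping 45 minutes
before a block boundary so a grace window never straddles one. Orders for
the same patient and medication are separated by > 48 h, making linkage
identifiable. One terminal `completed` pump record per order exercises
the state filter.

Corruption channels, all seeded and all recorded in the ledger:
per-record invalid patient IDs (nine categories, weights shaped like the
observed failure-mode mix) and missing medication names; per-block MAR,
SPR, or joint dose corruption with magnitudes drawn by default from a
mixture shaped like the observed reporting-bin distribution (the 0% bin
excluded — exact-dose discrepancies arise from the late-order channel
instead); and late order placement, which moves a block's opening order
event past its first administration by 31–120 minutes while leaving all
values equal. The generator consumes all stream-structure randomness
before any injection randomness, so regenerating with an all-zero mixture
at the same seed reproduces the base streams exactly and corruption can
be audited by diffing — this is how the conservation tests work. Ledger
magnitudes are stored as the same floating-point expression the detector
computes, so recovery is asserted to `1e-9` relative and observed at
machine precision.

The generator does *not* model pharmacokinetic plausibility of titration
trajectories, nurse shift structure, pump alarms and pauses as clinical
events, concurrent same-medication orders, or unit conversion (each
medication has one fixed dose unit; the method is unit-free arithmetic).
Passing tests therefore demonstrate correctness of the *rules* on streams
with realistic shape and timing, not robustness to every messiness of
production EHR extracts — most importantly, real MARs can carry order
keys, dialect rounding, and duplicated documentation that this model
deliberately leaves out of scope.

## Simulation sizes and numerical tolerances in the test suite

The suite exercises the pipeline at sizes chosen to make the statistics
sharp while keeping a full run in minutes: parameter-recovery runs use
cohorts of 25–80 patients; the 3%-injection recovery check uses 385
patients (≈ 1,000 orders); the kappa-independence property uses ≈ 2,900
analysis blocks with a 3/√N Monte-Carlo bound; the kappa oracle check
enumerates all 2×2 tables with N ≤ 30 and 20,000 seeded random tables
with N ≤ 200 against an expansion-based agreement computation at
`1e-12`. All stochastic tests fix their seeds. Published-table
percentage arithmetic is asserted to the printed precision (one unit in
the last printed decimal).

## Known limitations

* Free-text communication orders count as linkage activity but their
  dose content is not parsed; a dose change conveyed only in free text
  will surface as a (true-to-the-data) discrepancy.
* Pump records that fail validity screening are excluded, not rescued by
  fuzzy matching; planted dose errors on such records are unrecoverable
  by design, and the ledger evaluation counts them against sensitivity.
* Error causes (misprogramming vs. missed modification) and non-dose
  error types (e.g. premature stops) are out of scope; the pipeline
  detects and quantifies dose/rate discrepancies only.
* The block-attribution convention for MARs assumes non-overlapping
  same-medication orders; overlapping infusions of one medication in one
  patient would need an order-keyed MAR extract.
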