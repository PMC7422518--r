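---
title: "Identifying incident chronic dialysis patients from administrative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying incident chronic dialysis patients from administrative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialcohort)
```

## The problem

End-stage kidney disease patients on chronic dialysis interact with the
health system constantly — typically three hemodialysis sessions a week, or
a monthly-billed peritoneal dialysis regimen — so they are densely
represented in administrative billing data even where no dialysis registry
exists. The hard part of building a cohort from those data is not *finding*
dialysis events but deciding **who is an incident chronic case**: separating
patients who newly and durably started dialysis during the study window from
(i) prevalent patients who merely continued, (ii) patients dialyzed
transiently after acute kidney injury (AKI), (iii) short courses ended by
early death, recovery or relocation, (iv) visiting patients resident
elsewhere, and (v) admissions that only *prepared* for dialysis by creating
the vascular or peritoneal access.

`dialcohort` implements a rule-based case definition over two sources —
hospital discharge records (HDR) and ambulatory specialty visits (ASV) —
with a validation module (sensitivity, positive predictive value, percentage
agreement against a registry) and a synthetic-data generator that makes the
whole pipeline testable without any real health data.

## The procedure and its assumptions

### Index events

Three inclusion routes produce candidate index events (`hdr_index_candidates()`,
`asv_index_candidates()`):

* a dialysis-related **diagnosis** on an in-period admission (ESKD `585.6`,
  dialysis status `V45.1x`, dialysis encounter `V56.0`–`V56.8`), dated at the
  admission date;
* a dialysis **procedure** (`39.95`, `54.98`) dated inside the period;
  within one record the procedure route has absolute precedence and the
  earliest procedure date is used;
* an outpatient **dialysis service** (`39.95.1`–`39.95.9`, `54.98.1/.2`).

The index date is the earliest candidate (`assign_index_date()`). Date ties
are broken by source (`HDR_PROC` > `ASV` > `HDR_DX`), then modality
(HD > PD); this cross-source extension of the within-record procedure
precedence is our own determinism rule — any choice would do
epidemiologically, but the output must not depend on row order.

An admission whose only dialysis-related procedures are access creation
(`39.27`, `39.29`, `54.93`) is assumed to precede dialysis initiation and
never qualifies through a diagnosis. The stated rule attaches this guard to
the ESKD diagnosis; we apply it to every diagnosis route
(`fistula_exclusion_scope = "all_dx"`, the default) because an
access-creation admission signals that dialysis has not started regardless
of which dialysis diagnosis co-occurs. Setting
`fistula_exclusion_scope = "eskd_only"` restores the narrower reading.

### Exclusions

Exclusions run in a fixed order a→d so the per-patient audit trail
(`attr(cohort, "audit")`) is reproducible; since the criteria are
conjunctive, the cohort itself does not depend on the order.

* **(a) residence** — any in-period record with a present region different
  from the target region. A missing region is "unknown", never "different":
  administrative extracts drop residence often enough that treating absence
  as evidence would bias against complete-looking patients.
* **(b) prevalence** — any treatment in the closed window
  `[index − 365 d, index − 1 d]`. The index day itself is not "before".
* **(c) chronicity** — let `gap` be the days from the index to the last
  treatment within `(index, index + 365 d]` (0 if none). The patient is kept
  when `gap ≥ 30` days, or `gap ≥ 90` when dialysis followed AKI (a `584.x`
  diagnosis in the index admission or in an admission `0 ≤ index − adm < 90`
  days before). The unconventional 30-day floor (against the usual 90) is
  the definition's deliberate choice: 30–90-day patients consume real
  dialysis resources and can reach renal outcomes in that window.
* **(d) in-hospital death** at the index admission — only the variant that
  trusts inpatient treatment data (`ALG2`) applies it; outpatient-indexed
  patients are never tested against it.

"Treatments" means actual dialysis delivery: outpatient sessions/summaries
always, inpatient `39.95`/`54.98` procedures additionally under `ALG2`
(`build_timeline()`). Diagnosis codes never count as treatments — the
prevalence wording asks for a hemodialysis or peritoneal dialysis *found*,
not asserted, so a dialysis-status diagnosis in the lookback year does not
make a patient prevalent even under `ALG2`.

### Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `chronicity_days_non_aki` | 30 | days | chronicity floor; 60/90 used as sensitivity analyses |
| `chronicity_days_aki` | max(90, non-AKI) | days | AKI courses must prove durability longer; keeping the 90-day floor under the 60/90 variants preserves threshold monotonicity (raising the non-AKI threshold can only shrink the cohort) |
| `prevalence_lookback_days` | 365 | days | one year free of treatments defines "incident" |
| `followup_days` | 365 | days | horizon in which chronicity must be demonstrated |
| `code_system` | ICD9 | — | `ICD10` switches diagnosis classification to the crosswalk images; procedure/service codes stay ICD-9-CM, as in the Italian sources |

The input tables must cover the index period ± one year of dialysis events.
Coverage cannot be inferred from the absence of records, so
`run_algorithm(data_window = )` lets the caller declare the span their
extracts cover and errors naming any missing span; without the declaration
the requirement is the caller's responsibility. Records outside
`[start − lookback, end + followup]` are discarded up front, which makes the
no-influence window property literally true by construction.

### Numerical and degenerate-input choices

* All dates are day-granular `Date`s; every window above is defined by
  integer day arithmetic, and each boundary (364/365/366-day lookback,
  29/30-day gap, 89/90-day AKI gap and AKI-admission lag) is pinned by a
  dedicated test.
* Percentages are reported to one decimal, rounding halves away from zero
  (`6.25 → 6.3`); a 1e-9 epsilon guards exact halves against binary
  representation. Raw ratios are kept alongside rounded values in
  `accuracy_report()`. Undefined ratios (zero denominators) are `NA`, never 0.
* Duplicate records are dropped before processing; duplicate registry
  `(patient, inception)` pairs are constructor errors, but multiple
  inceptions per patient are legal (post-transplant re-entries) and any
  index-year inception makes a cohort entry a true positive.
* A cohort entry with no modality evidence at all defaults to `"HD"` with a
  warning (hemodialysis is the overwhelmingly more common modality).
* A missing per-procedure date falls back to the admission date, since
  discharge abstracts guarantee a date only for the main intervention.

## The validation model

`classify_cases()` cross-classifies cohort against registry by patient and
calendar year of the registry inception date: true positive (inception in
the index year), different-year match, not in registry, and missed
(index-year registry case absent from the cohort). Year matching is by
calendar year, not a ± window, because that is how the reference tables
categorize disagreement and how year-boundary discordance manifests. The
three metrics are `sensitivity = TP/(TP+missed)`, `PPV = TP/N`,
`agreement = TP/(N+missed)` (×100). The agreement denominator — identified
plus missed, not the union of the two sources — was selected by verifying
candidate formulas against all seven published variant columns; only this
one reproduces every printed value. Specificity and NPV are impossible:
the registry contains no dialysis-free subjects.

## What the generator emulates — and what it does not

`simulate_population()` writes the three tables plus a truth table under a
single seed (same seed, byte-identical output; the caller's RNG stream is
left untouched). Archetypes and their construction:

* **chronic HD**: index uniform in the period, sessions 3×/week (jittered
  within each 7-day block, first session pinned to the index date) for a
  full follow-up year; with probability 0.3 a "kickoff" admission carries
  `585.6` plus a dialysis procedure on the index date, reflecting the share
  of starts that happen in hospital.
* **chronic PD**: one summary record per calendar month dated the 1st.
* **prevalent**: sessions begin 30–365 days before the period and continue
  into it.
* **transient AKI**: an admission with `584.9` and an inpatient dialysis
  procedure, then sessions spanning a uniform 0–89-day gap. The
  AKI-admission-to-dialysis delay has no published distribution; the uniform
  choice is arbitrary and configurable in spirit (the archetype only needs
  its span to stay under 90 days).
* **transient short**: outpatient sessions spanning a uniform 0–29-day gap.
* **non-resident guest**: chronic pattern, all records carrying another
  region.
* **in-hospital death**: a prolonged (40–60 day) admission with repeated
  inpatient dialysis ending in death. The prolonged stay is deliberate: a
  short terminal admission would already fail the chronicity criterion, and
  the death criterion would never actually fire; this construction makes
  `ALG1` exclude the patient as non-chronic but `ALG2` specifically for the
  in-hospital death.
* **fistula-only**: an admission with `585.6` and only access-creation
  procedures.

The registry holds exactly the patients a nephrologist would enter: chronic
starters — never transients, guests, or deaths at initiation. Discordance
injectors then perturb the clean world one mechanism at a time:
`p_year_boundary` moves a starter's registry inception into late December of
the prior year while their administrative events start in January (the
patient becomes a different-year match; note this leaves sensitivity at
exactly 100% because the patient also leaves the index-year registry
denominator — the damage appears in PPV and agreement);
`p_residence_miscode` flips one in-period record's region (the algorithm
must drop the patient, who becomes a missed registry case);
`p_registry_only_short` spawns registry entries whose administrative history
spans under 30 days (correctly refused, hence missed). `expected_counts()`
turns the truth table into the exact cross-classification a correct
implementation must produce, which is the package's core recovery test.

What the generator does **not** model: real incidence rates or regional case
mix, seasonality, transplant re-entries, modality switches, alternating
dialysis/conservative trajectories, and coding noise beyond the three
mechanisms above. A green recovery test therefore establishes that the
implementation applies the stated rules exactly — not that the rules achieve
any particular accuracy on real data, where the published validation found
sensitivity near 91% and PPV near 84% for the best variant.

## Quickstart: the three-command chain

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dialcohort.R", package = "dialcohort"))')
Rscript $CLI simulate --seed 7 --outdir work
Rscript $CLI identify --hdr work/hdr.csv --asv work/asv.csv \
        --out work/cohort.csv --audit work/audit.csv
Rscript $CLI validate --cohort work/cohort.csv --registry work/registry.csv \
        --index-year 2014 --out work/metrics.csv
Rscript $CLI convert-codes 585.6 V56.8
```

Configuration files are plain `key = value` text; flags override file keys;
`identify` and `simulate` can write a JSON run manifest (timestamp, package
version, resolved configuration, input digests) for reproducibility audits.

## Known limitations

* A single configured index period; multi-year incident searches (which
  would dilute year-boundary discordance) are out of scope.
* Residence is taken from the event records themselves, mirroring the
  validated setting where a population registry was unavailable; with a
  proper residence registry criterion (a) should use it instead.
* The 60/90-day threshold variants are implemented as a uniform tightening
  with the AKI floor kept at 90 days; published variant cohort sizes are not
  monotone in the threshold, suggesting the original parameterization
  differed in some unstated way, so no test asserts the variants' raw counts.
* Intention-to-treat modality (the registry's convention) is approximated by
  first-observed modality.
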