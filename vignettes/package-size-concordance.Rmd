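---
title: "Auditing antibiotic package sizes against guideline treatment courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing antibiotic package sizes against guideline treatment courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coursefit)
```

## The problem

Oral antibiotics are mostly dispensed as manufacturer prepacked boxes, while
prescribing guidelines recommend a course defined by dose, dosing frequency
and duration. When the two do not line up, a patient who completes the
recommended course is left with surplus tablets. Leftover antibiotics feed
self-medication, pharmaceutical waste and — through both — antimicrobial
resistance, so package–guideline concordance is a stewardship quantity worth
measuring. `coursefit` implements that measurement as a reproducible
pipeline: registry ingest, course fitting, and stratified aggregation.

## The model

For a package holding $n$ units of a formulation with strength $s$, and a
regimen prescribing dose $d$ given $f$ times daily for $t$ days, the number
of units consumed is

$$ U(d, t) = u(d) \cdot f \cdot t, \qquad
   u(d) = \min\{k/2 : (k/2)\, s = d,\ k \in \mathbb{N}\}, $$

where $u(d)$, the units per administration, may be half-integral only for
formulations explicitly flagged as divisible (scored tablets); for all
others $u(d)$ must be a whole number, and a dose that is not an exact
multiple is *not constructible*. The minimal number of packages and the
leftover are then

$$ P = \lceil U / n \rceil, \qquad E = P\,n - U . $$

A (package, regimen) pair is **matched** when $E = 0$, i.e. the course
drains a whole number of boxes exactly. Adherence is fixed at 100%: the
audit measures the geometry of packaging, not behaviour.

Guidelines often print flexibility: a dose range ("250–500 mg") or a
duration interval ("10–14 days"). Both are resolved in the patient's and
payer's favour, by *leftover minimization*: the engine enumerates every
candidate dose and every whole day in the closed duration interval and
keeps the combination minimizing $E$, breaking ties by fewer packages, then
shortest duration (configurable), then smaller dose. Enumerating all whole
days — not just interval endpoints — matters: a 24-unit box at 2×1000 mg
over 10–14 days is drained exactly by a 12-day course, which endpoint-only
evaluation would miss.

A pair is evaluated at all only when the guideline names the substance
(after synonym canonicalization), uses the same unit system — milligrams
and international units are never interconverted, so an IU-denominated
penicillin V pack is simply not comparable with an mg-denominated regimen —
and at least one candidate dose is constructible. Pairs failing these gates
are reported as inapplicable ("n/a") and excluded from both the matched and
mismatched tallies (a switch can count them as mismatched for sensitivity
analysis).

## Exact arithmetic

All course arithmetic is carried in *half-units* (integers; one tablet = 2
half-units). Ceiling division and the leftover are computed with integer
operations and converted to units only at the API boundary, so a test such
as `extra_units == 0` can never be disturbed by floating-point drift, and
half-tablet leftovers (e.g. 0.5 tablet-equivalents for a 750 mg dose built
from scored 500 mg tablets) are represented exactly.

## Registry ingest

`parse_registry()` reads a registry CSV (one row per product, semicolon-
separated package sizes), collecting malformed rows instead of dropping
them. `filter_registry()` applies the inclusion workflow in a fixed,
documented order — ATC prefix (default `J01`), marketing status, oral form,
manufacturer-prespecified dosage unit, paediatric flag — logging each
excluded entry under the first rule it fails, so flowchart-style box counts
are well defined. `expand_and_merge()` explodes package sizes and collapses
products sharing (canonical substance, strength, unit, size) irrespective
of trade name; when merged products disagree on scoring, divisibility is
the OR (if any marketed product is scored, splitting is possible).
`annotate_reimbursement()` joins a payer list and stamps each package
`current`, `former` or `none`.

Two ingest decisions deserve a note. The size threshold ("30 or more units
excluded") is a configuration knob (`max_units_exclusive`), unset by
default, because the reference tables themselves retain 30- and 32-unit
packages; hard-coding the cut would make the shipped dataset irreproducible.
And paediatric status is an explicit data column, not a name heuristic —
weight-based dosing is excluded as a data property, never guessed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fit_policy(duration_tiebreak)` | `"shortest"` | among equal-leftover, equal-package fits, prefer the shorter course |
| `fit_policy(dose_candidates)` | `"endpoints"` | dose ranges evaluate printed endpoints; `"all_constructible"` adds every constructible intermediate dose |
| `fit_policy(adherence)` | `1.0` (fixed) | full-adherence assumption; asserted, not tunable |
| `filter_config(atc_prefix)` | `"J01"` | systemic antibacterials |
| `filter_config(max_units_exclusive)` | unset | optional package-size cut (units) |
| `summarize_matches(count_na_as_mismatch)` | `FALSE` | sensitivity switch for n/a pairs |

The endpoint default for dose ranges follows how flexible doses are printed
and audited in practice; the reference tables are consistent with endpoint
choice throughout. The tie-break order below leftover (packages → duration
→ dose) is this package's own convention: published tables annotate only
the chosen duration and contain no cell that discriminates the order.

## The packaged reference dataset

`paper_fixture()` ships a published national audit as plain-text data: 83
packages across 20 substances (the sore-throat and urinary-tract-infection
tables plus the label-only substances linezolid, moxifloxacin,
telithromycin and doxycycline), 55 regimens from the national guideline
body (ISKRA), NICE, IDSA and product labels (SmPC), the reimbursement
snapshot flags, and an expected-values file encoding every printed table
cell — (minimal packages, extra units, annotated duration) or n/a — keyed
by package, source and regimen text. Table reproduction is therefore a
table-driven test, not a pile of hand-written assertions.

Three aspects of the fixture are reconstructed *data*, flagged here rather
than buried in logic:

* **Divisibility** is not stated by the source tables; the flags are
  reverse-engineered from their n/a pattern (levofloxacin 500 mg,
  penicillin V and clindamycin 600 mg tablets scored; azithromycin 1000 mg,
  clarithromycin 500 mg, cephalexin 1000 mg not; the two amoxicillin
  1000 mg products differ, one scored and one not).
* The **extended-release** ciprofloxacin regimen is marked
  `modified_release`, making it inapplicable to immediate-release registry
  solids — that is how its printed n/a against constructible 4×250 mg
  arithmetic is honoured.
* The mg-denominated penicillin V comparator regimens are assigned to
  their guideline bodies on clinical-plausibility grounds; all are
  inapplicable (unit mismatch), so the assignment does not affect any
  count.

Counts the shipped dataset deliberately does **not** reproduce: the
original 295-product database and its reduction to 94 packages (the
national database is not printed and not retrievable offline); the
source's IDSA urinary-tract "15 mismatched" (the printed tables imply 13)
and its national combination total of 104 (the printed rows enumerate 106
applicable combinations). The package reports what the tables imply; only
quantities that are internally consistent with the printed tables are
asserted in the acceptance suite.

## Synthetic data

`generate_synthetic()` emulates the audited world at its stated scale — 23
substances, a handful of marketed package variants each (~90 packages),
strengths from the common oral set, sizes up to 30 units, scored tablets
about half the time — and plants ground truth per regimen: for a planted
match, units per dose, frequency, package count and duration are chosen so
the course consumes whole packages (a modular-arithmetic construction,
independent of the fitting engine); for a planted mismatch, the course is
constructed never to land on a package boundary for any candidate dose or
day. The planted fraction defaults to 0.5. Generation is a pure function
of the spec (seed included) and restores the caller's RNG state.

What a green synthetic test establishes: the engine's classification agrees
with arithmetic ground truth across random worlds. What it does not: that
real registries are clean (synthetic rows are well-formed), or anything
about how often real packages match — that is what the reference dataset
measures.

## Degenerate inputs and edge behaviour

Empty registries and empty regimen sets produce valid empty reports.
A substance present on only one side simply contributes no rows. Dose
construction caps nothing: a one-unit package simply costs one package per
ceiling step (8 packages for 7.5 tablets). Single-unit packages make
planted mismatches infeasible (every whole-unit course drains whole
packages), which the generator reports as an error rather than silently
bending the spec.

## Known limitations

* One package size per fit: completing a course by mixing different box
  sizes of the same product is out of scope, as in the audited tables.
* Splitting is exact halves only; no quarter-tablets, no combining
  different strengths in one administration.
* No pharmacokinetic equivalence of salts/esters and no mg↔IU conversion.
* Partial adherence is not modelled; the policy field exists but is
  asserted at 1.0.
* The reimbursement snapshot is a static fixture column, not a live payer
  query.
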