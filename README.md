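# coursefit

Do marketed antibiotic package sizes let a prescriber follow the guideline?

`coursefit` is an R package for pharmacoepidemiology / antimicrobial
stewardship audits of **package-size vs. treatment-course concordance**.
Given a drug-registry extract (one row per marketed oral antibiotic
product) and a set of guideline regimens (dose × frequency × duration), it
computes, for every applicable (package, regimen) pair, the minimal number
of identical packages needed to complete the course at full adherence and
the leftover units, then aggregates matched/mismatched counts by guideline
source, indication and reimbursement status. Leftover units are the
stewardship signal: every mismatched pair is surplus antibiotic sitting in
a household.

## The statistic

For a package of $n$ units of strength $s$ and a regimen $(d, f, t)$ (dose,
doses/day, days):

- units per administration $u(d) = k/2$, the smallest half-integer with
  $(k/2)\,s = d$ — half-units allowed only for scored (divisible) tablets,
  otherwise whole units; no exact multiple ⇒ the pair is inapplicable;
- course units $U = u(d) \cdot f \cdot t$;
- minimal packages $P = \lceil U/n \rceil$; leftover $E = P\,n - U$;
- **matched** ⇔ $E = 0$.

Dose ranges and flexible durations ("2×1000 mg, 10–14 days") are resolved
by minimizing $E$ over every candidate dose and every whole day in the
interval (ties: fewer packages, then shorter course, then smaller dose).
All arithmetic is exact (integer half-units internally).

## Worked example

```r
library(coursefit)

# one package, one flexible regimen
pkg <- drug_package("Co-amoxiclav", "tablet", 1000, "mg", 16)
reg <- regimen("ISKRA", "uti", "amoxicillin and clavulanic acid",
               1000, "mg", doses_per_day = 2, min_days = 10, max_days = 14)
fit_course(pkg, reg)
#> <course_fit> 1000 x 14 day(s): 28 units -> 2 package(s), 4 extra
```

The engine tried every course length from 10 to 14 days; 14 days (28
tablets) wastes least from two 16-tablet boxes — 4 tablets — and no choice
drains the boxes exactly, so the pair is mismatched.

```r
# the packaged reference audit (a published national dataset)
fx <- paper_fixture()
rows <- audit(fx$packages, fx$regimens)

summarize_matches(rows, source = "ISKRA", indication = "sore_throat")
#> <match_summary> source=ISKRA indication=sore_throat reimbursement=all
#>   23 applicable: 7 matched, 16 mismatched (7 n/a; 7 packages match >=1 regimen)

str(national_accordance(rows))
#> List of 4
#>  $ matched_total         : int 30
#>  $ combo_total           : int 106
#>  $ matched_reimbursed    : int 18
#>  $ combo_total_reimbursed: int 55
```

Of the 23 sore-throat (package, regimen) combinations the national
guideline makes comparable, only 7 drain whole boxes exactly; across both
audited indications 30 combinations match, 18 among currently reimbursed
packages. Seven further pairs are "n/a" — not mismatched but not
comparable (e.g. a 500 mg dose cannot be built from unscored 1000 mg
tablets).

## Command line

```sh
Rscript -e 'quit(status = coursefit::cli())' --args audit --fixture --out reports/
Rscript -e 'quit(status = coursefit::cli())' --args tables --fixture --out reports/
Rscript -e 'quit(status = coursefit::cli())' --args simulate --seed 7 --out sim/
```

`audit` writes `combos.csv`, `summary.json` and `exclusions.csv`; `tables`
renders per-substance tables with `n/a` cells and flexible-duration
annotations like `2 (14 days) | 4`; `simulate` writes a synthetic registry
+ regimen set with a planted ground-truth table. Exit codes: 0 ok, 2
unreadable input, 3 schema violation, 4 infeasible synthetic spec.

## Layout

- `R/` — domain model, registry ingest, course fitting, guideline matching,
  synthetic data, CLI.
- `inst/extdata/` — the reference dataset (registry CSV, regimen JSON,
  reimbursement CSV, expected table cells).
- `vignettes/package-size-concordance.Rmd` — model, assumptions, data
  provenance, limitations.
- `tests/testthat/` — unit, property (engine vs. brute-force oracle) and
  acceptance suites.
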