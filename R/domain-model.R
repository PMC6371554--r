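# Shared domain vocabulary: formulations, packages, regimens, and the
# dose-construction arithmetic everything else builds on.
#
# Unit bookkeeping convention: all course arithmetic is carried out in
# *half-units* (integers), i.e. one tablet = 2 half-units.  Only formulations
# flagged as divisible may contribute an odd number of half-units.  Results
# are converted back to units (possibly ending in .5) at the API boundary, so
# equality tests such as "leftover == 0" never touch inexact floats.

FORM_LEVELS <- c("tablet", "capsule", "other-solid")
UNIT_LEVELS <- c("mg", "IU")
REIMBURSEMENT_LEVELS <- c("current", "former", "none")
SOURCE_LEVELS <- c("ISKRA", "NICE", "IDSA", "SmPC")
INDICATION_LEVELS <- c("sore_throat", "uti", "other")

# Synonym table for joining registry and guideline spellings.  Keys are
# already lowercased/whitespace-normalized; values are canonical names.
SUBSTANCE_SYNONYMS <- c(
  "co-amoxiclav"                     = "amoxicillin-clavulanate",
  "coamoxiclav"                      = "amoxicillin-clavulanate",
  "amoxicillin and clavulanic acid"  = "amoxicillin-clavulanate",
  "amoxicillin with clavulanic acid" = "amoxicillin-clavulanate",
  "amoxicillin/clavulanic acid"      = "amoxicillin-clavulanate",
  "penicillin v"                     = "phenoxymethylpenicillin",
  "sulfametoxazole/trimethoprim"     = "co-trimoxazole",
  "sulfametoxazole, trimethoprim"    = "co-trimoxazole",
  "sulfamethoxazole/trimethoprim"    = "co-trimoxazole",
  "sulfamethoxazole, trimethoprim"   = "co-trimoxazole",
  "trimethoprim/sulfamethoxazole"    = "co-trimoxazole",
  "fosfomycinum"                     = "fosfomycin",
  "nitroxolin"                       = "nitroxoline",
  "flucloxacilin"                    = "flucloxacillin"
)

#' Canonicalize an active-substance name
#'
#' Lowercases, trims and collapses whitespace, then applies a synonym table so
#' that registry spellings (e.g. `"Co-amoxiclav"`, `"Penicillin V"`) and
#' guideline spellings (e.g. `"amoxicillin and clavulanic acid"`) join on one
#' canonical key.  The mapping is idempotent.
#'
#' @param raw_name Character vector of substance names; must be non-empty
#'   strings.
#' @return Character vector of canonical lowercase names.
#' @examples
#' canonicalize_substance("Co-amoxiclav")
#' canonicalize_substance("  Penicillin V ")
#' @export
canonicalize_substance <- function(raw_name) {
  if (!is.character(raw_name)) stop_input("substance name must be character")
  x <- gsub("\\s+", " ", trimws(tolower(raw_name)))
  if (any(!nzchar(x))) stop_input("substance name must be a nonempty string")
  hit <- match(x, names(SUBSTANCE_SYNONYMS))
  x[!is.na(hit)] <- unname(SUBSTANCE_SYNONYMS[hit[!is.na(hit)]])
  x
}

# Vectorized core: half-units needed per administration, NA when the dose
# cannot be built from whole tablets (or exact halves when divisible).
half_units_per_dose <- function(dose, strength, divisible) {
  k <- 2 * dose / strength
  k_int <- round(k)
  ok <- abs(k - k_int) < 1e-9 & k_int >= 1
  ok <- ok & (divisible | k_int %% 2 == 0)
  out <- ifelse(ok, k_int, NA_real_)
  as.integer(out)
}

#' Units of a formulation needed for one administered dose
#'
#' A dose is constructible from whole units, or from exact halves when the
#' formulation is divisible (scored tablets).  No other fractions and no
#' mixing of strengths are permitted, mirroring how dispensed solid oral
#' forms can actually be split.
#'
#' @param dose_amount Positive dose in the formulation's strength unit.
#' @param formulation A [formulation()] (or any list with `strength_value`
#'   and `divisible`).
#' @return Number of units (a positive multiple of 0.5), or `NA` when the
#'   dose is not constructible.
#' @examples
#' f <- formulation("levofloxacin", "tablet", 500, "mg", divisible = TRUE)
#' units_per_dose(750, f)  # 1.5
#' @export
units_per_dose <- function(dose_amount, formulation) {
  if (!is.numeric(dose_amount) || length(dose_amount) != 1L ||
      is.na(dose_amount) || dose_amount <= 0) {
    stop_input("dose_amount must be a single positive number")
  }
  hu <- half_units_per_dose(dose_amount, formulation$strength_value,
                            isTRUE(formulation$divisible))
  if (is.na(hu)) NA_real_ else hu / 2
}

#' Construct a formulation
#'
#' @param substance Active-substance name (stored as given; canonicalized at
#'   join time).
#' @param form One of `"tablet"`, `"capsule"`, `"other-solid"`.
#' @param strength_value Positive strength per unit.
#' @param strength_unit `"mg"` or `"IU"`.
#' @param divisible Can a unit be split into two equal halves?  Only tablets
#'   may be divisible.
#' @return A list of class `"formulation"`.
#' @export
formulation <- function(substance, form, strength_value, strength_unit,
                        divisible = FALSE) {
  form <- match.arg(form, FORM_LEVELS)
  strength_unit <- match.arg(strength_unit, UNIT_LEVELS)
  if (!is.numeric(strength_value) || length(strength_value) != 1L ||
      is.na(strength_value) || strength_value <= 0) {
    stop_input("strength_value must be a single positive number")
  }
  divisible <- isTRUE(divisible)
  if (divisible && form != "tablet") {
    stop_input("only tablets may be divisible (got form '%s')", form)
  }
  structure(list(substance = substance, form = form,
                 strength_value = strength_value,
                 strength_unit = strength_unit, divisible = divisible),
            class = "formulation")
}

format_strength <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}

#' Display label for a package, e.g. `"14x500 mg"`
#' @param units_per_package Integer units in the package.
#' @param strength_value,strength_unit Strength per unit.
#' @return Character label.
#' @export
package_label <- function(units_per_package, strength_value, strength_unit) {
  paste0(units_per_package, "x", format_strength(strength_value), " ",
         strength_unit)
}

#' Construct a marketed drug package (one row)
#'
#' @inheritParams formulation
#' @param units_per_package Positive integer count of units in the package.
#' @param atc_code ATC code (audits typically restrict to the J01 subtree).
#' @param reimbursement `"current"`, `"former"` or `"none"`.
#' @return A one-row `data.frame`; rows from repeated calls `rbind` into a
#'   package table as consumed by [audit()].
#' @export
drug_package <- function(substance, form, strength_value, strength_unit,
                         units_per_package, divisible = FALSE,
                         atc_code = "", reimbursement = "none") {
  f <- formulation(substance, form, strength_value, strength_unit, divisible)
  reimbursement <- match.arg(reimbursement, REIMBURSEMENT_LEVELS)
  if (!is.numeric(units_per_package) || length(units_per_package) != 1L ||
      is.na(units_per_package) || units_per_package < 1 ||
      units_per_package != round(units_per_package)) {
    stop_input("units_per_package must be a positive integer")
  }
  units_per_package <- as.integer(units_per_package)
  lab <- package_label(units_per_package, strength_value, strength_unit)
  data.frame(
    package_id = paste(canonicalize_substance(substance), lab),
    substance = substance, form = f$form,
    strength_value = strength_value, strength_unit = f$strength_unit,
    divisible = f$divisible, units_per_package = units_per_package,
    atc_code = atc_code, reimbursement = reimbursement,
    package_label = lab,
    stringsAsFactors = FALSE
  )
}

#' Construct a dose specification
#'
#' A fixed dose is a single option; a printed range such as "250-500 mg" is
#' the list of its discrete candidate doses (by default the two endpoints,
#' which is how flexible guideline doses are written).
#'
#' @param options Strictly increasing vector of positive dose amounts.
#' @param unit `"mg"` or `"IU"`.
#' @return List of class `"dose_spec"`.
#' @export
dose_spec <- function(options, unit) {
  unit <- match.arg(unit, UNIT_LEVELS)
  if (!is.numeric(options) || length(options) < 1L || anyNA(options) ||
      any(options <= 0)) {
    stop_input("dose options must be positive numbers")
  }
  if (is.unsorted(options, strictly = TRUE)) {
    stop_input("dose options must be strictly increasing")
  }
  structure(list(options = as.numeric(options), unit = unit),
            class = "dose_spec")
}

#' Construct a duration specification
#'
#' @param min_days,max_days Closed integer interval of allowed treatment
#'   days; a fixed duration has `min_days == max_days`.
#' @return List of class `"duration_spec"`.
#' @export
duration_spec <- function(min_days, max_days = min_days) {
  ok <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= 1 && x == round(x)
  if (!ok(min_days) || !ok(max_days) || min_days > max_days) {
    stop_input("need 1 <= min_days <= max_days (integers)")
  }
  structure(list(min_days = as.integer(min_days),
                 max_days = as.integer(max_days)),
            class = "duration_spec")
}

default_regimen_text <- function(doses_per_day, options, unit,
                                 min_days, max_days) {
  dose_txt <- paste(format_strength(options), collapse = "-")
  days_txt <- if (min_days == max_days) {
    sprintf("%d day%s", min_days, if (min_days == 1L) "" else "s")
  } else {
    sprintf("%d-%d days", min_days, max_days)
  }
  sprintf("%dx%s %s, %s", doses_per_day, dose_txt, unit, days_txt)
}

#' Construct a guideline regimen (one row)
#'
#' One drug-specific recommendation: dose (fixed or a discrete set of
#' candidates), administrations per day, and duration (fixed or a flexible
#' closed interval of whole days).  Weight-based doses are resolved to an
#' absolute maximum dose before a regimen is authored; the fitting engine
#' never sees body weights.
#'
#' @param source Guideline body: `"ISKRA"`, `"NICE"`, `"IDSA"` or `"SmPC"`.
#' @param indication `"sore_throat"`, `"uti"` or `"other"`.
#' @param substance Substance named by the guideline.
#' @param dose_options Positive, strictly increasing dose amounts.
#' @param unit `"mg"` or `"IU"`.
#' @param doses_per_day Positive integer administrations per day.
#' @param min_days,max_days Duration interval (see [duration_spec()]).
#' @param note Free-text qualifier (e.g. `"extended release"`).
#' @param modified_release If `TRUE` the regimen requires a modified-release
#'   product and is never constructible from immediate-release registry
#'   solids.
#' @param regimen_text Display text; derived from the fields when omitted.
#' @param regimen_id Stable identifier; derived when omitted.
#' @return One-row `data.frame` with a `dose_options` list-column; rows
#'   `rbind` into a regimen table as consumed by [audit()].
#' @export
regimen <- function(source, indication, substance, dose_options, unit,
                    doses_per_day, min_days, max_days = min_days,
                    note = "", modified_release = FALSE,
                    regimen_text = NULL, regimen_id = NULL) {
  source <- match.arg(source, SOURCE_LEVELS)
  indication <- match.arg(indication, INDICATION_LEVELS)
  ds <- dose_spec(dose_options, unit)
  du <- duration_spec(min_days, max_days)
  if (!is.numeric(doses_per_day) || length(doses_per_day) != 1L ||
      is.na(doses_per_day) || doses_per_day < 1 ||
      doses_per_day != round(doses_per_day)) {
    stop_input("doses_per_day must be a positive integer")
  }
  doses_per_day <- as.integer(doses_per_day)
  if (is.null(regimen_text)) {
    regimen_text <- default_regimen_text(doses_per_day, ds$options, ds$unit,
                                         du$min_days, du$max_days)
  }
  if (is.null(regimen_id)) {
    regimen_id <- paste(source, canonicalize_substance(substance),
                        regimen_text)
  }
  out <- data.frame(
    regimen_id = regimen_id, source = source, indication = indication,
    substance = substance, unit = ds$unit, doses_per_day = doses_per_day,
    min_days = du$min_days, max_days = du$max_days, note = note,
    modified_release = isTRUE(modified_release), regimen_text = regimen_text,
    stringsAsFactors = FALSE
  )
  out$dose_options <- list(ds$options)
  out
}
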