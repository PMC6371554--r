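# Core computation: for one package and one regimen, decide applicability and
# find the leftover-minimizing way to complete the recommended course.

#' Fitting policy
#'
#' @param duration_tiebreak Among (dose, day) choices attaining the minimal
#'   leftover and minimal package count, prefer the shortest (default) or
#'   longest duration.  Published concordance tables annotate only the chosen
#'   duration and never discriminate this order.
#' @param dose_candidates For dose ranges: `"endpoints"` (default; the
#'   discrete options stored on the regimen, normally the printed endpoints)
#'   or `"all_constructible"` (every constructible dose between the smallest
#'   and largest option, stepping by half or whole strength).
#' @param adherence Fixed at 1.0: the audit assumes the full course is taken.
#' @return List of class `"fit_policy"`.
#' @export
fit_policy <- function(duration_tiebreak = c("shortest", "longest"),
                       dose_candidates = c("endpoints", "all_constructible"),
                       adherence = 1.0) {
  duration_tiebreak <- match.arg(duration_tiebreak)
  dose_candidates <- match.arg(dose_candidates)
  if (!identical(as.numeric(adherence), 1.0)) {
    stop_input("adherence is fixed at 1.0 in this audit model")
  }
  structure(list(duration_tiebreak = duration_tiebreak,
                 dose_candidates = dose_candidates, adherence = 1.0),
            class = "fit_policy")
}

INAPPLICABILITY_REASONS <- c("none", "substance_not_named", "unit_mismatch",
                             "dose_not_constructible")

#' Can a regimen be evaluated against a package at all?
#'
#' A comparison is attempted only when the guideline names the same substance,
#' uses the same unit system (mg and IU are never interconverted), and at
#' least one candidate dose is constructible from whole or half units of the
#' formulation.  Modified-release regimens are never constructible from the
#' immediate-release solids a registry row describes.
#'
#' @param package One-row package table (see [drug_package()]).
#' @param regimen One-row regimen table (see [regimen()]).
#' @param policy A [fit_policy()].
#' @return List with `applicable` (logical) and `reason` (one of `"none"`,
#'   `"substance_not_named"`, `"unit_mismatch"`, `"dose_not_constructible"`).
#' @export
applicability <- function(package, regimen, policy = fit_policy()) {
  if (!identical(canonicalize_substance(package$substance),
                 canonicalize_substance(regimen$substance))) {
    return(list(applicable = FALSE, reason = "substance_not_named"))
  }
  if (!identical(package$strength_unit, regimen$unit)) {
    return(list(applicable = FALSE, reason = "unit_mismatch"))
  }
  if (isTRUE(regimen$modified_release)) {
    return(list(applicable = FALSE, reason = "dose_not_constructible"))
  }
  doses <- candidate_doses(regimen, package, policy)
  hu <- half_units_per_dose(doses, package$strength_value, package$divisible)
  if (all(is.na(hu))) {
    return(list(applicable = FALSE, reason = "dose_not_constructible"))
  }
  list(applicable = TRUE, reason = "none")
}

candidate_doses <- function(regimen, package, policy) {
  opts <- regimen$dose_options[[1L]]
  if (policy$dose_candidates == "endpoints" || length(opts) == 1L) {
    return(opts)
  }
  step <- package$strength_value / (if (package$divisible) 2 else 1)
  grid <- seq(min(opts), max(opts), by = step)
  sort(unique(c(opts, grid)))
}

#' Units needed for a full course at a fixed dose and duration
#'
#' @param dose_amount Per-administration dose (must be constructible).
#' @param doses_per_day Positive integer administrations per day.
#' @param days Positive integer treatment days.
#' @param formulation A [formulation()].
#' @return Units of the original formulation (multiple of 0.5).
#' @export
course_units <- function(dose_amount, doses_per_day, days, formulation) {
  ok_int <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= 1 && x == round(x)
  if (!ok_int(doses_per_day) || !ok_int(days)) {
    stop_input("doses_per_day and days must be positive integers")
  }
  u <- units_per_dose(dose_amount, formulation)
  if (is.na(u)) {
    stop_input("dose %s is not constructible from strength %s (check applicability first)",
               format_strength(dose_amount),
               format_strength(formulation$strength_value))
  }
  u * doses_per_day * days
}

#' Minimal packages and leftover units for a fixed dose and duration
#'
#' `min_packages` is the smallest whole number of identical packages covering
#' the course; `extra_units` is what remains once the course is complete.
#'
#' @param package One-row package table.
#' @param dose_amount Per-administration dose (must be constructible).
#' @param doses_per_day,days Positive integers.
#' @return List with `min_packages` and `extra_units`.
#' @export
fit_fixed <- function(package, dose_amount, doses_per_day, days) {
  hu <- half_units_per_dose(dose_amount, package$strength_value,
                            package$divisible)
  if (is.na(hu)) {
    stop_input("dose %s is not constructible from this package",
               format_strength(dose_amount))
  }
  course_hu <- hu * as.integer(doses_per_day) * as.integer(days)
  pack_hu <- 2L * package$units_per_package
  min_packages <- (course_hu + pack_hu - 1L) %/% pack_hu
  extra_hu <- min_packages * pack_hu - course_hu
  list(min_packages = as.integer(min_packages), extra_units = extra_hu / 2)
}

empty_fit <- function(reason) {
  list(applicable = FALSE, reason = reason,
       chosen_dose = NA_real_, chosen_days = NA_integer_,
       units_per_course = NA_real_, min_packages = NA_integer_,
       extra_units = NA_real_, matched = FALSE)
}

#' Fit a regimen to a package, minimizing leftover units
#'
#' Enumerates every candidate dose and every whole day in the duration
#' interval, computes the fixed fit for each, and returns the combination
#' minimizing leftover units, breaking ties by fewer packages, then by the
#' policy's duration preference, then by the smaller dose.  A pair is
#' *matched* when the chosen combination leaves zero extra units.
#'
#' @inheritParams applicability
#' @return A `course_fit` list: `applicable`, `reason`, `chosen_dose`,
#'   `chosen_days`, `units_per_course`, `min_packages`, `extra_units`,
#'   `matched`.
#' @examples
#' p <- drug_package("co-amoxiclav", "tablet", 1000, "mg", 16)
#' r <- regimen("ISKRA", "uti", "amoxicillin and clavulanic acid",
#'              1000, "mg", 2, 10, 14)
#' fit_course(p, r)  # 2 packages at 14 days, 4 extra
#' @export
fit_course <- function(package, regimen, policy = fit_policy()) {
  app <- applicability(package, regimen, policy)
  if (!app$applicable) {
    return(structure(empty_fit(app$reason), class = "course_fit"))
  }
  doses <- candidate_doses(regimen, package, policy)
  hu <- half_units_per_dose(doses, package$strength_value, package$divisible)
  doses <- doses[!is.na(hu)]
  hu <- hu[!is.na(hu)]
  days <- seq.int(regimen$min_days, regimen$max_days)
  grid <- expand.grid(di = seq_along(doses), day = days)
  course_hu <- hu[grid$di] * regimen$doses_per_day * grid$day
  pack_hu <- 2L * package$units_per_package
  packs <- (course_hu + pack_hu - 1L) %/% pack_hu
  extra_hu <- packs * pack_hu - course_hu
  day_key <- if (policy$duration_tiebreak == "shortest") grid$day else -grid$day
  best <- order(extra_hu, packs, day_key, doses[grid$di])[1L]
  structure(list(
    applicable = TRUE, reason = "none",
    chosen_dose = doses[grid$di[best]],
    chosen_days = as.integer(grid$day[best]),
    units_per_course = course_hu[best] / 2,
    min_packages = as.integer(packs[best]),
    extra_units = extra_hu[best] / 2,
    matched = extra_hu[best] == 0L
  ), class = "course_fit")
}

#' Exhaustive-search reference fit (test oracle)
#'
#' Independent re-implementation used to validate [fit_course()]: for every
#' candidate dose and day it accumulates the course unit by unit and finds
#' the covering package count by linear search rather than ceiling
#' arithmetic, then selects the winner with an explicit pairwise comparator.
#' Intended for small instances in tests only.
#'
#' @inheritParams applicability
#' @return A `course_fit` list (same shape as [fit_course()]).
#' @export
brute_force_oracle <- function(package, regimen, policy = fit_policy()) {
  app <- applicability(package, regimen, policy)
  if (!app$applicable) {
    return(structure(empty_fit(app$reason), class = "course_fit"))
  }
  strength <- package$strength_value
  piece <- if (package$divisible) strength / 2 else strength
  unit_of <- function(dose) {
    # smallest count of pieces reproducing the dose exactly, else NA
    for (n in seq_len(1000L)) {
      if (isTRUE(all.equal(n * piece, dose))) {
        return(n * piece / strength)
      }
      if (n * piece > dose) break
    }
    NA_real_
  }
  best <- NULL
  for (dose in candidate_doses(regimen, package, policy)) {
    u <- unit_of(dose)
    if (is.na(u)) next
    for (day in seq.int(regimen$min_days, regimen$max_days)) {
      units <- sum(rep(u, regimen$doses_per_day * day))
      p <- 0L
      while (p * package$units_per_package < units - 1e-9) p <- p + 1L
      if (p == 0L) p <- 1L
      cand <- list(dose = dose, day = day, units = units, packs = p,
                   extra = p * package$units_per_package - units)
      if (is.null(best) || oracle_better(cand, best, policy)) best <- cand
    }
  }
  if (is.null(best)) {
    return(structure(empty_fit("dose_not_constructible"),
                     class = "course_fit"))
  }
  structure(list(
    applicable = TRUE, reason = "none", chosen_dose = best$dose,
    chosen_days = as.integer(best$day), units_per_course = best$units,
    min_packages = best$packs, extra_units = best$extra,
    matched = abs(best$extra) < 1e-9
  ), class = "course_fit")
}

oracle_better <- function(a, b, policy) {
  if (abs(a$extra - b$extra) > 1e-9) return(a$extra < b$extra)
  if (a$packs != b$packs) return(a$packs < b$packs)
  if (a$day != b$day) {
    return(if (policy$duration_tiebreak == "shortest") a$day < b$day
           else a$day > b$day)
  }
  a$dose < b$dose
}

#' @export
print.course_fit <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("<course_fit> n/a (%s)\n", x$reason))
  } else {
    cat(sprintf(
      "<course_fit> %s x %d day(s): %s units -> %d package(s), %s extra%s\n",
      format_strength(x$chosen_dose), x$chosen_days,
      format_strength(x$units_per_course), x$min_packages,
      format_strength(x$extra_units), if (x$matched) " [matched]" else ""))
  }
  invisible(x)
}
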