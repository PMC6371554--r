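# Cross-referencing: every package against every same-substance regimen,
# match classification, and the aggregate counts a stewardship report needs.
#
# Counting convention: "matched"/"mismatched" tallies are per applicable
# (package, regimen) combination.  Inapplicable pairs (wrong unit system,
# dose not constructible) are excluded from both tallies by default; a switch
# lets them be counted as mismatched for sensitivity checks.

validate_packages <- function(packages) {
  req <- c("package_id", "substance", "form", "strength_value",
           "strength_unit", "divisible", "units_per_package",
           "reimbursement", "package_label")
  missing <- setdiff(req, names(packages))
  if (length(missing)) {
    stop_schema("package table is missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (!all(packages$strength_unit %in% UNIT_LEVELS)) {
    bad <- which(!packages$strength_unit %in% UNIT_LEVELS)[1L]
    stop_schema("package row %d: unit '%s' is not one of %s", bad,
                packages$strength_unit[bad],
                paste(UNIT_LEVELS, collapse = "/"))
  }
  if (!all(packages$reimbursement %in% REIMBURSEMENT_LEVELS)) {
    stop_schema("package reimbursement must be current/former/none")
  }
  if (any(packages$units_per_package < 1)) {
    stop_schema("units_per_package must be >= 1")
  }
  invisible(packages)
}

validate_regimens <- function(regimens) {
  req <- c("regimen_id", "source", "indication", "substance", "unit",
           "doses_per_day", "min_days", "max_days", "modified_release",
           "regimen_text", "dose_options")
  missing <- setdiff(req, names(regimens))
  if (length(missing)) {
    stop_schema("regimen table is missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (!all(regimens$unit %in% UNIT_LEVELS)) {
    bad <- which(!regimens$unit %in% UNIT_LEVELS)[1L]
    stop_schema("regimen row %d ('%s'): unit '%s' is not one of %s", bad,
                regimens$regimen_id[bad], regimens$unit[bad],
                paste(UNIT_LEVELS, collapse = "/"))
  }
  if (!all(regimens$source %in% SOURCE_LEVELS)) {
    stop_schema("regimen source must be one of %s",
                paste(SOURCE_LEVELS, collapse = "/"))
  }
  if (!all(regimens$indication %in% INDICATION_LEVELS)) {
    stop_schema("regimen indication must be one of %s",
                paste(INDICATION_LEVELS, collapse = "/"))
  }
  if (any(regimens$min_days < 1 | regimens$min_days > regimens$max_days)) {
    stop_schema("regimen durations must satisfy 1 <= min_days <= max_days")
  }
  for (i in seq_len(nrow(regimens))) {
    opts <- regimens$dose_options[[i]]
    if (!is.numeric(opts) || length(opts) < 1L || any(opts <= 0) ||
        is.unsorted(opts, strictly = TRUE)) {
      stop_schema("regimen row %d ('%s'): dose options must be positive and strictly increasing",
                  i, regimens$regimen_id[i])
    }
  }
  invisible(regimens)
}

empty_audit_rows <- function() {
  data.frame(
    package_id = character(), regimen_id = character(),
    substance = character(), package_label = character(),
    strength_value = numeric(), strength_unit = character(),
    units_per_package = integer(), reimbursement = character(),
    source = character(), indication = character(),
    regimen_text = character(), applicable = logical(),
    reason = character(), chosen_dose = numeric(),
    chosen_days = integer(), units_per_course = numeric(),
    min_packages = integer(), extra_units = numeric(), matched = logical(),
    stringsAsFactors = FALSE
  )
}

#' Audit a package table against a regimen table
#'
#' Builds the cross-product restricted to same-substance pairs (after
#' canonicalization) and fits every pair with [fit_course()].  Output order
#' is deterministic — substance, unit, strength, package size, guideline
#' source, regimen — regardless of input order.
#'
#' @param packages Package table (see [drug_package()], [expand_and_merge()]).
#' @param regimens Regimen table (see [regimen()], [regimens_from_json()]).
#' @param policy A [fit_policy()].
#' @return Data frame with one row per (package, regimen) combination:
#'   identifiers, package and regimen descriptors, and the course-fit fields
#'   (`applicable`, `reason`, `chosen_dose`, `chosen_days`,
#'   `units_per_course`, `min_packages`, `extra_units`, `matched`).
#' @export
audit <- function(packages, regimens, policy = fit_policy()) {
  validate_packages(packages)
  validate_regimens(regimens)
  pkg_sub <- canonicalize_substance(packages$substance)
  reg_sub <- canonicalize_substance(regimens$substance)
  pairs <- which(outer(pkg_sub, reg_sub, "=="), arr.ind = TRUE)
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]
    j <- pairs[k, 2L]
    p <- packages[i, , drop = FALSE]
    r <- regimens[j, , drop = FALSE]
    fit <- fit_course(p, r, policy)
    rows[[k]] <- data.frame(
      package_id = p$package_id, regimen_id = r$regimen_id,
      substance = pkg_sub[i], package_label = p$package_label,
      strength_value = p$strength_value, strength_unit = p$strength_unit,
      units_per_package = p$units_per_package,
      reimbursement = p$reimbursement,
      source = r$source, indication = r$indication,
      regimen_text = r$regimen_text,
      applicable = fit$applicable, reason = fit$reason,
      chosen_dose = fit$chosen_dose, chosen_days = fit$chosen_days,
      units_per_course = fit$units_per_course,
      min_packages = fit$min_packages, extra_units = fit$extra_units,
      matched = fit$matched,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_audit_rows()
  if (nrow(out) == 0L) return(out)
  ord <- order(out$substance, out$strength_unit, out$strength_value,
               out$units_per_package, match(out$source, SOURCE_LEVELS),
               out$regimen_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

filter_rows <- function(rows, source = "all", indication = "all",
                        reimbursement = "all") {
  keep <- rep(TRUE, nrow(rows))
  if (!identical(source, "all")) keep <- keep & rows$source %in% source
  if (!identical(indication, "all")) {
    keep <- keep & rows$indication %in% indication
  }
  if (identical(reimbursement, "current")) {
    keep <- keep & rows$reimbursement == "current"
  } else if (identical(reimbursement, "current_or_former")) {
    keep <- keep & rows$reimbursement %in% c("current", "former")
  } else if (!identical(reimbursement, "all")) {
    stop_input("reimbursement filter must be all/current/current_or_former")
  }
  rows[keep, , drop = FALSE]
}

#' Aggregate matched/mismatched counts for a guideline scope
#'
#' Combination-level counts tally applicable (package, regimen) pairs;
#' `package_level_matched` collapses over regimens and counts packages that
#' match at least one regimen in scope.
#'
#' @param rows Audit rows from [audit()].
#' @param source Guideline source filter (`"all"` or a subset of
#'   ISKRA/NICE/IDSA/SmPC).
#' @param indication Indication filter (`"all"`, `"sore_throat"`, `"uti"`,
#'   `"other"`).
#' @param reimbursement `"all"`, `"current"` or `"current_or_former"`.  The
#'   `"current"` stratum is the reimbursement-snapshot view used in headline
#'   counts; `"former"` listings are excluded from it.
#' @param count_na_as_mismatch Count inapplicable combinations as mismatched
#'   (off by default; provided for sensitivity analysis only).
#' @return List of class `"match_summary"` with the filters and counts
#'   `n_applicable_combos`, `n_matched`, `n_mismatched`, `n_inapplicable`,
#'   `package_level_matched`.
#' @export
summarize_matches <- function(rows, source = "all", indication = "all",
                              reimbursement = "all",
                              count_na_as_mismatch = FALSE) {
  scope <- filter_rows(rows, source, indication, reimbursement)
  app <- scope$applicable
  n_matched <- sum(scope$matched)
  n_mismatched <- sum(app & !scope$matched)
  if (isTRUE(count_na_as_mismatch)) n_mismatched <- n_mismatched + sum(!app)
  structure(list(
    source = source, indication = indication, reimbursement = reimbursement,
    n_applicable_combos = sum(app),
    n_matched = n_matched,
    n_mismatched = n_mismatched,
    n_inapplicable = sum(!app),
    package_level_matched = length(unique(scope$package_id[scope$matched]))
  ), class = "match_summary")
}

#' @export
print.match_summary <- function(x, ...) {
  cat(sprintf(
    "<match_summary> source=%s indication=%s reimbursement=%s\n  %d applicable: %d matched, %d mismatched (%d n/a; %d packages match >=1 regimen)\n",
    paste(x$source, collapse = "+"), paste(x$indication, collapse = "+"),
    x$reimbursement, x$n_applicable_combos, x$n_matched, x$n_mismatched,
    x$n_inapplicable, x$package_level_matched))
  invisible(x)
}

#' National-guideline accordance totals across both audited indications
#'
#' Sums matched and applicable (package, regimen) combinations over the
#' national (ISKRA) sore-throat and urinary-tract-infection audits, overall
#' and restricted to currently reimbursed packages.
#'
#' @param rows Audit rows covering both ISKRA indications.
#' @return List with `matched_total`, `combo_total`, `matched_reimbursed`,
#'   `combo_total_reimbursed`.
#' @export
national_accordance <- function(rows) {
  all_sum <- summarize_matches(rows, source = "ISKRA",
                               indication = c("sore_throat", "uti"))
  reimb <- summarize_matches(rows, source = "ISKRA",
                             indication = c("sore_throat", "uti"),
                             reimbursement = "current")
  list(matched_total = all_sum$n_matched,
       combo_total = all_sum$n_applicable_combos,
       matched_reimbursed = reimb$n_matched,
       combo_total_reimbursed = reimb$n_applicable_combos)
}

#' Per-substance package-level rollup
#'
#' For each substance with at least one audited combination in scope, counts
#' the packages considered and those matching at least one regimen.
#'
#' @inheritParams summarize_matches
#' @return Data frame with `substance`, `n_packages`, `n_matched_any`.
#' @export
package_rollup <- function(rows, source = "all", indication = "all") {
  scope <- filter_rows(rows, source, indication)
  if (nrow(scope) == 0L) {
    return(data.frame(substance = character(), n_packages = integer(),
                      n_matched_any = integer(), stringsAsFactors = FALSE))
  }
  subs <- sort(unique(scope$substance))
  out <- data.frame(
    substance = subs,
    n_packages = vapply(subs, function(s) {
      length(unique(scope$package_id[scope$substance == s]))
    }, integer(1)),
    n_matched_any = vapply(subs, function(s) {
      length(unique(scope$package_id[scope$substance == s & scope$matched]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
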