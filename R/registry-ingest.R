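# Registry ingest: parse a national drug-database extract and apply the
# audit's inclusion/exclusion workflow to produce the audit-ready package
# list, with an exclusion log that reproduces flowchart-style box counts.

REGISTRY_COLUMNS <- c("trade_name", "atc_code", "substance", "form",
                      "strength_value", "strength_unit", "divisible",
                      "package_sizes", "marketing_status", "dose_prespecified",
                      "paediatric")

MARKETING_LEVELS <- c("marketed", "not_marketed", "discontinued")

# Forms accepted by the oral-route rule.  Powders/solutions are oral but are
# removed later by the dose-prespecification rule, matching how the two
# exclusions are reported separately.
ORAL_FORMS <- c(FORM_LEVELS, "oral-powder", "oral-solution", "oral-suspension")

# Fixed exclusion-rule order; an entry is logged only under the first rule it
# fails, so per-rule counts are well defined.
EXCLUSION_RULES <- c("atc_prefix", "marketing_status", "oral_form",
                     "dose_prespecified", "paediatric")

#' Registry filter configuration
#'
#' @param atc_prefix Keep only entries whose ATC code starts with this prefix
#'   (`""` disables the rule).  Default `"J01"`, antibacterials for systemic
#'   use.
#' @param marketed_only Drop entries not currently marketed or permanently
#'   discontinued.
#' @param oral_only Keep only oral dosage forms.
#' @param require_prespecified_dose Drop forms without a manufacturer
#'   pre-specified dosage unit (e.g. powders for oral solutions).
#' @param max_units_exclusive Optional integer; package sizes with this many
#'   units *or more* are dropped at expansion time.  Unset by default: the
#'   published reference tables retain 30- and 32-unit packages even though
#'   the source workflow describes such a cut, so the threshold is a knob,
#'   not a constant.
#' @param include_paediatric Keep weight-dosed paediatric formulations
#'   (excluded by default).
#' @return List of class `"filter_config"`.
#' @export
filter_config <- function(atc_prefix = "J01", marketed_only = TRUE,
                          oral_only = TRUE, require_prespecified_dose = TRUE,
                          max_units_exclusive = NULL,
                          include_paediatric = FALSE) {
  if (!is.null(max_units_exclusive)) {
    if (!is.numeric(max_units_exclusive) || length(max_units_exclusive) != 1L ||
        is.na(max_units_exclusive) || max_units_exclusive < 1) {
      stop_input("max_units_exclusive must be >= 1 when set")
    }
    max_units_exclusive <- as.integer(max_units_exclusive)
  }
  structure(list(atc_prefix = atc_prefix,
                 marketed_only = isTRUE(marketed_only),
                 oral_only = isTRUE(oral_only),
                 require_prespecified_dose = isTRUE(require_prespecified_dose),
                 max_units_exclusive = max_units_exclusive,
                 include_paediatric = isTRUE(include_paediatric)),
            class = "filter_config")
}

parse_logical_cell <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(trimws(x)) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(trimws(x)) %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Parse a drug-registry CSV extract
#'
#' Required columns (exact header names): `trade_name`, `atc_code`,
#' `substance`, `form`, `strength_value`, `strength_unit`, `divisible`,
#' `package_sizes` (semicolon-separated positive integers),
#' `marketing_status`, `dose_prespecified`, `paediatric`.  Rows are parsed as
#' presented; exclusions happen later in [filter_registry()].  Malformed rows
#' are collected in the `"problems"` attribute (a data frame with `row`,
#' `field`, `message`), never silently dropped.
#'
#' @param file Path (or connection) to the registry CSV.
#' @return Data frame of raw registry entries with an `entry_id` column and a
#'   `"problems"` attribute.
#' @export
parse_registry <- function(file) {
  raw <- tryCatch(
    utils::read.csv(file, colClasses = "character", check.names = FALSE,
                    strip.white = TRUE),
    error = function(e) stop_format("cannot read registry CSV: %s",
                                    conditionMessage(e))
  )
  missing <- setdiff(REGISTRY_COLUMNS, names(raw))
  if (length(missing)) {
    stop_format("registry CSV is missing required column(s): %s",
                paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  problems <- list()
  note <- function(row, field, msg) {
    problems[[length(problems) + 1L]] <<-
      data.frame(row = row, field = field, message = msg,
                 stringsAsFactors = FALSE)
  }

  strength <- suppressWarnings(as.numeric(raw$strength_value))
  bad <- which(is.na(strength) | strength <= 0)
  for (i in bad) note(i, "strength_value",
                      sprintf("unparseable strength '%s'", raw$strength_value[i]))

  bad_unit <- which(!raw$strength_unit %in% UNIT_LEVELS)
  for (i in bad_unit) note(i, "strength_unit",
                           sprintf("unknown unit '%s'", raw$strength_unit[i]))

  divisible <- parse_logical_cell(raw$divisible)
  for (i in which(is.na(divisible))) note(i, "divisible", "not a logical")
  prespec <- parse_logical_cell(raw$dose_prespecified)
  for (i in which(is.na(prespec))) note(i, "dose_prespecified", "not a logical")
  paed <- parse_logical_cell(raw$paediatric)
  for (i in which(is.na(paed))) note(i, "paediatric", "not a logical")

  bad_status <- which(!raw$marketing_status %in% MARKETING_LEVELS)
  for (i in bad_status) note(i, "marketing_status",
                             sprintf("unknown status '%s'",
                                     raw$marketing_status[i]))

  sizes_ok <- grepl("^[0-9]+(;[0-9]+)*$", raw$package_sizes)
  for (i in which(!sizes_ok)) note(i, "package_sizes",
                                   sprintf("unparseable sizes '%s'",
                                           raw$package_sizes[i]))

  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  ok <- setdiff(seq_len(n), problems$row)

  entries <- data.frame(
    entry_id = ok,
    trade_name = raw$trade_name[ok], atc_code = raw$atc_code[ok],
    substance = raw$substance[ok], form = raw$form[ok],
    strength_value = strength[ok], strength_unit = raw$strength_unit[ok],
    divisible = divisible[ok], package_sizes = raw$package_sizes[ok],
    marketing_status = raw$marketing_status[ok],
    dose_prespecified = prespec[ok], paediatric = paed[ok],
    stringsAsFactors = FALSE
  )
  attr(entries, "problems") <- problems
  entries
}

#' Apply the inclusion/exclusion workflow to raw registry entries
#'
#' Rules fire in a fixed order — ATC prefix, marketing status, oral form,
#' dose prespecification, paediatric — and each excluded entry is logged under
#' the first rule it fails.
#'
#' @param entries Data frame from [parse_registry()].
#' @param config A [filter_config()].
#' @return List with `entries` (retained rows) and `log` (an `exclusion_log`:
#'   per-entry `(entry_id, rule)` pairs plus per-rule counts).
#' @export
filter_registry <- function(entries, config = filter_config()) {
  n <- nrow(entries)
  passes <- list(
    atc_prefix = if (nzchar(config$atc_prefix)) {
      startsWith(entries$atc_code, config$atc_prefix)
    } else rep(TRUE, n),
    marketing_status = if (config$marketed_only) {
      entries$marketing_status == "marketed"
    } else rep(TRUE, n),
    oral_form = if (config$oral_only) {
      entries$form %in% ORAL_FORMS
    } else rep(TRUE, n),
    dose_prespecified = if (config$require_prespecified_dose) {
      entries$dose_prespecified
    } else rep(TRUE, n),
    paediatric = if (!config$include_paediatric) {
      !entries$paediatric
    } else rep(TRUE, n)
  )
  excluded_rule <- rep(NA_character_, n)
  for (rule in EXCLUSION_RULES) {
    fail <- !passes[[rule]] & is.na(excluded_rule)
    excluded_rule[fail] <- rule
  }
  keep <- is.na(excluded_rule)
  log_entries <- data.frame(entry_id = entries$entry_id[!keep],
                            rule = excluded_rule[!keep],
                            stringsAsFactors = FALSE)
  counts <- vapply(EXCLUSION_RULES,
                   function(r) sum(log_entries$rule == r), integer(1))
  log <- structure(list(entries = log_entries, counts = counts,
                        n_input = n, n_retained = sum(keep)),
                   class = "exclusion_log")
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(entries = out, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("<exclusion_log> %d in, %d retained, %d excluded\n",
              x$n_input, x$n_retained, nrow(x$entries)))
  for (r in names(x$counts)) {
    if (x$counts[[r]] > 0) cat(sprintf("  %-18s %d\n", r, x$counts[[r]]))
  }
  invisible(x)
}

#' Expand package sizes and merge duplicate trade names
#'
#' Explodes the semicolon-separated size list into one candidate package per
#' size, applies the optional size threshold, and collapses entries sharing
#' (canonical substance, strength, unit, size) into a single package
#' irrespective of trade name.  Divisibility is taken as "any merged product
#' is scored"; form and ATC code come from the first contributing row.
#' Output is deterministically ordered by substance, unit, strength, size.
#'
#' @param entries Filtered registry entries.
#' @param config A [filter_config()] (only `max_units_exclusive` is used
#'   here).
#' @return Package table (one row per distinct package, reimbursement
#'   initialized to `"none"`).
#' @export
expand_and_merge <- function(entries, config = filter_config()) {
  if (nrow(entries) == 0L) {
    return(drug_package("x", "tablet", 1, "mg", 1)[0, , drop = FALSE])
  }
  size_list <- strsplit(entries$package_sizes, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(entries)), lengths(size_list))
  sizes <- as.integer(unlist(size_list))
  long <- entries[idx, , drop = FALSE]
  long$units_per_package <- sizes
  if (!is.null(config$max_units_exclusive)) {
    long <- long[long$units_per_package < config$max_units_exclusive, ,
                 drop = FALSE]
  }
  if (nrow(long) == 0L) {
    return(drug_package("x", "tablet", 1, "mg", 1)[0, , drop = FALSE])
  }
  long$substance_canonical <- canonicalize_substance(long$substance)
  key <- paste(long$substance_canonical, long$strength_unit,
               format_strength(long$strength_value), long$units_per_package,
               sep = "|")
  ord <- order(key, long$trade_name)
  long <- long[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  divisible_any <- tapply(long$divisible, key, any)
  merged <- long[first, , drop = FALSE]
  merged$divisible <- as.logical(divisible_any[key[first]])

  out <- data.frame(
    package_id = paste(merged$substance_canonical,
                       package_label(merged$units_per_package,
                                     merged$strength_value,
                                     merged$strength_unit)),
    substance = merged$substance_canonical,
    form = merged$form,
    strength_value = merged$strength_value,
    strength_unit = merged$strength_unit,
    divisible = merged$divisible,
    units_per_package = merged$units_per_package,
    atc_code = merged$atc_code,
    reimbursement = "none",
    package_label = package_label(merged$units_per_package,
                                  merged$strength_value,
                                  merged$strength_unit),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$substance, out$strength_unit, out$strength_value,
                   out$units_per_package), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate packages with reimbursement status
#'
#' @param packages Package table from [expand_and_merge()].
#' @param reimbursement_table Data frame with columns `substance`,
#'   `strength_value`, `strength_unit`, `units_per_package`, `status`
#'   (`"current"` or `"former"`).  Substances are canonicalized before
#'   joining; packages absent from the table get `"none"`.
#' @return The package table with `reimbursement` filled in.
#' @export
annotate_reimbursement <- function(packages, reimbursement_table) {
  req <- c("substance", "strength_value", "strength_unit",
           "units_per_package", "status")
  missing <- setdiff(req, names(reimbursement_table))
  if (length(missing)) {
    stop_format("reimbursement table is missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (!all(reimbursement_table$status %in% c("current", "former"))) {
    stop_schema("reimbursement status must be 'current' or 'former'")
  }
  key <- function(s, v, u, n) {
    paste(canonicalize_substance(s), format_strength(as.numeric(v)), u, n,
          sep = "|")
  }
  tab_key <- key(reimbursement_table$substance,
                 reimbursement_table$strength_value,
                 reimbursement_table$strength_unit,
                 reimbursement_table$units_per_package)
  if (anyDuplicated(tab_key)) {
    stop_schema("duplicate package keys in reimbursement table")
  }
  pkg_key <- key(packages$substance, packages$strength_value,
                 packages$strength_unit, packages$units_per_package)
  hit <- match(pkg_key, tab_key)
  packages$reimbursement <- ifelse(is.na(hit), "none",
                                   reimbursement_table$status[hit])
  packages
}
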