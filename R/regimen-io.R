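# Regimen file I/O (JSON).  One record per guideline recommendation.

#' Read a regimen table from JSON
#'
#' The file holds an array of records with fields `source`, `indication`,
#' `substance`, `dose_options` (array of numbers), `unit`, `doses_per_day`,
#' `min_days`, `max_days`, and optionally `note`, `modified_release`,
#' `regimen_text`, `regimen_id`.
#'
#' @param file Path to the JSON file.
#' @return Regimen table (see [regimen()]).
#' @export
regimens_from_json <- function(file) {
  recs <- tryCatch(
    jsonlite::fromJSON(file, simplifyDataFrame = FALSE),
    error = function(e) stop_format("cannot read regimen JSON: %s",
                                    conditionMessage(e))
  )
  if (!is.list(recs) || length(recs) == 0L) {
    stop_format("regimen JSON must be a nonempty array of records")
  }
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    req <- c("source", "indication", "substance", "dose_options", "unit",
             "doses_per_day", "min_days", "max_days")
    missing <- setdiff(req, names(r))
    if (length(missing)) {
      stop_schema("regimen record %d is missing field(s): %s", i,
                  paste(missing, collapse = ", "))
    }
    if (!r$unit %in% UNIT_LEVELS) {
      stop_schema("regimen record %d: unit '%s' is not one of %s", i,
                  r$unit, paste(UNIT_LEVELS, collapse = "/"))
    }
    tryCatch(
      regimen(source = r$source, indication = r$indication,
              substance = r$substance,
              dose_options = as.numeric(unlist(r$dose_options)),
              unit = r$unit, doses_per_day = r$doses_per_day,
              min_days = r$min_days, max_days = r$max_days,
              note = if (is.null(r$note)) "" else r$note,
              modified_release = isTRUE(r$modified_release),
              regimen_text = r$regimen_text, regimen_id = r$regimen_id),
      coursefit_input_error = function(e) {
        stop_schema("regimen record %d: %s", i, conditionMessage(e))
      }
    )
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$regimen_id)) {
    stop_schema("duplicate regimen_id values in regimen file")
  }
  rownames(out) <- NULL
  out
}

#' Write a regimen table to JSON
#'
#' Inverse of [regimens_from_json()]; output is deterministic for a given
#' table.
#'
#' @param regimens Regimen table.
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
regimens_to_json <- function(regimens, file) {
  recs <- lapply(seq_len(nrow(regimens)), function(i) {
    list(regimen_id = regimens$regimen_id[i],
         source = regimens$source[i],
         indication = regimens$indication[i],
         substance = regimens$substance[i],
         dose_options = as.numeric(regimens$dose_options[[i]]),
         unit = regimens$unit[i],
         doses_per_day = regimens$doses_per_day[i],
         min_days = regimens$min_days[i],
         max_days = regimens$max_days[i],
         note = regimens$note[i],
         modified_release = regimens$modified_release[i],
         regimen_text = regimens$regimen_text[i])
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file)
  invisible(file)
}
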