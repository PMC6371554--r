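registry_csv <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  header <- paste(c("trade_name", "atc_code", "substance", "form",
                    "strength_value", "strength_unit", "divisible",
                    "package_sizes", "marketing_status", "dose_prespecified",
                    "paediatric"), collapse = ",")
  path <- file.path(dir, "registry.csv")
  writeLines(c(header, rows), path)
  path
}

base_row <- function(trade = "Amoxi A", atc = "J01CA04",
                     substance = "amoxicillin", form = "tablet",
                     strength = "500", unit = "mg", divisible = "true",
                     sizes = "16;20", status = "marketed", prespec = "true",
                     paediatric = "false") {
  paste(trade, atc, substance, form, strength, unit, divisible, sizes,
        status, prespec, paediatric, sep = ",")
}

test_that("parse_registry reads rows and collects malformed ones", {
  path <- registry_csv(c(
    base_row(),
    base_row(trade = "Disc", status = "discontinued"),
    base_row(trade = "BadStrength", strength = "abc"),
    base_row(trade = "BadSizes", sizes = "16;x")
  ))
  entries <- parse_registry(path)
  # discontinued rows parse; exclusion is not the parser's job
  expect_equal(nrow(entries), 2L)
  expect_true("Disc" %in% entries$trade_name)
  probs <- attr(entries, "problems")
  expect_equal(nrow(probs), 2L)
  expect_setequal(probs$field, c("strength_value", "package_sizes"))
})

test_that("parse_registry fails loudly on a missing required column", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  writeLines(c("trade_name,atc_code,substance", "a,J01,x"), path)
  err <- expect_error(parse_registry(path),
                      class = "coursefit_format_error")
  expect_match(conditionMessage(err), "strength_unit")
})

test_that("filter_registry applies rules in fixed order with a complete log", {
  path <- registry_csv(c(
    base_row(trade = "Keep"),
    base_row(trade = "WrongATC", atc = "J02AC01"),
    base_row(trade = "NotMarketed", status = "not_marketed"),
    base_row(trade = "Injectable", form = "solution-for-injection"),
    base_row(trade = "Powder", form = "oral-powder", prespec = "false"),
    base_row(trade = "Kids", paediatric = "true"),
    # fails both ATC and marketing: must be logged once, under atc_prefix
    base_row(trade = "Both", atc = "J02AC01", status = "discontinued")
  ))
  entries <- parse_registry(path)
  res <- filter_registry(entries, filter_config())
  expect_equal(nrow(res$entries), 1L)
  expect_equal(res$entries$trade_name, "Keep")
  log <- res$log
  # conservation: excluded + retained = input
  expect_equal(nrow(log$entries) + nrow(res$entries), nrow(entries))
  expect_equal(unname(log$counts[c("atc_prefix", "marketing_status",
                                   "oral_form", "dose_prespecified",
                                   "paediatric")]),
               c(2L, 1L, 1L, 1L, 1L))
  expect_equal(anyDuplicated(log$entries$entry_id), 0L)

  # disabling every rule is the identity
  off <- filter_config(atc_prefix = "", marketed_only = FALSE,
                       oral_only = FALSE, require_prespecified_dose = FALSE,
                       include_paediatric = TRUE)
  res_off <- filter_registry(entries, off)
  expect_equal(nrow(res_off$entries), nrow(entries))
  expect_equal(nrow(res_off$log$entries), 0L)
})

test_that("expand_and_merge expands sizes, merges trade names, dedupes", {
  path <- registry_csv(c(
    base_row(trade = "Brand A", sizes = "16;20"),
    base_row(trade = "Brand B", sizes = "16"),
    base_row(trade = "Big", substance = "cefuroxime", atc = "J01DC02",
             strength = "500", divisible = "false", sizes = "10;20;30")
  ))
  entries <- parse_registry(path)
  pkgs <- expand_and_merge(entries, filter_config())
  expect_equal(nrow(pkgs), 5L)  # amox 16,20 + cefuroxime 10,20,30
  key <- paste(pkgs$substance, pkgs$strength_value, pkgs$strength_unit,
               pkgs$units_per_package)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(pkgs$package_label[pkgs$substance == "amoxicillin"],
               c("16x500 mg", "20x500 mg"))

  # size threshold is exclusive at the configured bound
  pkgs30 <- expand_and_merge(entries,
                             filter_config(max_units_exclusive = 30))
  expect_equal(sort(pkgs30$units_per_package[pkgs30$substance == "cefuroxime"]),
               c(10L, 20L))
  # unset threshold keeps 30-unit packs
  expect_true(30L %in% pkgs$units_per_package)
})

test_that("merged divisibility is the OR of contributing products", {
  path <- registry_csv(c(
    base_row(trade = "Scored", divisible = "true", sizes = "16"),
    base_row(trade = "Plain", divisible = "false", sizes = "16")
  ))
  pkgs <- expand_and_merge(parse_registry(path), filter_config())
  expect_equal(nrow(pkgs), 1L)
  expect_true(pkgs$divisible)
})

test_that("annotate_reimbursement joins canonically and defaults to none", {
  pkgs <- expand_and_merge(parse_registry(registry_csv(c(
    base_row(trade = "A", substance = "Co-amoxiclav", strength = "1000",
             atc = "J01CR02", divisible = "false", sizes = "14;16")
  ))), filter_config())
  tab <- data.frame(substance = "amoxicillin and clavulanic acid",
                    strength_value = 1000, strength_unit = "mg",
                    units_per_package = 14, status = "former",
                    stringsAsFactors = FALSE)
  out <- annotate_reimbursement(pkgs, tab)
  expect_equal(out$reimbursement[out$units_per_package == 14], "former")
  expect_equal(out$reimbursement[out$units_per_package == 16], "none")
  tab$status <- "sometimes"
  expect_error(annotate_reimbursement(pkgs, tab),
               class = "coursefit_schema_error")
})

test_that("pipeline is idempotent on its own output ordering", {
  fx_path <- system.file("extdata", "paper_packages.csv",
                         package = "coursefit")
  entries <- parse_registry(fx_path)
  res <- filter_registry(entries, filter_config())
  pkgs1 <- expand_and_merge(res$entries, filter_config())
  # permute entries: output must be identical (canonical ordering)
  set.seed(1)
  perm <- res$entries[sample(nrow(res$entries)), , drop = FALSE]
  pkgs2 <- expand_and_merge(perm, filter_config())
  rownames(pkgs2) <- NULL
  expect_identical(pkgs1, pkgs2)
})
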