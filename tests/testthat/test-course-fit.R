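test_that("applicability distinguishes its three failure reasons", {
  penv <- drug_package("Penicillin V", "tablet", 1e6, "IU", 30,
                       divisible = TRUE)
  azi1000 <- drug_package("azithromycin", "tablet", 1000, "mg", 1)
  amox <- drug_package("amoxicillin", "tablet", 500, "mg", 16)

  r_mg <- regimen("IDSA", "sore_throat", "phenoxymethylpenicillin", 250,
                  "mg", 4, 10)
  expect_identical(applicability(penv, r_mg)$reason, "unit_mismatch")

  r_azi <- regimen("ISKRA", "sore_throat", "azithromycin", 500, "mg", 1, 3)
  expect_identical(applicability(azi1000, r_azi)$reason,
                   "dose_not_constructible")

  expect_identical(applicability(amox, r_azi)$reason, "substance_not_named")

  r_amox <- regimen("IDSA", "sore_throat", "amoxicillin", 500, "mg", 2, 10)
  expect_true(applicability(amox, r_amox)$applicable)

  # modified-release products cannot be built from registry solids
  cipro <- drug_package("ciprofloxacin", "tablet", 250, "mg", 10)
  r_er <- regimen("IDSA", "uti", "ciprofloxacin", 1000, "mg", 1, 7,
                  modified_release = TRUE)
  expect_identical(applicability(cipro, r_er)$reason,
                   "dose_not_constructible")
})

test_that("course_units multiplies units per dose over the schedule", {
  tab500 <- formulation("cefuroxime", "tablet", 500, "mg")
  expect_equal(course_units(500, 2, 10, tab500), 20)
  levo <- formulation("levofloxacin", "tablet", 500, "mg", divisible = TRUE)
  expect_equal(course_units(750, 1, 5, levo), 7.5)
  expect_error(course_units(500, 2, 0, tab500),
               class = "coursefit_input_error")
  expect_error(course_units(250, 2, 10, tab500),
               class = "coursefit_input_error")
})

test_that("fit_fixed reproduces published fixed-course cells", {
  coamox14 <- drug_package("Co-amoxiclav", "tablet", 1000, "mg", 14)
  expect_equal(fit_fixed(coamox14, 1000, 2, 7),
               list(min_packages = 1L, extra_units = 0))

  penv <- drug_package("Penicillin V", "tablet", 1e6, "IU", 30,
                       divisible = TRUE)
  expect_equal(fit_fixed(penv, 1.5e6, 3, 10),
               list(min_packages = 2L, extra_units = 15))

  clinda <- drug_package("clindamycin", "capsule", 150, "mg", 16)
  expect_equal(fit_fixed(clinda, 300, 3, 10),
               list(min_packages = 4L, extra_units = 4))

  # exact fill always gives (1, 0)
  cefu <- drug_package("cefuroxime", "tablet", 500, "mg", 20)
  expect_equal(fit_fixed(cefu, 500, 2, 10),
               list(min_packages = 1L, extra_units = 0))
})

test_that("fit_course minimizes leftover over flexible durations and doses", {
  r_flex <- regimen("ISKRA", "uti", "Co-amoxiclav", 1000, "mg", 2, 10, 14)

  f16 <- fit_course(drug_package("Co-amoxiclav", "tablet", 1000, "mg", 16),
                    r_flex)
  expect_equal(f16$chosen_days, 14L)
  expect_equal(f16$min_packages, 2L)
  expect_equal(f16$extra_units, 4)
  expect_false(f16$matched)

  f21 <- fit_course(drug_package("Co-amoxiclav", "tablet", 1000, "mg", 21),
                    r_flex)
  expect_equal(f21$chosen_days, 10L)
  expect_equal(f21$min_packages, 1L)
  expect_equal(f21$extra_units, 1)

  # fewer packages loses to less leftover: 10x250 ciprofloxacin over 7-10
  # days takes 4 packages at 10 days (0 extra), not 3 at 7 days (2 extra)
  cip <- drug_package("ciprofloxacin", "tablet", 250, "mg", 10)
  r_cip <- regimen("ISKRA", "uti", "ciprofloxacin", 500, "mg", 2, 7, 10)
  f_cip <- fit_course(cip, r_cip)
  expect_equal(f_cip$min_packages, 4L)
  expect_equal(f_cip$chosen_days, 10L)
  expect_true(f_cip$matched)

  # dose range: leftover decides the dose, not dose size
  clar <- drug_package("clarithromycin", "tablet", 250, "mg", 14)
  r_nice <- regimen("NICE", "sore_throat", "clarithromycin", c(250, 500),
                    "mg", 2, 5)
  f_nice <- fit_course(clar, r_nice)
  expect_equal(f_nice$chosen_dose, 250)
  expect_equal(f_nice$min_packages, 1L)
  expect_equal(f_nice$extra_units, 4)

  ery <- drug_package("erythromycin", "tablet", 250, "mg", 16)
  r_ery <- regimen("NICE", "sore_throat", "erythromycin", c(500, 1000),
                   "mg", 2, 5)
  f_ery <- fit_course(ery, r_ery)
  expect_equal(f_ery$chosen_dose, 1000)
  expect_equal(f_ery$extra_units, 8)

  # half-tablet splitting yields half-integral leftovers, reported exactly
  levo <- drug_package("levofloxacin", "tablet", 500, "mg", 1,
                       divisible = TRUE)
  f_levo <- fit_course(levo, regimen("IDSA", "uti", "levofloxacin", 750,
                                     "mg", 1, 5))
  expect_identical(f_levo$extra_units, 0.5)
  expect_identical(f_levo$min_packages, 8L)
})

test_that("fit_course equals the brute-force oracle on random instances", {
  set.seed(20180816)
  n_app <- 0
  for (i in 1:1000) {
    inst <- random_instance()
    got <- fit_course(inst$pkg, inst$reg)
    want <- brute_force_oracle(inst$pkg, inst$reg)
    expect_identical(got$applicable, want$applicable)
    if (got$applicable) {
      n_app <- n_app + 1
      expect_identical(got$min_packages, as.integer(want$min_packages))
      expect_equal(got$extra_units, want$extra_units)
      expect_equal(got$chosen_dose, want$chosen_dose)
      expect_identical(got$chosen_days, as.integer(want$chosen_days))
      # structural invariants
      expect_true(got$extra_units >= 0 &&
                    got$extra_units < inst$pkg$units_per_package)
      expect_identical(got$matched, got$extra_units == 0)
      expect_equal(got$min_packages * inst$pkg$units_per_package,
                   got$units_per_course + got$extra_units)
    } else {
      expect_identical(got$reason, want$reason)
    }
  }
  expect_gt(n_app, 400)  # the instance generator must exercise real fits
})

test_that("widening a duration range never increases minimal leftover", {
  set.seed(7)
  for (i in 1:200) {
    inst <- random_instance()
    r <- inst$reg
    wide <- r
    wide$max_days <- r$max_days + 5L
    f1 <- fit_course(inst$pkg, r)
    f2 <- fit_course(inst$pkg, wide)
    if (f1$applicable) expect_lte(f2$extra_units, f1$extra_units)
  }
})

test_that("fixing the chosen dose and duration reproduces the same fit", {
  set.seed(11)
  for (i in 1:200) {
    inst <- random_instance()
    f <- fit_course(inst$pkg, inst$reg)
    if (!f$applicable) next
    fixed <- regimen(inst$reg$source, inst$reg$indication,
                     inst$reg$substance, f$chosen_dose, inst$reg$unit,
                     inst$reg$doses_per_day, f$chosen_days)
    f2 <- fit_course(inst$pkg, fixed)
    expect_equal(f2$min_packages, f$min_packages)
    expect_equal(f2$extra_units, f$extra_units)
  }
})

test_that("policy knobs: duration tiebreak and all_constructible doses", {
  # 10-unit pack, 1 unit twice daily: every day count 1..10 with 2*d <= 10
  # leaves distinct extras; days 5 and 10 both give 0 extra at 1 vs 2 packs
  pkg <- drug_package("drugx", "tablet", 500, "mg", 10)
  r <- regimen("SmPC", "other", "drugx", 500, "mg", 2, 1, 10)
  f_short <- fit_course(pkg, r, fit_policy(duration_tiebreak = "shortest"))
  expect_equal(f_short$chosen_days, 5L)  # fewer packages wins before tiebreak

  # equal extra AND equal packages: 250 mg x 10 days and 500 mg x 5 days
  # both drain one 5x500 pack exactly; the tiebreak decides
  pkg_half <- drug_package("drugx", "tablet", 500, "mg", 5, divisible = TRUE)
  r2 <- regimen("SmPC", "other", "drugx", c(250, 500), "mg", 1, 5, 10)
  f_s <- fit_course(pkg_half, r2, fit_policy(duration_tiebreak = "shortest"))
  f_l <- fit_course(pkg_half, r2, fit_policy(duration_tiebreak = "longest"))
  expect_equal(f_s$extra_units, 0)
  expect_equal(f_l$extra_units, 0)
  expect_equal(c(f_s$chosen_days, f_s$chosen_dose), c(5, 500))
  expect_equal(c(f_l$chosen_days, f_l$chosen_dose), c(10, 250))

  # all_constructible can find an intermediate dose endpoints miss
  pkg2 <- drug_package("drugx", "tablet", 100, "mg", 9)
  r3 <- regimen("SmPC", "other", "drugx", c(100, 500), "mg", 1, 3)
  f_ep <- fit_course(pkg2, r3, fit_policy(dose_candidates = "endpoints"))
  f_all <- fit_course(pkg2, r3,
                      fit_policy(dose_candidates = "all_constructible"))
  expect_gt(f_ep$extra_units, 0)
  expect_equal(f_all$chosen_dose, 300)
  expect_equal(f_all$extra_units, 0)

  expect_error(fit_policy(adherence = 0.8), class = "coursefit_input_error")
})
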