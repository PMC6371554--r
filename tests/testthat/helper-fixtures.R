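# Small in-code fixtures shared across test files.

tiny_packages <- function() {
  rbind(
    drug_package("amoxicillin", "tablet", 500, "mg", 16,
                 atc_code = "J01CA04", reimbursement = "current"),
    drug_package("amoxicillin", "tablet", 500, "mg", 20,
                 atc_code = "J01CA04"),
    drug_package("levofloxacin", "tablet", 500, "mg", 5, divisible = TRUE,
                 atc_code = "J01MA12"),
    drug_package("Penicillin V", "tablet", 1e6, "IU", 30, divisible = TRUE,
                 atc_code = "J01CE02", reimbursement = "former")
  )
}

tiny_regimens <- function() {
  rbind(
    regimen("ISKRA", "sore_throat", "amoxicillin", 500, "mg", 2, 10),
    regimen("IDSA", "uti", "levofloxacin", 750, "mg", 1, 5),
    regimen("IDSA", "sore_throat", "phenoxymethylpenicillin", 250, "mg",
            4, 10)
  )
}

# Random small instances for property tests; deterministic given the RNG
# state set by the caller.
random_instance <- function() {
  strength <- sample(c(100, 125, 250, 500, 1000), 1)
  divisible <- sample(c(TRUE, FALSE), 1)
  pkg <- drug_package("drugx", if (divisible) "tablet" else "capsule",
                      strength, "mg", sample(1:30, 1),
                      divisible = divisible)
  n_opts <- sample(1:2, 1)
  # draw dose options from half/whole multiples of strength, sometimes
  # unconstructible on purpose (odd half-units vs non-divisible)
  mult <- sort(sample(c(0.5, 1, 1.5, 2, 3), n_opts))
  opts <- unique(mult * strength)
  min_d <- sample(1:20, 1)
  reg <- regimen("SmPC", "other", "drugx", opts, "mg",
                 doses_per_day = sample(1:4, 1),
                 min_days = min_d, max_days = min_d + sample(0:10, 1))
  list(pkg = pkg, reg = reg)
}
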