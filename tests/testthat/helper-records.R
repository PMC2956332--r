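# Builders for hand-crafted and randomized participant records.

# One or more baseline records with every flag unanswered and every
# measurement missing, overridable field by field.
make_baseline <- function(n = 1, ...) {
  out <- tibble::tibble(id = paste0("T", seq_len(n)),
                        age = rep(50, n), sex = rep("female", n))
  for (f in lipidtrial:::baseline_flag_cols) out[[f]] <- rep(NA, n)
  for (f in c(lipidtrial:::lipid_cols, "weight", "height")) out[[f]] <- rep(NA_real_, n)
  over <- list(...)
  for (f in names(over)) out[[f]] <- over[[f]]
  out[, baseline_columns()]
}

# A record with every question answered "no" and benign measurements:
# nothing in it triggers any advice rule.
make_healthy <- function(n = 1, ...) {
  args <- list(...)
  flags <- setNames(as.list(rep(FALSE, length(lipidtrial:::baseline_flag_cols))),
                    lipidtrial:::baseline_flag_cols)
  flags$healthy_diet <- TRUE
  flags$regular_exercise <- TRUE
  flags$using_chol_margarine <- TRUE
  base <- c(list(n = n, recent_total_chol = 4.0, weight = 70, height = 180),
            flags)
  base[names(args)] <- args
  do.call(make_baseline, base)
}

# Diverse random records (frequent unanswered flags and missing lipids) for
# round-trip and invariance properties.
random_baseline <- function(n, seed) {
  spec <- cohort_spec(n, flag_answer_rate = 0.7,
                      reporting_rates = c(recent_total_chol = 0.5,
                                          recent_ldl = 0.4, weight = 0.8))
  generate_baseline(spec, seed = seed)
}

random_trial <- function(n, seed) {
  b <- random_baseline(n, seed)
  tr <- randomize_arms(b, seed = seed + 1)
  generate_followup(tr, outcome_spec(), seed = seed + 2)
}

# A minimal two-column eligibility/target rule set built inline, independent
# of the shipped default.
simple_rules <- function(tc_min = 9, tc_max = 5) {
  guideline_rules(
    eligibility = tibble::tibble(name = "everyone", when = list(character(0)),
                                 tc_min = tc_min, ldl_min = NA_real_),
    targets = tibble::tibble(name = "everyone", when = list(character(0)),
                             tc_max = tc_max, ldl_max = NA_real_),
    version_label = "test-rules")
}
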