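# Guideline rule sets.
#
# The trial's advice engine classified participants against the statin
# subsidy eligibility criteria and national lipid-target guidelines current
# at the time (2004 PBS criteria; 2001 CSANZ targets). The contents of those
# documents are not part of this package's sources, so the thresholds live
# entirely in a configurable rule set; the shipped default is a clearly
# labelled synthetic reconstruction of that style of guideline (risk-
# conditioned total-cholesterol / LDL thresholds), not a transcription.

#' Construct a guideline rule set
#'
#' A rule set has two ordered rule lists. *Eligibility rules* decide whether
#' an untreated person qualifies for statin therapy: each rule has a
#' predicate (a set of history/demographic flags, any one of which matches;
#' an empty set matches everyone) and qualifying lipid thresholds — the
#' person qualifies if total cholesterol is at least `tc_min` or LDL at
#' least `ldl_min`. The first rule whose predicate matches governs.
#' *Target rules* decide whether a treated person is controlled: matched the
#' same way, a person is above target if total cholesterol exceeds `tc_max`
#' or LDL exceeds `ldl_max`; a value exactly at the target counts as at
#' target. All thresholds are mmol/L.
#'
#' @param eligibility Tibble with columns `name` (character), `when` (list of
#'   character vectors of flag column names; `character(0)` = unconditional),
#'   `tc_min`, `ldl_min` (numeric, `NA` = not tested).
#' @param targets Tibble with columns `name`, `when`, `tc_max`, `ldl_max`.
#' @param version_label Character label echoed in rendered letters.
#' @return An object of class `guideline_rules`.
#' @seealso [default_guidelines()], [read_guidelines()]
#' @export
guideline_rules <- function(eligibility, targets, version_label) {
  eligibility <- tibble::as_tibble(eligibility)
  targets <- tibble::as_tibble(targets)
  check_rule_table(eligibility, c("tc_min", "ldl_min"), "eligibility")
  check_rule_table(targets, c("tc_max", "ldl_max"), "target")
  stopifnot(is.character(version_label), length(version_label) == 1)
  structure(list(eligibility = eligibility, targets = targets,
                 version_label = version_label),
            class = "guideline_rules")
}

check_rule_table <- function(rules, thr_cols, what) {
  if (!is.data.frame(rules) || nrow(rules) == 0) {
    stop(sprintf("rule set needs at least one %s rule", what), call. = FALSE)
  }
  need <- c("name", "when", thr_cols)
  if (!all(need %in% names(rules))) {
    stop(sprintf("%s rules need columns %s", what, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  for (i in seq_len(nrow(rules))) {
    w <- rules$when[[i]]
    if (length(w) > 0 && !all(w %in% baseline_flag_cols)) {
      stop(sprintf("%s rule '%s' references unknown flag(s): %s", what,
                   rules$name[i],
                   paste(setdiff(w, baseline_flag_cols), collapse = ", ")),
           call. = FALSE)
    }
    thr <- unlist(rules[i, thr_cols])
    if (all(is.na(thr))) {
      stop(sprintf("%s rule '%s' tests no lipid field", what, rules$name[i]),
           call. = FALSE)
    }
    if (any(!is.na(thr) & thr <= 0)) {
      stop(sprintf("%s rule '%s' has a non-positive threshold", what, rules$name[i]),
           call. = FALSE)
    }
  }
  invisible(rules)
}

#' @export
print.guideline_rules <- function(x, ...) {
  cat("Guideline rule set:", x$version_label, "\n")
  cat(sprintf("  %d eligibility rule(s), %d target rule(s); thresholds in mmol/L\n",
              nrow(x$eligibility), nrow(x$targets)))
  invisible(x)
}

#' The shipped default rule set (synthetic reconstruction)
#'
#' A plausible risk-conditioned reconstruction in the style of the
#' mid-2000s Australian guidelines the original advice service used. It is an
#' implementer encoding, not a transcription of any guideline document; swap
#' in your own via [guideline_rules()] or [read_guidelines()] for other
#' vintages.
#'
#' Eligibility (first matching rule governs): secondary prevention
#' (coronary, peripheral-vascular or cerebrovascular disease, or diabetes)
#' qualifies at total cholesterol >= 4.0; diagnosed or suspected familial
#' hypercholesterolemia at >= 5.5 (or LDL >= 4.0); other risk factors
#' (hypertension, smoking, family history of premature coronary disease,
#' aboriginal heritage) at >= 6.5; anyone at >= 7.5. Targets: high-risk
#' (secondary prevention / diabetes) total cholesterol <= 4.0 and
#' LDL <= 2.5; everyone else <= 5.5 and <= 3.5.
#'
#' @return A `guideline_rules` object.
#' @export
default_guidelines <- function() {
  eligibility <- tibble::tibble(
    name = c("secondary_prevention", "familial", "risk_factors", "general_population"),
    when = list(
      c("coronary_heart_disease", "peripheral_vascular_disease",
        "cerebrovascular_disease", "diabetes"),
      c("familial_hypercholesterolemia_dx", "told_genetic_hypercholesterolemia"),
      c("hypertension", "current_smoker", "family_hx_premature_chd",
        "aboriginal_heritage"),
      character(0)
    ),
    tc_min = c(4.0, 5.5, 6.5, 7.5),
    ldl_min = c(NA, 4.0, NA, NA)
  )
  targets <- tibble::tibble(
    name = c("high_risk", "general"),
    when = list(
      c("coronary_heart_disease", "peripheral_vascular_disease",
        "cerebrovascular_disease", "diabetes"),
      character(0)
    ),
    tc_max = c(4.0, 5.5),
    ldl_max = c(2.5, 3.5)
  )
  guideline_rules(eligibility, targets,
                  "synthetic-reconstruction-1 (2004 PBS / 2001 CSANZ vintage)")
}

#' Read / write a guideline rule set as JSON
#'
#' The on-disk form is a JSON object with `version_label` and two rule
#' arrays; each rule is `{name, when: [flag, ...], tc_min/ldl_min}` (or
#' `tc_max`/`ldl_max` for targets), thresholds in mmol/L, `null` = untested.
#' A copy of the shipped default lives at
#' `system.file("extdata", "guidelines-default-synthetic.json", package = "lipidtrial")`.
#'
#' @param path JSON file path.
#' @return `read_guidelines()` a `guideline_rules` object;
#'   `write_guidelines()` `path`, invisibly.
#' @export
read_guidelines <- function(path) {
  if (!file.exists(path)) stop(sprintf("guideline file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  parse_rules <- function(lst, thr_cols) {
    out <- tibble::tibble(
      name = purrr::map_chr(lst, "name"),
      when = purrr::map(lst, ~ as.character(unlist(.x$when))),
      thr1 = purrr::map_dbl(lst, ~ .x[[thr_cols[1]]] %||% NA_real_),
      thr2 = purrr::map_dbl(lst, ~ .x[[thr_cols[2]]] %||% NA_real_)
    )
    names(out)[3:4] <- thr_cols
    out
  }
  guideline_rules(parse_rules(raw$eligibility, c("tc_min", "ldl_min")),
                  parse_rules(raw$targets, c("tc_max", "ldl_max")),
                  raw$version_label)
}

#' @rdname read_guidelines
#' @param rules A `guideline_rules` object.
#' @export
write_guidelines <- function(rules, path) {
  stopifnot(inherits(rules, "guideline_rules"))
  as_list <- function(tbl) {
    purrr::pmap(tbl, function(...) {
      r <- list(...)
      r$when <- as.list(r$when)
      r
    })
  }
  jsonlite::write_json(
    list(version_label = rules$version_label,
         eligibility = as_list(rules$eligibility),
         targets = as_list(rules$targets)),
    path, auto_unbox = TRUE, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

# First-match rule resolution: index of the first rule whose predicate holds
# for each (imputed) record; NA where none matches.
match_rule <- function(data, rules) {
  idx <- rep(NA_integer_, nrow(data))
  for (i in seq_len(nrow(rules))) {
    w <- rules$when[[i]]
    hit <- if (length(w) == 0) {
      rep(TRUE, nrow(data))
    } else {
      Reduce(`|`, lapply(w, function(f) !is.na(data[[f]]) & data[[f]]))
    }
    idx[is.na(idx) & hit] <- i
  }
  idx
}

# Per-record screening total cholesterol: the highest level ever qualifies a
# person, so screening uses the larger of highest-ever and recent TC.
screening_tc <- function(data) {
  pmax(data$highest_total_chol, data$recent_total_chol, na.rm = TRUE)
}

#' Classify statin eligibility against a rule set
#'
#' Applies the eligibility rules to each (already imputed) record: the first
#' rule whose predicate matches is tested against its lipid thresholds.
#' Screening uses the larger of highest-ever and recent total cholesterol
#' (ever-qualifying levels count), and recent LDL where a rule tests LDL.
#' The result is `"eligible"` if any tested lipid reaches its threshold,
#' `"indeterminate"` if the decision needs a lipid value that is missing, and
#' `"not_eligible"` otherwise (including when no rule matches).
#'
#' @param data Imputed baseline tibble (see [impute_missing()]).
#' @param rules A `guideline_rules` object.
#' @return Character vector, one of `eligible`, `not_eligible`,
#'   `indeterminate` per record.
#' @export
classify_eligibility <- function(data, rules) {
  stopifnot(inherits(rules, "guideline_rules"))
  idx <- match_rule(data, rules$eligibility)
  tc <- screening_tc(data)
  ldl <- data$recent_ldl
  out <- rep("not_eligible", nrow(data))
  for (i in unique(idx[!is.na(idx)])) {
    rows <- which(idx == i)
    tc_min <- rules$eligibility$tc_min[i]
    ldl_min <- rules$eligibility$ldl_min[i]
    hit <- miss <- rep(FALSE, length(rows))
    if (!is.na(tc_min)) {
      hit <- hit | (!is.na(tc[rows]) & tc[rows] >= tc_min)
      miss <- miss | is.na(tc[rows])
    }
    if (!is.na(ldl_min)) {
      hit <- hit | (!is.na(ldl[rows]) & ldl[rows] >= ldl_min)
      miss <- miss | is.na(ldl[rows])
    }
    out[rows] <- dplyr::case_when(hit ~ "eligible",
                                  miss ~ "indeterminate",
                                  TRUE ~ "not_eligible")
  }
  out
}

#' Classify lipid-target attainment against a rule set
#'
#' For treated participants: matches each (imputed) record to its first
#' applicable target rule and compares the *recent* lipid values (current
#' control is what matters for targets) to the rule's ceilings. Above target
#' if any tested lipid exceeds its ceiling; a value exactly at the ceiling is
#' at target; indeterminate if the decision needs a missing lipid value.
#'
#' @inheritParams classify_eligibility
#' @return Character vector, one of `at_target`, `above_target`,
#'   `indeterminate` per record.
#' @export
classify_target_attainment <- function(data, rules) {
  stopifnot(inherits(rules, "guideline_rules"))
  idx <- match_rule(data, rules$targets)
  tc <- data$recent_total_chol
  ldl <- data$recent_ldl
  out <- rep("at_target", nrow(data))
  for (i in unique(idx[!is.na(idx)])) {
    rows <- which(idx == i)
    tc_max <- rules$targets$tc_max[i]
    ldl_max <- rules$targets$ldl_max[i]
    above <- miss <- rep(FALSE, length(rows))
    if (!is.na(tc_max)) {
      above <- above | (!is.na(tc[rows]) & tc[rows] > tc_max)
      miss <- miss | is.na(tc[rows])
    }
    if (!is.na(ldl_max)) {
      above <- above | (!is.na(ldl[rows]) & ldl[rows] > ldl_max)
      miss <- miss | is.na(ldl[rows])
    }
    out[rows] <- dplyr::case_when(above ~ "above_target",
                                  miss ~ "indeterminate",
                                  TRUE ~ "at_target")
  }
  out
}
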