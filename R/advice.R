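# The tailored-advice engine. Pure functions of (record, rule set): identical
# input always yields the identical plan and letter.

#' Impute unanswered questionnaire flags as "no"
#'
#' The advice algorithm treats a blank answer to any yes/no question as a
#' "no" — except lipid values, which stay missing: when they are absent the
#' advice is qualified and the participant is asked to have their cholesterol
#' measured rather than assumed to have any particular level. Answered
#' questions are never altered.
#'
#' @param data Baseline tibble.
#' @return The same tibble with every `NA` tri-state flag replaced by `FALSE`;
#'   lipids, weight, height, age and sex untouched.
#' @export
impute_missing <- function(data) {
  dplyr::mutate(data, dplyr::across(dplyr::all_of(baseline_flag_cols),
                                    ~ tidyr::replace_na(.x, FALSE)))
}

#' Familial-tendency flag
#'
#' Flags a likely familial tendency to cholesterol-related disease: total
#' cholesterol (highest-ever or recent) strictly above 9 mmol/L, aboriginal
#' heritage, a personal or family report of genetic hypercholesterolemia, a
#' diagnosed familial hypercholesterolemia, or the conjunction of a family
#' history of premature coronary heart disease with a personal high-
#' cholesterol diagnosis.
#'
#' @param data Imputed baseline tibble.
#' @return Logical vector, one flag per record. Missing lipids never trigger
#'   the lipid arm of the rule.
#' @export
familial_risk <- function(data) {
  tc <- screening_tc(data)
  (!is.na(tc) & tc > 9) |
    data$aboriginal_heritage |
    data$told_genetic_hypercholesterolemia |
    data$familial_hypercholesterolemia_dx |
    (data$family_hx_premature_chd & data$high_cholesterol_dx)
}

#' Nondrug lifestyle recommendations
#'
#' Weight loss if BMI is strictly above 24 and the person is not already
#' trying to lose weight; regular exercise and a healthy diet whenever not
#' already reported; cholesterol-lowering margarine for non-users with a
#' high-cholesterol diagnosis or a positive statin-eligibility finding.
#' An unknown BMI (weight or height missing) never triggers the weight rule.
#'
#' @param data Imputed baseline tibble.
#' @param eligibility Eligibility classification per record, from
#'   [classify_eligibility()].
#' @return Tibble of four logical columns: `rec_weight_loss`, `rec_exercise`,
#'   `rec_diet`, `rec_margarine`.
#' @export
nondrug_recommendations <- function(data, eligibility) {
  stopifnot(length(eligibility) == nrow(data))
  b <- bmi(data$weight, data$height)
  tibble::tibble(
    rec_weight_loss = !is.na(b) & b > 24 & !data$trying_to_lose_weight,
    rec_exercise = !data$regular_exercise,
    rec_diet = !data$healthy_diet,
    rec_margarine = !data$using_chol_margarine &
      (data$high_cholesterol_dx | eligibility == "eligible")
  )
}

drug_labels <- c(start_statin = "Commence statin therapy",
                 increase_statin = "Increase statin therapy",
                 no_change = "No change to lipid-lowering treatment",
                 indeterminate_lipids = "Treatment advice withheld pending lipid measurement")

nondrug_labels <- c(rec_weight_loss = "Weight loss",
                    rec_exercise = "Regular exercise",
                    rec_diet = "Healthy diet",
                    rec_margarine = "Cholesterol-lowering margarine")

#' Generate tailored advice plans
#'
#' The full per-participant advice algorithm. Missing answers are first
#' imputed as "no" (lipids excepted); then untreated participants are
#' screened for statin eligibility and treated participants for lipid-target
#' attainment against the rule set. The drug recommendation is
#' `start_statin` for the untreated eligible, `increase_statin` for the
#' treated above target, `indeterminate_lipids` when the governing
#' classification needs a missing lipid value (with `measure_lipids` set),
#' and `no_change` otherwise. Lifestyle recommendations and the familial-risk
#' flag are attached alongside a human-readable rationale line per triggered
#' rule. Deterministic: the same record and rules always yield the same plan.
#'
#' @param data Raw (unimputed) baseline tibble.
#' @param rules A `guideline_rules` object; defaults to the shipped
#'   synthetic reconstruction.
#' @return Tibble with one row per record: `id`, `drug`, `eligibility`,
#'   `target_status`, the four `rec_*` logicals, `familial_risk`,
#'   `measure_lipids`, and a `rationale` list-column of character vectors.
#' @export
generate_advice <- function(data, rules = default_guidelines()) {
  stopifnot(inherits(rules, "guideline_rules"))
  imp <- impute_missing(data)
  elig <- classify_eligibility(imp, rules)
  targ <- classify_target_attainment(imp, rules)
  treated <- imp$on_lipid_treatment
  drug <- dplyr::case_when(
    !treated & elig == "eligible" ~ "start_statin",
    !treated & elig == "indeterminate" ~ "indeterminate_lipids",
    treated & targ == "above_target" ~ "increase_statin",
    treated & targ == "indeterminate" ~ "indeterminate_lipids",
    TRUE ~ "no_change"
  )
  nd <- nondrug_recommendations(imp, elig)
  fam <- familial_risk(imp)
  out <- tibble::tibble(
    id = imp$id, drug = drug, eligibility = elig, target_status = targ,
    nd, familial_risk = fam,
    measure_lipids = drug == "indeterminate_lipids"
  )
  out$rationale <- rationale_lines(out)
  out
}

rationale_lines <- function(plan) {
  purrr::pmap(plan[, c("drug", names(nondrug_labels), "familial_risk")],
              function(drug, rec_weight_loss, rec_exercise, rec_diet,
                       rec_margarine, familial_risk) {
    lines <- character(0)
    lines <- c(lines, switch(drug,
      start_statin = "You appear to meet the criteria for subsidised cholesterol-lowering (statin) treatment and are not currently treated.",
      increase_statin = "You are on lipid-lowering treatment but your recent cholesterol level is above the recommended target.",
      indeterminate_lipids = "A full assessment of your situation was not possible without your cholesterol values; it would be helpful to have your cholesterol measured.",
      no_change = NULL))
    if (rec_weight_loss) lines <- c(lines, "Your body mass index is above 24 and you are not currently trying to lose weight.")
    if (rec_exercise) lines <- c(lines, "You report that you are not taking regular exercise.")
    if (rec_diet) lines <- c(lines, "You report that you are not eating a cholesterol-lowering diet.")
    if (rec_margarine) lines <- c(lines, "Cholesterol-lowering margarine is recommended for people with raised cholesterol who are not already using it.")
    if (familial_risk) lines <- c(lines, "Your answers suggest a possible familial tendency to high cholesterol; your relatives could also benefit from a cholesterol check.")
    lines
  })
}

#' Render tailored advice letters
#'
#' Plain-text letter per participant listing each recommendation with its
#' rationale, a fixed disclaimer that the advice may not take the full
#' medical history into account, and the rule-set version in the footer.
#' Byte-identical output for identical input.
#'
#' @param plan Advice tibble from [generate_advice()].
#' @param rules The rule set used (for the version footer).
#' @return Tibble with columns `id` and `letter` (one string per letter).
#' @export
render_letters <- function(plan, rules = default_guidelines()) {
  recs <- purrr::pmap_chr(
    plan[, c("drug", names(nondrug_labels), "rationale")],
    function(drug, rec_weight_loss, rec_exercise, rec_diet, rec_margarine,
             rationale) {
      items <- character(0)
      if (drug != "no_change") items <- drug_labels[[drug]]
      nd <- c(rec_weight_loss, rec_exercise, rec_diet, rec_margarine)
      items <- c(items, unname(nondrug_labels[nd]))
      if (length(items) == 0) {
        return("After review of your answers, no change to your current cholesterol management is recommended.\n")
      }
      body <- paste0("  * ", items, collapse = "\n")
      why <- paste0("  - ", rationale, collapse = "\n")
      paste0("Recommendations:\n", body, "\n\nWhy:\n", why, "\n")
    })
  letter <- paste0(
    "Dear participant ", plan$id, ",\n\n",
    "Thank you for completing the cholesterol questionnaire. ",
    "Based on the answers you provided, the following advice was generated for you.\n\n",
    recs, "\n",
    "Please note: this advice may not take into account your full medical history. ",
    "You should discuss these results with your regular doctor.\n\n",
    "Guideline rule set: ", rules$version_label, "\n")
  tibble::tibble(id = plan$id, letter = letter)
}
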