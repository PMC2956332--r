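# Trial orchestration: randomization, advice application, the
# intention-to-treat outcome table, the baseline characteristics table, and
# the end-to-end simulate -> randomize -> advise -> follow up -> analyze run.

#' Randomize participants 1:1
#'
#' Simple unrestricted randomization: each participant is independently
#' assigned to intervention or control with probability one half, with no
#' stratification or blocking — a large trial balances itself, and
#' unrestricted allocation is consistent with the unequal arm sizes such
#' trials end with. The assignment is a pure function of the seed and the
#' participant order.
#'
#' @param data Baseline tibble (non-empty).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param p_intervention Allocation probability (default 0.5).
#' @return Trial tibble: `data` plus an `arm` column and empty follow-up
#'   columns.
#' @export
randomize_arms <- function(data, seed = NULL, p_intervention = 0.5) {
  if (nrow(data) == 0) stop("cannot randomize an empty cohort", call. = FALSE)
  arms <- with_seed_if(seed, {
    tibble::tibble(id = data$id,
                   arm = ifelse(runif(nrow(data)) < p_intervention,
                                "intervention", "control"))
  })
  as_trial(data, arms)
}

#' Apply the intervention to a randomized trial
#'
#' Intervention-arm participants receive their full tailored advice plan
#' immediately. Control-arm participants receive only generic links at
#' baseline — a marker plan with no tailored content — and their full plan
#' only at study completion (`stage = "completion"`).
#'
#' @param trial Trial tibble with arms assigned.
#' @param rules A `guideline_rules` object.
#' @param stage `"baseline"` (default) or `"completion"`.
#' @return Advice tibble (as [generate_advice()]) plus `arm` and `plan_type`
#'   (`"tailored"` or `"generic_links"`); tailored columns are `NA` in
#'   generic rows.
#' @export
apply_intervention <- function(trial, rules = default_guidelines(),
                               stage = c("baseline", "completion")) {
  stage <- match.arg(stage)
  if (nrow(trial) == 0) {
    out <- generate_advice(trial[, baseline_cols], rules)
    out$arm <- character(0)
    out$plan_type <- character(0)
    return(out)
  }
  if (any(is.na(trial$arm))) stop("arms must be assigned first", call. = FALSE)
  plan <- generate_advice(trial[, baseline_cols], rules)
  plan$arm <- trial$arm
  tailored <- stage == "completion" | trial$arm == "intervention"
  plan$plan_type <- ifelse(tailored, "tailored", "generic_links")
  mask <- !tailored
  plan$drug[mask] <- NA
  plan$eligibility[mask] <- NA
  plan$target_status[mask] <- NA
  for (f in names(nondrug_labels)) plan[[f]][mask] <- NA
  plan$familial_risk[mask] <- NA
  plan$measure_lipids[mask] <- NA
  plan$rationale[mask] <- list(character(0))
  plan
}

itt_outcomes <- function() {
  c("primary", followup_flag_cols)
}

#' Intention-to-treat outcome table
#'
#' One two-group contrast per binary outcome. Numerators count responders
#' reporting the event; denominators are *all randomized* in each arm, so
#' non-responders count as event-free. The primary outcome is commenced OR
#' increased lipid-lowering treatment. In `display = "paper"` mode
#' percentages are rounded to one decimal and the printed difference is the
#' difference of the rounded percentages (a common reporting convention);
#' the default reports everything at full precision.
#'
#' @param trial Trial tibble with arms and follow-up columns.
#' @param conf_level Confidence level for the Wald intervals.
#' @param display `"full"` (default) or `"paper"`.
#' @return A tibble of class `itt_table`: one row per outcome with counts,
#'   percentages, difference, interval, chi-square and p-value.
#' @export
itt_outcome_table <- function(trial, conf_level = 0.95,
                              display = c("full", "paper")) {
  display <- match.arg(display)
  if (any(is.na(trial$arm))) stop("arms must be assigned first", call. = FALSE)
  event <- function(col) tidyr::replace_na(trial[[col]] & trial$fu_responded, FALSE)
  events <- purrr::map(setNames(paste0("fu_", followup_flag_cols),
                                followup_flag_cols), event)
  events <- c(list(primary = events$commenced_treatment | events$increased_treatment),
              events)
  is_int <- trial$arm == "intervention"
  n1 <- sum(is_int)
  n2 <- sum(!is_int)
  rows <- purrr::imap(events, function(ev, nm) {
    cmp <- proportion_difference(sum(ev[is_int]), n1, sum(ev[!is_int]), n2,
                                 conf_level = conf_level)
    dplyr::bind_cols(tibble::tibble(outcome = nm), tidy(cmp))
  })
  out <- dplyr::bind_rows(rows)
  if (display == "paper") {
    out <- dplyr::mutate(out,
      p1_pct = round(.data$p1_pct, 1), p2_pct = round(.data$p2_pct, 1),
      diff_pct = round(.data$p1_pct - .data$p2_pct, 1),
      ci_low_pct = round(.data$ci_low_pct, 2),
      ci_high_pct = round(.data$ci_high_pct, 2),
      p_value = round(.data$p_value, 2))
  }
  class(out) <- c("itt_table", class(out))
  out
}

#' Baseline characteristics table
#'
#' Per-arm summaries of every baseline field: count (percentage of the arm)
#' for categorical fields, mean, SD and n for continuous fields (including
#' derived BMI), plus a "number with data" column counting non-missing
#' answers. Two derived rows reuse the advice-engine classifiers: untreated
#' participants indicated for treatment, and treated participants not
#' reaching target (each computed on imputed records; lipid-indeterminate
#' records do not count, mirroring a qualified assessment).
#'
#' @param trial Trial tibble with arms assigned.
#' @param rules A `guideline_rules` object for the derived rows.
#' @return Tibble: `variable`, `kind` (`n_pct` / `mean_sd`),
#'   `number_with_data`, and per-arm `*_n`, `*_count`, `*_pct`, `*_mean`,
#'   `*_sd` columns (`int_` = intervention, `ctl_` = control).
#' @export
baseline_table <- function(trial, rules = default_guidelines()) {
  if (any(is.na(trial$arm))) stop("arms must be assigned first", call. = FALSE)
  is_int <- trial$arm == "intervention"
  n_int <- sum(is_int)
  n_ctl <- sum(!is_int)

  flag_row <- function(name, values) {
    tibble::tibble(
      variable = name, kind = "n_pct",
      number_with_data = sum(!is.na(values)),
      int_n = n_int, int_count = sum(values[is_int], na.rm = TRUE),
      int_pct = 100 * sum(values[is_int], na.rm = TRUE) / n_int,
      ctl_n = n_ctl, ctl_count = sum(values[!is_int], na.rm = TRUE),
      ctl_pct = 100 * sum(values[!is_int], na.rm = TRUE) / n_ctl,
      int_mean = NA_real_, int_sd = NA_real_,
      ctl_mean = NA_real_, ctl_sd = NA_real_)
  }
  num_row <- function(name, values) {
    vi <- values[is_int]; vc <- values[!is_int]
    tibble::tibble(
      variable = name, kind = "mean_sd",
      number_with_data = sum(!is.na(values)),
      int_n = sum(!is.na(vi)), int_count = NA_integer_, int_pct = NA_real_,
      ctl_n = sum(!is.na(vc)), ctl_count = NA_integer_, ctl_pct = NA_real_,
      int_mean = mean(vi, na.rm = TRUE), int_sd = sd(vi, na.rm = TRUE),
      ctl_mean = mean(vc, na.rm = TRUE), ctl_sd = sd(vc, na.rm = TRUE))
  }

  imp <- impute_missing(trial[, baseline_cols])
  elig <- classify_eligibility(imp, rules)
  targ <- classify_target_attainment(imp, rules)
  untreated_indicated <- !imp$on_lipid_treatment & elig == "eligible"
  treated_above <- imp$on_lipid_treatment & targ == "above_target"
  # "with data" for the derived rows = records whose classification resolved
  resolved_elig <- !imp$on_lipid_treatment & elig != "indeterminate"
  resolved_targ <- !(imp$on_lipid_treatment & targ == "indeterminate")

  derived_row <- function(name, values, with_data) {
    row <- flag_row(name, values)
    row$number_with_data <- sum(with_data)
    row
  }

  dplyr::bind_rows(
    flag_row("male", trial$sex == "male"),
    purrr::map(baseline_flag_cols, ~ flag_row(.x, trial[[.x]])),
    derived_row("untreated_indicated_for_treatment", untreated_indicated, resolved_elig),
    derived_row("on_treatment_not_at_target", treated_above, resolved_targ),
    num_row("age", trial$age),
    num_row("weight", trial$weight),
    num_row("height", trial$height),
    num_row("bmi", bmi(trial$weight, trial$height)),
    purrr::map(lipid_cols, ~ num_row(.x, trial[[.x]]))
  )
}

#' Configure an end-to-end simulated trial run
#'
#' @param seed Master integer seed; every random stage derives its own seed
#'   from it, so a fixed config reproduces the run byte for byte.
#' @param cohort A [cohort_spec()].
#' @param outcomes An [outcome_spec()].
#' @param rules A `guideline_rules` object, or a path to a JSON rule file.
#' @param conf_level Confidence level for all intervals.
#' @param display `"full"` or `"paper"` (see [itt_outcome_table()]).
#' @param out_dir Output directory (created if absent).
#' @param write_letters Write the intervention arm's tailored letters.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(seed, cohort = cohort_spec(2099),
                         outcomes = outcome_spec(),
                         rules = default_guidelines(),
                         conf_level = 0.95, display = "full",
                         out_dir = tempfile("trialrun"),
                         write_letters = TRUE) {
  if (is.character(rules)) {
    if (!file.exists(rules)) {
      stop(sprintf("configuration error: guideline rule-set path '%s' does not exist", rules),
           call. = FALSE)
    }
    rules <- read_guidelines(rules)
  }
  stopifnot(inherits(cohort, "cohort_spec"), inherits(outcomes, "outcome_spec"),
            inherits(rules, "guideline_rules"),
            is.numeric(seed), length(seed) == 1,
            conf_level > 0, conf_level < 1, display %in% c("full", "paper"))
  structure(list(seed = as.integer(seed), cohort = cohort, outcomes = outcomes,
                 rules = rules, conf_level = conf_level, display = display,
                 out_dir = out_dir, write_letters = isTRUE(write_letters)),
            class = "trial_config")
}

stage_seed <- function(seed, k) (seed * 7L + k) %% 2000000011L

#' Run the full simulated trial pipeline
#'
#' Executes simulate -> randomize -> advise -> follow up -> analyze and
#' writes `trial.csv`, `baseline_table.csv`, `outcome_table.csv`, tailored
#' `letters.txt` for the intervention arm (optional), and a `manifest.json`
#' recording the seeds, stage order and package version. A fixed config
#' reproduces identical outputs. Any stage failure aborts with the stage
#' name and cause.
#'
#' @param config A [trial_config()].
#' @return Invisibly, a list with the trial tibble, the two tables, the
#'   advice plans and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  baseline <- run_stage("simulate",
                        generate_baseline(config$cohort, seed = stage_seed(config$seed, 1L)))
  trial <- run_stage("randomize",
                     randomize_arms(baseline, seed = stage_seed(config$seed, 2L)))
  plans <- run_stage("advise", apply_intervention(trial, config$rules))
  trial <- run_stage("followup",
                     generate_followup(trial, config$outcomes,
                                       seed = stage_seed(config$seed, 3L)))
  base_tab <- run_stage("baseline_table", baseline_table(trial, config$rules))
  out_tab <- run_stage("analyze",
                       itt_outcome_table(trial, conf_level = config$conf_level,
                                         display = config$display))
  run_stage("write", {
    write_trial_csv(trial, file.path(config$out_dir, "trial.csv"))
    readr::write_csv(base_tab, file.path(config$out_dir, "baseline_table.csv"),
                     progress = FALSE)
    readr::write_csv(dplyr::select(out_tab, -dplyr::any_of("rationale")),
                     file.path(config$out_dir, "outcome_table.csv"),
                     progress = FALSE)
    if (config$write_letters) {
      tailored <- plans[plans$plan_type == "tailored", ]
      letters <- render_letters(tailored, config$rules)
      writeLines(paste(letters$letter, collapse = "\n----\n\n"),
                 file.path(config$out_dir, "letters.txt"))
    }
    manifest <- list(
      package = "lipidtrial",
      version = as.character(utils::packageVersion("lipidtrial")),
      seed = config$seed,
      stage_seeds = list(simulate = stage_seed(config$seed, 1L),
                         randomize = stage_seed(config$seed, 2L),
                         followup = stage_seed(config$seed, 3L)),
      n = config$cohort$n,
      conf_level = config$conf_level,
      display = config$display,
      rule_set = config$rules$version_label,
      stages = c("simulate", "randomize", "advise", "followup", "analyze", "write"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(list(trial = trial, baseline_table = base_tab,
                 outcome_table = out_tab, plans = plans,
                 out_dir = config$out_dir))
}
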