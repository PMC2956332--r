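#' @importFrom rlang .data %||%
#' @importFrom stats pchisq pnorm qnorm qt rbinom rlnorm runif sd setNames
#' @importFrom utils head
NULL

# Column inventories for the three record types. Tri-state questionnaire flags
# are stored as logical: TRUE = yes, FALSE = no, NA = unanswered. The
# "assume-no" imputation is a separate, observable step (impute_missing()),
# never applied at read time.

baseline_flag_cols <- c(
  "high_cholesterol_dx", "hypertension", "diabetes",
  "coronary_heart_disease", "peripheral_vascular_disease",
  "cerebrovascular_disease", "familial_hypercholesterolemia_dx",
  "told_genetic_hypercholesterolemia", "family_hx_premature_chd",
  "aboriginal_heritage", "current_smoker", "healthy_diet",
  "trying_to_lose_weight", "regular_exercise", "using_chol_margarine",
  "on_lipid_treatment"
)

lipid_cols <- c(
  "highest_total_chol", "recent_total_chol", "recent_ldl",
  "recent_hdl", "recent_triglyceride"
)

baseline_num_cols <- c("age", lipid_cols, "weight", "height")

baseline_cols <- c("id", "age", "sex", baseline_flag_cols,
                   lipid_cols, "weight", "height")

followup_flag_cols <- c(
  "commenced_treatment", "increased_treatment",
  "discussed_with_professional", "cholesterol_checked",
  "commenced_diet", "commenced_weight_loss", "commenced_exercise",
  "commenced_margarine", "stopped_smoking", "bp_checked", "referred_friend"
)

followup_num_cols <- c(
  "weeks_to_response", "n_friends_visited",
  "recent_total_chol", "recent_ldl", "recent_hdl", "recent_triglyceride",
  "current_weight"
)

followup_cols <- c("id", "responded", followup_flag_cols, followup_num_cols)

# Trial table = baseline columns + arm + follow-up columns prefixed "fu_"
# (avoids lipid-name clashes between the two questionnaires).
trial_cols <- function() {
  c(baseline_cols, "arm",
    paste0("fu_", setdiff(followup_cols, "id")))
}

#' Body mass index from weight and height
#'
#' BMI in kg/m^2 from weight in kilograms and height in centimetres. BMI is
#' always derived, never stored: the questionnaire collects weight and height.
#' Missing inputs propagate to a missing BMI.
#'
#' @param weight_kg Numeric vector of weights (kg).
#' @param height_cm Numeric vector of heights (cm).
#' @return Numeric vector of BMI values (kg/m^2), `NA` where either input is
#'   missing.
#' @examples
#' bmi(77.3, 170)
#' bmi(c(80, NA), c(200, 170))
#' @export
bmi <- function(weight_kg, height_cm) {
  weight_kg / (height_cm / 100)^2
}

#' Add a derived BMI column to a baseline table
#'
#' @param data A baseline tibble with `weight` and `height` columns.
#' @return `data` with a `bmi` column (kg/m^2) appended.
#' @export
add_bmi <- function(data) {
  dplyr::mutate(data, bmi = bmi(.data$weight, .data$height))
}

# --- parsing helpers ---------------------------------------------------------

# yes/no/"" -> TRUE/FALSE/NA; anything else is a row-level error.
parse_tristate <- function(x, field) {
  x <- trimws(x)
  bad <- which(!is.na(x) & x != "" & !(tolower(x) %in% c("yes", "no")))
  if (length(bad) > 0) {
    stop(sprintf("invalid tri-state value %s in row %d, field '%s' (expected yes/no/empty)",
                 dQuote(x[bad[1]]), bad[1], field), call. = FALSE)
  }
  out <- rep(NA, length(x))
  out[!is.na(x) & tolower(x) == "yes"] <- TRUE
  out[!is.na(x) & tolower(x) == "no"] <- FALSE
  as.logical(out)
}

parse_numeric <- function(x, field) {
  x <- trimws(x)
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("malformed numeric value %s in row %d, field '%s'",
                 dQuote(x[bad[1]]), bad[1], field), call. = FALSE)
  }
  out
}

check_schema <- function(found, expected, what) {
  extra <- setdiff(found, expected)
  missing <- setdiff(expected, found)
  if (length(extra) > 0 || length(missing) > 0) {
    stop(sprintf("%s schema mismatch: unknown column(s) %s; missing column(s) %s",
                 what,
                 if (length(extra)) paste(extra, collapse = ", ") else "<none>",
                 if (length(missing)) paste(missing, collapse = ", ") else "<none>"),
         call. = FALSE)
  }
  invisible(TRUE)
}

read_raw_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE, show_col_types = FALSE)
}

# --- baseline ----------------------------------------------------------------

#' Validate a baseline questionnaire table
#'
#' Checks the participant-level invariants: ids unique and non-empty, age at
#' least 18 (the trial was open to adults only), sex one of male/female when
#' given, and all lipid, weight and height values strictly positive when
#' present.
#'
#' @param data Baseline tibble.
#' @return `data`, invisibly, if valid; otherwise an error naming the first
#'   offending row and field.
#' @export
validate_baseline <- function(data) {
  check_schema(names(data), baseline_cols, "baseline")
  if (anyDuplicated(data$id)) stop("duplicate participant id", call. = FALSE)
  if (any(data$id == "" | is.na(data$id))) stop("empty participant id", call. = FALSE)
  bad_age <- which(!is.na(data$age) & data$age < 18)
  if (length(bad_age) > 0) {
    stop(sprintf("age below 18 in row %d (trial open to adults only)", bad_age[1]),
         call. = FALSE)
  }
  bad_sex <- which(!is.na(data$sex) & !(data$sex %in% c("male", "female")))
  if (length(bad_sex) > 0) {
    stop(sprintf("invalid sex %s in row %d", dQuote(data$sex[bad_sex[1]]), bad_sex[1]),
         call. = FALSE)
  }
  for (f in c(lipid_cols, "weight", "height")) {
    bad <- which(!is.na(data[[f]]) & data[[f]] <= 0)
    if (length(bad) > 0) {
      stop(sprintf("non-positive value in row %d, field '%s'", bad[1], f),
           call. = FALSE)
    }
  }
  invisible(data)
}

#' Read a baseline questionnaire CSV
#'
#' One row per participant; empty cells are missing; tri-state history and
#' lifestyle flags parse yes/no/empty. The file must carry exactly the
#' documented header (see `baseline_columns()`).
#'
#' @param path Path to a comma-separated, UTF-8, headered file.
#' @return A validated baseline tibble.
#' @seealso [write_baseline_csv()], [validate_baseline()]
#' @export
read_baseline_csv <- function(path) {
  raw <- read_raw_csv(path)
  check_schema(names(raw), baseline_cols, "baseline")
  out <- tibble::tibble(id = as.character(raw$id), age = parse_numeric(raw$age, "age"),
                        sex = dplyr::na_if(trimws(raw$sex), ""))
  for (f in baseline_flag_cols) out[[f]] <- parse_tristate(raw[[f]], f)
  for (f in c(lipid_cols, "weight", "height")) out[[f]] <- parse_numeric(raw[[f]], f)
  out <- out[, baseline_cols]
  validate_baseline(out)
  out
}

#' Documented column inventories
#'
#' The exact CSV headers used by the readers and writers, in order.
#' @return Character vector of column names.
#' @export
baseline_columns <- function() baseline_cols

#' @rdname baseline_columns
#' @export
followup_columns <- function() followup_cols

#' @rdname baseline_columns
#' @export
trial_columns <- function() trial_cols()

fmt_cell <- function(x) {
  if (is.logical(x)) {
    dplyr::case_when(is.na(x) ~ "", x ~ "yes", TRUE ~ "no")
  } else if (is.numeric(x)) {
    ifelse(is.na(x), "", vapply(x, format, "", digits = 15))
  } else {
    ifelse(is.na(x), "", as.character(x))
  }
}

write_record_csv <- function(data, path, cols) {
  out <- purrr::map_dfc(setNames(cols, cols), function(f) fmt_cell(data[[f]]))
  # empty table still gets its header row
  if (nrow(data) == 0) out <- tibble::as_tibble(setNames(as.list(rep("", length(cols))), cols))[0, ]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write baseline / follow-up / trial tables to CSV
#'
#' Inverse of the readers: comma-separated UTF-8, header row, `yes`/`no` for
#' answered flags and empty cells for missing values, so that
#' `read_*(write_*(x))` reproduces `x` exactly, including missingness.
#'
#' @param data Table of the matching type.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_baseline_csv <- function(data, path) {
  write_record_csv(data, path, baseline_cols)
}

# --- follow-up ---------------------------------------------------------------

#' Validate a follow-up outcome table
#'
#' Invariants: response latency is present exactly for responders; outcome
#' flags are absent for non-responders; no participant both commenced and
#' increased treatment (commencement applies to the untreated, an increase to
#' the treated).
#'
#' @param data Follow-up tibble.
#' @return `data`, invisibly, if valid.
#' @export
validate_followup <- function(data) {
  check_schema(names(data), followup_cols, "followup")
  bad <- which(xor(!is.na(data$weeks_to_response), data$responded))
  if (length(bad) > 0) {
    stop(sprintf("row %d: weeks_to_response must be present exactly when responded", bad[1]),
         call. = FALSE)
  }
  for (f in followup_flag_cols) {
    bad <- which(!data$responded & !is.na(data[[f]]))
    if (length(bad) > 0) {
      stop(sprintf("row %d: outcome '%s' reported by a non-responder", bad[1], f),
           call. = FALSE)
    }
  }
  both <- which(!is.na(data$commenced_treatment) & !is.na(data$increased_treatment) &
                  data$commenced_treatment & data$increased_treatment)
  if (length(both) > 0) {
    stop(sprintf("row %d: commenced and increased treatment are mutually exclusive", both[1]),
         call. = FALSE)
  }
  invisible(data)
}

#' Read a follow-up outcome CSV
#' @inheritParams read_baseline_csv
#' @return A validated follow-up tibble.
#' @export
read_followup_csv <- function(path) {
  raw <- read_raw_csv(path)
  check_schema(names(raw), followup_cols, "followup")
  out <- tibble::tibble(id = as.character(raw$id),
                        responded = parse_tristate(raw$responded, "responded"))
  for (f in followup_flag_cols) out[[f]] <- parse_tristate(raw[[f]], f)
  for (f in followup_num_cols) out[[f]] <- parse_numeric(raw[[f]], f)
  out <- out[, followup_cols]
  validate_followup(out)
  out
}

#' @rdname write_baseline_csv
#' @export
write_followup_csv <- function(data, path) {
  write_record_csv(data, path, followup_cols)
}

# --- trial -------------------------------------------------------------------

#' Assemble a trial table from baseline, arm assignments and follow-up
#'
#' Joins the three pieces by participant id into the single flat trial table
#' used by the analysis functions; follow-up columns are prefixed `fu_`.
#'
#' @param baseline Baseline tibble.
#' @param arms Tibble with columns `id` and `arm`
#'   (`"intervention"`/`"control"`), e.g. from [randomize_arms()].
#' @param followup Follow-up tibble, or `NULL` before follow-up exists.
#' @return A trial tibble with one row per randomized participant.
#' @export
as_trial <- function(baseline, arms, followup = NULL) {
  validate_baseline(baseline)
  stopifnot(all(c("id", "arm") %in% names(arms)))
  if (!all(arms$arm %in% c("intervention", "control"))) {
    stop("arm must be 'intervention' or 'control'", call. = FALSE)
  }
  if (is.null(followup)) {
    followup <- tibble::tibble(id = baseline$id, responded = FALSE)
    for (f in followup_flag_cols) followup[[f]] <- NA
    for (f in followup_num_cols) followup[[f]] <- NA_real_
    followup$responded <- NA  # no follow-up stage yet
  }
  fu <- dplyr::rename_with(followup, ~ paste0("fu_", .x), -"id")
  out <- dplyr::left_join(baseline, arms[, c("id", "arm")], by = "id")
  out <- dplyr::left_join(out, fu, by = "id")
  if (any(is.na(out$arm))) stop("every participant needs an arm assignment", call. = FALSE)
  out[, trial_cols()]
}

#' Read / write the flat trial CSV
#'
#' The trial table is the baseline table plus an `arm` column and the
#' follow-up columns prefixed `fu_`. Round-trips losslessly.
#'
#' @inheritParams read_baseline_csv
#' @return A trial tibble.
#' @export
read_trial_csv <- function(path) {
  raw <- read_raw_csv(path)
  check_schema(names(raw), trial_cols(), "trial")
  out <- tibble::tibble(id = as.character(raw$id), age = parse_numeric(raw$age, "age"),
                        sex = dplyr::na_if(trimws(raw$sex), ""))
  for (f in baseline_flag_cols) out[[f]] <- parse_tristate(raw[[f]], f)
  for (f in c(lipid_cols, "weight", "height")) out[[f]] <- parse_numeric(raw[[f]], f)
  out$arm <- dplyr::na_if(trimws(raw$arm), "")
  out$fu_responded <- parse_tristate(raw$fu_responded, "fu_responded")
  for (f in followup_flag_cols) out[[paste0("fu_", f)]] <- parse_tristate(raw[[paste0("fu_", f)]], paste0("fu_", f))
  for (f in followup_num_cols) out[[paste0("fu_", f)]] <- parse_numeric(raw[[paste0("fu_", f)]], paste0("fu_", f))
  out[, trial_cols()]
}

#' @rdname write_baseline_csv
#' @export
write_trial_csv <- function(data, path) {
  write_record_csv(data, path, trial_cols())
}
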