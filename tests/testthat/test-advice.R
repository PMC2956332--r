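test_that("unanswered questions are assumed negative, lipids excepted", {
  rec <- make_baseline(recent_total_chol = NA_real_, hypertension = TRUE)
  imp <- impute_missing(rec)
  expect_false(imp$diabetes)
  expect_false(imp$on_lipid_treatment)
  expect_true(imp$hypertension)          # answered questions unchanged
  expect_true(is.na(imp$recent_total_chol))
  full <- make_healthy()
  expect_equal(impute_missing(full), full)  # fully answered record untouched
})

test_that("the familial-tendency rule triggers on its published components", {
  yes <- function(...) {
    rec <- impute_missing(make_healthy(...))
    familial_risk(rec)
  }
  expect_true(yes(highest_total_chol = 9.5))
  expect_false(yes(highest_total_chol = 9.0))    # strictly above 9
  expect_true(yes(recent_total_chol = 9.5))
  expect_true(yes(aboriginal_heritage = TRUE))
  expect_true(yes(told_genetic_hypercholesterolemia = TRUE))
  expect_true(yes(familial_hypercholesterolemia_dx = TRUE))
  # family history alone is not enough: it needs the personal diagnosis too
  expect_false(yes(family_hx_premature_chd = TRUE))
  expect_true(yes(family_hx_premature_chd = TRUE, high_cholesterol_dx = TRUE))
  expect_false(yes())                             # nothing triggers
  expect_false(yes(highest_total_chol = NA_real_, recent_total_chol = NA_real_))
})

test_that("lifestyle recommendations follow their strict thresholds", {
  nd <- function(...) {
    rec <- impute_missing(make_healthy(...))
    nondrug_recommendations(rec, classify_eligibility(rec, default_guidelines()))
  }
  r <- nd(weight = 77.3, height = 170, trying_to_lose_weight = FALSE)
  expect_true(r$rec_weight_loss)   # BMI 26.75 > 24, not trying
  r <- nd(weight = 96, height = 200, trying_to_lose_weight = FALSE)
  expect_false(r$rec_weight_loss)  # BMI exactly 24: strict inequality
  r <- nd(weight = 77.3, height = 170, trying_to_lose_weight = TRUE)
  expect_false(r$rec_weight_loss)
  r <- nd(weight = NA_real_)
  expect_false(r$rec_weight_loss)  # unknown BMI never triggers
  r <- nd()
  expect_false(any(unlist(r)))     # healthy record: empty set
  r <- nd(healthy_diet = FALSE, regular_exercise = FALSE)
  expect_true(r$rec_diet && r$rec_exercise)
  # margarine needs a reason: diagnosis or positive eligibility
  r <- nd(using_chol_margarine = FALSE)
  expect_false(r$rec_margarine)
  r <- nd(using_chol_margarine = FALSE, high_cholesterol_dx = TRUE)
  expect_true(r$rec_margarine)
  r <- nd(using_chol_margarine = FALSE, coronary_heart_disease = TRUE,
          recent_total_chol = 6.7)
  expect_true(r$rec_margarine)     # eligibility-driven
})

test_that("the advice plan integrates drug, lifestyle and familial rules", {
  plan <- generate_advice(make_healthy(coronary_heart_disease = TRUE,
                                       recent_total_chol = 6.7))
  expect_equal(plan$drug, "start_statin")
  expect_false(plan$measure_lipids)
  expect_gt(length(plan$rationale[[1]]), 0)

  plan <- generate_advice(make_baseline(on_lipid_treatment = TRUE))
  expect_equal(plan$drug, "indeterminate_lipids")
  expect_true(plan$measure_lipids)

  plan <- generate_advice(make_healthy(on_lipid_treatment = TRUE,
                                       coronary_heart_disease = TRUE,
                                       recent_total_chol = 6.0))
  expect_equal(plan$drug, "increase_statin")

  plan <- generate_advice(make_healthy())
  expect_equal(plan$drug, "no_change")
  expect_false(any(unlist(plan[, paste0("rec_", c("weight_loss", "exercise",
                                                  "diet", "margarine"))])))
  expect_equal(length(plan$rationale[[1]]), 0)
})

test_that("advice is a pure function of record and rules", {
  recs <- random_baseline(100, seed = 5)
  p1 <- generate_advice(recs)
  p2 <- generate_advice(recs)
  expect_identical(p1, p2)
  l1 <- render_letters(p1)
  l2 <- render_letters(p2)
  expect_identical(l1$letter, l2$letter)
})

test_that("answering 'no' explicitly matches leaving the answer blank", {
  recs <- random_baseline(150, seed = 23)
  explicit <- dplyr::mutate(recs, dplyr::across(
    dplyr::all_of(lipidtrial:::baseline_flag_cols),
    ~ tidyr::replace_na(.x, FALSE)))
  expect_equal(generate_advice(recs), generate_advice(explicit))
  # and field by field, flipping one blank to an explicit no at a time
  rec <- make_baseline(recent_total_chol = 6.0, weight = 90, height = 170)
  for (f in lipidtrial:::baseline_flag_cols) {
    one <- rec
    one[[f]] <- FALSE
    expect_equal(generate_advice(one), generate_advice(rec), label = f)
  }
})

test_that("every hypothetical scenario in the tri-state grid yields a valid plan", {
  # exhaustive cross-product over the seven decision-driving flags, at three
  # lipid configurations each
  flags <- c("on_lipid_treatment", "coronary_heart_disease", "diabetes",
             "high_cholesterol_dx", "family_hx_premature_chd",
             "told_genetic_hypercholesterolemia", "aboriginal_heritage")
  states <- list(TRUE, FALSE, NA)
  grid <- do.call(tidyr::expand_grid, setNames(rep(list(c(TRUE, FALSE, NA)),
                                                   length(flags)), flags))
  lipid_cases <- list(list(recent_total_chol = 6.7, recent_ldl = 3.5),
                      list(recent_total_chol = 4.0, recent_ldl = 2.0),
                      list(recent_total_chol = NA_real_, recent_ldl = NA_real_))
  for (lip in lipid_cases) {
    recs <- make_baseline(n = nrow(grid))
    for (f in flags) recs[[f]] <- grid[[f]]
    recs$recent_total_chol <- lip$recent_total_chol
    recs$recent_ldl <- lip$recent_ldl
    plan <- generate_advice(recs)
    expect_equal(nrow(plan), nrow(grid))
    expect_true(all(plan$drug %in% c("start_statin", "increase_statin",
                                     "no_change", "indeterminate_lipids")))
    # plan-level invariants
    expect_true(all(plan$measure_lipids[plan$drug == "indeterminate_lipids"]))
    treated <- tidyr::replace_na(recs$on_lipid_treatment, FALSE)
    expect_true(all(treated[plan$drug == "increase_statin"]))
    expect_true(all(!treated[plan$drug == "start_statin"]))
    needs_rationale <- plan$drug != "no_change" | plan$familial_risk |
      plan$rec_weight_loss | plan$rec_exercise | plan$rec_diet | plan$rec_margarine
    expect_true(all(lengths(plan$rationale)[needs_rationale] > 0))
  }
})

test_that("letters carry the recommendations, rationale and disclaimer", {
  plan <- generate_advice(make_healthy(coronary_heart_disease = TRUE,
                                       recent_total_chol = 6.7,
                                       using_chol_margarine = FALSE))
  letter <- render_letters(plan)$letter
  expect_match(letter, "Commence statin therapy")
  expect_match(letter, "Cholesterol-lowering margarine")
  expect_match(letter, "may not take into account your full medical history")
  expect_match(letter, "synthetic-reconstruction", fixed = TRUE)

  quiet <- render_letters(generate_advice(make_healthy()))$letter
  expect_no_match(quiet, "statin therapy")
  expect_match(quiet, "no change to your current cholesterol management")
  expect_match(quiet, "may not take into account your full medical history")
})
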